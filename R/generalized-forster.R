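#' Exciton Hamiltonian of a subunit pigment cluster
#'
#' Builds the one-exciton Hamiltonian of the chlorophylls hosted by one (or
#' several, for a merged core cluster) subunits: site energies on the
#' diagonal, intra-cluster dipole couplings off-diagonal (cm^-1). No
#' distance cutoff is applied within a cluster.
#'
#' @param model a classified [eet_structure()].
#' @param subunit_id one or more subunit identifiers pooled into the
#'   cluster.
#' @param params an [eet_params()] list.
#' @param id label for the cluster (defaults to the subunit id(s) joined
#'   with `+`).
#' @return an object of class `eet_cluster` with `id`, `pigment_ids`,
#'   `dipoles` (the [pigment_dipoles()] rows), and `H`.
#' @export
cluster_hamiltonian <- function(model, subunit_id, params = eet_params(),
                                id = NULL) {
  dip <- pigment_dipoles(model, params)
  dip <- dip[dip$host_subunit %in% subunit_id, , drop = FALSE]
  if (!nrow(dip)) {
    abort(paste0("subunit(s) ", paste(subunit_id, collapse = "+"),
                 " contain no chlorophylls"))
  }
  n <- nrow(dip)
  H <- diag(dip$e_cm1, n, n)
  if (n > 1) {
    xyz <- as.matrix(dip[, c("x", "y", "z")])
    u <- as.matrix(dip[, c("ux", "uy", "uz")])
    V <- .coupling_block(xyz, u, dip$mu_D, xyz, u, dip$mu_D, params,
                         same = TRUE)
    H <- H + V
  }
  structure(list(id = id %||% paste(subunit_id, collapse = "+"),
                 subunit_id = subunit_id,
                 pigment_ids = dip$pigment_id,
                 dipoles = dip, H = H),
            class = "eet_cluster")
}

# vectorized coupling block between two pigment sets (same = TRUE zeroes
# the diagonal and symmetrizes trivially); distances below the contact
# floor abort, pairs beyond cutoff_A (if finite) get zero coupling
.coupling_block <- function(xyz1, u1, mu1, xyz2, u2, mu2, params,
                            same = FALSE, cutoff_A = Inf) {
  n1 <- nrow(xyz1); n2 <- nrow(xyz2)
  rx <- outer(xyz2[, 1], xyz1[, 1], "-")
  ry <- outer(xyz2[, 2], xyz1[, 2], "-")
  rz <- outer(xyz2[, 3], xyz1[, 3], "-")
  R <- sqrt(rx^2 + ry^2 + rz^2) # n2 x n1
  off <- if (same) !diag(TRUE, n1) else matrix(TRUE, n2, n1)
  if (any(R[off] < params$contact_floor_A)) {
    abort("pigment pair closer than the contact floor; dipole model invalid")
  }
  R[R == 0] <- Inf
  pref <- params$screening * .eet_const$dipole_prefactor_cm1
  if (params$coupling_scheme == "point") {
    rhx <- rx / R; rhy <- ry / R; rhz <- rz / R
    dd <- outer(u2[, 1], u1[, 1]) + outer(u2[, 2], u1[, 2]) +
      outer(u2[, 3], u1[, 3])
    p1 <- rhx * matrix(u1[, 1], n2, n1, byrow = TRUE) +
      rhy * matrix(u1[, 2], n2, n1, byrow = TRUE) +
      rhz * matrix(u1[, 3], n2, n1, byrow = TRUE)
    p2 <- rhx * u2[, 1] + rhy * u2[, 2] + rhz * u2[, 3]
    kappa <- dd - 3 * p1 * p2
    V <- pref * kappa * outer(mu2, mu1) / R^3
  } else {
    l <- params$extended_l_A
    acc <- 0
    for (s1 in c(1, -1)) {
      for (s2 in c(1, -1)) {
        dx <- rx + (s2 * l / 2) * u2[, 1] -
          (s1 * l / 2) * matrix(u1[, 1], n2, n1, byrow = TRUE)
        dy <- ry + (s2 * l / 2) * u2[, 2] -
          (s1 * l / 2) * matrix(u1[, 2], n2, n1, byrow = TRUE)
        dz <- rz + (s2 * l / 2) * u2[, 3] -
          (s1 * l / 2) * matrix(u1[, 3], n2, n1, byrow = TRUE)
        acc <- acc + s1 * s2 / sqrt(dx^2 + dy^2 + dz^2)
      }
    }
    V <- pref * outer(mu2 / l, mu1 / l) * acc
  }
  if (is.finite(cutoff_A)) V[R > cutoff_A] <- 0
  if (same) V[!off] <- 0
  t(V) # n1 x n2, row = set 1
}

#' Diagonalize a cluster and attach Boltzmann weights
#'
#' Eigen-decomposition of the cluster Hamiltonian (states in ascending
#' energy) plus thermal occupation weights
#' `P_a = exp(-e_a / kT) / sum(...)`; energies are shifted by their minimum
#' before exponentiation for numerical safety. The donor cluster is assumed
#' to equilibrate among its exciton states before transferring.
#'
#' @param cluster an `eet_cluster` from [cluster_hamiltonian()].
#' @param temperature_K temperature for the Boltzmann weights.
#' @return the cluster with `energies`, `vectors` (columns = states,
#'   ascending energy), `weights`, and `temperature_K` added.
#' @export
diagonalize <- function(cluster, temperature_K = 295) {
  stopifnot(inherits(cluster, "eet_cluster"))
  H <- cluster$H
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H)))) {
    abort("cluster Hamiltonian is not symmetric")
  }
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(eig$values)
  cluster$energies <- eig$values[ord]
  cluster$vectors <- eig$vectors[, ord, drop = FALSE]
  kT <- .eet_const$kB_cm1_per_K * temperature_K
  w <- exp(-(cluster$energies - min(cluster$energies)) / kT)
  cluster$weights <- w / sum(w)
  cluster$temperature_K <- temperature_K
  cluster
}

#' @export
print.eet_cluster <- function(x, ...) {
  cat("<eet_cluster> ", x$id, ": ", length(x$pigment_ids), " pigments",
      if (!is.null(x$energies)) paste0(", diagonalized (",
                                       round(min(x$energies)), "-",
                                       round(max(x$energies)), " cm^-1)"),
      "\n", sep = "")
  invisible(x)
}

#' Generalized Förster rate between two pigment clusters
#'
#' Transfer from a thermally equilibrated donor cluster to an acceptor
#' cluster:
#' `k = sum_a P_a sum_b 1.18 |V_ab|^2 J_ab` with exciton-state couplings
#' `V_ab = sum_ij c^D_ai c^A_bj V_ij` and `J_ab` the Gaussian overlap of
#' the donor-state emission (centered at `e_a - stokes`) with the
#' acceptor-state absorption (centered at `e_b`), both carrying the site
#' lineshape width.
#'
#' @param donor,acceptor diagonalized `eet_cluster` objects with disjoint
#'   pigment membership.
#' @param couplings pigment-level coupling matrix (cm^-1), rows = donor
#'   pigments, columns = acceptor pigments; computed from the model with
#'   [inter_cluster_couplings()] when omitted (then `model` is required).
#' @param params an [eet_params()] list (lineshape width, Stokes shift).
#' @param model optional [eet_structure()] used to build `couplings`.
#' @return rate in ps^-1, with the per-state-pair contribution matrix in
#'   `attr(, "state_contrib")`.
#' @export
gf_rate <- function(donor, acceptor, couplings = NULL,
                    params = eet_params(), model = NULL) {
  stopifnot(inherits(donor, "eet_cluster"), inherits(acceptor, "eet_cluster"))
  if (length(intersect(donor$pigment_ids, acceptor$pigment_ids))) {
    abort("donor and acceptor clusters share pigments")
  }
  if (is.null(donor$weights) || is.null(acceptor$energies)) {
    abort("clusters must be diagonalized first; see diagonalize()")
  }
  if (is.null(couplings)) {
    if (is.null(model)) abort("supply either couplings or a model")
    couplings <- inter_cluster_couplings(model, donor, acceptor, params)
  }
  stopifnot(nrow(couplings) == length(donor$pigment_ids),
            ncol(couplings) == length(acceptor$pigment_ids))
  sigma <- params$fwhm_cm1 / .eet_const$fwhm_to_sigma
  Vab <- t(donor$vectors) %*% couplings %*% acceptor$vectors
  Jab <- outer(donor$energies - params$stokes_cm1, acceptor$energies,
               function(ed, ea) .gauss_overlap(ed, sigma, ea, sigma))
  contrib <- donor$weights * .eet_const$rate_prefactor_ps * Vab^2 * Jab
  k <- sum(contrib)
  attr(k, "state_contrib") <- contrib
  k
}

#' @rdname gf_rate
#' @export
inter_cluster_couplings <- function(model, donor, acceptor,
                                    params = eet_params()) {
  d <- donor$dipoles; a <- acceptor$dipoles
  .coupling_block(as.matrix(d[, c("x", "y", "z")]),
                  as.matrix(d[, c("ux", "uy", "uz")]), d$mu_D,
                  as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(a[, c("ux", "uy", "uz")]), a$mu_D,
                  params, same = FALSE,
                  cutoff_A = params$distance_cutoff_A)
}

#' Subunit-to-subunit generalized Förster rate table
#'
#' Forms one exciton cluster per antenna/linker subunit (the entire core
#' chlorophyll set is pooled into a single acceptor cluster named `"core"`
#' unless `core_as_one = FALSE`), diagonalizes them, and computes directed
#' generalized Förster rates for every cluster pair. The full table is
#' returned; [report_cluster_table()] applies the map-rendering cutoff
#' (default: drop pairs slower than 25 ps).
#'
#' @param model a classified, layer-annotated [eet_structure()].
#' @param params an [eet_params()] list.
#' @param core_as_one pool all core subunits into one cluster?
#' @return a tibble of class `eet_cluster_table`: `donor`, `acceptor`,
#'   `donor_layer`, `acceptor_layer`, `rate_per_ps`, `tau_ps`,
#'   `top_state_pair`; the diagonalized clusters are attached as
#'   `attr(, "clusters")`.
#' @export
cluster_network <- function(model, params = eet_params(),
                            core_as_one = TRUE) {
  s <- model$subunits
  if (any(is.na(s$layer))) {
    abort("model must be layer-annotated; see annotate_layers()")
  }
  has_chl <- model$pigments |>
    filter(.data$is_eet_node) |>
    pull(.data$host_subunit) |>
    unique()
  core_ids <- s$subunit_id[s$family == "core" & s$subunit_id %in% has_chl]
  other_ids <- s$subunit_id[s$family != "core" & s$subunit_id %in% has_chl]

  clusters <- list()
  if (length(core_ids)) {
    if (core_as_one) {
      clusters[["core"]] <- cluster_hamiltonian(model, core_ids, params,
                                                id = "core")
    } else {
      for (cid in core_ids) {
        nm <- s$name[s$subunit_id == cid]
        clusters[[nm]] <- cluster_hamiltonian(model, cid, params, id = nm)
      }
    }
  }
  for (cid in other_ids) {
    nm <- s$name[s$subunit_id == cid]
    clusters[[nm]] <- cluster_hamiltonian(model, cid, params, id = nm)
  }
  clusters <- map(clusters, diagonalize,
                  temperature_K = params$temperature_K)

  layer_of <- function(cl) {
    if (identical(cl$id, "core")) 0L else
      unique(s$layer[s$subunit_id %in% cl$subunit_id])[1]
  }
  ids <- names(clusters)
  rows <- list()
  for (di in seq_along(ids)) {
    for (ai in seq_along(ids)) {
      if (di == ai) next
      dcl <- clusters[[di]]; acl <- clusters[[ai]]
      Vda <- inter_cluster_couplings(model, dcl, acl, params)
      if (!any(Vda != 0)) {
        k <- 0; top <- NA_character_
      } else {
        k <- gf_rate(dcl, acl, couplings = Vda, params = params)
        contrib <- attr(k, "state_contrib")
        best <- arrayInd(which.max(contrib), dim(contrib))
        top <- paste0("D", best[1], "->A", best[2])
        k <- as.numeric(k)
      }
      rows[[length(rows) + 1]] <- tibble(
        donor = dcl$id, acceptor = acl$id,
        donor_layer = layer_of(dcl), acceptor_layer = layer_of(acl),
        rate_per_ps = k,
        tau_ps = if (k > 0) 1 / k else Inf,
        top_state_pair = top
      )
    }
  }
  tab <- bind_rows(rows)
  attr(tab, "clusters") <- clusters
  attr(tab, "params") <- params
  class(tab) <- c("eet_cluster_table", class(tab))
  tab
}

#' @rdname cluster_network
#' @param tab an `eet_cluster_table`.
#' @param cutoff_ps map-rendering cutoff: pairs slower than this are
#'   omitted from the reported table (the full table is unaffected).
#' @export
report_cluster_table <- function(tab, cutoff_ps = 25) {
  tab[tab$tau_ps <= cutoff_ps, , drop = FALSE]
}

#' Write a cluster rate table
#'
#' @param tab an `eet_cluster_table`.
#' @param csv,json output paths (either may be `NULL`); the JSON carries a
#'   node/edge graph for visualization.
#' @return `tab`, invisibly.
#' @export
write_cluster_table <- function(tab, csv = NULL, json = NULL) {
  if (!is.null(csv)) write.csv(as.data.frame(tab), csv, row.names = FALSE)
  if (!is.null(json)) {
    nodes <- unique(c(tab$donor, tab$acceptor))
    jsonlite::write_json(
      list(nodes = nodes,
           edges = as.data.frame(tab[, c("donor", "acceptor",
                                         "rate_per_ps", "tau_ps")])),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tab)
}
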