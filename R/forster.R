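#' Excitonic coupling between two transition dipoles
#'
#' Point-dipole coupling `V = s * 5034 * kappa * mu1 * mu2 / R^3` (cm^-1;
#' mu in Debye, R in Angstrom, `s` a multiplicative screening factor) with
#' the orientation factor
#' `kappa = u1.u2 - 3 (u1.Rhat)(u2.Rhat)`. The `"extended"` scheme replaces
#' each point dipole by two charges +/- q = mu/l separated by `extended_l_A`
#' along the Qy axis, which is better behaved for close pairs; it reduces to
#' the point-dipole value as the separation shrinks.
#'
#' @param d1,d2 `transition_dipole` objects ([qy_dipole()]).
#' @param screening multiplicative screening factor (1 = vacuum).
#' @param scheme `"point"` or `"extended"`.
#' @param extended_l_A charge separation (A) for the extended scheme.
#' @param contact_floor_A center-center distances below this are refused
#'   (the dipole approximation is meaningless at contact).
#' @return coupling in cm^-1 (signed).
#' @export
dipole_coupling <- function(d1, d2, screening = 1,
                            scheme = c("point", "extended"),
                            extended_l_A = 8.7, contact_floor_A = 2) {
  scheme <- match.arg(scheme)
  rvec <- d2$origin - d1$origin
  R <- sqrt(sum(rvec^2))
  if (R < contact_floor_A) {
    abort(paste0("center-center distance ", signif(R, 4),
                 " A is below the contact floor (", contact_floor_A,
                 " A); the dipole approximation is invalid"))
  }
  if (scheme == "point") {
    rhat <- rvec / R
    kappa <- sum(d1$direction * d2$direction) -
      3 * sum(d1$direction * rhat) * sum(d2$direction * rhat)
    screening * .eet_const$dipole_prefactor_cm1 *
      kappa * d1$magnitude_D * d2$magnitude_D / R^3
  } else {
    q1 <- d1$magnitude_D / extended_l_A
    q2 <- d2$magnitude_D / extended_l_A
    acc <- 0
    for (s1 in c(1, -1)) {
      for (s2 in c(1, -1)) {
        p1 <- d1$origin + s1 * (extended_l_A / 2) * d1$direction
        p2 <- d2$origin + s2 * (extended_l_A / 2) * d2$direction
        acc <- acc + s1 * s2 / sqrt(sum((p1 - p2)^2))
      }
    }
    screening * .eet_const$dipole_prefactor_cm1 * q1 * q2 * acc
  }
}

#' Förster transfer rate from coupling and spectral overlap
#'
#' Golden-rule rate `k = 1.18 * V^2 * J` with V in cm^-1 and J in cm,
#' giving k in ps^-1. The prefactor is `4 pi^2 c` (c in cm/ps), i.e. the
#' `2 pi / hbar` golden-rule constant expressed in the spectroscopic unit
#' system.
#'
#' @param V_cm1 electronic coupling (cm^-1, sign irrelevant).
#' @param J_cm spectral overlap integral (cm, >= 0).
#' @return rate in ps^-1.
#' @export
forster_rate <- function(V_cm1, J_cm) {
  if (any(J_cm < 0)) abort("spectral overlap J must be >= 0")
  .eet_const$rate_prefactor_ps * V_cm1^2 * J_cm
}

#' Pairwise pigment-to-pigment Förster rate network
#'
#' Enumerates all ordered chlorophyll pairs within the Mg-Mg distance
#' cutoff, computes the excitonic coupling (shared by both directions) and
#' the direction-specific spectral overlap (donor emission, red-shifted by
#' the Stokes shift, against acceptor absorption), and returns the directed
#' rate network. Both directions of every retained pair are present.
#'
#' @param model a classified [eet_structure()].
#' @param params an [eet_params()] list.
#' @return a tibble of class `eet_rate_network`: `donor`, `acceptor`,
#'   `donor_subunit`, `acceptor_subunit`, `r_A`, `kappa`, `V_cm1`, `J_cm`,
#'   `rate_per_ps`, `tau_ps`, with the parameter set in
#'   `attr(, "params")`.
#' @export
pairwise_rates <- function(model, params = eet_params()) {
  dip <- pigment_dipoles(model, params)
  n <- nrow(dip)
  if (n < 2) abort("need at least two EET nodes for a rate network")
  xyz <- as.matrix(dip[, c("x", "y", "z")])
  u <- as.matrix(dip[, c("ux", "uy", "uz")])
  dmat <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(dmat) & dmat <= params$distance_cutoff_A,
               arr.ind = TRUE)
  if (!nrow(idx)) abort("no pigment pairs within the distance cutoff")
  i <- idx[, 1]; j <- idx[, 2]
  R <- dmat[idx]
  if (any(R < params$contact_floor_A)) {
    abort("pigment pair closer than the contact floor; dipole model invalid")
  }
  rv <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  rhat <- rv / R
  ui <- u[i, , drop = FALSE]; uj <- u[j, , drop = FALSE]
  kappa <- rowSums(ui * uj) - 3 * rowSums(ui * rhat) * rowSums(uj * rhat)
  pref <- params$screening * .eet_const$dipole_prefactor_cm1
  if (params$coupling_scheme == "point") {
    V <- pref * kappa * dip$mu_D[i] * dip$mu_D[j] / R^3
  } else {
    l <- params$extended_l_A
    V <- 0
    for (s1 in c(1, -1)) {
      for (s2 in c(1, -1)) {
        dvec <- rv + (s2 * l / 2) * uj - (s1 * l / 2) * ui
        V <- V + s1 * s2 / sqrt(rowSums(dvec^2))
      }
    }
    V <- pref * (dip$mu_D[i] / l) * (dip$mu_D[j] / l) * V
  }

  # direction-specific overlaps, cached over the distinct donor/acceptor
  # site-energy combinations (typically only a few species pairs)
  jfun <- .overlap_cache(params)
  J_fwd <- jfun(dip$e_cm1[i], dip$e_cm1[j])
  J_bwd <- jfun(dip$e_cm1[j], dip$e_cm1[i])

  net <- tibble(
    donor = c(dip$pigment_id[i], dip$pigment_id[j]),
    acceptor = c(dip$pigment_id[j], dip$pigment_id[i]),
    donor_subunit = c(dip$host_subunit[i], dip$host_subunit[j]),
    acceptor_subunit = c(dip$host_subunit[j], dip$host_subunit[i]),
    r_A = c(R, R),
    kappa = c(kappa, kappa),
    V_cm1 = c(V, V),
    J_cm = c(J_fwd, J_bwd),
    rate_per_ps = forster_rate(c(V, V), c(J_fwd, J_bwd))
  )
  net$tau_ps <- ifelse(net$rate_per_ps > 0, 1 / net$rate_per_ps, Inf)
  attr(net, "params") <- params
  class(net) <- c("eet_rate_network", class(net))
  net
}

# memoized donor-energy/acceptor-energy -> J (cm), quadrature-based so the
# network agrees with per-pair spectral_overlap() calls to rounding error
.overlap_cache <- function(params) {
  cache <- new.env(parent = emptyenv())
  function(e_d, e_a) {
    key <- paste(e_d, e_a, sep = "|")
    out <- numeric(length(key))
    for (k in unique(key)) {
      if (is.null(cache[[k]])) {
        sel <- match(k, key)
        d <- make_lineshapes(e_d[sel], params$fwhm_cm1, params$stokes_cm1)
        a <- make_lineshapes(e_a[sel], params$fwhm_cm1, params$stokes_cm1)
        cache[[k]] <- spectral_overlap(d$emission, a$absorption,
                                       grid_n = params$overlap_grid_n)
      }
      out[key == k] <- cache[[k]]
    }
    out
  }
}

#' Classify rates into map-rendering time-constant classes
#'
#' Labels each directed pair by its time-constant class using half-open
#' intervals `(a, b]` in time-constant space (default boundaries 1, 10,
#' 20 ps, i.e. classes `<1 ps`, `1-10 ps`, `10-20 ps`). Pairs slower than
#' the last boundary are dropped from the returned map — the full network
#' is untouched and remains available for kinetics.
#'
#' @param net an `eet_rate_network` (or any tibble with a `tau_ps` column).
#' @param thresholds_ps strictly increasing class boundaries (ps).
#' @return the retained rows with an added ordered factor `class`.
#' @export
classify_rates <- function(net, thresholds_ps = c(1, 10, 20)) {
  if (!length(thresholds_ps)) abort("thresholds must be non-empty")
  if (is.unsorted(thresholds_ps, strictly = TRUE)) {
    abort("thresholds must be strictly increasing")
  }
  labs <- c(paste0("<", thresholds_ps[1], " ps"),
            if (length(thresholds_ps) > 1) {
              paste0(head(thresholds_ps, -1), "-", tail(thresholds_ps, -1),
                     " ps")
            })
  keep <- net[net$tau_ps <= tail(thresholds_ps, 1), , drop = FALSE]
  keep$class <- cut(keep$tau_ps, breaks = c(0, thresholds_ps),
                    labels = labs, include.lowest = TRUE, right = TRUE,
                    ordered_result = TRUE)
  keep
}

#' Write a rate network as an edge list
#'
#' CSV edge list plus a JSON metadata block recording the coupling scheme,
#' screening and lineshape parameters used.
#'
#' @param net an `eet_rate_network`.
#' @param csv,json output paths (either may be `NULL`).
#' @return `net`, invisibly.
#' @export
write_rate_network <- function(net, csv = NULL, json = NULL) {
  if (!is.null(csv)) write.csv(as.data.frame(net), csv, row.names = FALSE)
  p <- attr(net, "params")
  if (!is.null(json) && !is.null(p)) {
    jsonlite::write_json(
      list(coupling_scheme = p$coupling_scheme, screening = p$screening,
           fwhm_cm1 = p$fwhm_cm1, stokes_cm1 = p$stokes_cm1,
           site_energy_nm = as.list(p$site_energy_nm),
           dipole_D = as.list(p$dipole_D),
           distance_cutoff_A = p$distance_cutoff_A),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(net)
}
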