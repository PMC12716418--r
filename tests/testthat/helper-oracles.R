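# Independent oracles used across test files. These deliberately avoid the
# package's vectorized code paths: plain scalar loops and closed forms.

# closed-form overlap of two unit-area Gaussians (sigma from fwhm)
oracle_gauss_overlap <- function(mu_d, mu_a, fwhm, stokes = 0) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  s2 <- 2 * sigma^2
  exp(-((mu_d - stokes) - mu_a)^2 / (2 * s2)) / sqrt(2 * pi * s2)
}

# scalar point-dipole coupling from raw geometry
oracle_point_coupling <- function(r1, u1, mu1, r2, u2, mu2, screening = 1) {
  rv <- r2 - r1
  R <- sqrt(sum(rv^2))
  rh <- rv / R
  kappa <- sum(u1 * u2) - 3 * sum(u1 * rh) * sum(u2 * rh)
  screening * 5034 * kappa * mu1 * mu2 / R^3
}

# brute-force directed Forster network: double loop over pigment records
# using only the single-record operations
oracle_pairwise_rates <- function(model, params) {
  p <- pigments(model)
  p <- p[p$is_eet_node, ]
  n <- nrow(p)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      di <- qy_dipole(p[i, ], params)
      dj <- qy_dipole(p[j, ], params)
      R <- sqrt(sum((di$origin - dj$origin)^2))
      if (R > params$distance_cutoff_A) next
      V <- dipole_coupling(di, dj, screening = params$screening,
                           scheme = params$coupling_scheme,
                           extended_l_A = params$extended_l_A,
                           contact_floor_A = params$contact_floor_A)
      ed <- site_energy(p[i, ], params)
      ea <- site_energy(p[j, ], params)
      em <- make_lineshapes(ed, params$fwhm_cm1, params$stokes_cm1)$emission
      ab <- make_lineshapes(ea, params$fwhm_cm1, params$stokes_cm1)$absorption
      J <- spectral_overlap(em, ab, grid_n = params$overlap_grid_n)
      rows[[length(rows) + 1]] <- data.frame(
        donor = p$pigment_id[i], acceptor = p$pigment_id[j],
        rate_per_ps = forster_rate(V, J))
    }
  }
  do.call(rbind, rows)
}

# exhaustive simple-path enumeration; returns the minimal path-sum (Inf if
# the sink is unreachable) and all optimal paths
oracle_best_route <- function(edges, source, sink, cutoff = 25) {
  edges <- edges[is.finite(edges$tau_ps) & edges$tau_ps <= cutoff, ]
  best <- list(tau = Inf, paths = list())
  recurse <- function(node, visited, acc, path) {
    if (node == sink) {
      if (acc < best$tau - 1e-12) {
        best$tau <<- acc
        best$paths <<- list(path)
      } else if (abs(acc - best$tau) <= 1e-12) {
        best$paths[[length(best$paths) + 1]] <<- path
      }
      return(invisible())
    }
    out <- edges[edges$donor == node & !(edges$acceptor %in% visited), ]
    for (r in seq_len(nrow(out))) {
      recurse(out$acceptor[r], c(visited, out$acceptor[r]),
              acc + out$tau_ps[r], c(path, out$acceptor[r]))
    }
  }
  recurse(source, source, 0, source)
  best
}

# Gillespie first-passage simulation to the trap state
oracle_mc_mfpt <- function(model, source, n_walkers = 1e5, seed = 42) {
  set.seed(seed)
  K <- model$K
  states <- model$states
  times <- numeric(n_walkers)
  cur <- rep(match(source, states), n_walkers)
  trap <- match("trap", states)
  alive <- rep(TRUE, n_walkers)
  t_acc <- numeric(n_walkers)
  out_rates <- -diag(K)
  for (step in 1:10000) {
    idx <- which(alive)
    if (!length(idx)) break
    s <- cur[idx]
    lam <- out_rates[s]
    t_acc[idx] <- t_acc[idx] + stats::rexp(length(idx), lam)
    nxt <- vapply(s, function(si) {
      w <- K[, si]
      w[si] <- 0
      sample.int(length(states), 1, prob = w)
    }, integer(1))
    cur[idx] <- nxt
    alive[idx] <- nxt != trap
  }
  stopifnot(!any(alive))
  list(mean = mean(t_acc), se = stats::sd(t_acc) / sqrt(n_walkers))
}

# minimal hand-built chlorophyll record for single-pigment operations
fake_chl <- function(id = "X_CLA_1", species = "chl_a",
                     mg = c(1, 0, 0), nb = c(0, 0, 0), nd = c(2, 0, 0)) {
  tibble::tibble(pigment_id = id, host_subunit = "X", resid = "CLA",
                 resno = 1, key_atoms = list(list(MG = mg, NB = nb, ND = nd)),
                 species = species, is_eet_node = TRUE)
}

# small two-subunit, two-pigments-each model for generalized Forster tests
fake_two_cluster_model <- function(sep = 18, intra = 9, tilt = 0.3) {
  rot <- function(v, a) c(v[1], cos(a) * v[2] - sin(a) * v[3],
                          sin(a) * v[2] + cos(a) * v[3])
  mk <- function(chain, x0, species) {
    tibble::tibble(
      pigment_id = paste0(chain, "_", c("CLA", "KC2"), "_", 101:102),
      host_subunit = chain,
      resid = c("CLA", "KC2"), resno = 101:102,
      key_atoms = list(
        list(MG = c(x0, 0, 0), NB = c(x0, -2, 0), ND = c(x0, 2, 0)),
        list(MG = c(x0, intra, 0),
             NB = c(x0, intra, 0) - 2 * rot(c(0, 1, 0), tilt),
             ND = c(x0, intra, 0) + 2 * rot(c(0, 1, 0), tilt))
      ),
      species = species, is_eet_node = TRUE)
  }
  eet_structure(
    tibble::tibble(subunit_id = c("A", "B"), name = c("SU-A", "SU-B"),
                   family = "Lhcq", layer = c(1L, 2L)),
    dplyr::bind_rows(mk("A", 0, c("chl_a", "chl_c")),
                     mk("B", sep, c("chl_a", "chl_a")))
  )
}
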