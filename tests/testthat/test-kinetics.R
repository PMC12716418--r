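# random small rate tables for property tests
random_rate_table <- function(n_states, seed, p_edge = 0.6, trapname = "core") {
  set.seed(seed)
  states <- c(paste0("s", seq_len(n_states - 1)), trapname)
  rows <- expand.grid(donor = states, acceptor = states,
                      stringsAsFactors = FALSE)
  rows <- rows[rows$donor != rows$acceptor, ]
  rows <- rows[runif(nrow(rows)) < p_edge, ]
  rows$rate_per_ps <- runif(nrow(rows), 0.01, 0.5)
  rows$tau_ps <- 1 / rows$rate_per_ps
  tibble::as_tibble(rows)
}

test_that("the rate matrix is assembled column-conservatively with an explicit trap", {
  tab <- tibble::tibble(donor = "a", acceptor = "core",
                        rate_per_ps = 0.3, tau_ps = 1 / 0.3)
  km <- build_kinetic_model(tab, trap_state = "core", trap_rate_per_ps = 0.7)
  K <- km$K
  expect_equal(km$states, c("a", "core", "trap"))
  expect_equal(K["core", "a"], 0.3)
  expect_equal(K["trap", "core"], 0.7)
  expect_equal(unname(colSums(K)), c(0, 0, 0), tolerance = 1e-14)
  expect_equal(K["a", "a"], -0.3)

  # all rates zero: frozen system
  frozen <- build_kinetic_model(
    tibble::tibble(donor = "a", acceptor = "core", rate_per_ps = 0),
    trap_state = "core", trap_rate_per_ps = 0)
  expect_true(all(frozen$K == 0))
  sol <- solve_kinetics(frozen, "a")
  occ <- sol$occupancy(c(0, 10, 1000))
  expect_equal(occ$occupancy[occ$state == "a"], c(1, 1, 1),
               tolerance = 1e-10)

  expect_error(build_kinetic_model(tab, trap_state = "missing"),
               "not present")
})

test_that("eigen-solutions reproduce closed forms for chains", {
  # irreversible 2-step chain: bi-exponential with lifetimes 1/k1, 1/k2
  k1 <- 0.4; k2 <- 0.05
  tab <- tibble::tibble(donor = "a", acceptor = "core", rate_per_ps = k1)
  km <- build_kinetic_model(tab, trap_state = "core", trap_rate_per_ps = k2)
  sol <- solve_kinetics(km, "a")
  expect_equal(sol$lifetimes_ps, sort(c(1 / k1, 1 / k2)), tolerance = 1e-10)
  t <- c(0.5, 2, 10, 40)
  occ <- sol$occupancy(t)
  expect_equal(occ$occupancy[occ$state == "a"], exp(-k1 * t),
               tolerance = 1e-10)
  # closed-form intermediate occupancy
  expect_equal(occ$occupancy[occ$state == "core"],
               k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t)),
               tolerance = 1e-10)
})

test_that("random 6-state models match numerical propagation and conserve probability", {
  skip_if_not_installed("deSolve")
  for (seed in c(1, 7, 23)) {
    tab <- random_rate_table(6, seed)
    km <- build_kinetic_model(tab, trap_state = "core",
                              trap_rate_per_ps = 1)
    sol <- solve_kinetics(km, km$states[1])
    times <- c(0, 0.5, 2, 5, 20, 80)
    occ <- sol$occupancy(times)

    p0 <- setNames(numeric(length(km$states)), km$states)
    p0[1] <- 1
    ode <- deSolve::lsoda(p0, times, function(t, y, parms) {
      list(as.vector(km$K %*% y))
    }, rtol = 1e-10, atol = 1e-12)
    for (ti in seq_along(times)) {
      got <- occ$occupancy[occ$time_ps == times[ti]]
      expect_equal(got, unname(ode[ti, -1]), tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
    # occupancy conservation including the absorbed fraction
    tot <- tapply(occ$occupancy, occ$time_ps, sum)
    expect_equal(as.numeric(tot), rep(1, length(times)), tolerance = 1e-8)
  }
})

test_that("MFPT is additive on chains, matches Monte Carlo, and flags unreachable traps", {
  # chain additivity: a -> b -> core -> trap
  tab <- tibble::tibble(donor = c("a", "b"), acceptor = c("b", "core"),
                        rate_per_ps = c(0.5, 0.2))
  km <- build_kinetic_model(tab, trap_state = "core", trap_rate_per_ps = 1)
  mf <- mfpt_to_trap(km)
  expect_equal(unname(mf["a"]), 1 / 0.5 + 1 / 0.2 + 1, tolerance = 1e-12)
  expect_equal(unname(mf["b"]), 1 / 0.2 + 1, tolerance = 1e-12)
  expect_equal(unname(mf["core"]), 1, tolerance = 1e-12)

  # reversible 4-state toy vs 1e5-walker Gillespie simulation
  tab4 <- tibble::tibble(
    donor = c("a", "b", "b", "c", "c", "a"),
    acceptor = c("b", "a", "c", "b", "core", "c"),
    rate_per_ps = c(0.30, 0.10, 0.25, 0.15, 0.40, 0.05))
  km4 <- build_kinetic_model(tab4, trap_state = "core",
                             trap_rate_per_ps = 0.5)
  mfa <- unname(mfpt_to_trap(km4, "a"))
  mc <- oracle_mc_mfpt(km4, "a", n_walkers = 1e5, seed = 99)
  expect_lt(abs(mfa - mc$mean), 3 * mc$se)

  # unreachable trap reported as infinite
  tab_iso <- tibble::tibble(donor = c("a", "z"), acceptor = c("core", "zz"),
                            rate_per_ps = c(0.2, 0.3))
  km_iso <- build_kinetic_model(tab_iso, trap_state = "core")
  expect_equal(unname(mfpt_to_trap(km_iso, "z")), Inf)
  expect_true(is.finite(mfpt_to_trap(km_iso, "a")))
})

test_that("best_route minimizes the path-sum with the 25 ps admissibility rule", {
  # single edge
  one <- tibble::tibble(donor = "a", acceptor = "core", tau_ps = 7,
                        rate_per_ps = 1 / 7)
  r <- best_route(one, "a", "core")
  expect_equal(r$route_tau_ps, 7)
  expect_equal(r$path, c("a", "core"))

  # two parallel 2-step routes (3+4 vs 2+6 ps): the 7 ps one wins; the
  # exhaustive enumeration sees both candidates
  par2 <- tibble::tibble(
    donor = c("s", "m1", "s", "m2"),
    acceptor = c("m1", "core", "m2", "core"),
    tau_ps = c(3, 4, 2, 6))
  par2$rate_per_ps <- 1 / par2$tau_ps
  r2 <- best_route(par2, "s", "core")
  oracle <- oracle_best_route(par2, "s", "core")
  expect_equal(r2$route_tau_ps, 7)
  expect_equal(oracle$tau, 7)
  expect_identical(r2$path, c("s", "m1", "core"))
  # exact ties are broken deterministically (lexicographic on names)
  tie <- tibble::tibble(
    donor = c("s", "mB", "s", "mA"),
    acceptor = c("mB", "core", "mA", "core"),
    tau_ps = c(3, 4, 3, 4), rate_per_ps = 1 / c(3, 4, 3, 4))
  o_tie <- oracle_best_route(tie, "s", "core")
  expect_equal(length(o_tie$paths), 2)
  expect_identical(best_route(tie, "s", "core")$path, c("s", "mA", "core"))
  expect_identical(best_route(tie, "s", "core")$path,
                   best_route(tie, "s", "core")$path)

  # a 30 ps edge is inadmissible
  slow <- tibble::tibble(donor = "a", acceptor = "core", tau_ps = 30,
                         rate_per_ps = 1 / 30)
  expect_equal(best_route(slow, "a", "core")$route_tau_ps, Inf)
  expect_equal(best_route(slow, "a", "core", cutoff_ps = 40)$route_tau_ps, 30)

  # random graphs: equality with exhaustive enumeration, and adding an
  # edge never worsens the optimum
  for (seed in c(2, 5, 11, 17)) {
    tab <- random_rate_table(6, seed, p_edge = 0.4)
    tab$tau_ps <- 1 / tab$rate_per_ps
    r <- best_route(tab, "s1", "core")
    o <- oracle_best_route(tab, "s1", "core")
    expect_equal(r$route_tau_ps, o$tau, tolerance = 1e-10)
    extra <- tibble::tibble(donor = "s1", acceptor = sample(tab$acceptor, 1),
                            rate_per_ps = 0.2, tau_ps = 5)
    r_aug <- best_route(dplyr::bind_rows(tab, extra), "s1", "core")
    expect_lte(r_aug$route_tau_ps, r$route_tau_ps + 1e-12)
  }
})

test_that("layer-averaged route constants equal hand enumeration; trees equal MFPT", {
  m <- make_layered_antenna(n_layers = 3, fibers = 2,
                            pigments_per_subunit = 4, core_pigments = 9,
                            seed = 7, orientation_noise_deg = 0)
  tab <- cluster_network(m)
  las <- layer_average_route_time(tab, layers = 3)
  # oracle: exhaustive route enumeration per source
  srcs <- sort(unique(tab$donor[tab$donor_layer == 3]))
  want <- mean(vapply(srcs, function(s) {
    oracle_best_route(as.data.frame(tab), s, "core")$tau
  }, numeric(1)))
  expect_equal(las$mean_route_tau_ps, want, tolerance = 1e-10)
  expect_equal(nrow(las$per_source), 2)
  expect_true(is.finite(las$mean_mfpt_ps))

  # per-source entries are exactly the individual route constants
  r1 <- best_route(tab, srcs[1], "core")
  expect_equal(las$per_source$route_tau_ps[
    las$per_source$source == srcs[1]], r1$route_tau_ps)

  # irreversible tree: MFPT coincides with the route constant
  chain <- tibble::tibble(donor = c("leaf", "mid"),
                          acceptor = c("mid", "core"),
                          rate_per_ps = c(0.25, 0.1))
  chain$tau_ps <- 1 / chain$rate_per_ps
  kmc <- build_kinetic_model(chain, trap_state = "core",
                             trap_rate_per_ps = 1e9)
  rt <- best_route(chain, "leaf", "core")
  expect_equal(unname(mfpt_to_trap(kmc, "leaf")), rt$route_tau_ps,
               tolerance = 1e-6)
})
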