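test_that("cluster Hamiltonians assemble site energies and pairwise couplings", {
  p <- eet_params()
  m <- fake_two_cluster_model()
  clA <- cluster_hamiltonian(m, "A", p)
  expect_equal(dim(clA$H), c(2, 2))
  expect_equal(diag(clA$H), c(1e7 / 663.5, 1e7 / 633.5), tolerance = 1e-12)
  # off-diagonal equals the scalar coupling oracle
  d1 <- qy_dipole(pigments(m)[1, ], p)
  d2 <- qy_dipole(pigments(m)[2, ], p)
  expect_equal(clA$H[1, 2], dipole_coupling(d1, d2), tolerance = 1e-12)
  expect_equal(clA$H, t(clA$H))

  # one-pigment cluster: 1x1 Hamiltonian = the site energy
  dm <- make_dimer(15, "parallel_perp_R")
  cl1 <- cluster_hamiltonian(dm, "A", p)
  expect_equal(cl1$H, matrix(1e7 / 663.5), tolerance = 1e-12)

  # element-wise brute-force assembly on a trimer
  tri <- make_layered_antenna(n_layers = 1, fibers = 1,
                              pigments_per_subunit = 3, core_pigments = 1,
                              seed = 3)
  chain <- subunits(tri)$subunit_id[subunits(tri)$layer == 1]
  clT <- cluster_hamiltonian(tri, chain, p)
  pg <- pigments(tri)[pigments(tri)$host_subunit == chain, ]
  for (i in 1:3) for (j in 1:3) {
    want <- if (i == j) site_energy(pg[i, ], p) else
      dipole_coupling(qy_dipole(pg[i, ], p), qy_dipole(pg[j, ], p))
    expect_equal(clT$H[i, j], want, tolerance = 1e-12)
  }

  expect_error(cluster_hamiltonian(dm, "nope", p), "no chlorophylls")
})

test_that("diagonalization gives textbook splitting, trace preservation, and Boltzmann limits", {
  p <- eet_params()
  # degenerate dimer: eigenenergies eps -/+ |V|
  m <- make_dimer(10, "parallel_perp_R", species = c("chl_a", "chl_a"))
  cl <- cluster_hamiltonian(m, c("A", "B"), p, id = "dimer")
  V <- cl$H[1, 2]
  eps <- cl$H[1, 1]
  cl <- diagonalize(cl, 295)
  expect_equal(cl$energies, c(eps - abs(V), eps + abs(V)), tolerance = 1e-9)
  expect_equal(sum(cl$energies), sum(diag(cl$H)), tolerance = 1e-9)
  expect_equal(sum(cl$weights), 1, tolerance = 1e-12)
  expect_equal(crossprod(cl$vectors), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # infinite temperature: uniform weights
  hot <- diagonalize(cl, 1e12)
  expect_equal(hot$weights, c(0.5, 0.5), tolerance = 1e-6)

  bad <- cl
  bad$H[1, 2] <- bad$H[1, 2] + 50
  expect_error(diagonalize(bad), "symmetric")
})

test_that("single-pigment clusters reduce generalized Förster to pairwise Förster", {
  p <- eet_params()
  for (R in c(9, 15, 24)) {
    m <- make_dimer(R, "parallel_perp_R", species = c("chl_c", "chl_a"))
    net <- pairwise_rates(m, p)
    clA <- diagonalize(cluster_hamiltonian(m, "A", p), p$temperature_K)
    clB <- diagonalize(cluster_hamiltonian(m, "B", p), p$temperature_K)
    k <- gf_rate(clA, clB, params = p, model = m)
    expect_equal(as.numeric(k),
                 net$rate_per_ps[net$donor == "A_KC2_101"],
                 tolerance = 1e-9)
  }
})

test_that("gf_rate equals an independently coded state-pair double sum", {
  p <- eet_params()
  m <- fake_two_cluster_model()
  clA <- diagonalize(cluster_hamiltonian(m, "A", p), p$temperature_K)
  clB <- diagonalize(cluster_hamiltonian(m, "B", p), p$temperature_K)
  Vda <- inter_cluster_couplings(m, clA, clB, p)
  k <- as.numeric(gf_rate(clA, clB, couplings = Vda, params = p))

  # oracle: explicit loops over donor/acceptor exciton states
  kT <- 0.69503476 * p$temperature_K
  w <- exp(-(clA$energies - min(clA$energies)) / kT)
  w <- w / sum(w)
  acc <- 0
  for (a in seq_along(clA$energies)) {
    for (b in seq_along(clB$energies)) {
      Vab <- 0
      for (i in 1:2) for (j in 1:2) {
        Vab <- Vab + clA$vectors[i, a] * clB$vectors[j, b] * Vda[i, j]
      }
      J <- oracle_gauss_overlap(clA$energies[a], clB$energies[b],
                                p$fwhm_cm1, stokes = p$stokes_cm1)
      acc <- acc + w[a] * 1.18 * Vab^2 * J
    }
  }
  expect_equal(k, acc, tolerance = 1e-12)
})

test_that("gf_rate is gauge invariant and vanishes for orthogonal couplings", {
  p <- eet_params()
  m <- fake_two_cluster_model()
  clA <- diagonalize(cluster_hamiltonian(m, "A", p), p$temperature_K)
  clB <- diagonalize(cluster_hamiltonian(m, "B", p), p$temperature_K)
  Vda <- inter_cluster_couplings(m, clA, clB, p)
  k0 <- as.numeric(gf_rate(clA, clB, couplings = Vda, params = p))
  for (flip in list(c(-1, 1), c(1, -1), c(-1, -1))) {
    clF <- clA
    clF$vectors <- sweep(clA$vectors, 2, flip, `*`)
    expect_equal(as.numeric(gf_rate(clF, clB, couplings = Vda, params = p)),
                 k0, tolerance = 1e-12)
  }

  # donor states orthogonal to the only coupled acceptor pattern -> rate 0
  expect_equal(as.numeric(gf_rate(clA, clB,
                                  couplings = matrix(0, 2, 2), params = p)),
               0)
  expect_error(gf_rate(clA, clA, couplings = Vda, params = p),
               "share pigments")
})

test_that("with zero intra-cluster coupling the rate is the Boltzmann-weighted pairwise sum", {
  p <- eet_params()
  m <- fake_two_cluster_model()
  clA <- cluster_hamiltonian(m, "A", p)
  clB <- cluster_hamiltonian(m, "B", p)
  clA$H[1, 2] <- clA$H[2, 1] <- 0
  clB$H[1, 2] <- clB$H[2, 1] <- 0
  clA <- diagonalize(clA, p$temperature_K)
  clB <- diagonalize(clB, p$temperature_K)
  Vda <- inter_cluster_couplings(m, clA, clB, p)
  k <- as.numeric(gf_rate(clA, clB, couplings = Vda, params = p))

  # site basis: Boltzmann over donor sites, plain Förster to each acceptor
  eD <- diag(cluster_hamiltonian(m, "A", p)$H)
  eAcc <- diag(cluster_hamiltonian(m, "B", p)$H)
  kT <- 0.69503476 * p$temperature_K
  w <- exp(-(eD - min(eD)) / kT)
  w <- w / sum(w)
  VdaSite <- inter_cluster_couplings(
    m, cluster_hamiltonian(m, "A", p), cluster_hamiltonian(m, "B", p), p)
  want <- 0
  for (i in 1:2) for (j in 1:2) {
    want <- want + w[i] * 1.18 * VdaSite[i, j]^2 *
      oracle_gauss_overlap(eD[i], eAcc[j], p$fwhm_cm1, p$stokes_cm1)
  }
  expect_equal(k, want, tolerance = 1e-9)
})

test_that("raising the temperature moves the rate monotonically to the state average", {
  p <- eet_params()
  m <- fake_two_cluster_model()
  clA0 <- cluster_hamiltonian(m, "A", p)
  clB0 <- cluster_hamiltonian(m, "B", p)
  Vda <- inter_cluster_couplings(m, clA0, clB0, p)
  k_at <- function(T) {
    as.numeric(gf_rate(diagonalize(clA0, T), diagonalize(clB0, T),
                       couplings = Vda, params = p))
  }
  k_inf <- k_at(1e12)
  ks <- vapply(c(150, 295, 1000, 1e4, 1e6), k_at, numeric(1))
  gaps <- abs(ks - k_inf)
  expect_true(all(diff(gaps) <= 1e-15))
})

test_that("cluster_network matches per-pair gf_rate and honors the reporting cutoff", {
  p <- eet_params()
  m <- make_layered_antenna(n_layers = 1, fibers = 2,
                            pigments_per_subunit = 4, core_pigments = 6,
                            seed = 13)
  tab <- cluster_network(m, p)
  expect_equal(nrow(tab), 6) # 3 clusters, all ordered pairs
  clusters <- attr(tab, "clusters")
  for (r in seq_len(nrow(tab))) {
    kk <- gf_rate(clusters[[tab$donor[r]]], clusters[[tab$acceptor[r]]],
                  params = p, model = m)
    expect_equal(tab$rate_per_ps[r], as.numeric(kk), tolerance = 1e-12)
  }

  # reporting rule: tau > 25 ps rows are dropped from the report only
  fake <- tibble::tibble(donor = c("x", "y"), acceptor = c("y", "x"),
                         rate_per_ps = c(1 / 30, 1 / 7),
                         tau_ps = c(30, 7))
  rep <- report_cluster_table(fake, cutoff_ps = 25)
  expect_equal(rep$donor, "y")
  expect_equal(nrow(fake), 2)

  # renaming subunits permutes but does not change the rates
  m2 <- rename_subunits(m, setNames(c("ANT-Q1", "ANT-Q2"),
                                    subunits(m)$subunit_id[2:3]))
  tab2 <- cluster_network(m2, p)
  expect_equal(sort(tab2$rate_per_ps), sort(tab$rate_per_ps),
               tolerance = 1e-12)
})
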