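test_that("the IRF-convolved exponential has the right limits", {
  t <- seq(-2, 20, by = 0.01)
  # fwhm = 0 reduces to a step exponential
  expect_equal(exp_conv_irf(3, 0, 0, t),
               ifelse(t >= 0, exp(-t / 3), 0))
  # far past the IRF the ratio to the pure exponential approaches a
  # constant (the IRF-induced amplitude factor), equal to 1 for fwhm << tau
  late <- t[t > 0 + 3 * 0.1]
  prof <- exp_conv_irf(3, 0, 0.1, late)
  expect_equal(prof / exp(-late / 3), rep(1, length(late)), tolerance = 1e-3)
  # half height at t0 when fwhm << tau
  expect_equal(exp_conv_irf(100, 0, 0.1, 0), 0.5, tolerance = 1e-3)
  expect_equal(exp_conv_irf(100, 5, 0.1, 5), 0.5, tolerance = 1e-3)
  # numerical convolution oracle: adaptive quadrature of the IRF integral,
  # split at the step to handle the kink
  tau <- 2; fwhm <- 0.4; s <- fwhm / (2 * sqrt(2 * log(2)))
  teval <- seq(-1.5, 9, by = 0.25)
  num <- vapply(teval, function(ti) {
    f <- function(u) exp(-(ti - u) / tau) * dnorm(u, 0, s)
    stats::integrate(f, lower = min(-12 * s, ti - 1e-12), upper = ti,
                     rel.tol = 1e-11, abs.tol = 1e-13)$value
  }, numeric(1))
  expect_lt(max(abs(exp_conv_irf(tau, 0, fwhm, teval) - num)), 1e-6)
  # no overflow deep in the pre-rise wing
  expect_equal(exp_conv_irf(0.16, 0, 0.07, -1), 0, tolerance = 1e-12)
  expect_true(all(is.finite(exp_conv_irf(5000, 0, 0.07,
                                         seq(-1, 3000, by = 1)))))
  expect_error(exp_conv_irf(-1, 0, 0.1, t), "> 0")
})

test_that("noiseless cubes are fitted to high precision", {
  cube <- make_ta_cube(lifetimes_ps = c(5, 500),
                       das_lobes = list(
                         data.frame(peak_nm = 675, width_nm = 8,
                                    amplitude = 1),
                         data.frame(peak_nm = 690, width_nm = 10,
                                    amplitude = -0.6)),
                       noise_sd = 0, irf_fwhm_ps = 0.1)
  fit <- fit_global(cube, 2, init = c(2, 800))
  expect_equal(fit$lifetimes_ps, c(5, 500), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-12)

  # single-component cube: DAS equals the generator spectrum
  mono <- make_ta_cube(lifetimes_ps = 20,
                       das_lobes = list(
                         data.frame(peak_nm = 680, width_nm = 10,
                                    amplitude = 0.7)),
                       noise_sd = 0, irf_fwhm_ps = 0.1)
  fit1 <- fit_global(mono, 1, init = 10)
  expect_equal(as.vector(fit1$das), attr(mono, "truth")$das[, 1],
               tolerance = 1e-6)
})

test_that("the separable fit agrees with a joint full-parameter fit", {
  cube <- make_ta_cube(
    lifetimes_ps = c(4, 80),
    das_lobes = list(data.frame(peak_nm = 672, width_nm = 9, amplitude = 1),
                     data.frame(peak_nm = 688, width_nm = 9,
                                amplitude = -0.5)),
    delays_ps = seq(-0.5, 400, length.out = 50),
    wavelengths_nm = seq(660, 700, length.out = 5),
    noise_sd = 0.02, irf_fwhm_ps = 0.2, seed = 8)
  sep <- fit_global(cube, 2, init = c(2, 50))

  # joint oracle: optimize lifetimes AND all DAS amplitudes together
  Y <- cube$signal
  resid_joint <- function(par) {
    taus <- exp(par[1:2])
    A <- matrix(par[-(1:2)], nrow = 2)
    C <- vapply(taus, exp_conv_irf, numeric(length(cube$delays_ps)),
                t0_ps = 0, fwhm_ps = 0.2, t_ps = cube$delays_ps)
    as.vector(Y - C %*% A)
  }
  C0 <- vapply(c(2, 50), exp_conv_irf, numeric(length(cube$delays_ps)),
               t0_ps = 0, fwhm_ps = 0.2, t_ps = cube$delays_ps)
  A0 <- qr.coef(qr(C0), Y)
  joint <- minpack.lm::nls.lm(c(log(c(2, 50)), as.vector(A0)),
                              fn = resid_joint,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  expect_equal(sep$lifetimes_ps, sort(exp(joint$par[1:2])),
               tolerance = 1e-4)
  expect_equal(sep$rss, sum(joint$fvec^2), tolerance = 1e-6)
})

test_that("residual norm never increases with the component count", {
  cube <- make_ta_cube(lifetimes_ps = c(1, 30, 800),
                       das_lobes = (list(
                         data.frame(peak_nm = 670, width_nm = 8,
                                    amplitude = 1),
                         data.frame(peak_nm = 685, width_nm = 10,
                                    amplitude = 0.8),
                         data.frame(peak_nm = 695, width_nm = 9,
                                    amplitude = -0.3))),
                       noise_sd = 0.01, seed = 4)
  rss <- vapply(1:4, function(n) fit_global(cube, n)$rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-8 * rss[1]))
})

test_that("lifetime recovery at 1% noise is unbiased and tight over seeds", {
  taus <- vapply(1:20, function(s) {
    cube <- make_ta_cube(
      lifetimes_ps = c(5, 500),
      das_lobes = list(data.frame(peak_nm = 675, width_nm = 8,
                                  amplitude = 1),
                       data.frame(peak_nm = 690, width_nm = 10,
                                  amplitude = -0.6)),
      noise_sd = 0.01, irf_fwhm_ps = 0.1, seed = s)
    fit_global(cube, 2, init = c(2, 800))$lifetimes_ps
  }, numeric(2))
  bias <- abs(rowMeans(taus) / c(5, 500) - 1)
  spread <- apply(taus, 1, sd) / rowMeans(taus)
  expect_true(all(bias < 0.05))
  expect_true(all(spread < 0.10))
})

test_that("component reports label transfer and long-lived signatures", {
  wl <- seq(660, 710, length.out = 51)
  mk_fit <- function(lifetimes, das) {
    structure(list(lifetimes_ps = lifetimes, das = das,
                   wavelengths_nm = wl, n_components = length(lifetimes)),
              class = "das_fit")
  }
  transfer <- -exp(-(wl - 685)^2 / 50) + 0.8 * exp(-(wl - 665)^2 / 50)
  longlived <- -exp(-(wl - 672)^2 / 60)
  fit <- mk_fit(c(2.5, 5000), cbind(transfer, longlived))
  rep <- report_components(fit)
  expect_equal(rep$label[1], "transfer (growth at red edge)")
  expect_equal(rep$label[2], "long-lived/uncoupled")
  expect_lt(rep$peak_nm[2], 680)

  empty <- mk_fit(numeric(), matrix(numeric(), nrow = length(wl), ncol = 0))
  expect_equal(nrow(report_components(empty)), 0)
})

test_that("TA cubes round-trip through CSV with their IRF metadata", {
  cube <- make_ta_cube(seed = 2)
  f <- tempfile(fileext = ".csv")
  write_ta_cube(cube, f)
  back <- read_ta_cube(f)
  expect_equal(back$signal, cube$signal, tolerance = 1e-8)
  expect_equal(back$delays_ps, cube$delays_ps, tolerance = 1e-8)
  expect_equal(back$wavelengths_nm, cube$wavelengths_nm, tolerance = 1e-8)
  expect_equal(back$irf_fwhm_ps, 0.07)
  unlink(f)
})

test_that("fit guards reject invalid component counts and degenerate setups", {
  cube <- make_ta_cube(seed = 1)
  expect_error(fit_global(cube, 0), "n_components")
  expect_error(fit_global(cube, 7), "n_components")
  few <- ta_cube(c(0, 1, 2), c(660, 670), matrix(1, 3, 2), 0.07, 0)
  expect_error(fit_global(few, 3), "more delays")
  two <- make_ta_cube(lifetimes_ps = c(10, 11),
                      das_lobes = list(
                        data.frame(peak_nm = 670, width_nm = 8,
                                   amplitude = 1),
                        data.frame(peak_nm = 690, width_nm = 8,
                                   amplitude = 0.5)),
                      noise_sd = 0)
  expect_warning(fit_global(two, 2, init = c(8, 14)), "degenerate")
})
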