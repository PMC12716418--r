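#' Qy transition dipole of a chlorophyll
#'
#' Builds the Qy transition dipole from the ring geometry: the origin is the
#' central Mg, the direction is the unit vector from the B-ring nitrogen
#' (NB) to the D-ring nitrogen (ND) — the standard chlorin Qy axis — and the
#' magnitude (Debye) is the configured per-species dipole strength.
#'
#' @param pigment a single pigment record (one row of `pigments(model)`).
#' @param params an [eet_params()] list supplying `dipole_D`.
#' @return a list of class `transition_dipole` with `origin` (A),
#'   `direction` (unit vector) and `magnitude_D`.
#' @export
qy_dipole <- function(pigment, params = eet_params()) {
  if (inherits(pigment, "tbl_df")) {
    stopifnot(nrow(pigment) == 1)
    pigment <- as.list(pigment)
    pigment$key_atoms <- pigment$key_atoms[[1]]
  }
  if (!(pigment$species %in% .chl_species) || !isTRUE(pigment$is_eet_node)) {
    abort(paste0("pigment ", pigment$pigment_id,
                 " is not an EET node (species ", pigment$species, ")"))
  }
  ka <- pigment$key_atoms
  need <- c("MG", "NB", "ND")
  if (!all(need %in% names(ka))) {
    abort(paste0("pigment ", pigment$pigment_id,
                 " is missing key atoms: ",
                 paste(setdiff(need, names(ka)), collapse = ", ")))
  }
  v <- ka$ND - ka$NB
  nv <- sqrt(sum(v^2))
  if (nv <= 1e-9) abort("degenerate Qy axis: NB and ND coincide")
  structure(list(origin = ka$MG, direction = v / nv,
                 magnitude_D = .dipole_strength_vec(pigment$species, params)),
            class = "transition_dipole")
}

#' Site energy of a pigment
#'
#' Per-pigment overrides (`params$site_energy_override_cm1`, keyed by
#' pigment id) win over the species defaults, which are derived from the
#' configured wavelengths by `E = 1e7 / lambda`.
#'
#' @param pigment a single pigment record (one row of `pigments(model)`).
#' @param params an [eet_params()] list.
#' @return site energy in cm^-1.
#' @export
site_energy <- function(pigment, params = eet_params()) {
  if (inherits(pigment, "tbl_df")) {
    stopifnot(nrow(pigment) == 1)
    pigment <- as.list(pigment)
  }
  if (!isTRUE(pigment$is_eet_node)) {
    abort(paste0("pigment ", pigment$pigment_id, " is not an EET node"))
  }
  .site_energy_vec(pigment$species, pigment$pigment_id, params)
}

#' Dipole and site-energy table for all EET nodes
#'
#' Vectorized companion of [qy_dipole()] and [site_energy()]: one row per
#' chlorophyll with origin (`x`,`y`,`z`, Mg position), unit Qy direction
#' (`ux`,`uy`,`uz`), dipole strength `mu_D` and site energy `e_cm1`.
#'
#' @param model a classified [eet_structure()].
#' @param params an [eet_params()] list.
#' @return a tibble, one row per EET node.
#' @export
pigment_dipoles <- function(model, params = eet_params()) {
  p <- model$pigments[model$pigments$is_eet_node, , drop = FALSE]
  if (!nrow(p)) abort("model has no EET nodes")
  geom <- map(p$key_atoms, function(ka) {
    v <- ka$ND - ka$NB
    c(ka$MG, v / sqrt(sum(v^2)))
  })
  g <- do.call(rbind, geom)
  tibble(
    pigment_id = p$pigment_id,
    host_subunit = p$host_subunit,
    species = p$species,
    x = g[, 1], y = g[, 2], z = g[, 3],
    ux = g[, 4], uy = g[, 5], uz = g[, 6],
    mu_D = .dipole_strength_vec(p$species, params),
    e_cm1 = .site_energy_vec(p$species, p$pigment_id, params)
  )
}

#' Gaussian absorption/emission lineshapes
#'
#' Area-normalized Gaussian lineshapes on the wavenumber axis. The emission
#' shape is the absorption shape displaced to lower energy by the Stokes
#' shift; both share the same width.
#'
#' @param energy_cm1 absorption center (cm^-1).
#' @param fwhm_cm1 full width at half maximum (cm^-1), > 0.
#' @param stokes_cm1 Stokes shift (cm^-1), >= 0.
#' @return list with `absorption` and `emission`, each a `lineshape`
#'   (fields `kind`, `center`, `fwhm`, `sigma`).
#' @export
make_lineshapes <- function(energy_cm1, fwhm_cm1, stokes_cm1 = 0) {
  if (fwhm_cm1 <= 0) abort("lineshape fwhm must be > 0")
  if (stokes_cm1 < 0) abort("stokes shift must be >= 0")
  mk <- function(center) {
    structure(list(kind = "gaussian", center = center, fwhm = fwhm_cm1,
                   sigma = fwhm_cm1 / .eet_const$fwhm_to_sigma),
              class = "lineshape")
  }
  list(absorption = mk(energy_cm1), emission = mk(energy_cm1 - stokes_cm1))
}

#' Evaluate a lineshape density
#'
#' @param ls a `lineshape` from [make_lineshapes()].
#' @param nu wavenumber grid (cm^-1).
#' @return density values (per cm^-1); unit area over the full axis.
#' @export
lineshape_density <- function(ls, nu) {
  stopifnot(inherits(ls, "lineshape"), ls$kind == "gaussian")
  stats::dnorm(nu, mean = ls$center, sd = ls$sigma)
}

#' Donor-acceptor spectral overlap integral
#'
#' `J = integral F_D(nu) A_A(nu) dnu` of the area-normalized donor emission
#' and acceptor absorption lineshapes, evaluated by the trapezoid rule on a
#' wavenumber grid spanning at least +/- 6 sigma of both shapes. Units: cm
#' (inverse wavenumber), matching per-wavenumber-normalized shapes.
#'
#' @param donor_emission,acceptor_absorption `lineshape` objects.
#' @param grid optional wavenumber grid; must cover +/- 6 sigma of both
#'   shapes or an error is raised (never silent truncation).
#' @param grid_n number of nodes when the grid is built internally.
#' @return overlap integral J in cm.
#' @export
spectral_overlap <- function(donor_emission, acceptor_absorption,
                             grid = NULL, grid_n = 6001) {
  stopifnot(inherits(donor_emission, "lineshape"),
            inherits(acceptor_absorption, "lineshape"))
  lo <- min(donor_emission$center - 6 * donor_emission$sigma,
            acceptor_absorption$center - 6 * acceptor_absorption$sigma)
  hi <- max(donor_emission$center + 6 * donor_emission$sigma,
            acceptor_absorption$center + 6 * acceptor_absorption$sigma)
  if (is.null(grid)) {
    grid <- seq(lo, hi, length.out = grid_n)
  } else {
    if (min(grid) > lo || max(grid) < hi) {
      abort("supplied grid does not cover +/- 6 sigma of both lineshapes")
    }
    grid <- sort(grid)
  }
  f <- lineshape_density(donor_emission, grid) *
    lineshape_density(acceptor_absorption, grid)
  pracma::trapz(grid, f)
}

# closed-form overlap of two area-normalized Gaussians (vectorized); the
# product of two Gaussians integrates to a Gaussian density of the center
# difference with combined variance
.gauss_overlap <- function(mu_d, sigma_d, mu_a, sigma_a) {
  s2 <- sigma_d^2 + sigma_a^2
  exp(-(mu_d - mu_a)^2 / (2 * s2)) / sqrt(2 * pi * s2)
}
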