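# Physical constants in the spectroscopic unit system used throughout:
# energies in wavenumbers (cm^-1), distances in Angstrom, dipoles in Debye,
# times in picoseconds.
.eet_const <- list(
  # point-dipole coupling prefactor: V[cm^-1] = 5034 * kappa * mu1*mu2 / R^3
  # (mu in D, R in Angstrom); CGS value of 1 D^2/A^3 expressed in cm^-1
  dipole_prefactor_cm1 = 5034,
  # golden-rule prefactor: k[ps^-1] = 1.18 * V[cm^-1]^2 * J[cm]
  # (numerically 4 pi^2 c with c in cm/ps)
  rate_prefactor_ps = 1.18,
  kB_cm1_per_K = 0.69503476,
  fwhm_to_sigma = 2 * sqrt(2 * log(2)),
  speed_of_light_cm_s = 2.99792458e10
)

.chl_species <- c("chl_a", "chl_c", "chl_c2_mgdg")
.car_species <- c("fucoxanthin", "hexanoyloxyfucoxanthin", "diadinoxanthin",
                  "gyroxanthin_diester", "beta_carotene")
.pigment_species <- c(.chl_species, .car_species, "other")

# chl_c2_mgdg carries the chromophore of chlorophyll c2; it shares the
# chl_c photophysics (site energy, dipole strength)
.effective_species <- function(species) {
  ifelse(species == "chl_c2_mgdg", "chl_c", species)
}

#' Convert wavelength to wavenumber (and back)
#'
#' The two scales are related by `E = 1e7 / lambda` with `lambda` in nm and
#' `E` in cm^-1; the transform is its own inverse.
#'
#' @param x wavelength in nm (`nm_to_wavenumber`) or energy in cm^-1
#'   (`wavenumber_to_nm`).
#' @return numeric vector on the other scale.
#' @export
#' @examples
#' nm_to_wavenumber(663.5) # Chl a Qy site energy, ~15071.6 cm^-1
nm_to_wavenumber <- function(x) {
  stopifnot(all(x > 0))
  1e7 / x
}

#' @rdname nm_to_wavenumber
#' @export
wavenumber_to_nm <- function(x) nm_to_wavenumber(x)

#' Model parameters for the EET calculations
#'
#' Collects every tunable quantity of the pigment model and the rate
#' calculations in one list, with defaults appropriate for a chlorophyll a/c
#' antenna. Pass name = value pairs to override individual entries.
#'
#' Defaults:
#' * `site_energy_nm`: Qy site energies, 663.5 nm (Chl a) and 633.5 nm
#'   (Chl c); internally converted to cm^-1.
#' * `dipole_D`: Qy transition-dipole strengths, 4.0 D (Chl a), 3.4 D (Chl c).
#' * `fwhm_cm1` / `stokes_cm1`: Gaussian lineshape width (250 cm^-1) and
#'   Stokes shift (100 cm^-1), shared by absorption and emission.
#' * `coupling_scheme`: `"point"` (ideal point dipole) or `"extended"`
#'   (two point charges +/- q separated by `extended_l_A` along the Qy axis).
#' * `screening`: multiplicative dielectric screening factor on couplings.
#' * `distance_cutoff_A`: Mg-Mg distance beyond which pairs are not
#'   enumerated (40 A); `contact_floor_A`: below this separation the dipole
#'   approximation is refused (2 A).
#' * `temperature_K`: temperature for Boltzmann weighting of donor exciton
#'   states (295 K).
#' * `class_thresholds_ps`: time-constant class boundaries for rate maps
#'   (1, 10, 20 ps; slower pairs are omitted from maps).
#' * `route_cutoff_ps`: slowest step admitted in route searches (25 ps).
#' * `trap_rate_per_ps`: irreversible photochemical trapping rate out of the
#'   core cluster (1 ps^-1).
#' * `overlap_grid_n`: number of trapezoid nodes for numerical spectral
#'   overlap integrals.
#'
#' @param ... name = value overrides of the defaults.
#' @return a named list of class `eet_params`.
#' @export
#' @examples
#' p <- eet_params(fwhm_cm1 = 300, screening = 1 / 1.4^2)
#' p$site_energy_cm1[["chl_a"]]
eet_params <- function(...) {
  p <- list(
    site_energy_nm = c(chl_a = 663.5, chl_c = 633.5),
    site_energy_override_cm1 = c(),
    dipole_D = c(chl_a = 4.0, chl_c = 3.4),
    fwhm_cm1 = 250,
    stokes_cm1 = 100,
    coupling_scheme = "point",
    extended_l_A = 8.7,
    screening = 1.0,
    contact_floor_A = 2,
    distance_cutoff_A = 40,
    temperature_K = 295,
    class_thresholds_ps = c(1, 10, 20),
    route_cutoff_ps = 25,
    trap_rate_per_ps = 1,
    overlap_grid_n = 6001
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown eet_params entries: ",
                   paste(bad, collapse = ", ")))
    }
    p[names(dots)] <- dots
  }
  stopifnot(p$fwhm_cm1 > 0, p$stokes_cm1 >= 0, p$screening > 0,
            p$contact_floor_A > 0, p$temperature_K > 0)
  p$site_energy_cm1 <- nm_to_wavenumber(p$site_energy_nm)
  class(p) <- c("eet_params", "list")
  p
}

# site energy (cm^-1) per pigment: per-pigment override wins, else species
# default; vectorized over species/pigment_id
.site_energy_vec <- function(species, pigment_id, params) {
  eff <- .effective_species(species)
  e <- unname(params$site_energy_cm1[eff])
  if (any(is.na(e))) {
    abort(paste0("no default site energy for species: ",
                 paste(unique(eff[is.na(e)]), collapse = ", ")))
  }
  ov <- params$site_energy_override_cm1
  if (length(ov)) {
    hit <- match(pigment_id, names(ov))
    e[!is.na(hit)] <- unname(ov[hit[!is.na(hit)]])
  }
  e
}

.dipole_strength_vec <- function(species, params) {
  eff <- .effective_species(species)
  m <- unname(params$dipole_D[eff])
  if (any(is.na(m))) {
    abort(paste0("no dipole strength configured for species: ",
                 paste(unique(eff[is.na(m)]), collapse = ", ")))
  }
  m
}
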