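# seeded generation without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.chl_key_atoms <- function(center, direction, half_span_A = 2) {
  list(MG = center,
       NB = center - half_span_A * direction,
       ND = center + half_span_A * direction)
}

#' Analytic chlorophyll dimer fixtures
#'
#' Two chlorophylls at center-center distance `R` along x with one of three
#' textbook orientations: `parallel_perp_R` (both dipoles perpendicular to
#' the separation, kappa = 1), `head_to_tail` (collinear, kappa = -2, the
#' strongest geometry, |kappa| = 2), `perpendicular` (mutually orthogonal,
#' kappa = 0). The closed-form orientation factor and the point-dipole
#' coupling per unit dipole product (`5034 * kappa / R^3`) are attached as
#' `attr(, "dimer")`.
#'
#' @param R center-center Mg distance (A), above the contact floor.
#' @param geometry one of `"parallel_perp_R"`, `"head_to_tail"`,
#'   `"perpendicular"`.
#' @param species length-2 species assignment.
#' @return an [eet_structure()] with the two pigments on separate subunits.
#' @export
make_dimer <- function(R, geometry = c("parallel_perp_R", "head_to_tail",
                                       "perpendicular"),
                       species = c("chl_a", "chl_a")) {
  geometry <- match.arg(geometry)
  if (R <= 2) abort("R must exceed the 2 A contact floor")
  stopifnot(length(species) == 2, all(species %in% .chl_species))
  dirs <- switch(geometry,
    parallel_perp_R = list(c(0, 0, 1), c(0, 0, 1)),
    head_to_tail = list(c(1, 0, 0), c(1, 0, 0)),
    perpendicular = list(c(0, 0, 1), c(0, 1, 0))
  )
  kappa <- switch(geometry, parallel_perp_R = 1, head_to_tail = -2,
                  perpendicular = 0)
  centers <- list(c(0, 0, 0), c(R, 0, 0))
  code <- c(chl_a = "CLA", chl_c = "KC2", chl_c2_mgdg = "KCM")[species]
  sub <- tibble(subunit_id = c("A", "B"), name = c("DIM-A", "DIM-B"),
                family = "Lhcq", layer = c(1L, 1L))
  pig <- tibble(
    pigment_id = c("A_" %+% code[1] %+% "_101", "B_" %+% code[2] %+% "_101"),
    host_subunit = c("A", "B"),
    resid = unname(code), resno = c(101, 101),
    key_atoms = map2(centers, dirs, .chl_key_atoms),
    species = species,
    is_eet_node = TRUE
  )
  m <- eet_structure(sub, pig, provenance = list(generator = "make_dimer"))
  attr(m, "dimer") <- list(geometry = geometry, R_A = R,
                           kappa = abs(kappa), kappa_signed = kappa,
                           V_per_D2_cm1 = .eet_const$dipole_prefactor_cm1 *
                             kappa / R^3)
  m
}

`%+%` <- function(a, b) paste0(a, b)

#' Layered fiber-like antenna lattice
#'
#' Synthetic supercomplex emulating a multi-layer antenna wrapped around a
#' central core: `fibers` radial chains of subunits, one subunit per layer
#' per fiber, at increasing radius. Within a subunit the chlorophylls sit
#' on a narrow tangential-vertical grid, so consecutive layers of the same
#' fiber face each other across `inter_layer_gap_A` while neighboring
#' fibers are separated by the (larger, radius-growing) arc gap — the
#' geometry that makes energy flow follow the fibers. The core is a
#' three-dimensional pigment block whose faces sit only `core_gap_A` from
#' the innermost layer, emulating the tight antenna-core contact that
#' makes the innermost-layer-to-core transfer the fastest step of the
#' cascade. Dipoles point along z, each perturbed by a random rotation of
#' up to `orientation_noise_deg`. Subunit names encode layer and fiber
#' (`ANT-L<layer>F<fiber>`); layer and family annotations are pre-filled.
#' Identical seeds give bit-identical models.
#'
#' @param n_layers number of antenna layers.
#' @param fibers subunits per layer (= number of radial fibers).
#' @param pigments_per_subunit chlorophylls per antenna subunit.
#' @param chl_c_fraction fraction of each subunit's pigments assigned
#'   chlorophyll c (placed deterministically).
#' @param intra_spacing_A pigment grid spacing within a subunit.
#' @param inter_layer_gap_A radial center-to-center gap between layers.
#' @param inner_gap_A floor on the arc gap between neighboring fiber
#'   centers at the innermost layer (outer layers have larger gaps).
#' @param core_gap_A gap between the core block face and the innermost
#'   layer.
#' @param core_pigments chlorophylls in the central core cluster.
#' @param orientation_noise_deg maximum random tilt of the dipole axes.
#' @param seed RNG seed (orientation noise only).
#' @return an [eet_structure()].
#' @export
make_layered_antenna <- function(n_layers = 6, fibers = 5,
                                 pigments_per_subunit = 10,
                                 chl_c_fraction = 0.25,
                                 intra_spacing_A = 10,
                                 inter_layer_gap_A = 22,
                                 inner_gap_A = 30,
                                 core_gap_A = 16,
                                 core_pigments = 40,
                                 orientation_noise_deg = 10,
                                 seed = 1) {
  stopifnot(n_layers >= 1, fibers >= 1, pigments_per_subunit >= 1,
            intra_spacing_A > 2, inter_layer_gap_A > 2, inner_gap_A > 2,
            core_gap_A > 2, chl_c_fraction >= 0, chl_c_fraction <= 1,
            orientation_noise_deg >= 0)
  .with_seed(seed, {
    chains <- c(LETTERS, letters)
    # core: compact 3D block at the origin
    nc <- ceiling(core_pigments^(1 / 3))
    gx <- (seq_len(nc) - (nc + 1) / 2) * intra_spacing_A
    core_xyz <- expand.grid(x = gx, y = gx, z = gx)[seq_len(core_pigments), ]
    core_extent <- max(abs(c(core_xyz$x, core_xyz$y)))
    dtheta <- 2 * pi / fibers
    r0 <- max(inner_gap_A / dtheta, core_extent + core_gap_A)

    subs <- list(tibble(subunit_id = "0", name = "CORE", family = "core",
                        layer = 0L))
    pigs <- list(.grid_subunit_pigments(
      chain = "0", centers = cbind(core_xyz$x, core_xyz$y, core_xyz$z),
      species = rep("chl_a", core_pigments),
      noise_deg = orientation_noise_deg))

    n_c <- round(chl_c_fraction * pigments_per_subunit)
    sp_sub <- rep("chl_a", pigments_per_subunit)
    if (n_c > 0) {
      sp_sub[round(seq(1, pigments_per_subunit, length.out = n_c))] <- "chl_c"
    }
    # narrow tangential footprint, extended vertically: subunits present a
    # flat face to the neighboring layers of their fiber
    ncol_t <- min(2L, pigments_per_subunit)
    nrow_z <- ceiling(pigments_per_subunit / ncol_t)
    gt <- (seq_len(ncol_t) - (ncol_t + 1) / 2) * intra_spacing_A
    gz <- (seq_len(nrow_z) - (nrow_z + 1) / 2) * intra_spacing_A
    grid_tz <- expand.grid(t = gt, z = gz)[seq_len(pigments_per_subunit), ]

    k <- 0
    for (l in seq_len(n_layers)) {
      r_l <- r0 + (l - 1) * inter_layer_gap_A
      for (f in seq_len(fibers)) {
        k <- k + 1
        theta <- (f - 1) * dtheta
        radial <- c(cos(theta), sin(theta), 0)
        tangent <- c(-sin(theta), cos(theta), 0)
        centers <- t(vapply(seq_len(pigments_per_subunit), function(i) {
          r_l * radial + grid_tz$t[i] * tangent + c(0, 0, grid_tz$z[i])
        }, numeric(3)))
        subs[[length(subs) + 1]] <- tibble(
          subunit_id = chains[k],
          name = sprintf("ANT-L%dF%d", l, f),
          family = "Lhcq", layer = as.integer(l))
        pigs[[length(pigs) + 1]] <- .grid_subunit_pigments(
          chain = chains[k], centers = centers, species = sp_sub,
          noise_deg = orientation_noise_deg)
      }
    }
    eet_structure(bind_rows(subs), bind_rows(pigs),
                  provenance = list(generator = "make_layered_antenna",
                                    seed = seed))
  })
}

.grid_subunit_pigments <- function(chain, centers, species, noise_deg) {
  n <- nrow(centers)
  code <- c(chl_a = "CLA", chl_c = "KC2", chl_c2_mgdg = "KCM")[species]
  dirs <- lapply(seq_len(n), function(i) {
    .jitter_direction(c(0, 0, 1), noise_deg)
  })
  tibble(
    pigment_id = paste0(chain, "_", code, "_", 100 + seq_len(n)),
    host_subunit = chain,
    resid = unname(code),
    resno = 100 + seq_len(n),
    key_atoms = lapply(seq_len(n), function(i) {
      .chl_key_atoms(as.numeric(centers[i, ]), dirs[[i]])
    }),
    species = unname(species),
    is_eet_node = TRUE
  )
}

# random rotation of at most `max_deg` about a random axis
.jitter_direction <- function(v, max_deg) {
  if (max_deg == 0) return(v)
  ang <- runif(1, 0, max_deg) * pi / 180
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ct <- cos(ang); st <- sin(ang)
  out <- v * ct + .cross3(ax, v) * st + ax * sum(ax * v) * (1 - ct)
  out / sqrt(sum(out^2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Census-matched pigment inventory fixture
#'
#' A 48-subunit placeholder supercomplex reproducing the pigment census of
#' the coccolithophore photosystem I antenna: 12 core subunits (95 Chl a,
#' 20 beta-carotene + 3 diadinoxanthin), one single-chlorophyll linker
#' (L_EFP), and 35 antenna subunits carrying 291 Chl a, 121 Chl c (9 of
#' them as the chlorophyll c2-MGDG adduct) and 224 carotenoids (109
#' fucoxanthin, 42 19'-hexanoyloxyfucoxanthin exclusively in Lhcq
#' subunits, 70 diadinoxanthin, 3 gyroxanthin-diester). Every Lhcq/Lhcf
#' subunit holds 4-5 Chl c; the 10 remaining antenna subunits share the
#' other 9. Coordinates are placeholder lattice positions — the fixture
#' guarantees census statistics and layer topology, not geometry. The
#' construction self-audits all census totals.
#'
#' @return an [eet_structure()], classified and layer-annotated.
#' @export
make_inventory_fixture <- function() {
  fam_map <- default_family_map()
  lay_map <- default_layer_map()
  ant_names <- paste0("EFCPI-", 1:35)
  core_names <- names(fam_map)[fam_map == "core"]
  chains <- c(as.character(0:9), "x", "y", "z", LETTERS, letters[1:9])
  all_names <- c(core_names, "L_EFP", ant_names)
  chain_of <- setNames(chains[seq_along(all_names)], all_names)

  # --- per-subunit pigment counts -----------------------------------------
  ord <- ant_names # paper numbering order; deterministic
  lhcqf <- ord[fam_map[ord] %in% c("Lhcq", "Lhcf")]
  other_ant <- setdiff(ord, lhcqf)
  n_chl_a <- setNames(c(rep(9L, 11), rep(8L, 24)), ord)          # 291
  n_chl_c <- setNames(integer(35), ord)
  n_chl_c[lhcqf] <- c(rep(4L, 13), rep(5L, 12))                  # 112
  n_chl_c[setdiff(other_ant, "EFCPI-18")] <- 1L                  # + 9 = 121
  n_car <- setNames(c(rep(7L, 14), rep(6L, 21)), ord)            # 224
  c2_mgdg_hosts <- lhcqf[1:9] # one Chl c2-MGDG adduct each

  car_pool <- c(fucoxanthin = 109L, hexanoyloxyfucoxanthin = 42L,
                diadinoxanthin = 70L, gyroxanthin_diester = 3L)
  pref <- list(
    Lhcq = c("fucoxanthin", "hexanoyloxyfucoxanthin", "gyroxanthin_diester",
             "diadinoxanthin"),
    Lhcf = c("fucoxanthin", "diadinoxanthin"),
    other = c("diadinoxanthin", "fucoxanthin")
  )

  subs <- list(); pigs <- list()
  add_subunit <- function(name, family, layer, species_vec, center) {
    chain <- chain_of[[name]]
    subs[[length(subs) + 1]] <<- tibble(
      subunit_id = chain, name = name, family = family,
      layer = as.integer(layer))
    if (!length(species_vec)) return(invisible())
    n <- length(species_vec)
    ng <- ceiling(sqrt(n))
    g <- expand.grid(a = (seq_len(ng) - (ng + 1) / 2) * 8,
                     b = (seq_len(ng) - (ng + 1) / 2) * 8)[seq_len(n), ]
    code <- c(chl_a = "CLA", chl_c = "KC2", chl_c2_mgdg = "KCM",
              fucoxanthin = "FXA", hexanoyloxyfucoxanthin = "HFX",
              diadinoxanthin = "DD6", gyroxanthin_diester = "GYE",
              beta_carotene = "BCR", other = "MGD")[species_vec]
    code[species_vec == "other_sq"] <- "LHG"
    is_chl <- species_vec %in% .chl_species
    pigs[[length(pigs) + 1]] <<- tibble(
      pigment_id = paste0(chain, "_", code, "_", 100 + seq_len(n)),
      host_subunit = chain, resid = unname(code),
      resno = 100 + seq_len(n),
      key_atoms = lapply(seq_len(n), function(i) {
        pos <- center + c(g$a[i], g$b[i], 0)
        if (is_chl[i]) .chl_key_atoms(pos, c(0, 0, 1))
        else list(C1 = pos, C2 = pos + c(0, 0, 3))
      }),
      species = ifelse(species_vec == "other_sq", "other",
                       unname(species_vec)),
      is_eet_node = is_chl)
    invisible()
  }

  # core: 95 Chl a, 20 beta-carotene, 3 diadinoxanthin, 26 lipids
  core_chl <- setNames(c(30L, 30L, rep(4L, 7), 3L, 2L, 2L)[1:12], core_names)
  stopifnot(sum(core_chl) == 95)
  core_car <- setNames(integer(12), core_names)
  core_car[c("PsaA", "PsaB")] <- c(10L, 10L)
  core_car[c("PsaF", "PsaJ", "PsaK")] <- 1L # remaining 3 of 23 are Ddx
  core_car_sp <- function(nm) {
    if (nm %in% c("PsaA", "PsaB")) rep("beta_carotene", core_car[[nm]])
    else rep("diadinoxanthin", core_car[[nm]])
  }
  core_lip <- setNames(c(rep(2L, 10), 3L, 3L), core_names) # 26 extra hets
  for (i in seq_along(core_names)) {
    nm <- core_names[i]
    ang <- 2 * pi * (i - 1) / 12
    center <- c(60 * cos(ang), 60 * sin(ang), 0)
    add_subunit(nm, "core", 0L,
                c(rep("chl_a", core_chl[[nm]]), core_car_sp(nm),
                  rep("other_sq", core_lip[[nm]])), center)
  }
  add_subunit("L_EFP", "linker", 1L, "chl_a", c(0, 0, 60))

  for (i in seq_along(ord)) {
    nm <- ord[i]
    fam <- unname(fam_map[nm])
    lay <- unname(lay_map[nm])
    ang <- 2 * pi * (i - 1) / 35 + 0.15 * lay
    center <- c((120 + 60 * lay) * cos(ang), (120 + 60 * lay) * sin(ang), 0)
    ncc <- n_chl_c[[nm]]
    chl_c_sp <- rep("chl_c", ncc)
    if (nm %in% c2_mgdg_hosts && ncc > 0) chl_c_sp[1] <- "chl_c2_mgdg"
    prefs <- pref[[if (fam %in% names(pref)) fam else "other"]]
    cars <- character(0)
    for (s in prefs) {
      take <- min(car_pool[[s]], n_car[[nm]] - length(cars))
      if (take > 0) {
        cars <- c(cars, rep(s, take))
        car_pool[[s]] <- car_pool[[s]] - take
      }
    }
    stopifnot(length(cars) == n_car[[nm]])
    lipids <- rep("other", sum(chl_c_sp == "chl_c2_mgdg")) # companion MGDG
    add_subunit(nm, fam, lay,
                c(rep("chl_a", n_chl_a[[nm]]), chl_c_sp, cars, lipids),
                center)
  }
  m <- eet_structure(bind_rows(subs), bind_rows(pigs),
                     provenance = list(generator = "make_inventory_fixture"))

  # construction self-audit against the encoded census
  p <- m$pigments
  stopifnot(
    sum(p$species == "chl_a") == 387,
    sum(p$species == "chl_c") == 112,
    sum(p$species == "chl_c2_mgdg") == 9,
    sum(p$species %in% .car_species) == 247,
    sum(p$species != "other") == 755,
    nrow(p) == 790,
    nrow(m$subunits) == 48,
    all(car_pool == 0)
  )
  m
}

#' Synthetic transient-absorption cube with known components
#'
#' Builds `signal = sum_k DAS_k(lambda) * c_k(t) + noise` from known
#' lifetimes and component spectra, with `c_k` the IRF-convolved
#' exponential of [exp_conv_irf()]. The default four components mirror a
#' chlorophyll a/c antenna-to-core cascade probed across the Qy bleach
#' region: a sub-ps relaxation/Chl c feeding component peaking near 680 nm,
#' a ~2.8 ps inner-antenna-to-core transfer with a negative blue lobe and
#' red-edge growth, a dominant ~62 ps antenna decay, and a 5 ns
#' long-lived/uncoupled component with a blue-shifted negative peak. Each
#' component spectrum is a sum of signed Gaussian lobes
#' (`peak_nm`, `width_nm`, `amplitude`). The zero-noise cube equals the
#' analytic model exactly; the true components are attached as
#' `attr(, "truth")`.
#'
#' @param lifetimes_ps component lifetimes.
#' @param das_lobes list (one element per component) of data frames with
#'   columns `peak_nm`, `width_nm`, `amplitude`.
#' @param delays_ps delay grid; default 120 points, -1 to 3000 ps,
#'   log-spaced after 1 ps.
#' @param wavelengths_nm wavelength grid; default 64 points, 660-710 nm.
#' @param irf_fwhm_ps Gaussian IRF width (default 0.07 ps, i.e. 70 fs).
#' @param t0_ps time zero.
#' @param noise_sd additive Gaussian noise, as a fraction of the maximum
#'   absolute clean signal.
#' @param seed RNG seed for the noise.
#' @return a [ta_cube()] with `attr(, "truth")`.
#' @export
make_ta_cube <- function(lifetimes_ps = c(0.16, 2.8, 62, 5000),
                         das_lobes = NULL,
                         delays_ps = NULL, wavelengths_nm = NULL,
                         irf_fwhm_ps = 0.07, t0_ps = 0, noise_sd = 0.01,
                         seed = 1) {
  stopifnot(all(lifetimes_ps > 0), noise_sd >= 0)
  if (is.null(delays_ps)) {
    delays_ps <- c(seq(-1, 1, by = 0.05),
                   exp(seq(log(1.07), log(3000), length.out = 79)))
  }
  if (is.null(wavelengths_nm)) {
    wavelengths_nm <- seq(660, 710, length.out = 64)
  }
  if (is.null(das_lobes)) {
    das_lobes <- .default_das_lobes()[seq_along(lifetimes_ps)]
  }
  stopifnot(length(das_lobes) == length(lifetimes_ps))
  das <- vapply(das_lobes, function(lb) {
    rowSums(vapply(seq_len(nrow(lb)), function(i) {
      lb$amplitude[i] *
        exp(-(wavelengths_nm - lb$peak_nm[i])^2 / (2 * lb$width_nm[i]^2))
    }, numeric(length(wavelengths_nm))))
  }, numeric(length(wavelengths_nm)))
  C <- .conv_design(lifetimes_ps, t0_ps, irf_fwhm_ps, delays_ps)
  clean <- C %*% t(das)
  noisy <- .with_seed(seed, {
    clean + noise_sd * max(abs(clean)) *
      matrix(rnorm(length(clean)), nrow(clean))
  })
  cube <- ta_cube(delays_ps, wavelengths_nm, noisy,
                  irf_fwhm_ps = irf_fwhm_ps, t0_ps = t0_ps)
  attr(cube, "truth") <- list(lifetimes_ps = lifetimes_ps, das = das,
                              clean = clean, noise_sd = noise_sd,
                              seed = seed)
  cube
}

.default_das_lobes <- function() {
  list(
    # sub-ps relaxation / Chl c -> Chl a feeding: positive near 680 nm
    data.frame(peak_nm = 680, width_nm = 12, amplitude = 1.0),
    # inner antenna -> core transfer: negative below 670, growth at the red
    data.frame(peak_nm = c(664, 686, 703), width_nm = c(8, 9, 10),
               amplitude = c(-0.45, 0.85, 0.35)),
    # dominant antenna -> core decay
    data.frame(peak_nm = 683, width_nm = 11, amplitude = 1.2),
    # long-lived / uncoupled Chl a: blue-shifted negative peak
    data.frame(peak_nm = 676, width_nm = 9, amplitude = -0.4)
  )
}
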