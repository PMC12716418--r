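#' Packaged residue-name and subunit annotation dictionaries
#'
#' Coordinate depositions differ in the het-codes used for the same
#' chromophore, and antenna subunit names carry the biological annotation
#' (LHC family, concentric layer) that the coordinate file does not. These
#' functions return the packaged default dictionaries; each accepting
#' function takes a user map that is merged over (and thus overrides) the
#' defaults.
#'
#' `default_het_map()`: het-code -> pigment species. `CLA` is chlorophyll a,
#' `KC1`/`KC2` chlorophyll c, `KCM` the chlorophyll c2 chromophore of the
#' c2-MGDG adduct, `FXA`/`HFX`/`DD6`/`GYE`/`BCR` the carotenoids
#' (fucoxanthin, 19'-hexanoyloxyfucoxanthin, diadinoxanthin,
#' gyroxanthin-diester, beta-carotene).
#'
#' `default_layer_map()`: antenna subunit name -> concentric layer 1-6
#' around the photosystem I core (layer 1 innermost). The linker L_EFP sits
#' against the first layer.
#'
#' `default_family_map()`: subunit name -> family (`core`, `linker`, `Lhcr`,
#' `Lhcq`, `Lhcf`, `RedCAP`, `CgLhcr9_homolog`).
#'
#' @return a named character (or integer) vector.
#' @export
default_het_map <- function() {
  c(CLA = "chl_a",
    KC1 = "chl_c",
    KC2 = "chl_c",
    KCM = "chl_c2_mgdg",
    FXA = "fucoxanthin",
    HFX = "hexanoyloxyfucoxanthin",
    DD6 = "diadinoxanthin",
    GYE = "gyroxanthin_diester",
    BCR = "beta_carotene")
}

#' @rdname default_het_map
#' @export
default_layer_map <- function() {
  lm <- c(
    setNames(rep(1L, 10), paste0("EFCPI-", c(1:3, 5:11))),
    setNames(rep(2L, 8), paste0("EFCPI-", c(4, 12:18))),
    setNames(rep(3L, 7), paste0("EFCPI-", 19:25)),
    setNames(rep(4L, 5), paste0("EFCPI-", 26:30)),
    setNames(rep(5L, 2), paste0("EFCPI-", 31:32)),
    setNames(rep(6L, 3), paste0("EFCPI-", 33:35)),
    L_EFP = 1L
  )
  lm
}

#' @rdname default_het_map
#' @export
default_family_map <- function() {
  core <- paste0("Psa", c("A", "B", "C", "D", "E", "F", "I", "J", "K",
                          "L", "M", "R"))
  c(
    setNames(rep("core", length(core)), core),
    L_EFP = "linker",
    `EFCPI-1` = "RedCAP",
    `EFCPI-3` = "CgLhcr9_homolog",
    `EFCPI-4` = "Lhcf",
    setNames(rep("Lhcr", 8), paste0("EFCPI-", c(2, 5, 6, 7, 9, 10, 11, 18))),
    setNames(rep("Lhcq", 24), paste0("EFCPI-", c(8, 12:17, 19:35)))
  )
}

# merge a user map over defaults; accepts a named vector, a named list, or
# a path to a YAML/JSON file of name: value pairs
.merge_map <- function(user, defaults) {
  if (is.null(user)) return(defaults)
  if (is.character(user) && length(user) == 1 && file.exists(user)) {
    user <- .read_config_file(user)
  }
  if (is.list(user)) user <- unlist(user)
  if (is.null(names(user)) || any(names(user) == "")) {
    abort("annotation maps must be named (name = value)")
  }
  out <- defaults
  out[names(user)] <- user
  out
}

.read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
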