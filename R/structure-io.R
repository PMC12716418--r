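#' @title Structure models of pigment-protein supercomplexes
#'
#' @description An `eet_structure` bundles two tibbles: `subunits` (one row
#' per chain: `subunit_id`, `name`, `family`, `layer`) and `pigments` (one
#' row per cofactor: `pigment_id`, `host_subunit`, `resid` het-code, `resno`,
#' `species`, `is_eet_node`, and a `key_atoms` list-column of named 3-vectors
#' in Angstrom). Coordinates are kept exactly as stored in the source file
#' (right-handed, no re-centering). Only chlorophyll species participate in
#' the excitation-transfer network (`is_eet_node`); carotenoids and
#' unrecognized het groups are carried through for counting only.
#'
#' @param subunits,pigments tibbles as described above.
#' @param provenance list describing the source (path, dialect).
#' @return an object of class `eet_structure`.
#' @export
eet_structure <- function(subunits, pigments, provenance = list()) {
  subunits <- as_tibble(subunits)
  pigments <- as_tibble(pigments)
  x <- structure(list(subunits = subunits, pigments = pigments,
                      provenance = provenance),
                 class = "eet_structure")
  validate_structure(x)
  x
}

#' @rdname eet_structure
#' @param x an `eet_structure`.
#' @export
validate_structure <- function(x) {
  stopifnot(inherits(x, "eet_structure"))
  p <- x$pigments
  s <- x$subunits
  if (anyDuplicated(p$pigment_id)) abort("pigment_ids are not unique")
  if (anyDuplicated(s$subunit_id)) abort("subunit_ids are not unique")
  orphan <- setdiff(p$host_subunit, s$subunit_id)
  if (length(orphan)) {
    abort(paste0("pigments reference unknown subunits: ",
                 paste(orphan, collapse = ", ")))
  }
  bad_sp <- setdiff(unique(p$species), .pigment_species)
  if (length(bad_sp)) {
    abort(paste0("unknown pigment species: ", paste(bad_sp, collapse = ", ")))
  }
  if (any(p$is_eet_node & !(p$species %in% .chl_species))) {
    abort("is_eet_node must be FALSE for non-chlorophyll pigments")
  }
  coords <- unlist(p$key_atoms, use.names = FALSE)
  if (length(coords) && !all(is.finite(coords))) {
    abort("non-finite key-atom coordinates")
  }
  invisible(x)
}

#' @rdname eet_structure
#' @export
pigments <- function(x) x$pigments

#' @rdname eet_structure
#' @export
subunits <- function(x) x$subunits

#' @export
print.eet_structure <- function(x, ...) {
  n_ant <- sum(!is.na(x$subunits$layer) & x$subunits$layer >= 1 &
                 x$subunits$family != "linker", na.rm = TRUE)
  cat("<eet_structure> ", nrow(x$subunits), " subunits (",
      n_ant, " antenna), ", nrow(x$pigments), " pigments, ",
      sum(x$pigments$is_eet_node), " EET nodes\n", sep = "")
  if (!is.null(x$provenance$path)) {
    cat("  source: ", x$provenance$path, " [", x$provenance$dialect, "]\n",
        sep = "")
  }
  invisible(x)
}

#' Parse a coordinate file into a structure model
#'
#' Reads an mmCIF or PDB file, collects every chain as a subunit and every
#' het-group residue as a pigment record, and classifies the pigments with
#' the packaged het-code dictionary (see [classify_pigments()]). Unknown
#' het-codes are retained with `species = "other"`. A chlorophyll missing
#' any of its required key atoms (central Mg, Qy-axis nitrogens NB/ND)
#' triggers a warning and is excluded from the EET network.
#'
#' @param path coordinate file.
#' @param dialect `"mmcif"` or `"pdb"`.
#' @param naming_map optional het-code -> species overrides, merged over
#'   [default_het_map()].
#' @return an [eet_structure()].
#' @export
#' @examples
#' m <- make_dimer(R = 10, geometry = "parallel_perp_R")
#' f <- tempfile(fileext = ".cif")
#' write_structure(m, f, dialect = "mmcif")
#' parse_structure(f, "mmcif")
parse_structure <- function(path, dialect = c("mmcif", "pdb"),
                            naming_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readLines(path, warn = FALSE)
  n_records <- sum(grepl("^(ATOM|HETATM)", raw))
  pdb <- tryCatch(
    if (dialect == "mmcif") {
      suppressWarnings(bio3d::read.cif(path))
    } else {
      bio3d::read.pdb(path)
    },
    error = function(e) {
      abort(paste0("cannot parse ", path, " as ", dialect, ": ",
                   conditionMessage(e)))
    }
  )
  at <- pdb$atom
  if (nrow(at) != n_records) {
    abort(paste0("parse error in ", path, ": ", n_records,
                 " ATOM/HETATM records but ", nrow(at),
                 " atoms parsed (truncated or corrupt file?)"))
  }
  if (nrow(at) == 0) abort(paste0("no atoms in ", path))
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z))) {
    bad <- which(!(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))[1]
    abort(paste0("parse error in ", path, ": non-numeric coordinates at ",
                 "atom record ", bad, " (truncated file?)"))
  }
  at$chain[is.na(at$chain)] <- "_"

  sub <- tibble(
    subunit_id = unique(at$chain),
    name = unique(at$chain),
    family = NA_character_,
    layer = NA_integer_
  )

  het <- at[at$type == "HETATM", , drop = FALSE]
  if (nrow(het)) {
    key <- paste(het$chain, het$resid, het$resno, sep = "|")
    idx <- split(seq_len(nrow(het)), factor(key, levels = unique(key)))
    pig <- tibble(
      pigment_id = map_chr(idx, function(i) {
        paste0(het$chain[i[1]], "_", het$resid[i[1]], "_", het$resno[i[1]])
      }),
      host_subunit = map_chr(idx, function(i) het$chain[i[1]]),
      resid = map_chr(idx, function(i) het$resid[i[1]]),
      resno = map_dbl(idx, function(i) het$resno[i[1]]),
      key_atoms = map(idx, function(i) {
        a <- het[i, , drop = FALSE]
        setNames(lapply(seq_len(nrow(a)),
                        function(k) c(a$x[k], a$y[k], a$z[k])),
                 a$elety)
      }),
      species = "other",
      is_eet_node = FALSE
    )
  } else {
    pig <- tibble(pigment_id = character(), host_subunit = character(),
                  resid = character(), resno = double(),
                  key_atoms = list(), species = character(),
                  is_eet_node = logical())
  }

  model <- eet_structure(sub, pig,
                         provenance = list(path = path, dialect = dialect))
  classify_pigments(model, naming_map = naming_map)
}

#' Assign pigment species from het-codes
#'
#' Maps each pigment's residue code to a species with the packaged
#' dictionary merged with `naming_map` overrides. The chlorophyll c2-MGDG
#' adduct is treated as a single chlorophyll c chromophore (its lipid tail
#' is ignored), so it joins the EET network like any chlorophyll c. A
#' chlorophyll only becomes an EET node if its Mg and both Qy-axis
#' nitrogens (NB, ND) are present, finite, and distinct. The operation is
#' idempotent.
#'
#' @param model an [eet_structure()].
#' @param naming_map optional het-code -> species map (named vector, list,
#'   or YAML/JSON path) merged over [default_het_map()].
#' @param quiet suppress the message listing unmapped het-codes.
#' @return the model with `species` and `is_eet_node` filled in.
#' @export
classify_pigments <- function(model, naming_map = NULL, quiet = FALSE) {
  stopifnot(inherits(model, "eet_structure"))
  map <- .merge_map(naming_map, default_het_map())
  p <- model$pigments
  if (!nrow(p)) return(model)
  sp <- unname(map[p$resid])
  sp[is.na(sp)] <- "other"
  bad <- setdiff(unique(sp), .pigment_species)
  if (length(bad)) {
    abort(paste0("naming map assigns unknown species: ",
                 paste(bad, collapse = ", ")))
  }
  unmapped <- unique(p$resid[!(p$resid %in% names(map))])
  if (length(unmapped) && !quiet) {
    inform(paste0("unmapped het-codes retained as species 'other': ",
                  paste(unmapped, collapse = ", ")))
  }
  geom_ok <- map_lgl(p$key_atoms, function(ka) {
    need <- c("MG", "NB", "ND")
    if (!all(need %in% names(ka))) return(FALSE)
    v <- unlist(ka[need])
    all(is.finite(v)) && sqrt(sum((ka$NB - ka$ND)^2)) > 1e-6
  })
  is_chl <- sp %in% .chl_species
  if (any(is_chl & !geom_ok)) {
    warn(paste0("chlorophylls missing Mg/NB/ND key atoms excluded from the ",
                "EET network: ",
                paste(p$pigment_id[is_chl & !geom_ok], collapse = ", ")))
  }
  p$species <- sp
  p$is_eet_node <- is_chl & geom_ok
  model$pigments <- p
  validate_structure(model)
  model
}

#' Rename subunits
#'
#' Coordinate files identify subunits only by chain id; analysis maps are
#' keyed by biological names (`EFCPI-23`, `PsaA`, ...). This replaces the
#' `name` column by `name_map[subunit_id]` (ids missing from the map keep
#' their current name).
#'
#' @param model an [eet_structure()].
#' @param name_map named character vector, `subunit_id -> name`.
#' @return the renamed model.
#' @export
rename_subunits <- function(model, name_map) {
  stopifnot(inherits(model, "eet_structure"))
  s <- model$subunits
  hit <- match(s$subunit_id, names(name_map))
  s$name[!is.na(hit)] <- unname(name_map[hit[!is.na(hit)]])
  model$subunits <- s
  model
}

#' Annotate subunits with family and concentric layer
#'
#' Antenna subunits are organized in concentric layers around the core
#' (layer 1 innermost). Assignments are looked up by subunit `name` in
#' `layer_map`/`family_map`, merged over the packaged defaults for the
#' 35-subunit coccolithophore antenna ([default_layer_map()],
#' [default_family_map()]). Core subunits always get layer 0; any
#' non-core subunit whose name is missing from the layer map is an error.
#'
#' @param model an [eet_structure()].
#' @param layer_map,family_map optional name -> value overrides.
#' @return the model with `family` and `layer` columns filled in.
#' @export
annotate_layers <- function(model, layer_map = NULL, family_map = NULL) {
  stopifnot(inherits(model, "eet_structure"))
  lmap <- .merge_map(layer_map, default_layer_map())
  fmap <- .merge_map(family_map, default_family_map())
  s <- model$subunits
  fam <- unname(fmap[s$name])
  s$family <- ifelse(is.na(fam), s$family, fam)
  if (any(is.na(s$family))) {
    abort(paste0("subunits with unknown family (extend family_map): ",
                 paste(s$name[is.na(s$family)], collapse = ", ")))
  }
  lay <- suppressWarnings(as.integer(unname(lmap[s$name])))
  lay[s$family == "core"] <- 0L
  if (any(is.na(lay))) {
    abort(paste0("antenna subunits missing from layer map: ",
                 paste(s$name[is.na(lay)], collapse = ", ")))
  }
  if (any(lay == 0L & s$family != "core") ||
      any(lay >= 1L & s$family == "core")) {
    abort("layer 0 is reserved for (and required of) core subunits")
  }
  s$layer <- lay
  model$subunits <- s
  model
}

#' Pigment inventory statistics
#'
#' Counts pigments per subunit and species and summarizes the antenna:
#' totals per species and mean pigments per antenna subunit (chlorophyll
#' c2-MGDG counted with chlorophyll c; all carotenoid species pooled).
#' Averages are reported to two decimals; with zero antenna subunits they
#' are `NA`, never zero.
#'
#' @param model a classified, layer-annotated [eet_structure()].
#' @return an object of class `eet_inventory` with elements `counts`
#'   (subunit x species tibble), `totals` (per species, plus pooled
#'   chlorophyll-c and carotenoid counts), `averages` (per antenna
#'   subunit), `n_pigments` and `n_het_groups`.
#' @export
inventory <- function(model) {
  stopifnot(inherits(model, "eet_structure"))
  if (any(is.na(model$subunits$layer))) {
    abort("model must be layer-annotated before inventory(); see annotate_layers()")
  }
  p <- model$pigments
  s <- model$subunits
  counts <- p |>
    count(.data$host_subunit, .data$species, name = "count") |>
    rename(subunit_id = "host_subunit") |>
    left_join(s, by = "subunit_id") |>
    select("subunit_id", "name", "family", "layer", "species", "count") |>
    arrange(.data$layer, .data$name, .data$species)

  totals <- counts |>
    group_by(.data$species) |>
    summarise(total = sum(.data$count), .groups = "drop")
  tot <- function(sp) sum(totals$total[totals$species %in% sp])

  antenna <- s$subunit_id[s$layer >= 1 & s$family != "linker"]
  n_ant <- length(antenna)
  ant_counts <- counts[counts$subunit_id %in% antenna, , drop = FALSE]
  atot <- function(sp) sum(ant_counts$count[ant_counts$species %in% sp])
  avg <- function(sp) if (n_ant == 0) NA_real_ else round(atot(sp) / n_ant, 2)

  res <- structure(list(
    counts = counts,
    totals = tibble(
      species = c(totals$species, "chl_c_all", "carotenoid_all"),
      total = c(totals$total, tot(c("chl_c", "chl_c2_mgdg")),
                tot(.car_species))
    ),
    antenna_totals = tibble(
      species = c("chl_a", "chl_c_all", "carotenoid_all"),
      total = c(atot("chl_a"), atot(c("chl_c", "chl_c2_mgdg")),
                atot(.car_species))
    ),
    averages = tibble(
      n_antenna_subunits = n_ant,
      mean_chl_a = avg("chl_a"),
      mean_chl_c = avg(c("chl_c", "chl_c2_mgdg")),
      mean_carotenoid = avg(.car_species)
    ),
    n_pigments = sum(p$species != "other"),
    n_het_groups = nrow(p)
  ), class = "eet_inventory")
  res
}

#' @export
print.eet_inventory <- function(x, ...) {
  cat("<eet_inventory> ", x$n_pigments, " pigments (",
      x$n_het_groups, " het groups)\n", sep = "")
  print(x$averages)
  invisible(x)
}

#' @export
tidy.eet_inventory <- function(x, ...) x$counts

#' @export
glance.eet_inventory <- function(x, ...) {
  bind_cols(x$averages,
            pivot_wider(x$antenna_totals, names_from = "species",
                        values_from = "total", names_prefix = "antenna_"))
}

#' Write inventory tables
#'
#' Writes the per-subunit species counts as CSV and the summary (totals and
#' per-antenna-subunit averages) as JSON.
#'
#' @param inv an `eet_inventory`.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return `inv`, invisibly.
#' @export
write_inventory <- function(inv, csv = NULL, json = NULL) {
  stopifnot(inherits(inv, "eet_inventory"))
  if (!is.null(csv)) write.csv(inv$counts, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(totals = inv$totals, antenna_totals = inv$antenna_totals,
           averages = inv$averages, n_pigments = inv$n_pigments,
           n_het_groups = inv$n_het_groups),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(inv)
}

# -- coordinate writers (used by the synthetic generators) -------------------

#' Write a structure model to mmCIF or PDB
#'
#' Serializes the het-group records of a model so it can be re-read with
#' [parse_structure()]. Only pigment/het records are written (the synthetic
#' models carry no polymer atoms). Chain identifiers must be single
#' characters for the PDB dialect.
#'
#' @param model an [eet_structure()].
#' @param path output file.
#' @param dialect `"mmcif"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, dialect = c("mmcif", "pdb")) {
  dialect <- match.arg(dialect)
  p <- model$pigments
  rows <- list()
  serial <- 0L
  for (i in seq_len(nrow(p))) {
    ka <- p$key_atoms[[i]]
    for (nm in names(ka)) {
      serial <- serial + 1L
      rows[[serial]] <- list(serial = serial, name = nm,
                             resid = p$resid[i], chain = p$host_subunit[i],
                             resno = p$resno[i], xyz = ka[[nm]],
                             elem = .atom_element(nm))
    }
  }
  if (dialect == "pdb") {
    if (any(nchar(model$subunits$subunit_id) != 1)) {
      abort("PDB output requires single-character chain identifiers")
    }
    lines <- map_chr(rows, function(r) {
      sprintf("HETATM%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              r$serial, r$name, r$resid, r$chain, r$resno,
              r$xyz[1], r$xyz[2], r$xyz[3], 1.0, 0.0, r$elem)
    })
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c("data_eetscape", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")))
    lines <- map_chr(rows, function(r) {
      sprintf("HETATM %d %s %s . %s %s 1 . ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
              r$serial, r$elem, r$name, r$resid, r$chain,
              r$xyz[1], r$xyz[2], r$xyz[3], r$resno, r$resid,
              r$chain, r$name)
    })
    writeLines(c(hdr, lines, "#"), path)
  }
  invisible(path)
}

.atom_element <- function(name) {
  if (grepl("^MG", name)) "MG"
  else if (grepl("^N", name)) "N"
  else if (grepl("^O", name)) "O"
  else "C"
}
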