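#' Build a clade schema
#'
#' The clade schema holds every numeric threshold and species set the
#' classifier uses: per-clade minimum presence, the alternative
#' single-representative rule, the counted-metazoan denominator, the focal
#' species (used for partitioning only, never for selection), the counted
#' non-metazoans with the foreign-leakage thresholds, and the control
#' (eukaryote-core) required/forbidden sets. All thresholds are
#' configurable; [default_clade_schema()] derives the standard layout from
#' a species table.
#'
#' @param clade_members Named list mapping clade label to character vector
#'   of species codes.
#' @param clade_min_presence Named integer vector: minimum number of
#'   species of that clade that must be present (names must be clades in
#'   `clade_members`; each minimum at most the clade size).
#' @param alternative_representatives Species codes of which at least one
#'   must be present (single-representative clades).
#' @param counted_metazoans Species codes counted toward
#'   `total_min_presence` (excludes the focal species).
#' @param total_min_presence Minimum number of counted metazoans present.
#' @param focal_species Species code used only to partition classified
#'   groups into present/absent.
#' @param nonmetazoan_counted Species codes counted as foreign.
#' @param max_foreign_species Maximum distinct foreign species tolerated.
#' @param max_foreign_rbbh_links Maximum RBBH links from each foreign gene
#'   to the metazoan members of its group.
#' @param control_required_species Species that must all be present for the
#'   eukaryote-core control label (empty set disables the label).
#' @param control_forbidden_species Species whose presence disqualifies the
#'   control label (typically prokaryotes).
#' @param species_universe All species codes the classifier may encounter;
#'   defaults to the union of every set above.
#' @return An object of class `clade_schema`.
#' @export
clade_schema <- function(clade_members,
                         clade_min_presence,
                         alternative_representatives = character(),
                         counted_metazoans,
                         total_min_presence,
                         focal_species = NULL,
                         nonmetazoan_counted = character(),
                         max_foreign_species = 2L,
                         max_foreign_rbbh_links = 3L,
                         control_required_species = character(),
                         control_forbidden_species = character(),
                         species_universe = NULL) {
  stopifnot(is.list(clade_members), !is.null(names(clade_members)))
  clade_min_presence <- setNames(as.integer(clade_min_presence),
                                 names(clade_min_presence))
  miss <- setdiff(names(clade_min_presence), names(clade_members))
  if (length(miss) > 0) {
    abort(sprintf("clade_min_presence names not in clade_members: %s",
                  paste(miss, collapse = ", ")))
  }
  for (cl in names(clade_min_presence)) {
    if (clade_min_presence[[cl]] < 0 ||
        clade_min_presence[[cl]] > length(clade_members[[cl]])) {
      abort(sprintf("clade_min_presence['%s'] must be in [0, %d].",
                    cl, length(clade_members[[cl]])))
    }
  }
  total_min_presence <- as.integer(total_min_presence)
  if (total_min_presence < 0 || total_min_presence > length(counted_metazoans)) {
    abort("total_min_presence must be between 0 and |counted_metazoans|.")
  }
  if (!is.null(focal_species) && focal_species %in% counted_metazoans) {
    abort("The focal species must not be part of counted_metazoans.")
  }
  if (max_foreign_species < 0 || max_foreign_rbbh_links < 0) {
    abort("Foreign-leakage thresholds must be non-negative.")
  }
  universe <- species_universe %||% unique(c(
    unlist(clade_members, use.names = FALSE), counted_metazoans,
    focal_species, nonmetazoan_counted,
    control_required_species, control_forbidden_species
  ))
  structure(list(
    clade_members = lapply(clade_members, as.character),
    clade_min_presence = clade_min_presence,
    alternative_representatives = as.character(alternative_representatives),
    counted_metazoans = as.character(counted_metazoans),
    total_min_presence = total_min_presence,
    focal_species = focal_species,
    nonmetazoan_counted = as.character(nonmetazoan_counted),
    max_foreign_species = as.integer(max_foreign_species),
    max_foreign_rbbh_links = as.integer(max_foreign_rbbh_links),
    control_required_species = as.character(control_required_species),
    control_forbidden_species = as.character(control_forbidden_species),
    species_universe = as.character(universe)
  ), class = "clade_schema")
}

#' @export
print.clade_schema <- function(x, ...) {
  cat("<clade_schema>\n")
  for (cl in names(x$clade_members)) {
    min_cl <- if (cl %in% names(x$clade_min_presence))
      x$clade_min_presence[[cl]] else NA
    cat(sprintf("  %s: %d species (min presence %s)\n",
                cl, length(x$clade_members[[cl]]),
                ifelse(is.na(min_cl), "-", min_cl)))
  }
  cat(sprintf("  alternative representatives: %s\n",
              paste(x$alternative_representatives, collapse = ", ")))
  cat(sprintf("  counted metazoans: %d (total min presence %d)\n",
              length(x$counted_metazoans), x$total_min_presence))
  cat(sprintf("  focal species: %s\n", x$focal_species %||% "-"))
  cat(sprintf("  counted non-metazoans: %d (max %d foreign species, max %d RBBH links)\n",
              length(x$nonmetazoan_counted), x$max_foreign_species,
              x$max_foreign_rbbh_links))
  cat(sprintf("  control required: %s\n",
              paste(x$control_required_species, collapse = ", ")))
  cat(sprintf("  control forbidden: %d species\n",
              length(x$control_forbidden_species)))
  invisible(x)
}

# all species codes treated as metazoan by the schema
metazoan_codes <- function(schema) {
  unique(c(unlist(schema$clade_members, use.names = FALSE),
           schema$counted_metazoans, schema$focal_species))
}

#' Derive the default clade schema from a species table
#'
#' Builds the standard selection layout: metazoan clades with minimum
#' presence 9 of 11 Craniata, 6 of 8 Arthropoda and 2 of 3 Nematoda (scaled
#' thresholds must be supplied explicitly for other layouts), at least one
#' of the single-representative clades (Urochordata, Cnidaria), a combined
#' total of at least 20 counted metazoans, the Placozoan as focal species,
#' and all well-sequenced non-metazoans as the counted foreign set with at
#' most 2 foreign species of at most 3 RBBH links each.
#'
#' @param species Species tibble from [read_species_table()].
#' @param clade_min_presence Named vector of per-clade minima.
#' @param alternative_clades Clades handled via the at-least-one-of rule.
#' @param total_min_presence Combined counted-metazoan minimum.
#' @param focal_clade Clade whose (single) species is the focal species.
#' @param prokaryote_clades Clade labels treated as prokaryotic for the
#'   control (eukaryote-core) forbidden set.
#' @param control_required_species Codes required for the control label;
#'   defaults to the intersection of the canonical five
#'   (`hsa`, `cel`, `dme`, `sce`, `ath`) with the table, and to none if not
#'   all five are present.
#' @inheritParams clade_schema
#' @return A `clade_schema`.
#' @export
default_clade_schema <- function(species,
                                 clade_min_presence = c(Craniata = 9L,
                                                        Arthropoda = 6L,
                                                        Nematoda = 2L),
                                 alternative_clades = c("Urochordata", "Cnidaria"),
                                 total_min_presence = 20L,
                                 focal_clade = "Placozoa",
                                 prokaryote_clades = c("Prokaryota", "Bacteria",
                                                       "Archaea"),
                                 max_foreign_species = 2L,
                                 max_foreign_rbbh_links = 3L,
                                 control_required_species = NULL) {
  check_columns(species, c("code", "clade", "is_metazoan", "well_sequenced"))
  mz <- species[species$is_metazoan, ]
  nonmz <- species[!species$is_metazoan, ]
  focal <- mz$code[mz$clade == focal_clade]
  if (length(focal) > 1) {
    abort(sprintf("Focal clade '%s' has %d species; expected one.",
                  focal_clade, length(focal)))
  }
  if (length(focal) == 0) focal <- NULL
  counted <- setdiff(mz$code, focal)
  clades <- split(mz$code, mz$clade)
  clades[[focal_clade]] <- NULL
  keep_min <- intersect(names(clade_min_presence), names(clades))
  if (is.null(control_required_species)) {
    five <- c("hsa", "cel", "dme", "sce", "ath")
    control_required_species <- if (all(five %in% species$code)) five else character()
  }
  clade_schema(
    clade_members = clades,
    clade_min_presence = clade_min_presence[keep_min],
    alternative_representatives = unlist(clades[intersect(alternative_clades,
                                                          names(clades))],
                                         use.names = FALSE) %||% character(),
    counted_metazoans = counted,
    total_min_presence = min(total_min_presence, length(counted)),
    focal_species = focal,
    nonmetazoan_counted = nonmz$code[nonmz$well_sequenced],
    max_foreign_species = max_foreign_species,
    max_foreign_rbbh_links = max_foreign_rbbh_links,
    control_required_species = control_required_species,
    control_forbidden_species = nonmz$code[nonmz$clade %in% prokaryote_clades],
    species_universe = species$code
  )
}

#' Write a clade schema as a flat key/value config file
#'
#' @param schema A `clade_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clade_schema <- function(schema, path) {
  stopifnot(inherits(schema, "clade_schema"))
  lines <- character()
  for (cl in names(schema$clade_members)) {
    lines <- c(lines, sprintf("clade_members.%s=%s", cl,
                              paste(schema$clade_members[[cl]], collapse = ",")))
  }
  for (cl in names(schema$clade_min_presence)) {
    lines <- c(lines, sprintf("clade_min_presence.%s=%d", cl,
                              schema$clade_min_presence[[cl]]))
  }
  kv <- function(key, val) sprintf("%s=%s", key, paste(val, collapse = ","))
  lines <- c(lines,
             kv("alternative_representatives", schema$alternative_representatives),
             kv("counted_metazoans", schema$counted_metazoans),
             kv("total_min_presence", schema$total_min_presence),
             kv("focal_species", schema$focal_species %||% ""),
             kv("nonmetazoan_counted", schema$nonmetazoan_counted),
             kv("max_foreign_species", schema$max_foreign_species),
             kv("max_foreign_rbbh_links", schema$max_foreign_rbbh_links),
             kv("control_required_species", schema$control_required_species),
             kv("control_forbidden_species", schema$control_forbidden_species),
             kv("species_universe", schema$species_universe))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clade schema from a flat key/value config file
#'
#' @param path Path written by [write_clade_schema()] (or hand-edited in
#'   the same format).
#' @return A `clade_schema`.
#' @export
read_clade_schema <- function(path) {
  kv <- read_kv_file(path)
  member_keys <- grep("^clade_members\\.", names(kv), value = TRUE)
  if (length(member_keys) == 0) abort("Schema config defines no clades.")
  clade_members <- lapply(kv[member_keys], split_csv_field)
  names(clade_members) <- sub("^clade_members\\.", "", member_keys)
  min_keys <- grep("^clade_min_presence\\.", names(kv), value = TRUE)
  mins <- vapply(kv[min_keys], function(v) as.integer(v), integer(1))
  names(mins) <- sub("^clade_min_presence\\.", "", min_keys)
  focal <- kv[["focal_species"]] %||% ""
  universe <- split_csv_field(kv[["species_universe"]] %||% "")
  clade_schema(
    clade_members = clade_members,
    clade_min_presence = mins,
    alternative_representatives = split_csv_field(kv[["alternative_representatives"]]),
    counted_metazoans = split_csv_field(kv[["counted_metazoans"]]),
    total_min_presence = as.integer(kv[["total_min_presence"]] %||% 0),
    focal_species = if (nzchar(focal)) focal else NULL,
    nonmetazoan_counted = split_csv_field(kv[["nonmetazoan_counted"]]),
    max_foreign_species = as.integer(kv[["max_foreign_species"]] %||% 2),
    max_foreign_rbbh_links = as.integer(kv[["max_foreign_rbbh_links"]] %||% 3),
    control_required_species = split_csv_field(kv[["control_required_species"]]),
    control_forbidden_species = split_csv_field(kv[["control_forbidden_species"]]),
    species_universe = if (length(universe) > 0) universe else NULL
  )
}
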