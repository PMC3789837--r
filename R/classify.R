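#' Per-group clade presence profile
#'
#' Summarises each ortholog group against a clade schema: species-level
#' counts per metazoan clade (paralogs count once), the number of counted
#' metazoans present, focal-species presence, and the number of counted
#' foreign (non-metazoan) species.
#'
#' @param groups Long groups tibble from [read_groups()].
#' @param schema A [clade_schema()].
#' @return A tibble with one row per group (input order preserved):
#'   `group_id`, one `n_<clade>` column per schema clade,
#'   `total_counted_present`, `focal_present`, `n_foreign_species`.
#' @export
clade_profile <- function(groups, schema) {
  stopifnot(inherits(schema, "clade_schema"))
  check_columns(groups, c("group_id", "species"))
  unknown <- setdiff(unique(groups$species), schema$species_universe)
  if (length(unknown) > 0) {
    abort(sprintf("Species absent from the schema universe: %s",
                  paste(unknown, collapse = ", ")))
  }
  ids <- unique(groups$group_id)
  pres <- distinct(groups[c("group_id", "species")])

  clade_tbl <- tibble(
    clade = rep(names(schema$clade_members),
                lengths(schema$clade_members)),
    species = unlist(schema$clade_members, use.names = FALSE)
  )
  counts <- inner_join(pres, clade_tbl, by = "species",
                       relationship = "many-to-many")
  counts <- count(counts, .data$group_id, .data$clade)
  wide <- tidyr::pivot_wider(counts, names_from = "clade",
                             names_prefix = "n_",
                             values_from = "n", values_fill = 0L)

  out <- tibble(group_id = ids)
  out <- left_join(out, wide, by = "group_id")
  for (cl in names(schema$clade_members)) {
    col <- paste0("n_", cl)
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]] <- as.integer(ifelse(is.na(out[[col]]), 0L, out[[col]]))
  }
  out <- out[c("group_id", paste0("n_", names(schema$clade_members)))]

  counted <- count(pres[pres$species %in% schema$counted_metazoans, ],
                   .data$group_id, name = "total_counted_present")
  out <- left_join(out, counted, by = "group_id")
  out$total_counted_present <-
    as.integer(ifelse(is.na(out$total_counted_present), 0L,
                      out$total_counted_present))
  focal_ids <- if (is.null(schema$focal_species)) character() else
    pres$group_id[pres$species == schema$focal_species]
  out$focal_present <- out$group_id %in% focal_ids
  nf <- count(pres[pres$species %in% schema$nonmetazoan_counted, ],
              .data$group_id, name = "n_foreign_species")
  out <- left_join(out, nf, by = "group_id")
  out$n_foreign_species <-
    as.integer(ifelse(is.na(out$n_foreign_species), 0L, out$n_foreign_species))
  out
}

#' Foreign members of each group, annotated with RBBH links
#'
#' Lists every member gene from a counted non-metazoan species, together
#' with its number of RBBH links into the metazoan members of the same
#' group (the false-positive leakage signal).
#'
#' @inheritParams clade_profile
#' @param rbbh RBBH edge tibble from [read_rbbh()], or `NULL` for no graph
#'   (all link counts 0).
#' @return Tibble `group_id`, `species`, `gene`, `rbbh_links`.
#' @export
foreign_rbbh_links <- function(groups, schema, rbbh = NULL) {
  stopifnot(inherits(schema, "clade_schema"))
  check_columns(groups, c("group_id", "species", "gene"))
  fm <- groups[groups$species %in% schema$nonmetazoan_counted,
               c("group_id", "species", "gene")]
  fm <- as_tibble(fm)
  if (nrow(fm) == 0 || is.null(rbbh) || nrow(rbbh) == 0) {
    fm$rbbh_links <- integer(nrow(fm))
    return(fm)
  }
  mz <- groups[groups$species %in% metazoan_codes(schema),
               c("group_id", "gene")]
  names(mz) <- c("group_id", "partner")
  both <- bind_rows(
    tibble(gene = rbbh$gene_a, partner = rbbh$gene_b),
    tibble(gene = rbbh$gene_b, partner = rbbh$gene_a)
  )
  cand <- inner_join(fm, both, by = "gene", relationship = "many-to-many")
  hits <- inner_join(cand, mz, by = c("group_id", "partner"))
  link_counts <- count(hits, .data$group_id, .data$gene, name = "rbbh_links")
  fm <- left_join(fm, link_counts, by = c("group_id", "gene"))
  fm$rbbh_links <- as.integer(ifelse(is.na(fm$rbbh_links), 0L, fm$rbbh_links))
  fm
}

#' Foreign-leakage check
#'
#' A group passes when it contains at most `max_foreign_species` distinct
#' counted non-metazoan species AND every foreign member gene has at most
#' `max_foreign_rbbh_links` RBBH links to the metazoan members of the
#' group (each threshold applied per foreign gene, not summed).
#'
#' @inheritParams foreign_rbbh_links
#' @return Tibble with one row per group: `group_id`, `n_foreign_species`,
#'   `max_foreign_links`, `pass_species`, `pass_rbbh`, `pass`.
#' @export
foreign_leakage_check <- function(groups, schema, rbbh = NULL) {
  fm <- foreign_rbbh_links(groups, schema, rbbh)
  ids <- unique(groups$group_id)
  by_group <- if (nrow(fm) == 0) {
    tibble(group_id = character(), n_foreign_species = integer(),
           max_foreign_links = integer())
  } else {
    summarise(group_by(fm, .data$group_id),
              n_foreign_species = n_distinct(.data$species),
              max_foreign_links = max(.data$rbbh_links),
              .groups = "drop")
  }
  out <- tibble(group_id = ids)
  out <- left_join(out, by_group, by = "group_id")
  out$n_foreign_species <-
    as.integer(ifelse(is.na(out$n_foreign_species), 0L, out$n_foreign_species))
  out$max_foreign_links <-
    as.integer(ifelse(is.na(out$max_foreign_links), 0L, out$max_foreign_links))
  out$pass_species <- out$n_foreign_species <= schema$max_foreign_species
  out$pass_rbbh <- out$max_foreign_links <= schema$max_foreign_rbbh_links
  out$pass <- out$pass_species & out$pass_rbbh
  out
}

#' Eukaryote-core (control) criterion
#'
#' TRUE for groups containing every control-required species and no
#' control-forbidden species. An empty required set disables the label
#' (always FALSE).
#'
#' @inheritParams clade_profile
#' @return Logical vector aligned with the groups' first-appearance order.
#' @export
is_eukaryote_core <- function(groups, schema) {
  stopifnot(inherits(schema, "clade_schema"))
  check_columns(groups, c("group_id", "species"))
  unknown <- setdiff(unique(groups$species), schema$species_universe)
  if (length(unknown) > 0) {
    abort(sprintf("Species absent from the schema universe: %s",
                  paste(unknown, collapse = ", ")))
  }
  ids <- unique(groups$group_id)
  req <- schema$control_required_species
  if (length(req) == 0) return(setNames(rep(FALSE, length(ids)), ids))
  pres <- distinct(groups[c("group_id", "species")])
  n_req <- count(pres[pres$species %in% req, ], .data$group_id)
  has_all <- ids %in% n_req$group_id[n_req$n == length(req)]
  forb <- unique(pres$group_id[pres$species %in% schema$control_forbidden_species])
  setNames(has_all & !(ids %in% forb), ids)
}

#' Classify ortholog groups against a clade schema
#'
#' The core decision procedure. A group is labelled `metazoan_specific`
#' when all of the following hold: every per-clade minimum presence is
#' met; at least one alternative representative is present; the combined
#' counted-metazoan presence reaches `total_min_presence`; and the
#' foreign-leakage check passes (at most `max_foreign_species` counted
#' non-metazoan species, each foreign gene with at most
#' `max_foreign_rbbh_links` RBBH links into the group's metazoan members).
#' Otherwise a group meeting the control criterion ([is_eukaryote_core()])
#' is labelled `eukaryote_core`, and anything else `other`. Focal-species
#' presence is never a selection criterion; it only feeds
#' [partition_by_species()].
#'
#' @inheritParams foreign_rbbh_links
#' @return An `ortho_classification` tibble, one row per group:
#'   `group_id`, `label`, the `n_<clade>` counts, `total_counted_present`,
#'   `focal_present`, `n_foreign_species`, `max_foreign_links`,
#'   `meets_eukaryote_core`, and `failed_criteria` (semicolon-joined tags
#'   from `clade:<label>`, `alt_representative`, `total_min`,
#'   `foreign_species`, `foreign_rbbh`; empty when all selection criteria
#'   hold). The schema and the per-foreign-gene link table are attached as
#'   attributes `schema` and `foreign_detail`.
#' @export
classify_groups <- function(groups, schema, rbbh = NULL) {
  prof <- clade_profile(groups, schema)
  leak <- foreign_leakage_check(groups, schema, rbbh)
  stopifnot(identical(prof$group_id, leak$group_id))

  fails <- list()
  for (cl in names(schema$clade_min_presence)) {
    fails[[paste0("clade:", cl)]] <-
      prof[[paste0("n_", cl)]] < schema$clade_min_presence[[cl]]
  }
  pres <- distinct(groups[c("group_id", "species")])
  if (length(schema$alternative_representatives) > 0) {
    alt_ids <- unique(
      pres$group_id[pres$species %in% schema$alternative_representatives])
    fails[["alt_representative"]] <- !(prof$group_id %in% alt_ids)
  }
  fails[["total_min"]] <- prof$total_counted_present < schema$total_min_presence
  fails[["foreign_species"]] <- !leak$pass_species
  fails[["foreign_rbbh"]] <- !leak$pass_rbbh

  fail_mat <- do.call(cbind, fails)
  tags <- names(fails)
  failed_criteria <- apply(fail_mat, 1, function(row)
    paste(tags[row], collapse = ";"))
  ms <- !apply(fail_mat, 1, any)

  euk <- unname(is_eukaryote_core(groups, schema))
  overlap <- ms & euk
  if (any(overlap)) {
    warn(sprintf(
      "%d group(s) satisfy both the metazoan-specific and eukaryote-core criteria (labelled metazoan_specific): %s",
      sum(overlap), paste(utils::head(prof$group_id[overlap], 5), collapse = ", ")))
  }

  out <- prof
  out$max_foreign_links <- leak$max_foreign_links
  out$meets_eukaryote_core <- euk
  out$label <- ifelse(ms, "metazoan_specific",
                      ifelse(euk, "eukaryote_core", "other"))
  out$failed_criteria <- failed_criteria
  out <- out[c("group_id", "label",
               paste0("n_", names(schema$clade_members)),
               "total_counted_present", "focal_present",
               "n_foreign_species", "max_foreign_links",
               "meets_eukaryote_core", "failed_criteria")]
  attr(out, "schema") <- schema
  attr(out, "foreign_detail") <- foreign_rbbh_links(groups, schema, rbbh)
  class(out) <- c("ortho_classification", class(tibble()))
  out
}

#' Partition classified groups by presence of a species
#'
#' Splits the `metazoan_specific` groups into those containing and those
#' lacking a given species (by default the schema's focal species). The
#' two sets are disjoint and jointly cover the metazoan-specific groups.
#'
#' @param classification An `ortho_classification` from [classify_groups()].
#' @param species_code Species code; defaults to the schema's focal species.
#' @param groups The long groups tibble; required when partitioning by a
#'   species other than the focal one (presence is then recomputed).
#' @return A list of class `species_partition` with elements `species`,
#'   `present` and `absent` (character vectors of group ids).
#' @export
partition_by_species <- function(classification, species_code = NULL,
                                 groups = NULL) {
  schema <- attr(classification, "schema")
  species_code <- species_code %||% schema$focal_species
  if (is.null(species_code)) abort("No species to partition by.")
  if (!species_code %in% schema$species_universe) {
    abort(sprintf("Unknown species code: %s", species_code))
  }
  ms <- classification[classification$label == "metazoan_specific", ]
  if (!is.null(schema$focal_species) &&
      identical(species_code, schema$focal_species)) {
    flag <- ms$focal_present
  } else {
    if (is.null(groups)) {
      abort("Supply `groups` to partition by a non-focal species.")
    }
    pres <- distinct(groups[c("group_id", "species")])
    flag <- ms$group_id %in% pres$group_id[pres$species == species_code]
  }
  structure(list(species = species_code,
                 present = ms$group_id[flag],
                 absent = ms$group_id[!flag]),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("<species_partition> by '%s': %d present, %d absent (of %d)\n",
              x$species, length(x$present), length(x$absent),
              length(x$present) + length(x$absent)))
  invisible(x)
}

#' @method glance ortho_classification
#' @export
glance.ortho_classification <- function(x, ...) {
  ms <- x[x$label == "metazoan_specific", ]
  tibble(
    n_groups = nrow(x),
    n_metazoan_specific = nrow(ms),
    n_eukaryote_core = sum(x$label == "eukaryote_core"),
    n_other = sum(x$label == "other"),
    n_focal_present = sum(ms$focal_present),
    n_focal_absent = sum(!ms$focal_present),
    pct_focal_present = if (nrow(ms) > 0)
      100 * mean(ms$focal_present) else NA_real_
  )
}

#' @method tidy ortho_classification
#' @export
tidy.ortho_classification <- function(x, ...) {
  out <- x
  attr(out, "schema") <- NULL
  attr(out, "foreign_detail") <- NULL
  class(out) <- class(tibble())
  out
}

#' Write a classification table
#'
#' @param classification An `ortho_classification`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  readr::write_tsv(tidy(classification), path, progress = FALSE)
  invisible(path)
}

#' Read back a classification table written by [write_classification()]
#'
#' @param path TSV path.
#' @return A tibble (without the schema attribute).
#' @export
read_classification <- function(path) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
}
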