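#' Genome-completeness approximation from core-gene coverage
#'
#' Approximates per-species gene coverage as the fraction of a reference
#' list of widely conserved, low-copy eukaryotic ortholog groups in which
#' the species has at least one member. Presence is binary per species per
#' group, so paralog counts never change coverage. Coverage is a QC
#' read-out only; it never gates classification.
#'
#' @param groups Long groups tibble from [read_groups()].
#' @param reference_ids Character vector of reference group ids; must be a
#'   subset of the collection's group ids and non-empty.
#' @param species Species tibble from [read_species_table()].
#' @return A `coverage_report` tibble with columns `code`, `is_metazoan`,
#'   `n_present`, `n_reference` and `coverage` (in `[0, 1]`), one row per
#'   species in `species` (species absent from every reference group get 0).
#' @export
coverage_report <- function(groups, reference_ids, species) {
  check_columns(groups, c("group_id", "species"))
  check_columns(species, c("code", "is_metazoan"))
  reference_ids <- unique(reference_ids)
  if (length(reference_ids) == 0) {
    abort("Empty reference set: need at least one reference group id.")
  }
  unknown <- setdiff(reference_ids, unique(groups$group_id))
  if (length(unknown) > 0) {
    abort(sprintf("Reference id(s) not present in the collection: %s",
                  paste(utils::head(unknown, 5), collapse = ", ")))
  }
  pres <- distinct(groups[groups$group_id %in% reference_ids,
                          c("group_id", "species")])
  n_present <- table(pres$species)
  out <- tibble(
    code = species$code,
    is_metazoan = species$is_metazoan,
    n_present = as.integer(ifelse(is.na(n_present[species$code]), 0L,
                                  n_present[species$code])),
    n_reference = length(reference_ids)
  )
  out$coverage <- out$n_present / out$n_reference
  class(out) <- c("coverage_report", class(out))
  out
}

#' @method glance coverage_report
#' @export
glance.coverage_report <- function(x, ...) {
  mz <- x[x$is_metazoan, ]
  tibble(
    n_species = nrow(x),
    reference_size = x$n_reference[1],
    mean_coverage_metazoan = mean(mz$coverage),
    min_coverage_metazoan = if (nrow(mz) > 0) min(mz$coverage) else NA_real_,
    mean_coverage_all = mean(x$coverage)
  )
}

#' Write a coverage report
#'
#' @param x A `coverage_report`.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  cols <- x[c("code", "n_present", "n_reference", "coverage")]
  if (format == "tsv") {
    readr::write_tsv(cols, path, progress = FALSE)
  } else {
    jsonlite::write_json(cols, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
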