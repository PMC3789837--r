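#' Read a species table
#'
#' Reads a tab-separated species table with header columns `code`, `name`,
#' `clade`, `is_metazoan` and `well_sequenced`. Lines starting with `#` are
#' comments. Species codes must be unique, non-empty and contain neither
#' whitespace nor `|` (they prefix gene identifiers).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `code`, `name`, `clade` (character) and
#'   `is_metazoan`, `well_sequenced` (logical), one row per species, file
#'   order preserved.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("code\tname\tclade\tis_metazoan\twell_sequenced",
#'              "tad\tTrichoplax adhaerens\tPlacozoa\ttrue\ttrue"), tf)
#' read_species_table(tf)
read_species_table <- function(path) {
  df <- readr::read_tsv(path, comment = "#", progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  check_columns(df, c("code", "name", "clade", "is_metazoan", "well_sequenced"),
                "species table")
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate species code(s): %s", paste(dup, collapse = ", ")))
  }
  bad <- df$code[!nzchar(df$code) | grepl("[|[:space:]]", df$code)]
  if (length(bad) > 0 || anyNA(df$code)) {
    abort(sprintf("Invalid species code(s): %s",
                  paste(unique(bad), collapse = ", ")))
  }
  if (anyNA(df$clade) || any(!nzchar(df$clade))) {
    abort("Every species needs a non-empty clade label.")
  }
  tibble(
    code = df$code,
    name = df$name,
    clade = df$clade,
    is_metazoan = parse_bool(df$is_metazoan, "is_metazoan"),
    well_sequenced = parse_bool(df$well_sequenced, "well_sequenced")
  )
}

#' Write a species table
#'
#' @param species Tibble as returned by [read_species_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(species, path) {
  check_columns(species, c("code", "name", "clade", "is_metazoan", "well_sequenced"))
  out <- species
  out$is_metazoan <- bool_to_text(out$is_metazoan)
  out$well_sequenced <- bool_to_text(out$well_sequenced)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an ortholog groups file
#'
#' Parses the OrthoMCL-style text dialect: one group per line,
#' `"GROUPID: sp|gene sp|gene ..."` with ASCII-whitespace-separated members.
#' Blank lines and `#` comments are skipped. Duplicate members within a line
#' are dropped with a warning; a duplicate group id or a member without `|`
#' is a hard error.
#'
#' @param path Path to a groups file.
#' @return A long tibble with one row per group member and columns
#'   `group_id`, `species` (code prefix) and `gene` (full `species|local`
#'   token). Group order follows the file; members keep line order.
#' @export
read_groups <- function(path) {
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- which(nzchar(trimmed) & !startsWith(trimmed, "#"))
  empty <- tibble(group_id = character(), species = character(), gene = character())
  if (length(keep) == 0) return(empty)
  raw <- trimmed[keep]

  colon <- regexpr(":", raw, fixed = TRUE)
  if (any(colon < 0)) {
    abort(sprintf("Line %d: missing ':' separator.", keep[which(colon < 0)[1]]))
  }
  ids <- trimws(substr(raw, 1, colon - 1))
  if (any(!nzchar(ids) | grepl("[[:space:]]", ids))) {
    abort(sprintf("Line %d: invalid group id.",
                  keep[which(!nzchar(ids) | grepl("[[:space:]]", ids))[1]]))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate group id(s): %s", paste(dup, collapse = ", ")))
  }

  rest <- trimws(substring(raw, colon + 1))
  if (any(!nzchar(rest))) {
    abort(sprintf("Line %d: group '%s' has no members.",
                  keep[which(!nzchar(rest))[1]], ids[which(!nzchar(rest))[1]]))
  }
  members <- strsplit(rest, "[[:space:]]+")
  lens <- lengths(members)
  genes <- unlist(members, use.names = FALSE)
  line_of <- rep(keep, lens)
  bad <- !is_valid_gene_id(genes)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("Line %d: malformed member '%s' (expected 'species|local').",
                  line_of[i], genes[i]))
  }

  out <- tibble(group_id = rep(ids, lens), gene = genes)
  dup_member <- duplicated(out)
  if (any(dup_member)) {
    warn(sprintf("Dropped %d duplicate member(s) within group(s): %s",
                 sum(dup_member),
                 paste(unique(out$group_id[dup_member]), collapse = ", ")))
    out <- out[!dup_member, ]
  }
  tibble(group_id = out$group_id,
         species = gene_species(out$gene),
         gene = out$gene)
}

#' Write an ortholog groups file in canonical form
#'
#' Groups are sorted by id and members lexicographically, so that
#' `read_groups(write_groups(x))` round-trips byte-identically on canonical
#' collections.
#'
#' @param groups Long tibble with columns `group_id` and `gene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  check_columns(groups, c("group_id", "gene"))
  g <- distinct(groups, .data$group_id, .data$gene)
  g <- arrange(g, .data$group_id, .data$gene)
  body <- tapply(g$gene, g$group_id, paste, collapse = " ")
  writeLines(paste0(names(body), ": ", as.character(body)), path)
  invisible(path)
}

#' Read an RBBH edge list
#'
#' Reads two-column tab-separated reciprocal-best-BLAST-hit gene pairs.
#' Edges are undirected: repeated and reversed duplicates collapse to a
#' single canonical edge (`gene_a < gene_b`); a self-edge or malformed gene
#' identifier is a hard error.
#'
#' @param path Path to a 2-column TSV (no header) of `species|local` tokens.
#' @return A tibble with character columns `gene_a`, `gene_b`, one row per
#'   undirected edge.
#' @export
read_rbbh <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_names = c("gene_a", "gene_b"),
                        col_types = "cc", progress = FALSE)
  if (nrow(df) == 0) return(tibble(gene_a = character(), gene_b = character()))
  check_gene_ids(c(df$gene_a, df$gene_b), "RBBH edge list")
  self <- df$gene_a == df$gene_b
  if (any(self)) {
    abort(sprintf("Self-edge(s) in RBBH input: %s",
                  paste(unique(df$gene_a[self]), collapse = ", ")))
  }
  canon <- tibble(gene_a = pmin(df$gene_a, df$gene_b),
                  gene_b = pmax(df$gene_a, df$gene_b))
  distinct(canon)
}

#' Write an RBBH edge list in canonical form
#'
#' @param rbbh Tibble with columns `gene_a`, `gene_b`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rbbh <- function(rbbh, path) {
  check_columns(rbbh, c("gene_a", "gene_b"))
  canon <- distinct(tibble(gene_a = pmin(rbbh$gene_a, rbbh$gene_b),
                           gene_b = pmax(rbbh$gene_a, rbbh$gene_b)))
  canon <- arrange(canon, .data$gene_a, .data$gene_b)
  readr::write_tsv(canon, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' RBBH degree of a gene into a gene subset
#'
#' Counts the edges incident to `gene` whose other endpoint lies in
#' `subset`. A gene absent from the graph has degree 0.
#'
#' @param rbbh Edge tibble from [read_rbbh()].
#' @param gene Single gene identifier.
#' @param subset Character vector of gene identifiers.
#' @return A non-negative integer.
#' @export
rbbh_degree <- function(rbbh, gene, subset) {
  check_columns(rbbh, c("gene_a", "gene_b"))
  stopifnot(length(gene) == 1)
  sum((rbbh$gene_a == gene & rbbh$gene_b %in% subset) |
      (rbbh$gene_b == gene & rbbh$gene_a %in% subset))
}

#' Species-to-group index
#'
#' @param groups Long groups tibble.
#' @return Tibble with columns `species`, `group_id`: one row per species
#'   per group the species appears in.
#' @export
group_species_index <- function(groups) {
  check_columns(groups, c("group_id", "species"))
  arrange(distinct(groups, .data$species, .data$group_id),
          .data$species, .data$group_id)
}
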