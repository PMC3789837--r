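# Internal helpers shared across modules.

# species prefix of a "species|local" gene token
gene_species <- function(gene) sub("\\|.*$", "", gene)

# local part (everything after the first '|')
gene_local <- function(gene) sub("^[^|]*\\|", "", gene)

# A gene identifier is "<species>|<local>": species token has no whitespace
# or '|'; local token has no whitespace (may itself contain '|').
is_valid_gene_id <- function(gene) {
  grepl("^[^|[:space:]]+\\|[^[:space:]]+$", gene)
}

check_gene_ids <- function(gene, where = "input") {
  bad <- unique(gene[!is_valid_gene_id(gene)])
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed gene identifier(s) in %s (expected 'species|local'): %s",
      where, paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

check_columns <- function(df, cols, where = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  where, paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

# Strict boolean parser for TSV fields; anything outside the accepted
# literals is a hard error naming the offending value.
parse_bool <- function(x, field) {
  low <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[low %in% c("true", "t", "yes", "1")] <- TRUE
  out[low %in% c("false", "f", "no", "0")] <- FALSE
  if (anyNA(out)) {
    abort(sprintf("Unknown boolean literal in column '%s': %s",
                  field, paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

bool_to_text <- function(x) ifelse(x, "true", "false")

# key=value config files ('#' comments, blank lines ignored)
read_kv_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(list())
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) {
    abort(sprintf("Malformed config line (no '='): %s", lines[which(eq < 0)[1]]))
  }
  keys <- trimws(substr(lines, 1, eq - 1))
  vals <- trimws(substring(lines, eq + 1))
  setNames(as.list(vals), keys)
}

split_csv_field <- function(x) {
  if (is.null(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}
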