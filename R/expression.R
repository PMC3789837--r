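#' Tissue keyword scheme
#'
#' Boolean keyword stems used to classify free-text expression
#' descriptions into six tissue types. Matching is plain case-insensitive
#' substring search (no word boundaries), so stems like `"intestin"` and
#' `"germ"` hit `"intestine"`/`"intestinal"` and `"germline"`.
#'
#' @return Named list of character vectors (one element per tissue).
#' @export
tissue_keywords <- function() {
  list(
    neuronal = c("nerv", "neuron"),
    muscle = c("muscle", "myo"),
    intestinal = c("gut", "intestin"),
    secretory_excretory = c("gland", "secretory", "excretory"),
    hypodermal = c("hypoderm", "epiderm"),
    reproductive = c("uter", "gonad", "germ", "sperm", "oocyt", "reproduct")
  )
}

#' Classify expression descriptions into tissue flags
#'
#' Deterministic, idempotent, case-insensitive keyword classification: a
#' tissue flag is TRUE iff at least one of its keyword stems occurs as a
#' substring of the text. Empty text yields all-FALSE flags.
#'
#' @param text Character vector of free-text expression descriptions.
#' @param keywords Keyword scheme, as from [tissue_keywords()].
#' @return Tibble with one row per input text and one logical column per
#'   tissue.
#' @export
#' @examples
#' classify_expression(c("pan-neuronal expression", "body wall muscle and gonad"))
classify_expression <- function(text, keywords = tissue_keywords()) {
  low <- stringr::str_to_lower(ifelse(is.na(text), "", text))
  flags <- lapply(keywords, function(stems) {
    hit <- rep(FALSE, length(low))
    for (s in stems) {
      hit <- hit | stringr::str_detect(low, stringr::fixed(tolower(s)))
    }
    hit
  })
  as_tibble(flags)
}

#' Expression summary of a gene set
#'
#' Counts, per tissue, the genes expressed in that tissue at all
#' (`n_any`) and the genes expressed in that tissue exclusively
#' (`n_specific`: exactly one of the six flags TRUE). Denominators are the
#' genes of the set with a non-empty expression description.
#'
#' @param expression Tibble with columns `gene`, `text`.
#' @param genes Optional character vector restricting the set; defaults to
#'   all genes in `expression`.
#' @param keywords Keyword scheme.
#' @return Tibble `tissue`, `n_specific`, `n_any`, `n_annotated`,
#'   `prop_specific`, `prop_any`.
#' @export
expression_summary <- function(expression, genes = NULL,
                               keywords = tissue_keywords()) {
  check_columns(expression, c("gene", "text"))
  ex <- expression
  if (!is.null(genes)) ex <- ex[ex$gene %in% genes, ]
  ex <- ex[!is.na(ex$text) & nzchar(trimws(ex$text)), ]
  ex <- distinct(ex, .data$gene, .keep_all = TRUE)
  n_annotated <- nrow(ex)
  flags <- classify_expression(ex$text, keywords)
  n_flags <- rowSums(as.matrix(flags))
  out <- tibble(
    tissue = names(keywords),
    n_specific = vapply(names(keywords), function(t)
      sum(flags[[t]] & n_flags == 1L), integer(1), USE.NAMES = FALSE),
    n_any = vapply(names(keywords), function(t)
      sum(flags[[t]]), integer(1), USE.NAMES = FALSE),
    n_annotated = n_annotated
  )
  if (n_annotated > 0) {
    out$prop_specific <- out$n_specific / n_annotated
    out$prop_any <- out$n_any / n_annotated
  } else {
    out$prop_specific <- NA_real_
    out$prop_any <- NA_real_
  }
  out
}

#' Reshape an expression summary for set comparison
#'
#' Produces the `measure`, `k`, `n` layout [compare_sets_fisher()] expects,
#' with one row per tissue for the chosen panel.
#'
#' @param summary Output of [expression_summary()].
#' @param panel `"any"` (all expression) or `"specific"` (tissue-specific
#'   only).
#' @return Tibble `measure`, `k`, `n`.
#' @export
expression_counts <- function(summary, panel = c("any", "specific")) {
  panel <- match.arg(panel)
  col <- if (panel == "any") "n_any" else "n_specific"
  tibble(measure = paste0(summary$tissue, "_", panel),
         k = summary[[col]],
         n = summary$n_annotated)
}
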