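#' Category enrichment of a gene set
#'
#' Hypergeometric over-/under-representation of each annotation category
#' in a foreground gene set against a background, with Benjamini-Hochberg
#' correction. Genes without any category annotation are excluded from
#' both the foreground and background denominators (the population is
#' "all genes with category annotations"). Both one-sided tails are
#' reported and each tail family is BH-adjusted separately across
#' categories; the reported direction is the smaller tail.
#'
#' @param categories Tibble with columns `gene`, `category` (one row per
#'   gene-category assignment; genes may carry several categories).
#' @param foreground Character vector of foreground genes; must be a
#'   subset of `background`.
#' @param background Character vector of background genes.
#' @param alpha Significance level for the `significant` flag (on `q`).
#' @return An `enrichment_table` tibble, one row per category with at
#'   least one annotated background gene: `category`, `k` (foreground in
#'   category), `n` (annotated foreground), `K` (background in category),
#'   `N` (annotated background), `p_over`, `p_under`, `q_over`, `q_under`,
#'   `direction`, `q`, `significant`; sorted by `q`.
#' @export
enrich_categories <- function(categories, foreground, background,
                              alpha = 0.05) {
  check_columns(categories, c("gene", "category"))
  foreground <- unique(foreground)
  background <- unique(background)
  outside <- setdiff(foreground, background)
  if (length(outside) > 0) {
    abort(sprintf("Foreground gene(s) missing from background: %s",
                  paste(utils::head(outside, 5), collapse = ", ")))
  }
  annotated <- unique(categories$gene)
  fg <- intersect(foreground, annotated)
  bg <- intersect(background, annotated)
  if (length(fg) == 0) {
    abort("No annotated foreground genes; enrichment is undefined.")
  }
  n <- length(fg)
  N <- length(bg)

  cat_bg <- categories[categories$gene %in% bg, ]
  cat_bg <- distinct(cat_bg, .data$gene, .data$category)
  K_tbl <- count(cat_bg, .data$category, name = "K")
  k_tbl <- count(cat_bg[cat_bg$gene %in% fg, ], .data$category, name = "k")
  out <- left_join(K_tbl, k_tbl, by = "category")
  out$k <- as.integer(ifelse(is.na(out$k), 0L, out$k))
  out$n <- n
  out$N <- N
  out$p_over <- hypergeom_tail(out$k, out$n, out$K, out$N, "over")
  out$p_under <- hypergeom_tail(out$k, out$n, out$K, out$N, "under")
  out$q_over <- bh_adjust(out$p_over)
  out$q_under <- bh_adjust(out$p_under)
  out$direction <- ifelse(out$p_over <= out$p_under, "over", "under")
  out$q <- ifelse(out$direction == "over", out$q_over, out$q_under)
  out$significant <- out$q < alpha
  out <- out[c("category", "k", "n", "K", "N", "p_over", "p_under",
               "q_over", "q_under", "direction", "q", "significant")]
  out <- arrange(out, .data$q, .data$category)
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_table", class(tibble()))
  out
}

#' @method glance enrichment_table
#' @export
glance.enrichment_table <- function(x, ...) {
  tibble(
    n_categories = nrow(x),
    n_foreground = if (nrow(x) > 0) x$n[1] else 0L,
    n_background = if (nrow(x) > 0) x$N[1] else 0L,
    n_significant = sum(x$significant),
    n_over = sum(x$significant & x$direction == "over"),
    n_under = sum(x$significant & x$direction == "under"),
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' @method tidy enrichment_table
#' @export
tidy.enrichment_table <- function(x, ...) {
  out <- x
  attr(out, "alpha") <- NULL
  class(out) <- class(tibble())
  out
}
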