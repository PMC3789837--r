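#' RNAi phenotype class map
#'
#' Groups curated RNAi phenotype codes into three super-classes:
#' `essential` (lethality/sterility), `development` (growth and body-shape
#' defects) and `movement` (motility and egg-laying defects). The three
#' sets must be pairwise disjoint. `other` lists codes that are recognised
#' (they count as an observed phenotype) but belong to no class.
#'
#' @param essential,development,movement,other Character vectors of
#'   phenotype codes.
#' @return A `phenotype_class_map` list.
#' @export
phenotype_class_map <- function(
    essential = c("Emb", "Ste", "Stp", "Lvl", "Adl"),
    development = c("Gro", "Lva", "Dpy", "Bmd", "Bli", "Slm", "Lon", "Sma",
                    "Pvl", "Muv"),
    movement = c("Unc", "Prl", "Rol", "Egl"),
    other = c("Clr", "Him", "Mlt", "Sck", "Rup")) {
  sets <- list(essential = essential, development = development,
               movement = movement)
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]])) > 0) {
        abort(sprintf("Phenotype classes '%s' and '%s' share codes.",
                      names(sets)[i], names(sets)[j]))
      }
    }
  }
  other <- setdiff(other, unlist(sets))
  structure(c(sets, list(other = other)), class = "phenotype_class_map")
}

#' Classify genes by RNAi phenotype codes
#'
#' A gene belongs to a class iff it carries at least one code of that
#' class; multi-class membership is allowed. Codes outside the class map
#' (including its `other` set) trigger a warning and are ignored. Genes in
#' `genes` without any (recognised) code get `any_phenotype = FALSE` —
#' they still count in the any-phenotype denominator, which is the set of
#' genes with RNAi data.
#'
#' @param phenotypes Tibble with columns `gene`, `code`.
#' @param genes Character vector: the gene set with RNAi data (the
#'   denominator for the any-phenotype proportion).
#' @param class_map A [phenotype_class_map()].
#' @return Tibble with one row per gene in `genes`: `gene`,
#'   `any_phenotype`, `essential`, `development`, `movement` (logical).
#' @export
classify_phenotypes <- function(phenotypes, genes,
                                class_map = phenotype_class_map()) {
  stopifnot(inherits(class_map, "phenotype_class_map"))
  check_columns(phenotypes, c("gene", "code"))
  genes <- unique(genes)
  ph <- phenotypes[phenotypes$gene %in% genes, ]
  known <- unlist(class_map, use.names = FALSE)
  unknown <- setdiff(unique(ph$code), known)
  if (length(unknown) > 0) {
    warn(sprintf("Ignoring unknown phenotype code(s): %s",
                 paste(unknown, collapse = ", ")))
    ph <- ph[ph$code %in% known, ]
  }
  flag_for <- function(codes) genes %in% unique(ph$gene[ph$code %in% codes])
  tibble(
    gene = genes,
    any_phenotype = genes %in% unique(ph$gene),
    essential = flag_for(class_map$essential),
    development = flag_for(class_map$development),
    movement = flag_for(class_map$movement)
  )
}

#' Phenotype-class proportions of a gene set
#'
#' The `any_phenotype` proportion is taken over all genes with RNAi data
#' (every row of the flags table); class proportions are taken over genes
#' displaying at least one phenotype.
#'
#' @param flags Output of [classify_phenotypes()].
#' @return Tibble with columns `measure` (`any_phenotype`, `essential`,
#'   `development`, `movement`), `k`, `n`, `prop`.
#' @export
phenotype_proportions <- function(flags) {
  check_columns(flags, c("gene", "any_phenotype", "essential", "development",
                         "movement"))
  n_rnai <- nrow(flags)
  n_any <- sum(flags$any_phenotype)
  out <- tibble(
    measure = c("any_phenotype", "essential", "development", "movement"),
    k = c(n_any, sum(flags$essential), sum(flags$development),
          sum(flags$movement)),
    n = c(n_rnai, n_any, n_any, n_any)
  )
  out$prop <- ifelse(out$n > 0, out$k / out$n, NA_real_)
  out
}

#' Compare class proportions of two gene sets by Fisher's exact test
#'
#' One 2x2 exact test per measure (in class vs not, set A vs set B), using
#' the two-sided probability-mass convention of [fisher_exact_2x2()].
#'
#' @param props_a,props_b Count tibbles from [phenotype_proportions()] or
#'   [expression_summary()] reshaped to `measure`, `k`, `n`.
#' @param labels Length-2 character vector naming the sets.
#' @return Tibble `measure`, `k_a`, `n_a`, `prop_a`, `k_b`, `n_b`,
#'   `prop_b`, `p_value`.
#' @export
compare_sets_fisher <- function(props_a, props_b, labels = c("A", "B")) {
  check_columns(props_a, c("measure", "k", "n"))
  check_columns(props_b, c("measure", "k", "n"))
  joined <- inner_join(props_a, props_b, by = "measure",
                       suffix = c("_a", "_b"))
  joined$p_value <- vapply(seq_len(nrow(joined)), function(i) {
    fisher_exact_2x2(joined$k_a[i], joined$n_a[i] - joined$k_a[i],
                     joined$k_b[i], joined$n_b[i] - joined$k_b[i])
  }, numeric(1))
  out <- tibble(
    measure = joined$measure,
    k_a = joined$k_a, n_a = joined$n_a,
    prop_a = ifelse(joined$n_a > 0, joined$k_a / joined$n_a, NA_real_),
    k_b = joined$k_b, n_b = joined$n_b,
    prop_b = ifelse(joined$n_b > 0, joined$k_b / joined$n_b, NA_real_),
    p_value = joined$p_value
  )
  attr(out, "labels") <- labels
  out
}
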