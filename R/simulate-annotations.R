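# Synthetic annotation bundles with planted category enrichment and
# planted phenotype / expression / interaction structure.

# phrase vocabulary: each tissue's phrases contain only that tissue's
# keyword stems; neutral phrases contain none
tissue_vocabulary <- function() {
  list(
    neuronal = c("expressed in head neurons", "pan-neuronal expression",
                 "subset of nerve cord cells"),
    muscle = c("body wall muscle", "pharyngeal myofilament cells",
               "vulval muscle"),
    intestinal = c("anterior gut cells", "strong intestinal signal"),
    secretory_excretory = c("excretory cell", "gland cells",
                            "secretory system"),
    hypodermal = c("hypodermal seam cells", "epidermis"),
    reproductive = c("gonad arms", "germline", "spermatheca",
                     "uterine cells"),
    neutral = c("pharyngeal cells", "coelomocytes", "tail cells",
                "head mesodermal cell")
  )
}

#' Configuration for a synthetic annotation bundle
#'
#' Per-set probability vectors are recycled to the number of gene sets;
#' the first set plays the role of the focal (e.g. lineage-specific)
#' foreground. The default planted proportions mirror a comparison where
#' the focal set is less often essential and more often neuronally
#' expressed than the conserved control set.
#'
#' @param n_categories Number of functional categories (`C01`, `C02`, ...).
#' @param n_background_extra Extra annotated background-only genes.
#' @param categories_per_gene Integer support for how many categories a
#'   gene carries.
#' @param enriched_folds Named numeric vector: sampling-weight fold change
#'   of those categories in the first gene set (>1 over-, <1
#'   under-represented).
#' @param p_any_phenotype Per-set probability that a gene with RNAi data
#'   shows any phenotype.
#' @param p_essential,p_development,p_movement Per-set class probabilities
#'   conditional on showing a phenotype (classes drawn independently; a
#'   phenotype-bearing gene hitting no class receives an out-of-class
#'   code).
#' @param p_expression_annotated Per-set probability of having an
#'   expression description.
#' @param p_tissue Named list tissue -> per-set any-expression
#'   probability.
#' @param p_interaction_within Per-set within-set edge density.
#' @param p_interaction_cross Cross-set edge density.
#' @param omim_key_probs Named probabilities over phenotype map keys.
#' @param p_uncharacterized Per-set probability that a gene lacks all
#'   three characterization flags.
#' @param seed Integer seed.
#' @return A validated `annotation_config` list.
#' @export
annotation_config <- function(n_categories = 20L,
                              n_background_extra = 2000L,
                              categories_per_gene = 1:3,
                              enriched_folds = c(C01 = 4, C02 = 0.25),
                              p_any_phenotype = c(0.55, 0.74),
                              p_essential = c(0.56, 0.80),
                              p_development = c(0.17, 0.09),
                              p_movement = c(0.07, 0.03),
                              p_expression_annotated = c(0.70, 0.70),
                              p_tissue = list(
                                neuronal = c(0.72, 0.54),
                                muscle = c(0.30, 0.30),
                                intestinal = c(0.25, 0.38),
                                secretory_excretory = c(0.10, 0.10),
                                hypodermal = c(0.15, 0.15),
                                reproductive = c(0.25, 0.25)),
                              p_interaction_within = c(0.002, 0.002),
                              p_interaction_cross = 0.0008,
                              omim_key_probs = c(`1` = 0.42, `2` = 0.21,
                                                 `3` = 0.16, `4` = 0.21),
                              p_uncharacterized = c(0.10, 0.05),
                              seed = 1L) {
  probs <- c(p_any_phenotype, p_essential, p_development, p_movement,
             p_expression_annotated, unlist(p_tissue),
             p_interaction_within, p_interaction_cross, p_uncharacterized)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (n_categories < 1) abort("Need at least one category.")
  bad <- setdiff(names(enriched_folds),
                 sprintf("C%02d", seq_len(n_categories)))
  if (length(bad) > 0) {
    abort(sprintf("enriched_folds names outside the category namespace: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(list(n_categories = as.integer(n_categories),
                 n_background_extra = as.integer(n_background_extra),
                 categories_per_gene = as.integer(categories_per_gene),
                 enriched_folds = enriched_folds,
                 p_any_phenotype = p_any_phenotype,
                 p_essential = p_essential,
                 p_development = p_development,
                 p_movement = p_movement,
                 p_expression_annotated = p_expression_annotated,
                 p_tissue = p_tissue,
                 p_interaction_within = p_interaction_within,
                 p_interaction_cross = p_interaction_cross,
                 omim_key_probs = omim_key_probs,
                 p_uncharacterized = p_uncharacterized,
                 seed = as.integer(seed)),
            class = "annotation_config")
}

# sample n_edges unordered pairs (i < j) uniformly without replacement
sample_within_pairs <- function(genes, density) {
  n <- length(genes)
  np <- n * (n - 1) / 2
  if (np == 0) return(tibble(gene_a = character(), gene_b = character()))
  n_edges <- rbinom(1, np, density)
  if (n_edges == 0) return(tibble(gene_a = character(), gene_b = character()))
  k <- sort(sample.int(np, n_edges))
  cum <- cumsum(seq_len(n - 1)) # pairs (1..j-1, j) for j = 2..n
  j <- findInterval(k - 1, c(0, cum)) # index into j = 2..n
  i <- k - c(0, cum)[j]
  tibble(gene_a = genes[i], gene_b = genes[j + 1])
}

sample_cross_pairs <- function(genes_a, genes_b, density) {
  np <- length(genes_a) * length(genes_b)
  if (np == 0) return(tibble(gene_a = character(), gene_b = character()))
  n_edges <- rbinom(1, np, density)
  if (n_edges == 0) return(tibble(gene_a = character(), gene_b = character()))
  k <- sample.int(np, n_edges)
  i <- ((k - 1) %% length(genes_a)) + 1
  j <- ((k - 1) %/% length(genes_a)) + 1
  tibble(gene_a = genes_a[i], gene_b = genes_b[j])
}

#' Simulate an annotation bundle with planted structure
#'
#' Samples per-gene annotations for disjoint gene sets: categories with
#' configurable fold enrichment in the first set, RNAi phenotype codes
#' realising planted any-phenotype and class probabilities, expression
#' descriptions concatenating tissue phrases so that keyword
#' classification recovers the planted flags exactly, within-/cross-set
#' interaction edges, OMIM phenotype map keys and characterization flags.
#' Planted per-gene truth is recorded in the bundle's `truth` element.
#'
#' @param gene_sets Named list of disjoint character vectors; the first
#'   set is the foreground.
#' @param config An [annotation_config()].
#' @param seed Seed override (defaults to the config's seed).
#' @param class_map Phenotype class map used to pick codes.
#' @return An `annotation_bundle` list with elements `categories`
#'   (`gene`, `category`), `phenotypes` (`gene`, `code`), `rnai_genes`,
#'   `expression` (`gene`, `text`), `interactions` (`gene_a`, `gene_b`),
#'   `omim` (`gene`, `map_key`), `characterized`, `gene_sets`, `truth`
#'   and `config`.
#' @export
simulate_annotations <- function(gene_sets, config = annotation_config(),
                                 seed = config$seed,
                                 class_map = phenotype_class_map()) {
  stopifnot(inherits(config, "annotation_config"))
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    abort("gene_sets must be a named list.")
  }
  all_genes <- unlist(gene_sets, use.names = FALSE)
  if (anyDuplicated(all_genes)) abort("gene_sets must be disjoint.")
  n_sets <- length(gene_sets)
  set.seed(seed)

  rcl <- function(p) rep_len(p, n_sets)
  p_any <- rcl(config$p_any_phenotype)
  p_ess <- rcl(config$p_essential)
  p_dev <- rcl(config$p_development)
  p_mov <- rcl(config$p_movement)
  p_expr <- rcl(config$p_expression_annotated)
  p_tis <- lapply(config$p_tissue, rcl)
  p_within <- rcl(config$p_interaction_within)
  p_unchar <- rcl(config$p_uncharacterized)

  set_of <- rep(names(gene_sets), lengths(gene_sets))

  # --- categories -----------------------------------------------------
  cats <- sprintf("C%02d", seq_len(config$n_categories))
  extra <- if (config$n_background_extra > 0)
    sprintf("bgx%05d", seq_len(config$n_background_extra)) else character()
  cat_genes <- c(all_genes, extra)
  is_fg <- cat_genes %in% gene_sets[[1]]
  base_w <- rep(1, config$n_categories)
  fg_w <- base_w
  fg_w[match(names(config$enriched_folds), cats)] <-
    config$enriched_folds
  n_per <- sample(config$categories_per_gene, length(cat_genes),
                  replace = TRUE)
  picks <- lapply(seq_along(cat_genes), function(i) {
    w <- if (is_fg[i]) fg_w else base_w
    sample(cats, n_per[i], prob = w)
  })
  categories <- tibble(gene = rep(cat_genes, n_per),
                       category = unlist(picks, use.names = FALSE))

  # --- phenotypes -----------------------------------------------------
  n_all <- length(all_genes)
  si <- match(set_of, names(gene_sets))
  any_ph <- runif(n_all) < p_any[si]
  ess <- any_ph & runif(n_all) < p_ess[si]
  dev <- any_ph & runif(n_all) < p_dev[si]
  mov <- any_ph & runif(n_all) < p_mov[si]
  none <- any_ph & !ess & !dev & !mov
  code_rows <- list(
    tibble(gene = all_genes[ess],
           code = sample(class_map$essential, sum(ess), replace = TRUE)),
    tibble(gene = all_genes[dev],
           code = sample(class_map$development, sum(dev), replace = TRUE)),
    tibble(gene = all_genes[mov],
           code = sample(class_map$movement, sum(mov), replace = TRUE)),
    tibble(gene = all_genes[none],
           code = sample(class_map$other, sum(none), replace = TRUE))
  )
  phenotypes <- arrange(bind_rows(code_rows), .data$gene)

  # --- expression -----------------------------------------------------
  vocab <- tissue_vocabulary()
  expr_ann <- runif(n_all) < p_expr[si]
  tissue_flags <- vapply(names(p_tis), function(t)
    expr_ann & runif(n_all) < p_tis[[t]][si], logical(n_all))
  if (is.null(dim(tissue_flags))) {
    tissue_flags <- matrix(tissue_flags, nrow = n_all,
                           dimnames = list(NULL, names(p_tis)))
  }
  texts <- vapply(seq_len(n_all), function(i) {
    if (!expr_ann[i]) return(NA_character_)
    on <- names(p_tis)[tissue_flags[i, ]]
    if (length(on) == 0) return(sample(vocab$neutral, 1))
    paste(vapply(on, function(t) sample(vocab[[t]], 1), character(1)),
          collapse = "; ")
  }, character(1))
  expression <- tibble(gene = all_genes[expr_ann],
                       text = texts[expr_ann])

  # --- interactions ---------------------------------------------------
  edges <- list()
  for (s in seq_len(n_sets)) {
    edges[[length(edges) + 1]] <-
      sample_within_pairs(gene_sets[[s]], p_within[s])
  }
  if (n_sets >= 2) {
    for (s in 2:n_sets) {
      edges[[length(edges) + 1]] <-
        sample_cross_pairs(gene_sets[[1]], gene_sets[[s]],
                           config$p_interaction_cross)
    }
  }
  interactions <- bind_rows(edges)
  if (nrow(interactions) > 0) {
    interactions <- distinct(
      tibble(gene_a = pmin(interactions$gene_a, interactions$gene_b),
             gene_b = pmax(interactions$gene_a, interactions$gene_b)))
  }

  # --- disease keys and characterization ------------------------------
  keys <- as.integer(names(config$omim_key_probs))
  omim <- tibble(gene = all_genes,
                 map_key = sample(keys, n_all, replace = TRUE,
                                  prob = config$omim_key_probs))
  unchar <- runif(n_all) < p_unchar[si]
  up <- !unchar & runif(n_all) < 0.9
  wb <- !unchar & runif(n_all) < 0.7
  pm <- !unchar & runif(n_all) < 0.8
  fixup <- !unchar & !up & !wb & !pm
  up[fixup] <- TRUE
  characterized <- tibble(gene = all_genes, uniprot_annotated = up,
                          wormbase_described = wb, pubmed_hit = pm)

  truth <- list(
    phenotype_flags = tibble(gene = all_genes, set = set_of,
                             any_phenotype = any_ph, essential = ess,
                             development = dev, movement = mov),
    tissue_flags = bind_cols(
      tibble(gene = all_genes, set = set_of, annotated = expr_ann),
      as_tibble(tissue_flags)),
    enriched_folds = config$enriched_folds
  )

  structure(list(categories = categories, phenotypes = phenotypes,
                 rnai_genes = all_genes, expression = expression,
                 interactions = interactions, omim = omim,
                 characterized = characterized, gene_sets = gene_sets,
                 truth = truth, config = config),
            class = "annotation_bundle")
}

#' Write an annotation bundle as TSV tables
#'
#' Multi-valued fields are semicolon-joined; `phenotypes.tsv` carries one
#' row per gene with RNAi data (empty code list allowed).
#'
#' @param bundle An `annotation_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_annotations <- function(bundle, dir) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cat_join <- summarise(group_by(bundle$categories, .data$gene),
                        categories = paste(sort(.data$category),
                                           collapse = ";"),
                        .groups = "drop")
  readr::write_tsv(cat_join, file.path(dir, "categories.tsv"),
                   progress = FALSE)
  ph <- summarise(group_by(bundle$phenotypes, .data$gene),
                  codes = paste(sort(.data$code), collapse = ";"),
                  .groups = "drop")
  ph <- left_join(tibble(gene = bundle$rnai_genes), ph, by = "gene")
  ph$codes[is.na(ph$codes)] <- ""
  readr::write_tsv(ph, file.path(dir, "phenotypes.tsv"), progress = FALSE)
  readr::write_tsv(bundle$expression, file.path(dir, "expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$interactions, file.path(dir, "interactions.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$omim, file.path(dir, "omim.tsv"), progress = FALSE)
  ch <- bundle$characterized
  for (col in c("uniprot_annotated", "wormbase_described", "pubmed_hit")) {
    ch[[col]] <- bool_to_text(ch[[col]])
  }
  readr::write_tsv(ch, file.path(dir, "characterized.tsv"), progress = FALSE)
  gs <- tibble(gene = unlist(bundle$gene_sets, use.names = FALSE),
               set = rep(names(bundle$gene_sets),
                         lengths(bundle$gene_sets)))
  readr::write_tsv(gs, file.path(dir, "gene_sets.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read an annotation bundle from a directory of TSV tables
#'
#' Inverse of [write_annotations()] (planted truth is not recoverable
#' from disk). Missing tables yield empty elements.
#'
#' @param dir Directory holding the tables.
#' @return An `annotation_bundle` (without `truth`/`config`).
#' @export
read_annotations <- function(dir) {
  rd <- function(file, col_types) {
    p <- file.path(dir, file)
    if (!file.exists(p)) return(NULL)
    readr::read_tsv(p, col_types = col_types, progress = FALSE)
  }
  cat_raw <- rd("categories.tsv", "cc")
  categories <- if (is.null(cat_raw) || nrow(cat_raw) == 0) {
    tibble(gene = character(), category = character())
  } else {
    lst <- strsplit(cat_raw$categories, ";", fixed = TRUE)
    tibble(gene = rep(cat_raw$gene, lengths(lst)),
           category = unlist(lst, use.names = FALSE))
  }
  ph_raw <- rd("phenotypes.tsv", "cc")
  rnai_genes <- character()
  phenotypes <- tibble(gene = character(), code = character())
  if (!is.null(ph_raw) && nrow(ph_raw) > 0) {
    rnai_genes <- ph_raw$gene
    codes <- ifelse(is.na(ph_raw$codes), "", ph_raw$codes)
    lst <- strsplit(codes, ";", fixed = TRUE)
    keep <- lengths(lst) > 0
    phenotypes <- tibble(gene = rep(ph_raw$gene, lengths(lst)),
                         code = unlist(lst, use.names = FALSE))
    phenotypes <- phenotypes[nzchar(phenotypes$code), ]
  }
  expr <- rd("expression.tsv", "cc") %||%
    tibble(gene = character(), text = character())
  inter <- rd("interactions.tsv", "cc") %||%
    tibble(gene_a = character(), gene_b = character())
  omim <- rd("omim.tsv", "ci") %||%
    tibble(gene = character(), map_key = integer())
  ch_raw <- rd("characterized.tsv", "cccc")
  characterized <- if (is.null(ch_raw)) {
    tibble(gene = character(), uniprot_annotated = logical(),
           wormbase_described = logical(), pubmed_hit = logical())
  } else {
    tibble(gene = ch_raw$gene,
           uniprot_annotated = parse_bool(ch_raw$uniprot_annotated,
                                          "uniprot_annotated"),
           wormbase_described = parse_bool(ch_raw$wormbase_described,
                                           "wormbase_described"),
           pubmed_hit = parse_bool(ch_raw$pubmed_hit, "pubmed_hit"))
  }
  gs_raw <- rd("gene_sets.tsv", "cc")
  gene_sets <- if (is.null(gs_raw)) list() else
    split(gs_raw$gene, gs_raw$set)
  structure(list(categories = categories, phenotypes = phenotypes,
                 rnai_genes = rnai_genes, expression = expr,
                 interactions = inter, omim = omim,
                 characterized = characterized, gene_sets = gene_sets,
                 truth = NULL, config = NULL),
            class = "annotation_bundle")
}
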