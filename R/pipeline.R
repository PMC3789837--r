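# Config-driven end-to-end runs. Configs are flat key=value files (or
# named lists); logs go to stderr via message(), data to files only.

#' Read a flat key=value run configuration
#'
#' @param path Path to a config file (`#` comments and blank lines
#'   ignored).
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  read_kv_file(path)
}

as_config <- function(config) {
  if (is.character(config) && length(config) == 1) read_run_config(config)
  else as.list(config)
}

require_inputs <- function(cfg, keys) {
  for (k in keys) {
    if (is.null(cfg[[k]])) abort(sprintf("Config key '%s' is required.", k))
    if (!file.exists(cfg[[k]])) {
      abort(sprintf("Input path for '%s' does not exist: %s", k, cfg[[k]]))
    }
  }
}

#' Run the classification stage
#'
#' Reads groups, species table and (optionally) RBBH edges and a schema
#' config, classifies every group, partitions the lineage-specific groups
#' by the focal species, optionally computes core-gene coverage, and
#' writes `classification.tsv`, `coverage.tsv` (when a reference list is
#' given) and `summary.json` to the output directory. Outputs are
#' deterministic given the inputs; any input error aborts before anything
#' is written.
#'
#' @param config Named list or path to a key=value file with keys:
#'   `groups`, `species` (required); `rbbh`, `schema`, `reference`
#'   (optional paths); `out` (output directory, default `"."`).
#' @return Invisibly, a list with `classification`, `coverage` (or
#'   `NULL`) and `summary`.
#' @export
run_classify <- function(config) {
  cfg <- as_config(config)
  require_inputs(cfg, c("groups", "species"))
  for (k in c("rbbh", "schema", "reference")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      abort(sprintf("Input path for '%s' does not exist: %s", k, cfg[[k]]))
    }
  }
  species <- read_species_table(cfg$species)
  groups <- read_groups(cfg$groups)
  rbbh <- if (!is.null(cfg$rbbh)) read_rbbh(cfg$rbbh) else NULL
  schema <- if (!is.null(cfg$schema)) read_clade_schema(cfg$schema)
  else default_clade_schema(species)

  message(sprintf("Classifying %d groups across %d species ...",
                  length(unique(groups$group_id)), nrow(species)))
  cls <- classify_groups(groups, schema, rbbh)
  summ <- glance(cls)

  coverage <- NULL
  cov_summary <- NULL
  if (!is.null(cfg$reference)) {
    ref_ids <- readLines(cfg$reference, warn = FALSE)
    ref_ids <- trimws(ref_ids)
    ref_ids <- ref_ids[nzchar(ref_ids) & !startsWith(ref_ids, "#")]
    coverage <- coverage_report(groups, ref_ids, species)
    counted <- coverage$code %in% schema$counted_metazoans
    with_focal <- counted | (!is.null(schema$focal_species) &
                               coverage$code %in% schema$focal_species)
    cov_summary <- list(
      reference_size = coverage$n_reference[1],
      mean_coverage_counted_metazoans = mean(coverage$coverage[counted]),
      mean_coverage_metazoans_with_focal = mean(coverage$coverage[with_focal]),
      min_coverage_metazoan = min(coverage$coverage[with_focal])
    )
  }

  out_dir <- cfg$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_classification(cls, file.path(out_dir, "classification.tsv"))
  if (!is.null(coverage)) {
    write_coverage(coverage, file.path(out_dir, "coverage.tsv"))
  }
  summary <- c(as.list(summ), list(coverage = cov_summary))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(classification = cls, coverage = coverage,
                 summary = summary))
}

#' Run the comparative-statistics stage
#'
#' Consumes an annotation bundle directory (see [write_annotations()])
#' whose `gene_sets.tsv` defines the two gene sets to compare (the first
#' set name in alphabetical order is the foreground unless `set_a`/
#' `set_b` name them), and writes enrichment, phenotype, expression,
#' interaction, disease and uncharacterized-gene reports plus a JSON
#' summary. Empty annotation tables produce empty reports with a warning
#' rather than an error.
#'
#' @param config Named list or path to a key=value file with keys:
#'   `annotations` (bundle directory, required); `set_a`, `set_b`
#'   (set names in `gene_sets.tsv`); `alpha` (significance level,
#'   default 0.05); `out` (output directory, default `"."`).
#' @return Invisibly, a list of the computed tables.
#' @export
run_compare <- function(config) {
  cfg <- as_config(config)
  if (is.null(cfg$annotations) || !dir.exists(cfg$annotations)) {
    abort("Config key 'annotations' must name an existing directory.")
  }
  alpha <- as.numeric(cfg$alpha %||% 0.05)
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1).")
  bundle <- read_annotations(cfg$annotations)
  sets <- bundle$gene_sets
  if (length(sets) < 2) {
    abort("gene_sets.tsv must define at least two gene sets.")
  }
  name_a <- cfg$set_a %||% names(sets)[1]
  name_b <- cfg$set_b %||% setdiff(names(sets), name_a)[1]
  set_a <- sets[[name_a]]
  set_b <- sets[[name_b]]
  out_dir <- cfg$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  summary <- list(set_a = name_a, set_b = name_b,
                  n_a = length(set_a), n_b = length(set_b), alpha = alpha)
  if (!is.null(cfg$classification)) {
    if (!file.exists(cfg$classification)) {
      abort(sprintf("Classification table not found: %s", cfg$classification))
    }
    cls_tbl <- read_classification(cfg$classification)
    summary$classification_labels <- as.list(table(cls_tbl$label))
  }

  # enrichment of set A against all annotated genes
  if (nrow(bundle$categories) > 0) {
    background <- unique(c(set_a, set_b, bundle$categories$gene))
    enr <- enrich_categories(bundle$categories, set_a, background, alpha)
    readr::write_tsv(tidy(enr), file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
    results$enrichment <- enr
    summary$enrichment <- as.list(glance(enr))
  } else {
    warn("Empty category table: skipping enrichment.")
    readr::write_tsv(tibble(category = character()),
                     file.path(out_dir, "enrichment.tsv"), progress = FALSE)
  }

  # phenotype classes
  if (length(bundle$rnai_genes) > 0) {
    flags_a <- classify_phenotypes(bundle$phenotypes,
                                   intersect(bundle$rnai_genes, set_a))
    flags_b <- classify_phenotypes(bundle$phenotypes,
                                   intersect(bundle$rnai_genes, set_b))
    props_a <- phenotype_proportions(flags_a)
    props_b <- phenotype_proportions(flags_b)
    cmp <- compare_sets_fisher(props_a, props_b, c(name_a, name_b))
    readr::write_tsv(cmp, file.path(out_dir, "phenotypes.tsv"),
                     progress = FALSE)
    results$phenotypes <- cmp
    summary$phenotypes <- setNames(as.list(cmp$p_value), cmp$measure)
  } else {
    warn("No RNAi genes: skipping phenotype comparison.")
    readr::write_tsv(tibble(measure = character()),
                     file.path(out_dir, "phenotypes.tsv"), progress = FALSE)
  }

  # expression panels (any and tissue-specific)
  if (nrow(bundle$expression) > 0) {
    sum_a <- expression_summary(bundle$expression, set_a)
    sum_b <- expression_summary(bundle$expression, set_b)
    rows <- list()
    for (panel in c("any", "specific")) {
      rows[[panel]] <- compare_sets_fisher(
        expression_counts(sum_a, panel), expression_counts(sum_b, panel),
        c(name_a, name_b))
    }
    expr_cmp <- bind_rows(rows)
    readr::write_tsv(expr_cmp, file.path(out_dir, "expression.tsv"),
                     progress = FALSE)
    results$expression <- expr_cmp
  } else {
    warn("Empty expression table: skipping expression comparison.")
    readr::write_tsv(tibble(measure = character()),
                     file.path(out_dir, "expression.tsv"), progress = FALSE)
  }

  # interaction partition
  if (nrow(bundle$interactions) > 0) {
    part <- interaction_partition(bundle$interactions, set_a, set_b,
                                  c(name_a, name_b))
    readr::write_tsv(part$counts, file.path(out_dir, "interactions.tsv"),
                     progress = FALSE)
    write_network(part, file.path(out_dir, "network_edges.tsv"))
    results$interactions <- part
    summary$interactions <- as.list(glance(part))
  } else {
    warn("Empty interaction table: skipping partition.")
    readr::write_tsv(tibble(edge_class = character()),
                     file.path(out_dir, "interactions.tsv"), progress = FALSE)
  }

  # disease and uncharacterized screens on the foreground
  disease <- if (nrow(bundle$omim) > 0)
    disease_filter(bundle$omim, set_a) else character()
  writeLines(disease, file.path(out_dir, "disease_genes.txt"))
  summary$n_disease <- length(disease)
  unchar <- if (nrow(bundle$characterized) > 0)
    flag_uncharacterized(bundle$characterized,
                         intersect(set_a, bundle$characterized$gene))
  else character()
  writeLines(unchar, file.path(out_dir, "uncharacterized_genes.txt"))
  summary$n_uncharacterized <- length(unchar)

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$summary <- summary
  invisible(results)
}

#' Run the simulation stage
#'
#' Generates a synthetic world (and derived annotation bundle) and writes
#' everything to disk in the package's file formats. The annotation gene
#' sets are the focal-organism (`cel`) genes of the planted
#' metazoan-core-like classes versus the planted eukaryote-core class.
#'
#' @param config Named list or key=value file path; recognised keys are
#'   the fields of [world_config()] (scalar values).
#' @param seed Integer seed driving all randomness.
#' @param out Output directory.
#' @return Invisibly, a list with `world` and `bundle`.
#' @export
run_simulate <- function(config = list(), seed = 1L, out = ".") {
  cfg <- as_config(config)
  wc_args <- list()
  for (k in c("dropout_rate", "p_focal_present", "paralog_prob")) {
    if (!is.null(cfg[[k]])) wc_args[[k]] <- as.numeric(cfg[[k]])
  }
  if (!is.null(cfg$n_nonmetazoan)) {
    wc_args$n_nonmetazoan <- as.integer(cfg$n_nonmetazoan)
  }
  wc_args$seed <- as.integer(seed)
  wc <- do.call(world_config, wc_args)
  world <- simulate_world(wc)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_world(world, out)

  model_org <- "cel"
  tr <- world$truth
  mz_ids <- tr$group_id[tr$class %in% c("metazoan_core",
                                        "eumetazoan_core_no_focal",
                                        "contaminated_metazoan")]
  euk_ids <- tr$group_id[tr$class == "eukaryote_core"]
  g <- world$groups
  set_a <- unique(g$gene[g$group_id %in% mz_ids & g$species == model_org])
  set_b <- unique(g$gene[g$group_id %in% euk_ids & g$species == model_org])
  bundle <- simulate_annotations(
    list(metazoan = set_a, eukaryote = set_b),
    annotation_config(seed = as.integer(seed) + 1L))
  write_annotations(bundle, file.path(out, "annotations"))
  invisible(list(world = world, bundle = bundle))
}
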