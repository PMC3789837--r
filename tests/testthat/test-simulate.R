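test_that("world generation is seed-deterministic", {
  w1 <- simulate_world(tiny_world_config(seed = 17))
  w2 <- simulate_world(tiny_world_config(seed = 17))
  expect_identical(w1$groups, w2$groups)
  expect_identical(w1$rbbh, w2$rbbh)
  expect_identical(w1$truth, w2$truth)
  w3 <- simulate_world(tiny_world_config(seed = 18))
  expect_false(identical(w1$groups, w3$groups))
})

test_that("planted classes realise their presence patterns pre-dropout", {
  w <- simulate_world(tiny_world_config(seed = 2))
  sc <- w$schema
  pres <- dplyr::distinct(w$groups[c("group_id", "species")])
  by_group <- split(pres$species, pres$group_id)
  tr <- w$truth
  for (i in seq_len(nrow(tr))) {
    sp <- by_group[[tr$group_id[i]]]
    cls <- tr$class[i]
    if (cls %in% c("metazoan_core", "eumetazoan_core_no_focal",
                   "contaminated_metazoan")) {
      expect_true(all(sc$counted_metazoans %in% sp))
      expect_equal(sc$focal_species %in% sp, tr$focal_present[i])
    }
    if (cls == "eukaryote_core") {
      expect_true(all(sc$control_required_species %in% sp))
      expect_length(intersect(sp, sc$control_forbidden_species), 0)
    }
    if (cls == "promiscuous") {
      expect_gte(length(intersect(sp, sc$control_forbidden_species)), 1)
    }
  }
  # truth covers every group exactly once
  expect_setequal(tr$group_id, unique(w$groups$group_id))
  expect_equal(anyDuplicated(tr$group_id), 0)
})

test_that("dropout only removes presence and lowers recall monotonically", {
  clean <- simulate_world(tiny_world_config(seed = 31))
  noisy <- simulate_world(tiny_world_config(seed = 31, dropout_rate = 0.5))
  pres_clean <- dplyr::distinct(clean$groups[c("group_id", "species")])
  pres_noisy <- dplyr::distinct(noisy$groups[c("group_id", "species")])
  # same planting (same seed): every observed pair existed pre-dropout
  expect_equal(nrow(dplyr::anti_join(pres_noisy, pres_clean,
                                     by = c("group_id", "species"))), 0)

  recall_of <- function(w) {
    cls <- tidy(classify_groups(w$groups, w$schema, w$rbbh))
    core <- w$truth$group_id[w$truth$class %in%
                               c("metazoan_core", "eumetazoan_core_no_focal")]
    mean(cls$label[match(core, cls$group_id)] == "metazoan_specific",
         na.rm = TRUE)
  }
  expect_equal(recall_of(clean), 1)
  expect_lt(recall_of(noisy), 1)
})

test_that("worlds round-trip through the file formats and classify identically", {
  w <- simulate_world(tiny_world_config(seed = 23))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  groups <- read_groups(file.path(dir, "groups.txt"))
  species <- read_species_table(file.path(dir, "species.tsv"))
  rbbh <- read_rbbh(file.path(dir, "rbbh.tsv"))
  schema <- read_clade_schema(file.path(dir, "schema.cfg"))
  expect_equal(species, w$species)
  direct <- dplyr::arrange(tidy(classify_groups(w$groups, w$schema, w$rbbh)),
                           group_id)
  reread <- dplyr::arrange(tidy(classify_groups(groups, schema, rbbh)),
                           group_id)
  expect_equal(direct$label, reread$label)
  expect_equal(direct$failed_criteria, reread$failed_criteria)
})

test_that("contamination degrees straddling the threshold split the labels", {
  cfg <- world_config(
    n_groups_per_class = c(contaminated_metazoan = 40),
    dropout_rate = 0, contamination_degrees = c(2, 3, 4, 5),
    n_nonmetazoan = 20, seed = 41)
  w <- simulate_world(cfg)
  cls <- tidy(classify_groups(w$groups, w$schema, w$rbbh))
  el <- expected_labels(w)
  merged <- dplyr::left_join(el, cls[c("group_id", "label")], by = "group_id")
  expect_equal(merged$label, merged$expected_label)
  # the planted degrees genuinely straddle the threshold
  expect_gt(sum(merged$expected_label == "metazoan_specific"), 0)
  expect_gt(sum(merged$expected_label == "other"), 0)
})

test_that("annotation bundles honour planted probabilities", {
  # degenerate: every phenotype-bearing gene is essential
  b1 <- simulate_annotations(list(A = paste0("a", 1:60)),
                             annotation_config(p_any_phenotype = 1,
                                               p_essential = 1, seed = 3))
  f1 <- classify_phenotypes(b1$phenotypes, b1$rnai_genes)
  expect_true(all(f1$essential))

  # planted neuronal any-expression 0.72 recovered within 3 binomial SE
  n <- 376
  b2 <- simulate_annotations(list(A = paste0("a", 1:n)),
                             annotation_config(p_expression_annotated = 1,
                                               seed = 13))
  s <- expression_summary(b2$expression, b2$gene_sets$A)
  p_hat <- s$prop_any[s$tissue == "neuronal"]
  se <- sqrt(0.72 * 0.28 / n)
  expect_lt(abs(p_hat - 0.72), 3 * se)
  # and the keyword classifier recovers the planted flags exactly
  tf <- b2$truth$tissue_flags
  got <- classify_expression(
    b2$expression$text[match(tf$gene, b2$expression$gene)])
  for (t in names(tissue_keywords())) {
    expect_equal(got[[t]], tf[[t]], info = t)
  }

  expect_error(simulate_annotations(list(A = c("x", "y"), B = c("y")),
                                    annotation_config()),
               "disjoint")
})

test_that("annotation bundles round-trip through their TSV formats", {
  b <- simulate_annotations(list(A = paste0("a", 1:40), B = paste0("b", 1:40)),
                            annotation_config(n_background_extra = 50,
                                              seed = 77))
  dir <- withr::local_tempdir()
  write_annotations(b, dir)
  back <- read_annotations(dir)
  expect_setequal(back$rnai_genes, b$rnai_genes)
  expect_equal(dplyr::arrange(back$categories, gene, category),
               dplyr::arrange(b$categories, gene, category))
  expect_equal(dplyr::arrange(back$phenotypes, gene, code),
               dplyr::arrange(b$phenotypes, gene, code))
  expect_equal(dplyr::arrange(back$interactions, gene_a, gene_b),
               dplyr::arrange(b$interactions, gene_a, gene_b))
  expect_equal(back$omim[order(back$omim$gene), ]$map_key,
               b$omim[order(b$omim$gene), ]$map_key)
  expect_setequal(names(back$gene_sets), names(b$gene_sets))
})
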