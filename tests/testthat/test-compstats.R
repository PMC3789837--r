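test_that("hypergeometric tails match enumeration and the tail identity", {
  expect_equal(hypergeom_tail(4, 4, 5, 10, "over"), 5 / 210)
  # forced draw: n == N implies k == K and the upper tail is 1
  expect_equal(hypergeom_tail(5, 10, 5, 10, "over"), 1)
  # k = 0 lower tail equals the single term P(X = 0)
  expect_equal(hypergeom_tail(0, 3, 4, 10, "under"), dhyper(0, 4, 6, 3))

  set.seed(3)
  for (rep in 1:50) {
    N <- sample(2:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(max(0, n - (N - K)):min(n, K), 1)
    for (tail in c("over", "under")) {
      expect_equal(hypergeom_tail(k, n, K, N, tail),
                   hyper_tail_enum(k, n, K, N, tail), tolerance = 1e-12)
    }
  }

  # P(X >= k) + P(X <= k) - P(X = k) == 1, exhaustively on small N
  for (N in 2:12) for (K in 0:N) for (n in 1:N) {
    ks <- max(0, n - (N - K)):min(n, K)
    tot <- hypergeom_tail(ks, n, K, N, "over") +
      hypergeom_tail(ks, n, K, N, "under") - dhyper(ks, K, N - K, n)
    expect_equal(tot, rep(1, length(ks)), tolerance = 1e-12)
  }

  expect_error(hypergeom_tail(5, 4, 5, 10, "over"), "hypergeom")
  expect_error(hypergeom_tail(2, 4, 1, 10, "over"), "hypergeom")
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_true(all(bh_adjust(runif(20)) <= 1))
  set.seed(8)
  for (rep in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_manual(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    # monotone on the sorted scale
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("two-sided Fisher matches exhaustive enumeration over margins", {
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_2x2(2, 3, 3, 2), fisher_enum(2, 3, 3, 2),
               tolerance = 1e-9)
  # exhaustive: every table with total N <= 14
  for (a in 0:4) for (b in 0:4) for (cc in 0:3) for (d in 0:3) {
    if (a + b + cc + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, cc, d), fisher_enum(a, b, cc, d),
                 tolerance = 1e-9)
  }
  # randomized larger tables up to N = 40
  set.seed(12)
  for (rep in 1:400) {
    cells <- as.vector(stats::rmultinom(1, sample(4:40, 1), runif(4)))
    expect_equal(do.call(fisher_exact_2x2, as.list(cells)),
                 do.call(fisher_enum, as.list(cells)), tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("enrichment reports both tails and recovers planted categories", {
  categories <- tibble::tibble(
    gene = c(paste0("f", 1:10), paste0("b", 1:10)),
    category = c(rep("hit", 10), rep("hit", 5), rep("miss", 5)))
  fg <- paste0("f", 1:10)
  bg <- c(fg, paste0("b", 1:10))
  enr <- enrich_categories(categories, fg, bg)
  hit <- enr[enr$category == "hit", ]
  expect_equal(hit$direction, "over")
  expect_lt(hit$p_over, hit$p_under)
  expect_equal(hit$k, 10)
  expect_equal(hit$n, 10)  # annotated foreground genes
  expect_equal(hit$N, 20)  # annotated background genes

  # planted 5-fold enrichment ranks first by q
  b <- simulate_annotations(
    list(A = paste0("a", 1:150), B = paste0("b", 1:150)),
    annotation_config(enriched_folds = c(C05 = 5),
                      n_background_extra = 500, seed = 21))
  bg_all <- unique(c(b$categories$gene, unlist(b$gene_sets)))
  enr2 <- enrich_categories(b$categories, b$gene_sets$A, bg_all)
  expect_equal(enr2$category[1], "C05")
  expect_true(enr2$significant[1])
  expect_equal(enr2$direction[1], "over")

  expect_error(enrich_categories(categories, c(fg, "stranger"), bg),
               "missing from background")
  expect_error(enrich_categories(categories, "unannotated", c("unannotated", bg)),
               "No annotated foreground")
})

test_that("uniform foregrounds keep the false-discovery rate near nominal", {
  set.seed(99)
  n_reps <- 200
  n_cat_sig <- 0
  n_cat_total <- 0
  # fixed null population: 300 genes, 15 categories, no planted structure
  genes <- paste0("g", 1:300)
  categories <- tibble::tibble(
    gene = rep(genes, 2),
    category = sample(sprintf("C%02d", 1:15), 600, replace = TRUE))
  for (r in 1:n_reps) {
    fg <- sample(genes, 40)
    enr <- enrich_categories(categories, fg, genes)
    n_cat_sig <- n_cat_sig + sum(enr$significant)
    n_cat_total <- n_cat_total + nrow(enr)
  }
  rate <- n_cat_sig / n_cat_total
  se <- sqrt(0.05 * 0.95 / n_cat_total)
  expect_lte(rate, 0.05 + 3 * se)
})

test_that("phenotype classes follow the code map and denominators", {
  ph <- tibble::tibble(
    gene = c("g1", "g2", "g2", "g4"),
    code = c("Emb", "Gro", "Unc", "Zzz"))
  expect_warning(
    flags <- classify_phenotypes(ph, c("g1", "g2", "g3", "g4")),
    "Zzz")
  g1 <- flags[flags$gene == "g1", ]
  expect_true(g1$essential && !g1$development && !g1$movement)
  g2 <- flags[flags$gene == "g2", ]
  expect_true(g2$development && g2$movement && !g2$essential)
  # g3 has RNAi data but no codes; g4 only an unknown code
  expect_false(flags$any_phenotype[flags$gene == "g3"])
  expect_false(flags$any_phenotype[flags$gene == "g4"])
  props <- phenotype_proportions(flags)
  expect_equal(props$n[props$measure == "any_phenotype"], 4)
  expect_equal(props$n[props$measure == "essential"], 2)

  expect_error(phenotype_class_map(essential = "Emb", development = "Emb"),
               "share codes")
})

test_that("set comparisons are symmetric and null-calibrated", {
  pa <- tibble::tibble(measure = "essential", k = 30, n = 100)
  pb <- tibble::tibble(measure = "essential", k = 30, n = 100)
  expect_equal(compare_sets_fisher(pa, pb)$p_value, 1)
  pb2 <- tibble::tibble(measure = "essential", k = 55, n = 100)
  p_ab <- compare_sets_fisher(pa, pb2)$p_value
  p_ba <- compare_sets_fisher(pb2, pa)$p_value
  expect_equal(p_ab, p_ba)
})

test_that("expression keywords reproduce the Boolean scheme", {
  fx <- c("pan-neuronal expression", "body wall muscle and gonad",
          "germline", "pharyngeal cells", "GUT GRANULES",
          "hypodermal seam cells; epidermis")
  flags <- classify_expression(fx)
  expect_true(flags$neuronal[1]); expect_equal(sum(unlist(flags[1, ])), 1)
  expect_true(flags$muscle[2] && flags$reproductive[2])
  expect_false(flags$neuronal[2])
  expect_true(flags$reproductive[3])  # substring 'germ'
  expect_false(any(unlist(flags[4, ])))
  expect_true(flags$intestinal[5])    # case-insensitive
  expect_true(flags$hypodermal[6])
  # deterministic and idempotent
  expect_identical(flags, classify_expression(fx))
})

test_that("expression summary separates tissue-specific from any expression", {
  ex <- tibble::tibble(
    gene = c("g1", "g2", "g3"),
    text = c("pan-neuronal expression",
             "head neurons and body wall muscle",
             ""))
  s <- expression_summary(ex)
  expect_equal(s$n_annotated, rep(2, 6))
  neu <- s[s$tissue == "neuronal", ]
  expect_equal(neu$n_any, 2)       # g1 and g2
  expect_equal(neu$n_specific, 1)  # only g1
  mus <- s[s$tissue == "muscle", ]
  expect_equal(mus$n_any, 1)
  expect_equal(mus$n_specific, 0)

  counts <- expression_counts(s, "any")
  expect_equal(counts$k[counts$measure == "neuronal_any"], 2)
})

test_that("interaction partition counts classes and conserves edges", {
  edges <- tibble::tibble(gene_a = c("a1", "a1"), gene_b = c("a2", "b1"))
  part <- interaction_partition(edges, c("a1", "a2"), "b1")
  cn <- part$counts
  expect_equal(cn$n[cn$edge_class == "withinA"], 1)
  expect_equal(cn$n[cn$edge_class == "cross"], 1)
  expect_equal(cn$n[cn$edge_class == "withinB"], 0)
  expect_equal(part$connected$frac_connected, c(1, 1))
  expect_equal(part$n_ignored, 0)

  none <- interaction_partition(edges[0, ], "a1", "b1")
  expect_equal(sum(none$counts$n), 0)
  expect_equal(none$connected$frac_connected, c(0, 0))

  allx <- interaction_partition(
    tibble::tibble(gene_a = "a1", gene_b = "b1"), "a1", "b1")
  expect_equal(allx$counts$prop_pooled[allx$counts$edge_class == "cross"], 1)

  # conservation on a random bundle + ignored edges counted
  b <- simulate_annotations(list(A = paste0("a", 1:80), B = paste0("b", 1:80)),
                            annotation_config(seed = 4))
  extra <- tibble::tibble(gene_a = "zz|1", gene_b = "a1")
  part2 <- interaction_partition(dplyr::bind_rows(b$interactions, extra),
                                 b$gene_sets$A, b$gene_sets$B)
  expect_equal(sum(part2$counts$n) + part2$n_ignored,
               nrow(b$interactions) + 1)

  expect_error(interaction_partition(edges, c("a1", "x"), c("x", "b1")),
               "disjoint")
})

test_that("disease and characterization filters apply their rules", {
  omim <- tibble::tibble(gene = c("g1", "g2", "g3"), map_key = c(3L, 2L, 3L))
  expect_equal(disease_filter(omim, c("g1", "g2", "g3")), c("g1", "g3"))
  expect_equal(disease_filter(omim[0, ], c("g1")), character())
  expect_equal(disease_filter(omim, character()), character())

  ch <- tibble::tibble(
    gene = c("u1", "u2", "u3"),
    uniprot_annotated = c(FALSE, TRUE, FALSE),
    wormbase_described = c(FALSE, FALSE, FALSE),
    pubmed_hit = c(FALSE, FALSE, FALSE))
  expect_equal(flag_uncharacterized(ch, ch$gene), c("u1", "u3"))
  expect_error(flag_uncharacterized(ch, c("u1", "ghost")), "ghost")
  expect_equal(flag_uncharacterized(ch, character()), character())
})
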