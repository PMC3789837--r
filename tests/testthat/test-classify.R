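schema <- standard_schema()
cran <- schema$clade_members$Craniata     # 11 species
arth <- schema$clade_members$Arthropoda   # 8 species
nema <- schema$clade_members$Nematoda     # 3 species

test_that("clade profile counts species once and tracks focal/foreign", {
  codes <- c(cran[1:9], arth[1:6], nema[1:2], "cin", cran[1], cran[1])
  g <- make_group("OG1", codes)
  prof <- clade_profile(g, schema)
  expect_equal(prof$n_Craniata, 9)      # paralogs counted once
  expect_equal(prof$n_Arthropoda, 6)
  expect_equal(prof$n_Nematoda, 2)
  expect_equal(prof$n_Urochordata, 1)
  expect_equal(prof$total_counted_present, 18)
  expect_false(prof$focal_present)
  expect_equal(prof$n_foreign_species, 0)

  focal_only <- clade_profile(make_group("OG2", "tad"), schema)
  expect_equal(focal_only$total_counted_present, 0)
  expect_true(focal_only$focal_present)

  with_yeast <- make_group("OG3", c(cran[1:9], "sce"))
  fm <- foreign_rbbh_links(with_yeast, schema)
  expect_equal(nrow(fm), 1)
  expect_equal(fm$species, "sce")

  unknown <- make_group("OG4", c("hsa", "zzz"))
  expect_error(clade_profile(unknown, schema), "zzz")
})

test_that("foreign-leakage check applies both thresholds per foreign gene", {
  base <- c(cran, arth, nema, "cin", "nve")
  mk <- function(id, foreign) make_group(id, c(base, foreign))
  g0 <- mk("F0", character())
  expect_true(foreign_leakage_check(g0, schema)$pass)

  # 2 foreign species with degrees {3, 1}: pass
  g2 <- mk("F2", c("sce", "ath"))
  sce_gene <- g2$gene[g2$species == "sce"]
  ath_gene <- g2$gene[g2$species == "ath"]
  mz_genes <- g2$gene[g2$species %in% base]
  rbbh <- tibble::tibble(
    gene_a = c(rep(sce_gene, 3), ath_gene),
    gene_b = mz_genes[1:4])
  chk <- foreign_leakage_check(g2, schema, rbbh)
  expect_true(chk$pass)
  expect_equal(chk$max_foreign_links, 3)

  # 1 foreign gene with 4 links: fail on the RBBH rule
  g1 <- mk("F1", "sce")
  sce1 <- g1$gene[g1$species == "sce"]
  mz1 <- g1$gene[g1$species %in% base]
  rbbh4 <- tibble::tibble(gene_a = rep(sce1, 4), gene_b = mz1[1:4])
  chk4 <- foreign_leakage_check(g1, schema, rbbh4)
  expect_false(chk4$pass)
  expect_false(chk4$pass_rbbh)
  expect_true(chk4$pass_species)

  # 3 foreign species, zero links: fail on the species-count rule
  g3 <- mk("F3", c("sce", "ath", "ddi"))
  chk3 <- foreign_leakage_check(g3, schema)
  expect_false(chk3$pass)
  expect_false(chk3$pass_species)
  expect_true(chk3$pass_rbbh)
})

test_that("metazoan-specific label obeys the boundary criteria", {
  # exactly at the clade minima with total 20: metazoan_specific
  at_bound <- c(cran[1:10], arth[1:7], nema[1:2], "cin")
  expect_equal(length(unique(at_bound)), 20)
  cls <- classify_groups(make_group("B1", at_bound), schema)
  expect_equal(cls$label, "metazoan_specific")
  expect_equal(cls$failed_criteria, "")

  # one species fewer (total 19): fails total_min only
  cls19 <- classify_groups(make_group("B2", at_bound[-1]), schema)
  expect_equal(cls19$label, "other")
  expect_equal(cls19$failed_criteria, "total_min")

  # missing both single representatives fails the alternative rule
  no_alt <- c(cran, arth, nema)
  cls_na <- classify_groups(make_group("B3", no_alt), schema)
  expect_equal(cls_na$label, "other")
  expect_match(cls_na$failed_criteria, "alt_representative")

  # rich group with a 5-link yeast ortholog fails only foreign_rbbh
  rich <- make_group("B4", c(cran[1:10], arth, nema, "nve", "cin", "sce"))
  sce_gene <- rich$gene[rich$species == "sce"]
  mz_genes <- rich$gene[rich$species != "sce"]
  rbbh5 <- tibble::tibble(gene_a = rep(sce_gene, 5), gene_b = mz_genes[1:5])
  cls5 <- classify_groups(rich, schema, rbbh5)
  expect_equal(cls5$label, "other")
  expect_equal(cls5$failed_criteria, "foreign_rbbh")
})

test_that("eukaryote-core control rule requires the five species and no prokaryote", {
  five <- c("hsa", "cel", "dme", "sce", "ath")
  ok <- make_group("E1", c(five, cran[2:6], arth[2:5], "ddi"))
  expect_true(unname(is_eukaryote_core(ok, schema)))
  missing_ath <- make_group("E2", setdiff(five, "ath"))
  expect_false(unname(is_eukaryote_core(missing_ath, schema)))
  with_coli <- make_group("E3", c(five, "eco"))
  expect_false(unname(is_eukaryote_core(with_coli, schema)))
})

test_that("labels are invariant under member and group permutation", {
  w <- simulate_world(tiny_world_config(seed = 5))
  cls <- classify_groups(w$groups, w$schema, w$rbbh)
  set.seed(1)
  shuffled <- w$groups[sample(nrow(w$groups)), ]
  cls2 <- classify_groups(shuffled, w$schema, w$rbbh)
  a <- dplyr::arrange(tidy(cls), group_id)
  b <- dplyr::arrange(tidy(cls2), group_id)
  expect_equal(a$label, b$label)
  expect_equal(a$failed_criteria, b$failed_criteria)
})

test_that("adding species moves labels monotonically", {
  # a metazoan_specific group stays metazoan_specific when another counted
  # metazoan is added
  base <- c(cran[1:10], arth[1:7], nema[1:2], "cin")
  grown <- classify_groups(make_group("M1", c(base, "nve")), schema)
  expect_equal(grown$label, "metazoan_specific")
  # an 'other' group cannot become metazoan_specific by adding a foreign
  # species (the foreign criteria only tighten)
  weak <- c(cran[1:5], arth[1:3])
  before <- classify_groups(make_group("M2", weak), schema)
  after <- classify_groups(make_group("M2", c(weak, "sce")), schema)
  expect_equal(before$label, "other")
  expect_equal(after$label, "other")
})

test_that("overlapping criteria fall to metazoan_specific with a warning", {
  both <- make_group("OV1", c(cran, arth, nema, "cin", "nve", "sce", "ath"))
  expect_warning(cls <- classify_groups(both, schema), "both")
  expect_equal(cls$label, "metazoan_specific")
  expect_true(cls$meets_eukaryote_core)
})

test_that("partitioning by the focal species matches planted flags", {
  w <- simulate_world(tiny_world_config(seed = 9))
  cls <- classify_groups(w$groups, w$schema, w$rbbh)
  part <- partition_by_species(cls)
  ms <- tidy(cls)[tidy(cls)$label == "metazoan_specific", ]
  expect_setequal(c(part$present, part$absent), ms$group_id)
  expect_length(intersect(part$present, part$absent), 0)
  truth <- w$truth
  planted_present <- truth$group_id[truth$focal_present &
                                      truth$group_id %in% ms$group_id]
  expect_setequal(part$present, planted_present)

  expect_error(partition_by_species(cls, "zzz"), "Unknown species")

  # empty case: no metazoan-specific groups
  only_other <- classify_groups(make_group("O1", c("hsa", "eco")), schema)
  p0 <- partition_by_species(only_other)
  expect_length(p0$present, 0)
  expect_length(p0$absent, 0)
})

test_that("classification of an empty-ish collection is well-behaved", {
  g <- make_group("Z1", "hsa")
  cls <- classify_groups(g, schema)
  expect_equal(nrow(cls), 1)
  expect_equal(cls$label, "other")
})
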