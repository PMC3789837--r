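ref_fixture <- function() {
  species <- tibble::tibble(
    code = c("aa", "bb"), name = c("A", "B"), clade = c("X", "Y"),
    is_metazoan = c(TRUE, FALSE), well_sequenced = TRUE)
  groups <- dplyr::bind_rows(
    make_group("R1", c("aa", "bb")),
    make_group("R2", c("aa")),
    make_group("R3", c("aa", "bb")),
    make_group("R4", c("bb")),
    make_group("X1", c("bb"))
  )
  list(species = species, groups = groups,
       ref = c("R1", "R2", "R3", "R4"))
}

test_that("coverage is the fraction of reference groups with presence", {
  fx <- ref_fixture()
  cov <- coverage_report(fx$groups, fx$ref, fx$species)
  expect_equal(cov$coverage[cov$code == "aa"], 0.75)
  expect_equal(cov$coverage[cov$code == "bb"], 0.75)
  expect_equal(cov$n_reference, c(4, 4))

  # full and zero coverage
  species3 <- dplyr::bind_rows(fx$species,
    tibble::tibble(code = "cc", name = "C", clade = "Z",
                   is_metazoan = FALSE, well_sequenced = TRUE))
  all_in <- dplyr::bind_rows(make_group("R1", c("aa")),
                             make_group("R2", c("aa")))
  cov2 <- coverage_report(all_in, c("R1", "R2"), species3)
  expect_equal(cov2$coverage[cov2$code == "aa"], 1.0)
  expect_equal(cov2$coverage[cov2$code == "cc"], 0.0)
})

test_that("coverage rejects unknown or empty reference sets", {
  fx <- ref_fixture()
  expect_error(coverage_report(fx$groups, c("R1", "nope"), fx$species),
               "nope")
  expect_error(coverage_report(fx$groups, character(), fx$species),
               "Empty reference")
})

test_that("coverage is monotone in presence and invariant to paralogs", {
  fx <- ref_fixture()
  base <- coverage_report(fx$groups, fx$ref, fx$species)
  # add species bb to R2 (previously absent): coverage must not decrease
  more <- dplyr::bind_rows(fx$groups, make_group("R2b", "bb"))
  more$group_id[more$group_id == "R2b"] <- "R2"
  cov_more <- coverage_report(more, fx$ref, fx$species)
  expect_gte(cov_more$coverage[cov_more$code == "bb"],
             base$coverage[base$code == "bb"])
  expect_equal(cov_more$coverage[cov_more$code == "aa"],
               base$coverage[base$code == "aa"])
  # paralogs: duplicate every member with a new gene id, coverage unchanged
  para <- fx$groups
  para$gene <- paste0(para$gene, "dup")
  doubled <- dplyr::bind_rows(fx$groups, para)
  cov_dup <- coverage_report(doubled, fx$ref, fx$species)
  expect_equal(cov_dup$coverage, base$coverage)
})

test_that("coverage summary reports metazoan means", {
  fx <- ref_fixture()
  cov <- coverage_report(fx$groups, fx$ref, fx$species)
  gl <- glance(cov)
  expect_equal(gl$mean_coverage_metazoan, 0.75)
  expect_equal(gl$reference_size, 4)
})
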