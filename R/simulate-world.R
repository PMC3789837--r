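# Synthetic ortholog worlds with planted truth.
#
# The generator emulates the statistical structure the classifier assumes:
# planted presence patterns per class, per-(group, species) dropout as an
# incomplete-genome model, and contaminating non-metazoan singletons whose
# RBBH degree toward the in-group metazoan genes is drawn from a
# configurable distribution.

#' Configuration for a synthetic ortholog world
#'
#' @param n_groups_per_class Named integer vector of group counts for the
#'   planted classes `metazoan_core`, `eumetazoan_core_no_focal`,
#'   `eukaryote_core`, `clade_restricted`, `promiscuous`,
#'   `contaminated_metazoan`. The default world is sized at roughly a
#'   tenth of a full ortholog database (about 2,500 groups).
#' @param dropout_rate Probability that a species' presence in a group is
#'   dropped (scalar, or named per-species vector; incomplete-genome
#'   model). Dropout acts per (group, species) pair, independently.
#' @param p_focal_present Probability that a planted metazoan-core (or
#'   eukaryote-core) group includes the focal Placozoan.
#' @param paralog_prob Probability that a member gains one species-level
#'   paralog.
#' @param contamination_degrees Integer support of the RBBH-degree
#'   distribution for contaminating foreign singletons.
#' @param contamination_weights Sampling weights over
#'   `contamination_degrees` (default uniform).
#' @param n_nonmetazoan Number of non-metazoan species (>= 10); the last
#'   one is flagged not-well-sequenced, so the counted foreign set has
#'   `n_nonmetazoan - 1` species (the full-size default 113 gives 112).
#' @param seed Integer seed; identical seed + config give a byte-identical
#'   world.
#' @return A validated `world_config` list.
#' @export
world_config <- function(n_groups_per_class = c(metazoan_core = 180L,
                                                eumetazoan_core_no_focal = 40L,
                                                eukaryote_core = 300L,
                                                clade_restricted = 700L,
                                                promiscuous = 1250L,
                                                contaminated_metazoan = 30L),
                         dropout_rate = 0.06,
                         p_focal_present = 0.66,
                         paralog_prob = 0.08,
                         contamination_degrees = 0:3,
                         contamination_weights = NULL,
                         n_nonmetazoan = 113L,
                         seed = 1L) {
  classes <- c("metazoan_core", "eumetazoan_core_no_focal", "eukaryote_core",
               "clade_restricted", "promiscuous", "contaminated_metazoan")
  counts <- setNames(integer(length(classes)), classes)
  counts[names(n_groups_per_class)] <- as.integer(n_groups_per_class)
  if (any(counts < 0)) abort("Group counts must be non-negative.")
  unknown <- setdiff(names(n_groups_per_class), classes)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown group class(es): %s", paste(unknown, collapse = ", ")))
  }
  if (any(dropout_rate < 0 | dropout_rate > 1) || p_focal_present < 0 ||
      p_focal_present > 1 || paralog_prob < 0 || paralog_prob > 1) {
    abort("Probabilities must lie in [0, 1].")
  }
  if (n_nonmetazoan < 10) abort("Need at least 10 non-metazoan species.")
  weights <- contamination_weights %||%
    rep(1, length(contamination_degrees))
  stopifnot(length(weights) == length(contamination_degrees))
  structure(list(n_groups_per_class = counts,
                 dropout_rate = dropout_rate,
                 p_focal_present = p_focal_present,
                 paralog_prob = paralog_prob,
                 contamination_degrees = as.integer(contamination_degrees),
                 contamination_weights = weights,
                 n_nonmetazoan = as.integer(n_nonmetazoan),
                 seed = as.integer(seed)),
            class = "world_config")
}

# Standard species layout: 11 Craniata + 1 Urochordata + 8 Arthropoda +
# 3 Nematoda + 1 Cnidaria (= 24 counted metazoans) + the focal Placozoan +
# n_nonmetazoan non-metazoans (fixed ten model organisms, then generated).
default_species_layout <- function(n_nonmetazoan = 113L) {
  mz <- tibble(
    code = c("hsa", "mmu", "rno", "cfa", "bta", "gga", "xtr", "dre", "tni",
             "tru", "mdo",
             "cin",
             "dme", "dps", "aga", "aae", "cqu", "ame", "nvi", "phu",
             "cel", "cbr", "bma",
             "nve", "tad"),
    name = c("Homo sapiens", "Mus musculus", "Rattus norvegicus",
             "Canis familiaris", "Bos taurus", "Gallus gallus",
             "Xenopus tropicalis", "Danio rerio", "Tetraodon nigroviridis",
             "Takifugu rubripes", "Monodelphis domestica",
             "Ciona intestinalis",
             "Drosophila melanogaster", "Drosophila pseudoobscura",
             "Anopheles gambiae", "Aedes aegypti", "Culex quinquefasciatus",
             "Apis mellifera", "Nasonia vitripennis", "Pediculus humanus",
             "Caenorhabditis elegans", "Caenorhabditis briggsae",
             "Brugia malayi",
             "Nematostella vectensis", "Trichoplax adhaerens"),
    clade = c(rep("Craniata", 11), "Urochordata", rep("Arthropoda", 8),
              rep("Nematoda", 3), "Cnidaria", "Placozoa"),
    is_metazoan = TRUE,
    well_sequenced = TRUE
  )
  fixed_nm <- tibble(
    code = c("sce", "spo", "ath", "osa", "ddi", "mbr", "pfa", "tgo",
             "eco", "bsu"),
    name = c("Saccharomyces cerevisiae", "Schizosaccharomyces pombe",
             "Arabidopsis thaliana", "Oryza sativa",
             "Dictyostelium discoideum", "Monosiga brevicollis",
             "Plasmodium falciparum", "Toxoplasma gondii",
             "Escherichia coli", "Bacillus subtilis"),
    clade = c("Fungi", "Fungi", "Viridiplantae", "Viridiplantae",
              "Amoebozoa", "Choanoflagellata", "Alveolata", "Alveolata",
              "Prokaryota", "Prokaryota"),
    is_metazoan = FALSE,
    well_sequenced = TRUE
  )
  n_extra <- n_nonmetazoan - nrow(fixed_nm)
  cycle <- c("Fungi", "Prokaryota", "Viridiplantae", "Prokaryota",
             "Alveolata", "Prokaryota", "Excavata", "Stramenopiles",
             "Prokaryota", "Choanoflagellata")
  extra <- tibble(
    code = sprintf("nm%03d", seq_len(n_extra)),
    name = sprintf("Synthetic non-metazoan %d", seq_len(n_extra)),
    clade = rep_len(cycle, n_extra),
    is_metazoan = FALSE,
    well_sequenced = TRUE
  )
  out <- bind_rows(mz, fixed_nm, extra)
  out$well_sequenced[nrow(out)] <- FALSE # one uncounted non-metazoan
  out
}

#' Simulate a synthetic ortholog world with planted truth
#'
#' Plants ortholog groups realising the defining presence pattern of each
#' class before dropout: `metazoan_core` spans every counted metazoan
#' (plus the focal species with probability `p_focal_present`);
#' `eumetazoan_core_no_focal` spans the counted metazoans but never the
#' focal Placozoan; `eukaryote_core` holds the five control species plus
#' assorted metazoans and non-prokaryote non-metazoans;
#' `clade_restricted` fills a single metazoan clade; `promiscuous` spreads
#' over metazoans, non-metazoans and at least one prokaryote;
#' `contaminated_metazoan` adds one or two foreign singleton genes with an
#' RBBH degree toward the group's metazoan genes drawn from the configured
#' distribution. Truth labels and focal presence are recorded pre-dropout;
#' groups emptied by dropout disappear from both collection and truth.
#'
#' @param config A [world_config()].
#' @param seed Seed override (defaults to the config's seed).
#' @return A `synthetic_world` list: `species` (table), `schema`
#'   (a [clade_schema()]), `groups` (long tibble), `rbbh` (edge tibble),
#'   `truth` (tibble `group_id`, `class`, `focal_present`,
#'   `n_foreign_species`, `max_foreign_links`) and `config`.
#' @export
simulate_world <- function(config = world_config(), seed = config$seed) {
  stopifnot(inherits(config, "world_config"))
  set.seed(seed)

  species <- default_species_layout(config$n_nonmetazoan)
  schema <- default_clade_schema(species)
  mz24 <- schema$counted_metazoans
  focal <- schema$focal_species
  counted_nm <- schema$nonmetazoan_counted
  prok <- intersect(counted_nm, schema$control_forbidden_species)
  nonprok_nm <- setdiff(counted_nm, prok)

  counts <- config$n_groups_per_class
  classes <- rep(names(counts), counts)
  n_groups <- length(classes)
  if (n_groups == 0) abort("Configuration plants no groups.")
  ids <- sprintf("OG%05d", seq_len(n_groups))

  draw_focal <- runif(n_groups) < config$p_focal_present
  species_sets <- vector("list", n_groups)
  focal_truth <- logical(n_groups)
  foreign_species <- vector("list", n_groups) # contaminants only
  for (i in seq_len(n_groups)) {
    cls <- classes[i]
    if (cls == "metazoan_core") {
      s <- mz24
      if (draw_focal[i]) { s <- c(s, focal); focal_truth[i] <- TRUE }
    } else if (cls == "eumetazoan_core_no_focal") {
      s <- mz24
    } else if (cls == "eukaryote_core") {
      req_mz <- intersect(schema$control_required_species, mz24)
      extra_mz <- sample(setdiff(mz24, req_mz), sample(8:18, 1))
      req_nm <- intersect(schema$control_required_species, counted_nm)
      nm_pool <- setdiff(nonprok_nm, req_nm)
      extra_nm <- sample(nm_pool, min(sample(3:10, 1), length(nm_pool)))
      s <- c(req_mz, extra_mz, req_nm, extra_nm)
      if (draw_focal[i]) { s <- c(s, focal); focal_truth[i] <- TRUE }
    } else if (cls == "clade_restricted") {
      cl <- sample(c("Craniata", "Arthropoda", "Nematoda"), 1)
      s <- schema$clade_members[[cl]]
    } else if (cls == "promiscuous") {
      n_mz <- sample(0:12, 1)
      s <- c(if (n_mz > 0) sample(mz24, n_mz) else character(),
             sample(nonprok_nm, min(sample(2:8, 1), length(nonprok_nm))),
             sample(prok, min(sample(1:4, 1), length(prok))))
    } else { # contaminated_metazoan
      s <- mz24
      if (draw_focal[i]) { s <- c(s, focal); focal_truth[i] <- TRUE }
      fs <- sample(counted_nm, sample(1:2, 1))
      foreign_species[[i]] <- fs
      s <- c(s, fs)
    }
    species_sets[[i]] <- s
  }

  lens <- lengths(species_sets)
  members <- tibble(
    group_id = rep(ids, lens),
    species = unlist(species_sets, use.names = FALSE)
  )
  members$gene <- paste0(members$species, "|g",
                         rep(seq_len(n_groups), lens))

  # species-level paralogs
  para <- members[runif(nrow(members)) < config$paralog_prob, ]
  if (nrow(para) > 0) {
    para$gene <- paste0(para$gene, "b")
    members <- bind_rows(members, para)
  }

  # background RBBH edges: chain consecutive metazoan genes within a group
  mz_all <- metazoan_codes(schema)
  mzm <- members[members$species %in% mz_all, ]
  mzm <- arrange(mzm, .data$group_id, .data$gene)
  nxt <- c(mzm$gene[-1], NA)
  same <- c(mzm$group_id[-1], NA) == mzm$group_id
  rbbh <- tibble(gene_a = mzm$gene[which(same)],
                 gene_b = nxt[which(same)])

  # contamination edges with planted degree
  truth_links <- integer(n_groups)
  cont_edges <- list()
  cont_idx <- which(classes == "contaminated_metazoan")
  for (i in cont_idx) {
    gid <- ids[i]
    mz_genes <- mzm$gene[mzm$group_id == gid]
    degs <- sample(config$contamination_degrees,
                   length(foreign_species[[i]]), replace = TRUE,
                   prob = config$contamination_weights)
    degs <- pmin(degs, length(mz_genes))
    truth_links[i] <- if (length(degs) > 0) max(degs) else 0L
    for (j in seq_along(foreign_species[[i]])) {
      if (degs[j] > 0) {
        fg <- paste0(foreign_species[[i]][j], "|g", i)
        cont_edges[[length(cont_edges) + 1]] <-
          tibble(gene_a = fg, gene_b = sample(mz_genes, degs[j]))
      }
    }
  }
  if (length(cont_edges) > 0) rbbh <- bind_rows(rbbh, cont_edges)
  rbbh <- distinct(tibble(gene_a = pmin(rbbh$gene_a, rbbh$gene_b),
                          gene_b = pmax(rbbh$gene_a, rbbh$gene_b)))

  truth <- tibble(
    group_id = ids,
    class = classes,
    focal_present = focal_truth,
    n_foreign_species = lengths(foreign_species),
    max_foreign_links = truth_links
  )

  # per-(group, species) dropout
  rate <- config$dropout_rate
  if (any(rate > 0)) {
    pres <- distinct(members[c("group_id", "species")])
    r <- if (is.null(names(rate))) rep(rate[1], nrow(pres)) else {
      rr <- rate[pres$species]
      ifelse(is.na(rr), 0, rr)
    }
    dropped <- pres[runif(nrow(pres)) < r, ]
    members <- anti_join(members, dropped, by = c("group_id", "species"))
    alive <- unique(members$group_id)
    truth <- truth[truth$group_id %in% alive, ]
    rbbh <- rbbh[rbbh$gene_a %in% members$gene &
                 rbbh$gene_b %in% members$gene, ]
  }

  structure(list(species = species, schema = schema,
                 groups = members[c("group_id", "species", "gene")],
                 rbbh = rbbh, truth = truth, config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d groups, %d species, %d RBBH edges\n",
              length(unique(x$groups$group_id)), nrow(x$species),
              nrow(x$rbbh)))
  print(table(x$truth$class))
  invisible(x)
}

#' Expected classification labels for a planted world
#'
#' Maps each planted class to the label the classifier should assign to
#' the pre-dropout presence pattern: the metazoan-core variants (and
#' contaminated groups whose planted contamination stays within the
#' foreign thresholds) are `metazoan_specific`; planted eukaryote-core
#' groups are `eukaryote_core`; everything else is `other`. Valid as an
#' oracle only for worlds generated without dropout.
#'
#' @param world A `synthetic_world`.
#' @return Tibble `group_id`, `class`, `expected_label`.
#' @export
expected_labels <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  tr <- world$truth
  sc <- world$schema
  cont_ok <- tr$n_foreign_species <= sc$max_foreign_species &
    tr$max_foreign_links <= sc$max_foreign_rbbh_links
  expected <- ifelse(
    tr$class %in% c("metazoan_core", "eumetazoan_core_no_focal"),
    "metazoan_specific",
    ifelse(tr$class == "contaminated_metazoan" & cont_ok,
           "metazoan_specific",
           ifelse(tr$class == "eukaryote_core", "eukaryote_core", "other")))
  tibble(group_id = tr$group_id, class = tr$class,
         expected_label = expected)
}

#' Write a synthetic world to the package's file formats
#'
#' Emits `species.tsv`, `groups.txt`, `rbbh.tsv`, `truth.tsv` and
#' `schema.cfg` under `dir`.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_species_table(world$species, file.path(dir, "species.tsv"))
  write_groups(world$groups, file.path(dir, "groups.txt"))
  write_rbbh(world$rbbh, file.path(dir, "rbbh.tsv"))
  tr <- world$truth
  tr$focal_present <- bool_to_text(tr$focal_present)
  readr::write_tsv(tr, file.path(dir, "truth.tsv"), progress = FALSE)
  write_clade_schema(world$schema, file.path(dir, "schema.cfg"))
  invisible(dir)
}
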