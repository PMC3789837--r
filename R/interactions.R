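#' Partition an interaction network between two gene sets
#'
#' Classifies every interaction edge as within set A, within set B, or
#' crossing the two sets; edges touching genes outside the union are
#' ignored (their count is reported). Because the field's usual summary is
#' ambiguous between pooling edges and averaging per gene, both read-outs
#' are emitted: pooled edge-class proportions, and the per-gene average
#' proportion of a gene's retained edges falling in each class.
#'
#' @param interactions Tibble with columns `gene_a`, `gene_b` (no
#'   self-pairs).
#' @param set_a,set_b Disjoint character vectors of genes.
#' @param labels Length-2 character vector naming the sets.
#' @return An `interaction_partition` list: `edges` (retained edges with
#'   `edge_class` in `withinA`/`withinB`/`cross`), `counts` (per-class
#'   counts and pooled proportions plus `n_ignored`), `connected`
#'   (per-set: genes with at least one retained edge and the connected
#'   fraction), `per_gene_mean` (per set and class, the mean per-gene
#'   proportion over connected genes).
#' @export
interaction_partition <- function(interactions, set_a, set_b,
                                  labels = c("A", "B")) {
  check_columns(interactions, c("gene_a", "gene_b"))
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(intersect(set_a, set_b)) > 0) {
    abort("set_a and set_b must be disjoint.")
  }
  if (any(interactions$gene_a == interactions$gene_b)) {
    abort("Interaction list contains self-pairs.")
  }
  in_a1 <- interactions$gene_a %in% set_a
  in_b1 <- interactions$gene_a %in% set_b
  in_a2 <- interactions$gene_b %in% set_a
  in_b2 <- interactions$gene_b %in% set_b
  edge_class <- rep(NA_character_, nrow(interactions))
  edge_class[in_a1 & in_a2] <- "withinA"
  edge_class[in_b1 & in_b2] <- "withinB"
  edge_class[(in_a1 & in_b2) | (in_b1 & in_a2)] <- "cross"
  ignored <- sum(is.na(edge_class))
  edges <- interactions[!is.na(edge_class), c("gene_a", "gene_b")]
  edges$edge_class <- edge_class[!is.na(edge_class)]

  n_by <- c(withinA = sum(edges$edge_class == "withinA"),
            withinB = sum(edges$edge_class == "withinB"),
            cross = sum(edges$edge_class == "cross"))
  retained <- sum(n_by)
  counts <- tibble(edge_class = names(n_by),
                   n = as.integer(n_by),
                   prop_pooled = if (retained > 0) unname(n_by / retained)
                   else rep(NA_real_, 3))

  touched <- c(edges$gene_a, edges$gene_b)
  connected <- tibble(
    set = labels,
    n_genes = c(length(set_a), length(set_b)),
    n_connected = c(length(intersect(set_a, touched)),
                    length(intersect(set_b, touched)))
  )
  connected$frac_connected <- ifelse(connected$n_genes > 0,
                                     connected$n_connected / connected$n_genes,
                                     NA_real_)

  # per-gene averaging: for each connected gene, the share of its retained
  # edges in each class, then averaged within its set
  long <- bind_rows(
    tibble(gene = edges$gene_a, edge_class = edges$edge_class),
    tibble(gene = edges$gene_b, edge_class = edges$edge_class)
  )
  per_gene <- count(long, .data$gene, .data$edge_class)
  per_gene <- mutate(group_by(per_gene, .data$gene),
                     share = .data$n / sum(.data$n))
  per_gene <- ungroup(per_gene)
  per_gene$set <- as.character(
    ifelse(per_gene$gene %in% set_a, labels[1],
           ifelse(per_gene$gene %in% set_b, labels[2], NA)))
  per_gene <- per_gene[!is.na(per_gene$set), ]
  # absent classes contribute share 0 for a connected gene, so the mean is
  # the summed share divided by the number of connected genes in the set
  sums <- summarise(group_by(per_gene, .data$set, .data$edge_class),
                    sum_share = sum(.data$share), .groups = "drop")
  grid <- tidyr::expand_grid(set = labels,
                             edge_class = c("withinA", "withinB", "cross"))
  per_gene_mean <- left_join(grid, sums, by = c("set", "edge_class"))
  per_gene_mean$sum_share[is.na(per_gene_mean$sum_share)] <- 0
  denom <- setNames(connected$n_connected, connected$set)
  per_gene_mean$mean_share <- ifelse(
    denom[per_gene_mean$set] > 0,
    per_gene_mean$sum_share / denom[per_gene_mean$set], NA_real_)
  per_gene_mean$sum_share <- NULL

  structure(list(edges = edges, counts = counts, connected = connected,
                 per_gene_mean = per_gene_mean, n_ignored = ignored,
                 labels = labels),
            class = "interaction_partition")
}

#' @export
print.interaction_partition <- function(x, ...) {
  cat(sprintf("<interaction_partition> %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  retained edges: %d (ignored %d)\n",
              sum(x$counts$n), x$n_ignored))
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %s: %d\n", x$counts$edge_class[i], x$counts$n[i]))
  }
  invisible(x)
}

#' @method tidy interaction_partition
#' @export
tidy.interaction_partition <- function(x, ...) x$edges

#' @method glance interaction_partition
#' @export
glance.interaction_partition <- function(x, ...) {
  cn <- x$counts
  tibble(
    n_within_a = cn$n[cn$edge_class == "withinA"],
    n_within_b = cn$n[cn$edge_class == "withinB"],
    n_cross = cn$n[cn$edge_class == "cross"],
    n_ignored = x$n_ignored,
    frac_connected_a = x$connected$frac_connected[1],
    frac_connected_b = x$connected$frac_connected[2]
  )
}

#' Export the partitioned network as a labelled edge list
#'
#' @param partition An `interaction_partition`.
#' @param path Output path (3-column TSV: `gene_a`, `gene_b`,
#'   `edge_class`).
#' @return `path`, invisibly.
#' @export
write_network <- function(partition, path) {
  stopifnot(inherits(partition, "interaction_partition"))
  readr::write_tsv(partition$edges, path, progress = FALSE)
  invisible(path)
}
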