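#' Filter a gene set to disease-associated genes
#'
#' Keeps the genes whose OMIM phenotype map key equals 3 — diseases whose
#' molecular basis is known.
#'
#' @param omim Tibble with columns `gene`, `map_key` (integer).
#' @param genes Character vector of genes to filter.
#' @return Sorted character vector of flagged genes.
#' @export
disease_filter <- function(omim, genes) {
  check_columns(omim, c("gene", "map_key"))
  keyed <- unique(omim$gene[omim$map_key == 3L])
  sort(intersect(unique(genes), keyed))
}

#' Flag uncharacterized genes
#'
#' A gene is uncharacterized when it has no UniprotKB functional
#' annotation AND no curated description AND no associated publications —
#' the intersection of the three negative screens. Every queried gene must
#' carry all three flags.
#'
#' @param characterized Tibble with columns `gene`, `uniprot_annotated`,
#'   `wormbase_described`, `pubmed_hit` (logical).
#' @param genes Character vector of genes to screen.
#' @return Sorted character vector of uncharacterized genes.
#' @export
flag_uncharacterized <- function(characterized, genes) {
  check_columns(characterized, c("gene", "uniprot_annotated",
                                 "wormbase_described", "pubmed_hit"))
  genes <- unique(genes)
  missing <- setdiff(genes, characterized$gene)
  if (length(missing) > 0) {
    abort(sprintf("No characterization flags for gene(s): %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  ch <- characterized[characterized$gene %in% genes, ]
  sort(ch$gene[!ch$uniprot_annotated & !ch$wormbase_described & !ch$pubmed_hit])
}
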