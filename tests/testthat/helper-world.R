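# Shared fixture builders (all generated in code).

# a small but structurally complete world configuration
tiny_world_config <- function(seed = 1, dropout_rate = 0, ...) {
  world_config(
    n_groups_per_class = c(metazoan_core = 20, eumetazoan_core_no_focal = 5,
                           eukaryote_core = 15, clade_restricted = 15,
                           promiscuous = 15, contaminated_metazoan = 8),
    dropout_rate = dropout_rate, n_nonmetazoan = 30, seed = seed, ...)
}

# the standard species table / schema without caring about groups
standard_species <- function() {
  simulate_world(world_config(
    n_groups_per_class = c(metazoan_core = 1),
    dropout_rate = 0, n_nonmetazoan = 12, seed = 1))$species
}

standard_schema <- function(species = standard_species()) {
  default_clade_schema(species)
}

# build a single-group long tibble from species codes (paralogs via
# repeated codes)
make_group <- function(id, codes) {
  counts <- table(codes)
  gene <- unlist(lapply(seq_along(codes), function(i) {
    paste0(codes[i], "|", id, "_", i)
  }))
  tibble::tibble(group_id = id, species = codes, gene = gene)
}

# write a text fixture to a temp file and return the path
write_fixture <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".txt",
                              .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}
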