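# Shared fixtures, built in code and memoized for the test session.

# A reduced synthetic bundle (6 species, 3 families) for stage-level tests.
small_config <- function(seed = 101L) {
  cfg <- sim_config(seed = seed, n_species = 6L, n_members = 2L,
                    expansion = c(HDA = 2L), background_genes = 12L)
  keep <- c("HDA", "SRT", "GNAT")
  cfg$families <- cfg$families[keep]
  cfg$motifs <- cfg$motifs[cfg$motifs$target_family %in% keep, ]
  cfg
}

small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_census(small_config())
    cache
  }
})

small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_full_census(small_bundle(), seed = 101L)
    cache
  }
})

# A tiny deterministic profile built from near-identical rows; scoring its
# own consensus should dominate random sequences.
toy_profile <- function(rows = c("MKLV", "MKLV", "MKIV"), family = "TOY") {
  build_profile(seed_alignment(family, paste0("r", seq_along(rows)), rows))
}

planted_truth_counts <- function(bundle) {
  tf <- bundle$truth$families
  tf <- tf[tf$family != "background", ]
  fams <- sort(unique(tf$family))
  tab <- table(factor(tf$species_id, levels = bundle$species$species_id),
               factor(tf$family, levels = fams))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}
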