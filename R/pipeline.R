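# High-level drivers chaining the census stages: profile build + calibration
# + scoring + zone classification + RBH validation + tabulation, consensus
# localization, and the promoter enrichment/conservation stage.

#' Run the profile-based family census on a proteome
#'
#' Builds a profile per seed alignment, calibrates its null-score Gumbel on
#' background sequences of the proteome's median length, scores every
#' protein against every profile (database size = number of proteins),
#' classifies hits into the accept/review/reject E-value zones, validates
#' primary review-zone hits by reciprocal best hit against the ungapped
#' seed sequences, and tabulates family sizes per species.
#'
#' @param seeds Named list of `seed_alignment`s (one per family/class).
#' @param proteome Combined sequence table.
#' @param species_of Named vector protein_id -> species_id.
#' @param species Species table.
#' @param accept_threshold,review_threshold E-value zone bounds.
#' @param n_random Calibration sample size per family.
#' @param seed Base seed; family `i` is calibrated with `seed + i`.
#' @param include_review Count RBH-confirmed review hits in the tabulation?
#' @param pseudocount Profile pseudocount.
#' @return List with `profiles`, `calibrations`, `records` (classified,
#'   RBH-validated hit table) and `tabulation`.
#' @export
run_family_census <- function(seeds, proteome, species_of, species,
                              accept_threshold = 1e-100,
                              review_threshold = 1e-3,
                              n_random = 1000L, seed = 1L,
                              include_review = TRUE, pseudocount = 0.5) {
  profiles <- lapply(seeds, build_profile, pseudocount = pseudocount)
  med_len <- median_length(nchar(proteome$sequence))
  calibrations <- setNames(lapply(seq_along(profiles), function(i) {
    calibrate_evalue(profiles[[i]], n_random = n_random, length = med_len,
                     seed = seed + i)
  }), names(profiles))
  hits <- score_proteome(profiles, calibrations, proteome, species_of)
  records <- classify(hits, accept_threshold, review_threshold)
  refs <- lapply(seeds, function(al) gsub("-", "", al$seqs))
  records <- validate_review_hits(records, proteome, refs)
  tab <- tabulate_family_sizes(records, species,
                               include_review = include_review)
  list(profiles = profiles, calibrations = calibrations,
       records = records, tabulation = tab)
}

#' Run the promoter-element stage for every species
#'
#' Extracts promoters for every gene of every species, scans them for the
#' motif library, tests per-(species, family, element) enrichment over the
#' species' universe of genes with an extractable promoter, and aggregates
#' cross-species conservation per family.
#'
#' @param genomes Named list species -> named scaffold vector.
#' @param loci Named list species -> gene-location table.
#' @param motifs Motif library.
#' @param family_sets Named list species -> (named list family -> gene ids);
#'   species without a family simply omit it (they are not examined for it).
#' @param promoter_length Promoter length in bp.
#' @param alpha Enrichment cutoff.
#' @param threshold Conservation fraction cutoff.
#' @return List with `promoters` (per species), `matches` (per species),
#'   `enrichment` (row-bound across species/families) and `conservation`
#'   (per family x element).
#' @export
run_promoter_stage <- function(genomes, loci, motifs, family_sets,
                               promoter_length = 2000L, alpha = 0.05,
                               threshold = 0.5) {
  promoters <- list()
  matches <- list()
  enr <- list()
  for (sp in names(genomes)) {
    promoters[[sp]] <- extract_promoters(genomes[[sp]], loci[[sp]],
                                         promoter_length)
    matches[[sp]] <- scan_promoters(promoters[[sp]], motifs)
    universe <- promoters[[sp]]$gene_id[promoters[[sp]]$length > 0L]
    for (fam in names(family_sets[[sp]])) {
      genes <- intersect(family_sets[[sp]][[fam]], universe)
      if (!length(genes)) next
      enr[[length(enr) + 1L]] <- enrich(
        sp, genes, universe, matches[[sp]], elements = motifs$name,
        alpha = alpha, family = fam)
    }
  }
  enrichment <- do.call(rbind, enr)
  conservation <- do.call(rbind, lapply(
    unique(enrichment$family), function(fam) {
      conserve(enrichment[enrichment$family == fam, , drop = FALSE],
               threshold = threshold)
    }))
  list(promoters = promoters, matches = matches, enrichment = enrichment,
       conservation = conservation)
}

#' Run every stage of the census on a simulated bundle
#'
#' Convenience driver for end-to-end runs on [simulate_census()] output:
#' family census, consensus localization, promoter enrichment/conservation
#' (family gene sets taken from the census assignments), and the
#' Kruskal-Wallis comparison of family sizes between the land-plant
#' (dicot + monocot) and algal/other species-type groups.
#'
#' @param bundle A bundle from [simulate_census()].
#' @param seed Seed for the E-value calibrations.
#' @param include_review Count RBH-confirmed review hits?
#' @param grouping Species-type grouping for the family-size comparison.
#' @return List with `census`, `localization`, `promoter` and `kw`.
#' @export
run_full_census <- function(bundle, seed = 1L, include_review = TRUE,
                            grouping = list(
                              c("dicot", "monocot"),
                              c("green_algae", "red_algae_glaucophyte",
                                "heterokont_other", "non_photosynthetic"))) {
  census <- run_family_census(bundle$seeds, bundle$proteome,
                              bundle$species_of, bundle$species,
                              seed = seed,
                              include_review = include_review)
  localization <- consensus_table(bundle$proteome, bundle$predictions)
  counted <- census$records[census$records$primary &
    (census$records$status == "accepted" |
       (include_review & census$records$status == "review" &
          census$records$rbh_confirmed == "yes")), , drop = FALSE]
  family_sets <- lapply(bundle$species$species_id, function(sp) {
    rows <- counted[counted$species_id == sp, , drop = FALSE]
    split(rows$protein_id, rows$family)
  })
  names(family_sets) <- bundle$species$species_id
  promoter <- run_promoter_stage(bundle$genomes, bundle$loci,
                                 bundle$motifs, family_sets,
                                 bundle$config$promoter_length)
  kw <- compare_family_sizes(census$tabulation, bundle$species, grouping)
  list(census = census, localization = localization, promoter = promoter,
       kw = kw)
}
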