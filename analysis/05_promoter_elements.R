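#!/usr/bin/env Rscript

# Step 5 — promoter element enrichment and cross-species conservation.
#
# Extracts 2000-bp strand-aware promoters (truncated at scaffold ends),
# scans them for exact non-overlapping element matches, tests per-(species,
# family, element) enrichment by the hypergeometric upper tail at p < 0.05,
# and flags elements enriched in at least half of the species examined.

suppressPackageStartupMessages(library(katcensus))

ind <- "results/simulated_inputs"
species <- read_species_table(file.path(ind, "species.tsv"))
motifs <- read_motif_library(file.path(ind, "motifs.tsv"))
genomes <- sapply(species$species_id, function(sp) {
  g <- read_fasta(file.path(ind, "genomes", paste0(sp, ".fasta")),
                  "nucleotide")
  setNames(g$sequence, g$id)
}, simplify = FALSE)
loci <- sapply(species$species_id, function(sp) {
  read_gene_locations(file.path(ind, "loci", paste0(sp, ".tsv")))
}, simplify = FALSE)

hits <- read.delim("results/census_hits.tsv")
assigned <- hits[hits$status == "accepted" |
                   (hits$status == "review" & hits$rbh_confirmed == "yes"), ]
family_sets <- sapply(species$species_id, function(sp) {
  rows <- assigned[assigned$species_id == sp, ]
  split(rows$protein_id, rows$family)
}, simplify = FALSE)

ps <- run_promoter_stage(genomes, loci, motifs, family_sets)

dir.create("results/promoters", showWarnings = FALSE, recursive = TRUE)
for (sp in species$species_id) {
  write_promoters(ps$promoters[[sp]],
                  file.path("results/promoters", paste0(sp, ".fasta")))
}
write_tsv(do.call(rbind, ps$matches)[, c("gene_id", "element", "count",
                                         "starts")],
          "results/element_matches.tsv")
write_tsv(ps$enrichment, "results/element_enrichment.tsv")
write_tsv(ps$conservation, "results/element_conservation.tsv")

n_trunc <- sum(vapply(ps$promoters, function(p) sum(p$truncated), 0L))
cat(sprintf("Promoters extracted: %d (%d truncated at scaffold ends)\n",
            sum(vapply(ps$promoters, nrow, 0L)), n_trunc))
cat(sprintf("Enrichment tests: %d; enriched at p < 0.05: %d\n",
            nrow(ps$enrichment), sum(ps$enrichment$enriched)))
cat("Conserved (family, element) pairs:\n")
print(ps$conservation[ps$conservation$conserved,
                      c("family", "element", "fraction")])
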