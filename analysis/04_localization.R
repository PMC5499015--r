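#!/usr/bin/env Rscript

# Step 4 — consensus subcellular localization.
#
# Applies the 3-of-5 majority rule (with primary/secondary fallback and the
# missing-N-terminal-methionine exclusion) to the five-predictor table and
# writes one consensus row per protein.

suppressPackageStartupMessages(library(katcensus))

ind <- "results/simulated_inputs"
species <- read_species_table(file.path(ind, "species.tsv"))
proteome <- do.call(rbind, lapply(species$species_id, function(sp) {
  read_fasta(file.path(ind, "proteomes", paste0(sp, ".fasta")), "protein")
}))
preds <- read_prediction_table(file.path(ind, "predictions.tsv"))

loc <- consensus_table(proteome, preds)
write_tsv(loc, "results/localization_consensus.tsv")

cat("Consensus localization written to results/localization_consensus.tsv\n")
cat("  verdict modes:\n")
print(table(loc$mode))
hits <- read.delim("results/census_hits.tsv")
fam_ids <- hits$protein_id[hits$status == "accepted"]
cat("  primary compartments of census-accepted proteins:\n")
print(table(loc$primary[loc$protein_id %in% fam_ids], useNA = "ifany"))
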