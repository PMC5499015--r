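#!/usr/bin/env Rscript

# Step 6 — family-size comparison across species types.
#
# Kruskal-Wallis rank-sum test per family, comparing per-species family
# sizes between land plants (dicots + monocots) and the algal/other
# divisions.

suppressPackageStartupMessages(library(katcensus))

ind <- "results/simulated_inputs"
species <- read_species_table(file.path(ind, "species.tsv"))
sizes <- read.delim("results/family_sizes.tsv")
tab <- as.matrix(sizes[, -1])
rownames(tab) <- sizes$species_id

kw <- compare_family_sizes(tab, species, list(
  c("dicot", "monocot"),
  c("green_algae", "red_algae_glaucophyte", "heterokont_other",
    "non_photosynthetic")))
write_tsv(kw, "results/family_size_kw.tsv")

cat("Land plants vs algae/other, per family (results/family_size_kw.tsv):\n")
print(kw, digits = 4)
sig <- kw$family[kw$p < 0.05]
cat("\nFamilies with significantly different sizes (p < 0.05):",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
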