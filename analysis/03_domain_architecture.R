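#!/usr/bin/env Rscript

# Step 3 — domain-architecture profiles.
#
# For every (family, species type) group of census-confirmed proteins:
# median protein length, per-domain prevalence with the <5% display filter,
# and 100-bin positional frequency histograms in median-length coordinates.
# One long-format TSV per family under results/domain_profiles/.

suppressPackageStartupMessages(library(katcensus))

ind <- "results/simulated_inputs"
dir.create("results/domain_profiles", recursive = TRUE,
           showWarnings = FALSE)

species <- read_species_table(file.path(ind, "species.tsv"))
hits <- read.delim("results/census_hits.tsv")
assigned <- hits[hits$status == "accepted" |
                   (hits$status == "review" & hits$rbh_confirmed == "yes"), ]
proteome <- do.call(rbind, lapply(species$species_id, function(sp) {
  read_fasta(file.path(ind, "proteomes", paste0(sp, ".fasta")), "protein")
}))
domains <- read_domain_table(file.path(ind, "domains.tsv"), proteome)
type_of <- setNames(species$species_type, species$species_id)

for (fam in sort(unique(assigned$family))) {
  fam_hits <- assigned[assigned$family == fam, ]
  rows <- list()
  for (st in unique(type_of[fam_hits$species_id])) {
    ids <- fam_hits$protein_id[type_of[fam_hits$species_id] == st]
    group_prot <- proteome[proteome$id %in% ids, ]
    group_dom <- domains[domains$protein_id %in% ids, ]
    prof <- profile_group(group_prot, group_dom, family = fam,
                          species_type = st)
    cat(sprintf("%-5s %-22s n=%2d median=%4d aa  domains kept: %s\n",
                fam, st, prof$n_proteins, prof$median_length,
                if (length(prof$prevalence))
                  paste(names(prof$prevalence), collapse = ", ")
                else "(none above 5%)"))
    f <- file.path("results/domain_profiles",
                   sprintf("%s_%s.tsv", fam, st))
    suppressWarnings(rows[[st]] <- render_profile(prof, f))
  }
}
cat("\nPer-group profiles written under results/domain_profiles/\n")
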