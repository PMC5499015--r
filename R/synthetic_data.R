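# Synthetic input generator: genomes with gene loci and planted promoter
# elements, proteomes with planted family members, seed alignments, domain
# tables and predictor tables, plus truth tables for every planted signal.
# Identical configurations produce byte-identical outputs.

default_families <- function() {
  list(
    HDA  = list(length = 420L, compartment = "nucleus",
                domains = list(
                  list(name = "histone_deacetylase", rel = c(0.15, 0.65),
                       prevalence = 1.00),
                  list(name = "ankyrin", rel = c(0.72, 0.82),
                       prevalence = 0.03))),
    SRT  = list(length = 310L, compartment = "mitochondrion",
                domains = list(
                  list(name = "sirtuin_catalytic", rel = c(0.20, 0.80),
                       prevalence = 1.00))),
    HDT  = list(length = 300L, compartment = "nucleus",
                domains = list(
                  list(name = "nucleoplasmin", rel = c(0.05, 0.35),
                       prevalence = 1.00))),
    GNAT = list(length = 320L, compartment = "cytosol",
                domains = list(
                  list(name = "acetyltransferase_gnat", rel = c(0.30, 0.75),
                       prevalence = 1.00))),
    MYST = list(length = 400L, compartment = "nucleus",
                domains = list(
                  list(name = "moz_sas", rel = c(0.35, 0.85),
                       prevalence = 1.00),
                  list(name = "zinc_finger_c2hc", rel = c(0.10, 0.18),
                       prevalence = 0.60))),
    CBP  = list(length = 500L, compartment = "nucleus",
                domains = list(
                  list(name = "kat11_catalytic", rel = c(0.40, 0.80),
                       prevalence = 1.00),
                  list(name = "bromodomain", rel = c(0.10, 0.25),
                       prevalence = 0.60))))
}

# Element strings are kept >= 7 bp so that chance presence of a pattern in
# a uniform 2000-bp promoter (~2000/4^len) stays at or below the declared
# background planting rate; no pattern is a substring of another.
default_motifs <- function() {
  data.frame(
    name = c("ABRE_like", "DRE_core", "GBOX_extended", "EVENING_ELEMENT",
             "TELO_BOX", "SITEII_MOTIF"),
    pattern = c("ACGTGTC", "ACCGACAT", "GCCACGTGGA", "AAAATATCT",
                "AAACCCTA", "TGGGCCCA"),
    category = c("cold_drought", "cold_drought", "light_circadian",
                 "light_circadian", "other", "other"),
    target_family = c("HDA", "HDT", "CBP", "GNAT", "MYST", "SRT"),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic census generator
#'
#' Bundles every tunable of [simulate_census()] with the package's default
#' study conditions: twelve species (two per species-type division), six
#' enzyme families with three members per species, member sequences at 15\%
#' divergence from the family consensus, six promoter elements planted at
#' probability 0.9 in their target family's promoters against a 5\%
#' background, five localization predictors at 90\% accuracy, and
#' per-family domain layouts including a rare (3\%) accessory domain that
#' exercises the display filter.
#'
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @param n_species Number of species (assigned round-robin over the six
#'   species types).
#' @param n_members Planted family members per (species, family).
#' @param expansion Named integer vector of extra members per family in
#'   species of the `expansion_types` divisions, emulating the land-plant
#'   expansion of deacetylase (and CBP) family sizes relative to algae.
#' @param expansion_types Species types receiving the expansion.
#' @param divergence Per-site substitution probability for planted members
#'   (in `[0, 0.5]`).
#' @param families Named list of family specs (`length`, `compartment`,
#'   `domains`).
#' @param motifs Motif library with a `target_family` column.
#' @param background_genes Non-family genes per species.
#' @param bg_length_range Length range for background proteins.
#' @param seed_rows,seed_divergence Seed-alignment depth and divergence.
#' @param insertion_prob,background_prob Element planting probabilities in
#'   target-family and non-target promoters.
#' @param predictor_accuracy Probability a predictor calls the true
#'   compartment.
#' @param none_prob Probability a predictor returns no call.
#' @param non_m_fraction Fraction of background proteins lacking an
#'   N-terminal methionine.
#' @param gene_length,segment_length,genes_per_scaffold Genome layout; each
#'   regular gene sits in its own segment with at least 2000 bp clearance
#'   on both sides.
#' @param edge_fraction Fraction of background genes placed near a scaffold
#'   end (1200 bp clearance) to exercise promoter truncation.
#' @param promoter_length Promoter length used when planting motifs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_species = 12L, n_members = 3L,
                       expansion = c(HDA = 2L, HDT = 2L, CBP = 1L),
                       expansion_types = c("dicot", "monocot"),
                       divergence = 0.15, families = default_families(),
                       motifs = default_motifs(), background_genes = 40L,
                       bg_length_range = c(250L, 450L), seed_rows = 6L,
                       seed_divergence = 0.08, insertion_prob = 0.9,
                       background_prob = 0.05, predictor_accuracy = 0.9,
                       none_prob = 0.03, non_m_fraction = 0.05,
                       gene_length = 600L, segment_length = 6000L,
                       genes_per_scaffold = 10L, edge_fraction = 0.05,
                       promoter_length = 2000L) {
  probs <- c(divergence, seed_divergence, insertion_prob, background_prob,
             predictor_accuracy, none_prob, non_m_fraction, edge_fraction)
  stopifnot(all(probs >= 0), all(probs <= 1), divergence <= 0.5,
            n_species >= 2L, n_members >= 1L, seed_rows >= 2L)
  if (segment_length - gene_length < 2L * promoter_length) {
    stop("gene footprint leaves < promoter_length clearance on a side",
         call. = FALSE)
  }
  stopifnot(all(names(expansion) %in% names(families)),
            all(expansion_types %in% SPECIES_TYPES))
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              n_members = as.integer(n_members),
              expansion = expansion, expansion_types = expansion_types,
              divergence = divergence,
              families = families, motifs = motifs,
              background_genes = as.integer(background_genes),
              bg_length_range = as.integer(bg_length_range),
              seed_rows = as.integer(seed_rows),
              seed_divergence = seed_divergence,
              insertion_prob = insertion_prob,
              background_prob = background_prob,
              predictor_accuracy = predictor_accuracy,
              none_prob = none_prob, non_m_fraction = non_m_fraction,
              gene_length = as.integer(gene_length),
              segment_length = as.integer(segment_length),
              genes_per_scaffold = as.integer(genes_per_scaffold),
              edge_fraction = edge_fraction,
              promoter_length = as.integer(promoter_length))
  class(cfg) <- "sim_config"
  cfg
}

random_protein <- function(length, background, start_m = TRUE) {
  body <- paste(sample(AA_ALPHABET20, length - 1L, replace = TRUE,
                       prob = background), collapse = "")
  first <- if (start_m) "M"
           else sample(setdiff(AA_ALPHABET20, "M"), 1L)
  paste0(first, body)
}

#' Mutate a consensus sequence into a diverged family member
#'
#' Per-site substitution: each position is replaced, independently with
#' probability `divergence`, by a residue drawn from the background
#' amino-acid distribution (which may redraw the original residue, so the
#' realised Hamming distance is slightly below `divergence * length`).
#'
#' @param sequence Consensus amino-acid sequence.
#' @param divergence Per-site substitution probability in `[0, 0.5]`.
#' @param seed Optional seed; when given, the caller's RNG stream is left
#'   untouched.
#' @param background Residue frequencies for substitution draws.
#' @return Mutated sequence of the same length.
#' @export
mutate_family_member <- function(sequence, divergence, seed = NULL,
                                 background = aa_background()) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  run <- function() {
    chars <- strsplit(sequence, "")[[1]]
    hit <- runif(length(chars)) < divergence
    if (any(hit)) {
      chars[hit] <- sample(AA_ALPHABET20, sum(hit), replace = TRUE,
                           prob = background)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Plant an exact promoter element upstream of a gene
#'
#' Overwrites a slot of the gene's oriented promoter with the exact element
#' pattern so that promoter extraction followed by [scan_element()] recovers
#' it: for minus-strand genes the reverse complement is written into genome
#' coordinates. The slot is chosen uniformly from a non-overlapping grid of
#' width `max(slot_width, nchar(pattern))` unless `offset` is given.
#' With `insert = FALSE` the genome is returned unchanged.
#'
#' @param genome Named character vector of scaffold sequences.
#' @param locus One gene-location row.
#' @param pattern Exact ACGT pattern.
#' @param insert Actually plant? (`FALSE` leaves the genome untouched and
#'   returns `offset = NA`.)
#' @param seed Optional seed for the slot draw.
#' @param promoter_length Promoter length the slot grid spans.
#' @param offset Optional fixed 0-based offset within the oriented promoter.
#' @param slot_width Slot grid width (defaults to the pattern length).
#' @return List with `genome` (modified) and `offset` (0-based within the
#'   oriented promoter).
#' @export
plant_motif <- function(genome, locus, pattern, insert = TRUE, seed = NULL,
                        promoter_length = 2000L, offset = NULL,
                        slot_width = nchar(pattern)) {
  if (!insert) return(list(genome = genome, offset = NA_integer_))
  plen <- nchar(pattern)
  stopifnot(slot_width >= plen)
  scaf <- genome[[locus$scaffold]]
  slen <- nchar(scaf)
  avail <- if (locus$strand == "+") {
    min(promoter_length, locus$start - 1L)
  } else {
    min(promoter_length, slen - locus$end)
  }
  n_slots <- avail %/% slot_width
  if (is.null(offset)) {
    if (n_slots < 1L) stop("no feasible slot for pattern in promoter of ",
                           locus$gene_id, call. = FALSE)
    pick <- function() (sample.int(n_slots, 1L) - 1L) * slot_width
    offset <- if (is.null(seed)) pick() else with_seed(seed, pick())
  }
  if (offset + plen > avail) {
    stop("offset outside promoter of ", locus$gene_id, call. = FALSE)
  }
  # map the 0-based oriented-promoter offset back to genome coordinates
  if (locus$strand == "+") {
    g_from <- locus$start - avail + offset
    substr(scaf, g_from, g_from + plen - 1L) <- pattern
  } else {
    g_to <- locus$end + avail - offset
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
    substr(scaf, g_to - plen + 1L, g_to) <- rc
  }
  genome[[locus$scaffold]] <- scaf
  list(genome = genome, offset = as.integer(offset))
}

make_seed_alignment <- function(family, consensus, cfg) {
  body <- substr(consensus, 2L, nchar(consensus))
  rows <- vapply(seq_len(cfg$seed_rows), function(i) {
    paste0("M", mutate_family_member(body, cfg$seed_divergence))
  }, character(1))
  # a mildly gapped block (kept: <50% gaps) and a majority-gapped block
  # (dropped from match states) exercise the column rule downstream
  L <- nchar(consensus)
  if (L >= 70L && cfg$seed_rows >= 6L) {
    for (i in c(cfg$seed_rows - 1L, cfg$seed_rows)) {
      substr(rows[i], 40L, 49L) <- "----------"
    }
    for (i in (cfg$seed_rows - 3L):cfg$seed_rows) {
      substr(rows[i], 60L, 69L) <- "----------"
    }
  }
  seed_alignment(family, sprintf("%s_seed%02d", family,
                                 seq_len(cfg$seed_rows)), rows)
}

#' Generate a full synthetic census input bundle with known truth
#'
#' Builds, deterministically from `config$seed`: a species table; per
#' species a genome (scaffolds with one gene per segment and at least
#' 2000 bp promoter clearance, plus a fraction of edge-proximal genes whose
#' promoters truncate), gene loci and a proteome in which the first genes
#' carry planted family members and the rest are background; per family a
#' seed alignment; domain, localization-prediction and motif tables; and
#' truth tables for planted family membership, localization, motif
#' positions and expected enrichment. When `out_dir` is given, every input
#' is also written in its external format.
#'
#' @param config A `sim_config`.
#' @param out_dir Optional output directory.
#' @return A bundle list: `config`, `species`, `genomes`, `loci` (per
#'   species), `proteome` (combined), `species_of` (protein -> species),
#'   `seeds`, `consensus`, `domains`, `predictions`, `motifs`, and `truth`
#'   (`families`, `localization`, `motif_positions`, `enrichment`).
#' @export
simulate_census <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  bg <- aa_background()
  fams <- names(cfg$families)
  species <- data.frame(
    species_id = sprintf("sp%02d", seq_len(cfg$n_species)),
    species_type = SPECIES_TYPES[((seq_len(cfg$n_species) - 1L) %%
                                    length(SPECIES_TYPES)) + 1L],
    stringsAsFactors = FALSE)

  # family consensus sequences and seed alignments
  consensus <- setNames(lapply(fams, function(f) {
    random_protein(cfg$families[[f]]$length, bg, start_m = TRUE)
  }), fams)
  seeds <- setNames(lapply(fams, function(f) {
    make_seed_alignment(f, consensus[[f]], cfg)
  }), fams)

  slot_w <- max(nchar(cfg$motifs$pattern))
  members_for <- function(fam, type) {
    extra <- if (type %in% cfg$expansion_types &&
                   fam %in% names(cfg$expansion)) {
      cfg$expansion[[fam]]
    } else 0L
    cfg$n_members + as.integer(extra)
  }

  genomes <- list()
  loci <- list()
  prot_rows <- list()
  truth_fam <- list()
  truth_loc <- list()
  truth_motif <- list()
  dom_rows <- list()
  pred_rows <- list()

  for (si in seq_len(cfg$n_species)) {
    sp <- species$species_id[si]
    fam_counts <- vapply(fams, members_for,
                         integer(1), type = species$species_type[si])
    n_genes <- sum(fam_counts) + cfg$background_genes
    n_edge <- min(cfg$background_genes,
                  round(cfg$edge_fraction * n_genes))
    gene_ids <- sprintf("%s_g%03d", sp, seq_len(n_genes))
    gene_family <- c(rep(fams, times = fam_counts),
                     rep("background", cfg$background_genes))
    is_edge <- c(rep(FALSE, n_genes - n_edge), rep(TRUE, n_edge))

    # genome layout: regular genes packed one per segment, edge genes on
    # their own short scaffolds
    n_reg <- sum(!is_edge)
    n_scaf <- ceiling(n_reg / cfg$genes_per_scaffold)
    genome <- character(0)
    loci_sp <- data.frame(gene_id = character(0), scaffold = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), stringsAsFactors = FALSE)
    reg_idx <- which(!is_edge)
    for (sc in seq_len(n_scaf)) {
      in_scaf <- reg_idx[((sc - 1L) * cfg$genes_per_scaffold + 1L):
                           min(sc * cfg$genes_per_scaffold, n_reg)]
      scaf_name <- sprintf("%s_scaf%02d", sp, sc)
      scaf_len <- length(in_scaf) * cfg$segment_length
      genome[scaf_name] <- paste(
        sample(c("A", "C", "G", "T"), scaf_len, replace = TRUE),
        collapse = "")
      for (k in seq_along(in_scaf)) {
        g <- in_scaf[k]
        start <- (k - 1L) * cfg$segment_length + cfg$promoter_length + 501L
        loci_sp <- rbind(loci_sp, data.frame(
          gene_id = gene_ids[g], scaffold = scaf_name, start = start,
          end = start + cfg$gene_length - 1L,
          strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE))
      }
    }
    for (g in which(is_edge)) {
      scaf_name <- sprintf("%s_edge_%s", sp, gene_ids[g])
      scaf_len <- cfg$gene_length + 1200L
      genome[scaf_name] <- paste(
        sample(c("A", "C", "G", "T"), scaf_len, replace = TRUE),
        collapse = "")
      strand <- sample(c("+", "-"), 1L)
      start <- if (strand == "+") 1201L else 1L
      loci_sp <- rbind(loci_sp, data.frame(
        gene_id = gene_ids[g], scaffold = scaf_name, start = start,
        end = start + cfg$gene_length - 1L, strand = strand,
        stringsAsFactors = FALSE))
    }
    loci_sp <- loci_sp[match(gene_ids, loci_sp$gene_id), ]
    rownames(loci_sp) <- NULL

    # plant promoter elements on a shared non-overlapping slot grid
    for (g in seq_len(n_genes)) {
      locus <- loci_sp[g, ]
      avail <- if (locus$strand == "+") {
        min(cfg$promoter_length, locus$start - 1L)
      } else {
        min(cfg$promoter_length,
            nchar(genome[[locus$scaffold]]) - locus$end)
      }
      free <- seq_len(avail %/% slot_w) - 1L
      for (mi in seq_len(nrow(cfg$motifs))) {
        el <- cfg$motifs[mi, ]
        p_ins <- if (identical(el$target_family, gene_family[g])) {
          cfg$insertion_prob
        } else cfg$background_prob
        if (runif(1) < p_ins && length(free) > 0L) {
          slot <- if (length(free) == 1L) free else sample(free, 1L)
          free <- setdiff(free, slot)
          planted <- plant_motif(genome, locus, el$pattern, insert = TRUE,
                                 promoter_length = cfg$promoter_length,
                                 offset = slot * slot_w)
          genome <- planted$genome
          truth_motif[[length(truth_motif) + 1L]] <- data.frame(
            species_id = sp, gene_id = locus$gene_id, element = el$name,
            offset = planted$offset, promoter_length = avail,
            stringsAsFactors = FALSE)
        }
      }
    }

    # proteome: planted family members, then background proteins
    for (g in seq_len(n_genes)) {
      fam <- gene_family[g]
      if (fam == "background") {
        len <- sample(cfg$bg_length_range[1]:cfg$bg_length_range[2], 1L)
        seqv <- random_protein(len, bg,
                               start_m = runif(1) >= cfg$non_m_fraction)
        true_comp <- sample(COMPARTMENTS, 1L)
      } else {
        cons <- consensus[[fam]]
        seqv <- paste0("M", mutate_family_member(
          substr(cons, 2L, nchar(cons)), cfg$divergence))
        true_comp <- cfg$families[[fam]]$compartment
      }
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        id = gene_ids[g], description = sp, sequence = seqv,
        stringsAsFactors = FALSE)
      truth_fam[[length(truth_fam) + 1L]] <- data.frame(
        protein_id = gene_ids[g], species_id = sp, family = fam,
        stringsAsFactors = FALSE)
      truth_loc[[length(truth_loc) + 1L]] <- data.frame(
        protein_id = gene_ids[g], compartment = true_comp,
        starts_with_m = substr(seqv, 1L, 1L) == "M",
        stringsAsFactors = FALSE)

      # five predictor calls
      call <- vapply(PREDICTORS, function(pr) {
        u <- runif(1)
        if (u < cfg$none_prob) return("none")
        if (u < cfg$none_prob +
              (1 - cfg$none_prob) * cfg$predictor_accuracy) {
          return(true_comp)
        }
        sample(setdiff(COMPARTMENTS, true_comp), 1L)
      }, character(1))
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        protein_id = gene_ids[g], predictor = PREDICTORS, call = call,
        stringsAsFactors = FALSE)

      # domain annotations for family members
      if (fam != "background") {
        L <- nchar(seqv)
        for (dspec in cfg$families[[fam]]$domains) {
          if (runif(1) < dspec$prevalence) {
            jitter <- sample(-5L:5L, 1L)
            d_start <- max(1L, round(dspec$rel[1] * L) + jitter)
            d_end <- min(L, round(dspec$rel[2] * L) + jitter)
            dom_rows[[length(dom_rows) + 1L]] <- data.frame(
              protein_id = gene_ids[g], domain_name = dspec$name,
              start = d_start, end = d_end,
              source = sample(c("pfam_like", "prosite_like"), 1L),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    genomes[[sp]] <- genome
    loci[[sp]] <- loci_sp
  }

  proteome <- do.call(rbind, prot_rows)
  truth_families <- do.call(rbind, truth_fam)
  truth_localization <- do.call(rbind, truth_loc)
  truth_motif_positions <- if (length(truth_motif)) {
    do.call(rbind, truth_motif)
  } else {
    data.frame(species_id = character(0), gene_id = character(0),
               element = character(0), offset = integer(0),
               promoter_length = integer(0))
  }
  truth_enrichment <- do.call(rbind, lapply(species$species_id, function(sp) {
    do.call(rbind, lapply(fams, function(f) {
      data.frame(species_id = sp, family = f,
                 element = cfg$motifs$name,
                 planted = cfg$motifs$target_family == f &
                   cfg$insertion_prob > cfg$background_prob,
                 stringsAsFactors = FALSE)
    }))
  }))

  bundle <- list(
    config = cfg, species = species, genomes = genomes, loci = loci,
    proteome = proteome,
    species_of = setNames(truth_families$species_id,
                          truth_families$protein_id),
    seeds = seeds, consensus = consensus,
    domains = do.call(rbind, dom_rows),
    predictions = do.call(rbind, pred_rows),
    motifs = cfg$motifs[, c("name", "pattern", "category")],
    motif_targets = setNames(cfg$motifs$target_family, cfg$motifs$name),
    truth = list(families = truth_families,
                 localization = truth_localization,
                 motif_positions = truth_motif_positions,
                 enrichment = truth_enrichment))

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a simulated bundle to disk in the pipeline's external formats
#'
#' @param bundle A bundle from [simulate_census()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  for (d in c("", "genomes", "loci", "proteomes", "seeds", "truth")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  write_tsv(bundle$species, file.path(out_dir, "species.tsv"))
  write_tsv(bundle$motifs, file.path(out_dir, "motifs.tsv"))
  write_tsv(bundle$domains, file.path(out_dir, "domains.tsv"))
  write_tsv(bundle$predictions, file.path(out_dir, "predictions.tsv"))
  for (sp in bundle$species$species_id) {
    g <- bundle$genomes[[sp]]
    write_fasta(data.frame(id = names(g), sequence = unname(g),
                           stringsAsFactors = FALSE),
                file.path(out_dir, "genomes", paste0(sp, ".fasta")))
    write_tsv(bundle$loci[[sp]],
              file.path(out_dir, "loci", paste0(sp, ".tsv")))
    prot <- bundle$proteome[bundle$species_of[bundle$proteome$id] == sp, ]
    write_fasta(prot,
                file.path(out_dir, "proteomes", paste0(sp, ".fasta")))
  }
  for (f in names(bundle$seeds)) {
    al <- bundle$seeds[[f]]
    write_fasta(data.frame(id = al$ids, sequence = al$seqs,
                           stringsAsFactors = FALSE),
                file.path(out_dir, "seeds", paste0(f, ".fasta")))
  }
  write_tsv(bundle$truth$families,
            file.path(out_dir, "truth", "families.tsv"))
  write_tsv(bundle$truth$localization,
            file.path(out_dir, "truth", "localization.tsv"))
  write_tsv(bundle$truth$motif_positions,
            file.path(out_dir, "truth", "motif_positions.tsv"))
  write_tsv(bundle$truth$enrichment,
            file.path(out_dir, "truth", "enrichment.tsv"))
  invisible(out_dir)
}
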