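# Profile-based family census: build position-specific profiles from seed
# alignments, score proteomes, calibrate E-values, apply accept/review/reject
# zones, validate review hits by reciprocal best hit, tabulate family sizes
# and compare them across species types.

seq_to_idx <- function(sequence) {
  idx <- match(strsplit(sequence, "")[[1]], AA_ALPHABET20) - 1L
  if (anyNA(idx)) {
    stop("sequence contains residues outside the 20-letter alphabet",
         call. = FALSE)
  }
  idx
}

#' Build a position-specific profile model from a seed alignment
#'
#' Alignment columns with at least 50\% gap characters are excluded from the
#' match states. For each retained column, emission probabilities are
#' `(count + pseudocount * background) / (n_nongap + pseudocount)` and are
#' converted to natural-log odds against the background; gaps contribute
#' nothing to the counts.
#'
#' @param alignment A `seed_alignment` (see [seed_alignment()]).
#' @param pseudocount Positive pseudocount mass distributed as `background`.
#' @param background Length-20 residue frequency vector (sums to 1), in
#'   canonical order; defaults to [aa_background()].
#' @param gap_open,gap_extend Affine gap penalties (positive numbers, on the
#'   log-odds scale) used when scoring sequences against the profile.
#' @return A `profile_model`: list with `family`, `emissions` (L x 20
#'   probability matrix), `logodds`, `background`, `pseudocount`,
#'   `gap_open`, `gap_extend`, and `kept_columns` (indices into the source
#'   alignment).
#' @export
build_profile <- function(alignment, pseudocount = 0.5,
                          background = aa_background(),
                          gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(alignment, "seed_alignment"), pseudocount > 0,
            length(background) == 20L,
            abs(sum(background) - 1) < 1e-9)
  m <- do.call(rbind, strsplit(alignment$seqs, ""))
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac < 0.5)
  if (!length(keep)) stop("no usable (<50% gap) columns", call. = FALSE)
  emissions <- matrix(0, nrow = length(keep), ncol = 20L,
                      dimnames = list(NULL, AA_ALPHABET20))
  for (k in seq_along(keep)) {
    col <- m[, keep[k]]
    col <- col[col != "-"]
    counts <- table(factor(col, levels = AA_ALPHABET20))
    emissions[k, ] <- (as.numeric(counts) + pseudocount * background) /
      (length(col) + pseudocount)
  }
  structure(list(family = alignment$family, emissions = emissions,
                 logodds = log(emissions) -
                   matrix(log(background), nrow(emissions), 20L, byrow = TRUE),
                 background = background, pseudocount = pseudocount,
                 gap_open = gap_open, gap_extend = gap_extend,
                 kept_columns = keep),
            class = "profile_model")
}

#' Score a protein against a profile model
#'
#' Best local-alignment log-odds score by affine-gap dynamic programming
#' (match / insert / delete states; inserts emit at background). The empty
#' alignment scores 0, so scores are non-negative. Deterministic.
#'
#' @param profile A `profile_model` from [build_profile()].
#' @param sequence Amino-acid sequence (character scalar) or a sequence
#'   record row with a `sequence` field.
#' @return Numeric scalar score (natural-log odds).
#' @export
score_protein <- function(profile, sequence) {
  stopifnot(inherits(profile, "profile_model"))
  if (is.list(sequence) || is.data.frame(sequence)) {
    sequence <- sequence$sequence
  }
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  cpp_score_profile(profile$logodds, seq_to_idx(sequence),
                    profile$gap_open, profile$gap_extend)
}

score_many <- function(profile, sequences) {
  idx <- lapply(sequences, seq_to_idx)
  cpp_score_profile_many(profile$logodds, idx, profile$gap_open,
                         profile$gap_extend)
}

#' Calibrate a Gumbel null-score distribution for a profile
#'
#' Scores `n_random` i.i.d. sequences drawn from the profile's background
#' residue distribution and fits a Gumbel location/scale by the method of
#' moments (`lambda = pi / (sd * sqrt(6))`,
#' `mu = mean - gamma / lambda`). Seeded and reproducible; the caller's RNG
#' stream is untouched.
#'
#' @param profile A `profile_model`.
#' @param n_random Number of null sequences (>= 200).
#' @param length Length of each null sequence (typically the median length
#'   of the proteome to be searched).
#' @param seed Integer seed.
#' @return A `gumbel_calibration`: list with `family`, `mu`, `lambda`,
#'   `n_random`, `length`, `seed`.
#' @export
calibrate_evalue <- function(profile, n_random = 1000L, length = 300L,
                             seed = 1L) {
  stopifnot(inherits(profile, "profile_model"), n_random >= 200L,
            length >= 1L)
  scores <- with_seed(seed, {
    seqs <- replicate(n_random, paste(
      sample(AA_ALPHABET20, length, replace = TRUE,
             prob = profile$background), collapse = ""))
    score_many(profile, seqs)
  })
  s2 <- var(scores)
  if (s2 <= 0) stop("degenerate null score distribution (zero variance)",
                    call. = FALSE)
  lambda <- pi / sqrt(6 * s2)
  mu <- mean(scores) - 0.5772156649015329 / lambda
  structure(list(family = profile$family, mu = mu, lambda = lambda,
                 n_random = n_random, length = length, seed = seed),
            class = "gumbel_calibration")
}

#' E-value of a score under a Gumbel calibration
#'
#' `E = db_size * (1 - exp(-exp(-lambda * (score - mu))))`, clamped to
#' `[0, db_size]`; computed via `expm1` with a direct `exp(-x)` tail so that
#' extreme scores yield accurate tiny E-values instead of underflowing to a
#' rounded intermediate.
#'
#' @param calibration A `gumbel_calibration`.
#' @param score Score(s) to convert.
#' @param db_size Number of sequences searched (>= 1).
#' @return Numeric E-value(s), monotone decreasing in `score`.
#' @export
evalue <- function(calibration, score, db_size) {
  stopifnot(inherits(calibration, "gumbel_calibration"), db_size >= 1)
  x <- calibration$lambda * (score - calibration$mu)
  t <- exp(-x)
  p <- ifelse(t < 1e-12, t, -expm1(-t))
  pmin(pmax(db_size * p, 0), db_size)
}

#' Classify scored hits into accept / review / reject E-value zones
#'
#' E-values below `accept_threshold` are accepted; E-values between the two
#' thresholds (inclusive) are flagged for review; anything above the review
#' ceiling is rejected. A protein scored against several families is
#' assigned to the family with the minimum E-value (its primary assignment);
#' other families' rows are retained as secondary. An exact E-value tie
#' between families demotes the tied rows to review status.
#'
#' @param hits Data frame with columns `protein_id`, `species_id`, `family`,
#'   `score`, `evalue`.
#' @param accept_threshold Accept zone ceiling (default `1e-100`).
#' @param review_threshold Review zone ceiling (default `1e-3`).
#' @return The input with added columns `status`
#'   (`accepted`/`review`/`rejected`), `primary` (logical; minimum-E family
#'   for the protein), and `rbh_confirmed` (initialised to `"not_run"`).
#' @export
classify <- function(hits, accept_threshold = 1e-100,
                     review_threshold = 1e-3) {
  stopifnot(accept_threshold < review_threshold)
  need <- c("protein_id", "species_id", "family", "score", "evalue")
  stopifnot(all(need %in% names(hits)))
  status <- ifelse(hits$evalue < accept_threshold, "accepted",
                   ifelse(hits$evalue <= review_threshold, "review",
                          "rejected"))
  primary <- logical(nrow(hits))
  tied <- logical(nrow(hits))
  for (p in unique(hits$protein_id)) {
    i <- which(hits$protein_id == p)
    best <- i[hits$evalue[i] == min(hits$evalue[i])]
    if (length(best) > 1L) {       # exact tie between families -> review
      tied[best] <- TRUE
      primary[best[1]] <- TRUE
    } else {
      primary[best] <- TRUE
    }
  }
  status[tied & status != "rejected"] <- "review"
  out <- hits
  out$status <- status
  out$primary <- primary
  out$rbh_confirmed <- "not_run"
  out
}

.cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .cache$BLOSUM62 <- e$BLOSUM62
  }
  .cache$BLOSUM62
}

pairwise_scores <- function(query, subjects) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(rep(query, length(subjects))),
    subject = Biostrings::AAStringSet(subjects),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
}

#' Validate a candidate by reciprocal best hit against reference sets
#'
#' The candidate is aligned (local, BLOSUM62, affine gaps) to every
#' reference. Its best-scoring reference must belong to a single family, and
#' when roles are reversed — that reference aligned against the candidate
#' and every other reference — the best hit must be the candidate. Exact
#' ties in either direction are treated as ambiguous.
#'
#' @param candidate Amino-acid sequence (character scalar).
#' @param family_references Named list: family -> character vector of
#'   reference sequences.
#' @return The confirmed family name, or `NA_character_` when the reciprocal
#'   check fails or is ambiguous.
#' @export
reciprocal_best_hit <- function(candidate, family_references) {
  stopifnot(length(family_references) >= 1L,
            all(lengths(family_references) >= 1L))
  fams <- rep(names(family_references), lengths(family_references))
  refs <- unlist(family_references, use.names = FALSE)
  fwd <- pairwise_scores(candidate, refs)
  best <- which(fwd == max(fwd))
  if (length(unique(fams[best])) > 1L) return(NA_character_)  # family tie
  b <- best[1]
  rev_subjects <- c(candidate, refs[-b])
  rev <- pairwise_scores(refs[b], rev_subjects)
  rb <- which(rev == max(rev))
  if (!(1L %in% rb) || length(rb) > 1L) return(NA_character_)
  fams[b]
}

#' Run reciprocal-best-hit validation on review-zone hits
#'
#' For each primary review-zone hit, confirms or rejects the claimed family
#' via [reciprocal_best_hit()]; accepted and rejected hits are left as
#' `"not_run"`.
#'
#' @param records Classified hit table from [classify()].
#' @param proteome Sequence table covering every hit protein.
#' @param family_references Named list: family -> reference sequences
#'   (typically the ungapped seed-alignment members).
#' @return `records` with `rbh_confirmed` set to `"yes"`/`"no"` on primary
#'   review hits.
#' @export
validate_review_hits <- function(records, proteome, family_references) {
  seqs <- setNames(proteome$sequence, proteome$id)
  idx <- which(records$status == "review" & records$primary)
  for (i in idx) {
    fam <- reciprocal_best_hit(seqs[[records$protein_id[i]]],
                               family_references)
    records$rbh_confirmed[i] <-
      if (!is.na(fam) && fam == records$family[i]) "yes" else "no"
  }
  records
}

#' Tabulate family sizes per species
#'
#' Counts primary accepted hits per (species, family); with
#' `include_review = TRUE`, review-zone hits confirmed by reciprocal best
#' hit are counted as well. Every species in the species table gets a row
#' (zero counts included), and every family a column.
#'
#' @param records Classified (and optionally RBH-validated) hit table.
#' @param species Species table (`species_id`, `species_type`).
#' @param include_review Count RBH-confirmed review hits too?
#' @return Integer matrix, rows = species, columns = families.
#' @export
tabulate_family_sizes <- function(records, species, include_review = FALSE) {
  unknown <- setdiff(unique(records$species_id), species$species_id)
  if (length(unknown)) {
    stop("hit(s) for unknown species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- records$primary & (records$status == "accepted" |
    (include_review & records$status == "review" &
       records$rbh_confirmed == "yes"))
  counted <- records[keep, , drop = FALSE]
  fams <- sort(unique(records$family))
  tab <- table(factor(counted$species_id, levels = species$species_id),
               factor(counted$family, levels = fams))
  m <- matrix(as.integer(tab), nrow = nrow(tab), ncol = ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Compare family sizes across species-type groups (Kruskal-Wallis)
#'
#' For each family, applies the Kruskal-Wallis rank-sum test (tie-corrected
#' H, chi-square approximation with groups - 1 degrees of freedom) to the
#' per-species counts, with species grouped by species type.
#'
#' @param tab Family tabulation matrix from [tabulate_family_sizes()].
#' @param species Species table.
#' @param grouping List of character vectors of species types; each vector
#'   defines one group. Every group must contain at least two species.
#' @return Data frame with columns `family`, `H`, `p`, `group_sizes`
#'   (comma-joined).
#' @export
compare_family_sizes <- function(tab, species, grouping) {
  stopifnot(length(grouping) >= 2L)
  type_of <- setNames(species$species_type, species$species_id)
  groups <- lapply(grouping, function(types) {
    species$species_id[species$species_type %in% types]
  })
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("each group needs >= 2 species (got sizes ",
         paste(sizes, collapse = ", "), ")", call. = FALSE)
  }
  res <- lapply(colnames(tab), function(fam) {
    x <- unlist(lapply(groups, function(sp) tab[sp, fam]))
    g <- factor(rep(seq_along(groups), sizes))
    if (length(unique(x)) == 1L) {            # fully tied: H = 0, p = 1
      return(data.frame(family = fam, H = 0, p = 1,
                        group_sizes = paste(sizes, collapse = ",")))
    }
    kt <- kruskal.test(x, g)
    data.frame(family = fam, H = unname(kt$statistic), p = kt$p.value,
               group_sizes = paste(sizes, collapse = ","))
  })
  do.call(rbind, res)
}

#' Score a proteome against a set of family profiles
#'
#' Scores every protein against every profile, converts scores to E-values
#' with the per-family calibrations, and returns the long hit table that
#' [classify()] consumes.
#'
#' @param profiles Named list of `profile_model`s.
#' @param calibrations Named list of `gumbel_calibration`s (same names).
#' @param proteome Sequence table with an `id` column; species are taken
#'   from `species_of`.
#' @param species_of Named character vector protein_id -> species_id.
#' @param db_size Database size for the E-value; defaults to the number of
#'   proteins scored.
#' @return Data frame `protein_id`, `species_id`, `family`, `score`,
#'   `evalue`.
#' @export
score_proteome <- function(profiles, calibrations, proteome, species_of,
                           db_size = nrow(proteome)) {
  stopifnot(identical(sort(names(profiles)), sort(names(calibrations))))
  res <- lapply(names(profiles), function(fam) {
    sc <- score_many(profiles[[fam]], proteome$sequence)
    data.frame(protein_id = proteome$id,
               species_id = unname(species_of[proteome$id]),
               family = fam, score = sc,
               evalue = evalue(calibrations[[fam]], sc, db_size),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$species_id)) {
    stop("protein(s) with unknown species", call. = FALSE)
  }
  out
}
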