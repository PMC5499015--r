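test_that("build_profile follows the 50% gap rule and the pseudocount limit", {
  # two identical rows, vanishing pseudocount: emission of M at column 1 -> 1
  al <- seed_alignment("F", c("a", "b"), c("MK", "MK"))
  p <- build_profile(al, pseudocount = 1e-9)
  expect_equal(unname(p$emissions[1, "M"]), 1, tolerance = 1e-6)

  # a 67%-gap column is excluded; an exactly-50% column is excluded too
  al <- seed_alignment("F", c("a", "b", "c"), c("MAK", "M-K", "M-K"))
  p <- build_profile(al)
  expect_equal(p$kept_columns, c(1L, 3L))
  al <- seed_alignment("F", c("a", "b"), c("MA", "M-"))
  expect_equal(build_profile(al)$kept_columns, 1L)

  expect_error(seed_alignment("F", c("a", "b"), c("-K", "M-")),
               "no column with < 50% gaps")
})

test_that("profile emissions sum to one for random seeded alignments", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    L <- sample(3:20, 1)
    rows <- vapply(seq_len(n), function(i) {
      s <- strsplit(random_aa_seq(L), "")[[1]]
      gap <- runif(L) < 0.2
      s[gap] <- "-"
      paste(s, collapse = "")
    }, character(1))
    if (!any(colMeans(do.call(rbind, strsplit(rows, "")) == "-") < 0.5)) next
    p <- build_profile(seed_alignment("F", paste0("r", 1:n), rows),
                       pseudocount = runif(1, 0.1, 2))
    expect_true(all(abs(rowSums(p$emissions) - 1) < 1e-9))
  }
})

test_that("score_protein is self-consistent, directional, and rejects empty input", {
  s <- "MKLVDEFGHIKW"
  p <- build_profile(seed_alignment("F", c("a", "b", "c"), rep(s, 3)))
  self <- score_protein(p, s)
  for (pos in c(1, 5, 12)) {
    mut <- s
    substr(mut, pos, pos) <- if (substr(s, pos, pos) == "A") "C" else "A"
    expect_gte(self, score_protein(p, mut))
  }
  expect_false(isTRUE(all.equal(
    self, score_protein(p, paste(rev(strsplit(s, "")[[1]]), collapse = "")))))
  expect_error(score_protein(p, ""), "empty sequence")
})

test_that("score_protein equals the exhaustive local-alignment oracle on small instances", {
  set.seed(21)
  for (rep in 1:40) {
    M <- sample(1:4, 1)
    L <- sample(1:6, 1)
    rows <- vapply(1:3, function(i) random_aa_seq(M), character(1))
    p <- build_profile(seed_alignment("F", paste0("r", 1:3), rows),
                       gap_open = runif(1, 0.5, 4), gap_extend = runif(1, 0.1, 1))
    seq <- random_aa_seq(L)
    expect_equal(score_protein(p, seq),
                 oracle_profile_score(p$logodds, aa_idx(seq),
                                      p$gap_open, p$gap_extend),
                 tolerance = 1e-10)
  }
})

test_that("Gumbel calibration is reproducible and its tail fits the empirical 5%", {
  p <- toy_profile(rows = replicate(4, random_aa_seq(30)))
  c1 <- calibrate_evalue(p, n_random = 300, length = 80, seed = 5)
  c2 <- calibrate_evalue(p, n_random = 300, length = 80, seed = 5)
  expect_identical(c1[c("mu", "lambda")], c2[c("mu", "lambda")])
  expect_gt(c1$lambda, 0)

  cal <- calibrate_evalue(p, n_random = 1000, length = 80, seed = 6)
  scores <- local({
    set.seed(6)
    seqs <- replicate(1000, paste(
      sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 80, replace = TRUE,
             prob = aa_background()), collapse = ""))
    vapply(seqs, function(s) score_protein(p, s), numeric(1))
  })
  q95 <- unname(quantile(scores, 0.95))
  p_fit <- evalue(cal, q95, db_size = 1)
  expect_lt(abs(p_fit - 0.05), 0.03)
})

test_that("evalue has the Gumbel closed form, monotonicity, and db scaling", {
  cal <- structure(list(family = "F", mu = 10, lambda = 0.4,
                        n_random = 1000L, length = 100L, seed = 1L),
                   class = "gumbel_calibration")
  expect_equal(evalue(cal, 10, 1), 1 - exp(-1), tolerance = 1e-12)
  sc <- seq(0, 200, by = 5)
  ev <- evalue(cal, sc, 100)
  expect_true(all(diff(ev) <= 0))
  expect_lt(evalue(cal, 1e6, 100), 1e-300)
  e1 <- evalue(cal, 60, 1)        # E << 1 regime
  expect_equal(evalue(cal, 60, 2) / e1, 2, tolerance = 1e-6)
})

test_that("classification zones and minimum-E family assignment behave as specified", {
  hits <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4", "p4", "p5", "p5"),
    species_id = "s", family = c("A", "A", "A", "A", "B", "A", "B"),
    score = 0,
    evalue = c(1e-150, 1e-50, 1e-2, 1e-120, 1e-80, 1e-40, 1e-40))
  rec <- classify(hits)
  expect_equal(rec$status[1:3], c("accepted", "review", "rejected"))
  # p4: assigned to min-E family A, B kept as secondary
  expect_true(rec$primary[rec$protein_id == "p4" & rec$family == "A"])
  expect_false(rec$primary[rec$protein_id == "p4" & rec$family == "B"])
  # p5: exact tie -> review status
  expect_true(all(rec$status[rec$protein_id == "p5"] == "review"))
  # the partition covers every hit exactly once
  expect_true(all(rec$status %in% c("accepted", "review", "rejected")))
})

test_that("reciprocal best hit confirms identity, rejects ties, matches a brute-force oracle", {
  set.seed(31)
  refA <- replicate(3, random_aa_seq(60))
  refB <- replicate(3, random_aa_seq(60))
  fam_refs <- list(A = refA, B = refB)
  expect_equal(reciprocal_best_hit(refA[1], fam_refs), "A")
  # symmetric duplicated reference in both families -> ambiguous
  tied <- list(A = c(refA, "MKLMKLMKL"), B = c(refB, "MKLMKLMKL"))
  expect_true(is.na(reciprocal_best_hit("MKLMKLMKL", tied)))

  # brute-force oracle: full pairwise score matrix, literal RBH definition
  for (rep in 1:10) {
    refs <- replicate(sample(4:8, 1), random_aa_seq(40))
    fams <- sample(c("A", "B"), length(refs), replace = TRUE)
    if (length(unique(fams)) < 2) fams[1:2] <- c("A", "B")
    frefs <- split(refs, fams)
    cand <- mutate_family_member(refs[1], 0.1, seed = rep)
    got <- reciprocal_best_hit(cand, frefs)
    sc_fwd <- vapply(refs, function(r) {
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(cand), Biostrings::AAString(r), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
        scoreOnly = TRUE)
    }, numeric(1), USE.NAMES = FALSE)
    b <- which(sc_fwd == max(sc_fwd))
    want <- NA_character_
    if (length(unique(fams[b])) == 1L) {
      b1 <- b[1]
      others <- c(cand, refs[-b1])
      sc_rev <- vapply(others, function(r) {
        Biostrings::pairwiseAlignment(
          Biostrings::AAString(refs[b1]), Biostrings::AAString(r),
          type = "local", substitutionMatrix = "BLOSUM62",
          gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
      }, numeric(1), USE.NAMES = FALSE)
      rb <- which(sc_rev == max(sc_rev))
      if (identical(rb, 1L)) want <- fams[b1]
    }
    expect_identical(got, want)
  }
})

test_that("family tabulation counts accepted hits, reports zeros, honours include_review", {
  species <- data.frame(species_id = c("s1", "s2", "s3"),
                        species_type = c("dicot", "monocot", "green_algae"))
  rec <- data.frame(
    protein_id = c("a", "b", "c", "d", "e"),
    species_id = c("s1", "s1", "s1", "s2", "s2"),
    family = c("HDA", "HDA", "HDA", "HDA", "SRT"),
    score = 0, evalue = 0,
    status = c("accepted", "accepted", "accepted", "review", "accepted"),
    primary = TRUE,
    rbh_confirmed = c("not_run", "not_run", "not_run", "yes", "not_run"))
  tab <- tabulate_family_sizes(rec, species, include_review = FALSE)
  expect_equal(tab["s1", "HDA"], 3L)
  expect_equal(tab["s2", "HDA"], 0L)
  expect_equal(tab["s3", "SRT"], 0L)
  tab2 <- tabulate_family_sizes(rec, species, include_review = TRUE)
  expect_equal(tab2["s2", "HDA"], 1L)
  rec$species_id[1] <- "s9"
  expect_error(tabulate_family_sizes(rec, species), "unknown species")
})

test_that("Kruskal-Wallis comparison matches the rank-sum hand computation", {
  species <- data.frame(species_id = paste0("s", 1:6),
                        species_type = rep(c("dicot", "green_algae"), each = 3))
  tab <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1,
                dimnames = list(paste0("s", 1:6), "HDA"))
  res <- compare_family_sizes(tab, species,
                              list("dicot", "green_algae"))
  expect_equal(res$H, 3.857, tolerance = 5e-4)
  expect_equal(res$group_sizes, "3,3")

  tied <- matrix(rep(2, 6), ncol = 1,
                 dimnames = list(paste0("s", 1:6), "HDA"))
  res <- compare_family_sizes(tied, species, list("dicot", "green_algae"))
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)

  # permuting species within a group leaves H unchanged
  perm <- tab[c(2, 3, 1, 6, 4, 5), , drop = FALSE]
  rownames(perm) <- paste0("s", 1:6)
  res2 <- compare_family_sizes(perm, species, list("dicot", "green_algae"))
  expect_equal(res2$H, 3.857, tolerance = 5e-4)

  expect_error(
    compare_family_sizes(tab, species[-(1:2), ], list("dicot", "green_algae")),
    ">= 2 species")
})
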