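revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

test_that("promoter extraction is strand-aware and truncates at scaffold ends", {
  set.seed(51)
  scaf <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                collapse = "")
  genome <- c(chr1 = scaf)

  plus <- list(gene_id = "g1", scaffold = "chr1", start = 2500L,
               end = 3000L, strand = "+")
  p <- extract_promoter(genome, plus)
  expect_equal(p$length, 2000L)
  expect_false(p$truncated)
  expect_equal(p$sequence, substr(scaf, 500, 2499))

  near <- list(gene_id = "g2", scaffold = "chr1", start = 1500L,
               end = 2000L, strand = "+")
  p <- extract_promoter(genome, near)
  expect_equal(p$length, 1499L)
  expect_true(p$truncated)
  expect_equal(p$sequence, substr(scaf, 1, 1499))

  minus <- list(gene_id = "g3", scaffold = "chr1", start = 1000L,
                end = 1800L, strand = "-")
  p1 <- extract_promoter(genome, minus)
  p2 <- extract_promoter(genome, minus)
  expect_identical(p1, p2)
  expect_equal(p1$sequence, revcomp(substr(scaf, 1801, 3800)))

  minus_end <- list(gene_id = "g4", scaffold = "chr1", start = 5000L,
                    end = 5500L, strand = "-")
  p <- extract_promoter(genome, minus_end)
  expect_equal(p$length, 500L)
  expect_true(p$truncated)

  outside <- list(gene_id = "g5", scaffold = "chr1", start = 5000L,
                  end = 6500L, strand = "+")
  expect_error(extract_promoter(genome, outside), "outside scaffold")
  expect_error(extract_promoter(genome, list(gene_id = "g6",
    scaffold = "chrX", start = 1L, end = 2L, strand = "+")),
    "scaffold not found")
})

test_that("scan_element performs greedy leftmost non-overlapping exact matching", {
  m <- scan_element("AAAA", "AA")
  expect_equal(m$starts, c(0L, 2L))
  expect_equal(m$count, 2L)

  expect_equal(scan_element("ACGT", "GG")$count, 0L)

  m <- scan_element("ACGTACGT", "ACGTACGT")
  expect_equal(m$starts, 0L)

  expect_equal(scan_element("ACG", "ACGTT")$count, 0L)  # pattern > promoter

  # non-overlap invariant and brute-force maximal-count oracle
  set.seed(52)
  for (rep in 1:60) {
    seq <- paste(sample(c("A", "C"), sample(30:120, 1), replace = TRUE),
                 collapse = "")
    pat <- paste(sample(c("A", "C"), sample(2:5, 1), replace = TRUE),
                 collapse = "")
    m <- scan_element(seq, pat)
    if (m$count > 1) {
      expect_true(all(diff(m$starts) >= nchar(pat)))
    }
    o <- oracle_scan(seq, pat)
    expect_equal(m$count, o$max_count)
    expect_true(all(m$starts %in% o$all_starts))
  }
})

test_that("hypergeom_upper matches enumeration and its boundary identities", {
  expect_equal(hypergeom_upper(0, 3, 4, 10), 1)
  expect_equal(hypergeom_upper(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeom_upper(4, 10, 4, 10), 1)   # K = N forces k = n
  expect_error(hypergeom_upper(5, 5, 4, 10))
  set.seed(53)
  for (rep in 1:100) {
    N <- sample(1:12, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    ks <- max(0, n + K - N):min(n, K)
    k <- ks[sample.int(length(ks), 1)]
    expect_equal(hypergeom_upper(k, K, n, N), oracle_hyper_upper(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("enrich applies the per-gene presence predicate and the 0.05 cutoff", {
  genes <- sprintf("g%03d", 1:100)
  fam <- genes[1:10]
  mk_matches <- function(present) {
    data.frame(gene_id = genes, element = "EL",
               count = as.integer(genes %in% present),
               starts = ifelse(genes %in% present, "0", ""))
  }
  # element in every universe gene -> p = 1, never enriched
  r <- enrich("sp", fam, genes, mk_matches(genes), elements = "EL")
  expect_equal(r$p, 1)
  expect_false(r$enriched)

  # family = universe -> k = K, p = 1
  r <- enrich("sp", genes, genes, mk_matches(genes[1:30]), elements = "EL")
  expect_equal(r$k, r$K)
  expect_equal(r$p, 1)

  # strong planted signal -> tiny p
  r <- enrich("sp", fam, genes, mk_matches(c(fam[1:9], genes[95])),
              elements = "EL", family = "HDA")
  expect_equal(r$k, 9L)
  expect_equal(r$K, 10L)
  expect_lt(r$p, 1e-8)
  expect_true(r$enriched)
  expect_equal(r$family, "HDA")

  expect_error(enrich("sp", character(0), genes, mk_matches(genes)),
               "empty family")
  expect_error(enrich("sp", "not_there", genes, mk_matches(genes)),
               "subset of the universe")

  # occurrence counts are preserved in the match table, not used by enrich
  mm <- mk_matches(fam[1])
  mm$count[mm$gene_id == fam[1]] <- 7L
  r7 <- enrich("sp", fam, genes, mm, elements = "EL")
  expect_equal(r7$k, 1L)
})

test_that("conservation uses >= 50% of the species examined", {
  mk <- function(n_enriched, n_total) {
    data.frame(species_id = sprintf("sp%02d", 1:n_total), family = "HDA",
               element = "EL", k = 1, K = 1, n = 1, N = 10, p = 0.5,
               enriched = c(rep(TRUE, n_enriched),
                            rep(FALSE, n_total - n_enriched)))
  }
  r <- conserve(mk(3, 5))
  expect_equal(r$fraction, 0.6)
  expect_true(r$conserved)
  expect_false(conserve(mk(2, 5))$conserved)
  expect_true(conserve(mk(3, 6))$conserved)       # exactly half counts
  expect_error(conserve(mk(1, 1)[0, ]), "zero species")
  two <- rbind(mk(1, 2), within(mk(1, 2), family <- "SRT"))
  expect_error(conserve(two), "single family")
})
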