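test_that("median_length is the exact (lower) median of member lengths", {
  prot <- function(lens) data.frame(id = paste0("p", seq_along(lens)),
                                    description = "",
                                    sequence = vapply(lens, random_aa_seq,
                                                      character(1)))
  expect_equal(median_length(prot(c(100, 200, 300))), 200L)
  expect_equal(median_length(prot(c(100, 200))), 100L)   # lower median
  set.seed(3)
  for (rep in 1:20) {
    lens <- sample(50:500, sample(1:9, 1))
    m <- median_length(lens)
    expect_true(m >= min(lens) && m <= max(lens))
    expect_true(m %in% lens)                              # attained length
  }
  expect_error(median_length(integer(0)), "empty group")
})

test_that("rescale_domain scales proportionally and preserves nesting", {
  expect_equal(rescale_domain(10, 50, 100, 200), c(20, 100))
  expect_equal(rescale_domain(7, 31, 120, 120), c(7, 31))  # identity
  outer <- rescale_domain(10, 90, 100, 250)
  inner <- rescale_domain(20, 60, 100, 250)
  expect_true(inner[1] >= outer[1] && inner[2] <= outer[2])
  se <- rescale_domain(1, 100, 100, 57)
  expect_lte(se[2], 57)
})

test_that("profile_group applies the 5% display filter after prevalence", {
  n <- 100
  prot <- data.frame(id = sprintf("p%03d", 1:n), description = "",
                     sequence = vapply(rep(200, n), random_aa_seq,
                                       character(1)))
  ann <- rbind(
    data.frame(protein_id = prot$id[1:4], domain_name = "rareX",
               start = 10, end = 60, source = "pfam_like"),
    data.frame(protein_id = prot$id, domain_name = "catalytic",
               start = 50, end = 150, source = "pfam_like"))
  dp <- profile_group(prot, ann, family = "HDA", species_type = "dicot",
                      bins = 10)
  expect_false("rareX" %in% names(dp$prevalence))   # 4/100 dropped
  expect_equal(unname(dp$prevalence["catalytic"]), 1)
  # 5/100 survives: the threshold is >= 0.05, denominators are group size
  ann5 <- rbind(ann, data.frame(protein_id = prot$id[5], domain_name = "rareX",
                                start = 10, end = 60, source = "pfam_like"))
  dp5 <- profile_group(prot, ann5, bins = 10)
  expect_equal(unname(dp5$prevalence["rareX"]), 0.05)
})

test_that("a full-length domain in a single protein fills every bin", {
  prot <- data.frame(id = "p1", description = "",
                     sequence = random_aa_seq(150))
  ann <- data.frame(protein_id = "p1", domain_name = "X",
                    start = 1, end = 150, source = "prosite_like")
  dp <- profile_group(prot, ann, bins = 25)
  expect_equal(unname(dp$prevalence["X"]), 1)
  expect_equal(unname(dp$positional["X", ]), rep(1, 25))
})

test_that("positional frequencies match a per-bin occupancy oracle and stay below prevalence", {
  set.seed(13)
  for (rep in 1:15) {
    n <- sample(2:5, 1)
    lens <- sample(60:140, n, replace = TRUE)
    prot <- data.frame(id = paste0("p", 1:n), description = "",
                       sequence = vapply(lens, random_aa_seq, character(1)))
    ann <- do.call(rbind, lapply(1:n, function(i) {
      k <- sample(0:2, 1)
      if (k == 0) return(NULL)
      st <- sort(sample(seq_len(lens[i] - 10), k))
      data.frame(protein_id = prot$id[i], domain_name = "D",
                 start = st, end = pmin(st + sample(5:30, k, replace = TRUE),
                                        lens[i]),
                 source = "pfam_like")
    }))
    if (is.null(ann) ||
        length(unique(ann$protein_id)) / n < 0.05) next
    B <- sample(4:12, 1)
    dp <- profile_group(prot, ann, bins = B)
    med <- dp$median_length
    # oracle: per bin, count proteins owning >= 1 rescaled interval that
    # intersects the closed bin interval
    oracle <- vapply(seq_len(B), function(b) {
      lo <- (b - 1) * med / B
      hi <- b * med / B
      hitters <- unique(unlist(lapply(seq_len(nrow(ann)), function(r) {
        li <- lens[match(ann$protein_id[r], prot$id)]
        s <- ann$start[r] / li * med
        e <- ann$end[r] / li * med
        if (s <= hi && e >= lo) ann$protein_id[r] else NULL
      })))
      length(hitters) / n
    }, numeric(1))
    expect_equal(unname(dp$positional["D", ]), oracle)
    expect_true(all(dp$positional["D", ] <= dp$prevalence[["D"]] + 1e-12))
    expect_true(all(dp$positional_occurrence["D", ] >=
                      dp$positional["D", ] - 1e-12))
  }
})

test_that("render_profile writes B rows per retained domain and is idempotent", {
  prot <- data.frame(id = c("p1", "p2"), description = "",
                     sequence = c(random_aa_seq(100), random_aa_seq(120)))
  ann <- data.frame(protein_id = c("p1", "p2"), domain_name = "cat",
                    start = c(10, 12), end = c(40, 50), source = "pfam_like")
  dp <- profile_group(prot, ann, family = "SRT", species_type = "monocot",
                      bins = 20)
  f <- withr::local_tempfile(fileext = ".tsv")
  df1 <- render_profile(dp, f)
  expect_equal(nrow(df1), 20L)
  on_disk <- read.delim(f)
  expect_equal(nrow(on_disk), 20L)
  df2 <- render_profile(dp, f)
  expect_identical(df1, df2)

  # everything filtered -> header-only TSV plus a warning
  rare <- data.frame(protein_id = "p1", domain_name = "cat",
                     start = 10, end = 40, source = "pfam_like")
  many <- data.frame(id = sprintf("q%02d", 1:30), description = "",
                     sequence = vapply(rep(100, 30), random_aa_seq,
                                       character(1)))
  dp0 <- profile_group(rbind(prot[0, ], many), rare[0, ], bins = 20)
  expect_warning(render_profile(dp0, f), "header only")
  expect_equal(nrow(read.delim(f)), 0L)
})
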