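# Promoter cis-element analysis: 2000-bp strand-aware upstream extraction
# (truncated at scaffold ends), exact non-overlapping motif scanning,
# per-(species, family, element) hypergeometric enrichment at p < 0.05, and
# a >= 50%-of-species conservation filter.

#' Extract the upstream promoter region of a gene
#'
#' For a plus-strand gene the promoter is the `length` bases immediately
#' upstream of the gene start (genome positions `start - length` to
#' `start - 1`, 1-based), clipped at the scaffold start; for a minus-strand
#' gene it is positions `end + 1` to `end + length`, clipped at the scaffold
#' end and reverse-complemented, so the returned sequence always reads 5'
#' to 3' on the gene's coding strand. The `truncated` flag records clipping.
#'
#' @param genome Named character vector or `DNAStringSet` of scaffold
#'   sequences.
#' @param locus One gene-location row (`gene_id`, `scaffold`, `start`,
#'   `end`, `strand`).
#' @param length Promoter length in bp (default 2000).
#' @return List with `gene_id`, `sequence`, `length`, `truncated`.
#' @export
extract_promoter <- function(genome, locus, length = 2000L) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!locus$scaffold %in% names(genome)) {
    stop("scaffold not found: ", locus$scaffold, call. = FALSE)
  }
  scaf <- genome[[locus$scaffold]]
  slen <- nchar(scaf)
  if (locus$end > slen || locus$start < 1L) {
    stop("locus ", locus$gene_id, " outside scaffold", call. = FALSE)
  }
  if (locus$strand == "+") {
    from <- max(1L, locus$start - length)
    to <- locus$start - 1L
    seq <- if (to >= from) substr(scaf, from, to) else ""
  } else {
    from <- locus$end + 1L
    to <- min(slen, locus$end + length)
    seq <- if (to >= from) substr(scaf, from, to) else ""
    seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  list(gene_id = locus$gene_id, sequence = seq, length = nchar(seq),
       truncated = nchar(seq) < length)
}

#' Extract promoters for a whole gene-location table
#'
#' @param genome Named scaffold sequences.
#' @param loci Gene-location table (see [read_gene_locations()]).
#' @param length Promoter length in bp.
#' @return Data frame `gene_id`, `sequence`, `length`, `truncated`.
#' @export
extract_promoters <- function(genome, loci, length = 2000L) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    p <- extract_promoter(genome, loci[i, ], length)
    data.frame(gene_id = p$gene_id, sequence = p$sequence,
               length = p$length, truncated = p$truncated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write promoters as FASTA with truncation-flag headers
#'
#' Headers have the form `gene_id|truncated=0/1`.
#'
#' @param promoters Promoter table from [extract_promoters()].
#' @param path Output FASTA path.
#' @export
write_promoters <- function(promoters, path) {
  recs <- data.frame(
    id = sprintf("%s|truncated=%d", promoters$gene_id,
                 as.integer(promoters$truncated)),
    sequence = promoters$sequence, stringsAsFactors = FALSE)
  write_fasta(recs, path)
}

#' Exact non-overlapping matches of an element in a promoter
#'
#' Greedy leftmost scan on the oriented promoter's forward strand: at each
#' position, an exact pattern match is recorded and the scan jumps past it,
#' otherwise it advances one base. For exact (non-degenerate) patterns this
#' attains the maximum number of non-overlapping matches. Offsets are
#' 0-based within the promoter. A pattern longer than the promoter yields
#' zero matches, not an error.
#'
#' @param promoter Promoter sequence (character scalar) or the list/row
#'   returned by [extract_promoter()].
#' @param pattern Exact DNA pattern over ACGT.
#' @return List with `starts` (sorted 0-based integer offsets) and `count`.
#' @export
scan_element <- function(promoter, pattern) {
  seq <- if (is.list(promoter)) promoter$sequence else promoter
  plen <- nchar(pattern)
  L <- nchar(seq)
  if (plen > L || L == 0L) return(list(starts = integer(0), count = 0L))
  # all (possibly overlapping) match starts, 1-based
  hits <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(list(starts = integer(0), count = 0L))
  starts <- integer(0)
  nextfree <- 1L
  for (h in hits) {
    if (h >= nextfree) {
      starts <- c(starts, h)
      nextfree <- h + plen
    }
  }
  # single 1-based -> 0-based conversion for reported offsets
  list(starts = starts - 1L, count = length(starts))
}

#' Scan every promoter for every element of a motif library
#'
#' @param promoters Promoter table from [extract_promoters()].
#' @param motifs Motif library from [read_motif_library()].
#' @return Data frame `gene_id`, `element`, `count`, `starts` (comma-joined
#'   0-based offsets; empty string when absent).
#' @export
scan_promoters <- function(promoters, motifs) {
  out <- expand.grid(gene_id = promoters$gene_id, element = motifs$name,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pat_of <- setNames(motifs$pattern, motifs$name)
  seq_of <- setNames(promoters$sequence, promoters$gene_id)
  res <- mapply(function(g, e) {
    m <- scan_element(seq_of[[g]], pat_of[[e]])
    c(count = m$count, starts = paste(m$starts, collapse = ","))
  }, out$gene_id, out$element, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  out$count <- vapply(res, function(r) as.integer(r[["count"]]), integer(1))
  out$starts <- vapply(res, function(r) r[["starts"]], character(1))
  out
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes without
#' replacement from a universe of `N` of which `K` carry the element.
#' Delegates to the exact log-space tail of [stats::phyper()].
#'
#' @param k Observed number of element-carrying genes in the drawn set.
#' @param K Element-carrying genes in the universe.
#' @param n Drawn (family) set size.
#' @param N Universe size.
#' @return Probability in `(0, 1]`.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 1, K <= N, n <= N,
            k <= min(n, K))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Promoter-element enrichment of a gene family within one species
#'
#' For each element, counts family genes (`k` of `n`) and universe genes
#' (`K` of `N`) whose promoters carry at least one match — enrichment is a
#' per-gene presence predicate; occurrence counts remain available in the
#' match table — and computes the hypergeometric upper tail. An element is
#' called enriched when `p < alpha` (no multiple-testing correction by
#' default; set `adjust = "BH"` for Benjamini-Hochberg on the per-species
#' element set).
#'
#' @param species_id Species label, recorded in the result.
#' @param family_genes Character vector of family gene ids (subset of the
#'   universe; non-empty).
#' @param universe_genes Character vector of all analyzed gene ids of the
#'   species (all genes with an extractable promoter).
#' @param matches Match table from [scan_promoters()] covering the universe.
#' @param elements Character vector of element names to test (defaults to
#'   all elements in `matches`).
#' @param alpha Significance cutoff (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param family Optional family label, recorded in the result.
#' @return Data frame `species_id`, `family`, `element`, `k`, `K`, `n`,
#'   `N`, `p`, `enriched`.
#' @export
enrich <- function(species_id, family_genes, universe_genes, matches,
                   elements = unique(matches$element), alpha = 0.05,
                   adjust = c("none", "BH"), family = NA_character_) {
  adjust <- match.arg(adjust)
  if (!length(family_genes)) stop("empty family gene set", call. = FALSE)
  if (!all(family_genes %in% universe_genes)) {
    stop("family genes must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe_genes)
  n <- length(family_genes)
  res <- lapply(elements, function(el) {
    hit <- matches$gene_id[matches$element == el & matches$count > 0L]
    K <- sum(universe_genes %in% hit)
    k <- sum(family_genes %in% hit)
    data.frame(species_id = species_id, family = family, element = el,
               k = k, K = K, n = n, N = N,
               p = hypergeom_upper(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  p_used <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$enriched <- p_used < alpha
  out
}

#' Cross-species conservation of an enriched element
#'
#' Aggregates per-species enrichment results for one family: an element is
#' conserved when it is enriched in at least `threshold` (default half) of
#' the species examined, where only species possessing the family count as
#' examined.
#'
#' @param results Row-bound [enrich()] results across species (one family).
#' @param threshold Conserved fraction cutoff; the comparison is `>=`.
#' @return Data frame `family`, `element`, `n_species_enriched`,
#'   `n_species_examined`, `fraction`, `conserved`.
#' @export
conserve <- function(results, threshold = 0.5) {
  if (!nrow(results)) stop("zero species examined", call. = FALSE)
  fam <- unique(results$family)
  if (length(fam) != 1L) {
    stop("conserve() expects results for a single family", call. = FALSE)
  }
  res <- lapply(unique(results$element), function(el) {
    r <- results[results$element == el, , drop = FALSE]
    n_ex <- length(unique(r$species_id))
    n_en <- length(unique(r$species_id[r$enriched]))
    data.frame(family = fam, element = el, n_species_enriched = n_en,
               n_species_examined = n_ex, fraction = n_en / n_ex,
               conserved = n_en / n_ex >= threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
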