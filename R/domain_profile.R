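# Domain-architecture summaries: per-group median protein length, rescaling
# of domain coordinates onto the group median, prevalence with a <5% display
# filter, and binned positional frequency histograms.

#' Median protein length of a group (lower median)
#'
#' Exact median of the member sequence lengths; for an even group size the
#' lower of the two middle order statistics is returned, so the median is
#' always an attained protein length.
#'
#' @param proteins Sequence table (with a `sequence` column) or an integer
#'   vector of lengths.
#' @return Integer median length.
#' @export
median_length <- function(proteins) {
  lens <- if (is.numeric(proteins)) as.integer(proteins)
          else nchar(proteins$sequence)
  if (!length(lens)) stop("empty group", call. = FALSE)
  sort(lens)[floor((length(lens) + 1L) / 2L)]
}

#' Rescale a domain interval to group-median coordinates
#'
#' Maps a 1-based inclusive domain interval in a protein of length
#' `protein_length` proportionally onto `[0, median]`:
#' `s = start / protein_length * median`, `e = end / protein_length *
#' median`. Real-valued; nesting and ordering are preserved.
#'
#' @param start,end Domain coordinates (1-based inclusive, `start <= end`).
#' @param protein_length Length of the annotated protein.
#' @param median Group median length (>= 1).
#' @return Numeric vector `c(s, e)` with `s <= e <= median`.
#' @export
rescale_domain <- function(start, end, protein_length, median) {
  stopifnot(start >= 1, start <= end, end <= protein_length, median >= 1)
  c(start, end) / protein_length * median
}

#' Build the domain-architecture profile of a protein group
#'
#' For one (family, species type) group: computes the group's (lower) median
#' protein length; rescales every domain annotation onto `[0, median]`;
#' computes per-domain prevalence (fraction of group proteins carrying at
#' least one copy — a per-protein predicate, so multiple copies count once);
#' drops domains seen in fewer than `min_prevalence` of the proteins (the
#' filter is applied after prevalence is computed on the full group); and
#' bins positional frequency over `bins` equal bins partitioning
#' `[0, median]`. Two positional variants are computed: `per_protein`
#' (fraction of proteins whose scaled domain interval overlaps the bin; the
#' default display value, bounded above by prevalence) and `per_occurrence`
#' (every domain copy contributes).
#'
#' @param proteins Sequence table for the group members.
#' @param annotations Domain-annotation table (see [read_domain_table()]);
#'   every annotated protein must be in `proteins`.
#' @param family,species_type Group labels, recorded in the result.
#' @param bins Number of positional bins (default 100).
#' @param min_prevalence Display filter threshold (default 0.05).
#' @return A `domain_profile`: list with `family`, `species_type`,
#'   `n_proteins`, `median_length`, `prevalence` (named vector over retained
#'   domains), `positional` and `positional_occurrence` (domain x bin
#'   matrices of frequencies in `[0, 1]`).
#' @export
profile_group <- function(proteins, annotations, family = NA_character_,
                          species_type = NA_character_, bins = 100L,
                          min_prevalence = 0.05) {
  if (bins < 1L) stop("bins must be >= 1", call. = FALSE)
  if (!nrow(proteins)) stop("empty group", call. = FALSE)
  extra <- setdiff(unique(annotations$protein_id), proteins$id)
  if (length(extra)) {
    stop("annotation for protein outside group: ", extra[1], call. = FALSE)
  }
  n <- nrow(proteins)
  med <- median_length(proteins)
  len_of <- setNames(nchar(proteins$sequence), proteins$id)
  prevalence_all <- vapply(
    unique(annotations$domain_name),
    function(d) {
      carriers <- unique(annotations$protein_id[annotations$domain_name == d])
      length(carriers) / n
    }, numeric(1))
  keep <- names(prevalence_all)[prevalence_all >= min_prevalence]
  edges_lo <- (seq_len(bins) - 1L) * med / bins
  edges_hi <- seq_len(bins) * med / bins
  per_protein <- matrix(0, length(keep), bins,
                        dimnames = list(keep, NULL))
  per_occurrence <- matrix(0, length(keep), bins,
                           dimnames = list(keep, NULL))
  for (d in keep) {
    ann <- annotations[annotations$domain_name == d, , drop = FALSE]
    hit_prot <- matrix(FALSE, n, bins,
                       dimnames = list(proteins$id, NULL))
    for (r in seq_len(nrow(ann))) {
      se <- rescale_domain(ann$start[r], ann$end[r],
                           len_of[[ann$protein_id[r]]], med)
      overlap <- se[1] <= edges_hi & se[2] >= edges_lo
      hit_prot[ann$protein_id[r], ] <- hit_prot[ann$protein_id[r], ] | overlap
      per_occurrence[d, ] <- per_occurrence[d, ] + overlap
    }
    per_protein[d, ] <- colSums(hit_prot) / n
    per_occurrence[d, ] <- per_occurrence[d, ] / n
  }
  structure(list(family = family, species_type = species_type,
                 n_proteins = n, median_length = med,
                 prevalence = prevalence_all[keep],
                 positional = per_protein,
                 positional_occurrence = per_occurrence,
                 bins = bins, min_prevalence = min_prevalence),
            class = "domain_profile")
}

#' Write a domain profile as a long-format TSV (and optionally plot it)
#'
#' Always writes the per-bin table (`group`, `domain`, `prevalence`,
#' `bin_index`, `frequency`), one row per retained domain per bin. When all
#' domains were filtered out the TSV carries the header only and a warning
#' is raised. Re-rendering from an unchanged profile is idempotent.
#'
#' @param profile A `domain_profile` from [profile_group()].
#' @param path Output TSV path.
#' @param which Positional variant to write: `"per_protein"` (default) or
#'   `"per_occurrence"`.
#' @return The written data frame, invisibly.
#' @export
render_profile <- function(profile, path,
                           which = c("per_protein", "per_occurrence")) {
  which <- match.arg(which)
  m <- if (which == "per_protein") profile$positional
       else profile$positional_occurrence
  group <- paste(profile$family, profile$species_type, sep = "/")
  if (!nrow(m)) {
    warning("all domains filtered below min_prevalence; writing header only",
            call. = FALSE)
    df <- data.frame(group = character(0), domain = character(0),
                     prevalence = numeric(0), bin_index = integer(0),
                     frequency = numeric(0))
  } else {
    df <- data.frame(
      group = group,
      domain = rep(rownames(m), each = ncol(m)),
      prevalence = rep(unname(profile$prevalence[rownames(m)]),
                       each = ncol(m)),
      bin_index = rep(seq_len(ncol(m)), nrow(m)),
      frequency = as.vector(t(m)),
      stringsAsFactors = FALSE)
  }
  write_tsv(df, path)
  invisible(df)
}

#' Plot a domain profile
#'
#' Base-graphics rendering of the positional histograms over the group
#' median length bar; cosmetic companion to [render_profile()].
#'
#' @param x A `domain_profile`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.domain_profile <- function(x, ...) {
  m <- x$positional
  if (!nrow(m)) {
    graphics::plot.new()
    graphics::title(main = "no domains above display threshold")
    return(invisible(NULL))
  }
  old <- graphics::par(mfrow = c(nrow(m), 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (d in rownames(m)) {
    graphics::barplot(m[d, ], names.arg = NULL, ylim = c(0, 1),
                      ylab = "frequency",
                      main = sprintf("%s (prevalence %.2f, median %d aa)",
                                     d, x$prevalence[[d]], x$median_length),
                      ...)
  }
  invisible(NULL)
}
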