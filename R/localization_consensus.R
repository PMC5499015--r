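# Consensus subcellular localization from five predictor calls: single
# compartment on a 3-of-5 majority, otherwise primary/secondary by vote
# frequency; proteins lacking an N-terminal methionine are unpredicted.

# Fixed priority used to break vote-count ties deterministically.
COMPARTMENT_PRIORITY <- c("nucleus", "cytosol", "mitochondrion",
                          "chloroplast", "secretory", "other")

#' Consensus localization of one protein from five predictor calls
#'
#' The rule is a pure function of the protein's leading residue and the
#' multiset of calls. A protein whose sequence does not begin with
#' methionine (`M`) is `unpredicted` regardless of the calls. Otherwise
#' `"none"` calls are discarded and compartment votes counted: any
#' compartment with at least 3 of the 5 votes gives a `single` verdict (the
#' bar is absolute — 3 of 5, not 3 of the non-none calls); otherwise the
#' most and second-most frequent compartments become primary and secondary,
#' with count ties broken by the fixed priority order nucleus > cytosol >
#' mitochondrion > chloroplast > secretory > other. If no predictor called
#' any compartment the protein is flagged low-evidence with no primary.
#'
#' @param sequence Amino-acid sequence of the protein.
#' @param calls Character vector of exactly 5 predictor calls (compartment
#'   labels or `"none"`); order is insignificant.
#' @return List with `mode` (`single` / `primary_secondary` /
#'   `unpredicted`), `primary`, `secondary` (compartment labels or `NA`),
#'   `votes` (named integer vector over compartments that received votes),
#'   and `low_evidence` (logical).
#' @export
consensus_localization <- function(sequence, calls) {
  if (length(calls) != 5L) {
    stop("exactly 5 predictor calls required, got ", length(calls),
         call. = FALSE)
  }
  bad <- setdiff(calls, c(COMPARTMENTS, "none"))
  if (length(bad)) stop("unknown compartment '", bad[1], "'", call. = FALSE)
  if (substr(sequence, 1L, 1L) != "M") {
    return(list(mode = "unpredicted", primary = NA_character_,
                secondary = NA_character_, votes = integer(0),
                low_evidence = FALSE))
  }
  votes <- table(factor(calls[calls != "none"],
                        levels = COMPARTMENT_PRIORITY))
  votes <- votes[votes > 0L]
  if (!length(votes)) {
    return(list(mode = "primary_secondary", primary = NA_character_,
                secondary = NA_character_, votes = integer(0),
                low_evidence = TRUE))
  }
  v <- as.integer(votes)
  names(v) <- names(votes)
  # names(votes) are already in priority order, so ties resolve by position
  ord <- order(-v)
  if (v[ord[1]] >= 3L) {
    return(list(mode = "single", primary = names(v)[ord[1]],
                secondary = NA_character_, votes = v, low_evidence = FALSE))
  }
  list(mode = "primary_secondary", primary = names(v)[ord[1]],
       secondary = if (length(v) >= 2L) names(v)[ord[2]] else NA_character_,
       votes = v, low_evidence = FALSE)
}

#' Consensus localization for a whole proteome
#'
#' Applies [consensus_localization()] to every protein; every proteome id
#' must be present in the prediction table.
#'
#' @param proteome Sequence table (from [read_fasta()]).
#' @param predictions Validated prediction table (from
#'   [read_prediction_table()]).
#' @return Data frame with one row per protein: `protein_id`, `mode`,
#'   `primary`, `secondary`, `votes` (e.g. `"nucleus=3;cytosol=1"`),
#'   `low_evidence`.
#' @export
consensus_table <- function(proteome, predictions) {
  missing <- setdiff(proteome$id, unique(predictions$protein_id))
  if (length(missing)) {
    stop("no predictions for protein(s): ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  calls_of <- split(predictions$call, predictions$protein_id)
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    cl <- consensus_localization(proteome$sequence[i],
                                 calls_of[[proteome$id[i]]])
    data.frame(protein_id = proteome$id[i], mode = cl$mode,
               primary = cl$primary, secondary = cl$secondary,
               votes = if (length(cl$votes))
                 paste(names(cl$votes), cl$votes, sep = "=", collapse = ";")
               else "",
               low_evidence = cl$low_evidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
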