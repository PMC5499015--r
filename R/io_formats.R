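# Readers and writers for every external representation the census touches.
# All tabular inputs are TSV with a header row; coordinates are 1-based
# inclusive at the file boundary. Readers reject malformed rows (with line
# numbers) rather than repairing them.

PROTEIN_CHARS <- "ACDEFGHIKLMNPQRSTVWYBJOUXZ*"
NUCLEOTIDE_CHARS <- "ACGTN"

check_alphabet <- function(seqs, ids, allowed, what) {
  pat <- sprintf("[^%s]", allowed)
  bad <- grepl(pat, seqs)
  if (any(bad)) {
    ch <- regmatches(seqs[bad][1], regexpr(pat, seqs[bad][1]))
    stop(sprintf("invalid %s character '%s' in sequence '%s'",
                 what, ch, ids[bad][1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a FASTA file into a sequence table
#'
#' Parses protein or nucleotide FASTA via \pkg{Biostrings}, uppercases the
#' sequences, and enforces the package's sequence invariants: unique
#' non-empty ids, non-empty sequences, and an alphabet consistent with
#' `kind`. Gap characters are rejected; use [read_alignment()] for aligned
#' (gapped) FASTA.
#'
#' @param path Path to a FASTA file.
#' @param kind `"protein"` or `"nucleotide"`.
#' @return A `data.frame` with columns `id`, `description`, `sequence`,
#'   in file order.
#' @seealso [write_fasta()], [read_alignment()]
#' @export
read_fasta <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  if (is.null(headers)) headers <- character(0)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (any(id == "")) stop("empty sequence id in ", path, call. = FALSE)
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate id ", dup[1], " in ", path, call. = FALSE)
  sequence <- toupper(as.character(set))
  if (any(sequence == "")) {
    stop("empty sequence for id ", id[sequence == ""][1], call. = FALSE)
  }
  if (any(grepl("-", sequence, fixed = TRUE))) {
    stop("gap character in ", kind, " FASTA ", path,
         " (aligned input? use read_alignment)", call. = FALSE)
  }
  allowed <- if (kind == "protein") PROTEIN_CHARS else NUCLEOTIDE_CHARS
  check_alphabet(sequence, id, allowed, kind)
  data.frame(id = id, description = description, sequence = sequence,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a sequence table as FASTA
#'
#' @param records A `data.frame` with `id`, `sequence` and optionally
#'   `description` columns, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  hdr <- ifelse(desc == "", records$id, paste(records$id, desc))
  wrap <- function(s) {
    if (nchar(s) <= width) return(s)
    paste(substring(s, seq(1L, nchar(s), width),
                    pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s))),
          collapse = "\n")
  }
  body <- vapply(records$sequence, wrap, character(1), USE.NAMES = FALSE)
  writeLines(paste0(">", hdr, "\n", body), path, sep = "\n")
  invisible(path)
}

#' Read an aligned FASTA file as a seed alignment
#'
#' Seed alignments are gapped protein FASTA with all rows the same length.
#' At least two rows are required and at least one column must have fewer
#' than 50\% gaps (otherwise no match column could be built).
#'
#' @param path Path to aligned FASTA.
#' @param family Family/class label to attach (defaults to the file name
#'   without extension).
#' @return An object of class `seed_alignment`: a list with `family`, `ids`
#'   and `seqs` (equal-length gapped sequences).
#' @export
read_alignment <- function(path, family = NULL) {
  if (is.null(family)) family <- sub("\\.[^.]*$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  id <- sub("\\s.*$", "", names(set))
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate id ", dup[1], " in ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  seed_alignment(family, id, seqs)
}

#' Construct a seed alignment object
#'
#' @param family Family label.
#' @param ids Row identifiers.
#' @param seqs Gapped, equal-length, uppercase protein sequences
#'   (gap character `-`).
#' @return A `seed_alignment` object.
#' @export
seed_alignment <- function(family, ids, seqs) {
  if (length(seqs) < 2L) stop("seed alignment needs >= 2 rows", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("seed alignment rows differ in length", call. = FALSE)
  }
  check_alphabet(gsub("-", "", seqs), ids, PROTEIN_CHARS, "protein")
  m <- do.call(rbind, strsplit(seqs, ""))
  gap_frac <- colMeans(m == "-")
  if (!any(gap_frac < 0.5)) {
    stop("seed alignment has no column with < 50% gaps", call. = FALSE)
  }
  structure(list(family = family, ids = ids, seqs = seqs),
            class = "seed_alignment")
}

read_tsv_checked <- function(path, columns) {
  stopifnot(file.exists(path))
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[columns]
}

# Header line is line 1, so data row i sits on file line i + 1.
row_line <- function(i) i + 1L

#' Read a gene-location table
#'
#' A minimal 5-column TSV (gene_id, scaffold, start, end, strand) with
#' 1-based inclusive coordinates, as exported from BioMart-style gene
#' annotation. For GFF3 input, see [read_gff3_genes()].
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `gene_id`, `scaffold`,
#'   `start`, `end` (integer, 1-based inclusive) and `strand` (`+`/`-`).
#' @export
read_gene_locations <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "scaffold", "start", "end",
                                 "strand"))
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("non-integer coordinate at line ", row_line(bad[1]), " of ", path,
         call. = FALSE)
  }
  bad <- which(start < 1L | start > end)
  if (length(bad)) {
    stop(sprintf("invalid interval (start > end or start < 1) at line %d of %s",
                 row_line(bad[1]), path), call. = FALSE)
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("unknown strand '%s' at line %d of %s",
                 df$strand[bad[1]], row_line(bad[1]), path), call. = FALSE)
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) stop("duplicate gene_id ", dup[1], call. = FALSE)
  data.frame(gene_id = df$gene_id, scaffold = df$scaffold,
             start = start, end = end, strand = df$strand,
             stringsAsFactors = FALSE)
}

#' Import gene loci from GFF3 (shim)
#'
#' Convenience importer for GFF3 annotation: keeps `gene` features only and
#' uses the `ID` attribute as `gene_id`. Provided for users whose gene
#' locations come as raw GFF3 rather than a BioMart-style export; the
#' resulting table is identical in shape to [read_gene_locations()] output.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-location `data.frame` (see [read_gene_locations()]).
#' @export
read_gff3_genes <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad)) {
    stop("malformed GFF3 record at data line ", bad[1], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  ids <- sub("^.*ID=([^;]+).*$", "\\1", m[, 9])
  no_id <- !grepl("ID=", m[, 9])
  if (any(no_id)) stop("gene feature without ID attribute", call. = FALSE)
  df <- data.frame(gene_id = ids, scaffold = m[, 1],
                   start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                   strand = m[, 7], stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-"))) {
    stop("unknown strand in GFF3 gene feature", call. = FALSE)
  }
  if (any(df$start > df$end)) stop("start > end in GFF3", call. = FALSE)
  df
}

#' Read a promoter-element (motif) library
#'
#' TSV with columns (name, pattern, category). Patterns are exact DNA
#' strings over ACGT (uppercased on read); categories must be one of the
#' three functional groups `cold_drought`, `light_circadian`, `other`.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `name`, `pattern`, `category`.
#' @export
read_motif_library <- function(path) {
  df <- read_tsv_checked(path, c("name", "pattern", "category"))
  if (nrow(df) == 0L) {
    warning("empty motif library: ", path, call. = FALSE)
    return(data.frame(name = character(0), pattern = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  pattern <- toupper(df$pattern)
  bad <- which(grepl("[^ACGT]", pattern))
  if (length(bad)) {
    stop(sprintf("non-ACGT character in pattern '%s' at line %d of %s",
                 df$pattern[bad[1]], row_line(bad[1]), path), call. = FALSE)
  }
  bad <- which(nchar(pattern) < 2L)
  if (length(bad)) {
    stop("pattern shorter than 2 bp at line ", row_line(bad[1]),
         call. = FALSE)
  }
  dup <- df$name[duplicated(df$name)]
  if (length(dup)) stop("duplicate element name ", dup[1], call. = FALSE)
  bad <- which(!df$category %in% MOTIF_CATEGORIES)
  if (length(bad)) {
    stop(sprintf("unknown category '%s' at line %d (expected %s)",
                 df$category[bad[1]], row_line(bad[1]),
                 paste(MOTIF_CATEGORIES, collapse = "/")), call. = FALSE)
  }
  data.frame(name = df$name, pattern = pattern, category = df$category,
             stringsAsFactors = FALSE)
}

#' Read a domain-annotation table
#'
#' TSV with columns (protein_id, domain_name, start, end, source), 1-based
#' inclusive amino-acid coordinates, `source` one of `pfam_like` /
#' `prosite_like`. When a proteome is supplied, annotations are
#' cross-checked against protein lengths.
#'
#' @param path Path to the TSV.
#' @param proteome Optional sequence table (from [read_fasta()]) used to
#'   validate that each annotation lies within its protein.
#' @return A `data.frame` of validated annotations.
#' @export
read_domain_table <- function(path, proteome = NULL) {
  df <- read_tsv_checked(path, c("protein_id", "domain_name", "start",
                                 "end", "source"))
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(start) | is.na(end) | start < 1L | start > end)
  if (length(bad)) {
    stop("invalid domain interval at line ", row_line(bad[1]), " of ", path,
         call. = FALSE)
  }
  bad <- which(!df$source %in% c("pfam_like", "prosite_like"))
  if (length(bad)) {
    stop(sprintf("unknown source '%s' at line %d", df$source[bad[1]],
                 row_line(bad[1])), call. = FALSE)
  }
  out <- data.frame(protein_id = df$protein_id, domain_name = df$domain_name,
                    start = start, end = end, source = df$source,
                    stringsAsFactors = FALSE)
  if (!is.null(proteome)) {
    len <- setNames(nchar(proteome$sequence), proteome$id)
    unknown <- which(!out$protein_id %in% names(len))
    if (length(unknown)) {
      stop("domain annotation for unknown protein ",
           out$protein_id[unknown[1]], call. = FALSE)
    }
    over <- which(out$end > len[out$protein_id])
    if (length(over)) {
      stop(sprintf("domain end %d exceeds length of protein %s (line %d)",
                   out$end[over[1]], out$protein_id[over[1]],
                   row_line(over[1])), call. = FALSE)
    }
  }
  out
}

#' Read a five-predictor localization table
#'
#' TSV with columns (protein_id, predictor, call). Each protein must have
#' exactly five rows, one per predictor; calls are compartment labels from
#' the closed six-label vocabulary, or `"none"`. Predictor-specific labels
#' must be mapped to this vocabulary beforehand via `alias`.
#'
#' @param path Path to the TSV.
#' @param alias Optional named character vector mapping predictor-specific
#'   compartment labels to the canonical vocabulary (names = foreign label,
#'   values = canonical label).
#' @return A validated `data.frame` with columns `protein_id`, `predictor`,
#'   `call`.
#' @export
read_prediction_table <- function(path, alias = NULL) {
  df <- read_tsv_checked(path, c("protein_id", "predictor", "call"))
  call <- df$call
  if (!is.null(alias)) {
    hit <- call %in% names(alias)
    call[hit] <- unname(alias[call[hit]])
  }
  bad <- which(!call %in% c(COMPARTMENTS, "none"))
  if (length(bad)) {
    stop(sprintf("unknown compartment '%s' at line %d (add an alias?)",
                 call[bad[1]], row_line(bad[1])), call. = FALSE)
  }
  counts <- table(df$protein_id)
  wrong <- names(counts)[counts != 5L]
  if (length(wrong)) {
    stop("protein(s) without exactly 5 predictor rows: ",
         paste(head(wrong, 5L), collapse = ", "), call. = FALSE)
  }
  per_prot_pred <- paste(df$protein_id, df$predictor)
  if (anyDuplicated(per_prot_pred)) {
    stop("duplicate (protein, predictor) row in ", path, call. = FALSE)
  }
  data.frame(protein_id = df$protein_id, predictor = df$predictor,
             call = call, stringsAsFactors = FALSE)
}

#' Read a species table
#'
#' TSV with columns (species_id, species_type); species types come from the
#' closed six-division vocabulary in [SPECIES_TYPES].
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with columns `species_id`, `species_type`.
#' @export
read_species_table <- function(path) {
  df <- read_tsv_checked(path, c("species_id", "species_type"))
  dup <- df$species_id[duplicated(df$species_id)]
  if (length(dup)) stop("duplicate species_id ", dup[1], call. = FALSE)
  bad <- which(!df$species_type %in% SPECIES_TYPES)
  if (length(bad)) {
    stop(sprintf("unknown species_type '%s' at line %d",
                 df$species_type[bad[1]], row_line(bad[1])), call. = FALSE)
  }
  data.frame(species_id = df$species_id, species_type = df$species_type,
             stringsAsFactors = FALSE)
}

#' Write a data frame as a TSV with header
#'
#' All pipeline outputs use this writer: tab-separated, header row, no
#' quoting, LF line endings, UTF-8.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
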