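# Reading and writing the standard formats: FASTA proteomes, annotation
# CSVs, prediction CSV/BED. All internal coordinates are 1-based inclusive
# (UniProt convention); conversion to 0-based half-open happens only at the
# BED boundary.

#' Read a protein FASTA file into a proteome table
#'
#' Parses a multi-record FASTA file of protein sequences. Accessions are
#' taken from UniProt-style headers (`sp|ACC|NAME` or `tr|ACC|NAME`) when
#' present, otherwise from the first whitespace-delimited token of the
#' header. Sequences are uppercased. The twenty canonical amino-acid letters
#' are accepted; the nonstandard letters X, U, B, Z are tolerated with a
#' warning; any other character is an error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `name` (remainder of the
#'   header, `NA` if absent), and `sequence`, one row per FASTA entry.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P04637|P53_HUMAN", "MEEPQSDPSV", ">Q99967", "MADHMMAM"),
#'            fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  .check_scalar_string(path, "path")
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L)
    stop("FASTA format error: no sequence records in ", path, call. = FALSE)
  headers <- names(seqs)
  sequence <- unname(toupper(as.character(seqs)))
  if (any(nchar(sequence) == 0L))
    stop("FASTA format error: empty sequence for header '",
         headers[which(nchar(sequence) == 0L)[1L]], "'", call. = FALSE)

  up_match <- regmatches(headers,
                         regexec("^(?:sp|tr)\\|([^| ]+)\\|(\\S*)", headers))
  accession <- character(length(headers))
  name <- rep(NA_character_, length(headers))
  for (i in seq_along(headers)) {
    if (length(up_match[[i]]) == 3L) {
      accession[i] <- up_match[[i]][2L]
      name[i] <- up_match[[i]][3L]
    } else {
      tokens <- strsplit(trimws(headers[i]), "\\s+")[[1L]]
      accession[i] <- tokens[1L]
      if (length(tokens) > 1L)
        name[i] <- paste(tokens[-1L], collapse = " ")
    }
  }
  if (any(accession == ""))
    stop("FASTA format error: empty accession in header", call. = FALSE)
  dup <- accession[duplicated(accession)]
  if (length(dup))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)

  bad <- grepl(paste0("[^", paste(.aa_alphabet(), collapse = ""), "]"),
               sequence)
  if (any(bad))
    stop("FASTA format error: sequence of '", accession[which(bad)[1L]],
         "' contains characters outside the amino-acid alphabet",
         call. = FALSE)
  n_nonstd <- sum(grepl(paste0("[", paste(aa_nonstandard(), collapse = ""),
                               "]"), sequence))
  if (n_nonstd > 0L)
    warning(n_nonstd, " sequence(s) contain nonstandard letters (X/U/B/Z); ",
            "they contribute no charge and never count as hydrophobic",
            call. = FALSE)

  tibble::tibble(accession = accession, name = name, sequence = sequence)
}

#' Write a proteome table to FASTA
#'
#' @param proteome Data frame with columns `accession`, `sequence`, and
#'   optionally `name`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteome, path) {
  .check_proteome(proteome)
  headers <- proteome$accession
  if ("name" %in% names(proteome)) {
    has_name <- !is.na(proteome$name) & proteome$name != ""
    headers[has_name] <- paste(headers[has_name], proteome$name[has_name])
  }
  x <- Biostrings::AAStringSet(proteome$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an activation-domain annotation CSV
#'
#' Reads an annotation table with required columns `accession`, `start`,
#' `end` (1-based inclusive). Extra columns are preserved. Rows with
#' `start > end` or `start < 1` are validation errors naming the row.
#'
#' @param path Path to a CSV file.
#' @param source_tag Optional string recorded in the `source` column of
#'   every entry (e.g. `"gold-standard"`, `"soto"`). When `NULL`, an
#'   existing `source` column is kept; otherwise `source` is set to `NA`.
#' @return A tibble of annotation entries.
#' @export
read_annotations <- function(path, source_tag = NULL) {
  .check_scalar_string(path, "path")
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("accession", "start", "end"), names(x))
  if (length(missing_cols))
    stop("annotation format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (anyNA(x$start) || anyNA(x$end))
    stop("annotation format error: non-integer start/end", call. = FALSE)
  bad <- which(x$start > x$end | x$start < 1L)
  if (length(bad))
    stop("annotation validation error at row ", bad[1L], ": start=",
         x$start[bad[1L]], ", end=", x$end[bad[1L]], call. = FALSE)
  if (!is.null(source_tag)) {
    .check_scalar_string(source_tag, "source_tag")
    x$source <- source_tag
  } else if (!("source" %in% names(x))) {
    x$source <- NA_character_
  }
  tibble::as_tibble(x)
}

#' Write an annotation or merged-entry table to CSV
#'
#' Inverse of [read_annotations()]; coordinates stay 1-based inclusive.
#'
#' @param entries Interval table with columns `accession`, `start`, `end`
#'   and any extra columns.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(entries, path) {
  .check_interval_frame(entries, "entries")
  out <- as.data.frame(entries)
  out <- out[, !vapply(out, is.list, logical(1L)), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write predictions as CSV (1-based) or BED (0-based half-open)
#'
#' The CSV dialect writes `accession,start,end` with 1-based inclusive
#' coordinates. The BED dialect writes tab-separated `accession`,
#' `start - 1`, `end` (0-based half-open), no header. An empty prediction
#' set yields a header-only CSV or an empty BED file.
#'
#' @param predictions Interval table with columns `accession`, `start`,
#'   `end`.
#' @param path Output file path.
#' @param dialect `"csv-1-based"` or `"bed-0-based"`.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(predictions, path,
                              dialect = c("csv-1-based", "bed-0-based")) {
  dialect <- match.arg(dialect)
  .check_interval_frame(predictions, "predictions")
  if (dialect == "csv-1-based") {
    out <- data.frame(accession = predictions$accession,
                      start = predictions$start, end = predictions$end)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- data.frame(accession = predictions$accession,
                      start = predictions$start - 1L, end = predictions$end)
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path Input file path.
#' @param dialect `"csv-1-based"` or `"bed-0-based"`.
#' @return A tibble with columns `accession`, `start`, `end` (1-based
#'   inclusive regardless of dialect).
#' @export
read_predictions <- function(path,
                             dialect = c("csv-1-based", "bed-0-based")) {
  dialect <- match.arg(dialect)
  .check_scalar_string(path, "path")
  if (!file.exists(path))
    stop("prediction file not found: ", path, call. = FALSE)
  if (dialect == "csv-1-based") {
    x <- utils::read.csv(path, stringsAsFactors = FALSE)
    x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  } else {
    if (file.size(path) == 0L) {
      x <- data.frame(accession = character(0), start = integer(0),
                      end = integer(0))
    } else {
      x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                             col.names = c("accession", "start", "end"))
      x$start <- as.integer(x$start) + 1L
      x$end <- as.integer(x$end)
    }
  }
  .check_interval_frame(x, "predictions")
  tibble::as_tibble(x)
}
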