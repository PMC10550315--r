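# Shared constants and interval helpers.

#' The twenty canonical amino-acid letters
#'
#' One-letter codes for the standard amino acids, in alphabetical order.
#' Nonstandard letters tolerated on input (X, U, B, Z) are in
#' [aa_nonstandard()].
#'
#' @return Character vector of length 20.
#' @export
aa_standard <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Nonstandard amino-acid letters tolerated on input
#'
#' X (unknown), U (selenocysteine), B (Asx), Z (Glx). These occur in real
#' UniProt entries; they contribute zero net charge, are never members of
#' hydrophobic residue sets, and count in composition denominators.
#'
#' @return Character vector of length 4.
#' @export
aa_nonstandard <- function() c("X", "U", "B", "Z")

.aa_alphabet <- function() c(aa_standard(), aa_nonstandard())

# Fast letter counting on a single string via byte comparison.
.count_letters <- function(sequence, letters) {
  if (length(letters) == 0L) return(0L)
  bytes <- as.integer(charToRaw(sequence))
  sum(bytes %in% as.integer(charToRaw(paste(letters, collapse = ""))))
}

.check_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
}

# Validate an accession-anchored interval table (1-based inclusive).
.check_interval_frame <- function(x, what = "interval set", allow_empty = TRUE) {
  if (!is.data.frame(x))
    stop(what, " must be a data frame with columns accession, start, end",
         call. = FALSE)
  missing_cols <- setdiff(c("accession", "start", "end"), names(x))
  if (length(missing_cols))
    stop(what, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!allow_empty && nrow(x) == 0L)
    stop(what, " must contain at least one interval", call. = FALSE)
  if (nrow(x)) {
    if (any(x$start < 1L))
      stop(what, ": start coordinates must be >= 1 (1-based inclusive)",
           call. = FALSE)
    if (any(x$end < x$start))
      stop(what, ": found end < start", call. = FALSE)
  }
  invisible(x)
}

.check_proteome <- function(proteome, what = "proteome") {
  if (!is.data.frame(proteome) ||
      !all(c("accession", "sequence") %in% names(proteome)))
    stop(what, " must be a data frame with columns accession and sequence",
         call. = FALSE)
  if (anyDuplicated(proteome$accession))
    stop(what, " contains duplicated accessions", call. = FALSE)
  invisible(proteome)
}

# Single-linkage merge of 1-based inclusive intervals: intervals overlapping
# by >= 1 residue are chained transitively; abutting intervals (gap 0,
# overlap 0) are NOT merged. Returns merged start/end plus, per merged
# interval, the indices of its members in the input order.
.merge_intervals <- function(start, end) {
  n <- length(start)
  if (n == 0L)
    return(list(start = integer(0), end = integer(0), members = list()))
  o <- order(start, end)
  m_start <- integer(0); m_end <- integer(0); members <- list()
  cur_s <- start[o[1L]]; cur_e <- end[o[1L]]; cur_m <- o[1L]
  for (k in o[-1L]) {
    if (start[k] <= cur_e) {            # overlap of >= 1 residue
      cur_e <- max(cur_e, end[k])
      cur_m <- c(cur_m, k)
    } else {
      m_start <- c(m_start, cur_s); m_end <- c(m_end, cur_e)
      members[[length(members) + 1L]] <- cur_m
      cur_s <- start[k]; cur_e <- end[k]; cur_m <- k
    }
  }
  m_start <- c(m_start, cur_s); m_end <- c(m_end, cur_e)
  members[[length(members) + 1L]] <- cur_m
  list(start = as.integer(m_start), end = as.integer(m_end),
       members = members)
}
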