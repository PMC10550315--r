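# Sliding-window decomposition of protein sequences and per-window
# composition properties. Windows ("tiles") default to 39 residues spaced
# every 1 residue; a sequence of length L yields max(0, floor((L - w)/s) + 1)
# tiles and sequences shorter than the window yield none (never padded).

#' Net charge of an amino-acid sequence
#'
#' Counted as K + R - D - E over the whole string; histidine and all other
#' letters (including nonstandard X/U/B/Z) contribute zero. Acidic regions
#' are negative under this convention.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Integer vector of net charges, one per input sequence.
#' @examples
#' net_charge("DWDWDWDWDWDWDWDWDWDW")  # -10
#' @export
net_charge <- function(sequence) {
  vapply(sequence, function(s) {
    .count_letters(s, c("K", "R")) - .count_letters(s, c("D", "E"))
  }, integer(1L), USE.NAMES = FALSE)
}

#' Count occurrences of a residue set in a sequence
#'
#' Total occurrences of any letter of `residue_set`, e.g. the W+F+Y+L count
#' of the hydrophobic axis of the boundary predictor.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param residue_set Nonempty character vector of canonical amino-acid
#'   letters; any other letter is an error.
#' @return Integer vector of counts.
#' @examples
#' count_residues("DWDWDWDWDWDWDWDWDWDW", c("W", "F", "Y", "L"))  # 10
#' @export
count_residues <- function(sequence, residue_set) {
  .check_residue_set(residue_set)
  vapply(sequence, .count_letters, integer(1L), letters = residue_set,
         USE.NAMES = FALSE)
}

.check_residue_set <- function(residue_set) {
  if (length(residue_set) == 0L)
    stop("residue_set must be nonempty", call. = FALSE)
  bad <- setdiff(toupper(residue_set), aa_standard())
  if (length(bad))
    stop("residue_set contains non-amino-acid letter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(residue_set)
}

#' Fraction of a sequence made of one amino acid
#'
#' `count(letter) / length`; the denominator includes nonstandard letters.
#' Used with the 15% rule to call Q-/P-/S-/A-/G-rich regions.
#'
#' @param sequence Character vector of nonempty amino-acid sequences.
#' @param letter Single amino-acid letter.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
composition_fraction <- function(sequence, letter) {
  .check_scalar_string(letter, "letter")
  if (any(nchar(sequence) == 0L))
    stop("composition_fraction: empty sequence", call. = FALSE)
  vapply(sequence, function(s) .count_letters(s, letter) / nchar(s),
         numeric(1L), USE.NAMES = FALSE)
}

#' Longest run of residues from a set
#'
#' Length of the longest maximal substring composed only of letters in
#' `residue_set` (e.g. runs of acidic residues with `c("D", "E")`); 0 when
#' no such letter occurs.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param residue_set Character vector of letters defining the run alphabet.
#' @return Integer vector of run lengths.
#' @examples
#' longest_run("AEEEDDA", c("D", "E"))  # 5
#' @export
longest_run <- function(sequence, residue_set) {
  vapply(sequence, function(s) {
    if (nchar(s) == 0L) return(0L)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    r <- rle(chars %in% residue_set)
    hits <- r$lengths[r$values]
    if (length(hits)) max(hits) else 0L
  }, integer(1L), USE.NAMES = FALSE)
}

# Per-window sums of an indicator/score vector, via cumulative sums.
.window_sums <- function(x, starts, window) {
  cs <- c(0, cumsum(x))
  as.integer(cs[starts + window] - cs[starts])
}

.tile_starts <- function(len, window, step) {
  if (len < window) return(integer(0))
  seq.int(1L, len - window + 1L, by = step)
}

#' Decompose one sequence into tiles with composition properties
#'
#' Chops a sequence into windows of `window` residues spaced every `step`
#' residues (1-39, 2-40, 3-41, ... for the defaults) and computes each
#' window's net charge (K + R - D - E) and hydrophobic residue count.
#'
#' @param sequence A single amino-acid sequence.
#' @param window Window length in residues (default 39).
#' @param step Spacing between window starts (default 1).
#' @param residue_set Letters counted on the hydrophobic axis (default
#'   W, F, Y, L).
#' @param accession Accession recorded on each tile.
#' @param keep_sequence Keep the tile sequences as a column (default TRUE).
#' @return A tibble with one row per tile: `accession`, `start`, `end`,
#'   `net_charge`, `hydro_count`, and optionally `sequence`. A sequence
#'   shorter than the window yields zero rows.
#' @examples
#' nrow(tile_sequence(strrep("A", 45)))  # 7 tiles
#' @export
tile_sequence <- function(sequence, window = 39L, step = 1L,
                          residue_set = c("W", "F", "Y", "L"),
                          accession = "protein", keep_sequence = TRUE) {
  .check_scalar_string(sequence, "sequence")
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L)
    stop("window and step must be >= 1", call. = FALSE)
  .check_residue_set(residue_set)
  len <- nchar(sequence)
  starts <- .tile_starts(len, window, step)
  if (length(starts) == 0L) {
    out <- tibble::tibble(accession = character(0), start = integer(0),
                          end = integer(0), net_charge = integer(0),
                          hydro_count = integer(0))
    if (keep_sequence) out$sequence <- character(0)
    return(out)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  charge_ind <- (chars %in% c("K", "R")) - (chars %in% c("D", "E"))
  hydro_ind <- as.integer(chars %in% residue_set)
  out <- tibble::tibble(
    accession = accession,
    start = starts,
    end = starts + window - 1L,
    net_charge = .window_sums(charge_ind, starts, window),
    hydro_count = .window_sums(hydro_ind, starts, window)
  )
  if (keep_sequence)
    out$sequence <- substring(sequence, out$start, out$end)
  out
}

#' Tile a whole proteome into a property table
#'
#' One row per tile over all proteins, with net charge and hydrophobic
#' count, suitable for 2-D histogramming over (net charge, hydro count).
#' Optional per-letter count columns (named `n_<letter>`) support
#' composition-enrichment analyses.
#'
#' @param proteome Data frame with columns `accession`, `sequence`.
#' @param window,step,residue_set As in [tile_sequence()].
#' @param letters Optional character vector; adds a count column per letter.
#' @param keep_sequence Keep tile sequences (default FALSE; tables over
#'   full proteomes get large).
#' @return A tibble of tiles ordered by accession then start.
#' @export
tile_table <- function(proteome, window = 39L, step = 1L,
                       residue_set = c("W", "F", "Y", "L"),
                       letters = NULL, keep_sequence = FALSE) {
  .check_proteome(proteome)
  pieces <- lapply(seq_len(nrow(proteome)), function(i) {
    tl <- tile_sequence(proteome$sequence[i], window = window, step = step,
                        residue_set = residue_set,
                        accession = proteome$accession[i],
                        keep_sequence = keep_sequence || length(letters) > 0L)
    if (length(letters) > 0L && nrow(tl) > 0L) {
      for (lt in letters)
        tl[[paste0("n_", lt)]] <- count_residues(tl$sequence, lt)
      if (!keep_sequence) tl$sequence <- NULL
    }
    tl
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0L) {
    out <- tile_sequence(strrep("A", 0L), window = window, step = step,
                         residue_set = residue_set,
                         keep_sequence = keep_sequence)
    out <- out[0L, , drop = FALSE]
    for (lt in letters) out[[paste0("n_", lt)]] <- integer(0)
  }
  tibble::as_tibble(out)
}
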