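# Curation, merging, and composition classification of activation-domain
# lists, and interval-overlap queries between accession-anchored sets.

#' Merge overlapping annotation entries per accession
#'
#' Entries sharing an accession whose intervals overlap by at least one
#' residue are merged transitively into a single entry spanning
#' `min(start)`-`max(end)` (the lower start and greater end). Sources of
#' merged members are concatenated (unique, semicolon-separated). Abutting
#' entries are not merged. Idempotent and order-independent; per accession
#' the output intervals are pairwise disjoint.
#'
#' @param entries Interval table with columns `accession`, `start`, `end`,
#'   and optionally `source`.
#' @return A tibble with columns `accession`, `start`, `end`, `source`,
#'   `n_merged`.
#' @examples
#' merge_entries(tibble::tibble(accession = c("P1", "P1"),
#'                              start = c(1L, 40L), end = c(50L, 80L)))
#' @export
merge_entries <- function(entries) {
  .check_interval_frame(entries, "entries")
  src <- if ("source" %in% names(entries)) as.character(entries$source)
         else rep(NA_character_, nrow(entries))
  pieces <- lapply(split(seq_len(nrow(entries)), entries$accession),
                   function(idx) {
    m <- .merge_intervals(entries$start[idx], entries$end[idx])
    tibble::tibble(
      accession = entries$accession[idx[1L]],
      start = m$start, end = m$end,
      source = vapply(m$members, function(mm) {
        s <- unique(src[idx[mm]])
        s <- s[!is.na(s)]
        if (length(s)) paste(s, collapse = ";") else NA_character_
      }, character(1L)),
      n_merged = vapply(m$members, length, integer(1L))
    )
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- tibble::tibble(accession = character(0), start = integer(0),
                          end = integer(0), source = character(0),
                          n_merged = integer(0))
  o <- order(out$accession, out$start, method = "radix")
  tibble::as_tibble(out[o, , drop = FALSE])
}

#' Classification thresholds for activation-domain composition classes
#'
#' @param acidic_charge_threshold A region is acidic when its net charge is
#'   strictly less than this (default -3).
#' @param richness_fraction A region is X-rich when letter X makes up at
#'   least this fraction of its residues (default 0.15).
#' @param richness_letters Letters tested for richness (default Q, P, S,
#'   A, G).
#' @return A list of class `classification_config`.
#' @export
classification_config <- function(acidic_charge_threshold = -3L,
                                  richness_fraction = 0.15,
                                  richness_letters = c("Q", "P", "S",
                                                       "A", "G")) {
  if (richness_fraction <= 0 || richness_fraction >= 1)
    stop("richness_fraction must be in (0, 1)", call. = FALSE)
  structure(list(acidic_charge_threshold =
                   as.integer(acidic_charge_threshold),
                 richness_fraction = richness_fraction,
                 richness_letters = toupper(richness_letters)),
            class = "classification_config")
}

#' Composition classes of one region
#'
#' A region is `acidic` when its net charge is strictly below the acidic
#' threshold, and `X-rich` when amino acid X makes up at least the richness
#' fraction of its residues. Labels are not mutually exclusive: a region
#' can be both acidic and S-rich. The full region sequence is classified
#' directly (never its tiles); many annotated domains are shorter than one
#' tiling window.
#'
#' @param sequence A single nonempty amino-acid sequence.
#' @param config A [classification_config()].
#' @return Character vector of labels (possibly empty), e.g.
#'   `c("acidic", "S-rich")`.
#' @examples
#' classify_region(strrep("Q", 39))  # "Q-rich"
#' @export
classify_region <- function(sequence, config = classification_config()) {
  .check_scalar_string(sequence, "sequence")
  if (nchar(sequence) == 0L)
    stop("classify_region: empty sequence", call. = FALSE)
  stopifnot(inherits(config, "classification_config"))
  labels <- character(0)
  if (net_charge(sequence) < config$acidic_charge_threshold)
    labels <- "acidic"
  for (lt in config$richness_letters)
    if (composition_fraction(sequence, lt) >= config$richness_fraction)
      labels <- c(labels, paste0(lt, "-rich"))
  labels
}

#' Classify every annotation entry against its parent sequence
#'
#' Extracts each entry's region from the loaded proteome and applies
#' [classify_region()]. Entries whose accession is absent from the
#' proteome, or whose coordinates exceed the parent length, are kept but
#' flagged (`labels` is `NA`) with a warning.
#'
#' @param entries Interval table (`accession`, `start`, `end`).
#' @param proteome Data frame with columns `accession`, `sequence`.
#' @param config A [classification_config()].
#' @return `entries` with added columns `labels` (semicolon-separated,
#'   empty string when no class applies, `NA` when unresolvable) and
#'   `flagged`.
#' @export
classify_entries <- function(entries, proteome,
                             config = classification_config()) {
  .check_interval_frame(entries, "entries")
  .check_proteome(proteome)
  idx <- match(entries$accession, proteome$accession)
  labels <- rep(NA_character_, nrow(entries))
  flagged <- is.na(idx)
  for (i in seq_len(nrow(entries))) {
    if (is.na(idx[i])) next
    parent <- proteome$sequence[idx[i]]
    if (entries$end[i] > nchar(parent)) { flagged[i] <- TRUE; next }
    region <- substr(parent, entries$start[i], entries$end[i])
    labels[i] <- paste(classify_region(region, config), collapse = ";")
  }
  if (any(flagged))
    warning(sum(flagged), " entr(ies) could not be classified ",
            "(accession absent from proteome or coordinates out of range)",
            call. = FALSE)
  out <- entries
  out$labels <- labels
  out$flagged <- flagged
  tibble::as_tibble(out)
}

#' Count entries per composition class
#'
#' Tabulates the classes assigned by [classify_entries()] over a list,
#' with the fraction of classifiable entries in each class (classes are
#' not mutually exclusive, so fractions need not sum to 1).
#'
#' @param classified Output of [classify_entries()].
#' @return A tibble with columns `label`, `n`, `fraction`.
#' @export
class_counts <- function(classified) {
  if (!("labels" %in% names(classified)))
    stop("expected the output of classify_entries()", call. = FALSE)
  ok <- !is.na(classified$labels)
  n_total <- sum(ok)
  lab <- unlist(strsplit(classified$labels[ok], ";", fixed = TRUE))
  lab <- lab[lab != ""]
  tab <- table(lab)
  tibble::tibble(label = names(tab), n = as.integer(tab),
                 fraction = as.integer(tab) / max(n_total, 1L))
}

#' Flag entries longer than half their protein
#'
#' Annotated domains spanning more than half of their transcription factor
#' have typically not been experimentally minimized; this flag supports
#' excluding them from restricted benchmarks. Entries without a loaded
#' parent sequence cannot be measured and get `NA` with a warning.
#'
#' @param entries Interval table (`accession`, `start`, `end`).
#' @param proteome Data frame with columns `accession`, `sequence`.
#' @return `entries` with an added logical column `long`.
#' @export
flag_long_entries <- function(entries, proteome) {
  .check_interval_frame(entries, "entries")
  .check_proteome(proteome)
  idx <- match(entries$accession, proteome$accession)
  parent_len <- nchar(proteome$sequence)[idx]
  out <- entries
  out$long <- (entries$end - entries$start + 1L) > parent_len / 2
  if (anyNA(out$long))
    warning(sum(is.na(out$long)), " entr(ies) lack a loaded parent ",
            "sequence and could not be length-flagged", call. = FALSE)
  tibble::as_tibble(out)
}

#' All overlapping pairs between two interval sets
#'
#' A pair matches when both intervals share an accession and overlap by at
#' least `min_overlap` residues. Besides the matched pairs, per-element hit
#' flags are returned for both sets; these are the quantities behind
#' overlap-count (precision) and proportion-found (sensitivity) columns: a
#' prediction spanning two truth entries counts once on the prediction
#' side, and each truth entry it covers counts on the truth side.
#'
#' @param set_a,set_b Interval tables (`accession`, `start`, `end`).
#' @param min_overlap Minimum shared residues (default 1, the most
#'   permissive threshold).
#' @return A list with `pairs` (tibble: `idx_a`, `idx_b`, `accession`,
#'   `overlap`), `hit_a`, `hit_b` (logical vectors along each input).
#' @export
overlap_pairs <- function(set_a, set_b, min_overlap = 1L) {
  .check_interval_frame(set_a, "set_a")
  .check_interval_frame(set_b, "set_b")
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)
  hit_a <- rep(FALSE, nrow(set_a))
  hit_b <- rep(FALSE, nrow(set_b))
  pair_rows <- list()
  idx_a_by <- split(seq_len(nrow(set_a)), set_a$accession)
  idx_b_by <- split(seq_len(nrow(set_b)), set_b$accession)
  for (acc in intersect(names(idx_a_by), names(idx_b_by))) {
    ia <- idx_a_by[[acc]]; ib <- idx_b_by[[acc]]
    fo <- IRanges::findOverlaps(
      IRanges::IRanges(set_a$start[ia], set_a$end[ia]),
      IRanges::IRanges(set_b$start[ib], set_b$end[ib]),
      minoverlap = min_overlap)
    if (length(fo) == 0L) next
    qa <- ia[S4Vectors::queryHits(fo)]
    qb <- ib[S4Vectors::subjectHits(fo)]
    hit_a[qa] <- TRUE; hit_b[qb] <- TRUE
    pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
      idx_a = qa, idx_b = qb, accession = acc,
      overlap = pmin(set_a$end[qa], set_b$end[qb]) -
        pmax(set_a$start[qa], set_b$start[qb]) + 1L)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows)
           else tibble::tibble(idx_a = integer(0), idx_b = integer(0),
                               accession = character(0),
                               overlap = integer(0))
  list(pairs = pairs, hit_a = hit_a, hit_b = hit_b)
}
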