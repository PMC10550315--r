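# Combining the mechanistic predictions with external prediction interval
# sets (e.g. exports of CNN models trained in yeast) and reporting
# consensus predictions.

#' Read an external prediction table (TSV)
#'
#' Expects tab-separated columns `accession`, `start`, `end`, optionally
#' `strength`; coordinates are normalized to 1-based inclusive (they are
#' assumed 1-based on input). Overlapping intervals per accession are
#' merged by default, since external exports often ship medium- and
#' high-strength calls for the same region.
#'
#' @param path Path to the TSV file.
#' @param name Optional set name recorded as attribute `name`.
#' @param merge_overlapping Merge per-accession overlapping intervals
#'   (default TRUE).
#' @return A tibble of intervals.
#' @export
read_external_predictions <- function(path, name = NULL,
                                      merge_overlapping = TRUE) {
  .check_scalar_string(path, "path")
  if (!file.exists(path))
    stop("external prediction file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("accession", "start", "end"), names(x))
  if (length(missing_cols))
    stop("external prediction format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  .check_interval_frame(x, "external predictions")
  out <- tibble::as_tibble(x)
  if (merge_overlapping) out <- merge_entries(out)
  if (!is.null(name)) attr(out, "name") <- name
  out
}

#' Convert per-residue scores to prediction intervals
#'
#' Applies the interval rule used for score-emitting external predictors:
#' a predicted domain is a run of at least `min_run` consecutive positions
#' with score at least `threshold` (the published rule for the ADpred CNN
#' uses 10 positions at score 0.8).
#'
#' @param scores Data frame with columns `accession`, `position` (1-based),
#'   `score`. Positions within an accession need not be sorted.
#' @param threshold Minimum per-position score (default 0.8).
#' @param min_run Minimum run length in positions (default 10).
#' @return A tibble of intervals (`accession`, `start`, `end`).
#' @export
scores_to_intervals <- function(scores, threshold = 0.8, min_run = 10L) {
  if (!is.data.frame(scores) ||
      !all(c("accession", "position", "score") %in% names(scores)))
    stop("scores must have columns accession, position, score",
         call. = FALSE)
  pieces <- lapply(split(scores, scores$accession), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    pass <- d$score >= threshold
    r <- rle(pass)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    tibble::tibble(accession = d$accession[1L],
                   start = d$position[starts_i[keep]],
                   end = d$position[ends_i[keep]])
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- tibble::tibble(accession = character(0), start = integer(0),
                          end = integer(0))
  tibble::as_tibble(out)
}

#' Keep our predictions that an external set confirms
#'
#' Returns the subset of `ours` overlapping at least one external interval
#' by `min_overlap` residues; our coordinates are retained (the consensus
#' keeps mechanistic-prediction boundaries). Each retained prediction is
#' annotated with its number of matching external intervals. For a
#' symmetric intersection of the two interval sets, set
#' `symmetric = TRUE`, which instead returns the overlapping sub-intervals
#' of matched pairs.
#'
#' @param ours Prediction table (`accession`, `start`, `end`, ...).
#' @param theirs External interval table.
#' @param min_overlap Minimum shared residues (default 1).
#' @param symmetric Return interval intersections instead of our retained
#'   predictions (default FALSE).
#' @return A tibble; in the default mode, the retained rows of `ours` plus
#'   a column `n_external_matches`.
#' @export
intersect_predictions <- function(ours, theirs, min_overlap = 1L,
                                  symmetric = FALSE) {
  .check_interval_frame(ours, "ours")
  .check_interval_frame(theirs, "theirs")
  ov <- overlap_pairs(ours, theirs, min_overlap = min_overlap)
  if (symmetric) {
    p <- ov$pairs
    out <- tibble::tibble(
      accession = p$accession,
      start = pmax(ours$start[p$idx_a], theirs$start[p$idx_b]),
      end = pmin(ours$end[p$idx_a], theirs$end[p$idx_b]))
    return(merge_entries(out)[, c("accession", "start", "end")])
  }
  out <- ours[ov$hit_a, , drop = FALSE]
  out$n_external_matches <- tabulate(ov$pairs$idx_a,
                                     nbins = nrow(ours))[ov$hit_a]
  tibble::as_tibble(out)
}

#' Consensus report across predictors and truth lists
#'
#' For the mechanistic prediction set, each external set, and each
#' mechanistic-by-external intersection, reports the set size and, against
#' every truth list, the overlap count (set elements hitting at least one
#' truth entry) and its proportion (precision).
#'
#' @param ours Mechanistic prediction table.
#' @param externals Named list of external interval tables.
#' @param truth_lists Named list of truth interval tables.
#' @param min_overlap Minimum shared residues (default 1).
#' @return A tibble with columns `predictor`, `truth`, `n_predictions`,
#'   `overlap_count`, `precision`.
#' @export
consensus_report <- function(ours, externals, truth_lists,
                             min_overlap = 1L) {
  .check_interval_frame(ours, "ours")
  if (length(externals) == 0L || is.null(names(externals)))
    stop("externals must be a named list of interval tables", call. = FALSE)
  if (length(truth_lists) == 0L || is.null(names(truth_lists)))
    stop("truth_lists must be a named list of interval tables",
         call. = FALSE)
  sets <- c(list(mechanistic = ours), externals)
  for (nm in names(externals))
    sets[[paste0("mechanistic+", nm)]] <-
      intersect_predictions(ours, externals[[nm]], min_overlap = min_overlap)
  rows <- list()
  for (set_nm in names(sets)) {
    s <- sets[[set_nm]]
    for (truth_nm in names(truth_lists)) {
      tr <- truth_lists[[truth_nm]]
      hits <- if (nrow(s) > 0L && nrow(tr) > 0L)
        sum(overlap_pairs(s, tr, min_overlap = min_overlap)$hit_a) else 0L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        predictor = set_nm, truth = truth_nm, n_predictions = nrow(s),
        overlap_count = hits,
        precision = if (nrow(s) > 0L) hits / nrow(s) else 0)
    }
  }
  do.call(rbind, rows)
}
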