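# Confusion metrics against truth lists, the length-distribution-preserving
# permutation null, composition enrichment tests, the motif-shuffle null,
# and predictor-variant scans.

#' Precision, recall, and F-score from confusion counts
#'
#' Prediction-level counting: `tp` predictions hit at least one truth
#' entry, `fp` hit none, so `tp + fp` is the number of predictions.
#' `tp_truth` truth entries are hit by at least one prediction and `fn`
#' by none. `ppv = tp / (tp + fp)`; `tpr = tp_truth / (tp_truth + fn)`;
#' `f = 2 * ppv * tpr / (ppv + tpr)`, defined as 0 when both are 0. When
#' prediction- and truth-level true-positive counts coincide (as in
#' published benchmark tables), leave `tp_truth` at its default.
#'
#' @param tp,fp,fn Confusion counts.
#' @param tp_truth Truth entries hit (defaults to `tp`).
#' @return A list with `ppv`, `tpr`, `f_score`.
#' @examples
#' evaluation_metrics(tp = 110, fp = 436, fn = 409)$f_score  # 0.207
#' @export
evaluation_metrics <- function(tp, fp, fn, tp_truth = tp) {
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  tpr <- if (tp_truth + fn > 0) tp_truth / (tp_truth + fn) else 0
  f <- if (ppv + tpr > 0) 2 * ppv * tpr / (ppv + tpr) else 0
  list(ppv = ppv, tpr = tpr, f_score = f)
}

#' Evaluate a prediction set against a truth list
#'
#' Overlap-based confusion counts at `min_overlap` shared residues:
#' true positives are predictions hitting at least one truth entry, false
#' positives are predictions hitting none (which may include genuinely
#' novel domains), false negatives are truth entries hit by nothing. True
#' negatives are protein-level: proteins carrying neither predictions nor
#' truth entries (only computable when the proteome is supplied).
#'
#' @param predictions Interval table of predictions.
#' @param truth Nonempty interval table of known domains.
#' @param proteome Optional proteome for the protein-level true-negative
#'   count.
#' @param min_overlap Minimum shared residues for a hit (default 1).
#' @return An object of class `ad_evaluation`: a list with `tp`, `fp`,
#'   `fn`, `tn`, `tp_truth`, `n_predictions`, `n_truth`, `ppv`, `tpr`,
#'   `f_score`.
#' @export
evaluate_predictions <- function(predictions, truth, proteome = NULL,
                                 min_overlap = 1L) {
  .check_interval_frame(predictions, "predictions")
  .check_interval_frame(truth, "truth", allow_empty = FALSE)
  ov <- overlap_pairs(predictions, truth, min_overlap = min_overlap)
  tp <- sum(ov$hit_a)
  fp <- nrow(predictions) - tp
  tp_truth <- sum(ov$hit_b)
  fn <- nrow(truth) - tp_truth
  tn <- NA_integer_
  if (!is.null(proteome)) {
    .check_proteome(proteome)
    covered <- union(predictions$accession, truth$accession)
    tn <- sum(!(proteome$accession %in% covered))
  }
  m <- evaluation_metrics(tp, fp, fn, tp_truth)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, tp_truth = tp_truth,
                 n_predictions = nrow(predictions), n_truth = nrow(truth),
                 ppv = m$ppv, tpr = m$tpr, f_score = m$f_score),
            class = "ad_evaluation")
}

#' @export
print.ad_evaluation <- function(x, ...) {
  cat("<ad_evaluation>\n")
  cat(sprintf("  predictions: %d   truth entries: %d\n",
              x$n_predictions, x$n_truth))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %s\n", x$tp, x$fp, x$fn,
              ifelse(is.na(x$tn), "-", x$tn)))
  cat(sprintf("  PPV %.3f  TPR %.3f  F %.3f\n", x$ppv, x$tpr, x$f_score))
  invisible(x)
}

#' Permutation test of prediction/truth overlap
#'
#' Tests whether predictions overlap a truth list more often than random
#' regions with the same per-protein structure. Each permutation samples,
#' without replacement, as many proteins as there are distinct predicted
#' accessions; each predicted accession's profile (number of predictions
#' and their lengths) is assigned to one sampled protein, inside which that
#' many regions of those lengths are placed uniformly at random. The null
#' statistic is the number of placed regions overlapping the truth list by
#' at least `min_overlap` residues (accession-matched). Keeping multiple
#' regions on one sampled protein preserves the fact that some proteins
#' carry several predictions, which makes the test more stringent than
#' treating predictions as independent. The p-value uses the add-one
#' convention `p = (r + 1) / (N + 1)` where `r` counts permutations with a
#' null overlap count at least the observed count, so p is never 0.
#'
#' A sampled protein shorter than a required region length is resampled
#' from the proteins not currently in the sample (bounded retries, then an
#' error).
#'
#' @param predictions Interval table of predictions; every accession must
#'   be present in the proteome.
#' @param truth Nonempty interval table of known domains.
#' @param proteome Proteome the random proteins are drawn from.
#' @param n_permutations Number of permutations (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param min_overlap Minimum shared residues for a hit (default 1).
#' @param max_retries Resampling attempts per too-short protein.
#' @return An object of class `ad_permtest`: a list with `p_value`,
#'   `observed`, `null_counts`, `n_permutations`.
#' @export
permutation_test <- function(predictions, truth, proteome,
                             n_permutations = 10000L, seed = NULL,
                             min_overlap = 1L, max_retries = 100L) {
  .check_interval_frame(predictions, "predictions")
  .check_interval_frame(truth, "truth", allow_empty = FALSE)
  .check_proteome(proteome)
  if (n_permutations < 1L)
    stop("n_permutations must be >= 1", call. = FALSE)
  if (nrow(predictions) == 0L)
    stop("permutation_test needs at least one prediction", call. = FALSE)
  unresolved <- setdiff(predictions$accession, proteome$accession)
  if (length(unresolved))
    stop("predicted accession(s) absent from proteome: ",
         paste(utils::head(unresolved, 3L), collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  observed <- sum(overlap_pairs(predictions, truth,
                                min_overlap = min_overlap)$hit_a)

  lengths_by_acc <- split(predictions$end - predictions$start + 1L,
                          predictions$accession)
  n_profiles <- length(lengths_by_acc)
  prot_acc <- proteome$accession
  prot_len <- nchar(proteome$sequence)
  n_prot <- length(prot_acc)
  if (n_profiles > n_prot)
    stop("more predicted accessions than proteins to sample from",
         call. = FALSE)
  truth_by_idx <- vector("list", n_prot)
  for (grp in split(seq_len(nrow(truth)), truth$accession)) {
    i <- match(truth$accession[grp[1L]], prot_acc)
    if (!is.na(i))
      truth_by_idx[[i]] <- cbind(truth$start[grp], truth$end[grp])
  }
  mo <- as.integer(min_overlap)
  all_lens <- unlist(lengths_by_acc, use.names = FALSE)
  region_rows <- split(seq_along(all_lens),
                       rep(seq_len(n_profiles),
                           lengths(lengths_by_acc)))
  profile_max <- vapply(lengths_by_acc, max, integer(1L))
  region_profile <- rep(seq_len(n_profiles), lengths(lengths_by_acc))
  no_retries_needed <- min(prot_len) >= max(all_lens)

  null_counts <- integer(n_permutations)
  for (perm in seq_len(n_permutations)) {
    samp <- sample.int(n_prot, n_profiles)
    if (!no_retries_needed) {
      in_sample <- logical(n_prot); in_sample[samp] <- TRUE
      for (j in seq_len(n_profiles)) {
        tries <- 0L
        while (prot_len[samp[j]] < profile_max[j]) {
          tries <- tries + 1L
          if (tries > max_retries)
            stop("could not sample a protein long enough for a region of ",
                 profile_max[j], " residues", call. = FALSE)
          in_sample[samp[j]] <- FALSE
          pj <- sample(which(!in_sample), 1L)
          in_sample[pj] <- TRUE
          samp[j] <- pj
        }
      }
    }
    len_here <- prot_len[samp][region_profile]
    s <- 1L + as.integer(floor(stats::runif(length(all_lens)) *
                                 (len_here - all_lens + 1L)))
    e <- s + all_lens - 1L
    cnt <- 0L
    for (j in seq_len(n_profiles)) {
      tmat <- truth_by_idx[[samp[j]]]
      if (is.null(tmat)) next
      idx <- region_rows[[j]]
      ts <- tmat[, 1L]; te <- tmat[, 2L]
      nt <- length(ts)
      if (nt == 1L) {
        cnt <- cnt + sum(pmin(e[idx], te) - pmax(s[idx], ts) + 1L >= mo)
      } else {
        ov <- pmin(rep(e[idx], each = nt), te) -
          pmax(rep(s[idx], each = nt), ts) + 1L >= mo
        cnt <- cnt + sum(.colSums(ov, nt, length(idx)) > 0L)
      }
    }
    null_counts[perm] <- cnt
  }
  r <- sum(null_counts >= observed)
  structure(list(p_value = (r + 1) / (n_permutations + 1),
                 observed = observed, null_counts = null_counts,
                 n_permutations = n_permutations),
            class = "ad_permtest")
}

#' @export
print.ad_permtest <- function(x, ...) {
  cat("<ad_permtest>\n")
  cat(sprintf("  observed overlap count: %d\n", x$observed))
  cat(sprintf("  null mean: %.2f (N = %d permutations)\n",
              mean(x$null_counts), x$n_permutations))
  cat(sprintf("  p = %.4g  [(r + 1)/(N + 1) convention]\n", x$p_value))
  invisible(x)
}

#' Per-feature composition comparison between two tile sets
#'
#' Welch two-sample t-tests of per-tile features (per-letter counts and
#' net charge) between two tile tables, with Bonferroni correction over
#' the number of features tested. The unequal-variance form is used
#' because the two tile populations typically differ wildly in size and
#' spread. Features with zero variance in both groups have an undefined
#' statistic and are flagged.
#'
#' @param tiles_a,tiles_b Tile tables carrying a `sequence` column (see
#'   [tile_table()] with `keep_sequence = TRUE`) and `net_charge`. Each
#'   must have at least 2 rows.
#' @param features Character vector of single letters and/or
#'   `"net_charge"`.
#' @param p_threshold Significance threshold on the corrected p (default
#'   0.01).
#' @return A tibble with columns `feature`, `mean_a`, `mean_b`,
#'   `statistic`, `p_value`, `p_bonferroni`, `significant`, `flagged`.
#' @export
composition_ttest <- function(tiles_a, tiles_b,
                              features = c(aa_standard(), "net_charge"),
                              p_threshold = 0.01) {
  if (nrow(tiles_a) < 2L || nrow(tiles_b) < 2L)
    stop("each tile group needs at least 2 tiles", call. = FALSE)
  feature_values <- function(tiles, f) {
    if (f == "net_charge") {
      if (!("net_charge" %in% names(tiles)))
        stop("tile table lacks a net_charge column", call. = FALSE)
      return(tiles$net_charge)
    }
    col <- paste0("n_", f)
    if (col %in% names(tiles)) return(tiles[[col]])
    if (!("sequence" %in% names(tiles)))
      stop("tile table needs a sequence column (or n_", f,
           ") to test feature '", f, "'", call. = FALSE)
    count_residues(tiles$sequence, f)
  }
  n_feat <- length(features)
  rows <- lapply(features, function(f) {
    va <- feature_values(tiles_a, f)
    vb <- feature_values(tiles_b, f)
    degenerate <- stats::var(va) == 0 && stats::var(vb) == 0
    if (degenerate && mean(va) == mean(vb)) {
      stat <- 0; p <- 1
    } else if (degenerate) {
      stat <- NA_real_; p <- NA_real_
    } else {
      tt <- stats::t.test(va, vb, var.equal = FALSE)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    tibble::tibble(feature = f, mean_a = mean(va), mean_b = mean(vb),
                   statistic = stat, p_value = p,
                   p_bonferroni = pmin(1, p * n_feat),
                   significant = !is.na(p) & pmin(1, p * n_feat) <
                     p_threshold,
                   flagged = degenerate)
  })
  do.call(rbind, rows)
}

#' Motif enrichment against a composition-preserving shuffle null
#'
#' Counts occurrences of short plain-string motifs (overlapping matches
#' allowed) in a set of sequences, then compares the total to totals from
#' uniform random shuffles of each sequence (composition preserved,
#' arrangement randomized). One-sided add-one p per motif:
#' `p = (r + 1) / (N + 1)` with `r` the number of shuffles whose null
#' total is at least the observed total. The default motifs are the
#' serine-proline and serine-glutamine phosphorylation motifs.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @param motifs Character vector of motifs, plain strings (default
#'   `c("SP", "SQ")`).
#' @param n_shuffles Number of shuffles (>= 1).
#' @param seed Optional integer seed.
#' @return A tibble with columns `motif`, `observed`, `null_mean`,
#'   `p_value`; attribute `null_totals` holds the full null matrix
#'   (shuffles x motifs).
#' @export
motif_shuffle_enrichment <- function(sequences, motifs = c("SP", "SQ"),
                                     n_shuffles = 1000L, seed = NULL) {
  if (length(sequences) == 0L)
    stop("need at least one sequence", call. = FALSE)
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  char_list <- strsplit(sequences, "", fixed = TRUE)
  motif_chars <- strsplit(motifs, "", fixed = TRUE)
  count_in <- function(chars, mot) {
    n <- length(chars); m <- length(mot)
    if (n < m) return(0L)
    hit <- rep(TRUE, n - m + 1L)
    for (k in seq_len(m))
      hit <- hit & chars[seq.int(k, n - m + k)] == mot[k]
    sum(hit)
  }
  observed <- vapply(motif_chars, function(mot)
    sum(vapply(char_list, count_in, integer(1L), mot = mot)), integer(1L))
  null_totals <- matrix(0L, nrow = n_shuffles, ncol = length(motifs))
  for (i in seq_len(n_shuffles)) {
    shuffled <- lapply(char_list, sample)
    null_totals[i, ] <- vapply(motif_chars, function(mot)
      sum(vapply(shuffled, count_in, integer(1L), mot = mot)), integer(1L))
  }
  p <- vapply(seq_along(motifs), function(j)
    (sum(null_totals[, j] >= observed[j]) + 1) / (n_shuffles + 1),
    numeric(1L))
  out <- tibble::tibble(motif = motifs, observed = observed,
                        null_mean = colMeans(null_totals), p_value = p)
  attr(out, "null_totals") <- null_totals
  out
}

#' Scan a list of boundary-model variants
#'
#' Runs [predict_proteome()] for every variant and summarizes overlap with
#' a truth list: number of passing tiles, number of predictions, overlap
#' count (predictions hitting truth), precision, and sensitivity
#' (proportion of truth entries found). Supports leave-one-residue-out,
#' residue-set substitution (with anchors re-derived via [from_anchors()]),
#' window-length, slope, and threshold sweeps — any list of models.
#'
#' @param proteome Data frame with columns `accession`, `sequence`.
#' @param truth Interval table of known domains (may be empty; overlap
#'   columns are then 0).
#' @param variants Nonempty (optionally named) list of [boundary_model()]
#'   objects.
#' @param min_overlap Minimum shared residues for a hit.
#' @return A tibble with one row per variant.
#' @export
variant_scan <- function(proteome, truth, variants, min_overlap = 1L) {
  if (length(variants) == 0L)
    stop("variants must be a nonempty list of boundary models",
         call. = FALSE)
  nms <- names(variants)
  if (is.null(nms)) nms <- paste0("variant_", seq_along(variants))
  nms[nms == ""] <- paste0("variant_", which(nms == ""))
  rows <- lapply(seq_along(variants), function(i) {
    preds <- predict_proteome(proteome, variants[[i]])
    n_pred <- nrow(preds)
    if (n_pred > 0L && nrow(truth) > 0L) {
      ov <- overlap_pairs(preds, truth, min_overlap = min_overlap)
      tp <- sum(ov$hit_a)
      found <- sum(ov$hit_b)
    } else {
      tp <- 0L; found <- 0L
    }
    tibble::tibble(variant = nms[i],
                   n_passing_tiles = attr(preds, "n_passing_tiles"),
                   n_predictions = n_pred,
                   overlap_count = tp,
                   precision = if (n_pred > 0L) tp / n_pred else 0,
                   sensitivity = if (nrow(truth) > 0L)
                     found / nrow(truth) else 0)
  })
  do.call(rbind, rows)
}
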