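# The boundary classifier over (net charge, hydrophobic count) space, and
# aggregation of passing tiles into predicted activation domains.
#
# Three named geometries, anchored by two reference 39-AA activation
# domains, CITED2 (net charge -9, W+F+Y+L = 10) and VP16 H1 (net charge
# -13, W+F+Y+L = 7):
#   original  (Charge <= -9) AND (W+F+Y+L >= 7) AND
#             (((Charge + 9) - (W+F+Y+L - 10)) <= 0)   [diagonal, slope 1]
#   corner    (Charge <= -9) AND (W+F+Y+L >= 7)        [no diagonal]
#   improved  (-13 <= Charge <= -8) AND (W+F+L >= 6)   [trapezoid]

#' Construct a boundary model
#'
#' A boundary model accepts a tile when all of the following hold:
#' `net_charge <= charge_max`; `net_charge >= charge_min` when `charge_min`
#' is given (trapezoid mode); `hydro_count >= hydro_min`; and, when a
#' diagonal is present, `(net_charge - anchor[1]) * slope -
#' (hydro_count - anchor[2]) <= 0` (the half-plane on the hydrophobic side
#' of a line of the given slope through the anchor point).
#'
#' @param residue_set Letters counted on the hydrophobic axis.
#' @param charge_max Maximum (least acidic) allowed net charge.
#' @param hydro_min Minimum hydrophobic residue count.
#' @param charge_min Optional lower net-charge bound (trapezoid mode);
#'   `NULL` for no lower bound.
#' @param slope Slope of the diagonal boundary, or `NULL` for corner mode.
#'   A vertical boundary (the corner geometry) is slope = infinity and is
#'   expressed by `slope = NULL`.
#' @param anchor Length-2 numeric `(charge, hydro)` the diagonal passes
#'   through; required when `slope` is given.
#' @param window Tile length the model is meant for (default 39).
#' @return An object of class `boundary_model`.
#' @seealso [preset_model()], [from_anchors()], [model_passes()]
#' @export
boundary_model <- function(residue_set = c("W", "F", "Y", "L"),
                           charge_max = -9L, hydro_min = 7L,
                           charge_min = NULL, slope = 1,
                           anchor = c(-9, 10), window = 39L) {
  .check_residue_set(residue_set)
  if (hydro_min < 0L) stop("hydro_min must be >= 0", call. = FALSE)
  if (!is.null(charge_min) && charge_min > charge_max)
    stop("charge_min must be <= charge_max", call. = FALSE)
  if (!is.null(slope)) {
    if (slope <= 0) stop("slope must be > 0", call. = FALSE)
    if (length(anchor) != 2L || anyNA(anchor))
      stop("a diagonal model needs a length-2 anchor (charge, hydro)",
           call. = FALSE)
  }
  structure(list(residue_set = toupper(residue_set),
                 charge_max = as.integer(charge_max),
                 charge_min = if (is.null(charge_min)) NULL
                              else as.integer(charge_min),
                 hydro_min = as.integer(hydro_min),
                 slope = slope,
                 anchor = if (is.null(slope)) NULL else as.numeric(anchor),
                 window = as.integer(window)),
            class = "boundary_model")
}

#' @export
print.boundary_model <- function(x, ...) {
  geom <- if (!is.null(x$charge_min)) "trapezoid"
          else if (!is.null(x$slope)) "diagonal" else "corner"
  cat("<boundary_model> ", geom, "\n", sep = "")
  cat("  hydrophobic set: ", paste(x$residue_set, collapse = ""),
      " (count >= ", x$hydro_min, ")\n", sep = "")
  if (!is.null(x$charge_min))
    cat("  net charge in [", x$charge_min, ", ", x$charge_max, "]\n",
        sep = "")
  else
    cat("  net charge <= ", x$charge_max, "\n", sep = "")
  if (!is.null(x$slope))
    cat("  diagonal: slope ", x$slope, " through (", x$anchor[1L], ", ",
        x$anchor[2L], ")\n", sep = "")
  cat("  window: ", x$window, " residues\n", sep = "")
  invisible(x)
}

#' Named preset boundary models
#'
#' `"original"`: diagonal model over W+F+Y+L, thresholds (-9, 7), slope-1
#' diagonal through (-9, 10). `"corner"`: the same thresholds without the
#' diagonal. `"improved"`: trapezoid over W+F+L, net charge in
#' \[-13, -8\] (inclusive at both ends), hydrophobic count >= 6.
#'
#' @param name One of `"original"`, `"corner"`, `"improved"`.
#' @return A [boundary_model()].
#' @export
preset_model <- function(name = c("original", "corner", "improved")) {
  name <- match.arg(name)
  switch(name,
    original = boundary_model(residue_set = c("W", "F", "Y", "L"),
                              charge_max = -9L, hydro_min = 7L,
                              slope = 1, anchor = c(-9, 10)),
    corner = boundary_model(residue_set = c("W", "F", "Y", "L"),
                            charge_max = -9L, hydro_min = 7L, slope = NULL),
    improved = boundary_model(residue_set = c("W", "F", "L"),
                              charge_max = -8L, charge_min = -13L,
                              hydro_min = 6L, slope = NULL))
}

#' Does a (net charge, hydro count) point pass a boundary model?
#'
#' Vectorized over `net_charge` and `hydro_count` (recycled).
#'
#' @param model A [boundary_model()].
#' @param net_charge Integer vector of tile net charges.
#' @param hydro_count Integer vector of tile hydrophobic counts.
#' @return Logical vector.
#' @examples
#' model_passes(preset_model("original"), -9, 10)   # TRUE (CITED2 anchor)
#' model_passes(preset_model("original"), -10, 7)   # FALSE (diagonal)
#' model_passes(preset_model("corner"), -10, 7)     # TRUE
#' @export
model_passes <- function(model, net_charge, hydro_count) {
  stopifnot(inherits(model, "boundary_model"))
  ok <- net_charge <= model$charge_max & hydro_count >= model$hydro_min
  if (!is.null(model$charge_min))
    ok <- ok & net_charge >= model$charge_min
  if (!is.null(model$slope))
    ok <- ok & ((net_charge - model$anchor[1L]) * model$slope -
                  (hydro_count - model$anchor[2L]) <= 0)
  ok
}

#' Derive a boundary model from two anchor sequences
#'
#' Re-derives the thresholds from the sequences of two reference tiles, the
#' mechanism used when the hydrophobic residue set or window length is
#' varied: `charge_max` is the larger (less acidic) anchor net charge,
#' `hydro_min` the smaller anchor hydrophobic count, and in diagonal mode
#' the line of the given slope is anchored at the less acidic anchor's
#' (charge, hydro) point.
#'
#' @param anchor1,anchor2 Amino-acid strings of length `window`.
#' @param residue_set Hydrophobic-axis letters used to recount the anchors.
#' @param slope Diagonal slope (diagonal mode only).
#' @param mode `"diagonal"` or `"corner"`.
#' @param window Window length; anchors of any other length are an error.
#' @return A [boundary_model()].
#' @export
from_anchors <- function(anchor1, anchor2,
                         residue_set = c("W", "F", "Y", "L"), slope = 1,
                         mode = c("diagonal", "corner"),
                         window = nchar(anchor1)) {
  mode <- match.arg(mode)
  .check_scalar_string(anchor1, "anchor1")
  .check_scalar_string(anchor2, "anchor2")
  if (nchar(anchor1) != window || nchar(anchor2) != window)
    stop("anchor sequences must have length equal to the window (",
         window, ")", call. = FALSE)
  ch <- net_charge(c(anchor1, anchor2))
  hy <- count_residues(c(anchor1, anchor2), residue_set)
  upper <- if (ch[1L] > ch[2L] || (ch[1L] == ch[2L] && hy[1L] >= hy[2L]))
    1L else 2L
  boundary_model(residue_set = residue_set,
                 charge_max = max(ch), hydro_min = min(hy),
                 slope = if (mode == "diagonal") slope else NULL,
                 anchor = c(ch[upper], hy[upper]), window = window)
}

#' Predict activation domains on one protein
#'
#' Tiles the sequence, marks tiles passing the boundary model, and merges
#' passing tiles whose intervals overlap by at least one residue
#' (transitive single-linkage chaining); each merged chain becomes one
#' prediction spanning the union of its members. Tiles that abut without
#' overlapping are not merged. Long merged chains may contain interior
#' positions whose own tiles do not individually pass.
#'
#' @param sequence A single amino-acid sequence.
#' @param model A [boundary_model()].
#' @param accession Accession recorded on the predictions.
#' @param step Tile spacing (default 1).
#' @return A tibble with columns `accession`, `start`, `end`, `n_tiles`,
#'   and list-column `tile_starts` (starts of member tiles), plus attribute
#'   `n_passing_tiles`.
#' @export
predict_protein <- function(sequence, model, accession = "protein",
                            step = 1L) {
  stopifnot(inherits(model, "boundary_model"))
  tl <- tile_sequence(sequence, window = model$window, step = step,
                      residue_set = model$residue_set,
                      accession = accession, keep_sequence = FALSE)
  pass <- which(model_passes(model, tl$net_charge, tl$hydro_count))
  merged <- .merge_intervals(tl$start[pass], tl$end[pass])
  out <- tibble::tibble(
    accession = rep(accession, length(merged$start)),
    start = merged$start,
    end = merged$end,
    n_tiles = vapply(merged$members, length, integer(1L)),
    tile_starts = lapply(merged$members,
                         function(m) tl$start[pass][sort(m)])
  )
  attr(out, "n_passing_tiles") <- length(pass)
  out
}

#' Predict activation domains over a proteome
#'
#' Applies [predict_protein()] to every record and returns all predictions
#' ordered by accession then start; the total number of passing tiles is
#' attached as attribute `n_passing_tiles`. Deterministic and invariant to
#' the order of input records.
#'
#' @param proteome Data frame with columns `accession`, `sequence`.
#' @param model A [boundary_model()].
#' @param step Tile spacing (default 1).
#' @return A tibble of predictions (see [predict_protein()]).
#' @export
predict_proteome <- function(proteome, model, step = 1L) {
  .check_proteome(proteome)
  pieces <- lapply(seq_len(nrow(proteome)), function(i)
    predict_protein(proteome$sequence[i], model,
                    accession = proteome$accession[i], step = step))
  n_pass <- sum(vapply(pieces, attr, integer(1L), which = "n_passing_tiles"))
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- predict_protein("", model)[0L, , drop = FALSE]
  o <- order(out$accession, out$start, method = "radix")
  out <- out[o, , drop = FALSE]
  attr(out, "n_passing_tiles") <- n_pass
  out
}

#' Split predictions longer than a maximum length
#'
#' Optional utility (off by default in every pipeline): splits each
#' prediction longer than `max_length` into `ceiling(length / max_length)`
#' consecutive pieces of near-equal length. Member-tile bookkeeping is
#' dropped on split pieces.
#'
#' @param predictions Prediction table (`accession`, `start`, `end`).
#' @param max_length Maximum retained length in residues.
#' @return A tibble with columns `accession`, `start`, `end`.
#' @export
split_predictions <- function(predictions, max_length) {
  .check_interval_frame(predictions, "predictions")
  if (max_length < 1L) stop("max_length must be >= 1", call. = FALSE)
  rows <- lapply(seq_len(nrow(predictions)), function(i) {
    s <- predictions$start[i]; e <- predictions$end[i]
    len <- e - s + 1L
    k <- ceiling(len / max_length)
    bounds <- floor(seq(s, e + 1L, length.out = k + 1L))
    data.frame(accession = predictions$accession[i],
               start = as.integer(bounds[-(k + 1L)]),
               end = as.integer(bounds[-1L] - 1L))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(accession = character(0), start = integer(0),
                      end = integer(0))
  tibble::as_tibble(out)
}

#' Default sub-region scheme for dissecting the boundary plane
#'
#' Configures the half-plane splits used by [assign_region()]. Regions A,
#' B, C partition the original (diagonal) acceptance region: A is the
#' high-hydrophobicity side (`hydro_count >= a_hydro`, the CITED2 side), C
#' is the strongly acidic remainder (`net_charge <= c_charge`, the VP16
#' side), B is what is left (balanced tiles). D is the corner region minus
#' the original region (points failing only the diagonal). E relaxes the
#' hydrophobic threshold by one outside the corner region; F additionally
#' relaxes the charge threshold by one. The A/B/C split approximates a
#' figure-only geometry and is fully configurable.
#'
#' @param base Original (diagonal) model.
#' @param corner Corner model with the same thresholds.
#' @param a_hydro Hydro count at or above which region A starts.
#' @param c_charge Net charge at or below which region C starts.
#' @param e_hydro Relaxed hydrophobic threshold of region E.
#' @param f_charge Relaxed charge threshold of region F.
#' @return A list of class `region_scheme`.
#' @export
region_scheme <- function(base = preset_model("original"),
                          corner = preset_model("corner"),
                          a_hydro = 10L, c_charge = -13L,
                          e_hydro = 6L, f_charge = -8L) {
  structure(list(base = base, corner = corner,
                 a_hydro = as.integer(a_hydro),
                 c_charge = as.integer(c_charge),
                 e_hydro = as.integer(e_hydro),
                 f_charge = as.integer(f_charge)),
            class = "region_scheme")
}

#' Assign (net charge, hydro count) points to boundary sub-regions
#'
#' Labels are mutually exclusive under the fixed precedence
#' A > B > C > D > E > F; points satisfying no region are `"none"`.
#'
#' @param net_charge,hydro_count Integer vectors (recycled).
#' @param scheme A [region_scheme()].
#' @return Character vector of labels in `{A, B, C, D, E, F, none}`.
#' @examples
#' assign_region(-10, 7)   # "D": passes the corner, fails the diagonal
#' assign_region(-9, 10)   # "A": the CITED2 anchor
#' @export
assign_region <- function(net_charge, hydro_count,
                          scheme = region_scheme()) {
  stopifnot(inherits(scheme, "region_scheme"))
  n <- max(length(net_charge), length(hydro_count))
  net_charge <- rep_len(net_charge, n)
  hydro_count <- rep_len(hydro_count, n)
  in_base <- model_passes(scheme$base, net_charge, hydro_count)
  in_corner <- model_passes(scheme$corner, net_charge, hydro_count)
  lab <- rep("none", n)
  is_a <- in_base & hydro_count >= scheme$a_hydro
  is_c <- in_base & !is_a & net_charge <= scheme$c_charge
  is_b <- in_base & !is_a & !is_c
  is_d <- in_corner & !in_base
  is_e <- !in_corner & net_charge <= scheme$corner$charge_max &
    hydro_count >= scheme$e_hydro
  is_f <- !in_corner & !is_e & net_charge <= scheme$f_charge &
    hydro_count >= scheme$e_hydro
  lab[is_f] <- "F"; lab[is_e] <- "E"; lab[is_d] <- "D"
  lab[is_c] <- "C"; lab[is_b] <- "B"; lab[is_a] <- "A"
  lab
}
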