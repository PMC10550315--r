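# Synthetic fixture generator: transcription-factor-like proteomes with
# planted segments of controlled net charge and hydrophobic count, plus
# matching truth annotations, so every other module is testable offline.

#' Default background residue frequencies
#'
#' Near-uniform over the 20 canonical letters with a mild K/R excess,
#' mimicking the slight positive charge of transcription factor tiles
#' (their DNA binding domains carry basic residues). Tryptophan is
#' excluded so that background windows rarely cross the predictor boundary
#' by chance at small sample sizes; this is configurable.
#'
#' @return Named numeric vector of frequencies summing to 1.
#' @export
default_background_frequencies <- function() {
  w <- stats::setNames(rep(1, 20L), aa_standard())
  w["W"] <- 0
  w[c("K", "R")] <- 1.5
  w / sum(w)
}

#' Neutral, hydrophobic-free background frequencies
#'
#' Uniform over G, S, A, T, N, Q, P: no charged and no predictor-set
#' residues, so background-only proteomes yield zero predictions under
#' every preset model. Used for guaranteed-clean planted-recovery
#' fixtures.
#'
#' @return Named numeric vector of frequencies summing to 1.
#' @export
neutral_background_frequencies <- function() {
  lt <- c("G", "S", "A", "T", "N", "Q", "P")
  stats::setNames(rep(1 / length(lt), length(lt)), lt)
}

#' Specify one kind of planted segment
#'
#' @param net_charge Target net charge of the planted segment.
#' @param hydro_count Target count of `residue_set` letters.
#' @param length Segment length in residues.
#' @param count How many such segments to plant.
#' @param residue_set Letters used for the hydrophobic content (default
#'   W, F, Y, L); must not contain charged letters.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(net_charge = -10L, hydro_count = 9L, length = 39L,
                       count = 20L, residue_set = c("W", "F", "Y", "L")) {
  if (abs(net_charge) + hydro_count > length)
    stop("unachievable plant: |net_charge| + hydro_count exceeds length",
         call. = FALSE)
  if (length(intersect(toupper(residue_set), c("K", "R", "D", "E"))))
    stop("plant residue_set must not contain charged letters", call. = FALSE)
  .check_residue_set(residue_set)
  structure(list(net_charge = as.integer(net_charge),
                 hydro_count = as.integer(hydro_count),
                 length = as.integer(length), count = as.integer(count),
                 residue_set = toupper(residue_set)),
            class = "plant_spec")
}

#' Specify a synthetic proteome
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer pair, inclusive protein length range.
#' @param background_frequencies Named letter frequencies of the
#'   background.
#' @param plants List of [plant_spec()] objects (may be empty).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 50L, length_range = c(250L, 400L),
                           background_frequencies =
                             default_background_frequencies(),
                           plants = list(plant_spec()), seed = 1L) {
  if (n_proteins < 1L) stop("n_proteins must be >= 1", call. = FALSE)
  if (length(length_range) != 2L || length_range[1L] > length_range[2L])
    stop("length_range must be an increasing integer pair", call. = FALSE)
  if (abs(sum(background_frequencies) - 1) > 1e-8)
    stop("background frequencies must sum to 1", call. = FALSE)
  if (is.null(names(background_frequencies)) ||
      !all(names(background_frequencies) %in% aa_standard()))
    stop("background frequencies must be named with canonical letters",
         call. = FALSE)
  for (p in plants) stopifnot(inherits(p, "plant_spec"))
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 background_frequencies = background_frequencies,
                 plants = plants, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Deterministic construction of a planted segment with exactly the target
# properties: acidic (or basic) letters supply the charge, residue_set
# letters the hydrophobic count, and charge-free non-set letters fill the
# remainder; the letters are then shuffled so composition is exact but
# arrangement random.
.build_plant <- function(plant) {
  charged <- if (plant$net_charge < 0L) {
    rep_len(c("D", "E"), -plant$net_charge)
  } else if (plant$net_charge > 0L) {
    rep_len(c("K", "R"), plant$net_charge)
  } else character(0)
  hydro <- rep_len(plant$residue_set, plant$hydro_count)
  filler_pool <- setdiff(c("G", "S", "A", "T", "N", "Q", "P"),
                         plant$residue_set)
  n_fill <- plant$length - length(charged) - length(hydro)
  filler <- rep_len(filler_pool, n_fill)
  paste(sample(c(charged, hydro, filler)), collapse = "")
}

#' Generate a synthetic proteome with planted segments and truth
#'
#' Background sequences are drawn letterwise from the background
#' frequencies. Each planted segment is constructed to have exactly its
#' target net charge and hydrophobic count, inserted (overwriting the
#' background, length preserved) at a random position of a random protein
#' such that plants never overlap each other; its coordinates are recorded
#' in the truth list. Fully reproducible under `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `proteome` (tibble: `accession`, `name`,
#'   `sequence`) and `truth` (tibble: `accession`, `start`, `end`,
#'   `source`, `net_charge`, `hydro_count`).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  letters_pool <- names(spec$background_frequencies)
  lens <- sample(seq.int(spec$length_range[1L], spec$length_range[2L]),
                 spec$n_proteins, replace = TRUE)
  sequences <- vapply(lens, function(L)
    paste(sample(letters_pool, L, replace = TRUE,
                 prob = spec$background_frequencies), collapse = ""),
    character(1L))
  accession <- sprintf("SYN%04d", seq_len(spec$n_proteins))
  occupied <- vector("list", spec$n_proteins)
  truth_rows <- list()
  for (plant in spec$plants) {
    if (plant$length > max(lens))
      stop("plant length exceeds every protein length", call. = FALSE)
    for (k in seq_len(plant$count)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        i <- sample.int(spec$n_proteins, 1L)
        if (lens[i] < plant$length) next
        s <- sample.int(lens[i] - plant$length + 1L, 1L)
        e <- s + plant$length - 1L
        occ <- occupied[[i]]
        clash <- !is.null(occ) && any(occ[, 1L] <= e & occ[, 2L] >= s)
        if (clash) next
        segment <- .build_plant(plant)
        substr(sequences[i], s, e) <- segment
        occupied[[i]] <- rbind(occ, c(s, e))
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          accession = accession[i], start = s, end = e, source = "plant",
          net_charge = plant$net_charge, hydro_count = plant$hydro_count)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place a plant without overlap; lower the plant ",
             "count or lengthen the proteins", call. = FALSE)
    }
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
           else tibble::tibble(accession = character(0), start = integer(0),
                               end = integer(0), source = character(0),
                               net_charge = integer(0),
                               hydro_count = integer(0))
  list(proteome = tibble::tibble(accession = accession,
                                 name = "synthetic TF-like protein",
                                 sequence = sequences),
       truth = truth)
}

#' Generate a background-only proteome with random truth intervals
#'
#' Calibration input for the permutation test: truth intervals are placed
#' uniformly at random, independent of sequence composition, so observed
#' and null overlap counts are exchangeable.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Inclusive protein length range (a constant length
#'   keeps observed and null placements exactly exchangeable).
#' @param n_truth Number of random truth intervals.
#' @param truth_length_range Inclusive truth-interval length range.
#' @param background_frequencies Background letter frequencies.
#' @param seed Integer seed.
#' @return A list with `proteome` and `truth` tibbles.
#' @export
generate_null_proteome <- function(n_proteins = 100L,
                                   length_range = c(300L, 300L),
                                   n_truth = 30L,
                                   truth_length_range = c(30L, 60L),
                                   background_frequencies =
                                     default_background_frequencies(),
                                   seed = 1L) {
  spec <- synthetic_spec(n_proteins = n_proteins,
                         length_range = length_range,
                         background_frequencies = background_frequencies,
                         plants = list(), seed = seed)
  out <- generate_proteome(spec)
  lens <- nchar(out$proteome$sequence)
  i <- sample.int(n_proteins, n_truth, replace = TRUE)
  tl <- sample(seq.int(truth_length_range[1L], truth_length_range[2L]),
               n_truth, replace = TRUE)
  bad <- which(lens[i] < tl)
  while (length(bad)) {          # redraw placements that cannot fit
    i[bad] <- sample.int(n_proteins, length(bad), replace = TRUE)
    tl[bad] <- sample(seq.int(truth_length_range[1L],
                              truth_length_range[2L]),
                      length(bad), replace = TRUE)
    bad <- which(lens[i] < tl)
  }
  s <- 1L + as.integer(floor(stats::runif(n_truth) * (lens[i] - tl + 1L)))
  truth <- tibble::tibble(accession = out$proteome$accession[i],
                          start = s, end = s + tl - 1L,
                          source = rep("random", n_truth))
  list(proteome = out$proteome, truth = truth)
}

#' Place random regions on random proteins
#'
#' Draws `n_proteins_used` distinct proteins and places
#' `n_per_protein` regions of lengths sampled from `length_range`
#' uniformly within each — a random "prediction set" for null experiments.
#'
#' @param proteome Data frame with columns `accession`, `sequence`.
#' @param n_proteins_used Number of distinct proteins to use.
#' @param n_per_protein Regions per chosen protein.
#' @param length_range Inclusive region length range.
#' @param seed Optional integer seed.
#' @return A tibble of intervals (`accession`, `start`, `end`).
#' @export
random_region_set <- function(proteome, n_proteins_used, n_per_protein,
                              length_range = c(39L, 60L), seed = NULL) {
  .check_proteome(proteome)
  if (!is.null(seed)) set.seed(seed)
  lens <- nchar(proteome$sequence)
  eligible <- which(lens >= length_range[2L])
  if (length(eligible) < n_proteins_used)
    stop("not enough proteins of sufficient length", call. = FALSE)
  chosen <- sample(eligible, n_proteins_used)
  rows <- lapply(chosen, function(i) {
    rl <- sample(seq.int(length_range[1L], length_range[2L]),
                 n_per_protein, replace = TRUE)
    s <- vapply(rl, function(l) sample.int(lens[i] - l + 1L, 1L),
                integer(1L))
    tibble::tibble(accession = proteome$accession[i], start = s,
                   end = s + rl - 1L)
  })
  do.call(rbind, rows)
}
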