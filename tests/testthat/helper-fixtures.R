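# Fixtures and independent oracles used across the test files. All
# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

random_aa_seq <- function(n, letters = aa_standard(), prob = NULL) {
  paste(sample(letters, n, replace = TRUE, prob = prob), collapse = "")
}

intervals <- function(accession, start, end) {
  tibble::tibble(accession = accession, start = as.integer(start),
                 end = as.integer(end))
}

# Brute-force interval union: merge any two intervals overlapping by >= 1
# residue, repeat to fixpoint. Quadratic and independent of the package's
# sweep-merge implementation.
oracle_union <- function(start, end) {
  iv <- unique(cbind(as.integer(start), as.integer(end)))
  repeat {
    n <- nrow(iv)
    merged <- FALSE
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (i >= j) next
        if (iv[i, 1] <= iv[j, 2] && iv[j, 1] <= iv[i, 2]) {
          iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  iv[order(iv[, 1]), , drop = FALSE]
}

# All-pairs overlap scan, independent of IRanges.
oracle_overlap_pairs <- function(a, b, min_overlap = 1L) {
  hits <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$accession[i] != b$accession[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1L
      if (ov >= min_overlap)
        hits <- rbind(hits, c(i, j, ov))
    }
  }
  hits
}

# A protein with a single planted 39-mer of exact (net charge, WFYL count),
# embedded in a neutral charge-free, hydrophobic-free background.
planted_protein <- function(net_charge, hydro_count, total_len = 200L,
                            at = 81L) {
  stopifnot(abs(net_charge) + hydro_count <= 39L)
  acidic <- rep_len(c("D", "E"), abs(net_charge))
  hydro <- rep_len(c("W", "F", "Y", "L"), hydro_count)
  fill <- rep_len(c("G", "S", "A", "T"), 39L - length(acidic) -
                    length(hydro))
  segment <- paste(sample(c(acidic, hydro, fill)), collapse = "")
  background <- random_aa_seq(total_len, c("G", "S", "A", "T", "N", "Q"))
  paste0(substr(background, 1L, at - 1L), segment,
         substr(background, at + 39L, total_len))
}

# Synthetic 39-mer anchor sequences with exactly the reference tile
# properties: (net charge -9, WFYL 10) and (net charge -13, WFYL 7).
synthetic_anchor <- function(net_charge, hydro_count) {
  paste(c(rep_len(c("D", "E"), -net_charge),
          rep_len(c("W", "F", "Y", "L"), hydro_count),
          rep_len(c("G", "S", "A", "T"),
                  39L + net_charge - hydro_count)),
        collapse = "")
}
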