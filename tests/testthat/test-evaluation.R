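test_that("metric identities hold on fuzzed confusion inputs", {
  # perfect predictions
  truth <- intervals("P1", c(10L, 100L), c(48L, 140L))
  ev <- evaluate_predictions(truth, truth)
  expect_equal(c(ev$ppv, ev$tpr, ev$f_score), c(1, 1, 1))
  # fuzz: tp + fp = n_predictions and all rates in [0, 1]
  set.seed(131)
  proteome <- tibble::tibble(accession = sprintf("P%02d", 1:20),
                             sequence = replicate(20L, random_aa_seq(200L)))
  for (trial in 1:20) {
    preds <- random_region_set(proteome, sample(3:10, 1L),
                               sample(1:3, 1L), c(20L, 60L))
    truth <- random_region_set(proteome, sample(3:10, 1L),
                               sample(1:3, 1L), c(20L, 60L))
    ev <- evaluate_predictions(preds, truth, proteome)
    expect_equal(ev$tp + ev$fp, nrow(preds))
    expect_equal(ev$tp_truth + ev$fn, nrow(truth))
    expect_true(all(c(ev$ppv, ev$tpr, ev$f_score) >= 0 &
                      c(ev$ppv, ev$tpr, ev$f_score) <= 1))
    expect_lte(ev$tn, nrow(proteome))
  }
  expect_error(evaluate_predictions(truth, truth[0L, ]), "at least one")
})

test_that("protein-level true negatives count uncovered proteins", {
  proteome <- tibble::tibble(accession = c("P1", "P2", "P3", "P4"),
                             sequence = replicate(4L, strrep("G", 100L)))
  preds <- intervals("P1", 1L, 40L)
  truth <- intervals("P2", 1L, 40L)
  ev <- evaluate_predictions(preds, truth, proteome)
  expect_equal(ev$tn, 2L)  # P3 and P4 carry neither
})

test_that("permutation test is seeded-reproducible with valid p-values", {
  set.seed(141)
  nul <- generate_null_proteome(n_proteins = 30L,
                                length_range = c(150L, 250L),
                                n_truth = 15L, seed = 9L)
  preds <- random_region_set(nul$proteome, 6L, 2L, c(39L, 50L), seed = 5L)
  a <- permutation_test(preds, nul$truth, nul$proteome,
                        n_permutations = 99L, seed = 17L)
  b <- permutation_test(preds, nul$truth, nul$proteome,
                        n_permutations = 99L, seed = 17L)
  expect_identical(a$null_counts, b$null_counts)
  expect_identical(a$p_value, b$p_value)
  expect_gt(a$p_value, 0)      # add-one convention: never exactly 0
  expect_lte(a$p_value, 1)
  # unresolvable accession violates the precondition
  bad <- intervals("NOPE", 1L, 39L)
  expect_error(permutation_test(bad, nul$truth, nul$proteome,
                                n_permutations = 9L), "absent")
})

test_that("predictions identical to sparse truth reach the minimal p", {
  # truth covers < 1% of residues; no random placement can beat a perfect
  # overlap count, so p = 1/(N + 1)
  syn <- generate_proteome(synthetic_spec(
    n_proteins = 40L, length_range = c(300L, 300L),
    plants = list(plant_spec(count = 5L)), seed = 23L))
  pt <- permutation_test(syn$truth[, c("accession", "start", "end")],
                         syn$truth, syn$proteome, n_permutations = 999L,
                         seed = 29L)
  expect_equal(pt$observed, 5L)
  expect_equal(pt$p_value, 1 / 1000)
})

test_that("composition t-tests flag planted shifts and only those", {
  set.seed(151)
  base_letters <- c("G", "S", "A", "T", "L")
  tiles_a <- tibble::tibble(
    sequence = replicate(400L, random_aa_seq(39L, base_letters,
                                             c(1, 1, 1, 1, 3))),
    net_charge = 0L)
  tiles_b <- tibble::tibble(
    sequence = replicate(400L, random_aa_seq(39L, base_letters,
                                             c(1, 1, 1, 1, 1))),
    net_charge = 0L)
  tiles_a$net_charge <- net_charge(tiles_a$sequence)
  tiles_b$net_charge <- net_charge(tiles_b$sequence)
  res <- composition_ttest(tiles_a, tiles_b,
                           features = c("L", "G", "net_charge"))
  expect_true(res$significant[res$feature == "L"])
  expect_gt(res$mean_a[res$feature == "L"],
            res$mean_b[res$feature == "L"])
  # net charge is structurally 0 in both groups: degenerate, flagged
  expect_true(res$flagged[res$feature == "net_charge"])
  expect_false(res$significant[res$feature == "net_charge"])
  # identical groups: statistic 0, corrected p = 1
  same <- composition_ttest(tiles_a, tiles_a, features = c("L", "G"))
  expect_true(all(same$p_bonferroni == 1))
  expect_false(any(same$significant))
})

test_that("motif shuffle null matches exact enumeration on a small case", {
  # "SPSPSPSP": 4 overlapping SP occurrences observed; the exact null mean
  # over all arrangements of 4 S and 4 P is 7 * (4/8) * (4/7) = 2
  exact_mean <- local({
    counts <- apply(utils::combn(8L, 4L), 2L, function(pos) {
      chars <- rep("P", 8L); chars[pos] <- "S"
      sum(chars[-8L] == "S" & chars[-1L] == "P")
    })
    mean(counts)
  })
  expect_equal(exact_mean, 2)
  res <- motif_shuffle_enrichment("SPSPSPSP", motifs = "SP",
                                  n_shuffles = 2000L, seed = 3L)
  expect_equal(res$observed, 4L)
  expect_lt(abs(res$null_mean - exact_mean), 0.1)
  expect_lt(res$p_value, 0.05)
  # motif absent entirely: observed 0, p = 1
  res0 <- motif_shuffle_enrichment(strrep("A", 30L), motifs = "SP",
                                   n_shuffles = 50L, seed = 3L)
  expect_equal(res0$observed, 0L)
  expect_equal(res0$p_value, 1)
  # seeded reproducibility
  r1 <- motif_shuffle_enrichment(c("SPQSPA", "AQSPSS"), n_shuffles = 99L,
                                 seed = 7L)
  r2 <- motif_shuffle_enrichment(c("SPQSPA", "AQSPSS"), n_shuffles = 99L,
                                 seed = 7L)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("variant scans rank the residue set matching planted signal", {
  # plants are rich in L only; among single-letter hydrophobic axes the
  # {L} variant must recover every plant
  syn <- generate_proteome(synthetic_spec(
    n_proteins = 30L, length_range = c(200L, 300L),
    background_frequencies = neutral_background_frequencies(),
    plants = list(plant_spec(net_charge = -10L, hydro_count = 9L,
                             count = 10L, residue_set = "L")),
    seed = 37L))
  variants <- list(
    L = boundary_model(residue_set = "L", charge_max = -9L, hydro_min = 7L,
                       slope = NULL),
    W = boundary_model(residue_set = "W", charge_max = -9L, hydro_min = 7L,
                       slope = NULL),
    F = boundary_model(residue_set = "F", charge_max = -9L, hydro_min = 7L,
                       slope = NULL))
  sc <- variant_scan(syn$proteome, syn$truth, variants)
  expect_equal(sc$sensitivity[sc$variant == "L"], 1)
  expect_equal(sc$sensitivity[sc$variant == "W"], 0)
  expect_equal(sc$n_predictions[sc$variant == "W"], 0L)
  # duplicate variants give identical rows
  sc2 <- variant_scan(syn$proteome, syn$truth,
                      list(a = variants$L, b = variants$L))
  expect_equal(sc2$n_predictions[1L], sc2$n_predictions[2L])
  expect_equal(sc2$overlap_count[1L], sc2$overlap_count[2L])
  # empty proteome: all-zero counts
  sc3 <- variant_scan(syn$proteome[0L, ], syn$truth, variants)
  expect_true(all(sc3$n_predictions == 0L))
  expect_true(all(sc3$overlap_count == 0L))
})
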