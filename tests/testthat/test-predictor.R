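test_that("preset boundary decisions match the published anchor algebra", {
  original <- preset_model("original")
  corner <- preset_model("corner")
  improved <- preset_model("improved")
  # the two anchor tiles pass the original model
  expect_true(model_passes(original, -9, 10))   # CITED2
  expect_true(model_passes(original, -13, 7))   # VP16 H1
  # (-10, 7) fails only the diagonal: (-10+9) - (7-10) = 2 > 0
  expect_false(model_passes(original, -10, 7))
  expect_true(model_passes(corner, -10, 7))
  # trapezoid lower charge bound is inclusive at -13, violated at -14
  expect_true(model_passes(improved, -13, 6))
  expect_false(model_passes(improved, -14, 10))
  expect_false(model_passes(improved, -7, 10))
  expect_false(model_passes(improved, -9, 5))
})

test_that("corner-mode acceptance is monotone; the diagonal only removes", {
  set.seed(61)
  corner <- preset_model("corner")
  original <- preset_model("original")
  improved <- preset_model("improved")
  for (trial in 1:200) {
    c1 <- sample(-20:0, 1L); h1 <- sample(0:15, 1L)
    if (model_passes(corner, c1, h1)) {
      # more acidic and/or more hydrophobic must also pass
      expect_true(model_passes(corner, c1 - sample(0:3, 1L),
                               h1 + sample(0:3, 1L)))
    }
    # diagonal region is a subset of the corner region
    if (model_passes(original, c1, h1))
      expect_true(model_passes(corner, c1, h1))
    # trapezoid is monotone in h within its charge band
    if (model_passes(improved, c1, h1))
      expect_true(model_passes(improved, c1, min(15L, h1 + 1L)))
  }
})

test_that("anchor-derived models recover thresholds from sequences", {
  set.seed(71)
  cited2_like <- synthetic_anchor(-9L, 10L)
  vp16_like <- synthetic_anchor(-13L, 7L)
  m <- from_anchors(cited2_like, vp16_like)
  expect_equal(m$charge_max, -9L)
  expect_equal(m$hydro_min, 7L)
  expect_equal(m$anchor, c(-9, 10))
  expect_equal(m$slope, 1)
  # decisions agree with the constant-based preset on the whole grid
  grid <- expand.grid(ch = -20:0, hy = 0:15)
  expect_equal(model_passes(m, grid$ch, grid$hy),
               model_passes(preset_model("original"), grid$ch, grid$hy))
  # corner mode omits the diagonal
  mc <- from_anchors(cited2_like, vp16_like, mode = "corner")
  expect_null(mc$slope)
  expect_true(model_passes(mc, -10, 7))
  # reduced residue set: thresholds re-derived by recounting the anchors
  ml <- from_anchors(cited2_like, vp16_like, residue_set = "L")
  expect_equal(ml$hydro_min, min(count_residues(c(cited2_like, vp16_like),
                                                "L")))
  # identical anchors give a degenerate but well-defined model
  mi <- from_anchors(cited2_like, cited2_like)
  expect_equal(mi$charge_max, -9L)
  expect_equal(mi$hydro_min, 10L)
  expect_error(from_anchors(substr(cited2_like, 1L, 38L), vp16_like),
               "length")
})

test_that("passing tiles chain into predictions; abutting tiles stay apart", {
  # tiles at starts 10 and 20 (window 39) overlap -> one chain 10-58
  m <- tadpred:::.merge_intervals(c(10L, 20L), c(48L, 58L))
  expect_equal(m$start, 10L)
  expect_equal(m$end, 58L)
  # disjoint tiles at starts 1 and 100 stay two chains
  m2 <- tadpred:::.merge_intervals(c(1L, 100L), c(39L, 138L))
  expect_equal(m2$start, c(1L, 100L))
  # abutting intervals (overlap 0) are NOT merged; 1-residue overlap is
  m3 <- tadpred:::.merge_intervals(c(1L, 40L), c(39L, 78L))
  expect_equal(length(m3$start), 2L)
  m4 <- tadpred:::.merge_intervals(c(1L, 39L), c(39L, 77L))
  expect_equal(length(m4$start), 1L)

  # at sequence level: one planted passing segment in a neutral protein
  set.seed(101)
  model <- preset_model("original")
  seg <- synthetic_anchor(-10L, 10L)
  neutral <- function(n) strrep("G", n)
  p1 <- predict_protein(paste0(neutral(9L), seg, neutral(100L)), model,
                        accession = "P1")
  expect_equal(nrow(p1), 1L)
  expect_lte(p1$start, 10L)
  expect_gte(p1$end, 48L)
  # two well-separated planted segments -> two predictions
  p2 <- predict_protein(paste0(seg, neutral(80L), seg), model,
                        accession = "P2")
  expect_equal(nrow(p2), 2L)
  # no passing tiles -> empty
  expect_equal(nrow(predict_protein(neutral(200L), model)), 0L)
})

test_that("prediction aggregation equals the brute-force union oracle", {
  set.seed(81)
  model <- preset_model("original")
  enriched <- c("D", "E", "W", "F", "Y", "L", "G", "S", "K")
  prob <- c(3, 3, 1, 2, 1, 3, 3, 3, 1)
  for (trial in 1:150) {
    s <- random_aa_seq(sample(39:160, 1L), enriched, prob)
    tl <- tile_sequence(s, keep_sequence = FALSE)
    pass <- model_passes(model, tl$net_charge, tl$hydro_count)
    got <- predict_protein(s, model)
    if (!any(pass)) {
      expect_equal(nrow(got), 0L)
      next
    }
    want <- oracle_union(tl$start[pass], tl$end[pass])
    expect_equal(got$start, unname(want[, 1L]))
    expect_equal(got$end, unname(want[, 2L]))
    # first and last member tiles of each prediction individually pass
    for (i in seq_len(nrow(got))) {
      ends_of_chain <- range(got$tile_starts[[i]])
      expect_true(all(pass[match(ends_of_chain, tl$start)]))
    }
    expect_equal(attr(got, "n_passing_tiles"), sum(pass))
    expect_equal(sum(got$n_tiles), sum(pass))
  }
})

test_that("proteome predictions are ordered and order-invariant", {
  set.seed(91)
  proteome <- tibble::tibble(
    accession = sprintf("P%02d", 1:12),
    sequence = replicate(12L, planted_protein(-10L, 10L)))
  model <- preset_model("original")
  a <- predict_proteome(proteome, model)
  b <- predict_proteome(proteome[sample(12L), ], model)
  expect_equal(a$accession, b$accession)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(attr(a, "n_passing_tiles"), attr(b, "n_passing_tiles"))
  expect_false(is.unsorted(a$accession))
})

test_that("boundary sub-regions partition the plane with fixed precedence", {
  expect_equal(assign_region(-10, 7), "D")   # corner minus diagonal
  expect_equal(assign_region(-9, 10), "A")   # CITED2 side
  expect_equal(assign_region(-13, 7), "C")   # VP16 side
  expect_equal(assign_region(-10, 9), "B")   # balanced interior
  expect_equal(assign_region(-9, 6), "E")    # hydro threshold relaxed by 1
  expect_equal(assign_region(-8, 9), "F")    # charge threshold relaxed by 1
  expect_equal(assign_region(0, 0), "none")
  # labels are exclusive and exhaustive over the grid
  grid <- expand.grid(ch = -20:0, hy = 0:15)
  lab <- assign_region(grid$ch, grid$hy)
  expect_true(all(lab %in% c("A", "B", "C", "D", "E", "F", "none")))
  in1 <- model_passes(preset_model("original"), grid$ch, grid$hy)
  in2 <- model_passes(preset_model("corner"), grid$ch, grid$hy)
  expect_true(all(lab[in1] %in% c("A", "B", "C")))
  expect_true(all(lab[in2 & !in1] == "D"))
})

test_that("long predictions can be split into bounded pieces", {
  pred <- intervals("P1", 1L, 120L)
  sp <- split_predictions(pred, max_length = 50L)
  expect_equal(nrow(sp), 3L)
  expect_true(all(sp$end - sp$start + 1L <= 50L))
  expect_equal(sp$start[1L], 1L)
  expect_equal(sp$end[nrow(sp)], 120L)
  expect_true(all(sp$start[-1L] == sp$end[-nrow(sp)] + 1L))
  # predictions within the bound are untouched
  expect_equal(nrow(split_predictions(intervals("P1", 5L, 40L), 50L)), 1L)
})
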