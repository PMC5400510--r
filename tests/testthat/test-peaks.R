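test_that("an all-zero track yields no consensus positions", {
  coords <- test_coords()
  zero <- new_dyad_track(numeric(3800), coords, normalized = TRUE)
  expect_identical(nrow(call_consensus_positions(zero)), 0L)
})

test_that("a synthetic bump above threshold is called at its centre with its height", {
  coords <- test_coords()
  trk <- bump_track(coords, centre = 500, height = 3)
  peaks <- call_consensus_positions(trk, threshold = 2)
  expect_identical(peaks$position_abs, 500L)
  expect_equal(peaks$height, 3)
  expect_identical(peaks$position_acs, to_acs_relative(500L, coords))
  # brute-force argmax agrees
  expect_identical(which.max(track_values(trk)) - 1L, 500L)
})

test_that("sub-threshold maxima are never called", {
  coords <- test_coords()
  trk <- bump_track(coords, centre = 500, height = 1.5)
  expect_identical(nrow(call_consensus_positions(trk, threshold = 2)), 0L)
  at <- bump_track(coords, centre = 500, height = 2)  # equality is not exceedance
  expect_identical(nrow(call_consensus_positions(at, threshold = 2)), 0L)
})

test_that("close maxima are suppressed greedily, keeping the highest", {
  coords <- test_coords()
  vals <- track_values(bump_track(coords, 300, 4)) +
    track_values(bump_track(coords, 360, 3))
  trk <- new_dyad_track(vals, coords, normalized = TRUE)
  peaks <- call_consensus_positions(trk, threshold = 2, min_separation = 120)
  expect_identical(nrow(peaks), 1L)
  expect_lte(abs(peaks$position_abs - 300L), 2L)
  wide <- call_consensus_positions(trk, threshold = 2, min_separation = 10)
  expect_identical(nrow(wide), 2L)
})

test_that("plateaus report their central position, left of centre when even", {
  coords <- template_coords("t", 1000, 500)
  odd <- numeric(1000)
  odd[501:503] <- 5  # positions 500-502
  expect_identical(
    call_consensus_positions(new_dyad_track(odd, coords, normalized = TRUE))$position_abs,
    501L
  )
  even <- numeric(1000)
  even[501:504] <- 5  # positions 500-503
  expect_identical(
    call_consensus_positions(new_dyad_track(even, coords, normalized = TRUE))$position_abs,
    501L
  )
})

test_that("raising the threshold never adds peaks", {
  coords <- test_coords()
  set.seed(13)
  trk <- make_landscape_preset("ISW2", coords) |>
    simulate_mnase_library(n = 20000, seed = 13) |>
    filter_by_length() |>
    compute_midpoints() |>
    build_track(coords) |>
    normalize_track()
  thresholds <- c(2, 50, 200, 500, 900)
  counts <- vapply(
    thresholds,
    function(th) nrow(call_consensus_positions(trk, threshold = th)),
    integer(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("every called peak is a supra-threshold local maximum of the track", {
  coords <- test_coords()
  trk <- make_landscape_preset("ISW1a", coords) |>
    simulate_mnase_library(n = 20000, seed = 17) |>
    filter_by_length() |>
    compute_midpoints() |>
    build_track(coords) |>
    normalize_track()
  peaks <- call_consensus_positions(trk, threshold = 2, min_separation = 120)
  vals <- track_values(trk)
  expect_gt(nrow(peaks), 0L)
  expect_true(all(peaks$height > 2))
  for (p in peaks$position_abs) {
    expect_gte(vals[p + 1L], max(vals[pmax(1, p):(p + 2L)]))
  }
  expect_true(all(diff(peaks$position_abs) >= 120))
})

test_that("peak calling commutes with a coordinate shift of the track", {
  coords <- template_coords("t", 2000, 1000)
  vals <- track_values(bump_track(coords, 600, 4))[1:2000] +
    track_values(bump_track(coords, 900, 3))[1:2000]
  k <- 25L
  shifted <- c(numeric(k), vals[1:(2000 - k)])
  p0 <- call_consensus_positions(new_dyad_track(vals, coords, normalized = TRUE))
  p1 <- call_consensus_positions(new_dyad_track(shifted, coords, normalized = TRUE))
  expect_identical(p1$position_abs, p0$position_abs + k)
})

test_that("unnormalized tracks are rejected by the peak caller", {
  coords <- test_coords()
  raw <- build_track(rep(500L, 100L), coords)
  expect_error(call_consensus_positions(raw), "normalized")
})

test_that("peak pairing recovers the +222 to +168 shift as -54 bp", {
  shifts <- pair_and_shift(222L, 168L, pairing_window = 100)
  expect_identical(nrow(shifts), 1L)
  expect_true(shifts$paired)
  expect_identical(shifts$shift_bp, -54L)
})

test_that("identical peak lists pair perfectly with zero shifts", {
  pos <- c(-200L, 222L, 387L)
  shifts <- pair_and_shift(pos, pos)
  expect_true(all(shifts$paired))
  expect_identical(shifts$shift_bp, c(0L, 0L, 0L))
})

test_that("peaks farther apart than the window stay unpaired on both sides", {
  shifts <- pair_and_shift(222L, 400L, pairing_window = 100)
  expect_identical(nrow(shifts), 2L)
  expect_true(all(!shifts$paired))
  expect_identical(sort(c(shifts$ref_position, shifts$alt_position)), c(222L, 400L))
})

test_that("pairing is one-to-one with closest-first assignment", {
  shifts <- pair_and_shift(c(100L, 140L), c(120L), pairing_window = 100)
  paired <- shifts[shifts$paired, ]
  expect_identical(nrow(paired), 1L)
  expect_identical(paired$ref_position, 100L)  # tie distance 20; smaller alt rule moot
  shifts2 <- pair_and_shift(c(100L), c(80L, 120L), pairing_window = 100)
  expect_identical(shifts2$alt_position[shifts2$paired], 80L)  # tie -> smaller alt
})

test_that("inter-dyad spacing summarizes mean and sample SD of gaps", {
  s <- estimate_spacing(c(100, 265, 430, 595))
  expect_equal(s$mean_spacing_bp, 165)
  expect_equal(s$sd_spacing_bp, 0)
  s2 <- estimate_spacing(c(100, 250, 430))
  expect_equal(s2$mean_spacing_bp, 165)
  expect_equal(s2$sd_spacing_bp, sd(c(150, 180)))
  expect_equal(s2$sd_spacing_bp, 21.2132, tolerance = 1e-4)
  expect_error(estimate_spacing(100), "fewer than two")
})
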