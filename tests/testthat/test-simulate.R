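test_that("remodeler presets plant their signature dyads", {
  coords <- test_coords()
  isw2 <- make_landscape_preset("ISW2", coords)
  expect_true(all(c(-54L, 168L) %in% isw2$dyads$position_acs))
  isw1a <- make_landscape_preset("ISW1a", coords)
  expect_true(222L %in% isw1a$dyads$position_acs)
  expect_false(any(
    isw1a$dyads$position_acs > isw1a$nfr[1] & isw1a$dyads$position_acs < isw1a$nfr[2]
  ))
  expect_error(make_landscape_preset("nonsense", coords), "Unknown landscape preset")
})

test_that("preset dyad weights normalize and dyads stay on the template", {
  coords <- test_coords()
  for (preset in c("ISW1a", "ISW2", "irregular", "single_dyad")) {
    ls <- make_landscape_preset(preset, coords, seed = 4)
    expect_equal(sum(ls$dyads$weight), 1)
    abs_pos <- from_acs_relative(ls$dyads$position_acs, coords)
    expect_true(all(abs_pos >= 0 & abs_pos < coords$length_bp))
  }
})

test_that("the irregular preset respects the 147 bp exclusion and its NFR", {
  coords <- test_coords()
  for (seed in 1:5) {
    ls <- make_landscape_preset("irregular", coords, seed = seed)
    pos <- sort(ls$dyads$position_acs)
    if (length(pos) > 1) expect_true(all(diff(pos) >= 147))
    expect_false(any(pos > ls$nfr[1] & pos < ls$nfr[2]))
  }
})

test_that("simulation is reproducible from its seed and n = 0 is allowed", {
  coords <- test_coords()
  ls <- make_landscape_preset("ISW2", coords)
  a <- simulate_mnase_library(ls, 500, seed = 99)
  b <- simulate_mnase_library(ls, 500, seed = 99)
  expect_identical(a$start, b$start)
  expect_identical(a$end, b$end)
  c <- simulate_mnase_library(ls, 500, seed = 100)
  expect_false(identical(a$start, c$start))
  expect_identical(nrow(simulate_mnase_library(ls, 0, seed = 1)), 0L)
})

test_that("the generator does not disturb the caller's RNG stream", {
  coords <- test_coords()
  ls <- make_landscape_preset("ISW2", coords)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_mnase_library(ls, 100, seed = 1))
  expect_identical(runif(1), before)
})

test_that("a noiseless single dyad yields one deterministic fragment geometry", {
  coords <- template_coords("ARS1_tpl", 3800, acs_offset = 1000)
  ls <- make_landscape_preset("single_dyad", coords, fuzz_sd = 0)
  lib <- simulate_mnase_library(ls, 50, seed = 1, frag_len_sd = 0)
  expect_true(all(lib$start == 927L))
  expect_true(all(lib$end == 1074L))
  expect_true(all(compute_midpoints(lib)$midpoint == 1000L))
})

test_that("fragment lengths follow the truncated normal footprint model", {
  coords <- test_coords()
  ls <- make_landscape_preset("ISW2", coords)
  lib <- simulate_mnase_library(ls, 10000, seed = 21)
  expect_true(all(lib$length >= 100 & lib$length <= 200))
  expect_lt(abs(mean(lib$length) - 147), 0.5)

  # goodness of fit against the rounded truncated Normal(147, 10) on [100, 200]
  breaks <- c(100, seq(125, 170, by = 5), 200)
  obs <- table(cut(lib$length, breaks, include.lowest = TRUE, right = TRUE))
  edges_lo <- c(99.5, seq(125, 170, by = 5) + 0.5)
  edges_hi <- c(seq(125, 170, by = 5) + 0.5, 200.5)
  mass <- pnorm(200.5, 147, 10) - pnorm(99.5, 147, 10)
  expected_p <- (pnorm(edges_hi, 147, 10) - pnorm(edges_lo, 147, 10)) / mass
  gof <- chisq.test(as.numeric(obs), p = expected_p, rescale.p = TRUE)
  expect_gt(gof$p.value, 0.01)
})

test_that("all fragments lie on the template even near the edges", {
  coords <- template_coords("ARS1_tpl", 3800, acs_offset = 150)
  ls <- make_landscape_preset("ISW2", coords)
  lib <- simulate_mnase_library(ls, 5000, seed = 8)
  expect_true(all(lib$start >= 0L))
  expect_true(all(lib$end <= 3800L))
})

test_that("background raising lowers normalized peak heights but not positions", {
  coords <- test_coords()
  run <- function(bg) {
    make_landscape_preset("ISW2", coords, background_frac = bg) |>
      simulate_mnase_library(20000, seed = 6) |>
      filter_by_length() |>
      compute_midpoints() |>
      build_track(coords) |>
      normalize_track() |>
      call_consensus_positions()
  }
  clean <- run(0)
  noisy <- run(0.5)
  shifts <- pair_and_shift(clean, noisy, pairing_window = 50)
  paired <- shifts[shifts$paired, ]
  expect_gt(nrow(paired), 10L)
  expect_true(all(abs(paired$shift_bp) < 5))
  match_h <- function(pks, pos) pks$height[match(pos, pks$position_acs)]
  expect_true(mean(
    match_h(noisy, paired$alt_position) < match_h(clean, paired$ref_position)
  ) > 0.9)
})
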