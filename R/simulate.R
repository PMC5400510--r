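#' Build a nucleosome landscape preset
#'
#' A landscape is the simulator's ground truth: a set of weighted, fuzzy dyad
#' positions (ACS-relative), a nucleosome-free region (NFR) in which no dyad
#' may lie, and a uniform background fraction. The presets emulate the
#' signature origin-proximal arrangements produced by different chromatin
#' remodelers on an *ARS1* template:
#'
#' * `"ISW1a"` — NFR over the origin (default \[-120, +120\]), flanking dyads
#'   at -200 and +222, and further dyads tiled outward at `spacing_bp`. The
#'   +222 downstream flank is the characteristic ISW1a position; the
#'   upstream -200 default is a package choice (no canonical value exists).
#' * `"ISW2"` — a nucleosome encroaching on the origin with its dyad at -54
#'   and the downstream flank pulled in to +168; remaining dyads tiled
#'   outward. The residual linker \[+20, +94\] between those two footprints
#'   is recorded as the (much reduced) NFR.
#' * `"irregular"` — dyads placed by seeded random sequential adsorption with
#'   a 147 bp minimum separation, keeping the NFR empty; models remodelers
#'   (SWI/SNF, RSC) or untreated templates that yield no uniform phasing.
#' * `"single_dyad"` — one dyad at ACS+0, weight 1, no background; a fixture
#'   for pipeline tests.
#'
#' Dyad weights are equal and normalized to sum to 1. Tiling stops 100 bp
#' from either template edge so that simulated fragments fit on the template.
#'
#' @param name Preset name: `"ISW1a"`, `"ISW2"`, `"irregular"`, or
#'   `"single_dyad"`.
#' @param coords A [template_coords()] object.
#' @param seed Integer seed; only the `"irregular"` preset draws random
#'   numbers.
#' @param fuzz_sd Positional fuzz (sd of the dyad-to-fragment-centre offset)
#'   in bp, applied to every dyad. Default 10.
#' @param spacing_bp Inter-dyad spacing for tiled presets. Default 165.
#' @param nfr Length-2 ACS-relative interval kept free of dyads (ignored by
#'   `"ISW2"` and `"single_dyad"`, which define their own).
#' @param background_frac Fraction of fragments drawn uniformly over the
#'   template, a noise floor (default 0.1; `"single_dyad"` uses 0).
#' @return A `nucleosome_landscape` object.
#' @export
make_landscape_preset <- function(name, coords, seed = 1L, fuzz_sd = 10,
                                  spacing_bp = 165, nfr = c(-120, 120),
                                  background_frac = 0.1) {
  stopifnot(inherits(coords, "template_coords"))
  edge_margin <- 100L
  lo <- min(
    to_acs_relative(edge_margin, coords),
    to_acs_relative(coords$length_bp - 1L - edge_margin, coords)
  )
  hi <- max(
    to_acs_relative(edge_margin, coords),
    to_acs_relative(coords$length_bp - 1L - edge_margin, coords)
  )
  tile_out <- function(anchor, step) {
    pos <- anchor
    while (pos[length(pos)] + step >= lo && pos[length(pos)] + step <= hi) {
      pos <- c(pos, pos[length(pos)] + step)
    }
    pos
  }
  dyads <- switch(name,
    ISW1a = {
      up <- tile_out(-200, -spacing_bp)
      down <- tile_out(222, spacing_bp)
      sort(c(up, down))
    },
    ISW2 = {
      nfr <- c(20, 94)
      up <- tile_out(-54, -spacing_bp)
      down <- tile_out(168, spacing_bp)
      sort(c(up, down))
    },
    irregular = {
      nfr <- as.integer(nfr)
      with_seed(seed, rsa_place(lo, hi, min_sep = 147L, nfr = nfr))
    },
    single_dyad = {
      nfr <- c(0L, 0L)
      background_frac <- 0
      0L
    },
    stop("Unknown landscape preset: ", name, call. = FALSE)
  )
  new_nucleosome_landscape(
    coords = coords,
    dyads = tibble::tibble(
      position_acs = as.integer(dyads),
      weight = rep(1 / length(dyads), length(dyads)),
      fuzz_sd = rep(fuzz_sd, length(dyads))
    ),
    nfr = as.integer(nfr),
    background_frac = background_frac,
    irregular = identical(name, "irregular"),
    preset = name
  )
}

new_nucleosome_landscape <- function(coords, dyads, nfr, background_frac,
                                     irregular = FALSE, preset = "custom") {
  stopifnot(inherits(coords, "template_coords"))
  w <- dyads$weight
  if (any(w <= 0)) {
    stop("Dyad weights must be positive.", call. = FALSE)
  }
  dyads$weight <- w / sum(w)
  in_nfr <- dyads$position_acs > nfr[1L] & dyads$position_acs < nfr[2L]
  if (nfr[2L] > nfr[1L] && any(in_nfr)) {
    stop("No dyad may lie inside the NFR.", call. = FALSE)
  }
  from_acs_relative(dyads$position_acs, coords)  # errors if off-template
  if (background_frac < 0 || background_frac >= 1) {
    stop("`background_frac` must be in [0, 1).", call. = FALSE)
  }
  structure(
    list(
      coords = coords, dyads = dyads, nfr = nfr,
      background_frac = background_frac, irregular = irregular,
      preset = preset
    ),
    class = "nucleosome_landscape"
  )
}

#' @export
print.nucleosome_landscape <- function(x, ...) {
  cat(sprintf(
    "<nucleosome_landscape> preset %s: %d dyads, NFR [%d, %d], background %.2f\n",
    x$preset, nrow(x$dyads), x$nfr[1L], x$nfr[2L], x$background_frac
  ))
  invisible(x)
}

#' Tidy the dyad table of a landscape
#'
#' @param x A `nucleosome_landscape`.
#' @param ... Unused.
#' @return A tibble with `position_acs`, `position_abs`, `weight`, `fuzz_sd`.
#' @export
tidy.nucleosome_landscape <- function(x, ...) {
  dplyr::mutate(
    x$dyads,
    position_abs = from_acs_relative(.data$position_acs, x$coords),
    .after = "position_acs"
  )
}

#' Plot a landscape's planted dyads and NFR
#'
#' @param object A `nucleosome_landscape`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nucleosome_landscape <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_acs, y = .data$weight)) +
    ggplot2::annotate(
      "rect",
      xmin = object$nfr[1L], xmax = object$nfr[2L],
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue"
    ) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position_acs, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Dyad position relative to ACS (bp)", y = "Weight",
      title = sprintf("Landscape preset: %s", object$preset)
    ) +
    ggplot2::theme_minimal()
}

# Random sequential adsorption of dyads with a minimum separation,
# excluding the NFR. Stops when max_fail consecutive proposals are rejected.
rsa_place <- function(lo, hi, min_sep, nfr, max_fail = 2000L) {
  placed <- integer(0)
  fails <- 0L
  while (fails < max_fail) {
    p <- as.integer(floor(stats::runif(1, lo, hi + 1)))
    in_nfr <- p > nfr[1L] && p < nfr[2L]
    too_close <- length(placed) > 0L && any(abs(placed - p) < min_sep)
    if (in_nfr || too_close) {
      fails <- fails + 1L
    } else {
      placed <- c(placed, p)
      fails <- 0L
    }
  }
  if (length(placed) == 0L) {
    stop("Random placement produced no dyads; check NFR and bounds.", call. = FALSE)
  }
  sort(placed)
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Simulate a paired-end MNase-seq fragment library
#'
#' Draws `n` fragments from a [nucleosome landscape][make_landscape_preset()].
#' With probability `background_frac` a fragment is background: its start is
#' uniform over the template. Otherwise a dyad is chosen by weight, the
#' fragment centre is the dyad plus rounded `Normal(0, fuzz_sd)` positional
#' fuzz, and the fragment is placed symmetrically about the centre. Fragment
#' lengths are `Normal(frag_len_mean, frag_len_sd)` rounded and rejected
#' outside `frag_len_bounds` — the ~147 bp mean is the canonical nucleosome
#' footprint. Fragments crossing a template edge are redrawn (preserving the
#' length distribution) up to `max_retries` passes.
#'
#' The generator is fully reproducible: the same seed and parameters give an
#' identical library, and the caller's RNG state is left untouched.
#'
#' @param landscape A `nucleosome_landscape`.
#' @param n Number of fragments.
#' @param seed Integer seed.
#' @param frag_len_mean,frag_len_sd Fragment length distribution in bp
#'   (defaults 147 and 10).
#' @param frag_len_bounds Inclusive truncation bounds for fragment length
#'   (default `c(100, 200)`).
#' @param max_retries Redraw passes allowed for edge-crossing fragments.
#' @return A fragment tibble (`template_id`, `start`, `end`, `length`) with
#'   attributes `landscape`, `n`, `seed`, and the length parameters; pipes
#'   directly into [filter_by_length()].
#' @export
simulate_mnase_library <- function(landscape, n, seed,
                                   frag_len_mean = 147, frag_len_sd = 10,
                                   frag_len_bounds = c(100, 200),
                                   max_retries = 100L) {
  stopifnot(inherits(landscape, "nucleosome_landscape"))
  n <- as.integer(n)
  stopifnot(n >= 0L)
  coords <- landscape$coords
  l <- coords$length_bp
  if (frag_len_bounds[2L] >= l) {
    stop("Fragment length bounds exceed the template scale.", call. = FALSE)
  }
  dyad_abs <- from_acs_relative(landscape$dyads$position_acs, coords)
  fuzz <- landscape$dyads$fuzz_sd
  w <- landscape$dyads$weight

  draw <- function(m) {
    len <- draw_trunc_lengths(m, frag_len_mean, frag_len_sd, frag_len_bounds)
    is_bg <- stats::runif(m) < landscape$background_frac
    start <- integer(m)
    if (any(is_bg)) {
      start[is_bg] <- as.integer(floor(stats::runif(sum(is_bg), 0, l)))
    }
    if (any(!is_bg)) {
      k <- sum(!is_bg)
      di <- sample.int(length(dyad_abs), k, replace = TRUE, prob = w)
      centre <- as.integer(round(dyad_abs[di] + stats::rnorm(k, 0, fuzz[di])))
      start[!is_bg] <- centre - len[!is_bg] %/% 2L
    }
    tibble::tibble(start = start, end = start + len)
  }

  frags <- with_seed(seed, {
    out <- draw(n)
    tries <- 0L
    repeat {
      bad <- which(out$start < 0L | out$end > l)
      if (length(bad) == 0L) break
      tries <- tries + 1L
      if (tries > max_retries) {
        stop(
          "Could not place all fragments on the template after ",
          max_retries, " redraw passes.",
          call. = FALSE
        )
      }
      out[bad, ] <- draw(length(bad))
      out
    }
    out
  })
  out <- tibble::tibble(
    template_id = rep(coords$template_id, n),
    start = frags$start,
    end = frags$end,
    length = frags$end - frags$start
  )
  attr(out, "landscape") <- landscape
  attr(out, "seed") <- as.integer(seed)
  attr(out, "frag_len_mean") <- frag_len_mean
  attr(out, "frag_len_sd") <- frag_len_sd
  attr(out, "frag_len_bounds") <- frag_len_bounds
  out
}

# Rounded, truncated-normal fragment lengths by rejection.
draw_trunc_lengths <- function(m, mean, sd, bounds) {
  if (m == 0L) {
    return(integer(0))
  }
  len <- as.integer(round(stats::rnorm(m, mean, sd)))
  repeat {
    bad <- which(len < bounds[1L] | len > bounds[2L])
    if (length(bad) == 0L) break
    len[bad] <- as.integer(round(stats::rnorm(length(bad), mean, sd)))
  }
  len
}
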