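#' Call consensus nucleosome dyad positions from a density track
#'
#' A consensus nucleosome position is a local maximum of the depth-normalized
#' dyad-density track whose height exceeds `threshold`. Discrete tracks can
#' plateau, so a "local maximum" is a maximal run of equal values with
#' strictly lower neighbours on both sides; the run's central position is
#' reported (left of centre on even-length plateaus). Maxima closer together
#' than `min_separation` are resolved greedily: candidates are visited in
#' descending height (ties broken leftmost) and a candidate is dropped if a
#' kept peak lies within `min_separation` bp. Two dyads cannot physically sit
#' closer than a nucleosome footprint allows, hence the 120 bp default, just
#' under the ~147 bp of DNA a histone octamer protects.
#'
#' The threshold (default 2) is compared against the per-million-normalized
#' density produced by [normalize_track()]; calling on an unnormalized track
#' is an error because threshold units are defined on the normalized signal.
#'
#' @param track A normalized `dyad_track`.
#' @param threshold Minimum height; only strict exceedance (`height >
#'   threshold`) is called. Default 2.
#' @param min_separation Minimum distance in bp between called peaks
#'   (default 120).
#' @return A tibble of peaks sorted by position: `position_abs`,
#'   `position_acs`, `height`, and `rank` (1 = highest).
#' @examples
#' coords <- template_coords("tpl", 3800, 1700)
#' lib <- make_landscape_preset("single_dyad", coords) |>
#'   simulate_mnase_library(n = 5000, seed = 1)
#' lib |>
#'   filter_by_length() |>
#'   compute_midpoints() |>
#'   build_track(coords) |>
#'   normalize_track() |>
#'   call_consensus_positions()
#' @export
call_consensus_positions <- function(track, threshold = 2, min_separation = 120) {
  stopifnot(inherits(track, "dyad_track"))
  if (!track$normalized) {
    stop(
      "Track must be normalized before peak calling ",
      "(threshold units are defined on the normalized signal).",
      call. = FALSE
    )
  }
  if (threshold <= 0) {
    stop("`threshold` must be positive.", call. = FALSE)
  }
  if (min_separation < 0) {
    stop("`min_separation` must be >= 0.", call. = FALSE)
  }
  cand <- local_maxima(track$values)
  cand <- cand[track$values[cand + 1L] > threshold]
  kept <- integer(0)
  if (length(cand) > 0L) {
    h <- track$values[cand + 1L]
    ord <- order(-h, cand)
    for (p in cand[ord]) {
      if (all(abs(kept - p) >= min_separation)) {
        kept <- c(kept, p)
      }
    }
    kept <- sort(kept)
  }
  heights <- track$values[kept + 1L]
  tibble::tibble(
    position_abs = kept,
    position_acs = if (length(kept)) to_acs_relative(kept, track$coords) else integer(),
    height = heights,
    rank = if (length(kept)) {
      order(order(-heights, kept))
    } else {
      integer()
    }
  )
}

# Central positions (0-based) of maximal equal-value runs that are strictly
# higher than both neighbouring runs; template edges never qualify.
local_maxima <- function(values) {
  runs <- rle(values)
  n <- length(runs$values)
  if (n < 3L) {
    return(integer(0))
  }
  idx <- 2:(n - 1L)
  is_max <- runs$values[idx] > runs$values[idx - 1L] &
    runs$values[idx] > runs$values[idx + 1L]
  idx <- idx[is_max]
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths   # 0-based run starts
  starts[idx] + (runs$lengths[idx] - 1L) %/% 2L
}

#' Pair consensus peaks across two conditions and measure dyad shifts
#'
#' Matches each reference peak to the nearest alternate-condition peak within
#' `pairing_window` bp, one-to-one, assigning the closest pairs first (ties
#' broken towards the smaller alternate position). The shift is `alt - ref`
#' in ACS-relative bp, so a nucleosome moving towards the ACS from +222 to
#' +168 reports a shift of -54 bp. Peaks in either list left without a
#' partner are reported with `paired = FALSE`.
#'
#' @param ref_peaks,alt_peaks Peak tibbles from [call_consensus_positions()]
#'   (their `position_acs` column is used), or plain integer vectors of
#'   ACS-relative positions. Both must come from the same coordinate system.
#' @param pairing_window Maximum pairing distance in bp (default 100).
#' @return A tibble with `ref_position`, `alt_position`, `shift_bp`, and
#'   `paired`, ordered by position.
#' @export
pair_and_shift <- function(ref_peaks, alt_peaks, pairing_window = 100) {
  ref <- peak_positions(ref_peaks)
  alt <- peak_positions(alt_peaks)
  pairs <- tidyr::expand_grid(i = seq_along(ref), j = seq_along(alt))
  if (nrow(pairs) > 0L) {
    pairs <- dplyr::mutate(pairs,
      dist = abs(ref[.data$i] - alt[.data$j]),
      alt_pos = alt[.data$j]
    )
    pairs <- dplyr::arrange(
      dplyr::filter(pairs, .data$dist <= pairing_window),
      .data$dist, .data$alt_pos
    )
  }
  ref_match <- rep(NA_integer_, length(ref))
  alt_used <- rep(FALSE, length(alt))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]
    j <- pairs$j[k]
    if (is.na(ref_match[i]) && !alt_used[j]) {
      ref_match[i] <- j
      alt_used[j] <- TRUE
    }
  }
  out <- tibble::tibble(
    ref_position = ref,
    alt_position = alt[ref_match],
    shift_bp = alt[ref_match] - ref,
    paired = !is.na(ref_match)
  )
  orphans <- which(!alt_used)
  if (length(orphans) > 0L) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      ref_position = NA_integer_,
      alt_position = alt[orphans],
      shift_bp = NA_integer_,
      paired = FALSE
    ))
  }
  dplyr::arrange(out, dplyr::coalesce(.data$ref_position, .data$alt_position))
}

peak_positions <- function(x) {
  if (is.data.frame(x)) {
    as.integer(x$position_acs)
  } else {
    as.integer(x)
  }
}

#' Mean inter-dyad spacing of a peak list
#'
#' Summarizes the regularity of a nucleosome array: the arithmetic mean of
#' successive inter-peak distances (the nucleosome repeat length estimate)
#' and the sample standard deviation of those distances as a regularity
#' score (0 for a perfectly phased array).
#'
#' @param peaks Peak tibble from [call_consensus_positions()] or an integer
#'   vector of positions; at least two peaks are required.
#' @return A one-row tibble: `mean_spacing_bp`, `sd_spacing_bp`, `n_peaks`.
#' @export
estimate_spacing <- function(peaks) {
  pos <- if (is.data.frame(peaks)) peaks$position_abs else as.numeric(peaks)
  pos <- sort(pos)
  if (length(pos) < 2L) {
    stop("Spacing is undefined for fewer than two peaks.", call. = FALSE)
  }
  gaps <- diff(pos)
  tibble::tibble(
    mean_spacing_bp = mean(gaps),
    sd_spacing_bp = if (length(gaps) > 1L) stats::sd(gaps) else 0,
    n_peaks = length(pos)
  )
}

#' Write consensus peaks as BED6
#'
#' `name` is a sequential peak id, `score` the density height, strand `.`.
#'
#' @param peaks Peak tibble from [call_consensus_positions()].
#' @param coords A [template_coords()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed6 <- function(peaks, coords, path) {
  stopifnot(inherits(coords, "template_coords"))
  df <- tibble::tibble(
    chrom = coords$template_id,
    start = peaks$position_abs,
    end = peaks$position_abs + 1L,
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = peaks$height,
    strand = "."
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
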