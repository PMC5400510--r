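#' Build a smoothed nucleosome dyad-density track
#'
#' Places a Gaussian kernel of standard deviation `bandwidth_bp` around each
#' fragment midpoint and sums the kernels into a per-base density over
#' `[0, length_bp)`. Each midpoint contributes total mass ~1 (the kernel is
#' the unit-mass normal density evaluated at integer offsets, truncated at
#' `truncation_sd` standard deviations; ~0.27% of the mass is lost to
#' truncation at the default 3 sd, plus whatever falls off the template near
#' its edges — no reflection or padding is applied). The track is linear in
#' the multiset of midpoints.
#'
#' The default bandwidth of 20 bp reads "20 bp Gaussian kernel" as the kernel
#' standard deviation, the usual convention in midpoint-smoothing analyses;
#' it is a parameter precisely because other readings (FWHM, window width)
#' exist.
#'
#' @param midpoints Tibble from [compute_midpoints()] or an integer vector of
#'   0-based midpoint positions.
#' @param coords A [template_coords()] object.
#' @param bandwidth_bp Kernel standard deviation in bp (default 20).
#' @param truncation_sd Kernel support half-width in standard deviations
#'   (default 3).
#' @return A `dyad_track` object: per-base density values plus the parameters
#'   and normalization state. Use [tidy()] for a tibble view, [autoplot()] to
#'   plot, [normalize_track()] to scale to read depth.
#' @examples
#' coords <- template_coords("tpl", 3800, 1700)
#' trk <- build_track(c(500L, 500L, 900L), coords)
#' max(track_values(trk))
#' @export
build_track <- function(midpoints, coords, bandwidth_bp = 20, truncation_sd = 3) {
  stopifnot(inherits(coords, "template_coords"))
  if (is.data.frame(midpoints)) {
    midpoints <- midpoints$midpoint
  }
  midpoints <- as.integer(midpoints)
  if (!is.numeric(bandwidth_bp) || bandwidth_bp <= 0) {
    stop("`bandwidth_bp` must be positive.", call. = FALSE)
  }
  if (truncation_sd <= 0) {
    stop("`truncation_sd` must be positive.", call. = FALSE)
  }
  l <- coords$length_bp
  if (length(midpoints) > 0L && any(midpoints < 0L | midpoints >= l)) {
    stop("Midpoints outside [0, length_bp).", call. = FALSE)
  }
  halfw <- as.integer(ceiling(truncation_sd * bandwidth_bp))
  values <- numeric(l)
  if (length(midpoints) > 0L) {
    kern <- stats::dnorm(-halfw:halfw, mean = 0, sd = bandwidth_bp)
    counts <- tabulate(midpoints + 1L, nbins = l)
    padded <- c(numeric(halfw), counts, numeric(halfw))
    smoothed <- stats::filter(padded, kern, method = "convolution", sides = 2)
    values <- as.numeric(smoothed[(halfw + 1L):(halfw + l)])
  }
  new_dyad_track(
    values = values,
    coords = coords,
    bandwidth_bp = bandwidth_bp,
    truncation_sd = truncation_sd,
    n_midpoints = length(midpoints),
    normalized = FALSE,
    scale_constant = 1
  )
}

#' Construct a dyad track from raw per-base values
#'
#' Low-level constructor, mainly useful for tests and for reading tracks back
#' from bedGraph. Most users should build tracks from midpoints with
#' [build_track()].
#'
#' @param values Numeric vector of per-base density, length `coords$length_bp`.
#' @param coords A [template_coords()] object.
#' @param bandwidth_bp,truncation_sd Kernel parameters the values were built
#'   with (metadata only here).
#' @param n_midpoints Number of midpoints aggregated into the values.
#' @param normalized Whether the values are already depth-normalized.
#' @param scale_constant The multiplicative factor already applied (1 if
#'   unnormalized).
#' @return A `dyad_track` object.
#' @export
new_dyad_track <- function(values, coords, bandwidth_bp = 20,
                           truncation_sd = 3, n_midpoints = 0L,
                           normalized = FALSE, scale_constant = 1) {
  stopifnot(inherits(coords, "template_coords"))
  values <- as.numeric(values)
  if (length(values) != coords$length_bp) {
    stop("`values` must have one entry per template base.", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("Track values must be non-negative.", call. = FALSE)
  }
  structure(
    list(
      values = values,
      coords = coords,
      bandwidth_bp = bandwidth_bp,
      truncation_sd = truncation_sd,
      n_midpoints = as.integer(n_midpoints),
      normalized = isTRUE(normalized),
      scale_constant = scale_constant
    ),
    class = "dyad_track"
  )
}

#' @rdname new_dyad_track
#' @param track A `dyad_track` object.
#' @export
track_values <- function(track) {
  stopifnot(inherits(track, "dyad_track"))
  track$values
}

#' @export
print.dyad_track <- function(x, ...) {
  cat(sprintf(
    "<dyad_track> %s: %d bp, %d midpoints, sigma = %g bp, %s (scale %g)\n",
    x$coords$template_id, x$coords$length_bp, x$n_midpoints, x$bandwidth_bp,
    if (x$normalized) "normalized" else "unnormalized", x$scale_constant
  ))
  cat(sprintf(
    "  max density %.6g at absolute position %d\n",
    max(x$values), which.max(x$values) - 1L
  ))
  invisible(x)
}

#' Normalize a dyad track to read depth
#'
#' Scales the track to signal per million filtered fragments: values are
#' multiplied by `1e6 / n_midpoints`. This makes tracks from libraries of
#' different depth directly comparable — duplicating every fragment of a
#' library leaves the normalized track unchanged. The factor applied is
#' recorded in `scale_constant` so any alternative depth scaling is a single
#' multiplicative change. Normalizing an already-normalized track is an
#' error, as is normalizing an empty one.
#'
#' @param track An unnormalized `dyad_track` from [build_track()].
#' @return The normalized `dyad_track`.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "dyad_track"))
  if (track$normalized) {
    stop("Track is already normalized.", call. = FALSE)
  }
  if (track$n_midpoints == 0L) {
    stop("Cannot normalize a track built from zero midpoints.", call. = FALSE)
  }
  scale <- 1e6 / track$n_midpoints
  track$values <- track$values * scale
  track$normalized <- TRUE
  track$scale_constant <- scale
  track
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a dyad track into a per-base tibble
#'
#' @param x A `dyad_track`.
#' @param ... Unused.
#' @return A tibble with `position` (absolute 0-based), `position_acs`
#'   (ACS-relative), and `density`.
#' @export
tidy.dyad_track <- function(x, ...) {
  pos <- seq_len(x$coords$length_bp) - 1L
  tibble::tibble(
    position = pos,
    position_acs = to_acs_relative(pos, x$coords),
    density = x$values
  )
}

#' One-row summary of a dyad track
#'
#' @param x A `dyad_track`.
#' @param ... Unused.
#' @return A one-row tibble with the template, parameters, normalization
#'   state, midpoint count, total signal mass, and the maximum density and
#'   its ACS-relative position.
#' @export
glance.dyad_track <- function(x, ...) {
  imax <- which.max(x$values) - 1L
  tibble::tibble(
    template_id = x$coords$template_id,
    length_bp = x$coords$length_bp,
    n_midpoints = x$n_midpoints,
    bandwidth_bp = x$bandwidth_bp,
    truncation_sd = x$truncation_sd,
    normalized = x$normalized,
    scale_constant = x$scale_constant,
    total_mass = sum(x$values),
    max_density = max(x$values),
    max_position_acs = to_acs_relative(imax, x$coords)
  )
}

#' Plot a dyad-density track
#'
#' Line plot of density against ACS-relative position, optionally annotated
#' with called consensus peaks.
#'
#' @param object A `dyad_track`.
#' @param peaks Optional peak tibble from [call_consensus_positions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dyad_track <- function(object, peaks = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position_acs, y = .data$density)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(
      x = "Position relative to ACS (bp)",
      y = if (object$normalized) "Dyad density (per million fragments)" else "Dyad density",
      title = object$coords$template_id
    ) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = .data$position_acs, y = .data$height),
      colour = "firebrick", size = 2
    )
  }
  p
}

#' @export
plot.dyad_track <- function(x, ...) print(autoplot(x, ...))
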