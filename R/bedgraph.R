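#' Write a dyad track as bedGraph
#'
#' Emits standard 4-column bedGraph (0-based half-open intervals) with runs
#' of equal value merged into single intervals and values rendered with at
#' least six significant digits, so a write/read round trip reproduces the
#' track within 1e-6.
#'
#' @param track A `dyad_track`.
#' @param coords A [template_coords()] object (defaults to the track's own).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_track_bedgraph()]
#' @export
write_track_bedgraph <- function(track, coords = track$coords, path) {
  stopifnot(inherits(track, "dyad_track"), inherits(coords, "template_coords"))
  runs <- rle(track$values)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  lines <- sprintf(
    "%s\t%d\t%d\t%.12g",
    coords$template_id, starts, ends, runs$values
  )
  ok <- tryCatch(
    {
      writeLines(lines, path)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) {
    stop("Cannot write bedGraph to ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read a bedGraph file back into a dyad track
#'
#' Positions not covered by any interval get value 0. Metadata that bedGraph
#' cannot carry (bandwidth, midpoint count, normalization state) must be
#' supplied by the caller if it matters downstream.
#'
#' @param path bedGraph path.
#' @param coords A [template_coords()] object.
#' @inheritParams new_dyad_track
#' @return A `dyad_track`.
#' @export
read_track_bedgraph <- function(path, coords, bandwidth_bp = 20,
                                truncation_sd = 3, n_midpoints = 0L,
                                normalized = FALSE, scale_constant = 1) {
  stopifnot(inherits(coords, "template_coords"))
  raw <- readr::read_tsv(
    path,
    col_names = c("template_id", "start", "end", "value"),
    col_types = "ciid",
    comment = "track",
    progress = FALSE
  )
  raw <- dplyr::filter(raw, .data$template_id == coords$template_id)
  values <- numeric(coords$length_bp)
  for (i in seq_len(nrow(raw))) {
    values[(raw$start[i] + 1L):raw$end[i]] <- raw$value[i]
  }
  new_dyad_track(
    values, coords,
    bandwidth_bp = bandwidth_bp, truncation_sd = truncation_sd,
    n_midpoints = n_midpoints, normalized = normalized,
    scale_constant = scale_constant
  )
}
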