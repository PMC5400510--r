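#' Define the coordinate system of an origin-bearing template
#'
#' MNase-seq landscapes around replication origins are conventionally plotted
#' relative to the first nucleotide of the ARS consensus sequence (ACS), with
#' zero at that base and coordinates increasing in a chosen orientation.
#' `template_coords()` records the template length, the absolute (0-based)
#' position of the ACS anchor, and the orientation in which ACS-relative
#' coordinates increase, so every downstream stage can convert between
#' absolute and ACS-relative positions without ambiguity.
#'
#' Internally every position is 0-based; intervals are half-open `[start, end)`.
#' SAM input (1-based) is converted on ingestion and BED is native.
#'
#' @param template_id Name of the template sequence (must match the reference
#'   name used in fragment files).
#' @param length_bp Template length in bp. Default 3800, the size of the
#'   linear *ARS1* origin fragment this package is designed around.
#' @param acs_offset Absolute 0-based position of the first nucleotide of the
#'   ACS on the template.
#' @param orientation `"forward"` if ACS-relative coordinates increase with
#'   absolute position, `"reverse"` if they decrease. The ACS strand on a
#'   given template is an experimental fact, so it is a configuration input,
#'   not a constant.
#'
#' @return An object of class `template_coords`.
#' @examples
#' coords <- template_coords("ARS1_tpl", length_bp = 3800, acs_offset = 1700)
#' to_acs_relative(1646, coords)  # -54
#' @export
template_coords <- function(template_id,
                            length_bp = 3800,
                            acs_offset = 1700,
                            orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(template_id), length(template_id) == 1L)
  length_bp <- as.integer(length_bp)
  acs_offset <- as.integer(acs_offset)
  if (length_bp <= 0L) {
    stop("`length_bp` must be a positive integer.", call. = FALSE)
  }
  if (acs_offset < 0L || acs_offset >= length_bp) {
    stop("`acs_offset` must satisfy 0 <= acs_offset < length_bp.", call. = FALSE)
  }
  structure(
    list(
      template_id = template_id,
      length_bp = length_bp,
      acs_offset = acs_offset,
      orientation = orientation
    ),
    class = "template_coords"
  )
}

#' @export
print.template_coords <- function(x, ...) {
  cat(sprintf(
    "<template_coords> %s: %d bp, ACS at %d (%s orientation)\n",
    x$template_id, x$length_bp, x$acs_offset, x$orientation
  ))
  invisible(x)
}

#' Convert absolute template positions to ACS-relative coordinates
#'
#' Zero is the first nucleotide of the ACS. In forward orientation the
#' ACS-relative coordinate is `position - acs_offset`; in reverse orientation
#' it is `acs_offset - position`. The mapping is a bijection on
#' `[0, length_bp)` and [from_acs_relative()] is its exact inverse.
#'
#' @param position Integer vector of absolute 0-based positions in
#'   `[0, length_bp)`.
#' @param coords A [template_coords()] object.
#' @return Integer vector of ACS-relative coordinates.
#' @export
to_acs_relative <- function(position, coords) {
  stopifnot(inherits(coords, "template_coords"))
  position <- as.integer(position)
  if (any(position < 0L | position >= coords$length_bp, na.rm = TRUE)) {
    stop("`position` out of range [0, length_bp).", call. = FALSE)
  }
  if (coords$orientation == "forward") {
    position - coords$acs_offset
  } else {
    coords$acs_offset - position
  }
}

#' @rdname to_acs_relative
#' @param position_acs Integer vector of ACS-relative coordinates that map
#'   inside the template.
#' @export
from_acs_relative <- function(position_acs, coords) {
  stopifnot(inherits(coords, "template_coords"))
  position_acs <- as.integer(position_acs)
  abs_pos <- if (coords$orientation == "forward") {
    coords$acs_offset + position_acs
  } else {
    coords$acs_offset - position_acs
  }
  if (any(abs_pos < 0L | abs_pos >= coords$length_bp, na.rm = TRUE)) {
    stop("ACS-relative position maps outside the template.", call. = FALSE)
  }
  abs_pos
}
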