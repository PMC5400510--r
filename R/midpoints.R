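#' Size-select fragments by length
#'
#' Retains exactly the fragments whose length lies in `[size_lo, size_hi]`,
#' bounds inclusive. MNase protection by a nucleosome covers ~147 bp, so the
#' default 125-175 bp window keeps mononucleosome-sized fragments and discards
#' subnucleosomal and dinucleosomal material. Input order is preserved and the
#' input is not modified.
#'
#' @param fragments Fragment tibble (see [read_fragments()]) with a `length`
#'   column, or `start`/`end` columns from which length is derived.
#' @param size_lo,size_hi Inclusive length bounds in bp (defaults 125 and 175).
#' @return A tibble with the retained fragments.
#' @export
filter_by_length <- function(fragments, size_lo = 125, size_hi = 175) {
  size_lo <- as.integer(size_lo)
  size_hi <- as.integer(size_hi)
  if (size_lo < 1L) {
    stop("`size_lo` must be >= 1.", call. = FALSE)
  }
  if (size_lo > size_hi) {
    stop("`size_lo` must not exceed `size_hi`.", call. = FALSE)
  }
  if (!"length" %in% names(fragments)) {
    fragments <- dplyr::mutate(fragments, length = .data$end - .data$start)
  }
  dplyr::filter(
    fragments,
    .data$length >= size_lo, .data$length <= size_hi
  )
}

#' Extract dyad-proxy midpoints from fragments
#'
#' The midpoint of a mononucleosome-sized MNase fragment approximates the
#' nucleosome dyad. Each fragment `[start, end)` yields one midpoint
#' `floor((start + end) / 2)`; even-length fragments have no integer centre,
#' so the floor convention is applied uniformly (a deterministic <= 0.5 bp
#' bias, symmetric across a landscape). The count of midpoints always equals
#' the count of input fragments.
#'
#' @param fragments Fragment tibble with `start` and `end` columns, typically
#'   after [filter_by_length()].
#' @return A tibble with columns `template_id` (if present in the input) and
#'   `midpoint`, carrying attribute `n_input_fragments`.
#' @export
compute_midpoints <- function(fragments) {
  mid <- (fragments$start + fragments$end) %/% 2L
  out <- if ("template_id" %in% names(fragments)) {
    tibble::tibble(template_id = fragments$template_id, midpoint = mid)
  } else {
    tibble::tibble(midpoint = mid)
  }
  attr(out, "n_input_fragments") <- nrow(fragments)
  out
}
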