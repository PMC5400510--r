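#' Express replicate intensities as percent of a reference condition's mean
#'
#' Standard densitometry-style quantification over biological replicates:
#' the mean intensity of the reference condition is set to 100% and every
#' individual intensity is expressed as a percentage of that mean
#' (`100 * intensity / mean(reference)`). Per condition, the mean and the
#' sample standard deviation (n - 1 denominator, the convention for small
#' numbers of biological replicates) of the percentages are reported; the
#' reference condition's mean is exactly 100 by construction. Percentages
#' are invariant under any common rescaling of the raw intensities, so
#' arbitrary densitometry units are fine.
#'
#' @param table A tidy data frame with columns `condition`, `replicate`, and
#'   `intensity` (non-negative).
#' @param reference The reference condition name (e.g. the high-salt-wash
#'   ISW1a reactions set to 100%).
#' @return A tibble with one row per condition: `condition`, `n`, `mean_pct`,
#'   `sd_pct`, and the list-column `values_pct` of per-replicate percentages.
#' @examples
#' tbl <- tibble::tibble(
#'   condition = rep(c("ISW1a", "ISW2"), each = 3),
#'   replicate = rep(1:3, 2),
#'   intensity = c(8, 10, 12, 4, 5, 6)
#' )
#' relative_to_reference(tbl, reference = "ISW1a")
#' @export
relative_to_reference <- function(table, reference) {
  stopifnot(all(c("condition", "replicate", "intensity") %in% names(table)))
  if (any(table$intensity < 0)) {
    stop("Intensities must be non-negative.", call. = FALSE)
  }
  if (!reference %in% table$condition) {
    stop("Reference condition '", reference, "' not present.", call. = FALSE)
  }
  ref_mean <- mean(table$intensity[table$condition == reference])
  if (ref_mean == 0) {
    stop("Reference condition mean is zero; percentages undefined.", call. = FALSE)
  }
  out <- table |>
    dplyr::mutate(pct = 100 * .data$intensity / ref_mean) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pct = 100 * mean(.data$intensity) / ref_mean,
      sd_pct = ifelse(dplyr::n() > 1L, stats::sd(.data$pct), 0),
      values_pct = list(.data$pct),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$condition != reference, .data$condition)
  class(out) <- c("relative_quant", class(out))
  out
}

#' Bar plot of percent-of-reference quantification
#'
#' Condition means with standard-deviation error bars and the individual
#' replicate values overplotted.
#'
#' @param object Result of [relative_to_reference()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relative_quant <- function(object, ...) {
  pts <- tidyr::unnest(object, "values_pct")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$condition, y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_pct - .data$sd_pct,
        ymax = .data$mean_pct + .data$sd_pct
      ),
      width = 0.25
    ) +
    ggplot2::geom_point(data = pts, ggplot2::aes(y = .data$values_pct)) +
    ggplot2::labs(x = NULL, y = "Percent of reference mean") +
    ggplot2::theme_minimal()
}
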