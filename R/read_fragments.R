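#' Read aligned MNase-seq fragments into a fragment tibble
#'
#' Ingests already-aligned paired-end MNase-seq fragments for a single
#' template from BED3, BEDPE, or SAM (proper pairs). Every record becomes one
#' row of a tibble with 0-based half-open coordinates; rows aligned to other
#' reference sequences are skipped with a message reporting the count, and
#' duplicate fragments are retained (no deduplication is applied).
#'
#' Format mapping:
#' * `bed3` — `chrom start end`, already 0-based half-open, used directly.
#' * `bedpe` — the fragment spans from the smallest mate start to the largest
#'   mate end.
#' * `sam` — proper pairs only (FLAG bit 0x2); the mate with a positive
#'   template-length field (TLEN) at 1-based position P yields the fragment
#'   `[P - 1, P - 1 + TLEN)`, so each pair contributes exactly one fragment.
#'   Pairs with TLEN = 0 are skipped and counted.
#'
#' @param path Path to the fragment file.
#' @param format One of `"bed3"`, `"bedpe"`, `"sam"`.
#' @param coords A [template_coords()] object; its `template_id` selects which
#'   reference name to keep.
#' @return A tibble with columns `template_id`, `start`, `end`, `length`.
#' @seealso [write_fragments_bed3()], [filter_by_length()]
#' @export
read_fragments <- function(path, format = c("bed3", "bedpe", "sam"), coords) {
  format <- match.arg(format)
  stopifnot(inherits(coords, "template_coords"))
  if (!file.exists(path)) {
    stop("Fragment file does not exist: ", path, call. = FALSE)
  }
  frags <- switch(format,
    bed3 = read_fragments_bed3(path),
    bedpe = read_fragments_bedpe(path),
    sam = read_fragments_sam(path)
  )
  n_other <- sum(frags$template_id != coords$template_id)
  if (n_other > 0L) {
    message(n_other, " fragment(s) on other templates skipped.")
    frags <- dplyr::filter(frags, .data$template_id == coords$template_id)
  }
  bad <- frags$start < 0L | frags$end > coords$length_bp | frags$start >= frags$end
  if (any(bad)) {
    stop(
      sum(bad), " fragment(s) fall outside [0, ", coords$length_bp,
      ") or have start >= end.",
      call. = FALSE
    )
  }
  dplyr::mutate(frags, length = .data$end - .data$start)
}

read_delim_checked <- function(path, n_cols, what) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#",
    progress = FALSE
  )
  if (nrow(raw) == 0L) {
    return(raw)
  }
  if (ncol(raw) < n_cols) {
    stop(what, " input needs at least ", n_cols, " columns.", call. = FALSE)
  }
  raw
}

check_integer_cols <- function(raw, cols, what) {
  for (j in cols) {
    v <- suppressWarnings(as.integer(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad) > 0L) {
      stop(
        "Unparseable ", what, " line ", bad[1L], ": column ", j,
        " is not an integer (", raw[[j]][bad[1L]], ").",
        call. = FALSE
      )
    }
    raw[[j]] <- v
  }
  raw
}

read_fragments_bed3 <- function(path) {
  raw <- read_delim_checked(path, 3L, "BED3")
  if (nrow(raw) == 0L) {
    return(tibble::tibble(
      template_id = character(), start = integer(), end = integer()
    ))
  }
  raw <- check_integer_cols(raw, 2:3, "BED3")
  tibble::tibble(
    template_id = raw[[1L]], start = raw[[2L]], end = raw[[3L]]
  )
}

read_fragments_bedpe <- function(path) {
  raw <- read_delim_checked(path, 6L, "BEDPE")
  if (nrow(raw) == 0L) {
    return(tibble::tibble(
      template_id = character(), start = integer(), end = integer()
    ))
  }
  raw <- check_integer_cols(raw, c(2:3, 5:6), "BEDPE")
  if (any(raw[[1L]] != raw[[4L]])) {
    stop("BEDPE mates on different templates are not supported.", call. = FALSE)
  }
  tibble::tibble(
    template_id = raw[[1L]],
    start = pmin(raw[[2L]], raw[[5L]]),
    end = pmax(raw[[3L]], raw[[6L]])
  )
}

read_fragments_sam <- function(path) {
  bam <- Rsamtools::asBam(
    path,
    destination = tempfile(fileext = ""),
    overwrite = TRUE,
    indexDestination = FALSE
  )
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "isize"),
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE)
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n_zero <- sum(rec$isize == 0L, na.rm = TRUE)
  if (n_zero > 0L) {
    message(n_zero, " SAM record(s) with TLEN = 0 skipped.")
  }
  keep <- !is.na(rec$isize) & rec$isize > 0L & !is.na(rec$pos)
  tibble::tibble(
    template_id = as.character(rec$rname[keep]),
    start = rec$pos[keep] - 1L,
    end = rec$pos[keep] - 1L + rec$isize[keep]
  )
}

#' Write fragments as BED3
#'
#' One fragment per row, 0-based half-open, tab-separated, no header.
#' A BED3 write/read round trip reproduces the fragment tibble exactly.
#'
#' @param fragments Fragment tibble with `template_id`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed3 <- function(fragments, path) {
  readr::write_tsv(
    dplyr::select(fragments, "template_id", "start", "end"),
    path,
    col_names = FALSE,
    progress = FALSE
  )
  invisible(path)
}
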