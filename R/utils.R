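# Shared constants and small helpers.
#
# Coordinate convention (package-wide): every interval held in memory is
# 0-based half-open [start, end); every human-facing report (TSV output,
# printed positions such as C202) is 1-based inclusive. Conversion lives
# here and nowhere else.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

NUC5 <- c("A", "C", "G", "T", "N")

#' Convert an internal interval to 1-based inclusive report coordinates
#'
#' @param start,end Integer vectors, 0-based half-open.
#' @return A tibble with columns `start_1` and `end_1` (1-based inclusive).
#' @keywords internal
#' @noRd
interval_to_report <- function(start, end) {
  tibble::tibble(start_1 = start + 1L, end_1 = end)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

revcomp <- function(x) {
  paste(rev(chars(chartr("ACGTN", "TGCAN", x))), collapse = "")
}

# Empty hit table with the shared DomainHit columns.
empty_hits <- function() {
  tibble::tibble(
    kind = character(), start = integer(), end = integer(),
    score = double(), method = character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
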