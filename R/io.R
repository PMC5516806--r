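# Stable tabular output: comma-separated, header row, UTF-8, '.' decimal,
# doubles printed with 9 significant digits so identical runs diff clean.

#' Write a result table as a bit-stable CSV
#'
#' Numeric columns are formatted with 9 significant digits (`%.9g`), so the
#' same computation always produces byte-identical files.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  fmt <- function(col) {
    if (is.double(col)) {
      out <- sprintf("%.9g", col)
      out[is.na(col)] <- "NA"
      out
    } else {
      as.character(col)
    }
  }
  chr <- tibble::as_tibble(lapply(x, fmt))
  readr::write_csv(chr, path, progress = FALSE)
  invisible(path)
}

#' Read a result CSV back into a tibble
#'
#' @param path CSV path written by [write_result_csv()].
#' @return A tibble with numeric columns restored.
#' @export
read_result_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
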