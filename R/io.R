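#' Read a multichannel series from delimited text
#'
#' Expects a rectangular numeric table: rows are time points, columns are
#' channels, with an optional header row of channel labels. The delimiter
#' is auto-detected (tab or comma) unless given. Ragged rows, non-numeric
#' cells and missing values are rejected with the offending row named —
#' visibility graphs need a gapless ordered index, so cleaning happens
#' upstream.
#'
#' @param path input file.
#' @param delimiter field separator; `NULL` auto-detects tab vs comma from
#'   the first line.
#' @return Numeric matrix with channel labels as column names.
#' @export
read_multivariate <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", first)) "\t" else ","
  }
  fields <- strsplit(first, delimiter, fixed = TRUE)[[1L]]
  header <- anyNA(suppressWarnings(as.numeric(fields)))
  tab <- read.table(path, sep = delimiter, header = header,
                    colClasses = "character", check.names = FALSE)
  width <- ncol(tab)
  body <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab)), ncol = width)
  )
  bad <- which(!is.finite(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric or missing value at row ", bad[1L, 1L],
         ", column ", bad[1L, 2L])
  }
  colnames(body) <- if (header) colnames(tab) else paste0("V", seq_len(width))
  body
}

#' Write a multichannel series as delimited text
#'
#' Header row of channel labels, then one row per time point; floats at
#' 17 significant digits so a read-back reproduces the matrix exactly.
#'
#' @param series numeric matrix (rows = time, columns = channels).
#' @param path output file.
#' @param delimiter field separator.
#' @export
write_multivariate <- function(series, path, delimiter = ",") {
  series <- check_multivariate(series, min_channels = 1L)
  labels <- colnames(series)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(series)))
  lines <- c(
    paste(labels, collapse = delimiter),
    apply(series, 1L, function(row) {
      paste(format(row, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = delimiter)
    })
  )
  writeLines(lines, path)
  invisible(path)
}
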