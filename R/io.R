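## Thin TIFF/CSV readers and writers for the pipeline's file formats.

#' Read a multi-page TIFF into an array
#'
#' Planes are read in file (plane-major) order into an `nx x ny x nz`
#' array.
#'
#' @param path TIFF file.
#' @param scale multiply intensities by this factor (TIFFs written by
#'   [write_synthetic_stack()] are stored on a 0..1 scale).
#' @return numeric array.
#' @export
read_channel_stack <- function(path, scale = 1) {
  planes <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(planes) * scale
  aperm(arr, c(1, 2, 3))
}

#' Read a 16-bit label-mask TIFF into an integer array
#'
#' @param path TIFF file written with label ids on a 0..65535 scale.
#' @return integer label array.
#' @export
read_label_stack <- function(path) {
  a <- round(read_channel_stack(path) * 65535)
  storage.mode(a) <- "integer"
  a
}

#' Write a cell table to CSV
#'
#' @param cells data frame of cell records.
#' @param path output file.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
}

#' Read a cell table from CSV
#'
#' @param path CSV written by [write_cell_table()].
#' @return data frame.
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a long-format count table from CSV
#'
#' Expects columns `gastruloid_id`, `condition`, `time_h`, `population`,
#' `count`.
#'
#' @param path CSV file.
#' @return data frame of class `count_table`.
#' @export
read_count_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gastruloid_id", "condition", "time_h", "population", "count")
  check_that(all(need %in% names(d)),
             paste("count table must have columns:",
                   paste(need, collapse = ", ")))
  check_that(all(d$count >= 0 & d$count == round(d$count)),
             "counts must be nonnegative integers")
  class(d) <- c("count_table", "data.frame")
  d
}
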