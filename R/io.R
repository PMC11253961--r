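# Plain-text readers and writers for the tabular artifacts the pipeline
# exchanges.  Column types are pinned so that a written table reads back
# losslessly.

#' Read and write per-cell screen records
#'
#' @param path CSV file path.
#' @name cell_records_io
NULL

#' @rdname cell_records_io
#' @param records per-cell records tibble.
#' @export
write_cell_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname cell_records_io
#' @export
read_cell_records <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    plate = readr::col_integer(),
    well = readr::col_character(),
    strain = readr::col_character(),
    replicate = readr::col_integer(),
    .default = readr::col_double()
  ))
}

#' Read and write plate maps
#'
#' @param path CSV file path.
#' @name platemap_io
NULL

#' @rdname platemap_io
#' @param platemap plate map tibble (plate, well, strain, replicate).
#' @export
write_platemap <- function(platemap, path) {
  readr::write_csv(platemap, path)
  invisible(path)
}

#' @rdname platemap_io
#' @export
read_platemap <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    plate = readr::col_integer(),
    well = readr::col_character(),
    strain = readr::col_character(),
    replicate = readr::col_integer()
  ))
}

#' Read and write SGA colony-density tables
#'
#' @param path CSV file path.
#' @name sga_io
NULL

#' @rdname sga_io
#' @param densities long-format density table.
#' @export
write_sga_densities <- function(densities, path) {
  readr::write_csv(densities, path)
  invisible(path)
}

#' @rdname sga_io
#' @export
read_sga_densities <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    plate = readr::col_character(),
    condition = readr::col_character(),
    query_strain = readr::col_character(),
    candidate_gene = readr::col_character(),
    density = readr::col_double(),
    day = readr::col_integer()
  ))
}

#' Read and write FRAP traces
#'
#' One file per cell with columns time_s, roi, reference, background.
#'
#' @param path CSV file path.
#' @name frap_io
NULL

#' @rdname frap_io
#' @param trace FRAP trace tibble.
#' @export
write_frap_trace <- function(trace, path) {
  readr::write_csv(trace, path)
  invisible(path)
}

#' @rdname frap_io
#' @export
read_frap_trace <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_double()
  ))
}
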