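# broom-style tidiers for the fitted/derived result objects.

#' Tidy wild-type thresholds into one row per metric
#'
#' @param x a `wt_thresholds` object.
#' @param ... unused.
#' @return tibble (metric, centre, spread, high, low).
#' @export
tidy.wt_thresholds <- function(x, ...) {
  dplyr::bind_rows(
    tibble(metric = "volume_ratio", !!!as.list(x$volume)),
    tibble(metric = "intensity_ratio", !!!as.list(x$intensity))
  )
}

#' One-line summary of wild-type thresholds
#'
#' @inheritParams tidy.wt_thresholds
#' @return one-row tibble.
#' @export
glance.wt_thresholds <- function(x, ...) {
  tibble(mode = x$mode, n_controls = x$n,
         quartile_convention = x$quartile_convention)
}

#' Tidy a screen result into the per-strain hit table
#'
#' @param x a `screen_result`.
#' @param ... unused.
#' @return tibble of strain summaries with the `call` column.
#' @export
tidy.screen_result <- function(x, ...) {
  as_tibble(x$hits)
}

#' One-line summary of a screen result
#'
#' @inheritParams tidy.screen_result
#' @return one-row tibble with class counts.
#' @export
glance.screen_result <- function(x, ...) {
  tibble(
    n_quantified = x$n_quantified,
    n_high = sum(x$hits$call == "high"),
    n_low = sum(x$hits$call == "low"),
    n_normal = sum(x$hits$call == "normal"),
    n_excluded = nrow(x$exclusions)
  )
}

#' Tidy an SGA result into per-pair calls
#'
#' @param x an `sga_result`.
#' @param ... unused.
#' @return tibble (query_strain, candidate_gene, log2_fc, call).
#' @export
tidy.sga_result <- function(x, ...) {
  dplyr::select(x$calls, "query_strain", "candidate_gene",
                "log2_fc", "call")
}

#' One-line summary of an SGA result
#'
#' @inheritParams tidy.sga_result
#' @return one-row tibble with pair and gene class counts.
#' @export
glance.sga_result <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$calls),
    n_sensitive = sum(x$calls$call == "sensitive"),
    n_resistant = sum(x$calls$call == "resistant"),
    n_unmeasured = sum(x$calls$call == "unmeasured"),
    n_essential = sum(x$genes$essential_for_resistance),
    n_repressor = sum(x$genes$repressor_of_resistance)
  )
}
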