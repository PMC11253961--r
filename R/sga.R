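# Torin1-resistance scoring of synthetic-genetic-array colony grids.
# Double mutants are scored by the log2 fold change of colony density on
# Torin1 versus DMSO control medium after flooring no-growth artifacts.

#' Floor no-growth colony densities
#'
#' Grid-based density measurement assigns empty positions low or negative
#' values.  Every negative density, and the lowest `bottom_fraction` of
#' positive densities (rank-based: the `floor(bottom_fraction * n)`
#' smallest positives, ties included), is converted to 1 to represent no
#' growth.  `NA` densities (unmeasured positions) are preserved.  The
#' operation is idempotent.
#'
#' @param densities numeric vector (NA allowed).
#' @param bottom_fraction fraction of positive densities floored.
#' @return vector of the same length.
#' @export
floor_densities <- function(densities, bottom_fraction = 0.05) {
  if (length(densities) == 0L) abort("`densities` is empty.")
  x <- densities
  x[!is.na(x) & x < 0] <- 1
  pos <- which(!is.na(x) & x > 0)
  k <- floor(bottom_fraction * length(pos))
  if (k >= 1) {
    thr <- sort(x[pos])[k]
    x[pos][x[pos] <= thr] <- 1
  }
  x
}

#' log2 fold change of growth on Torin1 versus DMSO
#'
#' Densities must already be floored (>= 1), so the ratio is defined
#' everywhere a colony was measured; an unmeasured density in either
#' condition gives `NA` (the pair is unmeasured).
#'
#' @param torin_density,dmso_density floored colony densities.
#' @return log2(torin / dmso), `NA` where either input is `NA`.
#' @export
growth_fold_change <- function(torin_density, dmso_density) {
  both <- !is.na(torin_density) & !is.na(dmso_density)
  if (any(torin_density[both] < 1) || any(dmso_density[both] < 1)) {
    abort("densities below 1: flooring contract violated (run floor_densities first).")
  }
  out <- rep(NA_real_, length(torin_density))
  out[both] <- log2(torin_density[both] / dmso_density[both])
  out
}

#' Classify a double mutant from its log2 fold change
#'
#' Sensitive means essentially no growth on Torin1: a log2 fold change
#' strictly below `cutoff` (default -10, i.e. growth reduced more than
#' about a thousandfold).  A fold change at or above the cutoff is
#' resistant; an undefined fold change is unmeasured.
#'
#' @param log2_fc numeric vector (NA = unmeasured).
#' @param cutoff sensitivity cutoff on the log2 scale.
#' @return character vector: `"sensitive"`, `"resistant"`, `"unmeasured"`.
#' @export
classify_double_mutant <- function(log2_fc, cutoff = -10) {
  dplyr::case_when(
    is.na(log2_fc) ~ "unmeasured",
    log2_fc < cutoff ~ "sensitive",
    TRUE ~ "resistant"
  )
}

#' Classify a candidate gene across the query-strain panel
#'
#' A candidate gene is essential for Torin1 resistance when its deletion
#' sensitizes at least `min_sensitive` of the Torin1-resistant RPL query
#' strains (3 of 5 in the reference design), and a repressor of
#' resistance when its deletion confers resistance on at least
#' `min_resistant` of the Torin1-sensitive control queries (2 of 3).
#' Unmeasured pairs never count toward either tally.
#'
#' @param calls named character vector (query strain -> call) or a data
#'   frame with `query_strain` and `call` columns.
#' @param resistant_queries ids of the Torin1-resistant RPL queries.
#' @param control_queries ids of the Torin1-sensitive control queries.
#' @param min_sensitive,min_resistant vote thresholds.
#' @return one-row tibble: `essential_for_resistance`,
#'   `repressor_of_resistance`, `n_sensitive_rpl`, `n_resistant_control`.
#' @export
classify_candidate_gene <- function(calls, resistant_queries, control_queries,
                                    min_sensitive = 3, min_resistant = 2) {
  if (length(intersect(resistant_queries, control_queries)) > 0) {
    abort("resistant and control query ids must be disjoint.")
  }
  if (is.data.frame(calls)) {
    calls <- setNames(calls$call, calls$query_strain)
  }
  n_sens <- sum(calls[resistant_queries] == "sensitive", na.rm = TRUE)
  n_res <- sum(calls[control_queries] == "resistant", na.rm = TRUE)
  tibble(
    essential_for_resistance = n_sens >= min_sensitive,
    repressor_of_resistance = n_res >= min_resistant,
    n_sensitive_rpl = n_sens,
    n_resistant_control = n_res
  )
}

#' Score a synthetic genetic array for Torin1 resistance
#'
#' Full scoring pipeline over a long-format colony-density table: floor
#' no-growth densities (per plate and condition by default, since each
#' physical plate has its own illumination and agar artifacts), compute
#' the log2 Torin1/DMSO fold change per (query, gene) pair, classify each
#' double mutant, and classify every candidate gene against the query
#' panel.
#'
#' @param densities long tibble with columns `condition` (`"DMSO"` /
#'   `"Torin1"`; other conditions are ignored), `query_strain`,
#'   `candidate_gene`, `density`, and optionally `plate` and `day`.
#' @param resistant_queries,control_queries query panel ids (see
#'   [classify_candidate_gene()]).
#' @param cutoff sensitivity cutoff on log2 fold change.
#' @param bottom_fraction fraction of positive densities floored.
#' @param floor_scope `"plate"` (per plate-condition group) or
#'   `"global"` (per condition across plates).
#' @param day scoring day when a `day` column is present (default: the
#'   last day imaged).
#' @return an `sga_result`: list with `calls` (per pair: log2_fc, call),
#'   `genes` (per-gene classification), and the query panel.
#' @export
sga_score <- function(densities, resistant_queries, control_queries,
                      cutoff = -10, bottom_fraction = 0.05,
                      floor_scope = c("plate", "global"), day = NULL) {
  floor_scope <- match.arg(floor_scope)
  stopifnot(all(c("condition", "query_strain", "candidate_gene", "density")
                %in% names(densities)))
  d <- as_tibble(densities)
  if ("day" %in% names(d)) {
    day <- day %||% max(d$day, na.rm = TRUE)
    d <- dplyr::filter(d, .data$day == !!day)
  }
  d <- dplyr::filter(d, .data$condition %in% c("DMSO", "Torin1"))
  grp <- if (floor_scope == "plate" && "plate" %in% names(d)) {
    c("plate", "condition")
  } else {
    "condition"
  }
  d <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(density = floor_densities(.data$density, bottom_fraction)) |>
    dplyr::ungroup()
  wide <- d |>
    dplyr::select("condition", "query_strain", "candidate_gene", "density") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "density")
  if (!all(c("DMSO", "Torin1") %in% names(wide))) {
    abort("both 'DMSO' and 'Torin1' conditions are required.")
  }
  calls <- wide |>
    dplyr::mutate(
      log2_fc = growth_fold_change(.data$Torin1, .data$DMSO),
      call = classify_double_mutant(.data$log2_fc, cutoff)
    )
  genes <- calls |>
    dplyr::group_by(.data$candidate_gene) |>
    dplyr::group_modify(function(df, key) {
      classify_candidate_gene(df, resistant_queries, control_queries)
    }) |>
    dplyr::ungroup()
  structure(
    list(calls = calls, genes = genes,
         resistant_queries = resistant_queries,
         control_queries = control_queries,
         cutoff = cutoff),
    class = "sga_result"
  )
}

#' @export
print.sga_result <- function(x, ...) {
  cat(sprintf("<sga_result> %d (query, gene) pairs: %d sensitive, %d resistant, %d unmeasured\n",
              nrow(x$calls),
              sum(x$calls$call == "sensitive"),
              sum(x$calls$call == "resistant"),
              sum(x$calls$call == "unmeasured")))
  cat(sprintf("  genes: %d essential for resistance, %d repressors of resistance\n",
              sum(x$genes$essential_for_resistance),
              sum(x$genes$repressor_of_resistance)))
  invisible(x)
}
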