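# Strain-level hit calling for the arrayed deletion screen.  Per-cell
# records from the imaging pipeline are filtered, collapsed to per-well
# medians, merged over the two mated duplicates of each strain, and
# compared with thresholds anchored on the repeated wild-type controls.

#' Filter per-cell records on nuclear GFP intensity and volume
#'
#' Empty or failed wells produce spurious cell records with low GFP
#' intensity and extreme segmented volumes.  The default retains records
#' with nuclear mean GFP intensity strictly above `min_intensity`
#' (arbitrary units) and nuclear GFP volume inside `volume_range`
#' (voxels, inclusive); `direction = "drop"` inverts the rule for audit.
#'
#' @param records data frame of per-cell records with columns
#'   `nuclear_mean_gfp` and `nuclear_gfp_volume` (plus any keys).
#' @param min_intensity intensity cut in arbitrary units.
#' @param volume_range inclusive voxel-volume window `c(lo, hi)`.
#' @param direction `"keep"` (retain records passing both cuts) or
#'   `"drop"` (remove them).
#' @return tibble of retained records; removal counts per well are
#'   reported via a message and attached as attribute `removed_by_well`.
#' @export
filter_cell_records <- function(records, min_intensity = 750,
                                volume_range = c(10, 200),
                                direction = c("keep", "drop")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(records),
            all(c("nuclear_mean_gfp", "nuclear_gfp_volume") %in% names(records)))
  pass <- records$nuclear_mean_gfp > min_intensity &
    records$nuclear_gfp_volume >= volume_range[1] &
    records$nuclear_gfp_volume <= volume_range[2]
  keep <- if (direction == "keep") pass else !pass
  removed <- records[!keep, , drop = FALSE]
  out <- as_tibble(records[keep, , drop = FALSE])
  by_well <- if (all(c("plate", "well") %in% names(removed))) {
    dplyr::count(as_tibble(removed), .data$plate, .data$well,
                 name = "n_removed")
  } else {
    tibble(n_removed = nrow(removed))
  }
  if (nrow(removed) > 0) {
    inform(sprintf("filter_cell_records: removed %d of %d record(s).",
                   nrow(removed), nrow(records)))
  }
  attr(out, "removed_by_well") <- by_well
  out
}

#' Per-well medians of the ratio readouts
#'
#' Collapses filtered cell records to one row per (plate, well) with the
#' median of each ratio metric and the cell count.  Wells with fewer than
#' `min_cells` cells are unreliable and are dropped (reported via the
#' `dropped_wells` attribute).
#'
#' @param records filtered cell records with `plate`, `well`,
#'   `rdna_volume_ratio`, `rdna_intensity_ratio` columns.
#' @param min_cells minimum cells per well.
#' @return tibble (plate, well, n_cells, median_volume_ratio,
#'   median_intensity_ratio) of surviving wells.
#' @export
summarize_wells <- function(records, min_cells = 30) {
  stopifnot(all(c("plate", "well", "rdna_volume_ratio",
                  "rdna_intensity_ratio") %in% names(records)))
  wells <- records |>
    dplyr::group_by(.data$plate, .data$well) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      median_volume_ratio = median(.data$rdna_volume_ratio),
      median_intensity_ratio = median(.data$rdna_intensity_ratio),
      .groups = "drop"
    )
  dropped <- dplyr::filter(wells, .data$n_cells < min_cells)
  out <- dplyr::filter(wells, .data$n_cells >= min_cells)
  if (nrow(dropped) > 0) {
    inform(sprintf("summarize_wells: dropped %d well(s) with < %d cells.",
                   nrow(dropped), min_cells))
  }
  attr(out, "dropped_wells") <- dropped
  out
}

#' Merge the two mated duplicates of each strain
#'
#' Each deletion strain is mated and imaged in duplicate; the strain
#' summary is the arithmetic mean of the two replicate-well medians.
#' Strains with fewer than two surviving replicate wells are not called
#' on a single replicate: they are excluded and listed with a reason.
#'
#' @param well_medians output of [summarize_wells()].
#' @param platemap data frame (plate, well, strain, replicate) mapping
#'   wells to strains; control wells may repeat a strain id.
#' @return tibble (strain, median_volume_ratio, median_intensity_ratio,
#'   n_cells_rep1, n_cells_rep2); excluded strains are attached as
#'   attribute `excluded` (strain, reason).
#' @export
merge_mated_duplicates <- function(well_medians, platemap) {
  stopifnot(all(c("plate", "well", "strain", "replicate") %in% names(platemap)))
  joined <- dplyr::inner_join(well_medians, as_tibble(platemap),
                              by = c("plate", "well"))
  unknown <- dplyr::anti_join(well_medians, as_tibble(platemap),
                              by = c("plate", "well"))
  if (nrow(unknown) > 0) {
    abort(paste0("wells with no strain mapping: ",
                 paste(paste(unknown$plate, unknown$well, sep = "/"),
                       collapse = ", ")))
  }
  per_strain <- joined |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(
      n_reps = dplyr::n_distinct(.data$replicate),
      median_volume_ratio = mean(.data$median_volume_ratio),
      median_intensity_ratio = mean(.data$median_intensity_ratio),
      n_cells_rep1 = sum(.data$n_cells[.data$replicate == 1]),
      n_cells_rep2 = sum(.data$n_cells[.data$replicate == 2]),
      .groups = "drop"
    )
  ok <- dplyr::filter(per_strain, .data$n_reps >= 2)
  excluded <- per_strain |>
    dplyr::filter(.data$n_reps < 2) |>
    dplyr::transmute(.data$strain, reason = "missing_replicate")
  # strains in the plate map that never produced a surviving well
  absent <- setdiff(unique(platemap$strain), per_strain$strain)
  if (length(absent) > 0) {
    excluded <- dplyr::bind_rows(
      excluded, tibble(strain = absent, reason = "insufficient_cells"))
  }
  out <- dplyr::select(ok, -"n_reps")
  attr(out, "excluded") <- excluded
  out
}

#' Wild-type-anchored hit thresholds
#'
#' The screen centre is the mean of the wild-type control medians (one
#' per control plate, eight in the reference design).  The high threshold
#' for each metric is the centre plus one third of the interquartile
#' range of those control medians; the low threshold is the centre minus
#' one quarter of it.  Quartiles are by linear interpolation.  An
#' alternative mode replaces the IQR fractions with +0.33 / -0.25
#' standard deviations.
#'
#' @param wt_medians data frame with columns `volume_ratio` and
#'   `intensity_ratio`: one row per control plate median (>= 2 rows).
#' @param mode `"iqr"` (default) or `"sd"`.
#' @return a `wt_thresholds` object.
#' @examples
#' wt <- tibble::tibble(
#'   volume_ratio = c(0.40, 0.45, 0.50, 0.50, 0.55, 0.55, 0.60, 0.65),
#'   intensity_ratio = c(1.8, 1.9, 2.0, 2.0, 2.1, 2.1, 2.2, 2.3))
#' compute_wt_thresholds(wt)
#' @export
compute_wt_thresholds <- function(wt_medians, mode = c("iqr", "sd")) {
  mode <- match.arg(mode)
  stopifnot(all(c("volume_ratio", "intensity_ratio") %in% names(wt_medians)))
  if (nrow(wt_medians) < 2L) {
    abort("at least 2 wild-type medians per metric are required.")
  }
  one <- function(x) {
    centre <- mean(x)
    if (mode == "iqr") {
      spread <- diff(quantile(x, c(0.25, 0.75), names = FALSE, type = 7))
      c(centre = centre, spread = spread,
        high = centre + spread / 3, low = centre - spread / 4)
    } else {
      spread <- sd(x)
      c(centre = centre, spread = spread,
        high = centre + 0.33 * spread, low = centre - 0.25 * spread)
    }
  }
  structure(
    list(volume = one(wt_medians$volume_ratio),
         intensity = one(wt_medians$intensity_ratio),
         mode = mode, n = nrow(wt_medians),
         quartile_convention = "linear interpolation (type 7)"),
    class = "wt_thresholds"
  )
}

#' @export
print.wt_thresholds <- function(x, ...) {
  cat(sprintf("<wt_thresholds> mode=%s (n=%d control medians)\n", x$mode, x$n))
  for (m in c("volume", "intensity")) {
    v <- x[[m]]
    cat(sprintf("  %-9s centre %.4f  spread %.4f  high %.4f  low %.4f\n",
                m, v["centre"], v["spread"], v["high"], v["low"]))
  }
  invisible(x)
}

#' Call screen hits against wild-type thresholds
#'
#' A strain is a high hit only if both its volume-ratio and
#' intensity-ratio summaries exceed the high thresholds, and a low hit
#' only if both fall below the low thresholds; anything else is normal.
#' The conjunction makes the call robust to a single-metric excursion.
#'
#' @param summaries strain summaries from [merge_mated_duplicates()].
#' @param thresholds a [compute_wt_thresholds()] object.
#' @return the summaries with a `call` column (`"high"`, `"low"`,
#'   `"normal"`).
#' @export
call_hits <- function(summaries, thresholds) {
  stopifnot(inherits(thresholds, "wt_thresholds"))
  v <- summaries$median_volume_ratio
  i <- summaries$median_intensity_ratio
  call <- dplyr::case_when(
    v > thresholds$volume["high"] & i > thresholds$intensity["high"] ~ "high",
    v < thresholds$volume["low"] & i < thresholds$intensity["low"] ~ "low",
    TRUE ~ "normal"
  )
  out <- dplyr::mutate(summaries, call = call)
  inform(sprintf("call_hits: %d high, %d low, %d normal of %d strains.",
                 sum(call == "high"), sum(call == "low"),
                 sum(call == "normal"), length(call)))
  out
}

#' Full screen pipeline: per-cell records to strain calls
#'
#' Chains [filter_cell_records()], [summarize_wells()],
#' [merge_mated_duplicates()], wild-type threshold computation and
#' [call_hits()].  Wild-type control medians are taken per control plate
#' by pooling that plate's wild-type cell records (the controls are
#' replicated within each plate) and taking the median per metric.
#'
#' @param cells per-cell records (see [filter_cell_records()]) with
#'   `plate`, `well` keys.
#' @param platemap plate map (plate, well, strain, replicate).
#' @param wt_plates plates whose wild-type controls anchor the
#'   thresholds.
#' @param wt_strain strain id of the wild-type control.
#' @param min_intensity,volume_range,direction record filters.
#' @param min_cells minimum cells per well.
#' @param threshold_mode `"iqr"` or `"sd"` (see
#'   [compute_wt_thresholds()]).
#' @return a `screen_result`: list with `hits` (strain calls),
#'   `thresholds`, `wt_medians`, `exclusions` (strain/well level, with
#'   reasons), and `n_quantified`.
#' @export
screen_call <- function(cells, platemap, wt_plates, wt_strain = "WT",
                        min_intensity = 750, volume_range = c(10, 200),
                        direction = "keep", min_cells = 30,
                        threshold_mode = "iqr") {
  platemap <- as_tibble(platemap)
  filtered <- filter_cell_records(cells, min_intensity, volume_range,
                                  direction)
  wells <- summarize_wells(filtered, min_cells)
  dropped_wells <- attr(wells, "dropped_wells")

  # wild-type control medians, one per designated control plate
  wt_wells <- platemap |>
    dplyr::filter(.data$strain == wt_strain, .data$plate %in% wt_plates)
  wt_cells <- dplyr::inner_join(filtered, wt_wells, by = c("plate", "well"))
  wt_medians <- wt_cells |>
    dplyr::group_by(.data$plate) |>
    dplyr::summarise(volume_ratio = median(.data$rdna_volume_ratio),
                     intensity_ratio = median(.data$rdna_intensity_ratio),
                     .groups = "drop")
  thresholds <- compute_wt_thresholds(
    dplyr::select(wt_medians, "volume_ratio", "intensity_ratio"),
    mode = threshold_mode)

  mutant_map <- dplyr::filter(platemap, .data$strain != wt_strain)
  mutant_wells <- dplyr::semi_join(wells, mutant_map, by = c("plate", "well"))
  summaries <- merge_mated_duplicates(mutant_wells, mutant_map)
  hits <- call_hits(summaries, thresholds)

  exclusions <- attr(summaries, "excluded") %||% tibble(strain = character(0),
                                                        reason = character(0))
  structure(
    list(hits = hits,
         thresholds = thresholds,
         wt_medians = wt_medians,
         exclusions = exclusions,
         dropped_wells = dropped_wells,
         n_quantified = nrow(hits)),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d strains quantified: %d high, %d low; %d excluded\n",
              x$n_quantified,
              sum(x$hits$call == "high"), sum(x$hits$call == "low"),
              nrow(x$exclusions)))
  invisible(x)
}

#' rDNA copy-number equivalence by the 10 percent rule
#'
#' Two strains are treated as having approximately equal 28S rRNA gene
#' copy number when the candidate differs from the reference by at most
#' `tol` (default 10 percent, boundary inclusive).
#'
#' @param strain_copies,wt_copies positive copy-number estimates.
#' @param tol relative tolerance.
#' @return logical vector.
#' @export
copy_number_equivalent <- function(strain_copies, wt_copies, tol = 0.10) {
  if (any(strain_copies <= 0) || any(wt_copies <= 0)) {
    abort("copy numbers must be positive.")
  }
  abs(strain_copies - wt_copies) / wt_copies <= tol
}
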