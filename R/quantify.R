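#' Quantify rDNA morphometrics for one segmented field or cell
#'
#' Runs the full imaging pipeline on a two-channel stack: per-slice white
#' top-hat background subtraction and Gaussian smoothing of the GFP and
#' mCherry channels, full-histogram 3D Otsu segmentation of each, and
#' compartment morphometrics on the resulting masks.  The rDNA extension
#' is reported in micrometres when both the rDNA object and bulk
#' chromatin are nonempty, `NA` otherwise.
#'
#' @param stack an [image_stack()] with `nuclear_gfp` and
#'   `nucleolar_mcherry` roles.
#' @param cell_id identifier copied into the output row.
#' @param se_side,sigma preprocessing parameters, see [preprocess_stack()].
#' @param weighted_extension intensity-weighted centroids for the
#'   extension (see [compute_extension()]).
#' @return one-row tibble: `cell_id`, the [measure_cell()] columns,
#'   `rdna_extension_um`, and the two Otsu thresholds.
#' @examples
#' sc <- sim_scene(seed = 1)
#' quantify_scene(sc$stack)
#' @export
quantify_scene <- function(stack, cell_id = "cell_1", se_side = 25, sigma = 1,
                           weighted_extension = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  for (role in c("nuclear_gfp", "nucleolar_mcherry")) {
    if (!has_channel(stack, role)) {
      abort(sprintf("channel role '%s' is required but missing.", role))
    }
  }
  gfp <- preprocess_stack(stack, "nuclear_gfp", se_side, sigma)
  mch <- preprocess_stack(stack, "nucleolar_mcherry", se_side, sigma)
  gm <- otsu_mask_3d(gfp)
  mm <- otsu_mask_3d(mch)
  masks <- derive_compartments(gm, mm)
  row <- measure_cell(masks, gfp)
  ext <- if (sum(masks$rdna) > 0L && sum(masks$bulk_chromatin) > 0L) {
    compute_extension(masks, gfp, stack$pixel_size_xy, stack$z_step,
                      weighted = weighted_extension)
  } else {
    NA_real_
  }
  dplyr::bind_cols(
    tibble(cell_id = cell_id),
    row,
    tibble(rdna_extension_um = ext,
           otsu_gfp = attr(gm, "threshold"),
           otsu_mcherry = attr(mm, "threshold"))
  )
}

#' Quantify a population of cells and stage it by cell length
#'
#' Applies [quantify_scene()] to each cell's stack, removes cells that do
#' not have exactly one nucleus, and assigns early/mid/late G2 stages by
#' cell-length tertiles over the retained population.
#'
#' @param cells tibble with columns `cell_id`, `cell_length`,
#'   `nucleus_count` (e.g. from [sim_population()]).
#' @param stacks named list of [image_stack()] objects keyed by `cell_id`.
#' @param ... passed to [quantify_scene()].
#' @return tibble of per-cell morphometrics joined with `cell_length` and
#'   `stage`.
#' @export
quantify_population <- function(cells, stacks, ...) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "cell_length", "nucleus_count") %in% names(cells)))
  kept <- filter_multinucleate(cells)
  rows <- purrr::map(kept$cell_id, function(id) {
    quantify_scene(stacks[[id]], cell_id = id, ...)
  })
  out <- dplyr::bind_rows(rows)
  staged <- stage_population(kept)
  out |>
    dplyr::left_join(staged, by = "cell_id") |>
    as_tibble()
}
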