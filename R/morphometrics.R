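# Per-cell compartment masks and the morphometric readouts computed on
# them.  The rDNA object is defined as the GFP (DNA) mask inside the
# mCherry (nucleolar) mask; bulk chromatin is the remainder of the
# nuclear mask.

#' Derive nuclear compartment masks from the two marker masks
#'
#' The nuclear mask is the GapR-GFP (DNA) segmentation; the nucleolar
#' mask is the Nhp2-mCherry segmentation.  The rDNA object is their
#' voxelwise intersection, and bulk chromatin is the nuclear mask with
#' the nucleolar voxels removed, so the set identities
#' `rdna == nucleus & nucleolus` and `bulk == nucleus & !nucleolus`
#' hold by construction and `bulk` and `rdna` are disjoint.
#'
#' @param gfp_mask,mcherry_mask logical 3D arrays of identical shape.
#' @return a `segmentation_masks` object: list with logical 3D volumes
#'   `nucleus`, `nucleolus`, `rdna`, `bulk_chromatin`.
#' @export
derive_compartments <- function(gfp_mask, mcherry_mask) {
  if (!identical(dim(gfp_mask), dim(mcherry_mask))) {
    abort("`gfp_mask` and `mcherry_mask` must have identical shape.")
  }
  g <- gfp_mask & TRUE   # strip attributes, coerce to logical
  m <- mcherry_mask & TRUE
  structure(
    list(nucleus = g,
         nucleolus = m,
         rdna = g & m,
         bulk_chromatin = g & !m),
    class = "segmentation_masks"
  )
}

#' @export
print.segmentation_masks <- function(x, ...) {
  cat(sprintf(
    "<segmentation_masks> nucleus %d | nucleolus %d | rdna %d | bulk %d voxels\n",
    sum(x$nucleus), sum(x$nucleolus), sum(x$rdna), sum(x$bulk_chromatin)))
  invisible(x)
}

#' Remove cells that do not have exactly one nucleus
#'
#' Cells with two nuclei have passed mitosis and are excluded so that the
#' analysis is restricted to G2 (late interphase); cells without a
#' detectable nucleus are unmeasurable and are excluded too.
#'
#' @param cells data frame with a `nucleus_count` column.
#' @return the retained rows, as a tibble; the number of removals is
#'   reported via a message and attached as attribute `n_removed`.
#' @export
filter_multinucleate <- function(cells) {
  stopifnot(is.data.frame(cells), "nucleus_count" %in% names(cells))
  keep <- cells$nucleus_count == 1L
  out <- as_tibble(cells[keep, , drop = FALSE])
  n_rm <- sum(!keep)
  if (n_rm > 0) {
    inform(sprintf("filter_multinucleate: removed %d cell(s) without exactly one nucleus.", n_rm))
  }
  attr(out, "n_removed") <- n_rm
  out
}

#' Per-cell morphometric readouts
#'
#' Volumes are voxel counts over each compartment mask; mean intensities
#' are arithmetic means of the GFP volume over the mask.  The three ratio
#' readouts are the rDNA volume normalized to the nuclear volume, the
#' rDNA mean GFP intensity normalized to the nuclear mean GFP intensity,
#' and the nucleolar (mCherry) volume normalized to the nuclear volume.
#' An empty rDNA object yields zero ratios and the flag
#' `"no_rdna_object"` rather than a dropped cell; a nucleolar mask
#' extending beyond the nuclear mask is flagged
#' `"nucleolus_outside_nucleus"`.
#'
#' @param masks a `segmentation_masks` object.
#' @param gfp 3D numeric array of GFP intensities, same shape as the masks.
#' @return one-row tibble with columns `nuclear_volume`,
#'   `nuclear_mean_gfp`, `rdna_volume`, `rdna_mean_gfp`,
#'   `nucleolar_volume`, `rdna_volume_ratio`, `rdna_intensity_ratio`,
#'   `mcherry_volume_ratio`, `flags`.
#' @export
measure_cell <- function(masks, gfp) {
  stopifnot(inherits(masks, "segmentation_masks"))
  if (!identical(dim(gfp), dim(masks$nucleus))) {
    abort("`gfp` must have the same shape as the masks.")
  }
  n_vol <- sum(masks$nucleus)
  if (n_vol == 0L) abort("nuclear mask is empty; cell is not measurable.")
  r_vol <- sum(masks$rdna)
  l_vol <- sum(masks$nucleolus)
  n_mean <- mean(gfp[masks$nucleus])
  flags <- character(0)
  if (r_vol > 0L) {
    r_mean <- mean(gfp[masks$rdna])
    vol_ratio <- r_vol / n_vol
    int_ratio <- r_mean / n_mean
  } else {
    r_mean <- NA_real_
    vol_ratio <- 0
    int_ratio <- 0
    flags <- c(flags, "no_rdna_object")
  }
  mch_ratio <- l_vol / n_vol
  if (any(masks$nucleolus & !masks$nucleus)) {
    flags <- c(flags, "nucleolus_outside_nucleus")
  }
  tibble(
    nuclear_volume = n_vol,
    nuclear_mean_gfp = n_mean,
    rdna_volume = r_vol,
    rdna_mean_gfp = r_mean,
    nucleolar_volume = l_vol,
    rdna_volume_ratio = vol_ratio,
    rdna_intensity_ratio = int_ratio,
    mcherry_volume_ratio = mch_ratio,
    flags = paste(flags, collapse = ";")
  )
}

weighted_centroid <- function(mask, weights) {
  idx <- which(mask, arr.ind = TRUE)
  w <- weights[mask]
  if (all(w == 0)) w <- rep(1, length(w))
  colSums(idx * w) / sum(w)
}

#' rDNA extension: distance between rDNA and bulk-chromatin midpoints
#'
#' The midpoint of each compartment is its GFP-intensity-weighted
#' centroid (binary centroids via `weighted = FALSE`).  The distance is
#' Euclidean in physical units, with z scaled by the slice spacing and
#' y/x by the lateral pixel size.
#'
#' @param masks a `segmentation_masks` object with nonempty `rdna` and
#'   `bulk_chromatin`.
#' @param gfp 3D GFP intensity array.
#' @param pixel_size_xy,z_step voxel geometry in micrometres.
#' @param weighted use intensity-weighted centroids (default) or binary.
#' @return extension in micrometres (scalar, >= 0).
#' @export
compute_extension <- function(masks, gfp, pixel_size_xy = 0.11, z_step = 0.3,
                              weighted = TRUE) {
  stopifnot(inherits(masks, "segmentation_masks"))
  for (region in c("rdna", "bulk_chromatin")) {
    if (sum(masks[[region]]) == 0L) {
      abort(sprintf("region '%s' is empty; extension is undefined.", region))
    }
  }
  w <- if (weighted) gfp else array(1, dim(gfp))
  c1 <- weighted_centroid(masks$rdna, w)
  c2 <- weighted_centroid(masks$bulk_chromatin, w)
  d <- (c1 - c2) * c(z_step, pixel_size_xy, pixel_size_xy)
  sqrt(sum(d^2))
}

#' Stage G2 cells by cell length
#'
#' Fission yeast grows by tip elongation through G2, so cell length ranks
#' cells within the interval: the shortest third of the population is
#' called early G2 and the longest third late G2, with the remainder mid
#' G2.  Boundaries are by rank on the sorted lengths (`round(fraction *
#' n)` cells at each extreme); cells whose length ties across a boundary
#' are all assigned to the less extreme class, so a population of equal
#' lengths is entirely mid G2.
#'
#' @param cells data frame with columns `cell_id` and `cell_length`
#'   (micrometres, positive).
#' @param fraction fraction of the population called at each extreme.
#' @return tibble `cell_id`, `cell_length`, `stage` with stage one of
#'   `"early_G2"`, `"mid_G2"`, `"late_G2"`.
#' @export
stage_population <- function(cells, fraction = 0.33) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "cell_length") %in% names(cells)))
  n <- nrow(cells)
  if (n == 0L) abort("`cells` is empty; staging is undefined.")
  len <- cells$cell_length
  if (any(!is.finite(len)) || any(len <= 0)) {
    abort("`cell_length` must be positive and finite.")
  }
  k <- round(fraction * n)
  s <- sort(len)
  stage <- rep("mid_G2", n)
  if (k >= 1) {
    lo <- s[k]
    # ties across the early boundary go to mid_G2
    early <- if (k < n && s[k + 1] == lo) len < lo else len <= lo
    hi <- s[n - k + 1]
    late <- if (k < n && s[n - k] == hi) len > hi else len >= hi
    stage[early] <- "early_G2"
    stage[late] <- "late_G2"
  }
  tibble(cell_id = cells$cell_id, cell_length = len, stage = stage)
}

#' Tukey-fence outlier removal
#'
#' Removes values outside `[Q1 - k * IQR, Q3 + k * IQR]` with quartiles
#' by linear interpolation of order statistics (the convention used
#' consistently wherever an interquartile range is computed in this
#' package).  Fewer than four values pass through unchanged with a
#' warning, since quartiles are not meaningful.
#'
#' @param values numeric vector.
#' @param k fence multiplier (1.5 = standard Tukey fences).
#' @return list with `kept` (input order preserved), `removed`, and
#'   `fences` (lower, upper).
#' @export
iqr_outlier_filter <- function(values, k = 1.5) {
  stopifnot(is.numeric(values))
  if (length(values) < 4L) {
    warn("fewer than 4 values: outlier filter passed through unchanged.")
    return(list(kept = values, removed = numeric(0),
                fences = c(NA_real_, NA_real_)))
  }
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  inside <- values >= fences[1] & values <= fences[2]
  list(kept = values[inside], removed = values[!inside], fences = fences)
}
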