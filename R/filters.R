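# Image filters used ahead of segmentation.  All 2D operations use a
# replicate boundary (edge pixels extended outward) so that the top-hat
# does not manufacture halos at the frame border.

pad_replicate <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(rep(1L, p), seq_len(nr), rep(nr, p)),
    c(rep(1L, p), seq_len(nc), rep(nc, p))]
}

crop_center <- function(m, p, nr, nc) {
  m[p + seq_len(nr), p + seq_len(nc)]
}

#' White top-hat background subtraction of a 2D slice
#'
#' Subtracts the grayscale morphological opening under a flat square
#' structuring element from the image.  Structures wider than the
#' structuring element survive the opening and are removed from the
#' result, so the top-hat retains objects smaller than `se_side` pixels
#' and suppresses smooth background (including any constant offset and
#' linear shading).  The output is clamped at zero; opening is
#' anti-extensive so the result never exceeds the input.
#'
#' @param slice 2D numeric matrix, finite and non-negative.
#' @param se_side side length in pixels of the square structuring element.
#' @return matrix of the same dimension, everywhere in `[0, slice]`.
#' @examples
#' m <- matrix(100, 50, 50)       # constant image
#' range(white_tophat_2d(m, 25))  # all zero
#' @export
white_tophat_2d <- function(slice, se_side = 25) {
  if (!is.matrix(slice)) abort("`slice` must be a 2D matrix.")
  if (!all(is.finite(slice))) abort("`slice` contains non-finite pixels.")
  if (se_side <= 0) abort("`se_side` must be a positive integer.")
  se_side <- as.integer(se_side)
  kern <- matrix(1, se_side, se_side)
  p <- se_side
  # EBImage grayscale morphology operates on [0, 1]; rescaling is
  # order-preserving, so min/max filters commute with it exactly
  scale <- max(slice)
  if (scale <= 0) return(slice * 0)
  padded <- pad_replicate(slice / scale, p)
  opened <- EBImage::dilate(EBImage::erode(padded, kern), kern) * scale
  out <- slice - crop_center(opened, p, nrow(slice), ncol(slice))
  pmax(out, 0)
}

#' Gaussian smoothing of a 2D slice
#'
#' Convolution with a normalized, sampled 2D Gaussian kernel truncated at
#' three standard deviations, with replicate boundary handling.  The
#' kernel has unit mass, so constant regions and total interior intensity
#' are preserved.
#'
#' @param slice 2D numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; must be positive.
#' @return smoothed matrix of the same dimension.
#' @export
gaussian_smooth_2d <- function(slice, sigma = 1) {
  if (!is.matrix(slice)) abort("`slice` must be a 2D matrix.")
  if (sigma <= 0) abort("`sigma` must be positive.")
  EBImage::gblur(slice, sigma = sigma, boundary = "replicate")
}

as_volume <- function(x, channel = NULL) {
  if (inherits(x, "image_stack")) {
    if (is.null(channel)) abort("`channel` must name a role for an image_stack.")
    get_channel(x, channel)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    x
  } else {
    abort("expected an image_stack or a 3D array.")
  }
}

#' Preprocess a 3D volume slice by slice
#'
#' Applies [white_tophat_2d()] followed by [gaussian_smooth_2d()]
#' independently to every z-slice.  Slices are treated in 2D because
#' axial sampling is much coarser than lateral sampling; the z dimension
#' is untouched, so permutation of input slices permutes the output the
#' same way.
#'
#' @param x an [image_stack()] or a 3D array `(z, y, x)`.
#' @param channel channel role when `x` is an image stack.
#' @param se_side square structuring element side for the top-hat, pixels.
#' @param sigma Gaussian smoothing width, pixels.
#' @return 3D array of the same dimensions as the input channel.
#' @export
preprocess_stack <- function(x, channel = NULL, se_side = 25, sigma = 1) {
  vol <- as_volume(x, channel)
  for (i in seq_len(dim(vol)[1])) {
    s <- white_tophat_2d(array(vol[i, , ], dim(vol)[2:3]), se_side)
    vol[i, , ] <- gaussian_smooth_2d(s, sigma)
  }
  vol
}

#' Otsu threshold of a 3D volume over its full histogram
#'
#' Finds the threshold maximizing the between-class variance of the
#' voxel-intensity histogram pooled over the entire volume (not per
#' slice).  For volumes with at most `n_bins` distinct values every
#' distinct value is examined as a candidate, so the search is exhaustive;
#' otherwise intensities are binned into `n_bins` equal-width bins and bin
#' midpoints are the candidates.  If several candidates attain the
#' maximum, their mean is returned, which places the threshold centrally
#' in an empty histogram gap.
#'
#' @param volume 3D numeric array with at least two distinct values.
#' @param n_bins histogram resolution for continuous data.
#' @return the scalar threshold.
#' @export
otsu_threshold <- function(volume, n_bins = 256) {
  v <- as.numeric(volume)
  u <- sort(unique(v))
  if (length(u) < 2L) abort("degenerate histogram: volume is constant.")
  if (length(u) <= n_bins) {
    cand <- u[-length(u)]
    cnt <- tabulate(match(v, u), nbins = length(u))
    lev <- u
  } else {
    br <- seq(u[1], u[length(u)], length.out = n_bins + 1)
    cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE),
                    nbins = n_bins)
    lev <- (br[-1] + br[-length(br)]) / 2
    cand <- lev[-length(lev)]
  }
  p <- cnt / sum(cnt)
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[length(mu)]
  w0 <- w0[-length(w0)]
  mu <- mu[-length(mu)]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mean(cand[abs(bcv - max(bcv)) < 1e-10 * max(bcv, .Machine$double.xmin)])
}

#' Otsu foreground mask of a 3D volume
#'
#' Voxels strictly above the [otsu_threshold()] are foreground.  The
#' threshold used is attached as the `"threshold"` attribute.
#'
#' @inheritParams otsu_threshold
#' @return logical 3D array with attribute `threshold`.
#' @export
otsu_mask_3d <- function(volume, n_bins = 256) {
  thr <- otsu_threshold(volume, n_bins)
  mask <- volume > thr
  attr(mask, "threshold") <- thr
  mask
}

erode_mask_2d <- function(mask, times = 1L) {
  # binary erosion with a 3 x 3 in-plane structuring element (1 in z),
  # applied independently per slice; replicate boundary
  kern <- matrix(1, 3, 3)
  d <- dim(mask)
  out <- mask
  for (t in seq_len(times)) {
    for (i in seq_len(d[1])) {
      m <- array(out[i, , ] * 1, d[2:3])
      p <- pad_replicate(m, 1L)
      e <- EBImage::erode(p, kern)
      out[i, , ] <- crop_center(e, 1L, d[2], d[3]) > 0.5
    }
  }
  out
}

#' Segment fluorescence channels of a BFP-tagged acquisition
#'
#' Channel-wise segmentation used for strains carrying an RNA Pol I
#' subunit tagged with BFP alongside the GFP and mCherry markers.  Each
#' fluorescence channel is background subtracted with a white top-hat
#' (square structuring element, default 15 px), smoothed with a Gaussian
#' (sigma 1 px), and thresholded at `threshold_factor` times the mean of
#' the processed channel (strictly above).  The GFP mask is then eroded
#' once and the BFP mask twice with a 3 x 3 x 1 structuring element to
#' trim boundary bleed between spectrally adjacent channels.
#'
#' @param stack an [image_stack()]; the `polI_bfp` role must be present.
#' @param se_side top-hat structuring element side, pixels.
#' @param sigma Gaussian width, pixels.
#' @param threshold_factor multiple of the processed-channel mean used as
#'   the threshold.
#' @return named list of logical 3D masks (one per fluorescence channel
#'   present), each with a `"threshold"` attribute.
#' @export
segment_bfp_stack <- function(stack, se_side = 15, sigma = 1,
                              threshold_factor = 2) {
  stopifnot(inherits(stack, "image_stack"))
  if (!has_channel(stack, "polI_bfp")) {
    abort("channel role 'polI_bfp' is required but missing.")
  }
  roles <- intersect(names(stack$channels),
                     c("nuclear_gfp", "nucleolar_mcherry", "polI_bfp"))
  erosions <- c(nuclear_gfp = 1L, nucleolar_mcherry = 0L, polI_bfp = 2L)
  out <- list()
  for (role in roles) {
    proc <- preprocess_stack(stack, role, se_side = se_side, sigma = sigma)
    thr <- threshold_factor * mean(proc)
    mask <- proc > thr
    if (erosions[[role]] > 0L) mask <- erode_mask_2d(mask, erosions[[role]])
    attr(mask, "threshold") <- thr
    out[[role]] <- mask
  }
  out
}
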