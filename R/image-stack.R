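#' Multi-channel 3D image stack
#'
#' Container for a multi-channel 3D fluorescence acquisition.  Voxels are
#' stored as a 4D array indexed `(channel, z, y, x)` in arbitrary intensity
#' units; channel roles name what each channel carries.  Physical geometry
#' is anisotropic: the lateral pixel size and the z step are carried
#' separately and used wherever distances are reported in micrometres.
#'
#' @param voxels 4D numeric array indexed `(channel, z, y, x)`; all values
#'   must be finite and non-negative.
#' @param channels named integer vector mapping channel roles to channel
#'   indices.  Recognised roles: `nuclear_gfp`, `nucleolar_mcherry`,
#'   `polI_bfp`, `transmitted`.
#' @param pixel_size_xy lateral pixel size in micrometres per pixel.
#' @param z_step axial spacing in micrometres per slice.
#'
#' @return An object of class `image_stack`.
#' @examples
#' vox <- array(runif(2 * 4 * 8 * 8), dim = c(2, 4, 8, 8))
#' stk <- image_stack(vox, c(nuclear_gfp = 1, nucleolar_mcherry = 2))
#' dim(get_channel(stk, "nuclear_gfp"))
#' @export
image_stack <- function(voxels, channels,
                        pixel_size_xy = 0.11, z_step = 0.3) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L) {
    abort("`voxels` must be a 4D array indexed (channel, z, y, x).")
  }
  if (!all(is.finite(voxels))) {
    abort("`voxels` must be finite everywhere.")
  }
  if (any(voxels < 0)) {
    abort("`voxels` must be non-negative.")
  }
  known <- c("nuclear_gfp", "nucleolar_mcherry", "polI_bfp", "transmitted")
  if (is.null(names(channels)) || !all(names(channels) %in% known)) {
    abort(paste0("`channels` must be a named vector with roles among: ",
                 paste(known, collapse = ", "), "."))
  }
  if (any(channels < 1L) || any(channels > dim(voxels)[1])) {
    abort("channel indices out of range for `voxels`.")
  }
  if (pixel_size_xy <= 0 || z_step <= 0) {
    abort("`pixel_size_xy` and `z_step` must be positive.")
  }
  structure(
    list(voxels = voxels,
         channels = vapply(channels, as.integer, integer(1)),
         pixel_size_xy = pixel_size_xy,
         z_step = z_step),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d channel(s), %d x %d x %d (z,y,x)\n",
              d[1], d[2], d[3], d[4]))
  cat("  roles: ",
      paste(sprintf("%s=%d", names(x$channels), x$channels), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  voxel: %.3f um (xy) x %.3f um (z)\n",
              x$pixel_size_xy, x$z_step))
  invisible(x)
}

#' Extract one channel of an image stack as a 3D volume
#'
#' @param stack an [image_stack()].
#' @param role channel role to extract (e.g. `"nuclear_gfp"`).
#' @return 3D numeric array indexed `(z, y, x)`.
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  if (!role %in% names(stack$channels)) {
    abort(sprintf("channel role '%s' is not present in this stack.", role))
  }
  idx <- stack$channels[[role]]
  d <- dim(stack$voxels)
  array(stack$voxels[idx, , , ], dim = d[2:4])
}

#' Does a stack carry a channel role?
#'
#' @inheritParams get_channel
#' @return logical scalar.
#' @export
has_channel <- function(stack, role) {
  inherits(stack, "image_stack") && role %in% names(stack$channels)
}
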