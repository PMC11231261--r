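#' Exact Euclidean distance transform with anisotropic voxels
#'
#' Distance, in physical units, from every voxel center to the nearest
#' voxel center inside \code{mask}. Voxels in the mask get 0; when the mask
#' is empty every voxel gets \code{Inf}. The transform is exact (separable
#' lower-envelope algorithm run per axis), and anisotropy is handled by
#' scaling sample positions by each axis's spacing.
#'
#' @param mask logical array (2D or 3D).
#' @param spacing physical size per axis, same order as \code{dim(mask)};
#'   defaults to unit spacing (pixel distances).
#' @param squared return squared distances (exact dyadic arithmetic for
#'   dyadic spacings; used where boundary decisions must be float-safe).
#' @return numeric array of (squared) distances, same shape as \code{mask}.
#' @export
distance_to_mask <- function(mask, spacing = NULL, squared = FALSE) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be an array")
  if (is.null(spacing)) spacing <- rep(1, length(d))
  if (length(spacing) != length(d))
    stop("spacing must have one entry per axis")
  dsq <- .edt_sq_cpp(as.logical(mask), as.integer(d), as.numeric(spacing))
  out <- if (squared) dsq else sqrt(dsq)
  array(out, dim = d)
}

#' Erode a binary mask by a Euclidean radius
#'
#' Keeps exactly the pixels/voxels lying strictly farther than
#' \code{radius} (in pixels) from the nearest background pixel, with the
#' image border counted as background. A 40x40 solid square eroded by 15
#' therefore leaves its 10x10 core; eroding a 20x20 square by 15 leaves
#' nothing. Used to trim segmentation artifacts at the egg edge.
#'
#' @param mask logical array.
#' @param radius non-negative erosion distance in pixels; 0 is the identity.
#' @return logical array, a subset of \code{mask}.
#' @export
erode_mask <- function(mask, radius) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be an array")
  mask <- array(as.logical(mask), dim = d)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("radius must be a single non-negative number")
  if (radius == 0) return(mask)
  # pad one background layer so the border counts as boundary
  pd <- d + 2L
  padded <- array(FALSE, dim = pd)
  idx <- lapply(d, function(n) seq_len(n) + 1L)
  padded <- do.call(`[<-`, c(list(padded), idx, list(mask)))
  dist_bg <- distance_to_mask(!padded, squared = TRUE)
  core <- do.call(`[`, c(list(dist_bg), idx, list(drop = FALSE)))
  array(mask & core > radius^2, dim = d)
}
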