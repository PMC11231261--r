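#' Multi-channel image stack with physical spacing
#'
#' The common currency of all pipelines: a named list of intensity arrays
#' (one per channel, all sharing one shape), per-axis physical spacing in
#' micrometres, and free-form acquisition metadata. Axis order is fixed as
#' \code{(y, x)} for 2D and \code{(z, y, x)} for 3D; all physical distances
#' are computed from voxel centers.
#'
#' @param data named list of numeric arrays (or a single array, taken as one
#'   channel). 2D arrays are indexed \code{(y, x)}, 3D arrays \code{(z, y, x)}.
#' @param spacing numeric vector of physical voxel sizes in micrometres, one
#'   per axis, in axis order. May be \code{NULL} for assays that do not need
#'   physical units.
#' @param channels character vector of channel role labels (e.g.
#'   \code{"brightfield"}, \code{"md"}, \code{"atg8a"}, \code{"axoneme"}).
#'   Defaults to \code{names(data)}.
#' @param metadata free-form list (time point in h AEL, egg id, genotype,
#'   QC flags such as \code{cellularization_failed}).
#' @param dtype_max maximum representable raw intensity (default 65535, the
#'   16-bit camera class the fixed thresholds refer to).
#' @return an object of class \code{image_stack}.
#' @export
image_stack <- function(data, spacing = NULL, channels = NULL,
                        metadata = list(), dtype_max = 65535) {
  if (is.array(data) || is.matrix(data)) data <- list(data)
  if (!is.list(data) || length(data) == 0L)
    stop("`data` must be a non-empty list of arrays")
  if (is.null(channels)) channels <- names(data)
  if (is.null(channels) || any(!nzchar(channels)))
    stop("channel roles must be provided (named `data` or `channels`)")
  if (length(channels) != length(data))
    stop("channel count (", length(data), ") does not match role list (",
         length(channels), ")")
  names(data) <- channels
  dims <- lapply(data, function(a) dim(as.array(a)))
  if (any(vapply(dims, length, 1L) != length(dims[[1L]])) ||
      !all(vapply(dims, identical, TRUE, dims[[1L]])))
    stop("all channels must share the same shape")
  nd <- length(dims[[1L]])
  if (nd < 2L || nd > 3L) stop("images must be 2D (y, x) or 3D (z, y, x)")
  data <- lapply(data, function(a) {
    a <- as.array(a)
    storage.mode(a) <- "double"
    if (!all(is.finite(a))) stop("intensities must be finite")
    if (any(a < 0)) stop("intensities must be >= 0")
    a
  })
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != nd)
      stop("spacing must have one entry per axis (", nd, ")")
    if (!all(is.finite(spacing)) || any(spacing <= 0))
      stop("spacing must be strictly positive")
    names(spacing) <- if (nd == 2L) c("y", "x") else c("z", "y", "x")
  }
  structure(
    list(data = data, spacing = spacing, channels = channels,
         metadata = metadata,
         dtype_info = list(bits = if (dtype_max > 255) 16L else 8L,
                           max = dtype_max)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data[[1L]])
  cat("image_stack: ", paste(d, collapse = " x "),
      " (", if (length(d) == 2L) "y,x" else "z,y,x", ")\n", sep = "")
  cat("  channels: ", paste(x$channels, collapse = ", "), "\n", sep = "")
  if (!is.null(x$spacing))
    cat("  spacing (um): ", paste(signif(x$spacing, 4), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @rdname image_stack
#' @param x an \code{image_stack}
#' @export
is_image_stack <- function(x) inherits(x, "image_stack")

#' Extract one channel of an image stack
#' @param stack an \code{image_stack}
#' @param channel channel role label
#' @return the channel's intensity array
#' @export
get_channel <- function(stack, channel) {
  stopifnot(is_image_stack(stack))
  if (!channel %in% stack$channels)
    stop("channel '", channel, "' not present (have: ",
         paste(stack$channels, collapse = ", "), ")")
  stack$data[[channel]]
}

#' Physical voxel volume of a 3D stack, in cubic micrometres
#' @param stack an \code{image_stack} with 3D data and known spacing
#' @export
voxel_volume_um3 <- function(stack) {
  stopifnot(is_image_stack(stack))
  if (is.null(stack$spacing))
    stop("stack has no physical spacing")
  prod(stack$spacing)
}

require_spacing <- function(stack, assay) {
  if (is.null(stack$spacing))
    stop("assay '", assay, "' needs physical spacing, but none is ",
         "available from metadata or override")
  stack$spacing
}
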