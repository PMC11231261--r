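# Segmentation and morphology primitives shared by all pipelines: a
# trainable random-forest pixel classifier over a multiscale feature bank
# (the in-repo counterpart of the interactive pixel classifiers used on
# the original data), rolling-ball background subtraction, Euclidean
# erosion (see distance.R) and connected-component labeling with size
# filtering.

# ---- multiscale per-pixel features --------------------------------------

features_2d <- function(img, scales) {
  img <- as.matrix(img)
  feats <- list(raw = as.numeric(img))
  for (s in scales) {
    sm <- as.matrix(EBImage::gblur(img, sigma = s))
    gy <- sm; gx <- sm
    gy[] <- 0; gx[] <- 0
    n <- nrow(sm); m <- ncol(sm)
    gy[2:(n - 1), ] <- (sm[3:n, ] - sm[1:(n - 2), ]) / 2
    gx[, 2:(m - 1)] <- (sm[, 3:m] - sm[, 1:(m - 2)]) / 2
    lap <- sm
    lap[] <- 0
    lap[2:(n - 1), 2:(m - 1)] <-
      sm[1:(n - 2), 2:(m - 1)] + sm[3:n, 2:(m - 1)] +
      sm[2:(n - 1), 1:(m - 2)] + sm[2:(n - 1), 3:m] -
      4 * sm[2:(n - 1), 2:(m - 1)]
    feats[[paste0("gauss_", s)]] <- as.numeric(sm)
    feats[[paste0("gradmag_", s)]] <- as.numeric(sqrt(gy^2 + gx^2))
    feats[[paste0("laplace_", s)]] <- as.numeric(lap)
  }
  do.call(cbind, feats)
}

# 3D stacks get 2D features slice-by-slice (the classifier is used on
# tube/puncta cross-sections; axial context is not needed at these scales)
pixel_features <- function(img, scales) {
  d <- dim(img)
  if (length(d) == 2L) return(features_2d(img, scales))
  if (length(d) != 3L) stop("image must be 2D or 3D")
  out <- NULL
  for (z in seq_len(d[1])) {
    f <- features_2d(img[z, , ], scales)
    if (is.null(out)) out <- matrix(NA_real_, prod(d), ncol(f),
                                    dimnames = list(NULL, colnames(f)))
    # slice z occupies positions z, z + d1, z + 2*d1, ... in column-major order
    out[seq(z, prod(d), by = d[1]), ] <- f
  }
  out
}

#' Train a random-forest pixel classifier
#'
#' Supervised per-pixel classification over a fixed multiscale feature
#' bank (raw intensity; Gaussian smooth, gradient magnitude and Laplacian
#' at each scale). Annotations may be sparse: label value 0 means
#' unlabeled, values 1..C are classes. Training is deterministic given
#' \code{seed} (single-threaded forest, seeded subsampling).
#'
#' @param images list of 2D/3D intensity arrays (or a single array).
#' @param label_masks list of integer arrays of the same shapes; 0 =
#'   unlabeled.
#' @param scales Gaussian scales (px) of the feature bank; at least 3.
#' @param n_trees forest size.
#' @param max_px_per_class training pixels subsampled per class.
#' @param seed RNG seed.
#' @return a \code{pixel_classifier}.
#' @export
train_pixel_classifier <- function(images, label_masks, scales = c(1, 2, 4),
                                   n_trees = 100, max_px_per_class = 4000,
                                   seed = 1L) {
  if (is.array(images) || is.matrix(images)) images <- list(images)
  if (is.array(label_masks) || is.matrix(label_masks))
    label_masks <- list(label_masks)
  if (length(images) != length(label_masks))
    stop("need one label mask per image")
  if (length(scales) < 3L) stop("feature bank needs at least 3 scales")
  feats <- NULL; labs <- integer()
  for (i in seq_along(images)) {
    f <- pixel_features(images[[i]], scales)
    l <- as.integer(label_masks[[i]])
    keep <- which(l > 0L)
    feats <- rbind(feats, f[keep, , drop = FALSE])
    labs <- c(labs, l[keep])
  }
  classes <- sort(unique(labs))
  if (length(classes) < 2L)
    stop("annotations must cover at least 2 classes")
  with_seed(seed, {
    sel <- unlist(lapply(classes, function(cl) {
      i <- which(labs == cl)
      if (length(i) > max_px_per_class) sample(i, max_px_per_class) else i
    }))
    df <- data.frame(feats[sel, , drop = FALSE])
    df$.class <- factor(labs[sel], levels = classes)
    model <- ranger::ranger(
      dependent.variable.name = ".class", data = df,
      num.trees = n_trees, probability = TRUE,
      num.threads = 1, seed = seed)
  })
  structure(list(model = model, scales = scales, classes = classes,
                 n_features = ncol(feats), version = 1L),
            class = "pixel_classifier")
}

#' Predict class probabilities / a class mask for an image
#'
#' @param clf a \code{pixel_classifier}.
#' @param image 2D/3D intensity array compatible with the classifier's
#'   feature bank.
#' @param target_class class label whose argmax mask to return.
#' @return logical array: argmax-class mask of \code{target_class}.
#' @export
predict_mask <- function(clf, image, target_class) {
  stopifnot(inherits(clf, "pixel_classifier"))
  probs <- predict_class_prob(clf, image)
  if (!target_class %in% clf$classes)
    stop("unknown target class: ", target_class)
  arg <- clf$classes[max.col(probs, ties.method = "first")]
  array(arg == target_class, dim = dim(image))
}

#' @rdname predict_mask
#' @return \code{predict_class_prob}: matrix of per-pixel class
#'   probabilities (rows sum to 1), columns in \code{clf$classes} order.
#' @export
predict_class_prob <- function(clf, image) {
  f <- pixel_features(image, clf$scales)
  if (ncol(f) != clf$n_features)
    stop("image incompatible with classifier feature bank")
  pr <- stats::predict(clf$model, data.frame(f), num.threads = 1)$predictions
  pr[, match(clf$classes, as.integer(colnames(pr))), drop = FALSE]
}

#' Save / load a pixel classifier bundle
#' @param clf a \code{pixel_classifier}
#' @param path file path (single-file bundle, versioned)
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "pixel_classifier"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "pixel_classifier") || is.null(clf$version))
    stop("not a pixel_classifier bundle")
  clf
}

# ---- rolling-ball background subtraction --------------------------------

#' Rolling-ball background subtraction
#'
#' Estimates the background of a 2D image as its grayscale morphological
#' opening with a disc structuring element of the given radius and
#' subtracts it: flat backgrounds vanish, peaks narrower than the disc are
#' preserved, plateaus wider than the disc are removed. The original
#' assays describe this step as a rolling ball with a "sigma" of 35
#' pixels, conflating a Gaussian parameter with a ball radius; this
#' implementation takes it as the disc radius, with an optional
#' Gaussian pre-smooth (\code{presmooth_sigma}) covering the other
#' reading.
#'
#' @param image 2D numeric array.
#' @param radius_px disc radius in pixels (>= 1).
#' @param presmooth_sigma optional Gaussian sigma applied to the image
#'   before background estimation (0 = off, the default).
#' @return background-subtracted array, clipped at 0.
#' @export
rolling_ball_subtract <- function(image, radius_px, presmooth_sigma = 0) {
  img <- as.matrix(image)
  if (!is.numeric(radius_px) || length(radius_px) != 1L || radius_px < 1)
    stop("radius_px must be a positive integer")
  radius_px <- as.integer(radius_px)
  brush <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
  src <- if (presmooth_sigma > 0)
    as.matrix(EBImage::gblur(img, sigma = presmooth_sigma)) else img
  # EBImage grayscale morphology clips to [0, 1]; opening commutes with
  # positive scaling, so normalize by the image maximum and scale back
  scale <- max(src, 1)
  bg <- as.matrix(EBImage::opening(src / scale, brush)) * scale
  pmax(img - bg, 0)
}

# ---- connected components with size filtering ---------------------------

#' Label connected components and filter small ones
#'
#' 8-connectivity in 2D, 26-connectivity in 3D; component labels are
#' assigned in raster-scan order of each component's first pixel, then
#' re-densified to 1..n after filtering. \code{min_size} is in pixels
#' (\code{units = "px"}) or cubic micrometres (\code{units = "um3"},
#' requires \code{spacing}); components strictly below it are removed.
#' \code{min_size = NA} applies the scale-free default used for egg
#' segments: 5\% of the largest component's size.
#'
#' @param mask logical array (2D or 3D).
#' @param spacing per-axis physical spacing in um (needed for um3 units
#'   and physical volumes).
#' @param min_size minimum component size to keep (see above).
#' @param units \code{"px"} or \code{"um3"}.
#' @param intensities optional named list of intensity arrays; per-object
#'   mean and total are reported for each.
#' @return a \code{labeled_objects}: \code{labels} array plus a per-object
#'   \code{table} (label, n_voxels, volume_um3, centroids, intensity
#'   summaries).
#' @export
label_and_filter <- function(mask, spacing = NULL, min_size = 0,
                             units = c("px", "um3"), intensities = NULL) {
  units <- match.arg(units)
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% 2:3)) stop("mask must be 2D or 3D")
  lab <- .label_components_cpp(as.logical(mask), as.integer(d))
  lab <- array(lab, dim = d)
  nlab <- max(lab)
  voxel_vol <- if (!is.null(spacing)) prod(spacing) else NA_real_
  if (nlab == 0L)
    return(new_labeled_objects(lab, integer(), spacing, voxel_vol,
                               intensities))
  counts <- tabulate(lab[lab > 0L], nbins = nlab)
  size <- if (units == "um3") {
    if (is.null(spacing)) stop("um3 size filter needs spacing")
    counts * voxel_vol
  } else counts
  if (is.na(min_size)) min_size <- 0.05 * max(size)
  keep <- which(size >= min_size)
  remap <- integer(nlab)
  remap[keep] <- seq_along(keep) # keeps raster order
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  new_labeled_objects(lab, counts[keep], spacing, voxel_vol, intensities)
}

new_labeled_objects <- function(labels, counts, spacing, voxel_vol,
                                intensities = NULL) {
  n <- length(counts)
  tab <- data.frame(label = seq_len(n), n_voxels = as.integer(counts),
                    volume_um3 = counts * voxel_vol)
  if (n > 0L) {
    idx <- which(labels > 0L)
    l <- labels[idx]
    ai <- arrayInd(idx, dim(labels))
    for (a in seq_len(ncol(ai))) {
      nm <- paste0("centroid_", (if (ncol(ai) == 2L) c("y", "x")
                                 else c("z", "y", "x"))[a])
      tab[[nm]] <- as.numeric(tapply(ai[, a], l, mean))
    }
    if (!is.null(intensities)) for (ch in names(intensities)) {
      v <- intensities[[ch]][idx]
      tab[[paste0("mean_", ch)]] <- as.numeric(tapply(v, l, mean))
      tab[[paste0("total_", ch)]] <- as.numeric(tapply(v, l, sum))
    }
  }
  structure(list(labels = labels, table = tab, spacing = spacing,
                 voxel_volume_um3 = voxel_vol),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat("labeled_objects: ", nrow(x$table), " object(s)\n", sep = "")
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Number of objects in a labeled_objects
#' @param objects a \code{labeled_objects}
#' @export
n_objects <- function(objects) nrow(objects$table)
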