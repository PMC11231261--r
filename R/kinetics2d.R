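# MD-elimination kinetics: per-frame normalized MD intensity (NMI) and
# per-egg time courses over hourly frames, plus an exponential decay fit
# for parameter recovery. The NMI statistic is
#   (mean MD-positive - mean MD-negative) * (positive area / egg area)
# computed on the rolling-ball background-subtracted MD channel inside the
# eroded, size-filtered egg mask.

#' Quantify one two-channel frame of the MD-elimination assay
#'
#' Pipeline: the egg mask comes from the pixel classifier on the
#' brightfield channel, eroded by \code{cfg$erosion_px} (Euclidean, px) to
#' avoid edge artifacts, with small non-egg components dropped
#' (\code{cfg$min_component_area_px}; \code{NA} = 5\% of the largest
#' component). The MD channel is rolling-ball background subtracted; MD
#' positive pixels are those above \code{cfg$threshold_md} inside the egg.
#' NMI is the mean positive minus mean negative intensity times the
#' positive area fraction. Degenerate cases: no positive pixels gives
#' NMI = 0; an all-positive egg takes the negative mean as 0.
#'
#' @param bf 2D brightfield channel (raw scale).
#' @param md 2D MD fluorescence channel (raw scale).
#' @param clf \code{pixel_classifier} trained for egg vs background on the
#'   brightfield channel.
#' @param cfg an \code{\link{analysis_config}}.
#' @param egg_class classifier label of the egg class (default 2; class 1
#'   is background by the package's annotation convention).
#' @param roi_mask optional manual egg-mask override (logical array); when
#'   given, classification/erosion/filtering are skipped, mirroring the
#'   manual region-correction hook of the original macro.
#' @param time_h,egg_id,cellularization_failed metadata carried through.
#' @return a \code{frame_measurement} list: egg_area_px,
#'   md_positive_area_px, mean_pos, mean_neg, nmi, time_h, egg_id, qc.
#' @export
quantify_frame <- function(bf, md, clf, cfg, egg_class = 2L,
                           roi_mask = NULL, time_h = NA_real_,
                           egg_id = NA_character_,
                           cellularization_failed = FALSE) {
  if (!identical(dim(bf), dim(md)))
    stop("brightfield and MD channels must share a shape")
  if (is.null(roi_mask)) {
    mask <- predict_mask(clf, bf, egg_class)
    mask <- erode_mask(mask, cfg$erosion_px)
    obj <- label_and_filter(mask, min_size = cfg$min_component_area_px,
                            units = "px")
    egg <- obj$labels > 0L
  } else {
    egg <- array(as.logical(roi_mask), dim = dim(bf))
  }
  if (!any(egg)) stop("empty egg mask after erosion/filtering")
  md2 <- rolling_ball_subtract(md, cfg$rolling_ball_radius_px,
                               cfg$rolling_ball_presmooth_sigma)
  pos <- md2 > cfg$threshold_md & egg
  neg <- egg & !pos
  n_pos <- sum(pos); n_egg <- sum(egg)
  mean_pos <- if (n_pos > 0) mean(md2[pos]) else 0
  mean_neg <- if (any(neg)) mean(md2[neg]) else 0
  nmi <- if (n_pos == 0) 0 else (mean_pos - mean_neg) * (n_pos / n_egg)
  structure(list(egg_area_px = n_egg, md_positive_area_px = n_pos,
                 mean_pos = mean_pos, mean_neg = mean_neg, nmi = nmi,
                 time_h = time_h, egg_id = egg_id,
                 qc = list(cellularization_failed =
                             isTRUE(cellularization_failed))),
            class = "frame_measurement")
}

#' Quantify a whole synthetic or acquired time-lapse
#'
#' Convenience driver: applies \code{\link{quantify_frame}} to every frame
#' of a time-lapse (list of two-channel \code{image_stack}s with
#' \code{time_h} metadata, as produced by \code{\link{make_timelapse_2d}}).
#'
#' @param frames list of \code{image_stack}s (channels
#'   \code{brightfield}, \code{md}).
#' @inheritParams quantify_frame
#' @return list of \code{frame_measurement}s.
#' @export
quantify_timelapse <- function(frames, clf, cfg, egg_class = 2L,
                               cellularization_failed = FALSE) {
  lapply(frames, function(fr) {
    quantify_frame(get_channel(fr, "brightfield"), get_channel(fr, "md"),
                   clf, cfg, egg_class = egg_class,
                   time_h = fr$metadata$time_h,
                   egg_id = fr$metadata$egg_id,
                   cellularization_failed = cellularization_failed)
  })
}

#' Assemble per-egg NMI time courses
#'
#' Groups frame measurements by egg and returns an eggs x time matrix of
#' NMI values. Eggs flagged as having failed cellularization are excluded
#' (their count is reported), mirroring the original exclusion of eggs
#' that failed to develop. Every retained egg must have a frame at each
#' configured time point.
#'
#' @param measurements list of \code{frame_measurement}s (possibly several
#'   eggs interleaved).
#' @param times time points in h AEL (default: sorted unique times seen).
#' @return list with \code{nmi} (matrix, rownames egg ids, colnames
#'   times), \code{times}, and \code{n_excluded}.
#' @export
build_timecourse <- function(measurements, times = NULL) {
  df <- data.frame(
    egg_id = vapply(measurements, function(m) m$egg_id, ""),
    time_h = vapply(measurements, function(m) m$time_h, 0),
    nmi = vapply(measurements, function(m) m$nmi, 0),
    failed = vapply(measurements, function(m)
      isTRUE(m$qc$cellularization_failed), TRUE))
  if (is.null(times)) times <- sort(unique(df$time_h))
  failed_eggs <- unique(df$egg_id[df$failed])
  df <- df[!df$egg_id %in% failed_eggs, , drop = FALSE]
  eggs <- unique(df$egg_id)
  mat <- matrix(NA_real_, length(eggs), length(times),
                dimnames = list(eggs, as.character(times)))
  for (i in seq_len(nrow(df))) {
    j <- match(df$time_h[i], times)
    if (is.na(j)) next
    mat[df$egg_id[i], j] <- df$nmi[i]
  }
  if (anyNA(mat)) {
    bad <- rownames(mat)[apply(mat, 1, anyNA)]
    stop("missing time point(s) for egg(s): ", paste(bad, collapse = ", "))
  }
  list(nmi = mat, times = times, n_excluded = length(failed_eggs))
}

#' Fit an exponential decay to an NMI time course
#'
#' Least-squares fit of \code{I0 * exp(-k * t)} (Levenberg-Marquardt,
#' started from a log-linear regression on the positive values). A
#' constant series gives k = 0 exactly; an all-zero series is an error.
#'
#' @param nmi non-negative NMI values.
#' @param times matching time points (hours); at least 3.
#' @return list(I0, k, k_se, fitted).
#' @export
fit_decay <- function(nmi, times) {
  y <- as.numeric(nmi); t <- as.numeric(times)
  if (length(y) != length(t) || length(y) < 3L)
    stop("need >= 3 matched time points")
  if (any(y < 0)) stop("NMI values must be >= 0")
  if (all(y == 0)) stop("all-zero series has no decay scale")
  if (stats::sd(y) == 0)
    return(list(I0 = y[1], k = 0, k_se = 0, fitted = y))
  pos <- y > 0
  start <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
    list(I0 = exp(cf[[1]]), k = max(-cf[[2]], 1e-6))
  } else list(I0 = max(y), k = 1)
  fit <- minpack.lm::nlsLM(y ~ I0 * exp(-k * t),
                           start = start,
                           lower = c(I0 = 0, k = 0),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  list(I0 = unname(cf["I0"]), k = unname(cf["k"]), k_se = unname(se),
       fitted = unname(stats::fitted(fit)))
}

#' Sparse class annotations from a ground-truth mask
#'
#' Samples a few annotated pixels per class (background = 1, foreground =
#' 2) from a known mask, emulating the sparse scribbles an interactive
#' classifier is trained on. Used to train classifiers on synthetic
#' scenes.
#'
#' @param truth_mask logical array.
#' @param n_per_class pixels sampled per class.
#' @param seed RNG seed.
#' @return integer array: 0 unlabeled, 1 background, 2 foreground.
#' @export
sparse_labels_from_mask <- function(truth_mask, n_per_class = 500,
                                    seed = 1L) {
  with_seed(seed, {
    lab <- array(0L, dim = dim(truth_mask))
    fg <- which(truth_mask); bg <- which(!truth_mask)
    lab[sample(bg, min(n_per_class, length(bg)))] <- 1L
    lab[sample(fg, min(n_per_class, length(fg)))] <- 2L
    lab
  })
}
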