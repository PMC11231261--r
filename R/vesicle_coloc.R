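# Vesicle-level two-channel colocalization with envelope-based
# background: per-vesicle normalized secondary means and positivity
# calls, the positive fraction, and pooled Pearson / Manders coefficients
# over vesicle voxels across eggs.

bbox_of <- function(idx, d) {
  ai <- arrayInd(idx, d)
  lapply(seq_along(d), function(a) range(ai[, a]))
}

#' Measure vesicles: envelope background and normalized secondary signal
#'
#' For each segmented vesicle (primary-channel object; callers apply the
#' 15 um^3 volume floor via \code{\link{label_and_filter}}), the secondary
#' channel mean is measured inside the vesicle; a guard envelope of
#' \code{cfg$guard_um} (published: 200 nm) separates the vesicle from its
#' background envelope of \code{cfg$background_um} (published "300 um",
#' read as 300 nm), whose secondary mean is the vesicle's local
#' background. Voxels of other vesicles never count as background. The
#' egg-level background is the unweighted mean of the per-vesicle
#' envelope means; the normalized secondary mean is the vesicle mean
#' minus the egg background. A vesicle whose secondary mean is below its
#' own envelope mean is omitted; otherwise it is positive iff its
#' normalized mean exceeds 0.
#'
#' @param objects \code{labeled_objects} of the primary channel (volume
#'   filter already applied).
#' @param secondary secondary-channel intensity array, same grid.
#' @param spacing physical spacing (um).
#' @param cfg an \code{\link{analysis_config}} (guard_um, background_um).
#' @return a \code{vesicle_records} data.frame: label, volume_um3,
#'   mean_secondary, envelope_mean, egg_background,
#'   normalized_secondary, status in {positive, negative, omitted}.
#' @export
measure_vesicles <- function(objects, secondary, spacing, cfg) {
  stopifnot(inherits(objects, "labeled_objects"))
  n <- n_objects(objects)
  if (n == 0L) stop("zero vesicles after filtering")
  d <- dim(secondary)
  if (!identical(dim(objects$labels), d))
    stop("objects and secondary channel are on different grids")
  g <- cfg$guard_um; b <- cfg$background_um
  pad <- ceiling((g + b) / spacing) + 1L
  lab <- objects$labels
  mean_sec <- env_mean <- numeric(n)
  for (i in seq_len(n)) {
    idx <- which(lab == i)
    bb <- bbox_of(idx, d)
    rng <- lapply(seq_along(d), function(a)
      max(1L, bb[[a]][1] - pad[a]):min(d[a], bb[[a]][2] + pad[a]))
    lab_c <- do.call(`[`, c(list(lab), rng, list(drop = FALSE)))
    sec_c <- do.call(`[`, c(list(secondary), rng, list(drop = FALSE)))
    own <- lab_c == i
    dist_c <- distance_to_mask(own, spacing)
    shell <- dist_c > g & dist_c <= g + b & lab_c == 0L
    if (!any(shell)) stop("empty background envelope for vesicle ", i)
    mean_sec[i] <- mean(sec_c[own])
    env_mean[i] <- mean(sec_c[shell])
  }
  egg_bg <- mean(env_mean)
  normalized <- mean_sec - egg_bg
  status <- ifelse(mean_sec < env_mean, "omitted",
                   ifelse(normalized > 0, "positive", "negative"))
  structure(data.frame(label = seq_len(n),
                       volume_um3 = objects$table$volume_um3,
                       mean_secondary = mean_sec,
                       envelope_mean = env_mean,
                       egg_background = egg_bg,
                       normalized_secondary = normalized,
                       status = status),
            class = c("vesicle_records", "data.frame"))
}

#' Positive fraction over non-omitted vesicles
#'
#' @param records a \code{vesicle_records} (or several rbind-ed, pooled
#'   across eggs).
#' @return list(fraction, n_positive, n_negative, n_omitted, n_total).
#' @export
classify_positive <- function(records) {
  st <- records$status
  n_pos <- sum(st == "positive"); n_neg <- sum(st == "negative")
  list(fraction = if (n_pos + n_neg > 0) n_pos / (n_pos + n_neg)
                  else NA_real_,
       n_positive = n_pos, n_negative = n_neg,
       n_omitted = sum(st == "omitted"), n_total = length(st))
}

#' Collect voxel intensities inside non-omitted vesicles
#'
#' Builds the pooled voxel table behind the Pearson and Manders
#' coefficients: primary and secondary intensities of every voxel inside
#' a non-omitted vesicle, with the egg background already subtracted from
#' the secondary channel for the positivity indicator.
#'
#' @param objects \code{labeled_objects} of the primary channel.
#' @param primary,secondary intensity arrays.
#' @param records matching \code{vesicle_records}.
#' @return data.frame(label, primary, secondary, secondary_positive).
#' @export
collect_vesicle_voxels <- function(objects, primary, secondary, records) {
  keep <- records$label[records$status != "omitted"]
  idx <- which(objects$labels %in% keep)
  data.frame(label = objects$labels[idx],
             primary = primary[idx],
             secondary = secondary[idx],
             secondary_positive =
               secondary[idx] - records$egg_background[1] > 0)
}

#' Pooled Pearson correlation over vesicle voxels
#'
#' One coefficient over all voxels inside non-omitted vesicle masks,
#' pooled across eggs ("pooled PCC").
#'
#' @param voxels one voxel table from
#'   \code{\link{collect_vesicle_voxels}}, or a list of them (one per
#'   egg).
#' @return Pearson correlation coefficient.
#' @export
pooled_pearson <- function(voxels) {
  if (is.data.frame(voxels)) voxels <- list(voxels)
  df <- do.call(rbind, voxels)
  if (nrow(df) < 2L) stop("need >= 2 pooled voxels")
  if (stats::sd(df$primary) == 0 || stats::sd(df$secondary) == 0)
    stop("zero variance in a channel")
  stats::cor(df$primary, df$secondary)
}

#' Pooled Manders coefficient M1 over vesicle voxels
#'
#' Fraction of the primary channel's total intensity residing in voxels
#' where the background-subtracted secondary channel is positive, pooled
#' across eggs. No Costes thresholding: the envelope-based egg background
#' is the positivity reference.
#'
#' @inheritParams pooled_pearson
#' @return M1 in [0, 1].
#' @export
manders_m1 <- function(voxels) {
  if (is.data.frame(voxels)) voxels <- list(voxels)
  df <- do.call(rbind, voxels)
  tot <- sum(df$primary)
  if (tot <= 0) stop("zero total primary signal")
  sum(df$primary[df$secondary_positive]) / tot
}
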