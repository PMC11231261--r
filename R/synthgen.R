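# Synthetic scenes with ground truth. Every downstream pipeline is tested
# against these: a 2D egg + decaying flagellar MD time-lapse, a 3D curved
# axoneme with puncta and a coaxial membrane tube, and a 3D field of
# two-channel vesicles with known positive fraction. All scenes are
# rendered deterministically from (params, seed) and come with a
# TruthManifest sufficient to re-render them bit-identically.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# cubic-spline interpolation through control points, uniform dense samples;
# pts is an n x ndim matrix, returns n_samples x ndim
sample_curve <- function(pts, n_samples = 600) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L) stop("curve needs at least 2 control points")
  t0 <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  if (t0[length(t0)] == 0) stop("degenerate curve (zero length)")
  tt <- seq(0, t0[length(t0)], length.out = n_samples)
  vapply(seq_len(ncol(pts)),
         function(j) stats::spline(t0, pts[, j], xout = tt)$y,
         numeric(n_samples))
}

# mark the voxel/pixel nearest to each physical-coordinate sample
rasterize_samples <- function(samples_um, shape, spacing) {
  # voxel centers sit at (i - 0.5) * h, so index i = round(x / h + 0.5)
  idx <- round(sweep(samples_um, 2, spacing, "/") + 0.5)
  # pmax/pmin with the matrix first so the dim attribute survives
  idx <- pmin(pmax(idx, 1),
              matrix(rep(shape, each = nrow(idx)), ncol = length(shape)))
  mask <- array(FALSE, dim = shape)
  mask[unique(idx, MARGIN = 1)] <- TRUE
  mask
}

# tube mask: voxels whose center lies within radius_um of the sampled curve
tube_mask <- function(samples_um, shape, spacing, radius_um) {
  seed_mask <- rasterize_samples(samples_um, shape, spacing)
  d <- distance_to_mask(seed_mask, spacing)
  d <= radius_um
}

# exact min distance from physical points to the dense curve polyline
dist_to_curve_um <- function(points_um, samples_um) {
  apply(points_um, 1, function(p) {
    sqrt(min(colSums((t(samples_um) - p)^2)))
  })
}

#' Parameters of the synthetic 2D egg time-lapse
#'
#' Emulates the live-imaging MD-elimination assay: an elliptical egg on a
#' brightfield-like channel, and a long curved flagellum whose MD channel
#' decays exponentially over hourly frames. Intensities are on the raw
#' 16-bit camera scale, so the default initial MD amplitude (30000 a.u.)
#' sits well above the fixed 1200 detection threshold through 3 h at the
#' control decay rate of 1 per hour.
#'
#' @param height,width canvas size (px).
#' @param egg_center,egg_semi_axes ellipse geometry, (y, x) in px.
#' @param flagellum_control_points n x 2 matrix (y, x) of spline control
#'   points; must lie inside the egg with margin for the tube width.
#' @param md_width_px flagellar tube width.
#' @param I0 initial MD amplitude above background (a.u.).
#' @param k decay rate per hour (>= 0).
#' @param background MD-channel background level (a.u.).
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param frames acquisition times in h AEL.
#' @param bf_interior,bf_exterior,bf_texture_sd brightfield egg interior /
#'   exterior levels and interior texture amplitude (a.u.).
#' @param seed RNG seed.
#' @return a \code{scene2d_params} list.
#' @export
scene2d_params <- function(height = 160, width = 220,
                           egg_center = c(80, 110),
                           egg_semi_axes = c(58, 92),
                           flagellum_control_points = NULL,
                           md_width_px = 5,
                           I0 = 30000, k = 1.0, background = 100,
                           noise_sd = 20, frames = c(0, 1, 2, 3),
                           bf_interior = 10000, bf_exterior = 2000,
                           bf_texture_sd = 1200, seed = 1L) {
  if (is.null(flagellum_control_points)) {
    th <- seq(-3.6, 0.8, length.out = 8)
    flagellum_control_points <- cbind(
      egg_center[1] + 0.55 * egg_semi_axes[1] * sin(th),
      egg_center[2] + 0.55 * egg_semi_axes[2] * cos(th))
  }
  p <- list(height = height, width = width, egg_center = egg_center,
            egg_semi_axes = egg_semi_axes,
            flagellum_control_points = as.matrix(flagellum_control_points),
            md_width_px = md_width_px, I0 = I0, k = k,
            background = background, noise_sd = noise_sd, frames = frames,
            bf_interior = bf_interior, bf_exterior = bf_exterior,
            bf_texture_sd = bf_texture_sd, seed = as.integer(seed))
  if (p$I0 <= p$background) stop("I0 must exceed background")
  if (p$k < 0) stop("decay rate k must be >= 0")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  # curve (including tube width) must stay inside the egg
  s <- sample_curve(p$flagellum_control_points, 400)
  rel <- sweep(s, 2, egg_center)
  margin <- (md_width_px / 2 + 2) / min(egg_semi_axes)
  if (any(rowSums(sweep(rel, 2, egg_semi_axes, "/")^2) > (1 - margin)^2))
    stop("flagellum curve leaves the egg interior")
  structure(p, class = "scene2d_params")
}

egg_mask_2d <- function(p) {
  yy <- matrix(seq_len(p$height), p$height, p$width)
  xx <- matrix(seq_len(p$width), p$height, p$width, byrow = TRUE)
  ((yy - p$egg_center[1]) / p$egg_semi_axes[1])^2 +
    ((xx - p$egg_center[2]) / p$egg_semi_axes[2])^2 <= 1
}

#' Generate a synthetic 2D MD-elimination time-lapse
#'
#' The MD channel along the flagellar tube is
#' \code{background + I0 * exp(-k * t)} plus Gaussian noise; off the tube
#' it is \code{background} plus noise. The brightfield channel shows a
#' textured egg interior against a darker exterior (no flagellum).
#'
#' @param params a \code{\link{scene2d_params}}.
#' @return list with \code{frames} (list of two-channel \code{image_stack},
#'   channels \code{brightfield}, \code{md}, with \code{time_h} metadata)
#'   and \code{manifest} (ground truth; re-rendering from
#'   \code{manifest$params} reproduces the scene bit-identically).
#' @export
make_timelapse_2d <- function(params) {
  stopifnot(inherits(params, "scene2d_params"))
  p <- params
  with_seed(p$seed, {
    egg <- egg_mask_2d(p)
    s <- sample_curve(p$flagellum_control_points, 1200)
    fl_seed <- rasterize_samples(s, c(p$height, p$width), c(1, 1))
    flag <- distance_to_mask(fl_seed) <= p$md_width_px / 2

    texture <- matrix(stats::rnorm(p$height * p$width, 0, p$bf_texture_sd),
                      p$height, p$width)
    texture <- as.matrix(EBImage::gblur(texture, sigma = 3))
    bf_base <- ifelse(egg, p$bf_interior + texture, p$bf_exterior)

    frames <- lapply(seq_along(p$frames), function(i) {
      t <- p$frames[i]
      amp <- p$I0 * exp(-p$k * t)
      md <- matrix(p$background, p$height, p$width)
      md[flag] <- md[flag] + amp
      if (p$noise_sd > 0) {
        md <- md + stats::rnorm(length(md), 0, p$noise_sd)
        bf <- bf_base + stats::rnorm(length(bf_base), 0, p$noise_sd)
      } else bf <- bf_base
      image_stack(list(brightfield = pmin(pmax(bf, 0), 65535),
                       md = pmin(pmax(md, 0), 65535)),
                  metadata = list(time_h = t, egg_id = sprintf("egg_s%d",
                                                              p$seed)))
    })
    manifest <- structure(
      list(kind = "timelapse_2d", params = p, seed = p$seed,
           true_md_amplitude = p$I0 * exp(-p$k * p$frames),
           true_md_mean = p$background + p$I0 * exp(-p$k * p$frames),
           frames_h = p$frames,
           flagellum_area_px = sum(flag), egg_area_px = sum(egg)),
      class = "truth_manifest")
    list(frames = frames, manifest = manifest)
  })
}

#' Parameters of the synthetic 3D scenes
#'
#' One parameter object covers both 3D assays. The axoneme scene renders a
#' curved axoneme tube, punctate objects whose radial density follows
#' \code{radial_weight(d)} out to \code{shell_count * shell_width_um}, and
#' a membrane tube coaxial with the axoneme filled to
#' \code{membrane_fill_fraction}. The vesicle scene renders spherical
#' two-channel vesicles with a known positive fraction.
#'
#' @param shape volume shape \code{c(z, y, x)} in voxels.
#' @param spacing voxel size \code{c(z, y, x)} in micrometres.
#' @param axoneme_control_points n x 3 matrix (z, y, x) in micrometres;
#'   default a gentle curve along x through the volume center.
#' @param axoneme_radius_um axoneme tube radius.
#' @param membrane_outer_um outer radius of the coaxial membrane tube
#'   (inner radius = axoneme radius).
#' @param membrane_fill_fraction fraction of membrane-tube voxels carrying
#'   signal (1 = intact membrane, 0 = fully cleared).
#' @param n_puncta,punctum_radius_um punctate objects (Atg8a-like).
#' @param radial_weight function of center distance d (um) giving relative
#'   placement density per unit volume; default uniform.
#' @param puncta_centers optional n x 3 matrix (um) bypassing random
#'   placement.
#' @param max_distance_um outer placement radius for puncta (default
#'   shell_count * shell_width of the published assay, 10 um).
#' @param n_vesicles,vesicle_radius_um_range,positive_fraction vesicle
#'   scene: count, radius range (um), true secondary-positive fraction.
#' @param intensity,secondary_offset,background,noise_sd intensity model
#'   (a.u., raw 16-bit scale).
#' @param negative_secondary_offset weak nonspecific secondary level
#'   carried by negative vesicles (a.u.); keeps true negatives above
#'   their own envelope (so they are retained, not omitted) while their
#'   normalized mean stays below the positives-elevated egg background.
#' @param intensity_jitter per-vesicle brightness spread (fraction);
#'   positives couple their secondary load to the primary gain, so the
#'   pooled voxel correlation is positive by construction.
#' @param psf_sigma_um isotropic Gaussian PSF sigma (um); \code{NA} (the
#'   default) means the assay default: no blur for the axoneme scene, 0.3
#'   um for the vesicle scene, whose envelope-background logic relies on
#'   optical spill-over just as the real assay does.
#' @param seed RNG seed.
#' @return a \code{scene3d_params} list.
#' @export
scene3d_params <- function(shape = c(48, 128, 128),
                           spacing = c(0.5, 0.25, 0.25),
                           axoneme_control_points = NULL,
                           axoneme_radius_um = 0.3,
                           membrane_outer_um = 0.6,
                           membrane_fill_fraction = 1.0,
                           n_puncta = 300, punctum_radius_um = 0.25,
                           radial_weight = NULL,
                           puncta_centers = NULL,
                           max_distance_um = 10,
                           n_vesicles = 200,
                           vesicle_radius_um_range = c(1.6, 2.1),
                           positive_fraction = 0.85,
                           intensity = 3000, secondary_offset = 1500,
                           negative_secondary_offset = 40,
                           intensity_jitter = 0.2,
                           psf_sigma_um = NA,
                           background = 100, noise_sd = 20, seed = 1L) {
  ext <- shape * spacing
  if (is.null(axoneme_control_points)) {
    xs <- seq(0.08, 0.92, length.out = 6) * ext[3]
    axoneme_control_points <- cbind(
      ext[1] / 2 + 0.06 * ext[1] * sin(seq(0, pi, length.out = 6)),
      ext[2] / 2 + 0.10 * ext[2] * sin(seq(0, 2 * pi, length.out = 6)),
      xs)
  }
  if (is.null(radial_weight)) radial_weight <- function(d) rep(1, length(d))
  p <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
            axoneme_control_points = as.matrix(axoneme_control_points),
            axoneme_radius_um = axoneme_radius_um,
            membrane_outer_um = membrane_outer_um,
            membrane_fill_fraction = membrane_fill_fraction,
            n_puncta = n_puncta, punctum_radius_um = punctum_radius_um,
            radial_weight = radial_weight,
            puncta_centers = if (is.null(puncta_centers)) NULL
                             else as.matrix(puncta_centers),
            max_distance_um = max_distance_um,
            n_vesicles = n_vesicles,
            vesicle_radius_um_range = vesicle_radius_um_range,
            positive_fraction = positive_fraction,
            intensity = intensity, secondary_offset = secondary_offset,
            negative_secondary_offset = negative_secondary_offset,
            intensity_jitter = intensity_jitter,
            psf_sigma_um = psf_sigma_um,
            background = background, noise_sd = noise_sd,
            seed = as.integer(seed))
  if (any(p$shape < 8)) stop("degenerate volume shape")
  if (any(p$spacing <= 0)) stop("spacing must be positive")
  if (p$positive_fraction < 0 || p$positive_fraction > 1)
    stop("positive_fraction must lie in [0, 1]")
  if (p$membrane_fill_fraction < 0 || p$membrane_fill_fraction > 1)
    stop("membrane_fill_fraction must lie in [0, 1]")
  if (p$membrane_outer_um <= p$axoneme_radius_um)
    stop("membrane tube must lie outside the axoneme")
  inside <- sweep(p$axoneme_control_points, 2, ext, "/")
  if (any(inside < 0.02) || any(inside > 0.98))
    stop("axoneme curve leaves the volume")
  structure(p, class = "scene3d_params")
}

# voxel-center physical coordinates along each axis
axis_centers <- function(shape, spacing)
  lapply(seq_along(shape), function(a) (seq_len(shape[a]) - 0.5) * spacing[a])

add_noise <- function(arr, sd) {
  if (sd > 0) arr <- arr + stats::rnorm(length(arr), 0, sd)
  array(pmin(pmax(arr, 0), 65535), dim = dim(arr))
}

# separable Gaussian PSF (shift-and-sum per axis, replicated edges)
blur_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox < 0.05) return(arr)
  r <- ceiling(3 * sigma_vox)
  w <- stats::dnorm(-r:r, 0, sigma_vox)
  w <- w / sum(w)
  d <- dim(arr); n <- d[axis]
  out <- array(0, d)
  for (j in -r:r) {
    idx <- pmin(pmax(seq_len(n) + j, 1L), n)
    ind <- rep(list(quote(expr = )), length(d))
    ind[[axis]] <- idx
    out <- out + w[j + r + 1] *
      do.call(`[`, c(list(arr), ind, list(drop = FALSE)))
  }
  out
}

gauss_blur_3d <- function(arr, sigma_um, spacing) {
  if (is.na(sigma_um) || sigma_um <= 0) return(arr)
  for (a in seq_along(spacing))
    arr <- blur_axis(arr, sigma_um / spacing[a], a)
  arr
}

#' Generate a synthetic 3D axoneme scene (puncta + membrane)
#'
#' Channels: \code{axoneme} (tube), \code{puncta} (spheres placed with
#' radial density \code{radial_weight(d)} around the axoneme) and
#' \code{membrane} (coaxial tube filled to \code{membrane_fill_fraction}).
#' The manifest records each punctum's exact center distance to the
#' axoneme curve and its 1-um shell index, plus the ground-truth
#' membrane/axoneme volume ratio.
#'
#' @param params a \code{\link{scene3d_params}}.
#' @return list(\code{stack}, \code{manifest}).
#' @export
make_axoneme_volume_3d <- function(params) {
  stopifnot(inherits(params, "scene3d_params"))
  p <- params
  with_seed(p$seed, {
    shape <- p$shape; spacing <- p$spacing
    curve <- sample_curve(p$axoneme_control_points, 1500)
    axo_seed <- rasterize_samples(curve, shape, spacing)
    d_curve <- distance_to_mask(axo_seed, spacing)
    axoneme <- d_curve <= p$axoneme_radius_um
    membrane_tube <- d_curve > p$axoneme_radius_um &
      d_curve <= p$membrane_outer_um
    keep <- stats::runif(sum(membrane_tube)) < p$membrane_fill_fraction
    membrane <- membrane_tube
    membrane[membrane_tube] <- keep

    # distances the shell assay measures are to the axoneme OBJECT (mask),
    # not its center line; placement and manifest truth use the same field
    d_mask <- distance_to_mask(axoneme, spacing)

    # puncta centers: voxel-center candidates weighted by radial_weight(d)
    if (is.null(p$puncta_centers)) {
      cand <- which(d_mask > p$punctum_radius_um &
                    d_mask <= p$max_distance_um)
      if (p$n_puncta > 0 && length(cand) < p$n_puncta)
        stop("not enough room for requested puncta")
      centers_idx <- if (p$n_puncta > 0)
        sample(cand, p$n_puncta, prob = p$radial_weight(d_mask[cand]))
      else integer()
      ai <- arrayInd(centers_idx, shape)
      centers <- sweep(ai - 0.5, 2, spacing, "*")
    } else {
      centers <- p$puncta_centers
      ci <- round(sweep(centers, 2, spacing, "/") + 0.5)
      ci <- pmin(pmax(ci, 1),
                 matrix(rep(shape, each = nrow(ci)), ncol = 3))
      centers_idx <- ci[, 1] + shape[1] * ((ci[, 2] - 1) +
                                             shape[2] * (ci[, 3] - 1))
    }
    n_pu <- nrow(centers)
    puncta <- array(FALSE, dim = shape)
    ax <- axis_centers(shape, spacing)
    pu_vol <- numeric(n_pu)
    if (n_pu > 0) for (i in seq_len(n_pu)) {
      sph <- sphere_voxels(centers[i, ], p$punctum_radius_um, shape, spacing, ax)
      puncta[sph] <- TRUE
      pu_vol[i] <- length(sph) * prod(spacing)
    }
    d_center <- if (n_pu > 0) d_mask[centers_idx] else numeric()
    # shell index by center distance, published binning ((k-1)w, kw], 1 um
    shell_idx <- ceiling(pmax(d_center, 1e-9))

    psf <- if (is.na(p$psf_sigma_um)) 0 else p$psf_sigma_um
    base <- function(mask) {
      a <- array(p$background, dim = shape)
      a[mask] <- a[mask] + p$intensity
      gauss_blur_3d(a, psf, spacing)
    }
    stack <- image_stack(
      list(axoneme = add_noise(base(axoneme), p$noise_sd),
           puncta = add_noise(base(puncta), p$noise_sd),
           membrane = add_noise(base(membrane), p$noise_sd)),
      spacing = spacing,
      metadata = list(egg_id = sprintf("scene3d_s%d", p$seed)))
    truth_ratio <- if (sum(axoneme) > 0) sum(membrane) / sum(axoneme) else NA
    manifest <- structure(
      list(kind = "axoneme_3d", params = p, seed = p$seed,
           puncta_centers_um = centers,
           puncta_center_distance_um = d_center,
           puncta_shell_index = shell_idx,
           puncta_volume_um3 = pu_vol,
           axoneme_voxels = sum(axoneme),
           membrane_voxels = sum(membrane),
           membrane_axoneme_ratio = truth_ratio,
           masks = list(axoneme = axoneme, puncta = puncta,
                        membrane = membrane)),
      class = "truth_manifest")
    list(stack = stack, manifest = manifest)
  })
}

# linear indices of voxels whose centers lie within radius of center_um
sphere_voxels <- function(center_um, radius_um, shape, spacing, ax) {
  rng <- lapply(1:3, function(a) {
    i <- which(abs(ax[[a]] - center_um[a]) <= radius_um + spacing[a])
    if (length(i) == 0L) integer() else i
  })
  if (any(vapply(rng, length, 1L) == 0L)) return(integer())
  g <- expand.grid(z = rng[[1]], y = rng[[2]], x = rng[[3]])
  dz <- ax[[1]][g$z] - center_um[1]
  dy <- ax[[2]][g$y] - center_um[2]
  dx <- ax[[3]][g$x] - center_um[3]
  keep <- dz^2 + dy^2 + dx^2 <= radius_um^2
  g <- g[keep, , drop = FALSE]
  g$z + shape[1] * ((g$y - 1) + shape[2] * (g$x - 1))
}

#' Generate a synthetic 3D two-channel vesicle scene
#'
#' Spherical vesicles are placed without overlap (including their guard +
#' background envelopes). The primary channel marks every vesicle; the
#' secondary channel is elevated only inside true positives, drawn
#' Bernoulli(\code{positive_fraction}) and recorded exactly in the
#' manifest.
#'
#' @param params a \code{\link{scene3d_params}}; vesicle fields apply.
#' @param envelope_um clearance added around each vesicle when enforcing
#'   non-overlap (default 0.2 + 0.3 um guard + background, plus margin).
#' @return list(\code{stack}, \code{manifest}).
#' @export
make_vesicle_volume_3d <- function(params, envelope_um = 0.6) {
  stopifnot(inherits(params, "scene3d_params"))
  p <- params
  with_seed(p$seed, {
    shape <- p$shape; spacing <- p$spacing
    ext <- shape * spacing
    n <- p$n_vesicles
    rr <- stats::runif(n, p$vesicle_radius_um_range[1],
                       p$vesicle_radius_um_range[2])
    centers <- matrix(NA_real_, n, 3)
    placed <- 0L
    tries <- 0L
    max_tries <- 2000L * n
    while (placed < n && tries < max_tries) {
      tries <- tries + 1L
      i <- placed + 1L
      margin <- rr[i] + envelope_um + 0.2
      cand <- stats::runif(3, margin, ext - margin)
      ok <- TRUE
      if (placed > 0L) {
        sep <- sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                  2, cand)^2))
        ok <- all(sep > rr[i] + rr[seq_len(placed)] + 2 * envelope_um + 0.1)
      }
      if (ok) { centers[i, ] <- cand; placed <- i }
    }
    if (placed < n)
      stop("cannot place ", n, " non-overlapping vesicles in this volume")
    positive <- stats::runif(n) < p$positive_fraction
    # per-vesicle brightness; positives couple the secondary load to it
    gain <- stats::runif(n, 1 - p$intensity_jitter, 1 + p$intensity_jitter)
    sec_level <- ifelse(positive, p$secondary_offset * gain,
                        p$negative_secondary_offset)

    primary <- array(p$background, dim = shape)
    secondary <- array(p$background, dim = shape)
    ax <- axis_centers(shape, spacing)
    for (i in seq_len(n)) {
      sph <- sphere_voxels(centers[i, ], rr[i], shape, spacing, ax)
      primary[sph] <- p$background + p$intensity * gain[i]
      secondary[sph] <- p$background + sec_level[i]
    }
    psf <- if (is.na(p$psf_sigma_um)) 0.3 else p$psf_sigma_um
    primary <- gauss_blur_3d(primary, psf, spacing)
    secondary <- gauss_blur_3d(secondary, psf, spacing)
    stack <- image_stack(
      list(vesicle_primary = add_noise(primary, p$noise_sd),
           vesicle_secondary = add_noise(secondary, p$noise_sd)),
      spacing = spacing,
      metadata = list(egg_id = sprintf("vesicles_s%d", p$seed)))
    manifest <- structure(
      list(kind = "vesicles_3d", params = p, seed = p$seed,
           centers_um = centers, radii_um = rr,
           primary_gain = gain, secondary_level = sec_level,
           true_positive = positive,
           true_positive_count = sum(positive),
           true_positive_fraction = mean(positive)),
      class = "truth_manifest")
    list(stack = stack, manifest = manifest)
  })
}

#' Re-render a scene from its truth manifest
#'
#' A manifest stores the full parameter set including the seed, so
#' re-rendering reproduces the original scene bit-identically.
#'
#' @param manifest a \code{truth_manifest}.
#' @export
render_from_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "truth_manifest"))
  switch(manifest$kind,
         timelapse_2d = make_timelapse_2d(manifest$params),
         axoneme_3d = make_axoneme_volume_3d(manifest$params),
         vesicles_3d = make_vesicle_volume_3d(manifest$params),
         stop("unknown manifest kind: ", manifest$kind))
}

#' Write a truth manifest as JSON (geometry, truth values, seed)
#'
#' Function-valued fields (the radial density) are recorded by name only;
#' voxel masks are omitted. The JSON form is for provenance; bit-identical
#' re-rendering uses the in-memory manifest.
#'
#' @param manifest a \code{truth_manifest}
#' @param path output JSON path
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest
  m$masks <- NULL
  m$params$radial_weight <- if (is.null(m$params$radial_weight)) NULL
                            else "<function>"
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
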