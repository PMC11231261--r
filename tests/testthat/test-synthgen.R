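test_that("2D time-lapse generation is deterministic and decays as stated", {
  p <- scene2d_params(seed = 5)
  a <- make_timelapse_2d(p)
  b <- make_timelapse_2d(p)
  expect_identical(a$frames[[1]]$data, b$frames[[1]]$data)
  expect_identical(a$manifest$true_md_mean, b$manifest$true_md_mean)

  # re-rendering from the manifest reproduces the scene bit-identically
  c <- render_from_manifest(a$manifest)
  expect_identical(c$frames[[4]]$data, a$frames[[4]]$data)

  # closed form: I0 = 1000, k = 1, no noise -> frame-1 amplitude 1000/e
  p0 <- scene2d_params(seed = 1, I0 = 1000, k = 1, noise_sd = 0)
  sc <- make_timelapse_2d(p0)
  flag_mean <- function(fr) {
    md <- get_channel(fr, "md")
    mean(md[md > p0$background + 50])
  }
  m1 <- flag_mean(sc$frames[[2]])
  expect_equal(m1, p0$background + 1000 * exp(-1), tolerance = 1e-9)
  expect_equal(sc$manifest$true_md_mean[2], 100 + 367.879441171,
               tolerance = 1e-6)

  # k = 0: flagellar mean equal across frames within 2 sd of the estimator
  pk <- scene2d_params(seed = 2, k = 0)
  sck <- make_timelapse_2d(pk)
  means <- vapply(sck$frames, function(fr) {
    md <- get_channel(fr, "md")
    mean(md[md > 10000])
  }, 0)
  se <- pk$noise_sd / sqrt(sck$manifest$flagellum_area_px)
  expect_true(max(means) - min(means) < 2 * se * 4)
})

test_that("2D scene parameter validation rejects degenerate geometry", {
  expect_error(scene2d_params(I0 = 50, background = 100), "exceed background")
  expect_error(scene2d_params(k = -1), "k must be >= 0")
  expect_error(
    scene2d_params(flagellum_control_points = cbind(c(10, 80), c(10, 110))),
    "leaves the egg")
})

test_that("3D axoneme scene records exact puncta ground truth", {
  # zero puncta: puncta channel is pure background (+ noise)
  p0 <- scene3d_params(seed = 3, shape = c(16, 48, 48), n_puncta = 0,
                       noise_sd = 0)
  s0 <- make_axoneme_volume_3d(p0)
  expect_true(all(get_channel(s0$stack, "puncta") == p0$background))

  # puncta placed at 2.5 um from a straight axoneme get shell index 3
  ext <- c(16, 64, 64) * c(0.5, 0.25, 0.25)
  straight <- cbind(rep(ext[1] / 2, 4), rep(ext[2] / 2, 4),
                    seq(1, ext[3] - 1, length.out = 4))
  centers <- cbind(ext[1] / 2, ext[2] / 2 + 2.5 + 0.3,
                   seq(3, ext[3] - 3, length.out = 5))
  pc <- scene3d_params(seed = 4, shape = c(16, 64, 64),
                       axoneme_control_points = straight,
                       puncta_centers = centers, noise_sd = 0)
  sc <- make_axoneme_volume_3d(pc)
  expect_true(all(sc$manifest$puncta_shell_index == 3L))

  # membrane fill fraction 0 -> ground-truth ratio 0
  pm <- scene3d_params(seed = 5, shape = c(16, 48, 48), n_puncta = 0,
                       membrane_fill_fraction = 0)
  sm <- make_axoneme_volume_3d(pm)
  expect_equal(sm$manifest$membrane_axoneme_ratio, 0)

  # determinism + manifest re-render
  pa <- scene3d_params(seed = 6, shape = c(16, 48, 48), n_puncta = 50)
  a <- make_axoneme_volume_3d(pa)
  b <- render_from_manifest(a$manifest)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$manifest$puncta_center_distance_um,
                   b$manifest$puncta_center_distance_um)
})

test_that("vesicle scene honors the positive fraction and non-overlap", {
  p1 <- scene3d_params(seed = 7, shape = c(32, 96, 96), n_vesicles = 12,
                       positive_fraction = 1, noise_sd = 0)
  s1 <- make_vesicle_volume_3d(p1)
  expect_true(all(s1$manifest$true_positive))

  p0 <- scene3d_params(seed = 8, shape = c(32, 96, 96), n_vesicles = 12,
                       positive_fraction = 0, noise_sd = 0,
                       negative_secondary_offset = 0, psf_sigma_um = 0)
  s0 <- make_vesicle_volume_3d(p0)
  expect_equal(sum(s0$manifest$true_positive), 0)
  expect_true(all(get_channel(s0$stack, "vesicle_secondary") ==
                    p0$background)) # flat secondary

  # manifest records the realized Bernoulli draw exactly
  pf <- scene3d_params(seed = 9, shape = c(64, 192, 192), n_vesicles = 200,
                       positive_fraction = 0.85)
  sf <- make_vesicle_volume_3d(pf)
  expect_equal(sf$manifest$true_positive_count,
               sum(sf$manifest$true_positive))
  expect_equal(sf$manifest$true_positive_fraction,
               sf$manifest$true_positive_count / 200)

  # pairwise separation respects vesicle radii plus envelopes
  cen <- sf$manifest$centers_um
  rad <- sf$manifest$radii_um
  dmin <- Inf
  for (i in 1:199) for (j in (i + 1):200) {
    gap <- sqrt(sum((cen[i, ] - cen[j, ])^2)) - rad[i] - rad[j]
    dmin <- min(dmin, gap)
  }
  expect_gt(dmin, 2 * (0.2 + 0.3)) # guard + background shells never touch

  # impossible placement errors out after bounded retries
  pbad <- scene3d_params(seed = 10, shape = c(16, 48, 48), n_vesicles = 500)
  expect_error(make_vesicle_volume_3d(pbad), "cannot place")
})

test_that("uniform radial density gives counts proportional to shell volume", {
  p <- scene3d_params(seed = 12, shape = c(48, 128, 128), n_puncta = 10000,
                      punctum_radius_um = 0.1, axoneme_radius_um = 0.1,
                      noise_sd = 0)
  sc <- make_axoneme_volume_3d(p)
  sh <- compute_shells(sc$manifest$masks$axoneme, p$spacing, K = 10, w = 1)
  counts <- tabulate(sc$manifest$puncta_shell_index, nbins = 10)
  # candidate voxels per shell (placement support), not idealized volumes:
  # the chi-square compares the draw against its own sampling design
  expect_gt(stats::chisq.test(counts,
                              p = sh$shell_volumes_um3 /
                                sum(sh$shell_volumes_um3))$p.value, 0.01)
})
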