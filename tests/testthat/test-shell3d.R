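test_that("shell partition matches first-neighbor geometry exactly", {
  m <- array(FALSE, c(9, 9, 9))
  m[5, 5, 5] <- TRUE
  sh <- compute_shells(m, c(1, 1, 1), K = 2, w = 1)
  # shell 1 at 1 um isotropic spacing is exactly the 6 face neighbors
  expect_equal(sum(sh$shell_index == 1L), 6L)
  nb <- which(sh$shell_index == 1L, arr.ind = TRUE)
  expect_true(all(rowSums(abs(sweep(nb, 2, c(5, 5, 5)))) == 1))
  expect_equal(sh$shell_volumes_um3[1], 6)

  expect_error(compute_shells(array(FALSE, c(3, 3, 3)), c(1, 1, 1)),
               "empty reference")
})

test_that("shell partitions equal the brute-force distance oracle", {
  set.seed(23)
  cases <- list(
    list(dim = c(13, 11, 12), sp = c(0.5, 0.25, 0.25)),
    list(dim = c(9, 17, 9), sp = c(1, 0.5, 2)),
    list(dim = c(21, 15, 1), sp = c(0.25, 0.25, 1)))
  for (cs in cases) {
    ref <- array(runif(prod(cs$dim)) < 0.04, dim = cs$dim)
    if (!any(ref)) ref[ceiling(cs$dim / 2)[1], 1, 1] <- TRUE
    sh <- compute_shells(ref, cs$sp, K = 4, w = 0.75)
    want <- brute_shell_index(ref, cs$sp, K = 4, w = 0.75)
    expect_identical(sh$shell_index, want)
  }

  # a straight axoneme line, exact equality again
  ref <- array(FALSE, c(7, 15, 15))
  ref[4, 8, ] <- TRUE
  sh <- compute_shells(ref, c(0.5, 0.5, 0.5), K = 10, w = 1)
  expect_identical(sh$shell_index,
                   brute_shell_index(ref, c(0.5, 0.5, 0.5), 10, 1))

  # K = 1 with w spanning the volume: every non-reference voxel in shell 1
  one <- array(FALSE, c(6, 6, 6)); one[3, 3, 3] <- TRUE
  shall <- compute_shells(one, c(1, 1, 1), K = 1, w = 20)
  expect_equal(sum(shall$shell_index == 1L), 6^3 - 1L)
})

test_that("cylinder shell volumes converge to the analytic annuli", {
  analytic <- function(k, w = 1) pi * ((k * w)^2 - ((k - 1) * w)^2)
  rel_err <- function(h) {
    n <- round(8 / h)
    ref <- array(FALSE, c(n, n, 5))
    ref[round(n / 2), round(n / 2), ] <- TRUE # line along x
    sh <- compute_shells(ref, c(h, h, 1), K = 3, w = 1)
    got <- sh$shell_volumes_um3 / 5 # per unit length
    max(abs(got - analytic(1:3)) / analytic(1:3))
  }
  e_coarse <- rel_err(0.25)
  e_fine <- rel_err(0.125)
  expect_lt(e_fine, e_coarse * 0.75) # error shrinks with resolution
  expect_lt(e_fine, 0.05)
})

test_that("smallest-fraction filter: count rule, singleton and tie rules", {
  # volumes 1..10, fraction 0.4: floor(0.4 * 10) = 4 smallest removed,
  # i.e. {1,2,3,4}; retained volume = (55 - 10)/55 = 45/55 by arithmetic
  m <- blob_mask(1:10)
  obj <- label_and_filter(m, min_size = 0, units = "px")
  expect_equal(obj$table$n_voxels, 1:10)
  f <- filter_smallest_objects(obj, 0.40)
  expect_equal(n_objects(f), 6L)
  expect_equal(f$table$n_voxels, 5:10)
  expect_equal(f$retained_volume_fraction, 45 / 55)

  # n = 1: floor(0.4) = 0, nothing removed
  one <- label_and_filter(blob_mask(9), min_size = 0, units = "px")
  expect_equal(n_objects(filter_smallest_objects(one, 0.40)), 1L)

  # all equal volumes: 4 of 10 removed by label order
  eq <- label_and_filter(blob_mask(rep(4, 10)), min_size = 0, units = "px")
  feq <- filter_smallest_objects(eq, 0.40)
  expect_equal(n_objects(feq), 6L)
  expect_equal(feq$retained_volume_fraction, 0.6)
  # survivors are the last six original labels, re-densified
  expect_equal(sort(unique(as.integer(feq$labels[feq$labels > 0]))), 1:6)
})

test_that("shell volume profiles normalize and conserve volume", {
  ref <- array(FALSE, c(10, 30, 30))
  ref[5, 15, ] <- TRUE
  sp <- c(1, 1, 1)
  sh <- compute_shells(ref, sp, K = 5, w = 1)
  # an object of 10 voxels entirely inside shell 3
  shell3 <- which(sh$shell_index == 3L)
  mask <- array(FALSE, dim = dim(ref))
  mask[shell3[1:10]] <- TRUE
  obj <- label_and_filter(mask, sp, min_size = 0)
  pr <- shell_volume_profile(obj, sh)
  expect_equal(pr$signal_volume_um3, c(0, 0, 10, 0, 0))
  expect_equal(pr$normalized_volume[3], 10 / sh$shell_volumes_um3[3])

  # no objects: all-zero profile
  pr0 <- shell_volume_profile(label_and_filter(array(FALSE, dim(ref)), sp),
                              sh)
  expect_true(all(pr0$signal_volume_um3 == 0))

  # conservation: totals equal object volume within K*w of the reference
  set.seed(29)
  rnd <- array(runif(prod(dim(ref))) < 0.1, dim = dim(ref))
  objr <- label_and_filter(rnd, sp, min_size = 0)
  prr <- shell_volume_profile(objr, sh)
  expect_equal(sum(prr$signal_volume_um3),
               sum(rnd & sh$shell_index > 0) * prod(sp))
  expect_true(all(prr$normalized_volume >= 0 & prr$normalized_volume <= 1))
})

test_that("membrane/axoneme ratio retains only touching objects", {
  axo <- array(FALSE, c(5, 10, 20))
  axo[3, 5, 3:12] <- TRUE # 10-voxel axoneme line

  # adjacent membrane: 5 voxels right next to the line
  mem <- array(FALSE, dim = dim(axo))
  mem[3, 6, 3:7] <- TRUE
  r <- membrane_axoneme_ratio(label_and_filter(mem, c(1, 1, 1)), axo)
  expect_equal(r$ratio, 0.5)

  # distant object only: ratio 0
  far <- array(FALSE, dim = dim(axo))
  far[3, 9, 3:7] <- TRUE
  r0 <- membrane_axoneme_ratio(label_and_filter(far, c(1, 1, 1)), axo)
  expect_equal(r0$ratio, 0)

  # mixed: adjacent 3 voxels + distant 7 over a 6-voxel axoneme
  axo2 <- array(FALSE, c(5, 10, 20)); axo2[3, 5, 3:8] <- TRUE
  mix <- array(FALSE, dim = dim(axo2))
  mix[3, 6, 3:5] <- TRUE          # touching, 3 voxels
  mix[3, 9, 3:9] <- TRUE          # 4 rows away, 7 voxels
  rm <- membrane_axoneme_ratio(label_and_filter(mix, c(1, 1, 1)), axo2)
  expect_equal(rm$ratio, 3 / 6)
  expect_equal(rm$retained_labels, 1L)

  expect_error(membrane_axoneme_ratio(label_and_filter(mix, c(1, 1, 1)),
                                      array(FALSE, dim(axo2))),
               "empty axoneme")
})

test_that("guarded background means subtract the envelope estimate", {
  sp <- c(0.5, 0.5, 0.5)
  target <- array(FALSE, c(12, 12, 12))
  target[6:7, 6:7, 6:7] <- TRUE
  sig <- array(100, dim = dim(target))
  sig[target] <- 500
  g <- guarded_background_mean(target, sig, guard_um = 0.5, bg_um = 1,
                               spacing = sp)
  expect_equal(g$raw_mean, 500)
  expect_equal(g$background_mean, 100)
  expect_equal(g$normalized_mean, 400)

  # uniform image: normalized 0
  u <- guarded_background_mean(target, array(250, dim(target)), 0.5, 1, sp)
  expect_equal(u$normalized_mean, 0)

  # synthetic tube with known +300 interior offset over noisy background
  p <- scene3d_params(seed = 31, shape = c(16, 48, 48), n_puncta = 0,
                      intensity = 300, noise_sd = 15)
  sc <- make_axoneme_volume_3d(p)
  axo <- sc$manifest$masks$axoneme
  # the tube reaches the volume faces, so the envelope is clipped there
  expect_warning(
    gm <- guarded_background_mean(axo, get_channel(sc$stack, "axoneme"),
                                  guard_um = 0.5, bg_um = 1,
                                  spacing = p$spacing),
    "clipped")
  se_bound <- 4 * 15 / sqrt(min(sum(axo), gm$n_background_voxels))
  expect_lt(abs(gm$normalized_mean - 300), se_bound + 1)

  expect_error(guarded_background_mean(array(FALSE, c(3, 3, 3)),
                                       array(0, c(3, 3, 3)), 0.5, 1, sp),
               "empty target")
})
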