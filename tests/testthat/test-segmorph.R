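test_that("pixel classifier separates two-intensity scenes and is deterministic", {
  set.seed(3)
  truth <- array(FALSE, c(60, 60))
  truth[15:45, 20:50] <- TRUE
  img <- matrix(100, 60, 60)
  img[truth] <- 1000
  img <- img + rnorm(length(img), 0, 10)
  labs <- sparse_labels_from_mask(truth, 300, seed = 2)
  clf <- train_pixel_classifier(img, labs, seed = 4)
  mask <- predict_mask(clf, img, 2L)
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.95)

  clf2 <- train_pixel_classifier(img, labs, seed = 4)
  expect_identical(predict_mask(clf2, img, 2L), mask)

  # probabilities sum to 1 per pixel
  pr <- predict_class_prob(clf, img)
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-12)

  # serialization roundtrip
  f <- tempfile(fileext = ".rds")
  save_classifier(clf, f)
  expect_identical(predict_mask(load_classifier(f), img, 2L), mask)

  # single-class annotations are an error
  labs1 <- labs
  labs1[labs1 == 1L] <- 0L
  expect_error(train_pixel_classifier(img, labs1, seed = 1),
               "at least 2 classes")
})

test_that("classifier accuracy beats the Bayes floor at >= 5 sd separation", {
  set.seed(8)
  for (sep_sd in c(5, 8)) {
    truth <- array(FALSE, c(50, 50))
    truth[10:40, 10:40] <- TRUE
    sd0 <- 40
    img <- matrix(500, 50, 50)
    img[truth] <- 500 + sep_sd * sd0
    img <- img + rnorm(length(img), 0, sd0)
    clf <- train_pixel_classifier(img, sparse_labels_from_mask(truth, 300,
                                                               seed = 5),
                                  seed = 5)
    acc <- mean(predict_mask(clf, img, 2L) == truth)
    bayes <- 1 - pnorm(sep_sd / 2, lower.tail = FALSE)
    expect_gte(acc, bayes - 0.05)
  }
})

test_that("classifier segments a 3D axoneme tube with Dice >= 0.9", {
  p <- scene3d_params(seed = 21, shape = c(24, 80, 80), n_puncta = 0)
  sc <- make_axoneme_volume_3d(p)
  vol <- get_channel(sc$stack, "axoneme")
  truth <- sc$manifest$masks$axoneme
  clf <- train_pixel_classifier(vol, sparse_labels_from_mask(truth, 1500,
                                                             seed = 6),
                                seed = 6)
  mask <- predict_mask(clf, vol, 2L)
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gte(dice, 0.9)
})

test_that("rolling-ball subtraction matches the direct opening oracle", {
  # constant image -> all zeros
  expect_true(all(rolling_ball_subtract(matrix(500, 40, 40), 35) == 0))

  # single bright pixel keeps its amplitude within 1%
  img <- matrix(100, 64, 64)
  img[30, 30] <- 600
  out <- rolling_ball_subtract(img, 35)
  expect_lt(abs(out[30, 30] - 500) / 500, 0.01)

  # broad plateau wider than 2*radius is removed at its center
  img2 <- matrix(0, 160, 160)
  img2[20:140, 20:140] <- 400
  out2 <- rolling_ball_subtract(img2, 35)
  expect_lte(out2[80, 80] / 400, 0.01)

  # oracle equality on a random 64x64 fixture, both radii
  set.seed(11)
  img3 <- matrix(runif(64 * 64, 0, 4000), 64, 64)
  for (r in c(7L, 35L)) {
    got <- rolling_ball_subtract(img3, r)
    want <- pmax(img3 - brute_opening_disc(img3, r), 0)
    expect_equal(got, want, tolerance = 1e-9)
  }

  # translation equivariance (away from borders)
  imgA <- matrix(50, 96, 96); imgA[40:44, 40:44] <- 900
  imgB <- matrix(50, 96, 96); imgB[47:51, 52:56] <- 900
  outA <- rolling_ball_subtract(imgA, 9)
  outB <- rolling_ball_subtract(imgB, 9)
  expect_equal(outA[40:44, 40:44], outB[47:51, 52:56])

  expect_error(rolling_ball_subtract(matrix(0, 5, 5), 0), "positive")
})

test_that("Euclidean erosion matches the distance-from-boundary rule", {
  sq40 <- array(TRUE, c(40, 40))
  e <- erode_mask(sq40, 15)
  expect_equal(sum(e), 100) # 10x10 core
  expect_true(all(which(e, arr.ind = TRUE) >= 16 &
                    which(e, arr.ind = TRUE) <= 25))

  expect_identical(erode_mask(sq40, 0), sq40) # identity
  expect_equal(sum(erode_mask(array(TRUE, c(20, 20)), 15)), 0) # vanishes

  # anti-extensive and monotone in radius
  set.seed(13)
  m <- matrix(runif(40 * 40) < 0.6, 40, 40)
  e5 <- erode_mask(m, 5); e8 <- erode_mask(m, 8)
  expect_true(all(!e5 | m))   # output subset of input
  expect_true(all(!e8 | e5))  # larger radius erodes more
})

test_that("component labeling, size filtering and volumes are exact", {
  m <- blob_mask(c(100, 5))
  obj <- label_and_filter(m, min_size = 10, units = "px")
  expect_equal(n_objects(obj), 1L)
  expect_equal(obj$table$n_voxels, 100L)

  # empty mask
  expect_equal(n_objects(label_and_filter(array(FALSE, c(5, 5)))), 0L)

  # sphere of radius 1.5 um at 0.25 um voxels has volume < 15 um^3
  sp <- rep(0.25, 3)
  ax <- lapply(c(24, 24, 24), function(n) (seq_len(n) - 0.5) * 0.25)
  ctr <- c(3, 3, 3)
  vox <- array(FALSE, c(24, 24, 24))
  for (z in 1:24) for (y in 1:24) for (x in 1:24)
    vox[z, y, x] <- (ax[[1]][z] - 3)^2 + (ax[[2]][y] - 3)^2 +
      (ax[[3]][x] - 3)^2 <= 1.5^2
  true_vol <- sum(vox) * prod(sp)
  expect_lt(true_vol, 15) # voxel-count oracle, approx 14.1
  obj3 <- label_and_filter(vox, sp, min_size = 15, units = "um3")
  expect_equal(n_objects(obj3), 0L)
  obj3b <- label_and_filter(vox, sp, min_size = 14, units = "um3")
  expect_equal(obj3b$table$volume_um3, true_vol)

  # volumes sum exactly to retained voxels times voxel volume
  set.seed(17)
  m3 <- array(runif(20^3) < 0.1, c(20, 20, 20))
  objs <- label_and_filter(m3, c(0.5, 0.25, 0.25), min_size = 5,
                           units = "px")
  expect_equal(sum(objs$table$volume_um3),
               sum(objs$labels > 0) * prod(c(0.5, 0.25, 0.25)))

  # labels are dense 1..n in raster order of first voxel
  expect_equal(sort(unique(as.integer(objs$labels[objs$labels > 0]))),
               seq_len(n_objects(objs)))

  # NA min_size applies the 5%-of-largest rule
  m2 <- blob_mask(c(400, 30, 9))
  auto <- label_and_filter(m2, min_size = NA, units = "px")
  expect_equal(auto$table$n_voxels, c(400L, 30L)) # 9 < 5% of 400 dropped
})
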