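test_that("split-plot ANOVA reproduces the hand-computed fixture", {
  # 2 groups x 3 times x 4 subjects, small integers
  y <- rbind(c(3, 5, 9), c(4, 6, 8), c(2, 4, 9), c(5, 7, 10),  # group a
             c(6, 7, 8), c(5, 8, 9), c(7, 7, 9), c(6, 9, 11))  # group b
  g <- rep(c("a", "b"), each = 4)
  r <- rm_anova_two_way(y, g)

  # independent oracle: explicit mean decomposition, written out here
  grand <- mean(y)
  subj <- rowMeans(y)
  ga <- mean(y[1:4, ]); gb <- mean(y[5:8, ])
  ss_group <- 3 * (4 * (ga - grand)^2 + 4 * (gb - grand)^2)
  ss_bs <- 3 * sum((subj - grand)^2)
  ss_subj <- ss_bs - ss_group
  tm <- colMeans(y)
  ss_time <- 8 * sum((tm - grand)^2)
  cm <- rbind(colMeans(y[1:4, ]), colMeans(y[5:8, ]))
  ss_cells_w <- 4 * (sum((cm[1, ] - ga)^2) + sum((cm[2, ] - gb)^2))
  ss_inter <- ss_cells_w - ss_time
  ss_err <- sum((y - grand)^2) - ss_bs - ss_cells_w

  expect_equal(r$table$ss, c(ss_group, ss_subj, ss_time, ss_inter, ss_err),
               tolerance = 1e-9)
  expect_equal(r$f_group, (ss_group / 1) / (ss_subj / 6), tolerance = 1e-9)
  expect_equal(r$f_time, (ss_time / 2) / (ss_err / 12), tolerance = 1e-9)
  expect_equal(r$f_interaction, (ss_inter / 2) / (ss_err / 12),
               tolerance = 1e-9)

  # cross-check against aov with an Error stratum
  df <- data.frame(y = as.numeric(y),
                   subj = factor(rep(1:8, 3)),
                   grp = factor(rep(g, 3)),
                   time = factor(rep(1:3, each = 8)))
  av <- summary(stats::aov(y ~ grp * time + Error(subj), data = df))
  f_aov_grp <- av[["Error: subj"]][[1]]["grp", "F value"]
  f_aov_time <- av[["Error: Within"]][[1]]["time", "F value"]
  f_aov_int <- av[["Error: Within"]][[1]]["grp:time", "F value"]
  expect_equal(r$f_group, f_aov_grp, tolerance = 1e-9)
  expect_equal(r$f_time, f_aov_time, tolerance = 1e-9)
  expect_equal(r$f_interaction, f_aov_int, tolerance = 1e-9)
})

test_that("ANOVA SS decomposition is conserved, including unbalanced groups", {
  set.seed(37)
  for (i in 1:5) {
    ns <- sample(3:7, 3, TRUE)
    y <- matrix(rnorm(sum(ns) * 4), sum(ns), 4)
    g <- rep(letters[1:3], ns)
    r <- rm_anova_two_way(y, g)
    expect_equal(sum(r$table$ss), r$ss_total, tolerance = 1e-9)
    expect_true(all(r$table$ss > -1e-9))
    # aov agreement holds with unequal group sizes too
    df <- data.frame(y = as.numeric(y),
                     subj = factor(rep(seq_len(nrow(y)), 4)),
                     grp = factor(rep(g, 4)),
                     time = factor(rep(1:4, each = nrow(y))))
    av <- summary(stats::aov(y ~ grp * time + Error(subj), data = df))
    expect_equal(r$f_time, av[["Error: Within"]][[1]]["time", "F value"],
                 tolerance = 1e-8)
    expect_equal(r$f_interaction,
                 av[["Error: Within"]][[1]]["grp:time", "F value"],
                 tolerance = 1e-8)
    expect_equal(r$f_group, av[["Error: subj"]][[1]]["grp", "F value"],
                 tolerance = 1e-8)
  }
})

test_that("constant responses are reported as degenerate", {
  y <- matrix(7, 6, 3)
  r <- rm_anova_two_way(y, rep(c("a", "b"), each = 3))
  expect_true(r$degenerate)
  expect_equal(r$ss_total, 0)
  expect_equal(r$f_group, 0)
  expect_equal(r$p_group, 1)
})

test_that("subjects missing a time point are excluded with a warning", {
  y <- matrix(rnorm(18), 6, 3)
  y[2, 3] <- NA
  expect_warning(r <- rm_anova_two_way(y, rep(c("a", "b"), each = 3)),
                 "excluded")
  expect_equal(sum(r$table$df[c(1, 2)]) + 1, 5) # 5 subjects left
})

test_that("Sidak and Holm-Sidak follow their closed forms", {
  expect_equal(sidak_adjust(0.05, m = 1), 0.05)
  expect_equal(sidak_adjust(0.05, m = 2), 1 - 0.95^2) # 0.0975
  expect_equal(sidak_adjust(1, m = 5), 1)
  expect_equal(holm_sidak_adjust(0.2), sidak_adjust(0.2, 1))
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)),
               c(1 - 0.99^2, max(1 - 0.99^2, 1 - 0.96^1)))
  expect_equal(holm_sidak_adjust(rep(0.03, 4)),
               rep(1 - 0.97^4, 4)) # all equal stay equal
  # adjusted >= raw; Holm-Sidak <= Sidak elementwise
  set.seed(41)
  p <- runif(8)
  hs <- holm_sidak_adjust(p)
  sk <- sidak_adjust(p)
  expect_true(all(hs >= p - 1e-15))
  expect_true(all(sk >= p - 1e-15))
  expect_true(all(hs <= sk + 1e-15))
  expect_error(sidak_adjust(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher's exact test equals enumeration and the reference", {
  got <- fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2))
  expect_equal(got$p, 2 / 252, tolerance = 1e-12) # full enumeration: 2/C(10,5)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p, 1.0)

  # sweep of tables with margins <= 12 against stats::fisher.test
  set.seed(43)
  for (i in 1:200) {
    repeat {
      x <- matrix(rpois(4, sample(1:4, 1)), 2)
      if (sum(x) <= 12 && all(rowSums(x) > 0) && all(colSums(x) > 0)) break
    }
    expect_equal(fisher_exact_2x2(x)$p, stats::fisher.test(x)$p.value,
                 tolerance = 1e-12)
    # invariance to row and column swaps
    expect_equal(fisher_exact_2x2(x[2:1, ])$p, fisher_exact_2x2(x)$p)
    expect_equal(fisher_exact_2x2(x[, 2:1])$p, fisher_exact_2x2(x)$p)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("pooled t test matches the hand-computed fixture", {
  r <- t_test_unpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-9) # -3.674
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(r$df, 4)

  same <- t_test_unpaired(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(t_test_unpaired(c(1, 1), c(2, 2)), "zero pooled variance")
})

test_that("Monte-Carlo many-to-one comparisons are seeded and sane", {
  set.seed(47)
  ctrl <- rnorm(10)
  trt <- list(rnorm(10, 2), rnorm(10, 0))
  a <- dunnett_mc(ctrl, trt, n_sim = 4000, seed = 9)
  b <- dunnett_mc(ctrl, trt, n_sim = 4000, seed = 9)
  expect_identical(a, b)
  expect_lt(a$p_adj_mc[1], 0.01) # large effect detected
  expect_gt(a$p_adj_mc[2], 0.05) # null treatment not flagged
  # adjusted p never below the raw two-sided p of the same contrast
  raw <- 2 * stats::pt(-abs(a$t[1]), df = 10 + 10 + 10 - 3)
  expect_gte(a$p_adj_mc[1] + 0.005, raw)
})
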