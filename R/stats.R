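# Statistical tests attached to the quantifications: balanced split-plot
# (two-way repeated-measures) ANOVA, Sidak and Holm-Sidak multiplicity
# adjustment, two-sided Fisher's exact test by full enumeration, and the
# pooled-variance unpaired Student t test.

#' Two-way repeated-measures (split-plot) ANOVA
#'
#' Mixed design: a between-subjects group factor (genotype), a
#' within-subjects repeated factor (time), subjects (eggs) nested in
#' groups, balanced and complete. Sums of squares follow the standard
#' split-plot decomposition; F for the group effect uses the
#' between-subject error (subjects within groups), F for time and the
#' interaction use the within-subject error. Subjects missing a time
#' point are excluded with a warning. No sphericity correction is
#' applied. A fully constant response is reported as degenerate (zero SS,
#' F = 0, p = 1).
#'
#' @param y response matrix, subjects x time points (e.g. the \code{nmi}
#'   matrix of \code{\link{build_timecourse}}).
#' @param group factor/vector of group labels, one per subject (row).
#' @return an \code{rm_anova} list: ANOVA table (SS, df, MS, F, p) for
#'   group, time, interaction and the two error strata, plus grand/cell
#'   means.
#' @export
rm_anova_two_way <- function(y, group) {
  y <- as.matrix(y)
  group <- as.factor(group)
  if (length(group) != nrow(y))
    stop("need one group label per subject row")
  if (anyNA(y)) {
    drop <- apply(y, 1, anyNA)
    warning(sum(drop), " subject(s) missing a time point; excluded")
    y <- y[!drop, , drop = FALSE]
    group <- droplevels(group[!drop])
  }
  a <- nlevels(group)
  if (a < 2L) stop("need >= 2 groups")
  b <- ncol(y)
  if (b < 2L) stop("need >= 2 time points")
  ng <- table(group)
  N <- nrow(y)
  grand <- mean(y)
  subj_mean <- rowMeans(y)
  grp_mean <- tapply(subj_mean, group, mean)          # per-group mean
  time_mean <- colMeans(y)
  cell_mean <- apply(y, 2, function(col) tapply(col, group, mean))
  cell_mean <- matrix(cell_mean, nrow = a) # groups x time

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- b * sum((subj_mean - grand)^2)
  ss_group <- b * sum(ng * (grp_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_time <- N * sum((time_mean - grand)^2)
  # time + interaction jointly (exact within-subject identity, valid for
  # unequal group sizes); interaction is the sequential remainder
  ss_tw <- sum(as.numeric(ng) *
                 rowSums((cell_mean - as.numeric(grp_mean))^2))
  ss_inter <- ss_tw - ss_time
  ss_within <- ss_total - ss_between_subj
  ss_err_within <- ss_within - ss_tw

  df_group <- a - 1L
  df_subj <- N - a
  df_time <- b - 1L
  df_inter <- (a - 1L) * (b - 1L)
  df_err <- (N - a) * (b - 1L)

  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  f_of <- function(ms_num, ms_den) {
    if (is.na(ms_num) || is.na(ms_den)) return(NA_real_)
    if (ms_den == 0) return(if (ms_num == 0) 0 else Inf)
    ms_num / ms_den
  }
  p_of <- function(f, df1, df2) {
    if (is.na(f)) return(NA_real_)
    if (!is.finite(f)) return(0)
    if (f == 0 && df2 > 0) return(1)
    stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  ms_group <- ms(ss_group, df_group); ms_subj <- ms(ss_subj_within, df_subj)
  ms_time <- ms(ss_time, df_time); ms_inter <- ms(ss_inter, df_inter)
  ms_err <- ms(ss_err_within, df_err)
  f_group <- f_of(ms_group, ms_subj)
  f_time <- f_of(ms_time, ms_err)
  f_inter <- f_of(ms_inter, ms_err)
  degenerate <- ss_total == 0

  tab <- data.frame(
    term = c("group", "subjects_within_group", "time", "group_x_time",
             "within_error"),
    ss = c(ss_group, ss_subj_within, ss_time, ss_inter, ss_err_within),
    df = c(df_group, df_subj, df_time, df_inter, df_err),
    ms = c(ms_group, ms_subj, ms_time, ms_inter, ms_err),
    f = c(f_group, NA, f_time, f_inter, NA),
    p = c(p_of(f_group, df_group, df_subj), NA,
          p_of(f_time, df_time, df_err),
          p_of(f_inter, df_inter, df_err), NA))
  structure(list(table = tab, ss_total = ss_total,
                 f_group = f_group, p_group = tab$p[1],
                 f_time = f_time, p_time = tab$p[3],
                 f_interaction = f_inter, p_interaction = tab$p[4],
                 degenerate = degenerate,
                 grand_mean = grand, cell_means = cell_mean),
            class = "rm_anova")
}

#' Sidak multiple-comparison adjustment
#'
#' \code{p_adj = 1 - (1 - p)^m}, clipped to 1.
#'
#' @param p raw p-values in [0, 1].
#' @param m number of comparisons (default \code{length(p)}).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, 1 - (1 - p)^m)
}

#' Holm-Sidak step-down adjustment
#'
#' Sort ascending; the i-th smallest gets \code{1 - (1 - p_(i))^(m - i +
#' 1)}, with a running maximum enforcing monotonicity; results return in
#' the input order.
#'
#' @param p raw p-values in [0, 1].
#' @return adjusted p-values (elementwise <= \code{\link{sidak_adjust}}).
#' @export
holm_sidak_adjust <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-sided Fisher's exact test for a 2x2 table, by enumeration
#'
#' With margins fixed, the two-sided p-value is the sum of hypergeometric
#' probabilities of every table whose probability does not exceed the
#' observed table's (a relative tolerance of 1e-7 guards against ties
#' broken by floating-point rounding, the convention of standard
#' implementations).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list(p, odds_table): the two-sided p and the support
#'   enumeration used.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.matrix(table)
  if (!all(dim(x) == 2L) || any(x < 0) || any(x != round(x)))
    stop("need a 2x2 table of non-negative integers")
  r1 <- sum(x[1, ]); c1 <- sum(x[, 1]); n <- sum(x)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n)
    stop("zero margin")
  support <- max(0, r1 + c1 - n):min(r1, c1) # feasible x[1,1] values
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(x[1, 1], c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p = min(1, p),
       odds_table = data.frame(x11 = support, prob = probs))
}

#' Two-tailed unpaired Student's t test (pooled variance)
#'
#' @param x,y numeric samples, n >= 2 each.
#' @return list(t, df, p).
#' @export
t_test_unpaired <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0,
                                        df = length(x) + length(y) - 2,
                                        p = 1))
    stop("zero pooled variance with unequal means")
  }
  res <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Monte-Carlo Dunnett-style many-to-one comparisons
#'
#' Optional approximation of Dunnett's test for comparing each treatment
#' group to a shared control at one time point: adjusted p-values are
#' estimated by simulating the null joint distribution of the maximum
#' absolute t statistic (shared control errors induce the correlation).
#' Seeded and approximate; the documented default adjustment elsewhere in
#' the package is Sidak.
#'
#' @param control numeric control sample.
#' @param treatments list of numeric treatment samples.
#' @param n_sim Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return data.frame(comparison, t, p_adj_mc).
#' @export
dunnett_mc <- function(control, treatments, n_sim = 20000, seed = 1L) {
  stopifnot(is.list(treatments), length(treatments) >= 1L)
  k <- length(treatments)
  n0 <- length(control)
  ns <- vapply(treatments, length, 1L)
  df <- n0 + sum(ns) - (k + 1)
  sp2 <- ((n0 - 1) * stats::var(control) +
            sum(vapply(treatments, function(g)
              (length(g) - 1) * stats::var(g), 0))) / df
  tstat <- vapply(seq_len(k), function(i)
    (mean(treatments[[i]]) - mean(control)) /
      sqrt(sp2 * (1 / ns[i] + 1 / n0)), 0)
  with_seed(seed, {
    maxnull <- replicate(n_sim, {
      z0 <- stats::rnorm(1, 0, 1 / sqrt(n0))
      zi <- stats::rnorm(k, 0, 1 / sqrt(ns))
      s <- sqrt(stats::rchisq(1, df) / df)
      max(abs((zi - z0) / (s * sqrt(1 / ns + 1 / n0))))
    })
    p_adj <- vapply(tstat, function(t) mean(maxnull >= abs(t)), 0)
  })
  data.frame(comparison = paste0("treatment", seq_len(k), "_vs_control"),
             t = tstat, p_adj_mc = p_adj)
}
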