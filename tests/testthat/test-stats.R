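# Individuality statistics: CV formulas, PIC, group tests, screening,
# outliers, balancing, QDA-LOOCV, stepwise ranking, diagnostics.

test_that("between- and within-individual CVs follow the formulas", {
  expect_equal(cv_between(rep(3, 10)), 0)
  expect_equal(cv_between(c(4, 6)), 100 * sqrt(2) / 5)          # 28.2843
  expect_equal(cv_within(c(4, 6)), 100 * sqrt(2) / 5 * (1 + 1 / 8))
  expect_error(cv_between(5), "2 values")
  expect_error(cv_within(c(-1, 1)), "zero mean")
  # n -> infinity: the small-sample correction vanishes
  set.seed(1)
  v <- rnorm(2e4, 10, 2)
  expect_equal(cv_within(v), cv_between(v), tolerance = 2e-5)
})

test_that("PIC is the ratio of CVb to the mean CVw", {
  expect_equal(round(pic(28.18, 20.41), 2), 1.38)
  expect_equal(round(pic(29.13, 18.60), 2), 1.57)
  expect_equal(pic(12, c(12, 12, 12)), 1)
  expect_error(pic(10, 0), "positive")
})

test_that("PIC table rows satisfy the defining identity", {
  set.seed(7)
  feats <- data.frame(
    avg_ipi_11_20 = rnorm(60, rep(c(3, 6, 9), each = 20), 0.5),
    duration_s = rnorm(60, 0.7, 0.2),
    prr = rnorm(60, rep(c(190, 110, 130), each = 20), 15))
  labels <- rep(c("a", "b", "c"), each = 20)
  pt <- pic_table(feats, labels, params = names(feats))
  expect_true(all(abs(pt$pic - pt$cvb / pt$mean_cvw) < 1e-12))
  expect_true(all(pt[paste0("cvw_", c("a", "b", "c"))] >= 0))
  # separated means -> PIC > 1; shared mean with large noise -> PIC <= ~1
  expect_gt(pt$pic[pt$parameter == "avg_ipi_11_20"], 1)
  expect_lt(pt$pic[pt$parameter == "duration_s"], 1.1)
})

test_that("Kruskal-Wallis matches the hand rank-sum oracle", {
  groups <- list(c(1, 4, 5), c(2, 3, 6))
  kw <- kruskal_wallis(groups)
  # oracle: H = 12/(N(N+1)) * sum R_i^2/n_i - 3(N+1), no ties
  r <- rank(unlist(groups))
  R <- c(sum(r[1:3]), sum(r[4:6]))
  H <- 12 / (6 * 7) * sum(R^2 / 3) - 3 * 7
  expect_equal(kw$statistic, H, tolerance = 1e-12)
  expect_equal(kw$df, 1)
  # shifted copies separate decisively
  set.seed(2)
  g1 <- rnorm(10)
  expect_lt(kruskal_wallis(list(g1, g1 + 100))$p_value, 0.01)
  expect_warning(k0 <- kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
  expect_equal(k0$statistic, 0)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("one-way ANOVA has F = t^2 for two groups and the right dfs", {
  set.seed(3)
  a <- rnorm(15, 0); b <- rnorm(12, 1)
  res <- one_way_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  # five groups with the study's analyzed sample sizes -> df (4, 182)
  sizes <- c(16, 97, 20, 21, 33)
  groups <- lapply(seq_along(sizes), function(i) rnorm(sizes[i], i))
  r5 <- one_way_anova(groups)
  expect_equal(r5$df1, 4)
  expect_equal(r5$df2, 182)
  # zero within-group variance is degenerate
  expect_true(one_way_anova(list(c(1, 1), c(1, 1)))$degenerate)
})

test_that("VIF screening matches the closed form and removes collinearity", {
  # features orthogonal to each other and the intercept -> all VIF 1
  set.seed(40)
  x <- qr.Q(qr(cbind(1, matrix(rnorm(400), 100, 4))))[, 2:5]
  v <- vif_screen(as.data.frame(x), threshold = 20)
  expect_equal(unname(v$vif_initial), rep(1, 4), tolerance = 1e-10)
  # exact correlation rho = 0.6 -> VIF = 1/(1 - 0.36)
  set.seed(4)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(200), 100))))[, 2:3]
  d <- data.frame(a = q[, 1], b = 0.6 * q[, 1] + sqrt(1 - 0.36) * q[, 2])
  v2 <- vif_screen(d, threshold = 100)
  expect_equal(unname(v2$vif_initial), c(1.5625, 1.5625), tolerance = 1e-9)
  # duplicated feature is infinitely inflated and removed first
  d3 <- data.frame(a = rnorm(50), b = rnorm(50))
  d3$c <- d3$a
  v3 <- vif_screen(d3, threshold = 20)
  expect_true(v3$removed[1] %in% c("a", "c"))
  expect_true(all(v3$vif_final < 20))
})

test_that("hand VIFs agree with the car implementation", {
  skip_if_not_installed("car")
  set.seed(5)
  d <- as.data.frame(matrix(rnorm(100 * 4), 100))
  mine <- vif_screen(d, threshold = 1e6)$vif_initial
  ref <- car::vif(lm(rnorm(100) ~ ., data = d))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("robust outlier flagging is calibrated and finds planted points", {
  set.seed(33)
  x <- matrix(rnorm(1000), 500, 2)
  ro <- robust_outliers(x, quantile = 0.975, seed = 7)
  expect_gt(mean(ro$flag), 0.01)
  expect_lt(mean(ro$flag), 0.05)
  x2 <- rbind(x, c(20, 20))
  ro2 <- robust_outliers(x2, seed = 7)
  expect_true(ro2$flag[501])
  expect_equal(which.max(ro2$distance2), 501L)
  expect_error(robust_outliers(matrix(1, 50, 2), seed = 1), "singular|failed")
  expect_error(robust_outliers(matrix(rnorm(8), 4, 2)), "rows")
})

test_that("class balancing subsamples only the oversized classes", {
  labels <- rep(c("H", "T", "G", "N", "M"), c(16, 97, 20, 21, 33))
  idx <- balance_classes(labels, target_n = 33, seed = 9)
  expect_equal(unname(c(table(labels[idx])[c("H", "T", "G", "N", "M")])),
               c(16, 33, 20, 21, 33))
  expect_identical(idx, balance_classes(labels, 33, seed = 9))
  expect_identical(balance_classes(labels, 200, seed = 1),
                   seq_along(labels))
  expect_error(balance_classes(labels, 0), "target_n")
})

test_that("QDA LOOCV separates well-separated classes completely", {
  set.seed(11)
  x <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 10), 20, 2))
  r <- qda_loocv(x, rep(c("a", "b"), each = 20))
  expect_equal(r$overall_pct, 100)
  expect_equal(sum(r$confusion), 40)
  expect_equal(unname(rowSums(r$confusion)), c(20, 20))
  expect_error(qda_loocv(matrix(rnorm(12), 6, 2), rep(c("a", "b"), 3)),
               "too small")
})

test_that("QDA LOOCV equals the brute-force per-fold refit oracle", {
  set.seed(12)
  for (rep in 1:3) {
    x <- rbind(matrix(rnorm(60), 20, 3),
               matrix(rnorm(60, 1.2), 20, 3),
               matrix(rnorm(60, -1), 20, 3))
    g <- rep(c("a", "b", "c"), each = 20)
    r <- qda_loocv(x, g)
    oracle <- loocv_refit_oracle(x, g, r$prior)
    expect_identical(as.character(r$predicted), oracle)
  }
})

test_that("stepwise selection finds a dominant feature and obeys the stop rule", {
  set.seed(13)
  n <- 30
  labels <- rep(c("a", "b", "c"), each = n)
  d <- data.frame(
    signal = rnorm(3 * n, rep(c(0, 8, 16), each = n), 0.5),
    noise1 = rnorm(3 * n),
    noise2 = rnorm(3 * n))
  sw <- stepwise_select(d, labels)
  expect_equal(sw$selected[1], "signal")
  sw1 <- stepwise_select(d, labels, improvement_min = 1.01)
  expect_length(sw1$selected, 1)
  expect_error(stepwise_select(d["signal"], labels), "2 candidate")
})

test_that("Box's M is zero for identical covariances and detects unequal ones", {
  set.seed(14)
  x1 <- matrix(rnorm(180), 60, 3)
  d0 <- covariance_diagnostics(rbind(x1, x1 + 5), rep(1:2, each = 60))
  expect_equal(d0$box_m$statistic, 0, tolerance = 1e-9)
  expect_equal(d0$box_m$df, 6)
  xa <- matrix(rnorm(150), 50, 3)
  xb <- matrix(rnorm(150, 0, sqrt(10)), 50, 3)
  dp <- covariance_diagnostics(rbind(xa, xb), rep(1:2, each = 50))
  expect_lt(dp$box_m$p_value, 0.01)
  expect_error(covariance_diagnostics(x1, rep(1, 60)), "2 classes")
})

test_that("Box's M null rejection rate is near nominal", {
  set.seed(15)
  ps <- replicate(150, {
    x <- matrix(rnorm(240 * 3), 240, 3)
    covariance_diagnostics(x, rep(1:2, each = 120))$box_m$p_value
  })
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("Mardia's tests behave on normal and skewed data", {
  set.seed(16)
  xn <- rbind(matrix(rnorm(600), 200, 3), matrix(rnorm(600, 2), 200, 3))
  dn <- covariance_diagnostics(xn, rep(1:2, each = 200))
  expect_gt(dn$mardia$skew_p, 0.01)
  expect_gt(dn$mardia$kurt_p, 0.01)
  xs <- rbind(matrix(rchisq(600, 2), 200, 3),
              matrix(rchisq(600, 2), 200, 3))
  ds <- covariance_diagnostics(xs, rep(1:2, each = 200))
  expect_lt(ds$mardia$skew_p, 1e-6)
})
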