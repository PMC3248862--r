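test_that("squared Pearson correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r2(x, 2 * x + 1), 1)
  # orthogonal-to-centering construction: zero correlation
  expect_equal(pearson_r2(c(-1, 0, 1, 0), c(0, 1, 0, -1) * 2 + 5), 0)
  set.seed(21)
  a <- rnorm(10); b <- rnorm(10)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r2(a, b), (num / den)^2, tolerance = 1e-12)
  expect_error(pearson_r2(rep(1, 5), a[1:5]), "degenerate variance")
})

test_that("correlation p-value uses the exact t transform", {
  expect_lt(pearson_pvalue(0.74, 9), 0.005)
  expect_equal(pearson_pvalue(0, 10), 1)
  expect_equal(pearson_pvalue(0.81, 5), 0.037, tolerance = 0.02)
  ex <- pearson_pvalue(1, 6)
  expect_equal(as.numeric(ex), 0)
  expect_true(attr(ex, "exact_fit"))
  # cross-check against cor.test on a concrete sample
  set.seed(4)
  x <- rnorm(12); y <- x + rnorm(12)
  ct <- cor.test(x, y)
  expect_equal(pearson_pvalue(cor(x, y)^2, 12), ct$p.value,
               tolerance = 1e-10)
})

test_that("calibration fit recovers exact lines and matches normal equations", {
  x <- c(0.2, 0.4, 0.6, 0.9)
  f <- fit_calibration(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  expect_equal(f$see, 0, tolerance = 1e-10)

  # hand-solved 2x2 normal equations on four fixed points
  xs <- c(0, 1, 2, 3); ys <- c(1, 3, 2, 6)
  sxx <- sum(xs^2) - sum(xs)^2 / 4
  sxy <- sum(xs * ys) - sum(xs) * sum(ys) / 4
  slope <- sxy / sxx
  intercept <- mean(ys) - slope * mean(xs)
  f2 <- fit_calibration(xs, ys)
  expect_equal(f2$slope, slope, tolerance = 1e-12)
  expect_equal(f2$intercept, intercept, tolerance = 1e-12)
  rss <- sum((ys - intercept - slope * xs)^2)
  expect_equal(f2$see, sqrt(rss / 2), tolerance = 1e-12)
  # SEE^2 * (n-2) is the residual sum of squares
  expect_equal(f2$see^2 * (f2$n_used - 2), rss, tolerance = 1e-12)
  # r2 agrees with the standalone correlation
  expect_equal(f2$r2, pearson_r2(xs, ys), tolerance = 1e-12)
  expect_error(fit_calibration(rep(0.5, 4), ys), "degenerate design")
  expect_error(fit_calibration(xs[1:2], ys[1:2]), "at least 3")
})

test_that("exclusions are explicit and bookkept", {
  set.seed(2)
  x <- runif(8, 0.3, 1); y <- 300 * x + rnorm(8, 0, 20)
  ids <- paste0("S", 1:8)
  f_all <- fit_calibration(x, y, ids)
  f_ex <- fit_calibration(x, y, ids, exclude = "S3")
  expect_equal(f_ex$n_used, 7)
  expect_equal(f_ex$n_used + length(f_ex$excluded_ids), length(x))
  ref <- fit_calibration(x[-3], y[-3])
  expect_equal(f_ex$slope, ref$slope)
  expect_equal(f_ex$see, ref$see)
  expect_false(isTRUE(all.equal(f_all$slope, f_ex$slope)))
  expect_error(fit_calibration(x, y, ids, exclude = "S99"), "unknown")
})

test_that("leave-one-out RMSE equals brute-force enumeration and the hat identity", {
  x <- c(0.1, 0.5, 0.8, 1.2)
  expect_equal(loocv_rmse(x, 5 * x + 2), 0, tolerance = 1e-10)
  set.seed(31)
  for (n in 4:8) {
    xs <- runif(n, 0.2, 1.2)
    ys <- 250 * xs + rnorm(n, 0, 25)
    got <- loocv_rmse(xs, ys)
    expect_equal(got, loocv_brute(xs, ys), tolerance = 1e-12)
    expect_equal(got, loocv_hat_oracle(xs, ys), tolerance = 1e-10)
  }
})

test_that("leave-one-out error is never below the in-sample residual RMSE", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    x <- runif(n, 0.2, 1.2)
    y <- 200 * x + rnorm(n, 0, 30)
    fit <- lm(y ~ x)
    in_sample <- sqrt(mean(residuals(fit)^2))
    expect_gte(loocv_rmse(x, y), in_sample)
  }
})

test_that("correlation table has the published 3-level x 6-covariate shape", {
  set.seed(12)
  n <- 9
  ids <- paste0("S", seq_len(n))
  lr <- expand.grid(subject_id = ids, level = bela_levels(),
                    stringsAsFactors = FALSE)
  lr$m_loss <- runif(nrow(lr), 0.3, 1)
  areas <- lr[c("subject_id", "level")]
  areas$vf_area_cm2 <- 300 * lr$m_loss + rnorm(nrow(lr), 0, 20)
  areas$sf_area_cm2 <- runif(nrow(lr), 50, 250)
  subjects <- data.frame(subject_id = ids, bmi = runif(n, 21, 30),
                         wc_cm = runif(n, 73, 108))
  tab <- correlation_table(lr, areas, subjects)
  expect_equal(nrow(tab), 18)
  expect_setequal(unique(tab$level), bela_levels())
  expect_setequal(unique(tab$covariate),
                  c("VF", "SF", "VF/SF", "SF/VF", "BMI", "WC"))
  # VF is generated from m_loss, so it attains the largest R^2 everywhere
  for (lv in bela_levels()) {
    s <- tab[tab$level == lv, ]
    expect_equal(s$covariate[which.max(s$r2)], "VF")
  }
  wide <- correlation_table(lr, areas, subjects, pivot = "wide")
  expect_equal(dim(wide), c(3, 13))

  # degenerate variance is surfaced per cell, not as a hard failure
  lr$m_loss <- 0.5
  tab2 <- correlation_table(lr, areas, subjects)
  expect_true(all(is.na(tab2$r2)))
  expect_true(all(grepl("degenerate", tab2$note)))

  # zero ratio denominators drop the subject from that column with a warning
  areas$vf_area_cm2[1] <- 0
  lr$m_loss <- runif(nrow(lr), 0.3, 1)
  expect_warning(tab3 <- correlation_table(lr, areas, subjects),
                 "zero ratio denominator")
  sfvf <- tab3[tab3$covariate == "SF/VF" & tab3$level == areas$level[1], ]
  expect_equal(sfvf$n_used, n - 1)
})

test_that("prediction applies the line with a 95% interval and extrapolation flag", {
  set.seed(14)
  x <- runif(12, 0.3, 1); y <- 300 * x + rnorm(12, 0, 25)
  f <- fit_calibration(x, y)
  # at the training mean the prediction is the response mean
  at_mean <- predict_vf(f, mean(x))
  expect_equal(at_mean$vf_pred, mean(y), tolerance = 1e-10)
  expect_false(at_mean$extrapolated)
  # slope 2, intercept 1 applied at 0.6
  g <- fit_calibration(c(0.1, 0.4, 0.8), 2 * c(0.1, 0.4, 0.8) + 1)
  expect_equal(predict_vf(g, 0.6)$vf_pred, 2.2, tolerance = 1e-10)
  expect_warning(far <- predict_vf(f, 5), "1.5x")
  expect_true(far$extrapolated)
  # interval equals the textbook prediction-interval half width
  p <- predict_vf(f, 0.7)
  s <- f$see
  hw <- qt(0.975, 10) * s * sqrt(1 + 1 / 12 +
         (0.7 - mean(x))^2 / sum((x - mean(x))^2))
  expect_equal(p$half_width, hw, tolerance = 1e-10)
})

test_that("prediction intervals cover close to their nominal 95%", {
  set.seed(41)
  hits <- 0; trials <- 400
  for (i in seq_len(trials)) {
    x <- runif(10, 0.3, 1)
    y <- 100 + 250 * x + rnorm(10, 0, 30)
    f <- fit_calibration(x, y)
    xnew <- runif(1, 0.35, 0.95)
    ynew <- 100 + 250 * xnew + rnorm(1, 0, 30)
    p <- predict_vf(f, xnew)
    hits <- hits + (abs(ynew - p$vf_pred) <= p$half_width)
  }
  expect_gt(hits / trials, 0.90)
  expect_lt(hits / trials, 0.99)
})

test_that("outlier flags are advisory, threshold-monotone, and hit planted points", {
  x <- c(0.2, 0.4, 0.6, 0.8, 1.0, 0.5)
  y <- 300 * x + 10
  y[6] <- y[6] + 400  # planted far point
  flagged <- flag_outliers(x, y, paste0("S", 1:6))
  expect_equal(flagged, "S6")
  expect_equal(flag_outliers(x[-6], y[-6], paste0("S", 1:5)), character(0))
  set.seed(55)
  xr <- runif(12, 0.2, 1.2); yr <- 300 * xr + rnorm(12, 0, 60)
  f25 <- flag_outliers(xr, yr, threshold = 2.5)
  f30 <- flag_outliers(xr, yr, threshold = 3.0)
  expect_true(all(f30 %in% f25))
})

test_that("generative slope is recovered inside its confidence interval", {
  # cohorts with a known linear area-rate relation and stated noise
  set.seed(61)
  cover <- 0
  for (i in 1:100) {
    m <- exp(rnorm(200, log(0.6), 0.35))
    vf <- -20 + 450 * m + rnorm(200, 0, 35)
    ci <- confint(lm(vf ~ m))[2, ]
    cover <- cover + (ci[1] <= 450 && 450 <= ci[2])
  }
  expect_gte(cover, 93)
})
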