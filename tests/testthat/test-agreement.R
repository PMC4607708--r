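test_that("paired_compare matches the closed-form worked example", {
  r <- paired_compare(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$mean_diff, 2)
  expect_equal(r$sd_diff, 1)
  expect_equal(r$t_stat, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(round(r$p_value, 4), 0.0742)
  expect_equal(r$ba_lower, 0)
  expect_equal(r$ba_upper, 4)
  expect_equal(r$ba_upper - r$ba_lower, 4 * r$sd_diff)
})

test_that("identical samples give zero difference and p = 1", {
  a <- c(250, 260, 270, 280)
  r <- paired_compare(a, a)
  expect_equal(r$mean_diff, 0)
  expect_true(is.na(r$t_stat))
  expect_equal(r$p_value, 1)

  # constant nonzero difference: t undefined, p = 0
  r2 <- paired_compare(a, a + 5)
  expect_equal(r2$mean_diff, 5)
  expect_equal(r2$p_value, 0)
})

test_that("t, p and r match the reference implementations on random samples", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    a <- rnorm(n, 300, 20)
    b <- a + rnorm(n, 2, 5)
    r <- paired_compare(a, b)
    tt <- t.test(b, a, paired = TRUE)
    expect_equal(r$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(r$mean_diff, unname(tt$estimate), tolerance = 1e-10)
    expect_equal(r$pearson_r, cor(a, b), tolerance = 1e-10)
  }
})

test_that("Bland-Altman limits contain ~95% of Gaussian differences", {
  set.seed(4)
  n <- 481  # ~ 37 eyes x 13 grid points
  a <- rnorm(n, 300, 30)
  b <- a + rnorm(n, 1.85, 7.5)
  r <- paired_compare(a, b)
  ba <- bland_altman_data(r)
  outside <- mean(ba$diff < r$ba_lower | ba$diff > r$ba_upper)
  expect_lte(outside, 0.10)
  expect_equal(r$ba_upper - r$ba_lower, 4 * sd(b - a))
})

test_that("repeatability reproduces the hand-computed example", {
  expect_equal(repeatability(c(100, 200), c(100, 200))$mean_abs_diff, 0)
  expect_equal(repeatability(c(100, 200), c(100, 200))$cor_pct, 0)

  r <- repeatability(c(100, 100), c(102, 98))
  expect_equal(r$mean_abs_diff, 2)
  expect_equal(r$cor_pct, 100 * 2 * sd(c(2, -2)) / 100)
  expect_equal(r$cor_pct, 4 * sqrt(2), tolerance = 1e-12)

  expect_error(repeatability(c(1, 2), c(1, 2, 3)), "paired")
  expect_error(repeatability(1, 1), "at least 2")
})

test_that("repeat-visit simulation yields a plausible repeatability coefficient", {
  set.seed(21)
  truth <- rnorm(12, 300, 17)
  v1 <- truth + rnorm(12, 0, 2.3)
  v2 <- truth + rnorm(12, 0, 2.3)
  r <- repeatability(v1, v2)
  # d ~ N(0, 2 * 2.3^2): CoR% concentrates near 100 * 2 * 3.25 / 300 ~ 2.2
  expect_gt(r$cor_pct, 0.5)
  expect_lt(r$cor_pct, 5)
})

test_that("OLS conversion is exact on noiseless lines", {
  x <- c(200, 220, 240, 260, 280)
  f <- fit_conversion(x, x)
  expect_equal(coef(f), c(intercept = 0, slope = 1), tolerance = 1e-12)

  y <- 28.945 + 0.9482 * x
  f2 <- fit_conversion(x, y, from = "A", to = "B")
  expect_equal(f2$intercept, 28.945, tolerance = 1e-10)
  expect_equal(f2$slope, 0.9482, tolerance = 1e-12)
  expect_equal(predict(f2, 250), 28.945 + 0.9482 * 250)

  expect_error(fit_conversion(rep(1, 5), 1:5), "variance")
  expect_error(fit_conversion(1:2, 1:2), "at least 3")
})

test_that("OLS matches lm and recovers a noisy slope within its standard error", {
  set.seed(2)
  x <- rnorm(37, 280, 18)
  y <- 5.2852 + 0.9875 * x + rnorm(37, 0, 3)
  f <- fit_conversion(x, y)
  ref <- lm(y ~ x)
  expect_equal(f$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(f$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  se <- summary(ref)$coefficients[2, 2]
  expect_lt(abs(f$slope - 0.9875), 3 * se)
})

test_that("OLS slope is unbiased over replicates", {
  set.seed(17)
  slopes <- replicate(500, {
    x <- rnorm(20, 300, 15)
    y <- 10 + 0.95 * x + rnorm(20, 0, 4)
    fit_conversion(x, y)$slope
  })
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.95), 3 * se_mean)
})

test_that("per-offset comparison drops missing pairs and pools per eye", {
  grid <- seq(-1, 1, 0.5)
  eyes <- sprintf("e%02d", 1:8)
  base <- expand.grid(eye_id = eyes, offset_mm = grid,
                      stringsAsFactors = FALSE)
  base$thickness_um <- 300 + as.integer(factor(base$eye_id))
  ta <- transform(base, device = "A", visit = 1, layer_pair = "RETINA")
  tb <- transform(base, device = "B", visit = 1, layer_pair = "RETINA")

  res0 <- per_point_compare(rbind(ta, tb), "A", "B")
  expect_true(all(vapply(res0$per_offset, function(r) r$mean_diff,
                         numeric(1)) == 0))
  expect_equal(res0$pooled$mean_diff, 0)

  tb2 <- tb; tb2$thickness_um <- tb2$thickness_um + 1.85
  res <- per_point_compare(rbind(ta, tb2), "A", "B")
  expect_equal(res$pooled$mean_diff, 1.85, tolerance = 1e-12)
  expect_equal(res$pooled$n, 8L)

  # a missing pair is dropped listwise for its offset only
  tb3 <- tb2
  tb3$thickness_um[tb3$eye_id == "e01" & tb3$offset_mm == -1] <- NA
  res3 <- per_point_compare(rbind(ta, tb3), "A", "B")
  expect_equal(res3$per_offset[["-1.0"]]$n, 7L)
  expect_equal(res3$per_offset[["0.0"]]$n, 8L)

  expect_error(per_point_compare(rbind(ta, tb)[0, ], "A", "B"), "common")
})

test_that("pooled bias recovery from a noisy synthetic cohort", {
  set.seed(31)
  grid <- seq(-3, 3, 0.5)
  rows <- list()
  for (i in 1:37) {
    anat <- 300 + rnorm(1, 0, 17)
    profile <- anat + 20 * abs(grid) / 3
    a <- profile + rnorm(13, 0, 7.5)
    b <- profile + 1.85 + rnorm(13, 0, 7.5)
    rows[[i]] <- rbind(
      data.frame(eye_id = sprintf("e%02d", i), device = "A", visit = 1,
                 layer_pair = "RETINA", offset_mm = grid, thickness_um = a),
      data.frame(eye_id = sprintf("e%02d", i), device = "B", visit = 1,
                 layer_pair = "RETINA", offset_mm = grid, thickness_um = b))
  }
  res <- per_point_compare(do.call(rbind, rows), "A", "B")
  se <- res$pooled$sd_diff / sqrt(res$pooled$n)
  expect_lt(abs(res$pooled$mean_diff - 1.85), 2 * se + 1e-12)
})

test_that("summary tables carry the B - A convention through", {
  set.seed(5)
  a <- rnorm(10, 300, 10); b <- a + rnorm(10, 2, 3)
  res <- list(fovea = paired_compare(a, b, label_a = "Cirrus",
                                     label_b = "Spectralis"),
              line1mm = paired_compare(a + 50, b + 50),
              allpoints = paired_compare(a + 70, b + 70))
  tab <- summary_table(res)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$level, c("fovea", "line1mm", "allpoints"))
  expect_equal(tab$difference, tab$mean_b - tab$mean_a, tolerance = 1e-12)
  expect_named(tab, c("level", "mean_a", "sd_a", "mean_b", "sd_b",
                      "difference", "pct_difference", "p_value"))
  expect_error(summary_table(list()), "no results")
})

test_that("difference-table arithmetic reproduces printed-style summaries", {
  tab <- device_difference_table(
    level = c("foveal_center", "line_1mm", "all_points"),
    mean_a = c(225.92, 280.37, 301.10), sd_a = c(17.02, 17.90, 39.07),
    mean_b = c(228.70, 282.15, 302.95), sd_b = c(18.42, 18.40, 38.57))
  expect_equal(tab$difference, c(2.78, 1.78, 1.85), tolerance = 1e-9)
  expect_equal(round(tab$pct_difference[1:2], 2), c(1.22, 0.63))
})

test_that("thickness tables round trip through CSV", {
  df <- data.frame(eye_id = "e1", device = "A", visit = 1,
                   layer_pair = "RETINA", offset_mm = 0, thickness_um = 250)
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  back <- read_thickness_table(f)
  expect_equal(back$thickness_um, 250)
  df2 <- df; df2$thickness_um <- NULL
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_thickness_table(f), "thickness_um")
  unlink(f)
})
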