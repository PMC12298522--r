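test_that("noiseless points recover curve parameters exactly", {
  x <- rep(3:8, each = 3)
  pts <- data.frame(x = x, cq = -3.347 * x + 44.17)
  cv <- fit_standard_curve(pts)
  expect_equal(cv$slope, -3.347, tolerance = 1e-9)
  expect_equal(cv$intercept, 44.17, tolerance = 1e-9)
  expect_equal(cv$r2, 1.0, tolerance = 1e-9)

  pts2 <- data.frame(x = 1:6, cq = -3.311 * (1:6) + 20)
  expect_equal(fit_standard_curve(pts2)$efficiency_pct, 100.46)

  expect_error(fit_standard_curve(data.frame(x = rep(5, 4), cq = 1:4)),
               "distinct")
  expect_error(fit_standard_curve(data.frame(x = c(1, 2), cq = c(1, 2))),
               "distinct")
})

test_that("slope-to-efficiency conversion matches published calculator values", {
  expect_equal(efficiency_from_slope(-3.311), 100.46)
  expect_equal(efficiency_from_slope(-3.370), 98.03)
  # a slope of one log10 per doubling cycle count is 100% efficiency
  expect_equal(efficiency_from_slope(-1 / log10(2)), 100.00)
  expect_error(efficiency_from_slope(3.3), "negative")
  # efficiency -> slope -> efficiency is the identity on (50, 150)
  for (e in seq(50, 150, by = 7.5))
    expect_equal(efficiency_from_slope(slope_from_efficiency(e), digits = 8L),
                 e, tolerance = 1e-6)
})

test_that("positivity is a strict threshold with NA treated as negative", {
  expect_true(all(is_positive(c(19.25, 19.27, 19.07))))
  expect_false(is_positive(35.0))
  expect_false(is_positive(NA_real_))
  expect_true(is_positive(34.999))
  expect_false(is_positive(36, threshold = 35))
  expect_true(is_positive(36, threshold = 40))
})

test_that("curve inversion is exact and round-trips with prediction", {
  cv <- standard_curve(-3.347, 44.17)
  expect_equal(cq_to_log_density(cv, 44.17), 0)
  expect_equal(cq_to_log_density(cv, 20.75), (20.75 - 44.17) / -3.347,
               tolerance = 1e-12)
  expect_equal(round(cq_to_log_density(cv, 20.75), 4), 6.9973)
  for (x in seq(-2, 9, by = 0.7))
    expect_equal(cq_to_log_density(cv, predict(cv, x)), x, tolerance = 1e-9)
})

test_that("the CFU/g formula obeys its arithmetic identities", {
  r <- cfu_per_gram(x = 7, A = 25, B = 225, C = 10)
  expect_equal(r$M, 1e9)
  expect_equal(r$log10_M, 9.00)
  expect_equal(cfu_per_gram(0, 1, 0, 1)$M, 1)
  expect_equal(cfu_per_gram(5, 25, 225, 1)$M, 1e6)
  # linear in the dilution factor and in the measured density
  base <- cfu_per_gram(4.3, 25, 225, 2)$M
  expect_equal(cfu_per_gram(4.3, 25, 225, 6)$M, 3 * base)
  expect_equal(cfu_per_gram(4.3 + 1, 25, 225, 2)$M, 10 * base)
  expect_error(cfu_per_gram(5, 0, 225, 1), "mass")
  expect_error(cfu_per_gram(5, 25, -1, 1), ">= 0")
})

test_that("replicate statistics reproduce the passage-stability table", {
  groups <- list(`5` = c(18.88, 18.78, 18.98),
                 `15` = c(18.92, 18.86, 18.27),
                 `25` = c(18.73, 18.38, 18.89),
                 `35` = c(17.98, 18.4, 18.5))
  st <- replicate_stats(groups)
  expect_equal(round(st$group_means, 2),
               c(`5` = 18.88, `15` = 18.68, `25` = 18.67, `35` = 18.29))
  expect_equal(round(st$sd_of_group_means, 2), 0.24)
  expect_equal(round(st$rsd_pct, 2), 1.31)
  # the SD of the raw values is a different (larger) quantity
  expect_gt(stats::sd(unlist(groups)), st$sd_of_group_means)

  ident <- replicate_stats(list(a = rep(19, 3), b = rep(19, 3)))
  expect_equal(ident$sd_of_group_means, 0)
  expect_equal(ident$rsd_pct, 0)

  single <- replicate_stats(list(only = c(20.1, 20.3, 20.2)))
  expect_true(single$sd_undefined)
  expect_equal(single$pooled_sd, stats::sd(c(20.1, 20.3, 20.2)))
  expect_error(replicate_stats(list(a = numeric())), "non-empty")
})

test_that("the detection limit is the monotone positivity frontier", {
  mk <- function(...) {
    v <- list(...)
    stats::setNames(v, as.character(8:(8 - length(v) + 1)))
  }
  ladder <- mk(rep(TRUE, 3), rep(TRUE, 3), rep(TRUE, 3), rep(TRUE, 3),
               rep(TRUE, 3), rep(TRUE, 3))
  ladder[["2"]] <- rep(FALSE, 3)
  expect_equal(detection_limit(ladder)$x_min, 3)

  none <- list(`5` = rep(FALSE, 3), `4` = rep(FALSE, 3))
  res <- detection_limit(none)
  expect_false(res$defined)
  expect_true(is.na(res$x_min))

  dropout <- mk(rep(TRUE, 3), rep(TRUE, 3), rep(TRUE, 3),
                c(TRUE, FALSE, TRUE), rep(TRUE, 3), rep(TRUE, 3))
  expect_warning(res2 <- detection_limit(dropout), "conservative")
  expect_equal(res2$x_min, 6)
  expect_true(res2$non_monotone)
})

test_that("fitting simulated dilution ladders recovers the parameters", {
  truth <- standard_curve(-3.347, 44.17)
  # exact recovery without noise
  pts0 <- simulate_cq(truth, levels = 3:8, reps = 3, noise_sd = 0,
                      seed = 10)
  cv0 <- fit_standard_curve(pts0)
  expect_equal(cv0$slope, truth$slope, tolerance = 1e-9)
  expect_equal(cv0$intercept, truth$intercept, tolerance = 1e-9)
  # noisy recovery within 3 standard errors, across seeded trials
  misses <- 0L
  for (seed in 1:100) {
    pts <- simulate_cq(truth, levels = 3:8, reps = 3, noise_sd = 0.15,
                       seed = seed)
    fit <- stats::lm(cq ~ x, data = pts)
    se <- summary(fit)$coefficients["x", "Std. Error"]
    cv <- fit_standard_curve(pts)
    if (abs(cv$slope - truth$slope) > 3 * se) misses <- misses + 1L
  }
  expect_lte(misses, 2L)  # ~0.3% expected exceedance rate at 3 SE
})

test_that("sample quantification composes inversion and the CFU formula", {
  cv <- standard_curve(-3.347, 44.17)
  cq <- predict(cv, 7) + c(-0.01, 0, 0.01)
  res <- quantify_sample(cv, cq, A = 25, B = 225, C = 10)
  expect_equal(res$x, 7, tolerance = 1e-6)
  expect_equal(res$log10_M, 9.00)
  expect_true(res$all_positive)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = rep(5, 3), cq = cq), f, row.names = FALSE)
  tab <- read_cq_table(f)
  expect_equal(nrow(tab), 3L)
})
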