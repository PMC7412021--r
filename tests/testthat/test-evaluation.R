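test_that("Pearson screening matches direct computation and flags significance", {
  set.seed(12)
  n <- 30
  gsv <- tibble::tibble(plot_id = sprintf("p%02d", 1:n),
                        gsv = runif(n, 60, 450))
  feats <- fuse_powers(tibble::tibble(
    plot_id = gsv$plot_id, acquisition = "1",
    odd = exp(-1 - 0.003 * gsv$gsv + rnorm(n, 0, 0.4)),
    dbl = 2 * gsv$gsv + 1,                      # exact linear: gamma = 1
    vol = rep(1, n), hlx = 0.01                 # vol: zero variance
  ))
  ct <- pearson_table(feats, gsv)
  expect_equal(ct$gamma[ct$feature == "dbl"], 1, tolerance = 1e-12)
  expect_true(ct$significant[ct$feature == "dbl"])
  expect_equal(ct$gamma[ct$feature == "odd"],
               cor(feats$odd, gsv$gsv), tolerance = 1e-12)
  # zero-variance feature reported missing
  expect_true(is.na(ct$gamma[ct$feature == "vol"]))
})

test_that("critical correlation values come from the t distribution", {
  # frozen from t = qt(0.995, 18) = 2.8784: r* = t/sqrt(t^2 + 18)
  expect_equal(critical_r(20, 0.01), 0.5614, tolerance = 1e-4)
  expect_equal(critical_r(50, 0.01), 0.3610, tolerance = 1e-4)
  # independent variables at large n stay below the critical value
  set.seed(77)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(abs(cor(x, y)), 0.05)
})

test_that("metrics match hand arithmetic and are scale invariant", {
  m <- gsv_metrics(c(100, 200), c(110, 190))
  expect_equal(m$rmse, 10)
  expect_equal(m$rrmse, 100 * 10 / 150, tolerance = 1e-12)
  perf <- gsv_metrics(c(50, 150, 300), c(50, 150, 300))
  expect_equal(unlist(perf[1, c("rmse", "rrmse", "r2")]),
               c(rmse = 0, rrmse = 0, r2 = 1))
  set.seed(3)
  o <- runif(20, 100, 400); p <- o + rnorm(20, 0, 30)
  m1 <- gsv_metrics(o, p); m2 <- gsv_metrics(3 * o, 3 * p)
  expect_equal(m1$rrmse, m2$rrmse, tolerance = 1e-12)
  expect_equal(m1$r2, m2$r2, tolerance = 1e-12)
  # brute-force formula agreement
  expect_equal(m1$rmse, sqrt(sum((p - o)^2) / 20), tolerance = 1e-12)
  expect_equal(m1$r2, cor(o, p)^2, tolerance = 1e-12)
  # alternative R2 definition exposed behind a flag
  expect_equal(gsv_metrics(o, p, r2_method = "ess")$r2,
               1 - sum((p - o)^2) / sum((o - mean(o))^2), tolerance = 1e-12)
})

test_that("exceedance counts relative errors over the threshold", {
  o <- c(100, 100, 100, 100)
  p <- c(100, 110, 90, 160)          # one plot off by 60%
  expect_equal(exceedance(o, p, 0.5), 0.25)
  expect_equal(exceedance(o, o, 0.5), 0)
  expect_equal(exceedance(o, p, 1e9), 0)
  expect_message(got <- exceedance(c(0, 100), c(10, 160), 0.5), "excluded")
  expect_equal(got, 1)
  expect_error(exceedance(o, p, -0.1), "threshold_rel")
})

test_that("LOOCV refits per fold, preserves order, and is exact on clean data", {
  cfg <- noise_free_config(n_plots = 12, seed = 5)
  sc <- sim_scene(cfg)
  d <- sc$features |>
    dplyr::filter(.data$acquisition == "1") |>
    dplyr::inner_join(sc$plots[, c("plot_id", "gsv")], by = "plot_id")
  cv <- loocv_gsv(d, sigma = "dbl", gsv = "gsv", model = "glm")
  expect_equal(nrow(cv), nrow(d))
  expect_equal(cv$predicted, d$gsv, tolerance = 1e-8)
  expect_lt(gsv_metrics(cv$observed, cv$predicted)$rmse, 1e-6)
  # permuting plots permutes predictions identically
  idx <- sample(nrow(d))
  cv2 <- loocv_gsv(d[idx, ], sigma = "dbl", gsv = "gsv", model = "glm")
  expect_equal(cv2$predicted, cv$predicted[idx], tolerance = 1e-10)
  expect_equal(cv2$plot_id, cv$plot_id[idx])
})

test_that("LOOCV with the semi-exponential model recovers curve data", {
  d <- semiexp_curve(beta_n = 0.22, beta_s = 0.04, k = 120,
                     gsv = seq(10, 400, 30))
  d$plot_id <- sprintf("p%02d", seq_len(nrow(d)))
  cv <- loocv_gsv(d, sigma = "sigma", gsv = "gsv", model = "semiexp")
  expect_true(all(cv$fold_ok))
  expect_equal(cv$predicted, d$gsv, tolerance = 1e-3)
})

test_that("single-image correlation aggregation reproduces published values", {
  rc <- reference_correlations()
  singles <- as.character(1:4)
  agg <- aggregate_correlations(rc, sources = singles, rule = "all")
  expect_equal(agg$mean_gamma[agg$feature == "odd"], -0.469)
  expect_equal(agg$mean_gamma[agg$feature == "dbl"], 0.511)
  expect_equal(agg$mean_gamma[agg$feature == "dbl_odd"], -0.476)
  expect_equal(agg$mean_gamma[agg$feature == "vol_odd"], -0.519)
  expect_equal(agg$mean_gamma[agg$feature == "dblxvol"], -0.510)
  expect_equal(agg$mean_gamma[agg$feature == "dblxvol_odd"], 0.507)
  sig <- aggregate_correlations(rc, sources = singles,
                                rule = "significant_only")
  expect_equal(sig$mean_gamma[sig$feature == "vol"], 0.399)
  expect_equal(sig$n_used[sig$feature == "vol"], 2)
  expect_error(aggregate_correlations(rc, sources = "99"), "no rows")
})

test_that("half-up rounding matches published-table conventions", {
  expect_equal(round_half_up(0.5065, 3), 0.507)
  expect_equal(round_half_up(-0.5095, 3), -0.510)
  expect_equal(round_half_up(0.3985, 3), 0.399)
  expect_equal(round_half_up(c(2.5, -2.5), 0), c(3, -3))
})
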