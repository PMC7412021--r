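test_that("GLM recovers exact log-linear parameters and inverts algebraically", {
  g <- c(0, 100, 200)
  d <- tibble::tibble(gsv = g, p = exp(1 - 0.01 * g))
  fit <- suppressWarnings(fit_gsv_glm(d, sigma = "p", gsv = "gsv"))
  expect_equal(coef(fit), c(a0 = 1, a1 = -0.01), tolerance = 1e-10)
  # hand algebra: sigma = e^-1 -> GSV = (−1 − 1)/(−0.01) = 200
  expect_equal(invert_gsv(fit, exp(-1)), 200, tolerance = 1e-10)
  # sigma = e^{a0} -> GSV = 0
  expect_equal(invert_gsv(fit, exp(fit$a0)), 0, tolerance = 1e-12)
  # round trip at arbitrary GSV
  gg <- c(17.3, 254.9, 431.1)
  expect_equal(invert_gsv(fit, exp(fit$a0 + fit$a1 * gg)), gg,
               tolerance = 1e-12)
})

test_that("GLM fit is permutation invariant and handles degenerate input", {
  set.seed(9)
  d <- tibble::tibble(gsv = runif(20, 50, 450))
  d$p <- exp(-2 + 0.003 * d$gsv + rnorm(20, 0, 0.3))
  f1 <- fit_gsv_glm(d, "p", "gsv")
  f2 <- fit_gsv_glm(d[sample(20), ], "p", "gsv")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  # constant sigma: a1 = 0, a0 = ln sigma — then inversion must refuse
  dc <- tibble::tibble(gsv = c(0, 100, 200), p = rep(2.5, 3))
  fc <- suppressWarnings(fit_gsv_glm(dc, "p", "gsv"))
  expect_equal(coef(fc), c(a0 = log(2.5), a1 = 0), tolerance = 1e-10)
  expect_error(invert_gsv(fc, 1), "a1 = 0")
  expect_error(fit_gsv_glm(tibble::tibble(gsv = rep(100, 5), p = 1:5),
                           "p", "gsv"), "identical")
  expect_error(suppressMessages(
    fit_gsv_glm(tibble::tibble(gsv = 1:5, p = c(-1, 0, 1, -2, 2)),
                "p", "gsv")), "at least 3")
})

test_that("non-positive powers are excluded with a reported count", {
  d <- tibble::tibble(gsv = c(0, 50, 100, 150, 200),
                      p = c(1, -0.1, exp(-0.5), 0, exp(-1)))
  expect_message(fit <- fit_gsv_glm(d, "p", "gsv"), "excluding 2")
  expect_equal(fit$n_excluded, 2)
  expect_equal(fit$n, 3)
  # inversion maps non-positive sigma to NA, not an error
  expect_true(is.na(invert_gsv(fit, -1)))
})

test_that("semi-exponential fit recovers generator parameters on clean data", {
  d <- semiexp_curve(beta_n = 0.20, beta_s = 0.05, k = 100)
  fit <- fit_gsv_semiexp(d, sigma = "sigma", gsv = "gsv")
  expect_true(fit$converged)
  expect_equal(fit$beta_n, 0.20, tolerance = 1e-6)
  expect_equal(fit$beta_s, 0.05, tolerance = 1e-6)
  expect_equal(fit$k, 100, tolerance = 1e-6)
  # model identities: sigma(0) = beta_n; asymptote = beta_s
  expect_equal(predict(fit, 0), fit$beta_n, tolerance = 1e-9)
  expect_equal(predict(fit, 1e9), fit$beta_s, tolerance = 1e-9)
  # increasing orientation (positive-correlation feature) also recovers
  d2 <- semiexp_curve(beta_n = 0.02, beta_s = 0.30, k = 150)
  fit2 <- fit_gsv_semiexp(d2, "sigma", "gsv")
  expect_equal(coef(fit2), c(beta_n = 0.02, beta_s = 0.30, k = 150),
               tolerance = 1e-6)
})

test_that("semi-exponential inversion saturates and floors as specified", {
  d <- semiexp_curve(beta_n = 0.20, beta_s = 0.05, k = 100)
  fit <- fit_gsv_semiexp(d, "sigma", "gsv")
  # sigma = beta_n -> 0; sigma at e^{-1} point -> k
  expect_equal(as.numeric(invert_gsv(fit, fit$beta_n)), 0, tolerance = 1e-6)
  sig_k <- fit$beta_s + (fit$beta_n - fit$beta_s) * exp(-1)
  expect_equal(as.numeric(invert_gsv(fit, sig_k)), fit$k, tolerance = 1e-6)
  # at/beyond the asymptote -> gsv_cap, flagged
  out <- invert_gsv(fit, c(fit$beta_s, 0.01), gsv_cap = 500)
  expect_equal(as.numeric(out), c(500, 500))
  expect_true(all(attr(out, "saturated")))
  # beyond the zero-GSV value -> 0, flagged
  out2 <- invert_gsv(fit, 0.25)
  expect_equal(as.numeric(out2), 0)
  expect_true(attr(out2, "floored"))
})

test_that("GLM inversion is unbounded while semi-exponential is capped", {
  set.seed(31)
  g <- runif(40, 60, 450)
  sig <- exp(-2.5 + 0.0035 * g + rnorm(40, 0, 0.3))
  dg <- tibble::tibble(gsv = g, p = sig)
  glm_fit <- fit_gsv_glm(dg, "p", "gsv")
  se_fit <- fit_gsv_semiexp(dg, "p", "gsv")
  big_sigma <- exp(glm_fit$a0 + glm_fit$a1 * c(1e3, 1e4, 1e5))
  expect_equal(invert_gsv(glm_fit, big_sigma), c(1e3, 1e4, 1e5),
               tolerance = 1e-9)                      # no finite ceiling
  extreme <- if (se_fit$beta_s > se_fit$beta_n) 1e6 else se_fit$beta_s
  capped <- invert_gsv(se_fit, extreme, gsv_cap = 500)
  expect_lte(as.numeric(capped), 500)                 # finite ceiling
})

test_that("slope estimate is unbiased across stochastic replicates", {
  a1_true <- 0.0035
  est <- purrr::map_dbl(1:200, function(s) {
    set.seed(s)
    g <- runif(50, 60, 450)
    sig <- exp(-2.5 + a1_true * g + rnorm(50, 0, 0.45))
    fit_gsv_glm(sigma = sig, gsv = g)$a1
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(median(est) - a1_true), 2 * mc_se * sqrt(pi / 2))
})

test_that("tidy and glance summarise fits in rectangular form", {
  d <- semiexp_curve()
  fit <- fit_gsv_semiexp(d, "sigma", "gsv", feature = "dbl")
  td <- tidy(fit)
  expect_equal(td$term, c("beta_n", "beta_s", "k"))
  gl <- glance(fit)
  expect_equal(gl$model, "semiexp")
  expect_true(gl$converged)
  dg <- tibble::tibble(gsv = c(0, 100, 200, 300),
                       p = exp(1 - 0.01 * c(0, 100, 200, 300)))
  fg <- suppressWarnings(fit_gsv_glm(dg, "p", "gsv"))
  expect_equal(tidy(fg)$estimate, c(1, -0.01), tolerance = 1e-10)
  expect_equal(glance(fg)$n, 4)
})
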