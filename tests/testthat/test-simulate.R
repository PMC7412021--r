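test_that("seeded scene generation is bit-reproducible", {
  cfg <- scene_config(n_plots = 10, seed = 1)
  s1 <- sim_scene(cfg)
  s2 <- sim_scene(cfg)
  expect_identical(s1$plots, s2$plots)
  expect_identical(s1$trees, s2$trees)
  expect_identical(s1$features, s2$features)
  # different seed changes the draw
  s3 <- sim_scene(scene_config(n_plots = 10, seed = 2))
  expect_false(identical(s1$plots$gsv, s3$plots$gsv))
})

test_that("tree lists reproduce each plot's true GSV within 1%", {
  sc <- sim_plots(scene_config(n_plots = 20, seed = 8))
  recon <- plots_gsv(sc$plots[, c("plot_id", "side_m")], sc$trees,
                     taper_constant(0.45))
  expect_true(all(abs(recon$gsv - sc$plots$gsv) / sc$plots$gsv < 0.01))
  expect_true(all(sc$trees$dbh_cm >= 5))
  # heights follow a monotone DBH-height curve
  ord <- order(sc$trees$dbh_cm)
  expect_true(all(diff(sc$trees$height_m[ord]) >= 0))
})

test_that("constant GSV law is honoured; degenerate multi-stratum law refused", {
  const <- scene_config(
    n_plots = 5,
    gsv_strata = tibble::tibble(stratum = "c", weight = 1,
                                min = 100, max = 100),
    seed = 4)
  sc <- sim_plots(const)
  expect_true(all(sc$plots$gsv == 100))
  recon <- plots_gsv(sc$plots[, c("plot_id", "side_m")], sc$trees,
                     taper_constant(0.45))
  expect_true(all(recon$gsv >= 99 & recon$gsv <= 101))
  degen <- scene_config(
    n_plots = 5,
    gsv_strata = tibble::tibble(stratum = c("a", "b"), weight = c(0.5, 0.5),
                                min = c(100, 200), max = c(100, 200)),
    seed = 4)
  expect_error(sim_plots(degen), "degenerate")
})

test_that("sampled GSV matches the mixture law moments", {
  cfg <- scene_config(n_plots = 50, seed = 21)
  mom <- gsv_law_moments(cfg$gsv_strata)
  # average over replicates: sample mean within 3 SE of the law mean
  means <- purrr::map_dbl(1:40, function(s) {
    mean(sim_plots(scene_config(n_plots = 50, seed = s))$plots$gsv)
  })
  se <- sqrt(mom$var / 50)
  expect_lt(abs(mean(means) - mom$mean), 3 * se / sqrt(length(means)))
  expect_true(all(abs(means - mom$mean) < 5 * se))
})

test_that("noise-free powers are exactly log-linear in GSV", {
  cfg <- noise_free_config(n_plots = 8, seed = 13)
  sc <- sim_scene(cfg)
  one <- dplyr::filter(sc$features, .data$acquisition == "1")
  d <- dplyr::inner_join(one, sc$plots[, c("plot_id", "gsv")], by = "plot_id")
  law <- cfg$power_law
  for (ch in c("odd", "dbl", "vol")) {
    row <- law[law$feature == ch, ]
    expect_equal(log(d[[ch]]), row$a0_true + row$a1_true * d$gsv,
                 tolerance = 1e-12)
  }
  # closed form: a0=1, a1=-0.01, GSV=100, no noise -> sigma = e^0 = 1
  cfg2 <- scene_config(
    n_plots = 3,
    gsv_strata = tibble::tibble(stratum = "c", weight = 1, min = 100, max = 100),
    power_law = tibble::tibble(feature = c("odd", "dbl", "vol", "hlx"),
                               a0_true = 1, a1_true = -0.01),
    noise_sd = 0,
    acquisitions = list(acquisition_meta("1")),
    seed = 1)
  f <- sim_powers(sim_plots(cfg2)$plots, cfg2)
  expect_equal(f$dbl, rep(1, 3), tolerance = 1e-12)
})

test_that("configured slope signs show up as correlation signs", {
  cfg <- scene_config(n_plots = 200, noise_sd = 0.1,
                      acquisitions = list(acquisition_meta("1")), seed = 17)
  sc <- sim_scene(cfg)
  d <- dplyr::inner_join(sc$features, sc$plots[, c("plot_id", "gsv")],
                         by = "plot_id")
  expect_gt(cor(d$dbl, d$gsv), 0)
  expect_lt(cor(d$odd, d$gsv), 0)
  expect_gt(cor(d$vol, d$gsv), 0)
})

test_that("coherency simulation honours the span and speckle converges with looks", {
  p <- tibble::tibble(odd = 1.2, dbl = 0.4, vol = 0.8, hlx = 0.1)
  t3 <- sim_t3(p)[[1]]
  expect_equal(Re(sum(diag(t3))), 2.5, tolerance = 1e-12)
  expect_error(sim_t3(tibble::tibble(odd = -1, dbl = 0, vol = 0, hlx = 0)),
               "nonnegative")
  # multilook draws: unbiased, trace concentrates as looks grow
  many <- sim_t3(p[rep(1, 200), ], looks = 64, seed = 5)
  traces <- purrr::map_dbl(many, ~ Re(sum(diag(.x))))
  expect_equal(mean(traces), 2.5, tolerance = 0.05)
  # trace of an L-look draw has variance sum(lambda^2)/L ~ 0.047 here
  expect_lt(sd(traces), 0.3)
  # Hermitian draws decompose without error
  dec <- suppressMessages(yamaguchi4(many[1:20]))
  expect_equal(dec$span, traces[1:20], tolerance = 1e-10)
})

test_that("temporally averaged Dbl correlates better than single images in most replicates", {
  wins <- purrr::map_lgl(1:200, function(s) {
    cfg <- scene_config(
      n_plots = 50, noise_sd = 0.45,
      acquisitions = purrr::map(as.character(1:4), acquisition_meta),
      seed = s)
    sc <- sim_scene(cfg)
    d <- dplyr::inner_join(sc$features, sc$plots[, c("plot_id", "gsv")],
                           by = "plot_id")
    singles <- purrr::map_dbl(split(d, d$acquisition),
                              ~ cor(.x$dbl, .x$gsv))
    avg <- temporal_average(sc$features, as.character(1:4))
    avg <- dplyr::inner_join(avg, sc$plots[, c("plot_id", "gsv")],
                             by = "plot_id")
    cor(avg$dbl, avg$gsv) > mean(singles)
  })
  expect_gte(mean(wins), 0.9)
})

test_that("more noise never helps the expected correlation", {
  mean_abs_cor <- function(noise_sd) {
    mean(purrr::map_dbl(1:30, function(s) {
      cfg <- scene_config(n_plots = 50, noise_sd = noise_sd,
                          acquisitions = list(acquisition_meta("1")),
                          seed = 1000 + s)
      sc <- sim_scene(cfg)
      d <- dplyr::inner_join(sc$features, sc$plots[, c("plot_id", "gsv")],
                             by = "plot_id")
      abs(cor(d$dbl, d$gsv))
    }))
  }
  cors <- purrr::map_dbl(c(0.2, 0.4, 0.8), mean_abs_cor)
  expect_true(all(diff(cors) < 0))
})

test_that("generator refuses invalid configuration", {
  expect_error(scene_config(n_plots = 2), "n_plots")
  expect_error(scene_config(noise_sd = -1), "noise_sd")
  expect_error(scene_config(looks = 0.5), "looks")
  expect_error(acquisition_meta("1", bias = c(foo = 1)), "subset")
  expect_error(acquisition_meta("1", extra_noise_sd = -0.1),
               "extra_noise_sd")
})
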