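#' Acquisition metadata for the synthetic scene
#'
#' One SAR acquisition within the growing season. `bias` is a
#' per-characteristic offset on the log-power scale representing
#' acquisition-level disturbance (ground moisture after rain, wind moving
#' the canopy); `extra_noise_sd` is additional log-power noise specific to
#' the acquisition. No meteorological model is attempted — disturbance is
#' abstract bias + noise.
#'
#' @param label acquisition label (e.g. `"1"`).
#' @param bias named numeric, offsets for `odd`, `dbl`, `vol`, `hlx`
#'   (missing names default to 0).
#' @param extra_noise_sd nonnegative additional log-noise SD.
#' @return A list of class `acquisition_meta`.
#' @export
acquisition_meta <- function(label, bias = c(), extra_noise_sd = 0) {
  assert_scalar_number(extra_noise_sd, "extra_noise_sd", min = 0)
  full <- setNames(numeric(4), base_power_names())
  if (length(bias)) {
    if (is.null(names(bias)) || !all(names(bias) %in% names(full))) {
      abort("bias must be named with a subset of odd, dbl, vol, hlx")
    }
    if (any(!is.finite(bias))) abort("bias must be finite")
    full[names(bias)] <- bias
  }
  structure(list(label = as.character(label), bias = full,
                 extra_noise_sd = extra_noise_sd),
            class = "acquisition_meta")
}

default_acquisitions <- function() {
  # one dry reference image, two post-rain images (wetter ground, noisier),
  # one windier late-season image — four acquisitions June-September
  list(
    acquisition_meta("1", extra_noise_sd = 0),
    acquisition_meta("2", bias = c(odd = 0.15, dbl = -0.10, vol = 0.05),
                     extra_noise_sd = 0.20),
    acquisition_meta("3", bias = c(odd = 0.10, dbl = -0.05, vol = 0.05),
                     extra_noise_sd = 0.25),
    acquisition_meta("4", bias = c(odd = -0.05, dbl = 0.05),
                     extra_noise_sd = 0.10)
  )
}

default_power_law <- function() {
  # log-linear power-GSV relations; signs follow the field pattern for
  # L-band over conifer plantation: surface return falls with stocking,
  # double-bounce rises, volume rises weakly, helix is negligible
  tibble::tibble(
    feature = base_power_names(),
    a0_true = c(-1.0, -2.5, -1.5, -5.0),
    a1_true = c(-0.0030, 0.0035, 0.0015, 0.0)
  )
}

default_gsv_strata <- function() {
  # young / immature / mature strata of a managed fir plantation
  tibble::tibble(
    stratum = c("young", "immature", "mature"),
    weight = c(0.10, 0.52, 0.38),
    min = c(60, 150, 300),
    max = c(150, 300, 450)
  )
}

#' Synthetic scene configuration
#'
#' Bundles every knob of the generator: number of plots, the GSV law (a
#' mixture of uniform age-class strata), the per-characteristic log-linear
#' power law `ln(sigma) = a0_true + a1_true * GSV`, the shared log-noise
#' SD, the acquisitions with their disturbance terms, optional multilook
#' speckle, and the root seed (all randomness derives from it through
#' fixed per-operation streams).
#'
#' @param n_plots number of plots (>= 3).
#' @param gsv_strata tibble with `weight`, `min`, `max` rows defining the
#'   GSV mixture (m3/ha); default three strata spanning 60-450.
#' @param power_law tibble `feature`, `a0_true`, `a1_true`.
#' @param noise_sd shared additive log-power noise SD (>= 0).
#' @param acquisitions list of [acquisition_meta()].
#' @param looks equivalent number of looks for speckle in coherency-matrix
#'   simulation, or `NULL` to disable (plot-level tables assume the
#'   spatial averaging has already made noise approximately log-normal).
#' @param side_m plot side length(s), m, recycled over plots.
#' @param shadow_frac fraction of plots flagged as radar shadow.
#' @param seed root integer seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_plots = 50,
                         gsv_strata = default_gsv_strata(),
                         power_law = default_power_law(),
                         noise_sd = 0.45,
                         acquisitions = default_acquisitions(),
                         looks = NULL,
                         side_m = 30,
                         shadow_frac = 0,
                         seed = 1) {
  if (n_plots < 3) abort("n_plots must be >= 3")
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  if (!is.null(looks)) assert_scalar_number(looks, "looks", min = 1)
  gsv_strata <- tibble::as_tibble(gsv_strata)
  if (any(gsv_strata$max < gsv_strata$min)) {
    abort("gsv_strata max must be >= min")
  }
  width <- sum(gsv_strata$weight * (gsv_strata$max - gsv_strata$min))
  if (width == 0 && n_plots > 1 && nrow(gsv_strata) == 1) {
    # zero-width law is allowed only as an explicit constant-GSV scene
    if (gsv_strata$min[1] != gsv_strata$max[1]) abort("invalid gsv_strata")
  }
  power_law <- tibble::as_tibble(power_law)
  if (!all(base_power_names() %in% power_law$feature)) {
    abort("power_law must cover odd, dbl, vol, hlx")
  }
  structure(list(
    n_plots = as.integer(n_plots), gsv_strata = gsv_strata,
    power_law = power_law, noise_sd = noise_sd,
    acquisitions = acquisitions, looks = looks,
    side_m = side_m, shadow_frac = shadow_frac,
    seed = as.integer(seed)
  ), class = "scene_config")
}

draw_gsv <- function(n, strata) {
  w <- strata$weight / sum(strata$weight)
  idx <- sample.int(nrow(strata), n, replace = TRUE, prob = w)
  runif(n, strata$min[idx], strata$max[idx])
}

#' Mean and variance of the configured GSV law
#'
#' Closed-form moments of the uniform-mixture GSV distribution, used to
#' check generated samples against the law.
#'
#' @param strata strata tibble as in [scene_config()].
#' @return List with `mean` and `var`.
#' @export
gsv_law_moments <- function(strata) {
  w <- strata$weight / sum(strata$weight)
  m_k <- (strata$min + strata$max) / 2
  v_k <- (strata$max - strata$min)^2 / 12
  m <- sum(w * m_k)
  list(mean = m, var = sum(w * (v_k + m_k^2)) - m^2)
}

# Monotone DBH-height curve for plantation fir (dbh cm -> height m)
dbh_height <- function(dbh) 1.3 + 1.1 * dbh^0.85

# Stem volume of one synthetic tree at the generator's constant taper
synth_tree_volume <- function(dbh, f = 0.45) {
  pi * (dbh / 200)^2 * (dbh_height(dbh) + 3) * f
}

#' Generate synthetic plots with tree lists
#'
#' Draws each plot's true GSV from the configured mixture law, then builds
#' a tree list (DBH >= 5 cm, heights from a monotone DBH-height curve,
#' constant taper 0.45) whose summed stem volume reproduces the plot's
#' true GSV within 1%: trees are drawn from a stocking-dependent DBH
#' distribution until the target volume is nearly reached, and the last
#' tree is sized to close the remaining gap exactly. Runs with the same
#' config are bit-identical.
#'
#' @param config a [scene_config()].
#' @return List with `plots` (tibble: `plot_id`, `x`, `y`, `side_m`,
#'   `shadow`, `gsv`) and `trees` (tibble: `plot_id`, `dbh_cm`,
#'   `height_m`).
#' @export
sim_plots <- function(config) {
  strata <- config$gsv_strata
  width <- sum(strata$weight * (strata$max - strata$min))
  if (width == 0 && config$n_plots > 1 &&
      !(nrow(strata) == 1 && strata$min[1] == strata$max[1])) {
    abort("degenerate zero-width gsv law with multiple plots")
  }
  n <- config$n_plots
  withr::with_seed(stream_seed(config$seed, "plots"), {
    gsv <- draw_gsv(n, strata)
    side <- rep_len(config$side_m, n)
    shadow <- runif(n) < config$shadow_frac
    grid <- ceiling(sqrt(n))
    plots <- tibble::tibble(
      plot_id = sprintf("p%02d", seq_len(n)),
      x = ((seq_len(n) - 1) %% grid) * 500 + 250,
      y = ((seq_len(n) - 1) %/% grid) * 500 + 250,
      side_m = side, shadow = shadow, gsv = gsv
    )
  })
  trees <- withr::with_seed(stream_seed(config$seed, "trees"), {
    purrr::map_dfr(seq_len(n), function(i) {
      make_tree_list(plots$plot_id[i], plots$gsv[i], plots$side_m[i])
    })
  })
  list(plots = plots, trees = trees)
}

make_tree_list <- function(plot_id, gsv, side, f = 0.45) {
  target <- gsv * side^2 / 1e4          # plot stem volume, m3
  dbh_mean <- 8 + 22 * min(gsv / 450, 1)
  dbh <- numeric(0); cum <- 0
  repeat {
    d <- max(5, rnorm(1, dbh_mean, 0.15 * dbh_mean))
    v <- synth_tree_volume(d, f)
    if (cum + v > target) break
    dbh <- c(dbh, d); cum <- cum + v
    if (length(dbh) > 5000) abort("runaway tree list")
  }
  gap <- target - cum
  if (gap >= synth_tree_volume(5, f)) {
    d_fix <- stats::uniroot(function(d) synth_tree_volume(d, f) - gap,
                            c(5, 400), tol = 1e-10)$root
    dbh <- c(dbh, d_fix)
  }
  tibble::tibble(plot_id = plot_id, dbh_cm = dbh,
                 height_m = dbh_height(dbh))
}

#' Generate per-acquisition decomposition powers for the plots
#'
#' For each plot, acquisition and base characteristic the linear power is
#' `sigma = exp(a0_true + a1_true * GSV + bias + eps)` with
#' `eps ~ N(0, noise_sd^2 + extra_noise_sd^2)` — the same exponential
#' relation the retrieval GLM inverts, used generatively. Powers are
#' strictly positive by construction; with `noise_sd = 0` and zero bias
#' the log-power is exactly linear in GSV. Fused characteristics are
#' appended.
#'
#' @param plots plots tibble from [sim_plots()] (needs `plot_id`, `gsv`).
#' @param config a [scene_config()].
#' @return Feature tibble: `plot_id`, `acquisition`, base powers, fused
#'   features.
#' @export
sim_powers <- function(plots, config) {
  law <- config$power_law
  withr::with_seed(stream_seed(config$seed, "powers"), {
    out <- purrr::map_dfr(config$acquisitions, function(acq) {
      sds <- sqrt(config$noise_sd^2 + acq$extra_noise_sd^2)
      pw <- purrr::map(base_power_names(), function(ch) {
        row <- law[law$feature == ch, ]
        mu <- row$a0_true + row$a1_true * plots$gsv + acq$bias[[ch]]
        exp(mu + rnorm(nrow(plots), 0, sds))
      })
      names(pw) <- base_power_names()
      tibble::tibble(plot_id = plots$plot_id, acquisition = acq$label,
                     odd = pw$odd, dbl = pw$dbl, vol = pw$vol,
                     hlx = pw$hlx)
    })
  })
  fuse_powers(out)
}

#' Simulate coherency matrices from decomposition powers
#'
#' Reconstructs each row's T3 via [powers_to_t3()] and, when `looks` is
#' finite, replaces it with a multilook draw `Z = (1/L) sum k k^H`,
#' `k ~ CN(0, T)` — the complex-Wishart speckle model. `trace(T)` equals
#' the power sum exactly when speckle is disabled and in expectation
#' otherwise.
#'
#' @param powers tibble with columns `odd`, `dbl`, `vol`, `hlx`.
#' @param looks equivalent number of looks (`NULL` disables speckle).
#' @param seed integer seed for the speckle draws.
#' @return List of 3x3 complex Hermitian matrices, one per row.
#' @export
sim_t3 <- function(powers, looks = NULL, seed = 1) {
  base <- purrr::pmap(powers[base_power_names()], function(odd, dbl, vol, hlx) {
    powers_to_t3(odd, dbl, vol, hlx)
  })
  if (is.null(looks)) return(base)
  assert_scalar_number(looks, "looks", min = 1)
  withr::with_seed(stream_seed(seed, "speckle"), {
    purrr::map(base, wishart_draw, looks = as.integer(looks))
  })
}

wishart_draw <- function(t3, looks) {
  eig <- eigen(t3, symmetric = TRUE)
  lam <- pmax(Re(eig$values), 0)
  a <- eig$vectors %*% diag(sqrt(lam))
  z <- matrix(0 + 0i, 3, 3)
  for (j in seq_len(looks)) {
    k <- a %*% complex(real = rnorm(3, 0, sqrt(0.5)),
                       imaginary = rnorm(3, 0, sqrt(0.5)))
    z <- z + k %*% Conj(t(k))
  }
  z / looks
}

#' Simulate a whole scene
#'
#' Convenience wrapper: plots + tree lists + per-acquisition feature
#' table from one config.
#'
#' @param config a [scene_config()].
#' @return List with `plots`, `trees`, `features`, `config`.
#' @export
sim_scene <- function(config = scene_config()) {
  inv <- sim_plots(config)
  features <- sim_powers(inv$plots, config)
  list(plots = inv$plots, trees = inv$trees, features = features,
       config = config)
}

#' Simulate co-registered power rasters over a GSV surface
#'
#' Builds a smooth synthetic GSV surface and, for one acquisition, the
#' four power bands from the configured log-linear law with independent
#' pixel noise. Used to exercise plot extraction and wall-to-wall mapping.
#'
#' @param config a [scene_config()].
#' @param acquisition label of the acquisition to simulate.
#' @param nrow,ncol raster dimensions.
#' @param res cell size, map units.
#' @return List: `gsv` ([power_raster()] of true GSV) and `bands` (named
#'   list of power rasters `odd`, `dbl`, `vol`, `hlx`).
#' @export
sim_power_rasters <- function(config, acquisition = "1",
                              nrow = 60, ncol = 60, res = 25) {
  labels <- purrr::map_chr(config$acquisitions, "label")
  if (!acquisition %in% labels) abort("unknown acquisition label")
  acq <- config$acquisitions[[match(acquisition, labels)]]
  rng <- range(c(config$gsv_strata$min, config$gsv_strata$max))
  withr::with_seed(stream_seed(config$seed, "pipeline"), {
    ramp <- outer(seq(0, 1, length.out = nrow),
                  seq(0, 1, length.out = ncol),
                  function(a, b) (a + b) / 2)
    gsv <- rng[1] + (rng[2] - rng[1]) *
      pmin(pmax(ramp + matrix(rnorm(nrow * ncol, 0, 0.05), nrow), 0), 1)
    sds <- sqrt(config$noise_sd^2 + acq$extra_noise_sd^2)
    bands <- purrr::map(base_power_names(), function(ch) {
      row <- config$power_law[config$power_law$feature == ch, ]
      mu <- row$a0_true + row$a1_true * gsv + acq$bias[[ch]]
      power_raster(exp(mu + matrix(rnorm(nrow * ncol, 0, sds), nrow)),
                   origin = c(0, (nrow - 1) * res), res = res)
    })
    names(bands) <- base_power_names()
    list(gsv = power_raster(gsv, origin = c(0, (nrow - 1) * res), res = res),
         bands = bands)
  })
}
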