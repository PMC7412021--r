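default_combinations <- function() {
  list("1", "2", "3", "4", c("1", "4"), c("2", "3"), c("1", "2", "3"),
       c("2", "3", "4"), c("1", "2", "3", "4"))
}

default_predictors <- function() {
  # Odd and Vol are screened but not used as predictors: surface return
  # reflects the ground, volume correlation is weak/not significant
  c("dbl", "dbl_odd", "vol_odd", "dblxvol", "dblxvol_odd")
}

#' Run the full synthetic retrieval pipeline
#'
#' simulate -> features -> temporal fusion -> fit -> LOOCV evaluation, as
#' one seeded, reproducible run. For every acquisition source (single
#' images and temporal combinations), every predictor and every model the
#' report carries LOOCV RMSE (m3/ha), RRMSE (%), R2 and the exceedance
#' fraction. When `out_dir` is given, feature tables and the report are
#' written as CSV, full-data fits as JSON, and a manifest records the
#' config hash and seed.
#'
#' @param config a [scene_config()].
#' @param combinations list of source label vectors; length-1 elements are
#'   single images, longer ones temporal averages.
#' @param predictors feature columns used as retrieval predictors.
#' @param models subset of `c("glm", "semiexp")`.
#' @param alpha significance level for Pearson screening.
#' @param threshold_rel relative error threshold for exceedance.
#' @param gsv_cap saturation cap for semi-exponential inversion, m3/ha.
#' @param out_dir optional output directory.
#' @return List of class `gsv_run`: `scene`, `sources` (per-source feature
#'   tibble), `correlations`, `fits`, `report`, `manifest`.
#' @export
run_gsv_pipeline <- function(config = scene_config(),
                             combinations = default_combinations(),
                             predictors = default_predictors(),
                             models = c("glm", "semiexp"),
                             alpha = 0.01, threshold_rel = 0.5,
                             gsv_cap = 500, out_dir = NULL) {
  models <- match.arg(models, c("glm", "semiexp"), several.ok = TRUE)
  if (length(predictors) < 1) abort("need at least one predictor")
  scene <- sim_scene(config)

  usable <- dplyr::filter(scene$plots, !.data$shadow)
  if (nrow(usable) < nrow(scene$plots)) {
    inform(paste0("discarding ", nrow(scene$plots) - nrow(usable),
                  " shadow plot(s) before model fitting"))
  }
  feats <- dplyr::semi_join(scene$features, usable, by = "plot_id")

  sources <- purrr::map_dfr(combinations, function(cmb) {
    if (length(cmb) == 1) {
      feats |>
        dplyr::filter(as.character(.data$acquisition) == cmb) |>
        dplyr::mutate(source = as.character(cmb), .after = "plot_id") |>
        dplyr::select(-"acquisition")
    } else {
      temporal_average(feats, cmb)
    }
  })

  correlations <- pearson_table(sources, usable, alpha = alpha)

  cells <- tidyr::expand_grid(
    source = unique(sources$source), feature = predictors, model = models
  )
  fit_eval <- purrr::pmap(cells, function(source, feature, model) {
    d <- sources |>
      dplyr::filter(.data$source == !!source) |>
      dplyr::inner_join(usable[, c("plot_id", "gsv")], by = "plot_id")
    fit <- tryCatch({
      if (model == "glm") {
        suppressMessages(fit_gsv_glm(d, sigma = feature, gsv = "gsv"))
      } else {
        fit_gsv_semiexp(d, sigma = feature, gsv = "gsv")
      }
    }, error = function(e) NULL)
    cv <- tryCatch(
      suppressWarnings(
        loocv_gsv(d, sigma = feature, gsv = "gsv", model = model,
                  gsv_cap = gsv_cap)),
      error = function(e) NULL
    )
    if (is.null(cv)) {
      return(list(fit = fit, row = tibble::tibble(
        source = source, feature = feature, model = model,
        rmse = NA_real_, rrmse = NA_real_, r2 = NA_real_,
        n = nrow(d), exceed_frac = NA_real_, threshold_rel = threshold_rel,
        failed_folds = NA_integer_)))
    }
    m <- gsv_metrics(cv$observed, cv$predicted)
    list(fit = fit, row = dplyr::bind_cols(
      tibble::tibble(source = source, feature = feature, model = model),
      m[, c("rmse", "rrmse", "r2", "n")],
      tibble::tibble(
        exceed_frac = suppressMessages(
          exceedance(cv$observed, cv$predicted, threshold_rel)),
        threshold_rel = threshold_rel,
        failed_folds = sum(!cv$fold_ok))
    ))
  })
  report <- purrr::map_dfr(fit_eval, "row")
  fits <- purrr::map(fit_eval, "fit")
  names(fits) <- paste(cells$source, cells$feature, cells$model, sep = "|")

  manifest <- list(
    package = "polsarvol",
    version = as.character(utils::packageVersion("polsarvol")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_plots = config$n_plots,
    sources = unique(sources$source),
    predictors = predictors, models = models,
    alpha = alpha, threshold_rel = threshold_rel, gsv_cap = gsv_cap
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(scene$plots, file.path(out_dir, "plots.csv"), row.names = FALSE)
    write.csv(sources, file.path(out_dir, "features.csv"), row.names = FALSE)
    write.csv(correlations, file.path(out_dir, "correlations.csv"),
              row.names = FALSE)
    write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    fits_json <- purrr::imap(fits, function(f, nm) {
      if (is.null(f)) return(list(cell = nm, failed = TRUE))
      c(list(cell = nm, model = class(f)[1]), unclass(f))
    })
    jsonlite::write_json(fits_json, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(scene = scene, sources = sources,
                 correlations = correlations, fits = fits,
                 report = report, manifest = manifest),
            class = "gsv_run")
}

#' @export
print.gsv_run <- function(x, ...) {
  cat("<gsv_run> seed", x$manifest$seed, "-", x$manifest$n_plots, "plots,",
      length(x$manifest$sources), "sources,",
      length(x$manifest$predictors), "predictors,",
      paste(x$manifest$models, collapse = "+"), "\n")
  best <- x$report[which.min(x$report$rrmse), ]
  if (nrow(best)) {
    cat(sprintf("  best cell: %s | %s | %s  RMSE %.2f m3/ha, RRMSE %.2f%%, R2 %.2f\n",
                best$model, best$feature, best$source,
                best$rmse, best$rrmse, best$r2))
  }
  invisible(x)
}

#' Wall-to-wall GSV map from power rasters
#'
#' Computes the chosen characteristic per pixel from the four power bands,
#' inverts the fitted retrieval model, and returns a GSV raster. Masked
#' pixels (any `NA` band value, or `TRUE` in `mask`) become `NA`. GLM
#' inversions can be clamped to `[0, gsv_cap]` for mapping, since the GLM
#' itself is unbounded.
#'
#' @param bands named list of [power_raster()] (`odd`, `dbl`, `vol`,
#'   `hlx`), co-registered.
#' @param fit a fitted `gsv_glm` or `gsv_semiexp`.
#' @param feature characteristic name (one of the seven).
#' @param mask optional logical matrix, `TRUE` = exclude.
#' @param gsv_cap cap, m3/ha.
#' @param clamp clamp GLM output to `[0, gsv_cap]` (default TRUE).
#' @return A [power_raster()] of GSV, m3/ha.
#' @export
map_gsv <- function(bands, fit, feature, mask = NULL, gsv_cap = 500,
                    clamp = TRUE) {
  need <- intersect(base_power_names(), names(bands))
  dims <- purrr::map(bands[need], ~ dim(.x$data))
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1) {
    abort("band rasters have mismatched grids")
  }
  ref <- bands[[need[1]]]
  fmat <- feature_matrix(purrr::map(bands, "data"), feature)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(fmat))) abort("mask grid mismatch")
    fmat[mask] <- NA_real_
  }
  g <- matrix(NA_real_, nrow(fmat), ncol(fmat))
  ok <- is.finite(fmat)
  vals <- invert_gsv_by_model(fit, fmat[ok], gsv_cap)
  if (inherits(fit, "gsv_glm") && clamp) {
    vals <- pmin(pmax(vals, 0), gsv_cap)
  }
  g[ok] <- vals
  power_raster(g, origin = ref$origin, res = ref$res)
}

invert_gsv_by_model <- function(fit, sigma, gsv_cap) {
  if (inherits(fit, "gsv_semiexp")) {
    as.numeric(invert_gsv(fit, sigma, gsv_cap = gsv_cap))
  } else {
    invert_gsv(fit, sigma)
  }
}

feature_matrix <- function(mats, feature) {
  switch(feature,
    odd = mats$odd, dbl = mats$dbl, vol = mats$vol, hlx = mats$hlx,
    dbl_odd = mats$dbl / mats$odd,
    vol_odd = mats$vol / mats$odd,
    dblxvol = mats$dbl * mats$vol,
    dblxvol_odd = mats$dbl * mats$vol / mats$odd,
    abort(paste0("unknown feature '", feature, "'"))
  )
}

#' Read a pipeline run configuration from YAML
#'
#' Thin loader turning a YAML file into a [scene_config()] plus pipeline
#' options; every field is optional and defaults to the package defaults.
#'
#' @param path YAML file path.
#' @return List with `config` and pipeline arguments for
#'   [run_gsv_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the 'yaml' package is required to read YAML configs")
  }
  raw <- yaml::read_yaml(path)
  cfg_args <- raw$scene %||% list()
  config <- do.call(scene_config, cfg_args)
  list(
    config = config,
    combinations = raw$combinations %||% default_combinations(),
    predictors = raw$predictors %||% default_predictors(),
    models = raw$models %||% c("glm", "semiexp"),
    alpha = raw$alpha %||% 0.01,
    threshold_rel = raw$threshold_rel %||% 0.5,
    gsv_cap = raw$gsv_cap %||% 500,
    out_dir = raw$out_dir
  )
}
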