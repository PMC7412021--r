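#' Replicated single-image vs time-series comparison
#'
#' Repeats the core experiment over many seeded synthetic scenes: for each
#' replicate, LOOCV RRMSE of the chosen predictor is computed for every
#' single acquisition and for the temporal average of all four, under one
#' or both retrieval models. This is the stochastic backbone for the claim
#' that temporal fusion improves retrieval accuracy.
#'
#' @param n_seeds number of replicates.
#' @param base_seed scene seeds are `base_seed + 1 ... base_seed + n_seeds`.
#' @param predictor feature column used as the predictor.
#' @param models subset of `c("glm", "semiexp")`.
#' @param config_fn function(seed) -> [scene_config()]; defaults to the
#'   standard study conditions.
#' @param gsv_cap saturation cap for the semi-exponential inversion.
#' @return Tibble: `seed`, `source`, `model`, `rrmse`, `rmse`, `r2`.
#' @export
temporal_gain_study <- function(n_seeds = 100, base_seed = 0,
                                predictor = "dblxvol_odd",
                                models = c("glm", "semiexp"),
                                config_fn = NULL, gsv_cap = 500) {
  models <- match.arg(models, c("glm", "semiexp"), several.ok = TRUE)
  config_fn <- config_fn %||% function(seed) scene_config(seed = seed)
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    seed <- base_seed + i
    sc <- sim_scene(config_fn(seed))
    singles <- purrr::map_chr(sc$config$acquisitions, "label")
    srcs <- c(as.list(singles), list(singles))
    purrr::map_dfr(srcs, function(cmb) {
      d <- if (length(cmb) == 1) {
        dplyr::filter(sc$features, as.character(.data$acquisition) == cmb)
      } else {
        temporal_average(sc$features, cmb)
      }
      d <- dplyr::inner_join(d, sc$plots[, c("plot_id", "gsv")],
                             by = "plot_id")
      purrr::map_dfr(models, function(mod) {
        cv <- suppressWarnings(
          loocv_gsv(d, sigma = predictor, gsv = "gsv", model = mod,
                    gsv_cap = gsv_cap))
        m <- gsv_metrics(cv$observed, cv$predicted)
        tibble::tibble(seed = seed,
                       source = paste(cmb, collapse = ","),
                       model = mod, rrmse = m$rrmse, rmse = m$rmse,
                       r2 = m$r2)
      })
    })
  })
}

#' Summarise a temporal-gain study
#'
#' Median RRMSE per source and model, plus whether the full time-series
#' source beats every single acquisition.
#'
#' @param study tibble from [temporal_gain_study()].
#' @return List with `medians` (tibble) and `fusion_wins` (named logical
#'   per model).
#' @export
summarise_temporal_gain <- function(study) {
  medians <- study |>
    dplyr::group_by(.data$model, .data$source) |>
    dplyr::summarise(median_rrmse = median(.data$rrmse), .groups = "drop")
  ts_label <- medians$source[which.max(nchar(medians$source))]
  fusion_wins <- purrr::map_lgl(
    split(medians, medians$model),
    function(m) {
      ts <- m$median_rrmse[m$source == ts_label]
      all(ts < m$median_rrmse[m$source != ts_label])
    })
  list(medians = medians, fusion_wins = fusion_wins, ts_label = ts_label)
}
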