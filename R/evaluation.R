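#' Pearson screening of characteristics against GSV
#'
#' Product-moment correlation of each feature column with observed GSV,
#' per source (acquisition or temporal combination), with a two-tailed
#' significance flag at level `alpha`: the flag is set when `|gamma|`
#' reaches the critical value `t / sqrt(t^2 + n - 2)`,
#' `t = qt(1 - alpha/2, n - 2)`. Screening at alpha = 0.01 is the usual
#' gate before a characteristic is admitted as a retrieval predictor.
#' Features with zero variance get `NA`.
#'
#' @param features feature tibble with `plot_id`, a `source` or
#'   `acquisition` column, and feature columns.
#' @param gsv tibble with `plot_id`, `gsv` (m3/ha).
#' @param alpha significance level (default 0.01).
#' @param columns feature columns to screen (default all seven).
#' @return Tibble: `source`, `feature`, `gamma`, `n`, `critical`,
#'   `significant`.
#' @export
pearson_table <- function(features, gsv, alpha = 0.01,
                          columns = feature_names()) {
  src_col <- if ("source" %in% names(features)) "source" else "acquisition"
  joined <- dplyr::inner_join(features, gsv[, c("plot_id", "gsv")],
                              by = "plot_id")
  joined |>
    tidyr::pivot_longer(dplyr::all_of(columns), names_to = "feature",
                        values_to = "value") |>
    dplyr::group_by(source = as.character(.data[[src_col]]),
                    .data$feature) |>
    dplyr::summarise(
      gamma = pearson_or_na(.data$value, .data$gsv),
      n = sum(is.finite(.data$value) & is.finite(.data$gsv)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      critical = critical_r(.data$n, alpha),
      significant = !is.na(.data$gamma) & abs(.data$gamma) >= .data$critical
    ) |>
    dplyr::mutate(feature = factor(.data$feature, levels = columns)) |>
    dplyr::arrange(.data$source, .data$feature) |>
    dplyr::mutate(feature = as.character(.data$feature))
}

pearson_or_na <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Critical correlation at a given sample size
#'
#' Two-tailed critical value of the Pearson coefficient:
#' `r* = t / sqrt(t^2 + n - 2)` with `t` the `1 - alpha/2` quantile of
#' Student's t on `n - 2` degrees of freedom.
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return Critical `|r|`.
#' @examples
#' critical_r(20, 0.01)  # 0.5614
#' @export
critical_r <- function(n, alpha = 0.01) {
  out <- rep(NA_real_, length(n))
  ok <- is.finite(n) & n >= 3
  tq <- qt(1 - alpha / 2, df = n[ok] - 2)
  out[ok] <- tq / sqrt(tq^2 + n[ok] - 2)
  out
}

#' Leave-one-out cross-validated GSV predictions
#'
#' For each plot the retrieval model is refitted on the other `n - 1`
#' plots — including, for the semi-exponential model, its data-driven
#' initialisation — and the held-out characteristic value is inverted to a
#' GSV prediction. Output row order matches input.
#'
#' @param data tibble of usable plots.
#' @param sigma,gsv column names (strings).
#' @param model `"glm"` or `"semiexp"`.
#' @param gsv_cap saturation cap passed to the semi-exponential inversion.
#' @return Tibble: `plot_id` (if present), `observed`, `predicted`,
#'   `fold_ok` (FALSE where a fold's fit failed; such predictions are NA).
#' @export
loocv_gsv <- function(data, sigma, gsv, model = c("glm", "semiexp"),
                      gsv_cap = 500) {
  model <- match.arg(model)
  n <- nrow(data)
  if (n < 4) abort("LOOCV needs at least 4 usable plots")
  s <- data[[sigma]]; g <- data[[gsv]]
  pred <- rep(NA_real_, n); ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      if (model == "glm") {
        fit <- suppressMessages(fit_gsv_glm(sigma = s[-i], gsv = g[-i]))
        invert_gsv(fit, s[i])
      } else {
        fit <- fit_gsv_semiexp(sigma = s[-i], gsv = g[-i])
        as.numeric(invert_gsv(fit, s[i], gsv_cap = gsv_cap))
      }
    }, error = function(e) NA_real_)
    if (is.na(res)) ok[i] <- FALSE
    pred[i] <- res
  }
  if (any(!ok)) {
    warn(paste0(sum(!ok), " of ", n, " LOOCV fold(s) failed"))
  }
  out <- tibble::tibble(observed = g, predicted = pred, fold_ok = ok)
  if ("plot_id" %in% names(data)) {
    out <- dplyr::bind_cols(data["plot_id"], out)
  }
  out
}

#' Accuracy metrics for predicted vs observed GSV
#'
#' `rmse = sqrt(mean((pred - obs)^2))` (m3/ha); `rrmse = 100 * rmse /
#' mean(obs)` (%); `r2` is, by default, the squared Pearson correlation of
#' observed and predicted — with cross-validated predictions the
#' alternative `1 - SSE/SST` can go negative, so squared correlation is
#' the default and `r2_method = "ess"` exposes the alternative.
#'
#' @param observed,predicted paired numeric vectors (length >= 2).
#' @param r2_method `"cor"` (squared correlation, default) or `"ess"`
#'   (`1 - SSE/SST`).
#' @return Tibble with `rmse`, `rrmse`, `r2`, `n`.
#' @export
gsv_metrics <- function(observed, predicted, r2_method = c("cor", "ess")) {
  r2_method <- match.arg(r2_method)
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 2) abort("need at least 2 paired finite observations")
  rmse <- sqrt(mean((p - o)^2))
  rrmse <- if (mean(o) == 0) NA_real_ else 100 * rmse / mean(o)
  r2 <- if (r2_method == "cor") {
    if (sd(o) == 0 || sd(p) == 0) NA_real_ else cor(o, p)^2
  } else {
    1 - sum((p - o)^2) / sum((o - mean(o))^2)
  }
  tibble::tibble(rmse = rmse, rrmse = rrmse, r2 = r2, n = length(o))
}

#' Fraction of plots exceeding a relative error threshold
#'
#' @param observed,predicted paired numeric vectors.
#' @param threshold_rel relative error threshold (> 0; default 0.5 i.e.
#'   50%).
#' @return Fraction of plots with `|pred - obs| / obs > threshold_rel`.
#'   Plots with `observed == 0` are excluded with a message.
#' @export
exceedance <- function(observed, predicted, threshold_rel = 0.5) {
  assert_scalar_number(threshold_rel, "threshold_rel", min = 0, strict = TRUE)
  ok <- is.finite(observed) & is.finite(predicted)
  zero <- ok & observed == 0
  if (any(zero)) {
    inform(paste0(sum(zero), " plot(s) with observed GSV 0 excluded from ",
                  "exceedance"))
  }
  use <- ok & !zero
  if (!any(use)) return(NA_real_)
  mean(abs(predicted[use] - observed[use]) / observed[use] > threshold_rel)
}

#' Average single-image correlations per feature
#'
#' Arithmetic mean of the Pearson coefficients over the single-acquisition
#' sources, per feature — the summary used to compare un-fused and fused
#' characteristics before and after combination. With
#' `rule = "significant_only"` entries flagged non-significant are dropped
#' before averaging. Report values are rounded half-away-from-zero to 3
#' decimals, matching published correlation tables.
#'
#' @param table a correlation table as from [pearson_table()] (columns
#'   `source`, `feature`, `gamma`, `significant`).
#' @param sources character vector of single-image source labels.
#' @param rule `"all"` or `"significant_only"`.
#' @param digits rounding for report output (default 3).
#' @return Tibble: `feature`, `mean_gamma`, `n_used`.
#' @export
aggregate_correlations <- function(table, sources,
                                   rule = c("all", "significant_only"),
                                   digits = 3) {
  rule <- match.arg(rule)
  sub <- dplyr::filter(table, .data$source %in% as.character(sources))
  if (nrow(sub) == 0) abort("no rows match the given sources")
  if (rule == "significant_only") {
    sub <- dplyr::filter(sub, .data$significant)
  }
  order_hint <- intersect(feature_names(), unique(table$feature))
  sub |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      mean_gamma = round_half_up(mean(.data$gamma, na.rm = TRUE), digits),
      n_used = sum(!is.na(.data$gamma)),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_gamma = ifelse(.data$n_used == 0, NA_real_,
                                      .data$mean_gamma)) |>
    dplyr::arrange(match(.data$feature, order_hint))
}

#' Published single-scene correlation table (L-band, Chinese fir plantation)
#'
#' Pearson coefficients between the seven Yamaguchi-derived characteristics
#' and field-measured GSV for four L-band quad-pol acquisitions over a
#' planted Chinese fir forest (sources `"1"`-`"4"`, acquired June-September
#' of one growing season) and five temporal combinations of them, as
#' printed in the study this package's methods follow. Significance flags
#' are at the 0.01 level as published. Used as the reference input for
#' [aggregate_correlations()] and as the calibration yardstick for the
#' synthetic-scene generator.
#'
#' @return Tibble in [pearson_table()] layout: `source`, `feature`,
#'   `gamma`, `significant`, plus `type` (`"single"` or `"time_series"`).
#' @export
reference_correlations <- function() {
  feats <- feature_names()
  rows <- list(
    list("1",       "single",      c(-0.557, 0.702, 0.437, -0.569, -0.626, -0.709, 0.624)),
    list("2",       "single",      c(-0.421, 0.392, 0.360, -0.473, -0.462, -0.479, 0.484)),
    list("3",       "single",      c(-0.415, 0.421, 0.210, -0.385, -0.461, -0.367, 0.415)),
    list("4",       "single",      c(-0.484, 0.529, 0.207, -0.476, -0.526, -0.483, 0.503)),
    list("1,4",     "time_series", c(-0.612, 0.696, 0.416, -0.588, -0.625, -0.673, 0.612)),
    list("2,3",     "time_series", c(-0.465, 0.466, 0.326, -0.467, -0.505, -0.466, 0.487)),
    list("1,2,3",   "time_series", c(-0.566, 0.623, 0.421, -0.550, -0.596, -0.609, 0.578)),
    list("2,3,4",   "time_series", c(-0.613, 0.659, 0.478, -0.590, -0.620, -0.655, 0.607)),
    list("1,2,3,4", "time_series", c(-0.594, 0.634, 0.436, -0.568, -0.608, -0.617, 0.590))
  )
  # published non-significant entries (0.01 level): Vol for sources 3, 4
  # and the 2,3 combination
  nonsig <- tibble::tibble(source = c("3", "4", "2,3"), feature = "vol")
  out <- purrr::map_dfr(rows, function(r) {
    tibble::tibble(source = r[[1]], type = r[[2]], feature = feats,
                   gamma = r[[3]])
  })
  out$significant <- !(paste(out$source, out$feature) %in%
                         paste(nonsig$source, nonsig$feature))
  out
}
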