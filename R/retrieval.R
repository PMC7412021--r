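#' Exponential GLM relating a polarimetric characteristic to GSV
#'
#' Fits `sigma = exp(a0 + a1 * GSV)` by ordinary least squares on the log
#' scale, `ln(sigma) = a0 + a1 * GSV` — the natural-log link linearises the
#' model so no starting values are needed. Non-positive `sigma` values
#' cannot enter the log and are excluded with a message (the count is kept
#' in the fit).
#'
#' @param data data frame with the observations.
#' @param sigma,gsv column names (strings) of the characteristic (linear
#'   power) and the observed GSV (m3/ha); or pass bare numeric vectors.
#' @param feature optional feature label stored in the fit.
#' @return An object of class `gsv_glm` with elements `a0`, `a1`, `n`,
#'   `sigma_resid` (residual SD on the log scale), `n_excluded`, `feature`.
#' @examples
#' d <- tibble::tibble(gsv = c(0, 100, 200), p = exp(1 - 0.01 * c(0, 100, 200)))
#' fit <- fit_gsv_glm(d, sigma = "p", gsv = "gsv")
#' coef(fit)   # a0 = 1, a1 = -0.01
#' @export
fit_gsv_glm <- function(data = NULL, sigma, gsv, feature = NULL) {
  v <- resolve_xy(data, sigma, gsv)
  keep <- is.finite(v$sigma) & is.finite(v$gsv) & v$sigma > 0
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    inform(paste0("excluding ", n_excl,
                  " observation(s) with non-positive or missing power"))
  }
  s <- v$sigma[keep]; g <- v$gsv[keep]
  if (length(s) < 3) abort("need at least 3 usable (sigma, gsv) pairs")
  if (length(unique(g)) < 2) {
    abort("all GSV values identical: slope unidentifiable")
  }
  fit <- lm(log(s) ~ g)
  structure(list(
    a0 = unname(coef(fit)[1]), a1 = unname(coef(fit)[2]),
    n = length(s), n_excluded = n_excl,
    # noise-free data trips lm's perfect-fit warning; only the SD is kept
    sigma_resid = suppressWarnings(summary(fit)$sigma),
    feature = feature %||% v$sigma_name
  ), class = "gsv_glm")
}

#' Invert the exponential GLM to GSV
#'
#' `GSV = (ln(sigma) - a0) / a1`. The inversion is monotone in `sigma`
#' (direction given by the sign of `a1`) and unbounded: there is no hard
#' saturation, which is what makes this model usable at high stand volumes.
#' Non-positive `sigma` yields `NA`.
#'
#' @param fit a `gsv_glm` object.
#' @param sigma numeric vector of characteristic values.
#' @param ... method-specific options; the `gsv_semiexp` method takes
#'   `gsv_cap`, the GSV (m3/ha, default 500) returned for values at or
#'   beyond the saturation asymptote.
#' @return Predicted GSV, m3/ha. The `gsv_semiexp` method attaches logical
#'   attributes `saturated` and `floored` marking the clamped entries.
#' @export
invert_gsv <- function(fit, sigma, ...) UseMethod("invert_gsv")

#' @rdname invert_gsv
#' @export
invert_gsv.gsv_glm <- function(fit, sigma, ...) {
  if (!is.finite(fit$a1) || abs(fit$a1) < .Machine$double.eps^0.75) {
    abort("a1 = 0: GLM cannot be inverted")
  }
  out <- rep(NA_real_, length(sigma))
  ok <- is.finite(sigma) & sigma > 0
  out[ok] <- (log(sigma[ok]) - fit$a0) / fit$a1
  out
}

#' @export
coef.gsv_glm <- function(object, ...) c(a0 = object$a0, a1 = object$a1)

#' @export
print.gsv_glm <- function(x, ...) {
  cat("Exponential GLM: ln(sigma) = a0 + a1 * GSV\n")
  cat(sprintf("  feature: %s   n = %d (excluded %d)\n",
              x$feature %||% "?", x$n, x$n_excluded))
  cat(sprintf("  a0 = %.6g   a1 = %.6g   residual SD (log) = %.4g\n",
              x$a0, x$a1, x$sigma_resid))
  invisible(x)
}

#' Semi-exponential (water-cloud type) saturation model
#'
#' Fits `sigma = beta_s + (beta_n - beta_s) * exp(-GSV / k)` by nonlinear
#' least squares (Levenberg-Marquardt). `beta_n` is the characteristic of
#' non-vegetated ground (GSV = 0), `beta_s` the asymptote of the densest
#' forest, and `k` (m3/ha) the saturation constant that bounds the
#' invertible range. Starting values come from the range of the data:
#' `beta_n` from the mean characteristic of the 10% lowest-GSV plots,
#' `beta_s` from the 10% highest, `k` from the median GSV; up to
#' `max_restarts` jittered restarts are attempted on non-convergence, after
#' which the fit is returned with `converged = FALSE` (consumers must
#' check). A `k` driven to its bounds is flagged the same way.
#'
#' @inheritParams fit_gsv_glm
#' @param max_restarts jittered re-initialisations on failure (default 5).
#' @param tol convergence tolerance on the sum of squares (default 1e-10).
#' @param max_iter iteration cap per attempt (default 500).
#' @return An object of class `gsv_semiexp` with `beta_n`, `beta_s`, `k`,
#'   `n`, `converged`, `k_at_bound`, `feature`.
#' @examples
#' g <- seq(0, 400, 50)
#' d <- tibble::tibble(gsv = g, p = 0.05 + 0.15 * exp(-g / 100))
#' fit_gsv_semiexp(d, sigma = "p", gsv = "gsv")
#' @export
fit_gsv_semiexp <- function(data = NULL, sigma, gsv, feature = NULL,
                            max_restarts = 5, tol = 1e-10, max_iter = 500) {
  v <- resolve_xy(data, sigma, gsv)
  keep <- is.finite(v$sigma) & is.finite(v$gsv)
  s <- v$sigma[keep]; g <- v$gsv[keep]
  if (length(s) < 4) abort("need at least 4 usable (sigma, gsv) pairs")
  if (length(unique(g)) < 2) abort("need more than one distinct GSV value")

  q <- max(1L, ceiling(0.1 * length(g)))
  ord <- order(g)
  bn0 <- mean(s[ord][seq_len(q)])
  bs0 <- mean(s[rev(ord)][seq_len(q)])
  k0 <- max(median(g), 1)
  if (abs(bn0 - bs0) < 1e-12) bn0 <- bs0 + sd(s) + 1e-9

  k_upper <- 50 * max(g)
  dat <- data.frame(s = s, g = g)
  attempt <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        s ~ beta_s + (beta_n - beta_s) * exp(-g / k),
        data = dat, start = start,
        lower = c(beta_s = -Inf, beta_n = -Inf, k = 1e-6),
        upper = c(beta_s = Inf, beta_n = Inf, k = k_upper),
        control = minpack.lm::nls.lm.control(
          maxiter = max_iter, ftol = tol, ptol = tol)
      ),
      error = function(e) NULL
    )
  }

  fit <- attempt(list(beta_s = bs0, beta_n = bn0, k = k0))
  tries <- 0
  # jittered restarts draw from a private stream so user-level RNG state
  # is untouched
  while (is.null(fit) && tries < max_restarts) {
    tries <- tries + 1
    jit <- withr::with_seed(stream_seed(tries, "restart"), {
      list(beta_s = bs0 * runif(1, 0.5, 1.5) + rnorm(1, 0, 0.1 * sd(s)),
           beta_n = bn0 * runif(1, 0.5, 1.5) + rnorm(1, 0, 0.1 * sd(s)),
           k = k0 * runif(1, 0.3, 3))
    })
    fit <- attempt(jit)
  }

  if (is.null(fit)) {
    return(structure(list(
      beta_n = NA_real_, beta_s = NA_real_, k = NA_real_,
      n = length(s), converged = FALSE, k_at_bound = FALSE,
      restarts = tries, feature = feature %||% v$sigma_name
    ), class = "gsv_semiexp"))
  }
  p <- coef(fit)
  k_at_bound <- p[["k"]] <= 2e-6 || p[["k"]] >= 0.999 * k_upper
  structure(list(
    beta_n = p[["beta_n"]], beta_s = p[["beta_s"]], k = p[["k"]],
    n = length(s), converged = !k_at_bound, k_at_bound = k_at_bound,
    restarts = tries, rss = sum(stats::resid(fit)^2),
    feature = feature %||% v$sigma_name
  ), class = "gsv_semiexp")
}

#' @rdname invert_gsv
#' @export
invert_gsv.gsv_semiexp <- function(fit, sigma, gsv_cap = 500, ...) {
  if (!isTRUE(fit$converged) && !isTRUE(fit$k_at_bound)) {
    abort("semi-exponential fit did not converge; cannot invert")
  }
  ratio <- (sigma - fit$beta_s) / (fit$beta_n - fit$beta_s)
  out <- rep(NA_real_, length(sigma))
  sat <- is.finite(ratio) & ratio <= 0          # at/beyond the asymptote
  below <- is.finite(ratio) & ratio > 1         # beyond the zero-GSV value
  mid <- is.finite(ratio) & ratio > 0 & ratio <= 1
  out[mid] <- -fit$k * log(ratio[mid])
  out[sat] <- gsv_cap
  out[below] <- 0
  attr(out, "saturated") <- sat
  attr(out, "floored") <- below
  out
}

#' @export
coef.gsv_semiexp <- function(object, ...) {
  c(beta_n = object$beta_n, beta_s = object$beta_s, k = object$k)
}

#' @export
print.gsv_semiexp <- function(x, ...) {
  cat("Semi-exponential model: sigma = beta_s + (beta_n - beta_s) * exp(-GSV/k)\n")
  cat(sprintf("  feature: %s   n = %d   converged: %s\n",
              x$feature %||% "?", x$n, x$converged))
  cat(sprintf("  beta_n = %.6g   beta_s = %.6g   k = %.6g m3/ha\n",
              x$beta_n, x$beta_s, x$k))
  invisible(x)
}

#' Model curve prediction (forward direction)
#'
#' @param object a fitted retrieval model.
#' @param gsv GSV values at which to evaluate the fitted curve.
#' @param ... unused.
#' @return Predicted characteristic values.
#' @export
predict.gsv_glm <- function(object, gsv, ...) {
  exp(object$a0 + object$a1 * gsv)
}

#' @rdname predict.gsv_glm
#' @export
predict.gsv_semiexp <- function(object, gsv, ...) {
  object$beta_s + (object$beta_n - object$beta_s) * exp(-gsv / object$k)
}

#' @export
tidy.gsv_glm <- function(x, ...) {
  tibble::tibble(term = c("a0", "a1"), estimate = c(x$a0, x$a1))
}

#' @export
tidy.gsv_semiexp <- function(x, ...) {
  tibble::tibble(term = c("beta_n", "beta_s", "k"),
                 estimate = c(x$beta_n, x$beta_s, x$k))
}

#' @export
glance.gsv_glm <- function(x, ...) {
  tibble::tibble(model = "glm", feature = x$feature %||% NA_character_,
                 n = x$n, n_excluded = x$n_excluded,
                 sigma_resid = x$sigma_resid)
}

#' @export
glance.gsv_semiexp <- function(x, ...) {
  tibble::tibble(model = "semiexp", feature = x$feature %||% NA_character_,
                 n = x$n, converged = x$converged,
                 k_at_bound = x$k_at_bound, restarts = x$restarts)
}

# Accept either data + column names or two bare vectors.
resolve_xy <- function(data, sigma, gsv) {
  if (!is.null(data)) {
    if (is.character(sigma)) {
      name <- sigma
      list(sigma = data[[sigma]], gsv = data[[gsv]], sigma_name = name)
    } else {
      abort("with `data`, pass column names as strings")
    }
  } else {
    list(sigma = sigma, gsv = gsv, sigma_name = NULL)
  }
}
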