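# Canonical unit-trace coherency bases for the four scattering mechanisms.
# Surface: all energy in T11; double-bounce: T22; volume: the random-dipole
# cloud diag(2,1,1)/4; helix: the standard left/right helix matrix.
t3_basis <- function(mechanism = c("surface", "double", "volume", "helix"),
                     helix_sign = 1) {
  mechanism <- match.arg(mechanism)
  switch(mechanism,
    surface = diag(c(1, 0, 0)) + 0i,
    double  = diag(c(0, 1, 0)) + 0i,
    volume  = diag(c(2, 1, 1)) / 4 + 0i,
    helix   = {
      m <- matrix(0 + 0i, 3, 3)
      m[2, 2] <- m[3, 3] <- 0.5 + 0i
      m[2, 3] <- 1i * helix_sign / 2
      m[3, 2] <- Conj(m[2, 3])
      m
    }
  )
}

#' Reconstruct a coherency matrix from decomposition powers
#'
#' Builds `T = P_odd T_surf + P_dbl T_dbl + P_vol T_vol + P_hlx T_hlx` from
#' canonical unit-trace Hermitian bases, so `trace(T)` equals the power sum.
#' The inverse operation is [yamaguchi4()].
#'
#' @param odd,dbl,vol,hlx nonnegative scattering powers (linear units).
#' @param helix_sign +1 or -1, handedness of the helix component.
#' @return A 3x3 complex Hermitian matrix.
#' @examples
#' powers_to_t3(odd = 1, dbl = 0, vol = 0, hlx = 0)   # diag(1, 0, 0)
#' @export
powers_to_t3 <- function(odd, dbl, vol, hlx = 0, helix_sign = 1) {
  p <- c(odd, dbl, vol, hlx)
  if (any(!is.finite(p)) || any(p < 0)) {
    abort("decomposition powers must be finite and nonnegative")
  }
  odd * t3_basis("surface") + dbl * t3_basis("double") +
    vol * t3_basis("volume") + hlx * t3_basis("helix", helix_sign)
}

check_hermitian <- function(t3, tol = 1e-10) {
  if (!is.matrix(t3) || !all(dim(t3) == c(3, 3))) {
    abort("t3 must be a 3x3 matrix")
  }
  scale <- max(Mod(t3), 1e-300)
  if (max(Mod(t3 - Conj(t(t3)))) > tol * max(scale, 1)) {
    abort("t3 is not Hermitian within tolerance")
  }
  if (any(Re(diag(t3)) < -tol * max(scale, 1))) {
    abort("t3 has a negative diagonal element")
  }
  invisible(t3)
}

# Single-matrix Yamaguchi four-component split. Branch constants (the
# asymmetric dipole-cloud coherency (1/30)[[15,+-5,0],[+-5,7,0],[0,0,8]] and
# the 2 dB co-pol ratio thresholds) follow Yamaguchi et al. (2005), IEEE
# TGRS 43(8). Negative intermediate powers are clipped with the remainder
# reassigned so the four powers always sum to trace(T).
yamaguchi4_one <- function(t3) {
  check_hermitian(t3)
  t11 <- Re(t3[1, 1]); t22 <- Re(t3[2, 2]); t33 <- Re(t3[3, 3])
  tp <- t11 + t22 + t33
  clipped <- FALSE

  phlx <- 2 * abs(Im(t3[2, 3]))

  # co-pol power ratio 10 log10(|Svv|^2 / |Shh|^2) from the Pauli basis
  shh2 <- (t11 + t22 + 2 * Re(t3[1, 2])) / 2
  svv2 <- (t11 + t22 - 2 * Re(t3[1, 2])) / 2
  ratio_db <- if (shh2 <= 0 || svv2 <= 0) {
    if (svv2 > shh2) Inf else if (shh2 > svv2) -Inf else 0
  } else {
    10 * log10(svv2 / shh2)
  }

  if (abs(ratio_db) <= 2) {
    pvol <- 4 * (t33 - phlx / 2)
    tv11 <- 1 / 2; tv22 <- 1 / 4; tv12 <- 0
  } else {
    pvol <- (15 / 4) * (t33 - phlx / 2)
    tv11 <- 1 / 2; tv22 <- 7 / 30
    tv12 <- if (ratio_db < -2) 1 / 6 else -1 / 6
  }
  if (pvol < 0) { pvol <- 0; clipped <- TRUE }

  if (phlx + pvol >= tp) {
    # volume + helix exhaust the span; surface/double vanish
    if (phlx > tp) { phlx <- tp; clipped <- TRUE }
    pvol <- tp - phlx
    podd <- 0; pdbl <- 0
  } else {
    # surface/double share is the span residual; splitting it (rather
    # than S + D, which drifts when pvol was clipped) keeps the sum
    # identity exact in every branch
    rem <- tp - pvol - phlx
    s <- t11 - pvol * tv11
    d <- t22 - pvol * tv22 - phlx / 2
    cc <- t3[1, 2] - pvol * tv12
    c2 <- Mod(cc)^2
    c0 <- t11 - t22 - t33 + phlx   # > 0: surface-dominant remainder
    if (c0 > 0) {
      pdbl <- if (s > 0) d - c2 / s else d
      podd <- rem - pdbl
    } else {
      podd <- if (d > 0) s - c2 / d else s
      pdbl <- rem - podd
    }
    if (podd < 0) { podd <- 0; pdbl <- rem; clipped <- TRUE }
    if (pdbl < 0) { pdbl <- 0; podd <- rem; clipped <- TRUE }
  }

  list(odd = podd, dbl = pdbl, vol = pvol, hlx = phlx,
       span = tp, clipped = clipped)
}

#' Yamaguchi four-component decomposition
#'
#' Splits a 3x3 polarimetric coherency matrix (or a list of them) into the
#' powers of surface (Odd), double-bounce (Dbl), volume (Vol) and helix
#' (Hlx) scattering. The helix power comes from the imaginary part of the
#' T23 entry; the volume power from the cross-polarised channel under a
#' dipole-cloud model selected by the co-polarised power ratio (the
#' symmetric random-dipole cloud within +-2 dB, oriented clouds outside);
#' the remainder is split between surface and double-bounce by the
#' model-based dominance criterion. The four powers always sum to
#' `trace(T)`; negative intermediates are clipped to zero with the
#' remainder reassigned (reported via a message).
#'
#' @param t3 a 3x3 complex Hermitian matrix, or a list of them.
#' @return A tibble with columns `odd`, `dbl`, `vol`, `hlx`, `span`
#'   (one row per matrix).
#' @examples
#' yamaguchi4(diag(c(1, 0, 0)))          # pure surface
#' yamaguchi4(powers_to_t3(2, 4, 1, 0))  # round trip
#' @export
yamaguchi4 <- function(t3) {
  if (is.matrix(t3)) t3 <- list(t3)
  res <- purrr::map(t3, yamaguchi4_one)
  out <- tibble::tibble(
    odd  = purrr::map_dbl(res, "odd"),
    dbl  = purrr::map_dbl(res, "dbl"),
    vol  = purrr::map_dbl(res, "vol"),
    hlx  = purrr::map_dbl(res, "hlx"),
    span = purrr::map_dbl(res, "span")
  )
  n_clip <- sum(purrr::map_lgl(res, "clipped"))
  if (n_clip > 0) {
    inform(paste0("negative intermediate power clipped in ", n_clip,
                  " matrix(es); span identity preserved"))
  }
  out
}

#' Fused polarimetric characteristics
#'
#' Adds the four fused predictors built from the base decomposition powers:
#' `Dbl/Odd`, `Vol/Odd`, `Dbl x Vol` and `Dbl x Vol/Odd` (columns
#' `dbl_odd`, `vol_odd`, `dblxvol`, `dblxvol_odd`). Arithmetic is on linear
#' powers. Rows with `odd == 0` get `NA` for the three ratio features —
#' missingness is propagated, not zeroed — and are counted in a message.
#'
#' @param powers tibble with columns `odd`, `dbl`, `vol` (rows are
#'   pixels or plots; extra columns pass through).
#' @return `powers` with the four fused columns appended.
#' @examples
#' fuse_powers(tibble::tibble(odd = 2, dbl = 4, vol = 1))
#' @export
fuse_powers <- function(powers) {
  need <- c("odd", "dbl", "vol")
  if (!all(need %in% names(powers))) {
    abort("powers must have columns odd, dbl, vol")
  }
  zero_odd <- !is.na(powers$odd) & powers$odd == 0
  if (any(zero_odd)) {
    inform(paste0(sum(zero_odd), " row(s) with odd == 0: ratio features ",
                  "set to NA"))
  }
  dplyr::mutate(
    powers,
    dbl_odd     = ifelse(zero_odd, NA_real_, .data$dbl / .data$odd),
    vol_odd     = ifelse(zero_odd, NA_real_, .data$vol / .data$odd),
    dblxvol     = .data$dbl * .data$vol,
    dblxvol_odd = ifelse(zero_odd, NA_real_,
                         .data$dbl * .data$vol / .data$odd)
  )
}

#' Temporal averaging of acquisitions
#'
#' Averages the base powers (`odd`, `dbl`, `vol`, `hlx`) arithmetically
#' across the acquisitions in `combination`, per plot, and then recomputes
#' the fused characteristics from the averaged powers (average-then-fuse).
#' The alternative order — averaging the per-acquisition fused ratios — is
#' available with `fuse_first = TRUE` for sensitivity analysis; the two
#' differ whenever powers vary across acquisitions.
#'
#' @param features tibble with columns `plot_id`, `acquisition`, the base
#'   powers and (if `fuse_first`) the fused columns.
#' @param combination character vector of >= 2 acquisition labels.
#' @param fuse_first average fused ratios instead of refusing averaged
#'   powers (default `FALSE`).
#' @return One row per plot with `source` set to the combination label
#'   (e.g. `"1,2,3,4"`), base powers and fused features.
#' @export
temporal_average <- function(features, combination, fuse_first = FALSE) {
  combination <- as.character(combination)
  if (length(combination) < 2) {
    abort("a temporal combination needs at least 2 acquisitions")
  }
  have <- unique(as.character(features$acquisition))
  if (!all(combination %in% have)) {
    abort(paste0("unknown acquisition label(s): ",
                 paste(setdiff(combination, have), collapse = ", ")))
  }
  sub <- dplyr::filter(features,
                       as.character(.data$acquisition) %in% combination)
  plot_sets <- split(as.character(sub$acquisition), sub$plot_id)
  if (length(unique(purrr::map_chr(
        plot_sets, ~ paste(sort(.x), collapse = "|")))) != 1L) {
    abort("plot sets differ across acquisitions in the combination")
  }
  label <- paste(combination, collapse = ",")
  cols <- if (fuse_first) c(base_power_names(), fused_feature_names())
          else base_power_names()
  avg <- sub |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                     .groups = "drop")
  if (!fuse_first) avg <- fuse_powers(avg)
  dplyr::mutate(avg, source = label, .after = "plot_id")
}
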