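#' Round half away from zero
#'
#' Published correlation tables in this field round ties away from zero
#' (0.5065 -> 0.507, -0.5095 -> -0.510), which differs from R's banker's
#' rounding in [round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_up(0.5065, 3)   # 0.507, where round() gives 0.506
#' round_half_up(-0.5095, 3)  # -0.510
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a relative eps so that values intended as exact halves survive
  # binary representation (0.5065 is stored slightly below the half)
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Deterministic per-operation seed streams derived from one root seed.
# Each named operation gets root_seed + a fixed small offset, kept < 2^31.
stream_seed <- function(seed, stream) {
  offsets <- c(
    plots = 101L, trees = 211L, powers = 307L, speckle = 401L,
    restart = 503L, pipeline = 601L
  )
  if (!stream %in% names(offsets)) {
    abort(paste0("unknown seed stream '", stream, "'"))
  }
  (as.integer(seed) + offsets[[stream]]) %% .Machine$integer.max
}

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    cmp <- if (strict) "> " else ">= "
    abort(paste0("`", name, "` must be a single finite number ", cmp, min))
  }
  invisible(x)
}

# Shared vocabulary: the three base powers used as predictors plus helix,
# and the four fused characteristics built from them.
base_power_names <- function() c("odd", "dbl", "vol", "hlx")
fused_feature_names <- function() c("dbl_odd", "vol_odd", "dblxvol", "dblxvol_odd")
feature_names <- function() {
  c("odd", "dbl", "vol", fused_feature_names())
}
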