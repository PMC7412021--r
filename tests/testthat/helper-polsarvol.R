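# Shared fixture builders (all programmatic; nothing read from disk).

# Noise-free scene: log-power exactly linear in GSV, no acquisition bias.
noise_free_config <- function(n_plots = 12, seed = 42) {
  scene_config(
    n_plots = n_plots,
    noise_sd = 0,
    acquisitions = list(
      acquisition_meta("1"), acquisition_meta("2"),
      acquisition_meta("3"), acquisition_meta("4")
    ),
    seed = seed
  )
}

# Random Hermitian PSD 3x3 matrix via A A^H.
random_psd_t3 <- function() {
  a <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
  a %*% Conj(t(a))
}

# Data drawn exactly from the semi-exponential curve.
semiexp_curve <- function(beta_n = 0.20, beta_s = 0.05, k = 100,
                          gsv = seq(0, 400, 50)) {
  tibble::tibble(gsv = gsv,
                 sigma = beta_s + (beta_n - beta_s) * exp(-gsv / k))
}
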