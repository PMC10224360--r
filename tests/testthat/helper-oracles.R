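# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the DFT is the O(n^2) definition, the quantiles are
# the linear-interpolation formula applied to a plain sort.

# direct discrete Fourier transform, one-sided squared magnitudes
naive_dft_power <- function(x) {
  n <- length(x)
  k <- 0:(n %/% 2)
  W <- exp(-2i * pi * outer(k, 0:(n - 1)) / n)
  Mod(as.vector(W %*% x))^2
}

# linear interpolation between order statistics (the type-7 convention),
# written out from the formula
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo >= n - 1) return(s[n])
  frac <- h - lo
  (1 - frac) * s[lo + 1] + frac * s[lo + 2]
}

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# small, fast generator configuration for unit tests
tiny_config <- function(duration_s = 120, n_replicates = 2, base_seed = 11,
                        ...) {
  generator_config(duration_s = duration_s, n_replicates = n_replicates,
                   base_seed = base_seed, ...)
}

# assemble a tidy feature table from a minutes x replicates value matrix
features_from_matrix <- function(values, feature = "abp:low",
                                 treatment = "t", phase = "before",
                                 units = "uV^2") {
  n_min <- nrow(values)
  n_rep <- ncol(values)
  tibble::tibble(
    plant_id = rep(sprintf("p%02d", seq_len(n_rep)), each = n_min),
    treatment = treatment, phase = phase,
    minute = rep(seq_len(n_min) - 1L, times = n_rep),
    feature = feature, value = as.vector(values), units = units
  )
}
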