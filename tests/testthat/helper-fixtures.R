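# Shared fixtures: the reference parameter set used throughout (a
# registry-calibrated module network) and small utilities.

ref_params <- function() homogenized_params(N = 12, tau = 8, T = 1240, Phi = 0.63)

ref_scenario <- function(...) transition_scenario(...)

# phase-type hitting-time CDF of the permissive state for a
# naive-protective module: direct path Exp(tau) w.p. F, two-step
# Exp(tau) * Exp(T) convolution w.p. 1 - F. Independent closed form used
# as the oracle for the single-module bracket.
phase_type_cdf <- function(tau, T, F, x) {
  two_step <- 1 - (T * exp(-x / T) - tau * exp(-x / tau)) / (T - tau)
  F * (1 - exp(-x / tau)) + (1 - F) * two_step
}

# empirical KS distance against a closed-form CDF, restricted to ages in
# [0, max_age] (censored onsets contribute to n but never to the ecdf)
ks_distance <- function(onsets, cdf_fn, max_age = 90) {
  n <- length(onsets)
  fin <- sort(onsets[is.finite(onsets)])
  Fx <- cdf_fn(fin)
  i <- seq_along(fin)
  max(abs(i / n - Fx), abs((i - 1) / n - Fx),
      abs(mean(onsets <= max_age) - cdf_fn(max_age)))
}
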