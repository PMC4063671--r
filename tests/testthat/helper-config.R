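# Shared config (loss-sd fit done once) and small constructors used across
# test files.
cfg <- priorcue_config()

random_mixture <- function(k = 3L, spread = 0.15) {
  w <- stats::runif(k)
  gm(w / sum(w), stats::runif(k, -spread, spread), stats::runif(k, 0.02, 0.08))
}

random_posterior <- function(k = 3L) {
  posterior_update(random_mixture(k), stats::runif(1, -0.1, 0.1),
                   stats::runif(1, 0.04, 0.12))
}

# KS distance between sorted draws and a cdf function
ks_distance <- function(draws, cdf) {
  n <- length(draws)
  u <- cdf(sort(draws))
  max(abs(u - (seq_len(n) - 0.5) / n)) + 0.5 / n
}
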