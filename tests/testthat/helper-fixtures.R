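# fixtures built in code; no files on disk

# two well-separated Gaussian clusters in d dimensions, first `informative`
# columns carry the separation, the rest are pure noise
make_cluster_data <- function(n_per = 20L, d = 6L, informative = 2L,
                              gap = 6, sd = 0.5, seed = 1L) {
  set.seed(seed)
  mu <- c(rep(gap, informative), rep(0, d - informative))
  a <- matrix(stats::rnorm(n_per * d, sd = sd), n_per, d)
  b <- sweep(matrix(stats::rnorm(n_per * d, sd = sd), n_per, d), 2L, mu, "+")
  list(beats = rbind(a, b),
       labels = c(rep("normal", n_per), rep("mi", n_per)))
}

quadratic_1d <- structure(
  function(x) if (is.matrix(x)) (x[, 1L] - 0.5)^2 else (x[1L] - 0.5)^2,
  batecg_vectorized = TRUE)

# noise sd that puts a record at the given SNR (dB) relative to its clean power
snr_noise_sd <- function(clean_samples, snr_db) {
  sqrt(mean(clean_samples^2) / 10^(snr_db / 10))
}
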