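test_that("Savitzky-Golay smoothing reproduces polynomials and matches the reference", {
  # degree <= polyorder signals pass through unchanged, edges included
  t <- seq(0, 1, length.out = 120)
  cubic <- 2 - t + 3 * t^2 - 0.5 * t^3
  expect_equal(denoise(cubic, window = 11, polyorder = 3), cubic,
               tolerance = 1e-9)
  expect_equal(denoise(rep(4.2, 50), window = 7, polyorder = 2), rep(4.2, 50))

  # frozen reference output (scipy.signal.savgol_filter, window 7, order 3,
  # mode "interp") on a fixed vector
  x <- c(0.001230, 0.298746, -0.274138, -0.890592, -0.454671, -0.991647,
         0.060144, 1.340215, -0.492207, -0.620475, 0.489842, 0.356887,
         0.105414, -0.930468, -0.029252)
  expected <- c(0.0608407381, 0.1180248333, -0.1905552381, -0.6099261429,
                -0.8760016667, -0.3060539048, 0.1282817143, 0.0896390000,
                0.1805937619, 0.0191750000, -0.0063098571, 0.1171349524,
                -0.1313236429, -0.3254722143, -0.2724147619)
  expect_equal(denoise(x, window = 7, polyorder = 3), expected,
               tolerance = 1e-9)

  expect_error(denoise(x, window = 6, polyorder = 3), "odd")
  expect_error(denoise(x, window = 7, polyorder = 7), "polyorder")
  expect_error(denoise(x, window = 21, polyorder = 3), "length")
})

test_that("smoothing reduces additive white noise on a band-limited signal", {
  set.seed(8)
  t <- seq(0, 2, by = 1e-3)
  clean <- sin(2 * pi * 3 * t)
  noise <- stats::rnorm(length(t), sd = sqrt(mean(clean^2) / 10))  # SNR 10 dB
  sm <- denoise(ecg_signal(clean + noise, fs = 1000), window = 25)
  expect_lt(mean((sm$samples - clean)^2), stats::var(noise))
})

test_that("R peaks are recovered within 10 ms, polarity-blind", {
  rec0 <- synth_record(n_beats = 12, noise_sd = 0, seed = 31)
  sd20 <- snr_noise_sd(rec0$signal$samples, 20)
  rec <- synth_record(n_beats = 12, noise_sd = sd20, seed = 31)
  sm <- denoise(rec$signal)
  pk <- detect_r_peaks(sm)
  expect_equal(length(pk), length(rec$r_peaks))
  expect_true(all(abs(pk - rec$r_peaks) <= 10))  # 10 samples = 10 ms @1 kHz
  expect_true(all(diff(pk) >= 0.2 * sm$fs))      # refractory gap

  inv <- ecg_signal(-sm$samples, sm$fs)
  expect_identical(detect_r_peaks(inv), pk)

  expect_warning(flat <- detect_r_peaks(ecg_signal(rep(0, 3000), 1000)),
                 "no QRS")
  expect_identical(flat, integer(0))
  expect_error(detect_r_peaks(ecg_signal(rep(0, 100), 1000)), "two seconds")
})

test_that("segmentation cuts 1/3-left, 2/3-right RR windows and drops edges", {
  sig <- ecg_signal(seq_len(2400) * 1.0, fs = 1000)
  # peaks at 1001 and 1301 (1-based): reference RR for both is 300
  beats <- segment_beats(sig, c(1001L, 1301L))
  expect_equal(length(beats), 2L)
  expect_equal(length(beats[[1L]]), 300L)          # 100 left + 200 right
  expect_equal(attr(beats, "r_offsets"), c(100L, 100L))
  expect_equal(beats[[1L]][1L], 901)               # starts at R - RR/3
  expect_equal(beats[[1L]][300L], 1200)            # half-open end

  # constant RR = fs: every kept beat is exactly one second long
  pk <- seq(1500L, 8500L, by = 1000L)
  sig2 <- ecg_signal(stats::rnorm(10000), fs = 1000)
  b2 <- segment_beats(sig2, pk)
  expect_true(all(lengths(b2) == 1000L))

  # first peak too close to the record start is dropped
  b3 <- segment_beats(sig, c(50L, 1301L))  # needs 417 left samples, has 49
  expect_lt(length(b3), 2L)

  expect_warning(b4 <- segment_beats(sig, 1001L), "fewer than two")
  expect_equal(length(b4), 0L)
})

test_that("beat resampling preserves endpoints, constants and the identity grid", {
  ramp <- as.numeric(0:299)
  r <- resample_beat(ramp, 200)
  expect_equal(length(r), 200L)
  expect_equal(r[1L], 0)
  expect_equal(r[200L], 299)
  expect_equal(r, seq(0, 299, length.out = 200))  # closed form for a ramp

  x <- stats::rnorm(200)
  expect_equal(resample_beat(x, 200), x)
  expect_equal(resample_beat(rep(2.5, 37), 200), rep(2.5, 200))
  expect_error(resample_beat(1, 200), "at least 2")
})

test_that("the full preprocessing pipeline yields 200-wide beats with the R at ~1/3", {
  rec <- synth_record(n_beats = 10, noise_sd = 0.01, seed = 12)
  bm <- build_beat_matrix(list(list(signal = rec$signal, label = "normal",
                                    id = "synthA")))
  expect_s3_class(bm, "beat_matrix")
  expect_equal(ncol(bm$beats), 200L)
  expect_gte(nrow(bm$beats), 8L)   # boundary beats may drop
  expect_lte(nrow(bm$beats), 10L)
  expect_true(all(bm$labels == "normal"))
  expect_true(all(is.finite(bm$beats)))
  # the R wave lands at the 1/3 point of the resampled frame
  peaks_at <- apply(bm$beats, 1L, which.max)
  expect_true(all(abs(peaks_at - round(200 / 3)) <= 2))

  # deterministic: no RNG anywhere in the pipeline
  bm2 <- build_beat_matrix(list(list(signal = rec$signal, label = "normal")))
  expect_equal(bm$beats, bm2$beats)

  expect_error(build_beat_matrix(list()), "no records")
  # an unusable record is skipped with a warning; all-bad input errors
  short <- list(signal = ecg_signal(rep(0, 3000), 1000), label = "mi")
  expect_error(suppressWarnings(build_beat_matrix(list(short))), "no beats")
})
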