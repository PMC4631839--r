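#' Single-lead ECG signal container
#'
#' @param samples Numeric vector of amplitudes (mV); must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param lead Lead label (free text; lead III in the reference protocol).
#' @export
ecg_signal <- function(samples, fs, lead = "III") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive sampling rate in Hz", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("ECG samples must be finite", call. = FALSE)
  structure(list(samples = samples, fs = fs, lead = as.character(lead)),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("ECG signal: %d samples at %g Hz (%.2f s), lead %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$lead))
  invisible(x)
}

# round-half-up, so segmentation windows are bit-reproducible regardless of
# R's banker's rounding
round_half_up <- function(x) floor(x + 0.5)

sgolay_projection <- function(window, polyorder) {
  half <- (window - 1L) %/% 2L
  J <- outer(seq(-half, half), 0:polyorder, "^")
  J %*% solve(crossprod(J), t(J))
}

#' Savitzky-Golay smoothing
#'
#' Moving least-squares polynomial smoothing (the "Sgolay" FIR filter used to
#' denoise the raw trace). Interior samples are the central row of the
#' projection matrix applied to the sliding window; the first and last
#' half-windows are the off-center rows applied to the edge windows, i.e. a
#' polynomial is fitted to each edge window and evaluated there (the same
#' contract as MATLAB `sgolayfilt` / scipy's `mode = "interp"`). Output
#' length equals input length; polynomials of degree at most `polyorder`
#' pass through unchanged.
#'
#' @param signal An [ecg_signal()] (or bare numeric vector).
#' @param window Odd window length; defaults to the nearest odd integer to
#'   25 ms of samples (0.025 * fs) when the input carries a sampling rate.
#' @param polyorder Polynomial degree (< window), default 3.
#' @return Same type as the input: smoothed [ecg_signal()] or numeric vector.
#' @export
denoise <- function(signal, window = NULL, polyorder = 3L) {
  is_sig <- inherits(signal, "ecg_signal")
  x <- if (is_sig) signal$samples else as.numeric(signal)
  if (is.null(window)) {
    if (!is_sig) stop("window is required for a bare numeric vector", call. = FALSE)
    window <- round_half_up(0.025 * signal$fs)
    if (window %% 2L == 0L) window <- window + 1L
    window <- max(window, polyorder + 2L)
    if (window %% 2L == 0L) window <- window + 1L
  }
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be smaller than window", call. = FALSE)
  if (window > length(x)) stop("window exceeds signal length", call. = FALSE)
  B <- sgolay_projection(window, polyorder)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  y <- stats::filter(x, B[half + 1L, ], sides = 2L)
  y <- as.numeric(y)
  head_w <- x[seq_len(window)]
  tail_w <- x[(n - window + 1L):n]
  y[seq_len(half)] <- drop(B[seq_len(half), , drop = FALSE] %*% head_w)
  y[(n - half + 1L):n] <- drop(B[(half + 2L):window, , drop = FALSE] %*% tail_w)
  if (is_sig) ecg_signal(y, fs = signal$fs, lead = signal$lead) else y
}

#' R-peak detection
#'
#' Derivative-square-integrate detector with an adaptive threshold, in the
#' spirit of Pan-Tompkins: the squared first difference is smoothed with a
#' 150 ms moving average, regions above a fraction of its maximum become
#' candidate QRS complexes, each candidate is refined to the sample of
#' largest absolute (median-centred) amplitude within +/- 50 ms, and a
#' refractory period is enforced. Because the energy signal and the
#' refinement both ignore polarity, an inverted lead yields the same peaks.
#'
#' @param signal An [ecg_signal()] at least two seconds long.
#' @param refractory Minimum peak separation in seconds (default 0.2).
#' @param threshold_frac Fraction of the maximum smoothed energy used as the
#'   detection threshold (default 0.25).
#' @return Strictly increasing 1-based sample indices. A signal with no
#'   detectable QRS energy returns `integer(0)` with a warning.
#' @export
detect_r_peaks <- function(signal, refractory = 0.2, threshold_frac = 0.25) {
  stopifnot(inherits(signal, "ecg_signal"))
  x <- signal$samples
  fs <- signal$fs
  if (length(x) < 2 * fs)
    stop("signal must be at least two seconds long", call. = FALSE)
  energy <- diff(x)^2
  w <- max(3L, round_half_up(0.15 * fs))
  ma <- as.numeric(stats::filter(energy, rep(1 / w, w), sides = 2L))
  ma[is.na(ma)] <- 0
  peak_e <- max(ma)
  if (peak_e <= .Machine$double.eps) {
    warning("no QRS energy found; returning no peaks")
    return(integer(0))
  }
  thr <- threshold_frac * peak_e
  above <- ma > thr
  # contiguous supra-threshold runs -> one candidate each
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  xc <- abs(x - stats::median(x))
  half <- round_half_up(0.05 * fs)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    c0 <- seg[which.max(ma[seg])]
    lo <- max(1L, c0 - half)
    hi <- min(length(x), c0 + half)
    cand <- c(cand, lo - 1L + which.max(xc[lo:hi]))
  }
  cand <- sort(unique(cand))
  if (!length(cand)) {
    warning("no QRS energy found; returning no peaks")
    return(integer(0))
  }
  gap <- refractory * fs
  kept <- cand[1L]
  for (p in cand[-1L]) {
    last <- kept[length(kept)]
    if (p - last >= gap) {
      kept <- c(kept, p)
    } else if (xc[p] > xc[last]) {
      kept[length(kept)] <- p   # within refractory: keep the stronger one
    }
  }
  kept
}

#' Cut beats around R peaks (1/3 left, 2/3 right of the RR interval)
#'
#' Each beat spans `[R - round(RR/3), R + round(2 RR/3))` where RR is the
#' beat's reference interval: the preceding RR for every peak after the
#' first, and the following RR for the first peak (the only length scale
#' available there). Rounding is half-up. Beats whose window would cross the
#' record boundary are dropped.
#'
#' @param signal An [ecg_signal()].
#' @param r_peaks Strictly increasing 1-based R-peak indices (>= 2 of them).
#' @return List of numeric beat vectors; attribute `r_offsets` carries the
#'   0-based offset of the R sample inside each kept beat, and `kept_peaks`
#'   the peak indices that produced them. Fewer than two peaks give an empty
#'   list with a warning.
#' @export
segment_beats <- function(signal, r_peaks) {
  stopifnot(inherits(signal, "ecg_signal"))
  n <- length(signal$samples)
  if (length(r_peaks) < 2L) {
    warning("fewer than two R peaks; no RR interval, no beats")
    out <- list()
    attr(out, "r_offsets") <- integer(0)
    attr(out, "kept_peaks") <- integer(0)
    return(out)
  }
  rr_ref <- c(diff(r_peaks)[1L], diff(r_peaks))
  beats <- list()
  r_offsets <- integer(0)
  kept <- integer(0)
  for (i in seq_along(r_peaks)) {
    left <- round_half_up(rr_ref[i] / 3)
    right <- round_half_up(2 * rr_ref[i] / 3)
    start <- r_peaks[i] - left
    end <- r_peaks[i] + right - 1L   # half-open window, length left + right
    if (start < 1L || end > n) next
    beats[[length(beats) + 1L]] <- signal$samples[start:end]
    r_offsets <- c(r_offsets, left)
    kept <- c(kept, r_peaks[i])
  }
  attr(beats, "r_offsets") <- r_offsets
  attr(beats, "kept_peaks") <- kept
  beats
}

#' Resample a beat to a fixed width
#'
#' Linear interpolation onto `n` equally spaced points spanning the beat;
#' endpoints are preserved exactly and a constant beat stays constant.
#'
#' @param beat Numeric vector of length >= 2.
#' @param n Output width (default 200).
#' @export
resample_beat <- function(beat, n = 200L) {
  if (length(beat) < 2L) stop("beat must have at least 2 samples", call. = FALSE)
  stats::approx(seq(0, 1, length.out = length(beat)), beat,
                xout = seq(0, 1, length.out = n))$y
}

#' Labelled fixed-width beat matrix
#'
#' @param beats Numeric matrix, one beat per row.
#' @param labels Per-beat class labels (length `nrow(beats)`).
#' @param provenance Optional per-beat source-record ids.
#' @export
beat_matrix <- function(beats, labels, provenance = NULL) {
  beats <- as.matrix(beats)
  if (!is.numeric(beats) || any(!is.finite(beats)))
    stop("beats must be a finite numeric matrix", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(beats))
    stop("one label per beat row is required", call. = FALSE)
  if (is.null(provenance)) provenance <- rep(NA_character_, nrow(beats))
  structure(list(beats = beats, labels = labels,
                 provenance = as.character(provenance)),
            class = "beat_matrix")
}

#' @export
print.beat_matrix <- function(x, ...) {
  cat(sprintf("Beat matrix: %d beats x %d samples; labels: %s\n",
              nrow(x$beats), ncol(x$beats),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Full preprocessing pipeline: records to beat matrix
#'
#' For each `(signal, label)` record: Savitzky-Golay denoise, R-peak
#' detection, RR-based segmentation, resampling to `n` samples. Records that
#' fail (e.g. too few peaks) are skipped with a warning; an empty total is an
#' error. The pipeline has no random component, so identical input yields an
#' identical matrix.
#'
#' @param records List of `list(signal = <ecg_signal>, label = <chr>,
#'   id = <chr optional>)`.
#' @param n Beat width after resampling (default 200).
#' @param window,polyorder Denoising parameters, see [denoise()].
#' @return A [beat_matrix()]; attribute `beat_counts` logs per-record yields.
#' @export
build_beat_matrix <- function(records, n = 200L, window = NULL, polyorder = 3L) {
  if (!length(records)) stop("no records supplied", call. = FALSE)
  rows <- list()
  labels <- character(0)
  prov <- character(0)
  counts <- integer(length(records))
  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    id <- if (!is.null(rec$id)) rec$id else sprintf("record%d", ri)
    got <- tryCatch({
      sm <- denoise(rec$signal, window = window, polyorder = polyorder)
      pk <- detect_r_peaks(sm)
      beats <- segment_beats(sm, pk)
      lapply(beats, resample_beat, n = n)
    }, error = function(e) {
      warning(sprintf("record %s skipped: %s", id, conditionMessage(e)))
      list()
    })
    counts[ri] <- length(got)
    if (length(got)) {
      rows <- c(rows, got)
      labels <- c(labels, rep(rec$label, length(got)))
      prov <- c(prov, rep(id, length(got)))
    }
  }
  if (!length(rows)) stop("no beats could be extracted from any record", call. = FALSE)
  bm <- beat_matrix(do.call(rbind, rows), labels, prov)
  attr(bm, "beat_counts") <- counts
  bm
}
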