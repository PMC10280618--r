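#' Detect systolic peaks in a PPG waveform
#'
#' Local maxima exceeding an adaptive threshold (mean + 0.3 SD of a centred
#' 5-second sliding window), kept greedily by descending amplitude with a
#' minimum separation of 0.333 s (<= 180 bpm).
#'
#' @param signal Numeric PPG waveform (ideally denoised).
#' @param fs Sampling rate in Hz.
#' @return Ascending integer vector of peak sample indices.
#' @export
detect_peaks <- function(signal, fs) {
  n <- length(signal)
  if (n < 2 * fs) stop("need at least 2 s of samples for peak detection")
  w <- max(3L, round(5 * fs))
  half <- w %/% 2L
  cs <- cumsum(c(0, signal))
  cs2 <- cumsum(c(0, signal^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1L
  mu <- (cs[hi + 1L] - cs[lo]) / cnt
  v <- pmax((cs2[hi + 1L] - cs2[lo]) / cnt - mu^2, 0)
  thr <- mu + 0.3 * sqrt(v)

  i <- 2:(n - 1L)
  cand <- i[signal[i] > signal[i - 1L] & signal[i] >= signal[i + 1L] &
              signal[i] > thr[i]]
  if (length(cand) == 0) stop("no peaks detected")
  min_sep <- 0.333 * fs
  keep <- logical(length(cand))
  ord <- order(-signal[cand], cand)          # amplitude desc, index asc
  taken <- integer(0)
  for (j in ord) {
    if (all(abs(cand[j] - taken) >= min_sep)) {
      keep[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  peaks <- sort(cand[keep])
  if (length(peaks) < 3) stop("fewer than 3 peaks detected")
  peaks
}

#' Peak-to-peak interval series with physiologic filtering
#'
#' Converts peak indices to PP intervals in ms and drops intervals outside
#' the physiologic band \[333, 1500\] ms together with their timestamps.
#'
#' @param peaks Ascending peak sample indices (at least 3).
#' @param fs Sampling rate in Hz.
#' @return A list of class `pp_series` with `intervals_ms` and
#'   `peak_times_s` (the time of the trailing peak of each interval, plus
#'   the leading peak at the front; `length(peak_times_s) ==
#'   length(intervals_ms) + 1`).
#' @export
compute_pp_intervals <- function(peaks, fs) {
  stopifnot(length(peaks) >= 3, !is.unsorted(peaks))
  iv <- diff(peaks) * 1000 / fs
  times <- peaks / fs
  ok <- iv >= 333 & iv <= 1500
  iv <- iv[ok]
  if (length(iv) < 2) stop("fewer than 2 physiologic PP intervals remain")
  # keep the timestamp of the trailing peak of each surviving interval
  keep_times <- c(times[1L], times[-1L][ok])
  structure(list(intervals_ms = iv, peak_times_s = keep_times),
            class = "pp_series")
}

#' Time-domain heart rate variability features
#'
#' Returns meanPP, SDNN, RMSSD, SDSD (all ms), NN50 (count of successive
#' differences strictly greater than 50 ms in magnitude) and pNN50 (%).
#' Sample (n-1) standard deviations throughout.
#'
#' @param pp A `pp_series` from [compute_pp_intervals()].
#' @return Named numeric vector of length 6.
#' @export
hrv_time_features <- function(pp) {
  iv <- pp$intervals_ms
  if (length(iv) < 3) stop("need at least 3 intervals for HRV time features")
  d <- diff(iv)
  nn50 <- sum(abs(d) > 50)
  c(meanPP = mean(iv),
    sdnn = stats::sd(iv),
    rmssd = sqrt(mean(d^2)),
    sdsd = stats::sd(d),
    nn50 = nn50,
    pnn50 = 100 * nn50 / length(d))
}

# Welch power spectral density of a uniformly sampled series.
# Hamming-windowed segments of length nseg with 50% overlap, mean removed
# per segment; density normalised so that trapezoidal integration over
# frequency returns power in squared input units.
welch_psd <- function(x, fs, nseg = min(256L, length(x))) {
  n <- length(x)
  nseg <- min(nseg, n)
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = step)
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nseg) - 1L) / (nseg - 1L))
  u <- sum(win^2)
  acc <- NULL
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- Mod(stats::fft(seg))^2 / (u * fs)
    acc <- if (is.null(acc)) p else acc + p
  }
  p <- acc / length(starts)
  half <- floor(nseg / 2)
  freq <- (0:half) * fs / nseg
  dens <- p[1:(half + 1L)]
  # one-sided: double every bin except DC (and Nyquist when nseg even)
  dbl <- rep(2, half + 1L); dbl[1L] <- 1
  if (nseg %% 2 == 0) dbl[half + 1L] <- 1
  list(freq = freq, psd = dens * dbl)
}

trapz_band <- function(freq, psd, lo, hi) {
  sel <- freq >= lo & freq < hi
  if (sum(sel) < 2) return(0)
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Frequency-domain heart rate variability features
#'
#' The PP tachogram is cubic-spline interpolated to a uniform 4 Hz grid,
#' mean-removed, and its Welch power spectral density integrated over the
#' standard bands: VLF \[0, 0.04) Hz, LF \[0.04, 0.15) Hz, HF \[0.15, 0.4) Hz,
#' with TP over \[0, Nyquist\]. Also returns LF/HF (capped at 1e6 when
#' HF = 0), and the normalised powers LFnu = 100 LF/(LF+HF),
#' HFnu = 100 HF/(LF+HF).
#'
#' @param pp A `pp_series` spanning at least 30 s.
#' @param fs_resample Uniform resampling rate for the tachogram (Hz).
#' @return Named numeric vector: tp, vlf, lf, hf, lfhf, lfnu, hfnu.
#' @export
hrv_freq_features <- function(pp, fs_resample = 4) {
  t <- pp$peak_times_s[-1L]                 # interval i at its trailing peak
  v <- pp$intervals_ms
  if (max(t) - min(t) < 30) {
    stop("tachogram span below 30 s; cannot estimate LF/HF band powers")
  }
  grid <- seq(min(t), max(t), by = 1 / fs_resample)
  x <- stats::spline(t, v, xout = grid, method = "fmm")$y
  sp <- welch_psd(x - mean(x), fs_resample)
  tp <- trapz_band(sp$freq, sp$psd, 0, max(sp$freq) + 1e-9)
  vlf <- trapz_band(sp$freq, sp$psd, 0, 0.04)
  lf <- trapz_band(sp$freq, sp$psd, 0.04, 0.15)
  hf <- trapz_band(sp$freq, sp$psd, 0.15, 0.4)
  lfhf <- if (hf > 0) lf / hf else 1e6
  denom <- lf + hf
  lfnu <- if (denom > 0) 100 * lf / denom else 0
  hfnu <- if (denom > 0) 100 * hf / denom else 0
  c(tp = tp, vlf = vlf, lf = lf, hf = hf, lfhf = lfhf,
    lfnu = lfnu, hfnu = hfnu)
}

#' Descriptive statistics of the instantaneous heart rate
#'
#' Heart rates HR = 60000 / PP (bpm). Returns mean, median, mode (centre of
#' the most populated 1-bpm bin, ties to the lowest bin), sample variance,
#' SD, range, interquartile range, skewness (m3 / m2^1.5), kurtosis
#' (m4 / m2^2, non-excess) and the unscaled median absolute deviation.
#' Zero-variance series report skewness = kurtosis = 0.
#'
#' @param pp A `pp_series`.
#' @return Named numeric vector of length 10.
#' @export
hr_stats_features <- function(pp) {
  iv <- pp$intervals_ms
  if (length(iv) < 2) stop("need at least 2 intervals for HR statistics")
  hr <- 60000 / iv
  bins <- floor(hr + 0.5)                 # 1-bpm bins centred on integers
  tab <- table(bins)
  mode_hr <- as.numeric(names(tab)[which.max(tab)])  # ties -> lowest bin
  m <- mean(hr)
  ctr <- hr - m
  m2 <- mean(ctr^2)
  skew <- if (m2 > 0) mean(ctr^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(ctr^4) / m2^2 else 0
  c(mean = m,
    median = stats::median(hr),
    mode = mode_hr,
    var = stats::var(hr),
    sd = stats::sd(hr),
    range = max(hr) - min(hr),
    iqr = stats::IQR(hr),
    skew = skew,
    kurt = kurt,
    mad = stats::median(abs(hr - stats::median(hr))))
}

#' Mean and sample variance of an absorption-channel waveform
#'
#' @param signal Non-empty numeric vector (denoised 1450/1650 nm PPG).
#' @return Named numeric vector `c(mean, var)` (variance uses n-1; 0 for a
#'   single sample).
#' @export
absorption_features <- function(signal) {
  stopifnot(length(signal) > 0)
  v <- if (length(signal) > 1) stats::var(signal) else 0
  c(mean = mean(signal), var = v)
}

#' Hours since the previous meal
#'
#' Difference between the acquisition time and the latest meal at or before
#' it; if the acquisition precedes the first meal of the day, the gap is
#' computed across midnight from the previous day's last scheduled meal.
#'
#' @param acq_time Acquisition time, hours after midnight.
#' @param meal_times Ascending meal times, hours after midnight.
#' @return Hours since the previous meal.
#' @export
meal_time_feature <- function(acq_time, meal_times) {
  if (length(meal_times) == 0) stop("meal schedule is empty")
  meal_times <- sort(meal_times)
  before <- meal_times[meal_times <= acq_time]
  if (length(before) > 0) {
    acq_time - max(before)
  } else {
    24 + acq_time - max(meal_times)
  }
}

#' Canonical names of the 103-feature vector
#'
#' Category partition 1/2/8/52/40: meal timing (1), blood pressures (2),
#' absorption mean/variance for the four slow channels (8), 13 HRV features
#' for each of the four fast channels (52), and 10 heart-rate statistics for
#' each fast channel (40).
#'
#' @return Character vector of length 103.
#' @export
feature_names <- function() {
  hrv_names <- c("meanPP", "sdnn", "rmssd", "sdsd", "nn50", "pnn50",
                 "tp", "vlf", "lf", "hf", "lfhf", "lfnu", "hfnu")
  hr_names <- c("mean", "median", "mode", "var", "sd", "range", "iqr",
                "skew", "kurt", "mad")
  abs_ch <- c("1450a", "1450b", "1650a", "1650b")
  fast_ch <- paste0("880", letters[1:4])
  c("cat1_meal_dt",
    "cat2_sbp", "cat2_dbp",
    paste0("cat3_", rep(abs_ch, each = 2), "_", c("mean", "var")),
    paste0("cat4_", rep(fast_ch, each = 13), "_", hrv_names),
    paste0("cat5_", rep(fast_ch, each = 10), "_", hr_names))
}

#' Extract the 103-feature vector of one measurement
#'
#' @param m One row of a measurement tibble (as a list or one-row tibble)
#'   with denoised `ppg` channels, `acq_time`, `meal_times`, `sbp`, `dbp`.
#' @return Named numeric vector of length 103 in the canonical order.
#' @export
measurement_features <- function(m) {
  if (is.data.frame(m)) m <- as.list(m[1, ])
  ppg <- m$ppg
  if (is.list(ppg) && length(ppg) == 1 && !inherits(ppg[[1]], "ppg_record")) {
    ppg <- ppg[[1]]
  }
  meal_times <- m$meal_times
  if (is.list(meal_times)) meal_times <- meal_times[[1]]
  if (length(ppg) != 8) stop("a measurement must carry exactly 8 channels")

  cat1 <- meal_time_feature(m$acq_time, meal_times)
  cat2 <- c(m$sbp, m$dbp)
  cat3 <- numeric(0)
  for (k in 5:8) {
    rec <- ppg[[k]]
    cat3 <- c(cat3, tryCatch(absorption_features(rec$samples),
      error = function(e) stop("channel ", k - 5L, " (", rec$wavelength_nm,
                               " nm) absorption features failed: ",
                               conditionMessage(e))))
  }
  cat4 <- numeric(0); cat5 <- numeric(0)
  for (k in 1:4) {
    rec <- ppg[[k]]
    pp <- tryCatch({
      peaks <- detect_peaks(rec$samples, rec$fs)
      compute_pp_intervals(peaks, rec$fs)
    }, error = function(e) stop("channel ", k - 1L,
                                " (880 nm) PP extraction failed: ",
                                conditionMessage(e)))
    cat4 <- c(cat4, hrv_time_features(pp), hrv_freq_features(pp))
    cat5 <- c(cat5, hr_stats_features(pp))
  }
  out <- c(cat1, cat2, cat3, cat4, cat5)
  names(out) <- feature_names()
  out
}

#' Extract features for every measurement of a table
#'
#' Maps [measurement_features()] over the rows of a (denoised) measurement
#' tibble and returns a features-by-measurement table carrying the
#' companion reference columns.
#'
#' @param data A measurement tibble (see [generate_dataset()]), denoised.
#' @return A tibble with `subject_id`, `measurement_id`, `glucose_ref` and
#'   the 103 feature columns.
#' @export
extract_features <- function(data) {
  feats <- purrr::map(seq_len(nrow(data)), function(i) {
    measurement_features(as.list(data[i, ]))
  })
  fmat <- do.call(rbind, feats)
  dplyr::bind_cols(
    tibble::tibble(subject_id = data$subject_id,
                   measurement_id = data$measurement_id,
                   glucose_ref = data$glucose_ref),
    tibble::as_tibble(fmat)
  )
}
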