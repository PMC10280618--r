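#' Configuration for the synthetic PPG/glucose generator
#'
#' Bundles every tunable of the synthetic data generator: cohort size,
#' recording geometry (two slow near-infrared absorption wavelengths at
#' 50 Hz, one fast 880 nm wavelength at 1000 Hz), the diet-driven glucose
#' range, the strength of the glucose coupling into the waveform's DC level
#' and AC amplitude, the LF/HF beat-interval modulation bands, and the
#' noise/drift levels.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param measurements_per_subject Measurements per subject (default 36:
#'   three per day over the 12-day diet protocol).
#' @param duration_s Seconds of PPG per channel per measurement (default 60).
#' @param fs_slow Sampling rate of the 1450/1650 nm channels (Hz, default 50).
#' @param fs_fast Sampling rate of the 880 nm channels (Hz, default 1000).
#' @param glucose_range Attainable glucose range in mmol/L (default
#'   `c(3.5, 13)`); trajectories are clamped into it.
#' @param coupling Dimensionless strength scaling the glucose-to-waveform
#'   maps (default 1).
#' @param hrv_lf_hz,hrv_hf_hz Band centres of the low- and high-frequency
#'   beat-interval modulation (Hz, defaults 0.1 and 0.25).
#' @param noise_sd White-noise SD added to each waveform (amplitude units,
#'   default 0.02).
#' @param drift_amp Peak amplitude of the slow baseline drift (default 0.05).
#' @param seed Root integer seed; all randomness derives from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 8L,
                         measurements_per_subject = 36L,
                         duration_s = 60,
                         fs_slow = 50,
                         fs_fast = 1000,
                         glucose_range = c(3.5, 13),
                         coupling = 1,
                         hrv_lf_hz = 0.1,
                         hrv_hf_hz = 0.25,
                         noise_sd = 0.02,
                         drift_amp = 0.05,
                         seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    measurements_per_subject = as.integer(measurements_per_subject),
    duration_s = duration_s, fs_slow = fs_slow, fs_fast = fs_fast,
    glucose_range = as.numeric(glucose_range), coupling = coupling,
    hrv_lf_hz = hrv_lf_hz, hrv_hf_hz = hrv_hf_hz,
    noise_sd = noise_sd, drift_amp = drift_amp, seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$fs_slow >= cfg$fs_fast) stop("fs_slow must be below fs_fast")
  if (length(cfg$glucose_range) != 2 ||
      cfg$glucose_range[1] >= cfg$glucose_range[2]) {
    stop("glucose_range must be an increasing (low, high) pair")
  }
  if (cfg$fs_slow <= 0 || cfg$fs_fast <= 0 || cfg$duration_s <= 0 ||
      cfg$hrv_lf_hz <= 0 || cfg$hrv_hf_hz <= 0) {
    stop("rates and durations must be positive")
  }
  if (cfg$n_subjects < 1 || cfg$measurements_per_subject < 1) {
    stop("cohort sizes must be at least 1")
  }
  if (cfg$noise_sd < 0 || cfg$drift_amp < 0) stop("noise levels must be >= 0")
  invisible(cfg)
}

# fixed daily meal schedule, hours after midnight
MEAL_SCHEDULE <- c(7.5, 12.5, 18.5)

# derive a child seed deterministically from the root seed; kept < 2^31
child_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 1000003 + (v %% 65521) + 17) %% 2147483629
  as.integer(h)
}

#' Diet-driven glucose trajectory for one subject
#'
#' Simulates 12 days of glucose readings at three post-meal measurement
#' times per day under the three-phase diet protocol: a low-glucose
#' ketogenic phase (days 1-4), a normal-diet phase (days 5-8) and a
#' high-glucose phase with post-meal cola spikes (days 9-12). Values are
#' clamped into `config$glucose_range`.
#'
#' @param config A [synth_config()].
#' @param subject_seed Integer seed for this subject's trajectory.
#' @return A tibble with `day`, `meal_index`, `time_h` (hours after the
#'   protocol start) and `glucose` (mmol/L), one row per measurement slot.
#' @export
generate_glucose_trajectory <- function(config, subject_seed = config$seed) {
  validate_synth_config(config)
  n_days <- 12L
  slots <- expand.grid(meal_index = seq_along(MEAL_SCHEDULE), day = 1:n_days)
  slots <- slots[order(slots$day, slots$meal_index), ]
  phase <- cut(slots$day, c(0, 4, 8, 12), labels = FALSE)
  base_mean <- c(4.4, 6.0, 8.2)[phase]            # ketogenic / normal / cola
  spike <- ifelse(phase == 3 & slots$meal_index >= 2, 2.2, 0)
  old <- .Random.seed_guard(child_seed(subject_seed, 101L))
  on.exit(old(), add = TRUE)
  wander <- as.numeric(stats::filter(stats::rnorm(nrow(slots), 0, 0.45),
                                     0.6, method = "recursive"))
  g <- base_mean + spike + wander
  g <- pmin(pmax(g, config$glucose_range[1]), config$glucose_range[2])
  tibble::tibble(
    day = slots$day,
    meal_index = slots$meal_index,
    time_h = (slots$day - 1) * 24 + MEAL_SCHEDULE[slots$meal_index] + 1,
    glucose = g
  )
}

# save/restore RNG state around seeded sections
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' Beat-interval sequence with LF/HF structure
#'
#' Mean interval 800 ms modulated by two sinusoids at the configured LF and
#' HF band centres plus white jitter. Glucose couples into the intervals
#' the way reduced autonomic regulation does at hyperglycemia: the HF
#' modulation depth shrinks and the mean heart rate rises slightly as
#' glucose rises, so both the HRV and the HR feature blocks carry glucose
#' information.
#'
#' @param n_beats Number of intervals to generate.
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param glucose Glucose level in mmol/L steering the coupling (default 6,
#'   a neutral level).
#' @param jitter_sd White jitter SD in ms (default 10; 0 gives a purely
#'   deterministic modulation).
#' @return Numeric vector of beat intervals in ms.
#' @export
generate_beat_intervals <- function(n_beats, config, seed = config$seed,
                                    glucose = 6, jitter_sd = 10) {
  old <- .Random.seed_guard(child_seed(seed, 211L))
  on.exit(old(), add = TRUE)
  t_approx <- cumsum(rep(0.8, n_beats)) - 0.8       # seconds, nominal
  hf_depth <- max(25 * (1 + config$coupling * 0.12 * (6 - glucose)), 3)
  mean_iv <- 800 - config$coupling * 12 * (glucose - 6)
  lf <- 35 * sin(2 * pi * config$hrv_lf_hz * t_approx +
                   stats::runif(1, 0, 2 * pi))
  hf <- hf_depth * sin(2 * pi * config$hrv_hf_hz * t_approx +
                         stats::runif(1, 0, 2 * pi))
  iv <- mean_iv + lf + hf + stats::rnorm(n_beats, 0, jitter_sd)
  pmax(iv, 400)
}

#' Synthesise one PPG channel
#'
#' The waveform is a glucose-coupled DC level plus a train of two-Gaussian
#' pulses (systolic peak and a dicrotic bump at 0.4 of the beat) scaled by a
#' glucose-coupled AC amplitude, plus a slow sinusoidal baseline drift and
#' white noise. The 880 nm channels are generated AC-coupled (no DC offset),
#' mirroring HRV-oriented fast front-ends; the 1450/1650 nm absorption
#' channels carry the glucose-dependent DC level.
#'
#' @param beat_intervals_ms Positive beat intervals in ms; must cover at
#'   least 5 beats over `duration_s`.
#' @param wavelength_nm One of 880, 1450, 1650.
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param glucose Reference glucose in mmol/L.
#' @param config A [synth_config()].
#' @param seed Integer seed for this channel's noise and drift phase.
#' @return A list of class `ppg_record` with `samples`, `fs`,
#'   `wavelength_nm`, `channel_id` (set by the caller), and `n_beats`, the
#'   number of pulse peaks planted inside the recording.
#' @export
generate_ppg_record <- function(beat_intervals_ms, wavelength_nm, fs,
                                duration_s, glucose, config,
                                seed = config$seed) {
  if (any(beat_intervals_ms <= 0)) stop("beat intervals must be positive")
  if (!wavelength_nm %in% c(880, 1450, 1650)) {
    stop("wavelength_nm must be one of 880, 1450, 1650")
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  beat_times <- cumsum(c(0.4, beat_intervals_ms / 1000))  # first peak at .4 s
  beat_times <- beat_times[beat_times < duration_s - 0.2]
  if (length(beat_times) < 5) stop("duration must cover at least 5 beats")

  # affine glucose coupling: DC rises, AC falls (saturating at 0)
  dc <- if (wavelength_nm == 880) 0 else
    config$coupling * (1.0 + 0.08 * glucose)
  ac <- max(config$coupling * (0.60 - 0.025 * glucose), 0.05)

  wave <- rep(dc, n)
  iv_s <- c(beat_intervals_ms / 1000,
            beat_intervals_ms[length(beat_intervals_ms)] / 1000)
  for (k in seq_along(beat_times)) {
    tk <- beat_times[k]
    Tk <- iv_s[min(k, length(iv_s))]
    # systolic peak + dicrotic bump at 0.4 of the beat
    wave <- wave +
      ac * exp(-((t - tk)^2) / (2 * (0.11 * Tk)^2)) +
      0.35 * ac * exp(-((t - tk - 0.4 * Tk)^2) / (2 * (0.16 * Tk)^2))
  }
  old <- .Random.seed_guard(child_seed(seed, 307L, round(wavelength_nm)))
  on.exit(old(), add = TRUE)
  phase <- stats::runif(1, 0, 2 * pi)
  wave <- wave + config$drift_amp * sin(2 * pi * 0.03 * t + phase)
  wave <- wave + stats::rnorm(n, 0, config$noise_sd)
  structure(
    list(samples = wave, fs = fs, wavelength_nm = wavelength_nm,
         channel_id = NA_integer_, n_beats = length(beat_times)),
    class = "ppg_record"
  )
}

#' @export
print.ppg_record <- function(x, ...) {
  cat("<ppg_record>", x$wavelength_nm, "nm |", x$fs, "Hz |",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Generate a synthetic multi-wavelength PPG dataset
#'
#' For each subject, measurement slots are sampled along the subject's
#' 12-day diet-driven glucose trajectory; each measurement carries eight
#' PPG channels (four at 880 nm sampled fast, two at 1450 nm and two at
#' 1650 nm sampled slow), reference glucose, blood pressures, the
#' acquisition time and the daily meal schedule. Fully deterministic given
#' the config seed.
#'
#' @param config A [synth_config()].
#' @return A tibble with one row per measurement: `subject_id`,
#'   `measurement_id`, `glucose_ref`, `sbp`, `dbp`, `acq_time`,
#'   `meal_times` (list-column), `ppg` (list-column of 8 `ppg_record`s) and
#'   `n_beats` (planted beat count of the fast channels).
#' @examples
#' cfg <- synth_config(n_subjects = 1, measurements_per_subject = 2,
#'                     duration_s = 35, seed = 7)
#' d <- generate_dataset(cfg)
#' nrow(d)
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    traj <- generate_glucose_trajectory(config, child_seed(config$seed, s))
    # evenly thin the 36 trajectory slots to measurements_per_subject
    idx <- unique(round(seq(1, nrow(traj),
                            length.out = config$measurements_per_subject)))
    while (length(idx) < config$measurements_per_subject) {
      extra <- setdiff(seq_len(nrow(traj)), idx)
      if (length(extra) == 0) break
      idx <- sort(c(idx, extra[1]))
    }
    old <- .Random.seed_guard(child_seed(config$seed, s, 557L))
    sbp <- stats::rnorm(length(idx), 118, 8)
    dbp <- stats::rnorm(length(idx), 76, 6)
    old()
    for (k in seq_along(idx)) {
      slot <- traj[idx[k], ]
      mseed <- child_seed(config$seed, s, k, 701L)
      n_beats_needed <- ceiling(config$duration_s / 0.4) + 5L
      iv <- generate_beat_intervals(n_beats_needed, config, mseed,
                                    glucose = slot$glucose)
      ppg <- vector("list", 8L)
      for (ch in 0:3) {
        rec <- generate_ppg_record(iv, 880, config$fs_fast,
                                   config$duration_s, slot$glucose, config,
                                   child_seed(mseed, ch))
        rec$channel_id <- ch
        ppg[[ch + 1L]] <- rec
      }
      wl_slow <- c(1450, 1450, 1650, 1650)
      for (ch in 0:3) {
        rec <- generate_ppg_record(iv, wl_slow[ch + 1L], config$fs_slow,
                                   config$duration_s, slot$glucose, config,
                                   child_seed(mseed, 10L + ch))
        rec$channel_id <- ch
        ppg[[ch + 5L]] <- rec
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = s,
        measurement_id = k,
        glucose_ref = slot$glucose,
        sbp = sbp[k], dbp = dbp[k],
        acq_time = MEAL_SCHEDULE[slot$meal_index] + 1,
        meal_times = list(MEAL_SCHEDULE),
        ppg = list(ppg),
        n_beats = ppg[[1]]$n_beats
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Denoise every PPG channel of a measurement table
#'
#' Applies [denoise_ppg()] to each of the eight channels of every
#' measurement row.
#'
#' @param data A measurement tibble from [generate_dataset()].
#' @param window,wordlength Passed to [denoise_ppg()].
#' @return The same tibble with the `ppg` list-column denoised.
#' @export
denoise_measurements <- function(data, window = 32L, wordlength = 13L) {
  data$ppg <- purrr::map(data$ppg, function(chans) {
    purrr::map(chans, function(rec) {
      rec$samples <- denoise_ppg(rec$samples, window, wordlength)
      rec
    })
  })
  data
}
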