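## Synthetic ambulatory patient: four wearable channels at their native rates
## driven by a latent pre-ictal process with known ground truth. This is the
## test bed standing in for clinical recordings that were never deposited:
## every downstream stage (synchronization, GP repair, subspace
## identification, ranking, fault suites) is validated against it.

#' Configuration for the synthetic ambulatory patient
#'
#' Defaults emulate the acquisition scenario the models target: a patient
#' monitored for about a month accruing at least eight migraine events, with
#' channels at their native rates (TEMP and EDA at 1 Hz, SpO2 at 3 Hz, HR at
#' 1 Hz, optionally raw ECG at 250 Hz), circadian baseline drift, and a
#' latent pre-ictal driver that precedes each pain onset by `lead_time`
#' minutes.
#'
#' @param duration_days length of the recording in days
#' @param n_migraines number of migraine events (>= 1, or 0 for a pure
#'   baseline recording)
#' @param lead_time minutes by which the latent driver leads pain onset (> 0)
#' @param attack_duration_range min/max pain duration in minutes
#' @param snr_db per-channel signal-to-noise ratio in dB (`Inf` = noise off)
#' @param gap_rate expected number of dropout gaps per channel per day
#' @param gap_length_range min/max gap length in minutes
#' @param seed integer; fully determines the output
#' @param make_ecg if `TRUE`, emit a 250 Hz template-based ECG pulse train
#'   instead of the 1 Hz HR channel (exercises [ecg_to_hr()])
#' @param effect_sizes named per-channel peak deflection of the pre-ictal
#'   response, in channel units
#' @param circadian_amp named per-channel amplitude of the 24-h sinusoid
#' @param intrinsic_frac intrinsic (physiological, AR(1) at minute scale)
#'   variability per channel, as a fraction of the effect size; always
#'   present regardless of `snr_db` -- real autonomic signals fluctuate, and
#'   it is this broadband content that makes the channels persistently
#'   exciting for subspace identification
#' @return an object of class `synthetic_config`
#' @export
synthetic_config <- function(duration_days = 28,
                             n_migraines = 12,
                             lead_time = 60,
                             attack_duration_range = c(60, 240),
                             snr_db = 20,
                             gap_rate = 2,
                             gap_length_range = c(5, 30),
                             seed = 1L,
                             make_ecg = FALSE,
                             effect_sizes = c(TEMP = 0.8, EDA = 3,
                                              HR = 12, SpO2 = -3),
                             circadian_amp = c(TEMP = 0.5, EDA = 1,
                                               HR = 5, SpO2 = 0.5),
                             intrinsic_frac = 0.1) {
  stopifnot(duration_days > 0, lead_time > 0, n_migraines >= 0,
            length(attack_duration_range) == 2,
            diff(attack_duration_range) >= 0,
            gap_rate >= 0, length(gap_length_range) == 2)
  structure(list(duration_days = duration_days, n_migraines = n_migraines,
                 lead_time = lead_time,
                 attack_duration_range = attack_duration_range,
                 snr_db = snr_db, gap_rate = gap_rate,
                 gap_length_range = gap_length_range,
                 seed = as.integer(seed), make_ecg = make_ecg,
                 effect_sizes = effect_sizes, circadian_amp = circadian_amp,
                 intrinsic_frac = intrinsic_frac),
            class = "synthetic_config")
}

#' One sensor channel at its native rate
#'
#' @param name one of `TEMP`, `EDA`, `SpO2`, `ECG`, `HR`
#' @param rate sampling rate in Hz
#' @param time numeric vector of timestamps in minutes, strictly increasing
#' @param values numeric vector, finite outside gaps
#' @param units channel units (degC, uS, %, raw, bpm)
#' @param gap_mask data.frame with columns `start`, `end` (minutes) listing
#'   missing intervals
#' @return an object of class `channel_series`
#' @export
channel_series <- function(name, rate, time, values, units,
                           gap_mask = data.frame(start = numeric(0),
                                                 end = numeric(0))) {
  stopifnot(length(time) == length(values))
  if (is.unsorted(time, strictly = TRUE)) stop("timestamps must be strictly increasing")
  if (!all(is.finite(values)))
    stop("channel values must be finite; gaps are sample removals, not NAs")
  structure(list(name = name, rate = rate, time = time, values = values,
                 units = units, gap_mask = as.data.frame(gap_mask)),
            class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %s @ %g Hz [%s], %d samples, %d gap(s)\n",
              x$name, x$rate, x$units, length(x$values), nrow(x$gap_mask)))
  invisible(x)
}

channel_units <- c(TEMP = "degC", EDA = "uS", SpO2 = "%", HR = "bpm",
                   ECG = "raw")
channel_baselines <- c(TEMP = 33, EDA = 5, HR = 70, SpO2 = 97)

## Saturation constants used by the fault suites (per-channel plausible
## stuck-at values); loss faults read 0.
#' Default per-channel saturation fault values
#' @return named numeric vector (TEMP 35 degC, EDA 25 uS, HR 100 bpm, SpO2 80%)
#' @export
saturation_defaults <- function() c(TEMP = 35, EDA = 25, HR = 100, SpO2 = 80)

# random stable LTI generator matrices for the latent pre-ictal response
rand_stable_lti <- function(nx, radius) {
  A <- matrix(stats::rnorm(nx * nx), nx, nx)
  A * (radius / max(spectral_radius(A), 1e-9))
}

#' Generate a synthetic ambulatory recording with known ground truth
#'
#' Pain events are placed in disjoint slots across the recording; each gets a
#' two-semi-Gaussian true intensity curve. A latent stable LTI state (fast
#' poles, spectral radius 0.6 so its readout is nearly in phase with its
#' input) is excited by the driver -- the pain curve advanced by `lead_time`
#' minutes -- and each channel reads out baseline + circadian sinusoid +
#' slow random walk + effect_size * latent readout, plus white measurement
#' noise set by `snr_db`. No gaps are injected here (see [inject_gaps()]).
#'
#' @param config a [synthetic_config()]
#' @return a list with class `raw_recording` entries `channels` (named list
#'   of [channel_series()]), `duration_min`, and `truth`: a `ground_truth`
#'   list of `events` (data.frame aura_start/pain_start/peak_time/pain_end),
#'   `true_curves`, `annotations`, `latent_states`, `driver`, `pain`,
#'   `lead_time`
#' @export
generate_patient <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  t_min <- round(config$duration_days * 1440)
  grid <- seq_len(t_min) - 1          # minute stamps 0 .. t_min-1

  ## --- event placement -------------------------------------------------
  n_ev <- config$n_migraines
  events <- data.frame(aura_start = numeric(0), pain_start = numeric(0),
                       peak_time = numeric(0), pain_end = numeric(0))
  true_curves <- list()
  if (n_ev > 0) {
    slot <- t_min / n_ev
    max_span <- config$lead_time + 40 + max(config$attack_duration_range) + 120
    if (slot < max_span)
      stop(sprintf(paste("capacity error: %d events need slots of >= %.0f min",
                         "but only %.0f min each are available"),
                   n_ev, max_span, slot))
    for (e in seq_len(n_ev)) {
      dur <- stats::runif(1, config$attack_duration_range[1],
                          config$attack_duration_range[2])
      aura_dur <- stats::runif(1, 20, 40)
      lo <- (e - 1) * slot + config$lead_time + aura_dur + 60
      hi <- e * slot - dur - 60
      pain_start <- stats::runif(1, lo, hi)
      peak <- pain_start + stats::runif(1, 0.25, 0.45) * dur
      pain_end <- pain_start + dur
      aura_start <- pain_start - aura_dur
      events[e, ] <- c(aura_start, pain_start, peak, pain_end)
      true_curves[[e]] <- symptomatic_curve(
        mu1 = peak,
        sigma1 = (peak - aura_start) / sqrt(2 * log(1 / 0.05)),
        mu2 = peak,
        sigma2 = (pain_end - peak) / sqrt(2 * log(1 / 0.05)))
    }
  }

  pain <- numeric(t_min)
  for (cv in true_curves) pain <- pmax(pain, evaluate_curve(cv, grid))
  ## driver: the pain curve advanced in time by lead_time
  driver <- numeric(t_min)
  for (cv in true_curves)
    driver <- pmax(driver, evaluate_curve(cv, grid + config$lead_time))

  ## --- latent LTI response ---------------------------------------------
  nx <- 3L
  A <- rand_stable_lti(nx, 0.6)
  B <- matrix(abs(stats::rnorm(nx)), nx, 1)
  Cm <- matrix(stats::rnorm(4 * nx), 4, nx,
               dimnames = list(c("TEMP", "EDA", "HR", "SpO2"), NULL))
  X <- matrix(0, t_min, nx)
  x <- numeric(nx)
  for (k in seq_len(t_min - 1)) {
    x <- drop(A %*% x + B * driver[k])
    X[k + 1, ] <- x
  }
  effect <- X %*% t(Cm)               # t_min x 4
  for (ch in colnames(effect)) {
    m <- max(abs(effect[, ch]))
    effect[, ch] <- if (m > 0) effect[, ch] * sign(sum(effect[, ch] * driver)) / m
                    else driver      # degenerate readout: fall back to driver
  }

  ## --- per-channel minute-level clean signals --------------------------
  clean <- list()
  for (ch in c("TEMP", "EDA", "HR", "SpO2")) {
    circ <- config$circadian_amp[[ch]] *
      sin(2 * pi * grid / 1440 + stats::runif(1, 0, 2 * pi))
    rw <- cumsum(stats::rnorm(t_min, sd = 0.02 * config$circadian_amp[[ch]]))
    rw <- stats::filter(rw, rep(1 / 60, 60), sides = 2)
    rw[is.na(rw)] <- 0
    intrinsic <- as.numeric(stats::filter(
      stats::rnorm(t_min, sd = config$intrinsic_frac *
                     abs(config$effect_sizes[[ch]]) * sqrt(1 - 0.9^2)),
      0.9, method = "recursive"))
    clean[[ch]] <- channel_baselines[[ch]] + circ + as.numeric(rw) +
      intrinsic + config$effect_sizes[[ch]] * effect[, ch]
  }
  clean$SpO2 <- pmin(clean$SpO2, 100)

  ## --- native-rate sampling with noise ---------------------------------
  snr <- config$snr_db
  snr_for <- function(ch) if (length(snr) > 1) snr[[ch]] else snr
  to_native <- function(ch, rate) {
    step <- 1 / (60 * rate)
    tt <- seq(0, t_min - 1, by = step)
    v <- stats::approx(grid, clean[[ch]], xout = tt, rule = 2)$y
    s <- snr_for(ch)
    if (is.finite(s)) {
      noise_sd <- stats::sd(clean[[ch]]) / 10^(s / 20)
      v <- v + stats::rnorm(length(v), sd = noise_sd)
    }
    channel_series(ch, rate, tt, v, channel_units[[ch]])
  }

  channels <- list(TEMP = to_native("TEMP", 1), EDA = to_native("EDA", 1),
                   SpO2 = to_native("SpO2", 3))
  if (config$make_ecg) {
    channels$ECG <- synth_ecg(clean$HR, t_min)
  } else {
    channels$HR <- to_native("HR", 1)
  }

  annotations <- if (n_ev > 0) {
    lapply(seq_len(n_ev), function(e)
      annotate_event(events[e, ], true_curves[[e]]))
  } else list()

  truth <- structure(list(events = events, true_curves = true_curves,
                          annotations = annotations, latent_states = X,
                          driver = driver, pain = pain,
                          lead_time = config$lead_time),
                     class = "ground_truth")
  structure(list(channels = channels, duration_min = t_min, truth = truth),
            class = "raw_recording")
}

# sample the true curve into signed punctual marks, as a patient would
annotate_event <- function(ev, curve) {
  rise <- seq(ev$aura_start + 2, ev$peak_time, length.out = 5)
  fall <- seq(ev$peak_time, ev$pain_end - 1, length.out = 5)[-1]
  tt <- c(rise, fall)
  lev <- 10 * evaluate_curve(curve, tt)
  pain_annotation(aura_start = ev$aura_start, pain_start = ev$pain_start,
                  pain_end = ev$pain_end,
                  marks = data.frame(t = tt, delta = diff(c(0, lev))),
                  global_index = 7L)
}

# template-based quasi-periodic ECG pulse train at 250 Hz whose
# instantaneous rate follows the minute-level HR trace
synth_ecg <- function(hr_min, t_min, rate = 250) {
  n <- t_min * 60 * rate
  tt_sec <- seq_len(n) / rate          # seconds
  hr_at <- function(t_sec)
    stats::approx(seq_len(t_min) - 1, hr_min, xout = t_sec / 60, rule = 2)$y
  beats <- numeric(0)
  t <- 0
  while (t < t_min * 60) {
    rr <- 60 / hr_at(t)
    t <- t + rr
    beats <- c(beats, t)
  }
  v <- numeric(n)
  tmpl_halfwidth <- 0.02               # 20 ms Gaussian "R wave"
  for (b in beats) {
    i0 <- max(1L, floor((b - 0.05) * rate))
    i1 <- min(n, ceiling((b + 0.05) * rate))
    if (i0 > n) break
    idx <- i0:i1
    v[idx] <- v[idx] + exp(-((tt_sec[idx] - b)^2) / (2 * tmpl_halfwidth^2))
  }
  channel_series("ECG", rate, tt_sec / 60, v, "raw")
}

#' Inject Bluetooth-dropout-style gaps into a recording
#'
#' Gap start times are drawn from a Poisson process with rate
#' `config$gap_rate` per channel per day; lengths are uniform on
#' `config$gap_length_range`. Samples inside the drawn intervals are removed
#' from the channel and the intervals recorded in its gap mask. Samples
#' outside gaps are untouched.
#'
#' @param recording a `raw_recording` with no prior gaps
#' @param config a [synthetic_config()]
#' @param forced_gaps optional named list: per channel a data.frame
#'   `start`,`end` of gaps to impose deterministically (used by tests and
#'   fault scripts); suppresses random drawing for those channels
#' @return the recording with gaps removed and masks filled
#' @export
inject_gaps <- function(recording, config = synthetic_config(),
                        forced_gaps = NULL) {
  stopifnot(inherits(recording, "raw_recording"))
  if (config$gap_rate < 0) stop("gap_rate must be >= 0")
  if (any(vapply(recording$channels, function(ch) nrow(ch$gap_mask) > 0,
                 logical(1))))
    stop("recording already carries gap annotations")
  set.seed(config$seed + 104729L)      # decoupled from generate_patient draws
  days <- recording$duration_min / 1440
  for (nm in names(recording$channels)) {
    ch <- recording$channels[[nm]]
    gaps <- if (!is.null(forced_gaps) && nm %in% names(forced_gaps)) {
      as.data.frame(forced_gaps[[nm]])
    } else if (is.null(forced_gaps) && config$gap_rate > 0) {
      ng <- stats::rpois(1, config$gap_rate * days)
      if (ng > 0) {
        st <- sort(stats::runif(ng, 0, recording$duration_min))
        len <- stats::runif(ng, config$gap_length_range[1],
                            config$gap_length_range[2])
        data.frame(start = st, end = pmin(st + len, recording$duration_min))
      } else data.frame(start = numeric(0), end = numeric(0))
    } else data.frame(start = numeric(0), end = numeric(0))
    if (nrow(gaps) > 0) {
      # merge overlaps so the mask lists disjoint intervals
      gaps <- gaps[order(gaps$start), , drop = FALSE]
      merged <- gaps[1, , drop = FALSE]
      for (i in seq_len(nrow(gaps))[-1]) {
        if (gaps$start[i] <= merged$end[nrow(merged)]) {
          merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], gaps$end[i])
        } else merged <- rbind(merged, gaps[i, ])
      }
      drop <- rep(FALSE, length(ch$time))
      for (i in seq_len(nrow(merged)))
        drop <- drop | (ch$time >= merged$start[i] & ch$time < merged$end[i])
      recording$channels[[nm]] <- channel_series(
        ch$name, ch$rate, ch$time[!drop], ch$values[!drop], ch$units,
        gap_mask = merged)
    }
  }
  recording
}

#' List the gap intervals of every channel
#' @param recording a `raw_recording`
#' @return named list of data.frames `start`,`end` in minutes
#' @export
list_gaps <- function(recording) {
  lapply(recording$channels, function(ch) ch$gap_mask)
}
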