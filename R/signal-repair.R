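## Preprocessing: multi-rate channels are anti-alias filtered and decimated
## onto a shared 1-sample-per-minute grid, dropout gaps are imputed with a
## Gaussian process (posterior variance kept as a confidence band), and HR
## is derived from ECG by R-peak detection.

FEATURES <- c("TEMP", "EDA", "HR", "SpO2")

#' Construct a synchronized 1-min four-feature frame
#' @keywords internal
#' @noRd
new_frame <- function(grid, features, confidence, imputed, absent = character(0)) {
  structure(list(grid = grid, features = features, confidence = confidence,
                 imputed = imputed, absent = absent),
            class = "synchronized_frame")
}

#' @export
print.synchronized_frame <- function(x, ...) {
  cat(sprintf("<synchronized_frame> %d min, features: %s%s\n",
              length(x$grid), paste(setdiff(FEATURES, x$absent), collapse = ", "),
              if (length(x$absent))
                paste0(" (absent: ", paste(x$absent, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Synchronize multi-rate channels onto a common 1-min grid
#'
#' Channels sampled faster than the 1/60 Hz target are low-pass filtered with
#' a linear-phase windowed-sinc FIR decimator (cutoff at the target Nyquist
#' 1/120 Hz, order ~ 10x the decimation factor, Hamming window) and sampled
#' at the grid timestamps with the group delay compensated, so grid values
#' are phase-aligned across channels. Channels already at or below the grid
#' rate are resampled by linear interpolation (identity for a 1/min input).
#' Gap intervals propagate to the per-feature imputed mask; a channel that is
#' entirely missing raises the absent-feature flag consumed by the
#' sensor-dependent model selection system.
#'
#' @param channels named list of [channel_series()] (names within
#'   TEMP/EDA/HR/SpO2; convert ECG with [ecg_to_hr()] first)
#' @param fir_order_factor FIR order = factor x decimation factor
#' @return a `synchronized_frame`
#' @export
synchronize <- function(channels, fir_order_factor = 10) {
  stopifnot(length(channels) > 0)
  nms <- vapply(channels, function(ch) ch$name, character(1))
  names(channels) <- nms
  if (!all(nms %in% FEATURES))
    stop("synchronize expects TEMP/EDA/HR/SpO2 channels (run ecg_to_hr first)")

  present <- nms[vapply(channels, function(ch) length(ch$values) > 1, logical(1))]
  if (length(present) == 0) stop("no channel has data")
  t0 <- max(vapply(channels[present], function(ch) ch$time[1], numeric(1)))
  t1 <- min(vapply(channels[present], function(ch) max(ch$time), numeric(1)))
  grid <- seq(ceiling(t0), floor(t1), by = 1)

  feat <- matrix(NA_real_, length(grid), length(FEATURES),
                 dimnames = list(NULL, FEATURES))
  imputed <- matrix(FALSE, length(grid), length(FEATURES),
                    dimnames = list(NULL, FEATURES))
  absent <- setdiff(FEATURES, present)

  for (nm in present) {
    ch <- channels[[nm]]
    dec <- ch$rate * 60                       # samples per minute
    if (dec <= 1 + 1e-9) {
      vals <- stats::approx(ch$time, ch$values, xout = grid, rule = 2)$y
    } else {
      # regularize to the native grid (gaps become NA, bridged by linear
      # interpolation purely to keep the FIR well-defined; the mask below
      # marks them for GP imputation)
      step <- 1 / dec
      nat_t <- seq(ch$time[1], max(ch$time), by = step)
      idx <- round((ch$time - ch$time[1]) / step) + 1L
      nat_v <- rep(NA_real_, length(nat_t))
      nat_v[idx[idx >= 1 & idx <= length(nat_t)]] <-
        ch$values[idx >= 1 & idx <= length(nat_t)]
      nat_v <- na_interp(nat_v)
      order <- ceiling(fir_order_factor * dec / 2) * 2   # even
      taps <- fir_lowpass(order, cutoff = 1 / (120 * ch$rate))
      y <- fft_convolve(nat_v, taps)
      delay <- order / 2
      # filtered sample i (native grid) lives at y[i + delay]
      gi <- round((grid - ch$time[1]) * dec) + 1L
      gi <- pmin(pmax(gi, 1L), length(nat_t))
      vals <- y[gi + delay]
    }
    feat[, nm] <- vals
    if (nrow(ch$gap_mask) > 0) {
      half_support <- if (dec > 1) (fir_order_factor / 2) / 2 else 0  # minutes
      for (i in seq_len(nrow(ch$gap_mask)))
        imputed[grid >= ch$gap_mask$start[i] - half_support &
                  grid <= ch$gap_mask$end[i] + half_support, nm] <- TRUE
    }
  }
  conf <- matrix(0, length(grid), length(FEATURES),
                 dimnames = list(NULL, FEATURES))
  new_frame(grid, feat, conf, imputed, absent)
}

## squared-exponential kernel matrix
se_kernel <- function(t1, t2, len, s2) {
  d <- outer(t1, t2, "-")
  s2 * exp(-d^2 / (2 * len^2))
}

# fit (length-scale, signal var, noise var) by marginal likelihood
# maximization on a subsample of observed points
gp_fit_hyper <- function(t, y, max_n = 200) {
  if (length(t) > max_n) {
    keep <- sort(sample.int(length(t), max_n))
    t <- t[keep]; y <- y[keep]
  }
  mu <- mean(y); yc <- y - mu
  v <- stats::var(yc)
  if (v < 1e-12) return(list(len = 30, s2 = 1e-8, sn2 = 1e-8, mu = mu))
  nll <- function(p) {
    len <- exp(p[1]); s2 <- exp(p[2]); sn2 <- exp(p[3])
    K <- se_kernel(t, t, len, s2) + diag(sn2 + 1e-10, length(t))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    0.5 * sum(yc * alpha) + sum(log(diag(ch)))
  }
  p0 <- log(c(30, v, v / 100))
  fit <- tryCatch(stats::optim(p0, nll, method = "L-BFGS-B",
                               lower = log(c(2, v * 1e-4, v * 1e-8)),
                               upper = log(c(1440, v * 100, v * 10))),
                  error = function(e) list(par = p0))
  list(len = exp(fit$par[1]), s2 = exp(fit$par[2]), sn2 = exp(fit$par[3]),
       mu = mu)
}

#' Gaussian-process gap filling on a synchronized frame
#'
#' Each feature's masked (imputed) grid points are replaced by the posterior
#' mean of a squared-exponential + white-noise GP conditioned on nearby
#' observed points; the posterior standard deviation is stored in the
#' `confidence` slot. Hyperparameters are fitted per feature by marginal
#' likelihood maximization. Observed samples are never modified.
#'
#' @param frame a `synchronized_frame`
#' @param min_obs refuse to impute a feature observed at fewer grid points
#'   than this (the feature keeps/gains the absent flag)
#' @param max_gap_min gaps longer than this many minutes are left unimputed
#'   (GP extrapolation over long dropouts is unreliable)
#' @param context_min observed points within this distance of a gap are used
#'   as conditioning set
#' @return the frame with gaps filled and confidence populated
#' @export
gp_fill <- function(frame, min_obs = 10, max_gap_min = 120,
                    context_min = 240) {
  stopifnot(inherits(frame, "synchronized_frame"))
  for (nm in setdiff(FEATURES, frame$absent)) {
    mask <- frame$imputed[, nm] | !is.finite(frame$features[, nm])
    if (!any(mask)) next
    obs <- which(!mask)
    if (length(obs) < min_obs) {
      frame$absent <- union(frame$absent, nm)
      next
    }
    hyp <- gp_fit_hyper(frame$grid[obs], frame$features[obs, nm])
    runs <- rle(as.vector(mask))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      gi <- starts[r]:ends[r]
      if (length(gi) > max_gap_min) next
      tg <- frame$grid[gi]
      near <- obs[abs(frame$grid[obs] - mean(tg)) <=
                    context_min + length(gi) / 2]
      if (length(near) < min_obs) next
      if (length(near) > 300) near <- near[round(seq(1, length(near), length.out = 300))]
      to <- frame$grid[near]
      yo <- frame$features[near, nm] - hyp$mu
      K <- se_kernel(to, to, hyp$len, hyp$s2) +
        diag(hyp$sn2 + 1e-8 * hyp$s2, length(to))
      ch <- chol(K)
      Ks <- se_kernel(tg, to, hyp$len, hyp$s2)
      alpha <- backsolve(ch, forwardsolve(t(ch), yo))
      frame$features[gi, nm] <- hyp$mu + drop(Ks %*% alpha)
      v <- forwardsolve(t(ch), t(Ks))
      post_var <- pmax(hyp$s2 - colSums(v^2), 0)
      frame$confidence[gi, nm] <- sqrt(post_var)
      frame$imputed[gi, nm] <- TRUE
    }
  }
  frame
}

#' Derive a 1 Hz heart-rate channel from ECG by R-peak detection
#'
#' Pan-Tompkins-style pipeline: band-pass (5-15 Hz, linear-phase FIR),
#' differentiate, square, moving-window integrate (150 ms), then adaptive
#' thresholding with a 250 ms refractory period. Instantaneous HR is
#' 60/RR in bpm, interpolated to 1 Hz. Windows longer than `gap_window_s`
#' seconds with no detectable peak are marked as gaps.
#'
#' @param ecg a [channel_series()] named `ECG` at its native rate
#' @param gap_window_s peakless stretch (seconds) marked as a gap
#' @return a 1 Hz `HR` [channel_series()] in bpm
#' @export
ecg_to_hr <- function(ecg, gap_window_s = 10) {
  stopifnot(inherits(ecg, "channel_series"), ecg$name == "ECG")
  fs <- ecg$rate
  n <- length(ecg$values)
  span <- if (n > 0) max(ecg$time) - ecg$time[1] else 0
  empty_hr <- function() channel_series(
    "HR", 1, numeric(0), numeric(0), "bpm",
    gap_mask = data.frame(start = if (n > 0) ecg$time[1] else 0,
                          end = if (n > 0) max(ecg$time) else 0))
  if (n < fs * 3 || stats::sd(ecg$values) < 1e-12) return(empty_hr())

  ord <- ceiling(fs / 5 / 2) * 2
  bp <- fir_lowpass(ord, 15 / fs) - fir_lowpass(ord, 5 / fs)
  y <- fft_convolve(ecg$values, bp)[(ord / 2 + 1):(ord / 2 + n)]
  d <- c(0, diff(y)) * fs
  sq <- d^2
  wint <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / wint, wint), sides = 2))
  integ[is.na(integ)] <- 0

  thr <- 0.3 * stats::quantile(integ, 0.99)
  refr <- round(0.250 * fs)
  above <- integ > thr
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      seg <- i:j
      peaks <- c(peaks, seg[which.max(integ[seg])])
      i <- j + refr
    }
    i <- i + 1L
  }
  if (length(peaks) < 3) return(empty_hr())

  beat_t <- ecg$time[peaks]                 # minutes
  rr_min <- diff(beat_t)                    # minutes per beat
  hr <- 1 / rr_min                          # bpm (= 60/RR with RR in seconds)
  hr_t <- beat_t[-1]

  out_t <- seq(ecg$time[1], max(ecg$time), by = 1 / 60)   # 1 Hz
  out_v <- stats::approx(hr_t, hr, xout = out_t, rule = 2)$y

  # peakless stretches -> gaps
  gap_thresh <- gap_window_s / 60
  big <- which(rr_min > gap_thresh)
  gaps <- if (length(big))
    data.frame(start = beat_t[big], end = beat_t[big + 1L])
  else data.frame(start = numeric(0), end = numeric(0))
  if (nrow(gaps) > 0) {
    drop <- rep(FALSE, length(out_t))
    for (i in seq_len(nrow(gaps)))
      drop <- drop | (out_t >= gaps$start[i] & out_t < gaps$end[i])
    out_t <- out_t[!drop]; out_v <- out_v[!drop]
  }
  channel_series("HR", 1, out_t, out_v, "bpm", gap_mask = gaps)
}
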