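# Shared fixtures, built lazily once per test run. Everything is generated
# in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, build) {
  if (!exists(key, envir = .fx)) assign(key, build(), envir = .fx)
  get(key, envir = .fx)
}

# small ambulatory patient: 6 days, 3 events, high SNR, a few gaps
fx_small_config <- function() {
  synthetic_config(duration_days = 6, n_migraines = 3, lead_time = 60,
                   snr_db = 30, gap_rate = 1, seed = 7)
}

fx_small_recording <- function() fx_memo("rec_small", function() {
  cfg <- fx_small_config()
  inject_gaps(generate_patient(cfg), cfg)
})

fx_small_frame <- function() fx_memo("frame_small", function() {
  preprocess_recording(fx_small_recording())
})

# study config scaled for test runtime: thinned grid, shorter context
fx_small_study_config <- function() {
  study_config(ph_grid = seq(10, 40, by = 10), nx_grid = 2:4,
               context_before_min = 600, seed = 3)
}

fx_small_windows <- function() fx_memo("windows_small", function() {
  rec <- fx_small_recording()
  make_migraine_windows(fx_small_frame(), rec$truth$annotations,
                        fx_small_study_config())
})

# per-migraine best models on the small fixture (four features)
fx_small_models <- function() fx_memo("models_small", function() {
  sc <- fx_small_study_config()
  lapply(fx_small_windows(), function(w) {
    best_model(train_grid(w$inputs, w$y, ph_grid = sc$ph_grid,
                          nx_grid = sc$nx_grid))
  })
})

# a known discrete LTI system for identification oracles
fx_lti_sim <- function(N, m = 2, seed = 1, snr_db = Inf,
                       A = matrix(c(0.7, 0.2, 0,
                                    -0.2, 0.6, 0.1,
                                    0, 0.1, 0.5), 3, 3, byrow = TRUE)) {
  set.seed(seed)
  nx <- nrow(A)
  B <- matrix(stats::rnorm(nx * m), nx, m)
  C <- matrix(stats::rnorm(nx), 1, nx)
  U <- matrix(stats::rnorm(N * m), N, m,
              dimnames = list(NULL, paste0("u", seq_len(m))))
  x <- numeric(nx)
  y <- numeric(N)
  for (k in seq_len(N)) {
    y[k] <- drop(C %*% x)
    x <- drop(A %*% x + B %*% U[k, ])
  }
  if (is.finite(snr_db)) y <- y + stats::rnorm(N, sd = stats::sd(y) / 10^(snr_db / 20))
  list(U = U, y = y, A = A, B = B, C = C)
}

# hand-built state-space model with known matrices (identity normalization)
fx_manual_model <- function(A, B, C, D = matrix(0, 1, ncol(B)),
                            K = matrix(0, nrow(A), 1),
                            input_names = paste0("u", seq_len(ncol(B)))) {
  structure(list(A = A, B = B, C = C, D = D, K = K, nx = nrow(A),
                 ph = 10, ph_eff = 10, reduced_ph = FALSE, fh_train = 30,
                 input_names = input_names,
                 normalization = list(
                   mu = stats::setNames(rep(0, ncol(B)), input_names),
                   sd = stats::setNames(rep(1, ncol(B)), input_names),
                   y_mu = 0),
                 fit_type = "prediction", training_fit = NA_real_,
                 rank_flag = FALSE, unstable_flag = FALSE),
            class = "state_space_model")
}

# random repair-toy trace: one long event plus short blips, all separated
fx_repair_toy <- function(seed) {
  set.seed(seed)
  n <- 1440
  pred <- numeric(n)
  ev_len <- sample(60:120, 1)
  ev_start <- sample(200:400, 1)
  ev_idx <- ev_start:(ev_start + ev_len - 1)
  pred[ev_idx] <- stats::runif(ev_len, 0.55, 1)
  n_blips <- sample(1:4, 1)
  blip_idx <- integer(0)
  cursor <- ev_start + ev_len + 30
  for (b in seq_len(n_blips)) {
    len <- sample(3:59, 1)
    start <- cursor + sample(10:60, 1)
    if (start + len > n - 10) break
    idx <- start:(start + len - 1)
    pred[idx] <- stats::runif(len, 0.55, 1)
    blip_idx <- c(blip_idx, idx)
    cursor <- start + len
  }
  list(pred = pred, event_idx = ev_idx, blip_idx = blip_idx)
}
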