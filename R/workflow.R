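## End-to-end study protocol: split episodes, train the per-migraine grid,
## cross-validate, build per-feature-subset ensembles into the model
## hierarchy, score the held-out test episodes, and replay a frame
## minute-by-minute as the deployed real-time loop.

#' Study configuration
#'
#' Collects every tunable of the protocol. Defaults follow the study design:
#' 75/25 per-episode split, horizons 1..100 min, a 70% fit threshold, a 50%
#' decider threshold, a 60-min repair span, a 30-min trained future horizon
#' (pharmacokinetics of acute medication), and the four-feature set plus all
#' size-3 subsets.
#'
#' @param split_fraction fraction of episodes used for training/validation
#' @param seed integer seed controlling the split
#' @param horizons validation horizons in minutes
#' @param fit_threshold percent fit defining an achieved horizon
#' @param decider_threshold percent probability opening a detection
#' @param repair_span_min minimum real-event span for the repair loop
#' @param future_horizon trained future horizon in minutes
#' @param feature_subsets list of character vectors (size-4 + size-3 by
#'   default; duos are deliberately excluded)
#' @param ph_grid,nx_grid training grid (200 combinations by default)
#' @param context_before_min,context_after_min training-window context
#'   around an event (minutes)
#' @param eval_before_min,eval_after_min fit-evaluation segment around an
#'   event (minutes)
#' @return an object of class `study_config`
#' @export
study_config <- function(split_fraction = 0.75, seed = 1L,
                         horizons = 1:100, fit_threshold = 70,
                         decider_threshold = 50, repair_span_min = 60,
                         future_horizon = 30,
                         feature_subsets = default_feature_subsets(),
                         ph_grid = seq(5, 100, by = 5), nx_grid = 1:10,
                         context_before_min = 1200, context_after_min = 60,
                         eval_before_min = 120, eval_after_min = 60) {
  stopifnot(split_fraction > 0, split_fraction < 1,
            fit_threshold > 0, fit_threshold < 100,
            decider_threshold > 0, decider_threshold < 100,
            all(horizons >= 1))
  structure(as.list(environment()), class = "study_config")
}

#' The four-feature set plus every three-feature subset
#' @return list of character vectors
#' @export
default_feature_subsets <- function() {
  quad <- FEATURES
  c(list(quad), lapply(seq_along(quad), function(i) quad[-i]))
}

#' Per-episode train/test split
#'
#' Seeded random split at `split_fraction`, always per episode (never per
#' sample): `n_train = round(fraction * n)`.
#'
#' @param n_migraines number of episodes (>= 4)
#' @param config a [study_config()]
#' @return list with integer vectors `train` and `test`
#' @export
split_dataset <- function(n_migraines, config = study_config()) {
  if (n_migraines < 4) stop("need at least 4 migraine episodes to split")
  set.seed(config$seed)
  n_train <- round(config$split_fraction * n_migraines)
  train <- sort(sample.int(n_migraines, n_train))
  list(train = train, test = setdiff(seq_len(n_migraines), train))
}

#' Preprocess a raw recording into a gap-free 1-min frame
#'
#' Converts ECG to HR if needed (the derived HR is then GP-repaired along
#' with the other features), synchronizes all channels to the 1-min grid and
#' imputes gaps with the Gaussian process.
#'
#' @param recording a `raw_recording`
#' @param ... passed to [gp_fill()]
#' @return a `synchronized_frame`
#' @export
preprocess_recording <- function(recording, ...) {
  channels <- recording$channels
  if ("ECG" %in% names(channels)) {
    channels$HR <- ecg_to_hr(channels$ECG)
    channels$ECG <- NULL
  }
  frame <- synchronize(channels)
  gp_fill(frame, ...)
}

#' Cut per-migraine modeling windows out of a frame
#'
#' Each annotated episode becomes a window spanning
#' `[aura_start - context_before_min, pain_end + context_after_min]` with
#' the fitted symptomatic curve as output `y`; `eval_idx` marks the fit
#' evaluation segment `[aura_start - eval_before_min,
#' pain_end + eval_after_min]`.
#'
#' @param frame a `synchronized_frame`
#' @param annotations list of [pain_annotation()]
#' @param config a [study_config()]
#' @return list of migraine windows (`grid`, `inputs`, `y`, `eval_idx`,
#'   `event`, `curve`)
#' @export
make_migraine_windows <- function(frame, annotations,
                                  config = study_config()) {
  feats <- setdiff(FEATURES, frame$absent)
  lapply(annotations, function(ann) {
    curve <- build_symptomatic_curve(ann)
    lo <- ann$aura_start - config$context_before_min
    hi <- ann$pain_end + config$context_after_min
    idx <- which(frame$grid >= lo & frame$grid <= hi)
    if (length(idx) < 50) stop("frame does not cover the episode window")
    grid <- frame$grid[idx]
    eval_idx <- which(grid >= ann$aura_start - config$eval_before_min &
                        grid <= ann$pain_end + config$eval_after_min)
    list(grid = grid,
         inputs = frame$features[idx, feats, drop = FALSE],
         y = evaluate_curve(curve, grid),
         eval_idx = eval_idx,
         event = data.frame(aura_start = ann$aura_start,
                            pain_start = ann$pain_start,
                            pain_end = ann$pain_end),
         curve = curve)
  })
}

#' Cut event-free baseline windows out of a frame
#'
#' @param frame a `synchronized_frame`
#' @param annotations episode annotations to stay clear of
#' @param length_min window length in minutes
#' @param margin_min minimum distance from any episode
#' @param n_max maximum number of windows returned
#' @return list of windows shaped like [make_migraine_windows()] output but
#'   with `y = 0` and an empty `event`
#' @export
make_baseline_windows <- function(frame, annotations, length_min = 480,
                                  margin_min = 360, n_max = 10) {
  feats <- setdiff(FEATURES, frame$absent)
  busy <- rep(FALSE, length(frame$grid))
  for (ann in annotations)
    busy <- busy | (frame$grid >= ann$aura_start - margin_min &
                      frame$grid <= ann$pain_end + margin_min)
  free <- runs_to_intervals(!busy, frame$grid)
  out <- list()
  for (r in seq_len(nrow(free))) {
    lo <- free$A[r]
    while (lo + length_min <= free$B[r] && length(out) < n_max) {
      idx <- which(frame$grid >= lo & frame$grid < lo + length_min)
      out[[length(out) + 1L]] <- list(
        grid = frame$grid[idx],
        inputs = frame$features[idx, feats, drop = FALSE],
        y = numeric(length(idx)),
        eval_idx = seq_along(idx),
        event = data.frame(aura_start = numeric(0), pain_start = numeric(0),
                           pain_end = numeric(0)),
        curve = NULL)
      lo <- lo + length_min
    }
    if (length(out) >= n_max) break
  }
  out
}

#' Full train-validate-ensemble path for every feature subset
#'
#' For the four-feature set and each triad: per-training-migraine grid
#' search, cross-validation ranking, selection of the best third, ensemble
#' averaging, and ensemble validation on the training migraines left out of
#' the ensemble. Results are ordered into the model hierarchy by average
#' horizon.
#'
#' @param frame a preprocessed `synchronized_frame`
#' @param annotations list of [pain_annotation()]
#' @param config a [study_config()]
#' @param split optional precomputed split (list `train`, `test`)
#' @return list: `hierarchy` (a [model_hierarchy()]), `subset_table`
#'   (data.frame of per-subset fh stats), `split`, `windows`, `per_subset`
#'   (models, ranking, ensemble per subset)
#' @export
run_feature_subset_study <- function(frame, annotations,
                                     config = study_config(),
                                     split = NULL) {
  windows <- make_migraine_windows(frame, annotations, config)
  if (is.null(split)) split <- split_dataset(length(windows), config)
  train_w <- windows[split$train]

  per_subset <- list()
  entries <- list()
  rows <- list()
  for (fs in config$feature_subsets) {
    if (!all(fs %in% colnames(train_w[[1]]$inputs))) next
    key <- paste(fs, collapse = "-")
    models <- lapply(train_w, function(w) {
      tg <- train_grid(w$inputs[, fs, drop = FALSE], w$y,
                       ph_grid = config$ph_grid, nx_grid = config$nx_grid,
                       fh_train = config$future_horizon)
      best_model(tg)
    })
    ranking <- cross_validate(models, train_w, config$horizons,
                              config$fit_threshold,
                              config$decider_threshold,
                              config$repair_span_min)
    ensemble <- build_average_model(ranking, models)
    holdout <- train_w[setdiff(seq_along(train_w), ensemble$member_ids)]
    if (length(holdout) == 0) holdout <- train_w
    ensemble <- validate_ensemble(ensemble, holdout, config$horizons,
                                  config$fit_threshold,
                                  config$decider_threshold,
                                  config$repair_span_min)
    per_subset[[key]] <- list(models = models, ranking = ranking,
                              ensemble = ensemble)
    entries[[length(entries) + 1L]] <-
      list(feature_set = fs, ensemble = ensemble, fh = ensemble$fh)
    rows[[length(rows) + 1L]] <-
      data.frame(subset = key, fh_min = ensemble$fh[["fh_min"]],
                 fh_average = ensemble$fh[["fh_average"]],
                 fh_max = ensemble$fh[["fh_max"]],
                 fh_sigma = ensemble$fh[["fh_sigma"]])
  }
  list(hierarchy = model_hierarchy(entries),
       subset_table = do.call(rbind, rows),
       split = split, windows = windows, per_subset = per_subset)
}

#' Score an ensemble on held-out episodes and baseline stretches
#'
#' Runs the deployed prediction path (horizon = the subset's validated
#' average capped at 30 min, decider, repair) over each window, computes the
#' per-event fit over the evaluation segment, and aggregates detections into
#' confusion counts and TPR/PPV/F-score. Used both within-patient (test
#' stage) and cross-patient (one patient's hierarchy over another's frames).
#'
#' @param ensemble a validated `ensemble_model`
#' @param test_windows migraine windows to score
#' @param baseline_windows optional event-free windows (detections there are
#'   false positives)
#' @param config a [study_config()]
#' @return list: `counts` ([confusion_counts()]), `metrics` ([f_score()]
#'   output), `per_event` data.frame (fit, detected), `horizon_used`
#' @export
run_test_stage <- function(ensemble, test_windows,
                           baseline_windows = list(),
                           config = study_config()) {
  h <- max(1L, min(round(ensemble$fh[["fh_average"]]),
                   config$future_horizon))
  tp <- 0L; fp <- 0L; fn <- 0L
  per_event <- data.frame(fit = numeric(0), detected = logical(0))
  for (w in test_windows) {
    tr <- ensemble_predict(ensemble, w$inputs, w$y, k = h, grid = w$grid,
                           decider_threshold = config$decider_threshold,
                           min_event_min = config$repair_span_min)
    fit <- compute_fit(w$y[w$eval_idx], tr$predicted[w$eval_idx])
    cnt <- score_detections(tr$detections, w$event, fit,
                            config$fit_threshold)
    tp <- tp + cnt$tp; fp <- fp + cnt$fp; fn <- fn + cnt$fn
    per_event <- rbind(per_event,
                       data.frame(fit = fit, detected = cnt$tp > 0))
  }
  for (w in baseline_windows) {
    preds <- vapply(ensemble$members,
                    function(m) {
                      yh <- simulate_model(m, w$inputs)
                      yh
                    }, numeric(length(w$y)))
    tr <- linear_decider(rowMeans(preds), grid = w$grid,
                         threshold = config$decider_threshold)
    tr <- repair_prediction(tr, min_event_min = config$repair_span_min,
                            threshold = config$decider_threshold)
    fp <- fp + nrow(tr$detections)
  }
  counts <- confusion_counts(tp, fp, fn)
  metrics <- tryCatch(f_score(counts), error = function(e) NULL)
  list(counts = counts, metrics = metrics, per_event = per_event,
       horizon_used = h)
}

#' Replay a frame minute-by-minute through the deployed loop
#'
#' At every minute the sensor status (from the optional fault script) is
#' sensed, the hierarchy picks the best available feature-subset ensemble,
#' its members advance one simulation step (pain is unobserved at deployment
#' time, so innovations are zero) and emit the prediction at the entry's
#' validated average horizon capped at 30 min. The linear decider watches
#' the newest prediction (the estimate for `t + horizon`): an alarm fires on
#' the rising edge of the 50% probability threshold. When the excursion
#' later ends short of the repair span it is retracted and logged as a
#' suppressed false positive -- the streaming counterpart of the offline
#' repair loop. Alarms, retractions, subset switches and suspensions are
#' logged with the lead time against the ground-truth events when given.
#'
#' @param frame a `synchronized_frame` to replay
#' @param hierarchy a [model_hierarchy()]
#' @param config a [study_config()]
#' @param truth_events optional data.frame (aura_start, pain_start,
#'   pain_end) for lead-time bookkeeping
#' @param fault_script optional data.frame (start, end, feature, mode) with
#'   mode `"lost"` or `"saturated"`; readings of faulted features are
#'   overwritten accordingly during `[start, end)`
#' @return list: `alarms` data.frame (time, horizon, subset, lead_min,
#'   retracted), `log` data.frame (time, stage, message), and `predicted`
#'   (the raw streamed prediction series, aligned to `frame$grid` then
#'   extending one horizon beyond)
#' @export
simulate_realtime <- function(frame, hierarchy, config = study_config(),
                              truth_events = NULL, fault_script = NULL) {
  grid <- frame$grid
  n <- length(grid)
  sat <- saturation_defaults()
  entries <- hierarchy$entries

  # per-entry precomputation: horizon, member prediction operators
  prep <- lapply(entries, function(e) {
    h <- max(1L, min(round(e$fh[["fh_average"]]), config$future_horizon))
    mems <- lapply(e$ensemble$members, function(m) {
      Apow <- diag(m$nx); Ssum <- matrix(0, m$nx, m$nx)
      if (h > 1) for (k in 2:h) { Ssum <- Ssum + Apow; Apow <- m$A %*% Apow }
      list(m = m, G1 = m$C %*% Apow, G2 = m$C %*% Ssum %*% m$B + m$D,
           x = numeric(m$nx))
    })
    list(h = h, mems = mems, fs = e$feature_set)
  })

  predicted <- numeric(n + max(vapply(prep, `[[`, numeric(1), "h")))
  alarms <- data.frame(time = numeric(0), horizon = numeric(0),
                       subset = character(0), lead_min = numeric(0),
                       retracted = logical(0))
  log <- data.frame(time = numeric(0), stage = character(0),
                    message = character(0))
  log_row <- function(t, stage, msg)
    rbind(log, data.frame(time = t, stage = stage, message = msg))

  last_sel <- NA_integer_
  excursion_start <- NA_real_      # wall time the current supra run began
  open_alarm <- NA_integer_        # row in `alarms` of the current excursion

  status_at <- function(t) {
    st <- character(0)
    if (!is.null(fault_script)) {
      act <- fault_script[fault_script$start <= t & t < fault_script$end, ]
      if (nrow(act))
        st <- stats::setNames(as.character(act$mode), act$feature)
    }
    sensor_status(st)
  }

  for (ti in seq_len(n)) {
    t <- grid[ti]
    st <- status_at(t)
    u_raw <- frame$features[ti, , drop = TRUE]
    for (nm in names(st$status)) {
      if (st$status[[nm]] == "lost") u_raw[nm] <- 0
      if (st$status[[nm]] == "saturated") u_raw[nm] <- sat[[nm]]
    }

    # advance every entry's members (cheap; keeps fallbacks warm)
    for (ei in seq_along(prep)) {
      for (mi in seq_along(prep[[ei]]$mems)) {
        mm <- prep[[ei]]$mems[[mi]]
        un <- (u_raw[mm$m$input_names] - mm$m$normalization$mu) /
          mm$m$normalization$sd
        prep[[ei]]$mems[[mi]]$x <- drop(mm$m$A %*% mm$x) +
          drop(mm$m$B %*% un)
      }
    }

    sel <- tryCatch(sdms2_select(hierarchy, st), error = function(e) NULL)
    if (is.null(sel)) {
      if (!identical(last_sel, -1L)) {
        log <- log_row(t, "suspend", "no model for current sensor status")
        last_sel <- -1L
      }
      next
    }
    si <- attr(sel, "index")
    if (!identical(si, last_sel)) {
      log <- log_row(t, "select",
                     paste0("subset ", paste(sel$feature_set, collapse = "-")))
      last_sel <- si
    }
    pe <- prep[[si]]
    vals <- vapply(pe$mems, function(mm) {
      un <- (u_raw[mm$m$input_names] - mm$m$normalization$mu) /
        mm$m$normalization$sd
      drop(mm$G1 %*% mm$x) + drop(mm$G2 %*% un) + mm$m$normalization$y_mu
    }, numeric(1))
    newest <- min(max(mean(vals), -0.2), 1.2)
    predicted[ti + pe$h] <- newest

    supra <- 100 * min(max(newest, 0), 1) >= config$decider_threshold
    if (supra && is.na(excursion_start)) {
      excursion_start <- t
      lead <- NA_real_
      if (!is.null(truth_events) && nrow(truth_events) > 0) {
        nxt <- truth_events$pain_start[truth_events$pain_start >= t - 120]
        if (length(nxt)) lead <- min(nxt) - t
      }
      alarms <- rbind(alarms, data.frame(
        time = t, horizon = pe$h,
        subset = paste(sel$feature_set, collapse = "-"),
        lead_min = lead, retracted = FALSE))
      open_alarm <- nrow(alarms)
      log <- log_row(t, "alarm",
                     sprintf("probability >= %g%% predicted for t=%.0f",
                             config$decider_threshold, t + pe$h))
    } else if (!supra && !is.na(excursion_start)) {
      span <- t - excursion_start
      if (span < config$repair_span_min && !is.na(open_alarm)) {
        alarms$retracted[open_alarm] <- TRUE
        log <- log_row(t, "retract",
                       sprintf("excursion of %.0f min < %g min: false positive",
                               span, config$repair_span_min))
      }
      excursion_start <- NA_real_
      open_alarm <- NA_integer_
    }
  }
  list(alarms = alarms, log = log, predicted = predicted)
}
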