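## Validation-side machinery: the linear decider maps raw predictions to a
## migraine probability, the repair loop removes short spurious excursions
## (the N4SID predictions oscillate around zero between attacks), models are
## ranked by the prediction horizon they sustain at the 70% fit threshold,
## and the best third is averaged into the deployed ensemble.

#' Construct a prediction trace
#' @keywords internal
#' @noRd
new_trace <- function(grid, predicted, probability, detections) {
  structure(list(grid = grid, predicted = predicted,
                 probability = probability, detections = detections),
            class = "prediction_trace")
}

#' @export
print.prediction_trace <- function(x, ...) {
  cat(sprintf("<prediction_trace> %d min, %d detection(s)\n",
              length(x$grid), nrow(x$detections)))
  invisible(x)
}

#' Map a raw prediction to a migraine probability and detections
#'
#' The linear decider projects the normalized predicted pain linearly onto a
#' 0-100% probability of a migraine episode:
#' `probability = 100 * clamp(predicted, 0, 1)`. A detection is open while
#' the probability is at or above `threshold` (50% by default).
#'
#' @param predicted raw model output on the symptomatic curve's 0-1 scale
#'   (oscillation artifacts below 0 clamp to 0%)
#' @param grid minute timestamps (defaults to 0-based minutes)
#' @param threshold detection threshold in percent
#' @return a `prediction_trace` with `probability` and `(A, B)` detection
#'   intervals
#' @export
linear_decider <- function(predicted, grid = seq_along(predicted) - 1,
                           threshold = 50) {
  probability <- 100 * pmin(pmax(predicted, 0), 1)
  pos <- probability >= threshold
  det <- runs_to_intervals(pos, grid)
  new_trace(grid, predicted, probability, det)
}

# contiguous TRUE runs -> data.frame(A, B) of grid times
runs_to_intervals <- function(flag, grid) {
  if (!any(flag))
    return(data.frame(A = numeric(0), B = numeric(0)))
  r <- rle(as.vector(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(A = grid[starts[keep]], B = grid[ends[keep]])
}

#' Remove short false-positive excursions from a prediction trace
#'
#' Iterative five-step loop over the trace: (1) select a scan window; (2)
#' mark probability >= `threshold` points as positives and search forward for
#' further supra-threshold points inside the same positive excursion of the
#' predicted curve; (3) if the farthest supra-threshold points span less
#' than `min_event_min` minutes, the excursion is a false positive -- its
#' predicted and probability values are zeroed between the surrounding zero
#' crossings; (4) surviving candidates get Marks A and B at the left- and
#' right-hand zero crossings; (5) the window shifts to start at Mark B and
#' the steps repeat. Applying the repair twice equals applying it once.
#'
#' @param trace a `prediction_trace`
#' @param min_event_min minimum supra-threshold span (minutes, inclusive)
#'   for a real event; 60 by default
#' @param threshold probability threshold in percent
#' @param scan_window_min length of the scan window in step (1)
#' @return the repaired `prediction_trace`; detections hold the kept events'
#'   Marks A/B
#' @export
repair_prediction <- function(trace, min_event_min = 60, threshold = 50,
                              scan_window_min = 360) {
  stopifnot(inherits(trace, "prediction_trace"))
  n <- length(trace$grid)
  if (n == 0) return(trace)
  pred <- trace$predicted
  prob <- trace$probability
  grid <- trace$grid
  det_A <- numeric(0); det_B <- numeric(0)

  i <- 1L
  while (i <= n) {
    w_end <- min(n, i + scan_window_min - 1L)
    pos_idx <- which(prob[i:w_end] >= threshold)
    if (length(pos_idx) == 0L) {
      if (w_end == n) break
      i <- w_end + 1L
      next
    }
    first <- i + pos_idx[1L] - 1L
    # the positive excursion of the predicted curve containing `first`
    a <- first
    while (a > 1L && pred[a - 1L] > 0) a <- a - 1L
    b <- first
    while (b < n && pred[b + 1L] > 0) b <- b + 1L
    supra <- which(prob[a:b] >= threshold) + a - 1L
    span <- grid[supra[length(supra)]] - grid[supra[1L]] + 1
    if (span < min_event_min) {
      pred[a:b] <- 0
      prob[a:b] <- 0
    } else {
      det_A <- c(det_A, grid[a])
      det_B <- c(det_B, grid[b])
    }
    i <- b + 1L
  }
  new_trace(grid, pred, prob, data.frame(A = det_A, B = det_B))
}

#' Horizon sustained by one fit-vs-horizon curve
#'
#' The achievable horizon is the largest `k` before the first sustained drop
#' (>= `sustain` consecutive horizons) below the fit threshold; a curve that
#' never reaches the threshold contributes horizon 0 (flagged via attribute
#' `"never_reached"`).
#'
#' @param fits fit values (percent) per horizon
#' @param horizons the horizons (minutes) the fits belong to
#' @param fit_threshold percent threshold (70 by default)
#' @param sustain number of consecutive sub-threshold horizons defining a
#'   sustained drop
#' @return horizon in minutes
#' @export
horizon_from_curve <- function(fits, horizons, fit_threshold = 70,
                               sustain = 3) {
  ok <- is.finite(fits) & fits >= fit_threshold
  if (!any(ok)) {
    out <- 0
    attr(out, "never_reached") <- TRUE
    return(out)
  }
  below <- !ok
  run <- rle(below)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  drop_at <- starts[run$values & run$lengths >= sustain]
  cut <- if (length(drop_at)) drop_at[1L] else length(horizons) + 1L
  cand <- which(ok & seq_along(horizons) < cut)
  if (length(cand) == 0L) {
    out <- 0
    attr(out, "never_reached") <- TRUE
    return(out)
  }
  horizons[max(cand)]
}

#' Cross-validate migraine models and rank them by achievable horizon
#'
#' Each model `M_i`, trained on migraine `i`, is validated against every
#' other migraine `j != i`: predictions are made for each horizon, passed
#' through the linear decider and the repair loop, and scored with the fit
#' metric over the migraine's evaluation segment. Each of the `M - 1`
#' fit-vs-horizon curves yields the largest horizon sustaining
#' `fit >= fit_threshold`; per model these aggregate to
#' `fh_min/fh_average/fh_max/fh_sigma`. The ranking sorts by `fh_average`,
#' ties by `fh_min` ("ensure the higher minimums"), remaining ties by model
#' index.
#'
#' @param models list of `state_space_model`s (one per training migraine)
#' @param migraines list of migraine windows as built by
#'   [make_migraine_windows()]
#' @param horizons prediction horizons in minutes (default 1..100)
#' @param fit_threshold percent fit threshold (default 70)
#' @param decider_threshold percent probability threshold (default 50)
#' @param min_event_min repair span threshold in minutes (default 60)
#' @param model_migraine_idx integer vector mapping each model to the index
#'   (in `migraines`) of its own training migraine, which is excluded from
#'   its validation; `NA` entries validate against every migraine
#' @return an object of class `model_ranking`: data.frame `stats`
#'   (model, fh_min, fh_average, fh_max, fh_sigma), integer vector `order`,
#'   and the per-pair horizon matrix `horizons_by_pair`
#' @export
cross_validate <- function(models, migraines, horizons = 1:100,
                           fit_threshold = 70, decider_threshold = 50,
                           min_event_min = 60,
                           model_migraine_idx = seq_along(models)) {
  M <- length(models)
  if (length(migraines) < 2 && any(!is.na(model_migraine_idx)))
    stop("cross-validation needs >= 2 migraines")
  hb <- matrix(NA_real_, M, length(migraines))
  for (im in seq_len(M)) {
    for (jm in seq_along(migraines)) {
      if (!is.na(model_migraine_idx[im]) && jm == model_migraine_idx[im]) next
      w <- migraines[[jm]]
      preds <- predict_multi_horizon(models[[im]], w$inputs, w$y, horizons)
      fits <- vapply(seq_along(horizons), function(r) {
        tr <- linear_decider(preds[r, ], grid = w$grid,
                             threshold = decider_threshold)
        tr <- repair_prediction(tr, min_event_min = min_event_min,
                                threshold = decider_threshold)
        compute_fit(w$y[w$eval_idx], tr$predicted[w$eval_idx])
      }, numeric(1))
      hb[im, jm] <- horizon_from_curve(fits, horizons, fit_threshold)
    }
  }
  stats <- data.frame(
    model = seq_len(M),
    fh_min = apply(hb, 1, min, na.rm = TRUE),
    fh_average = apply(hb, 1, mean, na.rm = TRUE),
    fh_max = apply(hb, 1, max, na.rm = TRUE),
    fh_sigma = apply(hb, 1, stats::sd, na.rm = TRUE))
  rank_model_stats(stats, horizons_by_pair = hb)
}

#' Rank per-model horizon statistics
#'
#' @param stats data.frame with columns model, fh_min, fh_average, fh_max
#'   (fh_sigma optional)
#' @param horizons_by_pair optional per-pair horizon matrix carried along
#' @return a `model_ranking`
#' @export
rank_model_stats <- function(stats, horizons_by_pair = NULL) {
  stopifnot(all(c("model", "fh_min", "fh_average", "fh_max") %in%
                  names(stats)))
  stopifnot(all(stats$fh_min <= stats$fh_average + 1e-9),
            all(stats$fh_average <= stats$fh_max + 1e-9))
  ord <- order(-stats$fh_average, -stats$fh_min, stats$model)
  structure(list(stats = stats, order = stats$model[ord],
                 horizons_by_pair = horizons_by_pair),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("<model_ranking>\n")
  print(x$stats[match(x$order, x$stats$model), ], row.names = FALSE)
  invisible(x)
}

#' Number of ensemble members for M validated models
#'
#' One third of the models, rounded (`M = 15 -> 5`, `M = 8 -> 3`), never
#' fewer than one; `M < 3` falls back to a single member with a warning.
#' @param M number of models
#' @return integer member count
#' @export
m_best_size <- function(M) {
  if (M < 3) {
    warning("fewer than 3 models: ensemble reduced to a single member")
    return(1L)
  }
  max(1L, as.integer(round(M / 3)))
}

#' Build the averaged ensemble from the top-ranked models
#'
#' Selects the top `round(M/3)` models of the ranking; the ensemble
#' prediction is the unweighted arithmetic mean of the member predictions at
#' each time and horizon, with the repair loop applied to the averaged
#' trace.
#'
#' @param ranking a `model_ranking`
#' @param models the model list the ranking refers to
#' @param m_best optional member count override
#' @return an object of class `ensemble_model` with `members`,
#'   `member_ids`, `feature_set`, and (once validated) `fh` stats
#' @export
build_average_model <- function(ranking, models, m_best = NULL) {
  stopifnot(inherits(ranking, "model_ranking"))
  M <- length(models)
  if (is.null(m_best)) m_best <- m_best_size(M)
  ids <- ranking$order[seq_len(min(m_best, M))]
  members <- models[ids]
  fsets <- unique(lapply(members, function(m) m$input_names))
  if (length(fsets) != 1)
    stop("ensemble members must share the same feature subset")
  structure(list(members = members, member_ids = ids,
                 feature_set = fsets[[1]], fh = NULL),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d members, features: %s\n",
              length(x$members), paste(x$feature_set, collapse = ",")))
  if (!is.null(x$fh))
    cat(sprintf("  fh (min/avg/max) = %.0f/%.1f/%.0f min\n",
                x$fh["fh_min"], x$fh["fh_average"], x$fh["fh_max"]))
  invisible(x)
}

#' Averaged, repaired ensemble prediction at one horizon
#'
#' @param ensemble an `ensemble_model`
#' @param inputs,y migraine window data (see [predict_k_ahead()])
#' @param k horizon in minutes
#' @param grid minute timestamps
#' @param decider_threshold,min_event_min decider / repair parameters
#' @return a repaired `prediction_trace`
#' @export
ensemble_predict <- function(ensemble, inputs, y, k,
                             grid = seq_along(y) - 1,
                             decider_threshold = 50, min_event_min = 60) {
  preds <- vapply(ensemble$members,
                  function(m) predict_k_ahead(m, inputs, y, k),
                  numeric(length(y)))
  avg <- rowMeans(preds)
  tr <- linear_decider(avg, grid = grid, threshold = decider_threshold)
  repair_prediction(tr, min_event_min = min_event_min,
                    threshold = decider_threshold)
}

#' Validate an ensemble over migraines and attach its horizon stats
#'
#' For each migraine the member predictions are averaged per horizon,
#' repaired, and scored; the per-migraine sustained horizons aggregate to
#' the ensemble's `fh_min/fh_average/fh_max/fh_sigma`.
#'
#' @inheritParams cross_validate
#' @param ensemble an `ensemble_model`
#' @return the ensemble with its `fh` stats filled in (and per-migraine
#'   horizons as attribute `"per_migraine"`)
#' @export
validate_ensemble <- function(ensemble, migraines, horizons = 1:100,
                              fit_threshold = 70, decider_threshold = 50,
                              min_event_min = 60) {
  hs <- vapply(migraines, function(w) {
    preds <- lapply(ensemble$members, function(m)
      predict_multi_horizon(m, w$inputs, w$y, horizons))
    avg <- Reduce(`+`, preds) / length(preds)
    fits <- vapply(seq_along(horizons), function(r) {
      tr <- linear_decider(avg[r, ], grid = w$grid,
                           threshold = decider_threshold)
      tr <- repair_prediction(tr, min_event_min = min_event_min,
                              threshold = decider_threshold)
      compute_fit(w$y[w$eval_idx], tr$predicted[w$eval_idx])
    }, numeric(1))
    as.numeric(horizon_from_curve(fits, horizons, fit_threshold))
  }, numeric(1))
  ensemble$fh <- c(fh_min = min(hs), fh_average = mean(hs),
                   fh_max = max(hs),
                   fh_sigma = if (length(hs) > 1) stats::sd(hs) else 0)
  attr(ensemble$fh, "per_migraine") <- hs
  ensemble
}
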