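## Event-based scoring (TPR / PPV / F-score), sensor-fault robustness
## suites, and the sensor-dependent model selection hierarchy consulted at
## run time when sensors drop out or saturate.

#' Confusion counts for event-based detection
#' @param tp,fp,fn non-negative integers
#' @return an object of class `confusion_counts`
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, fn = 0L) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Score detections against ground-truth events
#'
#' A true positive is an event overlapped (>= `min_overlap` minutes) by a
#' detection whose event-window fit is at or above `fit_threshold`: a
#' detection without a reliable fit counts as a miss. Detections overlapping
#' no event are false positives.
#'
#' @param detections data.frame with columns `A`, `B` (minutes)
#' @param truth_events data.frame with columns `aura_start`, `pain_end`
#'   (minutes); the event window is their span
#' @param fit_per_event numeric vector, fit (percent) achieved over each
#'   event's evaluation window
#' @param fit_threshold percent (default 70)
#' @param min_overlap minimum intersection in minutes (default 1)
#' @return a `confusion_counts`
#' @export
score_detections <- function(detections, truth_events, fit_per_event,
                             fit_threshold = 70, min_overlap = 1) {
  detections <- as.data.frame(detections)
  truth_events <- as.data.frame(truth_events)
  ne <- nrow(truth_events)
  stopifnot(length(fit_per_event) == ne)
  overlap <- function(a1, b1, a2, b2) pmin(b1, b2) - pmax(a1, a2)
  event_hit <- logical(ne)
  det_used <- rep(FALSE, nrow(detections))
  for (e in seq_len(ne)) {
    if (nrow(detections) == 0) break
    ov <- overlap(detections$A, detections$B,
                  truth_events$aura_start[e], truth_events$pain_end[e])
    hits <- ov >= min_overlap
    det_used <- det_used | hits
    event_hit[e] <- any(hits) && is.finite(fit_per_event[e]) &&
      fit_per_event[e] >= fit_threshold
  }
  confusion_counts(tp = sum(event_hit),
                   fp = sum(!det_used),
                   fn = sum(!event_hit))
}

#' True positive rate, precision and F-score from confusion counts
#'
#' `TPR = Tp/(Tp+Fn)`, `PPV = Tp/(Tp+Fp)`, `F = 2 TPR PPV/(TPR+PPV)`, all in
#' percent. With zero detections (`Tp + Fp = 0`) the PPV is reported as
#' 100% by convention (an undetecting model makes no false claims), so a
#' zero-Tp run scores `(TPR 0, PPV 100, F 0)`. All-zero counts are an
#' error.
#'
#' @param counts a [confusion_counts()]
#' @return list with exact `tpr`, `ppv`, `f` (percent) and integer-rounded
#'   `rounded = c(TPR, PPV, F)` for report parity
#' @export
f_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp + fn == 0) stop("F-score undefined: no events, no detections")
  tpr <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else 100
  f <- if (is.na(tpr)) NA_real_
       else if (tpr + ppv == 0) 0
       else 2 * tpr * ppv / (tpr + ppv)
  list(tpr = tpr, ppv = ppv, f = f,
       rounded = c(TPR = round(tpr), PPV = round(ppv), F = round(f)))
}

#' F-score from already-computed rates
#'
#' The published trust tables report integer TPR and PPV whose denominators
#' differ (TPR counts events, PPV counts detections), so their F column is
#' the harmonic mean of the two rates rather than of one consistent count
#' triple. This helper reproduces that arithmetic.
#'
#' @param tpr,ppv rates in percent
#' @return list with exact `f` and integer-rounded
#'   `rounded = c(TPR, PPV, F)`
#' @export
f_score_from_rates <- function(tpr, ppv) {
  f <- if (tpr + ppv == 0) 0 else 2 * tpr * ppv / (tpr + ppv)
  list(f = f, rounded = c(TPR = round(tpr), PPV = round(ppv), F = round(f)))
}

#' Sensor status vector
#'
#' @param status named character vector over TEMP/EDA/HR/SpO2 with values
#'   `"ok"`, `"lost"` or `"saturated"`; omitted features are `"ok"`
#' @param saturation_values per-feature stuck-at constants (defaults from
#'   [saturation_defaults()]); loss reads 0
#' @return an object of class `sensor_status`
#' @export
sensor_status <- function(status = character(0),
                          saturation_values = saturation_defaults()) {
  full <- stats::setNames(rep("ok", length(FEATURES)), FEATURES)
  if (length(status)) {
    stopifnot(all(names(status) %in% FEATURES),
              all(status %in% c("ok", "lost", "saturated")))
    full[names(status)] <- status
  }
  structure(list(status = full, saturation_values = saturation_values),
            class = "sensor_status")
}

#' Overwrite faulted features in a synchronized frame
#'
#' Pure transformation: lost features read 0, saturated features read their
#' per-feature stuck-at constant, over the whole frame. The input frame is
#' not mutated (copy semantics), so applying and discarding a fault leaves
#' the original data bit-exact.
#'
#' @param frame a `synchronized_frame` (or a migraine window with an
#'   `inputs` matrix)
#' @param status a [sensor_status()]
#' @return the modified copy
#' @export
apply_faults <- function(frame, status) {
  stopifnot(inherits(status, "sensor_status"))
  target <- if (inherits(frame, "synchronized_frame")) frame$features
            else frame$inputs
  for (nm in names(status$status)) {
    if (!(nm %in% colnames(target))) next   # fault on absent feature: no-op
    if (status$status[[nm]] == "lost") target[, nm] <- 0
    if (status$status[[nm]] == "saturated")
      target[, nm] <- status$saturation_values[[nm]]
  }
  if (inherits(frame, "synchronized_frame")) frame$features <- target
  else frame$inputs <- target
  frame
}

#' Sensor-fault robustness suite
#'
#' For each fault mode the affected feature is overwritten over the whole
#' validation window (0 for loss, the saturation constant otherwise), the
#' ensemble is re-validated, and the horizons at the fit threshold are
#' tabulated -- one row per fault, mirroring a robustness report.
#'
#' @param ensemble a validated `ensemble_model`
#' @param migraines migraine windows (see [make_migraine_windows()])
#' @param faults named list of [sensor_status()] objects (names label rows)
#' @param horizons,fit_threshold,decider_threshold,min_event_min see
#'   [validate_ensemble()]
#' @return data.frame fault, fh_min, fh_average, fh_max, fh_sigma
#' @export
run_fault_suite <- function(ensemble, migraines, faults, horizons = 1:100,
                            fit_threshold = 70, decider_threshold = 50,
                            min_event_min = 60) {
  rows <- lapply(names(faults), function(nm) {
    st <- faults[[nm]]
    mig_f <- lapply(migraines, apply_faults, status = st)
    ens <- validate_ensemble(ensemble, mig_f, horizons, fit_threshold,
                             decider_threshold, min_event_min)
    data.frame(fault = nm, fh_min = ens$fh[["fh_min"]],
               fh_average = ens$fh[["fh_average"]],
               fh_max = ens$fh[["fh_max"]],
               fh_sigma = ens$fh[["fh_sigma"]])
  })
  do.call(rbind, rows)
}

#' Hierarchy of feature-subset ensembles
#'
#' Built once at validation time, ordered by decreasing average horizon;
#' consulted at run time according to sensor availability.
#'
#' @param entries list of lists with elements `feature_set` (character),
#'   `ensemble` (an `ensemble_model` or `NULL` in constructed tests), and
#'   `fh` (named numeric with fh_min/fh_average/fh_max)
#' @return an object of class `model_hierarchy`
#' @export
model_hierarchy <- function(entries) {
  fsets <- lapply(entries, `[[`, "feature_set")
  if (anyDuplicated(vapply(fsets, paste, character(1), collapse = "-")))
    stop("hierarchy feature sets must be distinct")
  avg <- vapply(entries, function(e) e$fh[["fh_average"]], numeric(1))
  structure(list(entries = entries[order(-avg)]), class = "model_hierarchy")
}

#' @export
print.model_hierarchy <- function(x, ...) {
  cat("<model_hierarchy>\n")
  for (e in x$entries)
    cat(sprintf("  %-22s h = (%g, %g, %g)\n",
                paste(e$feature_set, collapse = "-"),
                e$fh[["fh_min"]], e$fh[["fh_average"]], e$fh[["fh_max"]]))
  invisible(x)
}

#' Select the best available ensemble given the sensor status
#'
#' Returns the first (highest-ranked) hierarchy entry whose feature set
#' contains only sensors currently `ok`; deterministic and order-respecting.
#'
#' @param hierarchy a [model_hierarchy()]
#' @param status a [sensor_status()]
#' @return the selected entry (list with `feature_set`, `ensemble`, `fh`),
#'   with attribute `"index"`; error if no entry is satisfiable (prediction
#'   suspended)
#' @export
sdms2_select <- function(hierarchy, status) {
  stopifnot(inherits(hierarchy, "model_hierarchy"),
            inherits(status, "sensor_status"))
  ok <- names(status$status)[status$status == "ok"]
  for (i in seq_along(hierarchy$entries)) {
    e <- hierarchy$entries[[i]]
    if (all(e$feature_set %in% ok)) {
      attr(e, "index") <- i
      return(e)
    }
  }
  stop("no model available for the current sensor status: prediction suspended")
}
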