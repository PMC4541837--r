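## Plain-text interchange: per-channel CSV (`timestamp_iso8601,value`),
## annotation / ground-truth / model JSON, frame CSV with imputation flags,
## ranking CSV. Internal timestamps are minutes since the recording origin.

iso_origin_default <- "2026-01-01T00:00:00Z"

min_to_iso <- function(minutes, origin = iso_origin_default) {
  o <- as.POSIXct(origin, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  format(o + minutes * 60, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

iso_to_min <- function(iso, origin = iso_origin_default) {
  o <- as.POSIXct(origin, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  t <- as.POSIXct(iso, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  as.numeric(difftime(t, o, units = "mins"))
}

#' Write one channel as `timestamp_iso8601,value` CSV
#' @param channel a [channel_series()]
#' @param path output file
#' @param origin ISO-8601 timestamp of minute 0
#' @export
write_channel_csv <- function(channel, path,
                              origin = iso_origin_default) {
  df <- data.frame(timestamp_iso8601 = min_to_iso(channel$time, origin),
                   value = channel$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a channel CSV written by [write_channel_csv()]
#' @param path input file
#' @param name,rate,units channel metadata (not stored in the CSV)
#' @param origin ISO-8601 timestamp of minute 0
#' @return a [channel_series()]
#' @export
read_channel_csv <- function(path, name, rate, units,
                             origin = iso_origin_default) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  channel_series(name, rate, iso_to_min(df$timestamp_iso8601, origin),
                 df$value, units)
}

#' Write pain annotations as JSON
#'
#' Schema per element:
#' `{aura_start, pain_start, pain_end, marks: [{t, delta}], global_index}`,
#' timestamps in minutes since the recording origin.
#' @param annotations list of [pain_annotation()]
#' @param path output file
#' @export
write_annotations_json <- function(annotations, path) {
  payload <- lapply(annotations, function(a)
    list(aura_start = a$aura_start, pain_start = a$pain_start,
         pain_end = a$pain_end,
         marks = lapply(seq_len(nrow(a$marks)), function(i)
           list(t = a$marks$t[i], delta = a$marks$delta[i])),
         global_index = a$global_index))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read pain annotations written by [write_annotations_json()]
#' @param path input file
#' @return list of [pain_annotation()]
#' @export
read_annotations_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(a) {
    marks <- do.call(rbind, lapply(a$marks, function(m)
      data.frame(t = m$t, delta = m$delta)))
    pain_annotation(a$aura_start, a$pain_start, a$pain_end, marks,
                    a$global_index)
  })
}

#' Write ground truth (events + true curve parameters) as JSON
#' @param truth the `truth` element of a `raw_recording`
#' @param path output file
#' @export
write_ground_truth_json <- function(truth, path) {
  payload <- list(
    lead_time = truth$lead_time,
    events = truth$events,
    true_curves = lapply(truth$true_curves, function(cv)
      list(mu1 = cv$mu1, sigma1 = cv$sigma1, mu2 = cv$mu2,
           sigma2 = cv$sigma2)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a full recording to a directory
#'
#' One CSV per channel, `annotations.json`, `ground_truth.json`.
#' @param recording a `raw_recording`
#' @param dir output directory (created if missing)
#' @export
write_recording_csv <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(recording$channels))
    write_channel_csv(recording$channels[[nm]],
                      file.path(dir, paste0(nm, ".csv")))
  write_annotations_json(recording$truth$annotations,
                         file.path(dir, "annotations.json"))
  write_ground_truth_json(recording$truth,
                          file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Write a synchronized frame as CSV
#'
#' Columns `timestamp,TEMP,EDA,HR,SpO2,imputed_flags`; the flag column lists
#' the imputed features pipe-separated (empty when none).
#' @param frame a `synchronized_frame`
#' @param path output file
#' @export
write_frame_csv <- function(frame, path) {
  flags <- apply(frame$imputed, 1, function(r)
    paste(colnames(frame$imputed)[r], collapse = "|"))
  df <- data.frame(timestamp = frame$grid, frame$features,
                   imputed_flags = flags, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a frame CSV written by [write_frame_csv()]
#' @param path input file
#' @return a `synchronized_frame`
#' @export
read_frame_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feat <- as.matrix(df[, FEATURES])
  imp <- matrix(FALSE, nrow(df), length(FEATURES),
                dimnames = list(NULL, FEATURES))
  fl <- strsplit(ifelse(is.na(df$imputed_flags), "", df$imputed_flags), "\\|")
  for (i in seq_along(fl))
    if (length(fl[[i]])) imp[i, fl[[i]]] <- TRUE
  absent <- FEATURES[colSums(is.finite(feat)) == 0]
  new_frame(df$timestamp, feat,
            matrix(0, nrow(df), length(FEATURES),
                   dimnames = list(NULL, FEATURES)),
            imp, absent)
}

#' Serialize a state-space model to JSON
#' @param model a `state_space_model`
#' @param path output file
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    A = model$A, B = model$B, C = model$C, D = model$D, K = model$K,
    nx = model$nx, ph = model$ph, fh_train = model$fh_train,
    input_names = model$input_names,
    normalization = list(mu = as.list(model$normalization$mu),
                         sd = as.list(model$normalization$sd),
                         y_mu = model$normalization$y_mu),
    training_fit = model$training_fit)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a model JSON written by [write_model_json()]
#' @param path input file
#' @return a `state_space_model`
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  structure(list(
    A = as_mat(p$A), B = as_mat(p$B), C = as_mat(p$C), D = as_mat(p$D),
    K = matrix(unlist(p$K), ncol = 1),
    nx = p$nx, ph = p$ph, ph_eff = p$ph, reduced_ph = FALSE,
    fh_train = p$fh_train, input_names = p$input_names,
    normalization = list(mu = unlist(p$normalization$mu),
                         sd = unlist(p$normalization$sd),
                         y_mu = p$normalization$y_mu %||% 0),
    fit_type = "prediction", training_fit = p$training_fit,
    rank_flag = FALSE, unstable_flag = FALSE),
    class = "state_space_model")
}

#' Write a model ranking as CSV (model, fh_min, fh_average, fh_max,
#' fh_sigma), best first
#' @param ranking a `model_ranking`
#' @param path output file
#' @export
write_ranking_csv <- function(ranking, path) {
  df <- ranking$stats[match(ranking$order, ranking$stats$model), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
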