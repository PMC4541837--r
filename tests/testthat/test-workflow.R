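# Study orchestration: split, subset study, hierarchy, realtime replay.

test_that("episode split honors the configured fraction and seed", {
  s <- split_dataset(20, study_config(seed = 1))
  expect_equal(length(s$train), 15)
  expect_equal(length(s$test), 5)
  expect_equal(sort(c(s$train, s$test)), 1:20)
  # the smaller patient-B style dataset: 8 train / 4 test at 2/3
  sB <- split_dataset(12, study_config(split_fraction = 2 / 3, seed = 4))
  expect_equal(length(sB$train), 8)
  expect_equal(length(sB$test), 4)
  expect_identical(split_dataset(20, study_config(seed = 1)), s)
  expect_error(split_dataset(3, study_config()), "at least 4")
})

test_that("default feature subsets are the quad plus four triads", {
  fs <- default_feature_subsets()
  expect_equal(length(fs), 5)
  expect_equal(lengths(fs), c(4, 3, 3, 3, 3))
  expect_true(all(vapply(fs, function(x)
    all(x %in% c("TEMP", "EDA", "HR", "SpO2")), logical(1))))
})

test_that("migraine windows carry inputs, output curve and eval segment", {
  rec <- fx_small_recording()
  ws <- fx_small_windows()
  expect_equal(length(ws), 3)
  for (i in seq_along(ws)) {
    w <- ws[[i]]
    ev <- rec$truth$events[i, ]
    expect_equal(colnames(w$inputs), c("TEMP", "EDA", "HR", "SpO2"))
    expect_equal(length(w$y), nrow(w$inputs))
    expect_equal(max(w$y), 1, tolerance = 1e-3)  # minute grid vs exact peak
    expect_true(all(w$grid[w$eval_idx] >= ev$aura_start - 120 - 1))
    expect_true(all(w$grid[w$eval_idx] <= ev$pain_end + 60 + 1))
    # fitted output curve tracks the generator's true curve
    truth_y <- evaluate_curve(rec$truth$true_curves[[i]], w$grid)
    expect_gt(compute_fit(truth_y[w$eval_idx], w$y[w$eval_idx]), 85)
  }
})

fx_study <- function() fx_memo("study_small", function() {
  rec <- fx_small_recording()
  sc <- fx_small_study_config()
  run_feature_subset_study(fx_small_frame(), rec$truth$annotations, sc,
                           split = list(train = 1:3, test = integer(0)))
})

test_that("the subset study evaluates five subsets into an ordered hierarchy", {
  study <- fx_study()
  expect_equal(nrow(study$subset_table), 5)
  avg <- vapply(study$hierarchy$entries, function(e) e$fh[["fh_average"]],
                numeric(1))
  expect_true(all(diff(avg) <= 1e-9))
  for (e in study$hierarchy$entries)
    expect_identical(e$ensemble$feature_set, e$feature_set)
})

test_that("the study is a pure function of (data, config)", {
  study <- fx_study()
  rec <- fx_small_recording()
  again <- run_feature_subset_study(fx_small_frame(),
                                    rec$truth$annotations,
                                    fx_small_study_config(),
                                    split = list(train = 1:3,
                                                 test = integer(0)))
  expect_equal(again$subset_table, study$subset_table)
})

test_that("test stage scores held-out events and baselines", {
  study <- fx_study()
  rec <- fx_small_recording()
  sc <- fx_small_study_config()
  top <- study$hierarchy$entries[[1]]
  base_w <- make_baseline_windows(fx_small_frame(), rec$truth$annotations,
                                  n_max = 2)
  res <- run_test_stage(top$ensemble, fx_small_windows()[1],
                        baseline_windows = base_w, config = sc)
  expect_s3_class(res$counts, "confusion_counts")
  expect_lte(res$horizon_used, 30)
  expect_equal(nrow(res$per_event), 1)
  expect_equal(res$counts$tp + res$counts$fn, 1)
})

test_that("realtime replay alarms ahead of pain and switches under sensor loss", {
  study <- fx_study()
  rec <- fx_small_recording()
  frame <- fx_small_frame()
  sc <- fx_small_study_config()
  ev <- rec$truth$events[2, ]
  idx <- which(frame$grid >= ev$aura_start - 600 &
                 frame$grid <= ev$pain_end + 120)
  sub <- structure(list(grid = frame$grid[idx],
                        features = frame$features[idx, ],
                        confidence = frame$confidence[idx, ],
                        imputed = frame$imputed[idx, ],
                        absent = frame$absent),
                   class = "synchronized_frame")
  rt <- simulate_realtime(sub, study$hierarchy, sc,
                          truth_events = rec$truth$events)
  live <- rt$alarms[!rt$alarms$retracted, ]
  expect_gt(nrow(live), 0)
  expect_true(any(live$lead_min > 0))

  # scripted mid-stream loss of a feature used by the top subset
  lose <- study$hierarchy$entries[[1]]$feature_set[1]
  script <- data.frame(start = sub$grid[50], end = max(sub$grid) + 1,
                       feature = lose, mode = "lost")
  rt2 <- simulate_realtime(sub, study$hierarchy, sc,
                           truth_events = rec$truth$events,
                           fault_script = script)
  sel <- rt2$log[rt2$log$stage == "select", ]
  expect_gte(nrow(sel), 2)
  after <- strsplit(sel$message[nrow(sel)], " ")[[1]][2]
  expect_false(lose %in% strsplit(after, "-")[[1]])
})

test_that("event-free replay raises no standing alarms", {
  study <- fx_study()
  rec <- fx_small_recording()
  frame <- fx_small_frame()
  base_w <- make_baseline_windows(frame, rec$truth$annotations,
                                  length_min = 720, n_max = 1)
  w <- base_w[[1]]
  sub <- structure(list(grid = w$grid, features = w$inputs,
                        confidence = NULL, imputed = NULL,
                        absent = frame$absent),
                   class = "synchronized_frame")
  rt <- simulate_realtime(sub, study$hierarchy, fx_small_study_config())
  expect_equal(nrow(rt$alarms[!rt$alarms$retracted, ]), 0)
})

test_that("a hierarchy transfers to another patient's frames (cross-patient protocol)", {
  study <- fx_study()
  sc <- fx_small_study_config()
  cfgB <- synthetic_config(duration_days = 4, n_migraines = 2, lead_time = 45,
                           snr_db = 25, gap_rate = 0, seed = 21)
  recB <- generate_patient(cfgB)
  frameB <- preprocess_recording(recB)
  wB <- make_migraine_windows(frameB, recB$truth$annotations, sc)
  res <- run_test_stage(study$hierarchy$entries[[1]]$ensemble, wB,
                        config = sc)
  expect_equal(res$counts$tp + res$counts$fn, 2)
  expect_true(all(is.finite(res$per_event$fit)))
})
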