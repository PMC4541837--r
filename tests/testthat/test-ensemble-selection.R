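# Linear decider, false-positive repair, cross-validation ranking,
# averaged ensemble.

test_that("linear decider projects prediction to probability and detects", {
  tr <- linear_decider(c(0, 0.5, 1.0, -0.3, 0.49))
  expect_equal(tr$probability, c(0, 50, 100, 0, 49))
  # 0.5 is the detection boundary (probability >= 50 opens a detection)
  expect_equal(nrow(tr$detections), 1)
  expect_equal(tr$detections$A, 1)
  expect_equal(tr$detections$B, 2)
})

test_that("repair keeps long events with zero-crossing marks and drops blips", {
  n <- 720
  pred <- numeric(n)
  pred[96:100] <- 0.3          # sub-threshold shoulder before the event
  pred[101:190] <- 0.8         # 90-min supra-threshold event
  pred[191:195] <- 0.2         # decaying shoulder
  pred[300:319] <- 0.7
  pred[400:419] <- 0.9
  pred[500:519] <- 0.6
  tr <- repair_prediction(linear_decider(pred))
  # event kept, marks A/B at the zero crossings (shoulders included)
  expect_equal(tr$detections$A, 95)    # grid is 0-based
  expect_equal(tr$detections$B, 194)
  expect_equal(tr$predicted[96:195], pred[96:195])
  # the three 20-min blips are zeroed in prediction and probability
  blips <- c(300:319, 400:419, 500:519)
  expect_true(all(tr$predicted[blips] == 0))
  expect_true(all(tr$probability[blips] == 0))
  # everything else untouched
  rest <- setdiff(seq_len(n), c(blips, 96:195))
  expect_equal(tr$predicted[rest], pred[rest])
})

test_that("repair leaves an all-zero trace unchanged", {
  tr <- repair_prediction(linear_decider(numeric(500)))
  expect_equal(tr$predicted, numeric(500))
  expect_equal(nrow(tr$detections), 0)
  empty <- repair_prediction(linear_decider(numeric(0)))
  expect_equal(length(empty$predicted), 0)
})

test_that("repair is idempotent and exact on randomized toy traces", {
  for (seed in 1:25) {
    toy <- fx_repair_toy(seed)
    tr1 <- repair_prediction(linear_decider(toy$pred))
    expect_true(all(tr1$predicted[toy$blip_idx] == 0))
    expect_equal(tr1$predicted[toy$event_idx], toy$pred[toy$event_idx])
    tr2 <- repair_prediction(tr1)
    expect_identical(tr1, tr2)
  }
})

test_that("repair never decreases the fit when blips lie outside the event", {
  set.seed(77)
  for (rep in 1:10) {
    toy <- fx_repair_toy(100 + rep)
    n <- length(toy$pred)
    y <- numeric(n)
    y[toy$event_idx] <- 1        # true event occupies the long excursion
    raw <- linear_decider(toy$pred)
    rep_tr <- repair_prediction(raw)
    expect_gte(compute_fit(y, rep_tr$predicted), compute_fit(y, raw$predicted))
  }
})

test_that("sustained-drop rule extracts the achievable horizon", {
  fits <- c(90, 85, 80, 75, 72, 69, 71, 69, 68, 67, rep(50, 10))
  expect_equal(horizon_from_curve(fits, 1:20), 7)
  # monotone curve: largest k at threshold
  expect_equal(horizon_from_curve(seq(100, 5, length.out = 20), 1:20), 7)
  h0 <- horizon_from_curve(rep(30, 10), 1:10)
  expect_equal(as.numeric(h0), 0)
  expect_true(attr(h0, "never_reached"))
  expect_equal(horizon_from_curve(rep(90, 10), 1:10), 10)
})

test_that("ranking reproduces the published ordering rules", {
  stats <- data.frame(
    model = c(2, 6, 8, 10, 13),
    fh_min = c(17, 18, 17, 10, 19),
    fh_average = c(20, 22, 20, 16, 20),
    fh_max = c(22, 25, 24, 22, 21))
  r <- rank_model_stats(stats)
  # best average first; ties by higher minimum; remaining tie by index
  expect_equal(r$order, c(6, 13, 2, 8, 10))
  expect_error(rank_model_stats(data.frame(model = 1, fh_min = 10,
                                           fh_average = 5, fh_max = 12)))
})

test_that("ensemble sizing follows the one-third rule", {
  expect_equal(m_best_size(15), 5)
  expect_equal(m_best_size(8), 3)
  expect_equal(m_best_size(12), 4)
  expect_warning(sz <- m_best_size(2), "single member")
  expect_equal(sz, 1)
})

test_that("an ensemble of identical members equals any single member", {
  m <- fx_small_models()[[1]]
  w <- fx_small_windows()[[2]]
  rk <- rank_model_stats(data.frame(model = 1:3, fh_min = 5,
                                    fh_average = 10, fh_max = 15))
  ens <- build_average_model(rk, list(m, m, m), m_best = 3)
  etr <- ensemble_predict(ens, w$inputs, w$y, k = 10, grid = w$grid)
  single <- repair_prediction(linear_decider(
    predict_k_ahead(m, w$inputs, w$y, 10), grid = w$grid))
  expect_equal(etr$predicted, single$predicted, tolerance = 1e-12)
})

test_that("members with mismatched feature subsets are rejected", {
  ms <- fx_small_models()
  w <- fx_small_windows()[[1]]
  m_alt <- best_model(train_grid(w$inputs[, c("TEMP", "EDA", "HR")], w$y,
                                 ph_grid = c(10, 20), nx_grid = 2:3))
  rk <- rank_model_stats(data.frame(model = 1:2, fh_min = 1,
                                    fh_average = 2, fh_max = 3))
  expect_error(build_average_model(rk, list(ms[[1]], m_alt), m_best = 2),
               "share")
})

test_that("cross-validation aggregates per-pair horizons into ranked stats", {
  models <- fx_small_models()
  windows <- fx_small_windows()
  r <- cross_validate(models, windows, horizons = 1:40)
  expect_s3_class(r, "model_ranking")
  expect_equal(nrow(r$stats), length(models))
  expect_true(all(r$stats$fh_min <= r$stats$fh_average))
  expect_true(all(r$stats$fh_average <= r$stats$fh_max))
  # own training migraine excluded
  expect_true(all(is.na(diag(r$horizons_by_pair))))
  # one model, one other migraine: stats collapse to that curve's horizon
  r1 <- cross_validate(models[1], windows[2], horizons = 1:40,
                       model_migraine_idx = NA)
  expect_equal(r1$stats$fh_min, r1$stats$fh_max)
  expect_equal(r1$stats$fh_average, r1$stats$fh_min)
})
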