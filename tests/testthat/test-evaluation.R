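# Event-based scoring, fault suites, SDMS2 hierarchy selection.

test_that("detections are scored against events with the fit gate", {
  ev <- data.frame(aura_start = 100, pain_end = 300)
  det <- data.frame(A = 150, B = 250)
  c1 <- score_detections(det, ev, fit_per_event = 75)
  expect_equal(c(c1$tp, c1$fp, c1$fn), c(1, 0, 0))
  # overlapping detection but unreliable fit counts as a miss
  c2 <- score_detections(det, ev, fit_per_event = 55)
  expect_equal(c(c2$tp, c2$fp, c2$fn), c(0, 0, 1))
  # detections on an asymptomatic trace are false positives
  c3 <- score_detections(data.frame(A = c(10, 500), B = c(40, 560)),
                         ev[0, ], fit_per_event = numeric(0))
  expect_equal(c(c3$tp, c3$fp, c3$fn), c(0, 2, 0))
  # sub-minute overlap does not count
  c4 <- score_detections(data.frame(A = 0, B = 100.5), ev, 90)
  expect_equal(c(c4$tp, c4$fp, c4$fn), c(0, 1, 1))
})

test_that("f_score follows the defining formulas and conventions", {
  m <- f_score(confusion_counts(3, 1, 2))
  expect_equal(m$tpr, 60)
  expect_equal(m$ppv, 75)
  expect_equal(m$f, 2 * 60 * 75 / 135)
  # zero detections: PPV reported as 100, F collapses to 0
  z <- f_score(confusion_counts(0, 0, 4))
  expect_equal(c(z$tpr, z$ppv, z$f), c(0, 100, 0))
  expect_error(f_score(confusion_counts(0, 0, 0)), "undefined")
  expect_error(confusion_counts(-1, 0, 0))
})

test_that("F equals the harmonic-mean identity on random counts", {
  set.seed(11)
  for (rep in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    if (tp + fp + fn == 0 || tp + fn == 0) next
    m <- f_score(confusion_counts(tp, fp, fn))
    expect_equal(m$f, 100 * 2 * tp / (2 * tp + fp + fn), tolerance = 1e-12)
  }
})

test_that("fault application is pure and ignores absent features", {
  fr <- fx_small_frame()
  orig <- fr$features
  st <- sensor_status(c(EDA = "lost", SpO2 = "saturated"))
  faulted <- apply_faults(fr, st)
  expect_true(all(faulted$features[, "EDA"] == 0))
  expect_true(all(faulted$features[, "SpO2"] == saturation_defaults()["SpO2"]))
  expect_identical(fr$features, orig)   # source untouched
  # fault on a feature absent from a window's subset: no-op
  w <- fx_small_windows()[[1]]
  w$inputs <- w$inputs[, c("TEMP", "HR"), drop = FALSE]
  w2 <- apply_faults(w, sensor_status(c(EDA = "lost")))
  expect_identical(w2$inputs, w$inputs)
})

test_that("saturation defaults carry the documented stuck-at values", {
  expect_equal(saturation_defaults(),
               c(TEMP = 35, EDA = 25, HR = 100, SpO2 = 80))
})

test_that("fault suite reproduces the clean run under no fault and degrades under loss", {
  models <- fx_small_models()
  windows <- fx_small_windows()
  rk <- cross_validate(models, windows, horizons = 1:40)
  ens <- build_average_model(rk, models, m_best = 1)
  ens <- validate_ensemble(ens, windows[-ens$member_ids], horizons = 1:40)
  faults <- c(list(none = sensor_status()),
              lapply(stats::setNames(nm = c("TEMP", "EDA", "HR", "SpO2")),
                     function(f) sensor_status(stats::setNames("lost", f))))
  tab <- run_fault_suite(ens, windows[-ens$member_ids], faults,
                         horizons = 1:40)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$fh_average[tab$fault == "none"],
               unname(ens$fh["fh_average"]))
  # losing the most informative channel strictly degrades the horizon
  expect_lt(min(tab$fh_average[tab$fault != "none"]),
            tab$fh_average[tab$fault == "none"])
})

test_that("sdms2 selection is deterministic, order-respecting and total", {
  fs <- list(c("TEMP", "EDA", "HR", "SpO2"), c("TEMP", "EDA", "HR"),
             c("TEMP", "EDA", "SpO2"), c("TEMP", "HR", "SpO2"),
             c("EDA", "HR", "SpO2"))
  entries <- lapply(seq_along(fs), function(i)
    list(feature_set = fs[[i]], ensemble = NULL,
         fh = c(fh_min = 10 - i, fh_average = 50 - i, fh_max = 90 - i)))
  h <- model_hierarchy(entries)
  # all ok -> top entry
  top <- sdms2_select(h, sensor_status())
  expect_equal(attr(top, "index"), 1)
  # EDA lost -> first EDA-free entry
  sel <- sdms2_select(h, sensor_status(c(EDA = "lost")))
  expect_false("EDA" %in% sel$feature_set)
  expect_equal(attr(sel, "index"), 4)   # TEMP-HR-SpO2 precedes EDA-HR-SpO2
  # exhaustive: selected index is minimal among satisfiable entries
  for (bad in list("TEMP", "HR", c("TEMP", "EDA"), c("HR", "SpO2"))) {
    st <- sensor_status(stats::setNames(rep("lost", length(bad)), bad))
    ok <- setdiff(c("TEMP", "EDA", "HR", "SpO2"), bad)
    satisf <- which(vapply(h$entries, function(e)
      all(e$feature_set %in% ok), logical(1)))
    if (length(satisf) == 0) {
      expect_error(sdms2_select(h, st), "suspended")
    } else {
      expect_equal(attr(sdms2_select(h, st), "index"), min(satisf))
    }
  }
  # all sensors lost -> no-model error
  st_all <- sensor_status(c(TEMP = "lost", EDA = "lost", HR = "lost",
                            SpO2 = "lost"))
  expect_error(sdms2_select(h, st_all), "suspended")
  # hierarchy orders by average horizon and rejects duplicate subsets
  expect_error(model_hierarchy(entries[c(1, 1)]), "distinct")
})
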