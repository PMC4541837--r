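# Fit metric, N4SID identification, k-step prediction, training grid.

test_that("compute_fit matches hand-derived values and guards its domain", {
  y <- c(0, 1, 2)
  expect_equal(compute_fit(y, y), 100)
  expect_equal(compute_fit(y, rep(mean(y), 3)), 0)
  expect_equal(compute_fit(y, c(0, 1, 1)), 100 * (1 - 1 / sqrt(2)))
  expect_error(compute_fit(y, c(1, 2)), "equal length")
  expect_error(compute_fit(rep(1, 5), rep(1, 5)), "constant")
  # may be negative for predictions worse than the mean
  expect_lt(compute_fit(y, c(5, -4, 9)), 0)
})

test_that("compute_fit agrees with a brute-force norm oracle", {
  set.seed(123)
  for (rep in 1:50) {
    n <- sample(5:200, 1)
    y <- stats::rnorm(n)
    yhat <- y + stats::rnorm(n, sd = runif(1, 0.01, 3))
    oracle <- 100 * (1 - norm(as.matrix(y - yhat), "F") /
                       norm(as.matrix(y - mean(y)), "F"))
    expect_equal(compute_fit(y, yhat), oracle, tolerance = 1e-12)
  }
})

test_that("noise-free third-order dynamics are recovered", {
  sim <- fx_lti_sim(2000, seed = 1)
  m <- fit_n4sid(sim$U[1:1500, ], sim$y[1:1500], nx = 3, ph = 20)
  expect_equal(m$nx, 3)
  # eigenvalues of the true A are invariants of the input-output behavior
  expect_equal(sort(Mod(eigen(m$A)$values)),
               sort(Mod(eigen(sim$A)$values)), tolerance = 0.02)
  yh <- simulate_model(m, sim$U, clamp = FALSE)
  expect_gt(compute_fit(sim$y[1501:2000], yh[1501:2000]), 95)
})

test_that("white-noise output with uninformative inputs trains near zero fit", {
  set.seed(4)
  U <- matrix(stats::rnorm(1200 * 2), 1200, 2)
  y <- stats::rnorm(1200)
  m <- fit_n4sid(U, y, nx = 3, ph = 20)
  expect_lt(abs(m$training_fit), 15)
})

test_that("input scaling is absorbed by the normalization", {
  sim <- fx_lti_sim(800, seed = 2)
  m1 <- fit_n4sid(sim$U, sim$y, nx = 3, ph = 15)
  m2 <- fit_n4sid(sim$U * 100, sim$y, nx = 3, ph = 15)
  p1 <- predict_k_ahead(m1, sim$U, sim$y, 10, clamp = FALSE)
  p2 <- predict_k_ahead(m2, sim$U * 100, sim$y, 10, clamp = FALSE)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("every returned predictor is stable", {
  set.seed(9)
  for (rep in 1:8) {
    sim <- fx_lti_sim(600, seed = rep, snr_db = 15,
                      A = { M <- matrix(stats::rnorm(9), 3)
                            M * (0.9 / max(Mod(eigen(M)$values))) })
    m <- fit_n4sid(sim$U, sim$y, nx = sample(2:6, 1), ph = sample(10:30, 1))
    expect_lt(max(Mod(eigen(m$A - m$K %*% m$C)$values)), 1)
    expect_lte(max(Mod(eigen(m$A)$values)), 0.98 + 1e-8)
  }
})

test_that("k-step prediction is exact for a deterministic system with held inputs", {
  A <- matrix(c(0.8, 0.1, 0, 0.5), 2, 2)
  B <- matrix(c(1, 0.3), 2, 1)
  C <- matrix(c(0.7, -0.4), 1, 2)
  m <- fx_manual_model(A, B, C)
  # constant input: zero-order hold assumption is exact
  N <- 120
  U <- matrix(1, N, 1, dimnames = list(NULL, "u1"))
  x <- c(0, 0); y <- numeric(N)
  for (k in seq_len(N)) { y[k] <- drop(C %*% x); x <- drop(A %*% x + B * 1) }
  for (k in c(1, 5, 30)) {
    p <- predict_k_ahead(m, U, y, k, clamp = FALSE)
    expect_equal(p[(k + 1):N], y[(k + 1):N], tolerance = 1e-10)
  }
  # zero inputs, zero state -> zero prediction
  U0 <- matrix(0, N, 1, dimnames = list(NULL, "u1"))
  expect_equal(predict_k_ahead(m, U0, numeric(N), 10, clamp = FALSE),
               numeric(N))
})

test_that("short-horizon prediction error does not exceed long-horizon error", {
  errs <- sapply(1:5, function(s) {
    sim <- fx_lti_sim(900, seed = 10 + s, snr_db = 20)
    m <- fit_n4sid(sim$U, sim$y, nx = 3, ph = 15)
    p1 <- predict_k_ahead(m, sim$U, sim$y, 1, clamp = FALSE)
    p30 <- predict_k_ahead(m, sim$U, sim$y, 30, clamp = FALSE)
    idx <- 40:900
    c(var(sim$y[idx] - p1[idx]), var(sim$y[idx] - p30[idx]))
  })
  expect_true(all(errs[1, ] <= errs[2, ] + 1e-12))
})

test_that("prediction outputs are clamped to the symptomatic scale by default", {
  sim <- fx_lti_sim(600, seed = 3)
  m <- fit_n4sid(sim$U, sim$y, nx = 3, ph = 10)
  p <- predict_k_ahead(m, sim$U, sim$y, 5)
  expect_true(all(p >= -0.2 & p <= 1.2))
  expect_warning(predict_k_ahead(m, sim$U, sim$y, 101), "outside")
})

test_that("train_grid enumerates the full 200-combination search space", {
  w <- fx_small_windows()[[2]]
  tg <- train_grid(w$inputs, w$y)        # default ph 5..100 x nx 1..10
  expect_equal(nrow(tg$grid), 200)
  expect_equal(sort(unique(tg$grid$ph)), seq(5, 100, by = 5))
  expect_equal(sort(unique(tg$grid$nx)), 1:10)
  expect_false(any(tg$grid$skipped))
  expect_true(is.finite(tg$grid$fit[tg$best]))
  expect_equal(tg$grid$fit[tg$best], max(tg$grid$fit, na.rm = TRUE))
})

test_that("train_grid is deterministic and skips infeasible rows on tiny windows", {
  sim <- fx_lti_sim(400, seed = 6, snr_db = 20)
  t1 <- train_grid(sim$U, sim$y, ph_grid = c(10, 20), nx_grid = 2:3)
  t2 <- train_grid(sim$U, sim$y, ph_grid = c(10, 20), nx_grid = 2:3)
  expect_equal(t1$grid, t2$grid)
  # 30-sample window cannot support order 8
  tiny <- train_grid(sim$U[1:30, ], sim$y[1:30],
                     ph_grid = c(5, 50), nx_grid = c(1, 8))
  expect_true(any(tiny$grid$skipped))
  expect_error(fit_n4sid(sim$U[1:20, ], sim$y[1:20], nx = 8, ph = 50),
               "too short")
})

test_that("a generator with short memory is matched by short past horizons", {
  # y depends on u through a fast (few-minute) filter: the best past horizon
  # must stay in the sanity envelope ph <= 60
  sim <- fx_lti_sim(1300, seed = 8, snr_db = 25)
  tg <- train_grid(sim$U, sim$y)
  expect_lte(tg$grid$ph[tg$best], 60)
})

test_that("models survive a JSON round trip", {
  sim <- fx_lti_sim(600, seed = 12, snr_db = 20)
  m <- fit_n4sid(sim$U, sim$y, nx = 3, ph = 10)
  f <- tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  p1 <- predict_k_ahead(m, sim$U, sim$y, 10)
  p2 <- predict_k_ahead(m2, sim$U, sim$y, 10)
  expect_equal(p1, p2, tolerance = 1e-12)
})
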