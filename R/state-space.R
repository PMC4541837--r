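## Subspace identification of combined deterministic-stochastic linear
## state-space models
##
##   x_{k+1} = A x_k + B u_k + w_k
##   y_k     = C x_k + D u_k + v_k
##
## from the four 1/min features (inputs u) to the symptomatic curve (output
## y), using the N4SID scheme: block-Hankel construction with `ph` past and
## future block rows, oblique projection of the future outputs onto the past
## along the future inputs, SVD rank truncation at the model order nx, and
## least-squares recovery of the system matrices. The innovation covariances
## give the Kalman predictor gain K through a discrete algebraic Riccati
## equation, so every model can be run in one-step predictor form
## x^_{j+1} = A x^_j + B u_j + K (y_j - C x^_j - D u_j).

#' Similarity fit between a reference and a predicted series
#'
#' `fit = 100 * (1 - ||y - yhat|| / ||y - mean(y)||)` (2-norms). 100 means a
#' perfect prediction, 0 the performance of the constant mean predictor;
#' values can be negative.
#'
#' @param y reference series (not constant, length >= 2)
#' @param yhat predicted series of equal length
#' @return fit in percent
#' @export
compute_fit <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2) stop("need at least 2 samples")
  denom <- sqrt(sum((y - mean(y))^2))
  if (denom < 1e-300) stop("fit undefined for constant y")
  100 * (1 - sqrt(sum((y - yhat)^2)) / denom)
}

## ---- internal N4SID machinery -----------------------------------------

# remove from the row space of X its projection onto the row space of B
proj_perp <- function(X, B) {
  G <- tcrossprod(B)
  X - (tcrossprod(X, B) %*% pinv(G)) %*% B
}

# oblique projection of the row space of X onto W along U
proj_oblique <- function(X, U, W) {
  Xp <- proj_perp(X, U)
  Wp <- proj_perp(W, U)
  (tcrossprod(Xp, Wp) %*% pinv(tcrossprod(Wp))) %*% W
}

# shared per-(window, ph) computation: Hankel blocks, the two oblique
# projections and the SVD; nx-specific realization happens in n4sid_realize
n4sid_project <- function(U, y, i) {
  U <- as.matrix(U)
  m <- ncol(U); N <- nrow(U)
  j <- N - 2L * i + 1L
  if (j < 2L) return(NULL)
  Uh <- block_hankel(t(U), 2L * i, j) / sqrt(j)
  Yh <- block_hankel(matrix(y, 1), 2L * i, j) / sqrt(j)
  Up <- Uh[seq_len(m * i), , drop = FALSE]
  Uf <- Uh[(m * i + 1L):(2L * m * i), , drop = FALSE]
  Yp <- Yh[seq_len(i), , drop = FALSE]
  Yf <- Yh[(i + 1L):(2L * i), , drop = FALSE]
  Upp <- Uh[seq_len(m * (i + 1L)), , drop = FALSE]
  Uff <- Uh[(m * (i + 1L) + 1L):(2L * m * i), , drop = FALSE]
  Ypp <- Yh[seq_len(i + 1L), , drop = FALSE]
  Yff <- Yh[(i + 2L):(2L * i), , drop = FALSE]

  Oi <- proj_oblique(Yf, Uf, rbind(Up, Yp))
  Oi1 <- proj_oblique(Yff, Uff, rbind(Upp, Ypp))
  sv <- svd(Oi)
  list(sv = sv, Oi = Oi, Oi1 = Oi1,
       Ui = Uh[(m * i + 1L):(m * (i + 1L)), , drop = FALSE],
       Yi = Yh[i + 1L, , drop = FALSE],
       i = i, j = j, m = m)
}

# realize (A, B, C, D, K) at order nx from a projection
n4sid_realize <- function(proj, nx, estimate_d = FALSE) {
  i <- proj$i; m <- proj$m
  nx_eff <- min(nx, i - 1L, sum(proj$sv$d > 1e-12 * proj$sv$d[1]))
  nx_eff <- max(nx_eff, 1L)
  rank_flag <- nx_eff < nx
  U1 <- proj$sv$u[, seq_len(nx_eff), drop = FALSE]
  s1 <- proj$sv$d[seq_len(nx_eff)]
  Gam <- U1 %*% diag(sqrt(s1), nx_eff)
  Gam1 <- Gam[seq_len(i - 1L), , drop = FALSE]
  Xi <- pinv(Gam) %*% proj$Oi
  Xi1 <- pinv(Gam1) %*% proj$Oi1

  RHS <- rbind(Xi, proj$Ui)
  Gr <- tcrossprod(RHS)
  # mild relative ridge: the features are readouts of a common autonomic
  # state and can be strongly collinear
  Gr <- Gr + diag(1e-8 * mean(diag(Gr)), nrow(Gr))
  Pr <- pinv(Gr)
  Theta_x <- (tcrossprod(Xi1, RHS) %*% Pr)
  A <- Theta_x[, seq_len(nx_eff), drop = FALSE]
  B <- Theta_x[, nx_eff + seq_len(m), drop = FALSE]
  # enforce simulation stability (k-step roll-forward uses powers of A)
  A_st <- stabilize_matrix(A, 0.98)
  unstable_flag <- !isTRUE(all.equal(A_st, A, tolerance = 1e-12))
  A <- A_st
  if (estimate_d) {
    Theta_y <- (tcrossprod(proj$Yi, RHS) %*% Pr)
    C <- Theta_y[, seq_len(nx_eff), drop = FALSE]
    D <- Theta_y[, nx_eff + seq_len(m), drop = FALSE]
  } else {
    C <- tcrossprod(proj$Yi, Xi) %*% pinv(tcrossprod(Xi))
    D <- matrix(0, 1, m)
  }

  Ex <- Xi1 - Theta_x %*% RHS
  Ey <- proj$Yi - C %*% Xi - D %*% proj$Ui
  jj <- proj$j
  Q <- tcrossprod(Ex) / jj
  R <- tcrossprod(Ey) / jj
  S <- tcrossprod(Ex, Ey) / jj
  K <- dare_kalman_gain(A, C, Q + diag(1e-12, nx_eff), R + 1e-12, S)
  if (is.null(K)) K <- matrix(0, nx_eff, 1)
  tries <- 0
  while (spectral_radius(A - K %*% C) >= 1 && tries < 30) {
    K <- K / 2
    tries <- tries + 1
  }
  if (spectral_radius(A - K %*% C) >= 1) K <- matrix(0, nx_eff, 1)
  list(A = A, B = B, C = C, D = D, K = K, nx = nx_eff,
       rank_flag = rank_flag, unstable_flag = unstable_flag)
}

# largest feasible number of block rows for N samples and m inputs
n4sid_max_rows <- function(N, m) floor((N + 1) / (2 * (m + 1) + 2))

#' Fit an N4SID state-space model
#'
#' @param inputs numeric matrix (N x U) of feature values on the 1-min grid;
#'   column names are the feature subset
#' @param y numeric length-N symptomatic-curve series (the model output)
#' @param nx model order, 1..10
#' @param ph past horizon in minutes (block-row count of the Hankel
#'   matrices); if the window is too short for `ph`, the effective horizon is
#'   reduced and flagged
#' @param fh_train future horizon (minutes) at which the training fit is
#'   reported; 30 by default (the pharmacokinetically motivated target)
#' @param fit_type `"prediction"` (fit of the `fh_train`-min-ahead
#'   prediction, default) or `"simulation"` (pure simulation from inputs)
#' @param estimate_d estimate a direct feedthrough term (default `FALSE`,
#'   `D = 0`)
#' @return an object of class `state_space_model` with matrices `A,B,C,D,K`,
#'   the effective `nx`, `ph`, `input_names`, per-feature `normalization`,
#'   `training_fit`, and flags
#' @export
fit_n4sid <- function(inputs, y, nx, ph, fh_train = 30,
                      fit_type = c("prediction", "simulation"),
                      estimate_d = FALSE) {
  fit_type <- match.arg(fit_type)
  inputs <- as.matrix(inputs)
  if (is.null(colnames(inputs)))
    colnames(inputs) <- paste0("u", seq_len(ncol(inputs)))
  stopifnot(nrow(inputs) == length(y), nx >= 1, ph >= 2)
  m <- ncol(inputs); N <- nrow(inputs)

  mu <- colMeans(inputs)
  sd_ <- apply(inputs, 2, stats::sd)
  sd_[sd_ < 1e-9] <- 1
  Un <- sweep(sweep(inputs, 2, mu), 2, sd_, "/")
  y_mu <- mean(y)
  yc <- y - y_mu

  i_max <- n4sid_max_rows(N, m)
  if (i_max < max(3L, nx + 1L))
    stop(sprintf("window too short (%d samples) for order %d", N, nx))
  i <- min(ph, i_max)
  proj <- n4sid_project(Un, yc, i)
  if (is.null(proj)) stop("window too short for the requested past horizon")
  real <- n4sid_realize(proj, nx, estimate_d)

  model <- structure(
    c(real,
      list(ph = ph, ph_eff = i, reduced_ph = i < ph, fh_train = fh_train,
           input_names = colnames(inputs),
           normalization = list(mu = mu, sd = sd_, y_mu = y_mu),
           fit_type = fit_type)),
    class = "state_space_model")
  tf <- tryCatch({
    yh <- if (fit_type == "prediction")
      predict_k_ahead(model, inputs, y, k = fh_train)
    else simulate_model(model, inputs)
    compute_fit(y, yh)
  }, error = function(e) NA_real_)
  model$training_fit <- tf
  model
}

#' @export
print.state_space_model <- function(x, ...) {
  cat(sprintf(
    "<state_space_model> nx=%d, ph=%d%s, inputs: %s, training fit %.1f%%\n",
    x$nx, x$ph, if (x$reduced_ph) sprintf(" (eff. %d)", x$ph_eff) else "",
    paste(x$input_names, collapse = ","),
    x$training_fit))
  invisible(x)
}

# apply the stored z-score normalization to a new input window
normalize_inputs <- function(model, inputs) {
  inputs <- as.matrix(inputs)[, model$input_names, drop = FALSE]
  sweep(sweep(inputs, 2, model$normalization$mu), 2,
        model$normalization$sd, "/")
}

# one-step predictor filter; returns nx x N matrix whose column j is
# x^_{j+1|j}
predictor_states <- function(model, Un, y) {
  A <- model$A; B <- model$B; C <- model$C; D <- model$D; K <- model$K
  y <- y - model$normalization$y_mu
  N <- nrow(Un); nx <- model$nx
  X <- matrix(0, nx, N)
  x <- numeric(nx)
  for (jj in seq_len(N)) {
    e <- y[jj] - sum(C * x) - sum(D * Un[jj, ])
    x <- drop(A %*% x) + drop(B %*% Un[jj, ]) + drop(K) * e
    X[, jj] <- x
  }
  X
}

#' Predict the output k minutes ahead along a whole window
#'
#' The predictor form is iterated over the observed data; at each minute `j`
#' the state is rolled `k` steps forward with the innovation set to zero and
#' the inputs held at their last observed value (zero-order hold: at
#' prediction time only past data exist). The raw output is clamped to
#' `[-0.2, 1.2]` before the downstream probability mapping.
#'
#' @param model a `state_space_model`
#' @param inputs N x U feature matrix (unnormalized, full feature columns ok)
#' @param y length-N observed output used by the innovation filter
#' @param k prediction horizon in minutes (>= 1; > 100 is outside the
#'   validated range and warns)
#' @param clamp clamp the output to `[-0.2, 1.2]` (default)
#' @return length-N vector: element `t` is the prediction of `y[t]` made at
#'   `t - k` (the first `k` elements, with no usable past, are 0)
#' @export
predict_k_ahead <- function(model, inputs, y, k, clamp = TRUE) {
  stopifnot(inherits(model, "state_space_model"), k >= 1)
  if (k > 100) warning("horizon k > 100 min is outside the validated range")
  drop(predict_multi_horizon(model, inputs, y, horizons = k, clamp = clamp))
}

#' Predictions at several horizons in one filter pass
#'
#' @inheritParams predict_k_ahead
#' @param horizons integer vector of horizons (minutes)
#' @param clamp clamp the output to `[-0.2, 1.2]` (the symptomatic-curve
#'   scale); disable for generic system-identification use
#' @return length(horizons) x N matrix of clamped predictions (rows named by
#'   horizon)
#' @export
predict_multi_horizon <- function(model, inputs, y, horizons, clamp = TRUE) {
  Un <- normalize_inputs(model, inputs)
  N <- nrow(Un)
  stopifnot(length(y) == N)
  X <- predictor_states(model, Un, y)
  A <- model$A; B <- model$B; C <- model$C; D <- model$D
  kmax <- max(horizons)
  out <- matrix(0, length(horizons), N,
                dimnames = list(as.character(horizons), NULL))
  Apow <- diag(model$nx)            # A^(k-1), starts at A^0
  Ssum <- matrix(0, model$nx, model$nx)  # sum_{r=0}^{k-2} A^r
  for (k in seq_len(kmax)) {
    if (k > 1) {
      Ssum <- Ssum + Apow
      Apow <- A %*% Apow
    }
    hit <- match(k, horizons)
    if (!is.na(hit)) {
      G1 <- C %*% Apow                      # 1 x nx
      G2 <- C %*% Ssum %*% B + D            # 1 x m
      yh <- drop(G1 %*% X) + drop(Un %*% t(G2)) + model$normalization$y_mu
      # yh[j] is the prediction for time j + k
      row <- numeric(N)
      valid <- seq_len(N - k)
      row[valid + k] <- yh[valid]
      out[hit, ] <- if (clamp) pmin(pmax(row, -0.2), 1.2) else row
    }
  }
  out
}

#' Pure simulation of the model output from inputs alone
#'
#' Runs the state equation with the innovations (and hence the measured
#' output) ignored: the deployment-time mode, where pain is not observed.
#'
#' @inheritParams predict_k_ahead
#' @return length-N simulated output
#' @export
simulate_model <- function(model, inputs, clamp = TRUE) {
  Un <- normalize_inputs(model, inputs)
  A <- model$A; B <- model$B; C <- model$C; D <- model$D
  N <- nrow(Un)
  yh <- numeric(N)
  x <- numeric(model$nx)
  for (jj in seq_len(N)) {
    yh[jj] <- sum(C * x) + sum(D * Un[jj, ]) + model$normalization$y_mu
    x <- drop(A %*% x) + drop(B %*% Un[jj, ])
  }
  if (clamp) pmin(pmax(yh, -0.2), 1.2) else yh
}

#' Exhaustive (past horizon, order) training grid for one migraine
#'
#' Fits every combination of past horizon `ph` in `ph_grid` (default 5..100
#' min in steps of 5) and order `nx` in `nx_grid` (default 1..10) -- 200
#' combinations at the defaults -- and reports the training fit at the fixed
#' 30-min future horizon. The best model maximizes that fit. Grid rows whose
#' past horizon exceeds what the window supports are fitted at the reduced
#' feasible horizon and flagged; windows too short for any fit at an order
#' have those entries skipped and logged in the result.
#'
#' @param inputs N x U feature matrix for one migraine window (event plus
#'   pre-attack context)
#' @param y symptomatic-curve output over the same window
#' @param ph_grid,nx_grid grids searched
#' @param fh_train future horizon (min) of the reported fit
#' @param fit_type see [fit_n4sid()]
#' @return an object of class `training_grid`: data.frame `grid`
#'   (ph, nx, fit, reduced_ph, skipped), list `models`, and `best`
#' @export
train_grid <- function(inputs, y, ph_grid = seq(5, 100, by = 5),
                       nx_grid = 1:10, fh_train = 30,
                       fit_type = "prediction") {
  inputs <- as.matrix(inputs)
  m <- ncol(inputs); N <- nrow(inputs)
  mu <- colMeans(inputs)
  sd_ <- apply(inputs, 2, stats::sd); sd_[sd_ < 1e-9] <- 1
  Un <- sweep(sweep(inputs, 2, mu), 2, sd_, "/")
  y_mu <- mean(y)
  yc <- y - y_mu
  i_max <- n4sid_max_rows(N, m)

  grid <- expand.grid(ph = ph_grid, nx = nx_grid)
  grid <- grid[order(grid$ph, grid$nx), ]
  grid$fit <- NA_real_
  grid$reduced_ph <- FALSE
  grid$skipped <- FALSE
  models <- vector("list", nrow(grid))

  for (ph in ph_grid) {
    rows <- which(grid$ph == ph)
    i <- min(ph, i_max)
    if (i < 3L) {
      grid$skipped[rows] <- TRUE
      next
    }
    proj <- n4sid_project(Un, yc, i)
    if (is.null(proj)) {
      grid$skipped[rows] <- TRUE
      next
    }
    for (r in rows) {
      nx <- grid$nx[r]
      if (i_max < nx + 1L) {
        grid$skipped[r] <- TRUE
        next
      }
      real <- n4sid_realize(proj, nx)
      model <- structure(
        c(real, list(ph = ph, ph_eff = i, reduced_ph = i < ph,
                     fh_train = fh_train,
                     input_names = colnames(inputs),
                     normalization = list(mu = mu, sd = sd_, y_mu = y_mu),
                     fit_type = fit_type)),
        class = "state_space_model")
      tf <- tryCatch({
        yh <- if (fit_type == "prediction")
          predict_k_ahead(model, inputs, y, k = fh_train)
        else simulate_model(model, inputs)
        compute_fit(y, yh)
      }, error = function(e) NA_real_)
      model$training_fit <- tf
      grid$fit[r] <- tf
      grid$reduced_ph[r] <- i < ph
      models[[r]] <- model
    }
  }
  ok <- which(!grid$skipped & is.finite(grid$fit))
  best <- if (length(ok)) ok[which.max(grid$fit[ok])] else NA_integer_
  structure(list(grid = grid, models = models, best = best),
            class = "training_grid")
}

#' @export
print.training_grid <- function(x, ...) {
  ns <- sum(x$grid$skipped)
  cat(sprintf("<training_grid> %d (ph, nx) combinations (%d skipped)\n",
              nrow(x$grid), ns))
  if (!is.na(x$best))
    cat(sprintf("  best: ph=%d nx=%d fit=%.1f%%\n",
                x$grid$ph[x$best], x$grid$nx[x$best], x$grid$fit[x$best]))
  invisible(x)
}

#' Best model of a training grid
#' @param tg a `training_grid`
#' @return the `state_space_model` with the highest training fit
#' @export
best_model <- function(tg) {
  stopifnot(inherits(tg, "training_grid"))
  if (is.na(tg$best)) stop("no feasible grid entry")
  tg$models[[tg$best]]
}
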