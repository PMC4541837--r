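## Symptomatic pain curve: subjective pain annotations are turned into a
## normalized two-semi-Gaussian intensity curve, which is the output signal
## every state-space model is trained to reproduce.
##
## All timestamps in the package are numeric minutes since the start of the
## recording; the I/O layer converts to/from ISO-8601.

#' Create a pain annotation
#'
#' A patient annotates each migraine with three timestamps (aura start, pain
#' start, pain end) and a sequence of signed punctual pain-change marks on an
#' unbounded scale: positive when the pain grows, negative when it recedes.
#' A coarse 0-10 global intensity index is stored but not modeled.
#'
#' @param aura_start,pain_start,pain_end timestamps in minutes since the
#'   recording start, with `aura_start <= pain_start < pain_end`
#' @param marks data.frame with columns `t` (minutes) and `delta` (signed
#'   pain change); all `t` must lie in `[aura_start, pain_end]`
#' @param global_index integer 0-10 overall pain rating
#' @return an object of class `pain_annotation`
#' @export
pain_annotation <- function(aura_start, pain_start, pain_end, marks,
                            global_index = 5L) {
  stopifnot(is.numeric(aura_start), is.numeric(pain_start),
            is.numeric(pain_end))
  if (!(aura_start <= pain_start && pain_start < pain_end))
    stop("need aura_start <= pain_start < pain_end")
  marks <- as.data.frame(marks)
  if (!all(c("t", "delta") %in% names(marks)))
    stop("marks must have columns 't' and 'delta'")
  marks <- marks[order(marks$t), , drop = FALSE]
  if (nrow(marks) && (min(marks$t) < aura_start || max(marks$t) > pain_end))
    stop("marks must lie within [aura_start, pain_end]")
  if (global_index < 0 || global_index > 10)
    stop("global_index must be in 0..10")
  structure(list(aura_start = aura_start, pain_start = pain_start,
                 pain_end = pain_end, marks = marks,
                 global_index = as.integer(global_index)),
            class = "pain_annotation")
}

#' Create a symptomatic curve
#'
#' The curve rises as a semi-Gaussian `exp(-(t - mu1)^2 / (2 sigma1^2))` for
#' `t <= mu1`, is 1 on `[mu1, mu2]`, and falls as
#' `exp(-(t - mu2)^2 / (2 sigma2^2))` for `t >= mu2`. Amplitude is always
#' normalized to 1.
#'
#' @param mu1,mu2 peak timestamps (minutes), `mu1 <= mu2`
#' @param sigma1,sigma2 rising / falling half-widths in minutes, both > 0
#' @param truncated logical flag: profile never returned toward zero
#'   (typically a medicated attack), so `sigma2` is an extrapolation
#' @return an object of class `symptomatic_curve`
#' @export
symptomatic_curve <- function(mu1, sigma1, mu2 = mu1, sigma2 = sigma1,
                              truncated = FALSE) {
  if (!(sigma1 > 0 && sigma2 > 0)) stop("sigmas must be positive")
  if (mu1 > mu2) stop("mu1 must be <= mu2")
  structure(list(mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2,
                 truncated = truncated),
            class = "symptomatic_curve")
}

#' Evaluate a symptomatic curve on a time grid
#'
#' @param curve a [symptomatic_curve()]
#' @param times numeric vector of timestamps (minutes)
#' @return numeric vector of intensities in `[0, 1]`
#' @export
evaluate_curve <- function(curve, times) {
  stopifnot(inherits(curve, "symptomatic_curve"))
  y <- numeric(length(times))
  lo <- times <= curve$mu1
  hi <- times >= curve$mu2
  y[lo] <- exp(-(times[lo] - curve$mu1)^2 / (2 * curve$sigma1^2))
  y[hi] <- exp(-(times[hi] - curve$mu2)^2 / (2 * curve$sigma2^2))
  y[!lo & !hi] <- 1
  y
}

#' Fit the symptomatic curve to a pain annotation
#'
#' The signed marks are cumulatively summed into a piecewise-linear pain
#' profile anchored at zero at `aura_start`, normalized to unit maximum; the
#' peak time becomes `mu1 = mu2`. `sigma1` is then fitted by least squares
#' against the profile on `[aura_start, peak]` and `sigma2` on
#' `[peak, pain_end]` (method `"ls"`), or both are solved from the anchor
#' condition curve = 0.05 at `aura_start` / `pain_end` (method `"anchor"`,
#' the fallback for sparse marks).
#'
#' A profile whose final value stays above 25% of the peak is flagged
#' `truncated` (medication typically cut the recording of the decay short);
#' its falling width then comes from the anchor rule.
#'
#' @param annotation a [pain_annotation()]
#' @param method `"ls"` (default) or `"anchor"`
#' @return a [symptomatic_curve()]
#' @export
build_symptomatic_curve <- function(annotation, method = c("ls", "anchor")) {
  stopifnot(inherits(annotation, "pain_annotation"))
  method <- match.arg(method)
  marks <- annotation$marks
  if (nrow(marks) == 0L || !any(marks$delta > 0))
    stop("no positive pain mark: profile has no peak")

  pt <- c(annotation$aura_start, marks$t)
  pv <- c(0, cumsum(marks$delta))
  pv <- pmax(pv, 0)
  peak_val <- max(pv)
  pv <- pv / peak_val
  peak <- pt[which.max(pv)]

  truncated <- pv[length(pv)] > 0.25

  anchor_sigma <- function(delta) {
    # curve(t) = 0.05 at distance delta from the peak
    max(delta, 1) / sqrt(2 * log(1 / 0.05))
  }

  fit_half <- function(lo, hi, side) {
    delta <- if (side == "rise") peak - lo else hi - peak
    if (method == "anchor" || delta < 2 || sum(pt >= lo & pt <= hi) < 3)
      return(anchor_sigma(delta))
    grid <- seq(lo, hi, by = 1)
    prof <- stats::approx(pt, pv, xout = grid, rule = 2)$y
    obj <- function(s) {
      g <- exp(-(grid - peak)^2 / (2 * s^2))
      sum((g - prof)^2)
    }
    stats::optimize(obj, interval = c(0.5, 10 * max(delta, 2)))$minimum
  }

  sigma1 <- fit_half(annotation$aura_start, peak, "rise")
  sigma2 <- if (truncated) {
    anchor_sigma(annotation$pain_end - peak)
  } else {
    fit_half(peak, annotation$pain_end, "fall")
  }
  symptomatic_curve(mu1 = peak, sigma1 = sigma1, mu2 = peak, sigma2 = sigma2,
                    truncated = truncated)
}

#' @export
print.symptomatic_curve <- function(x, ...) {
  cat(sprintf(
    "<symptomatic_curve> peak at t = [%.1f, %.1f] min, sigma = (%.1f, %.1f) min%s\n",
    x$mu1, x$mu2, x$sigma1, x$sigma2,
    if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}
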