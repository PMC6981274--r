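#' Plasmid-nicking time course
#'
#' Fractions of supercoiled substrate cleaved at each time point, one
#' column per replicate. Times are shared across replicates.
#'
#' @param times minutes, non-negative, ascending.
#' @param fractions numeric matrix (time x replicate), all values in
#'   `[0, 1]`; a vector is treated as a single replicate.
#' @return An object of class `time_course`.
#' @export
time_course <- function(times, fractions) {
  times <- as.numeric(times)
  fractions <- as.matrix(fractions)
  if (length(times) != nrow(fractions))
    stop("times and fraction rows must agree")
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be non-negative and strictly ascending")
  if (any(fractions < -1e-9 | fractions > 1 + 1e-9))
    stop("fractions must lie in [0, 1]")
  structure(list(times = times, fractions = fractions,
                 replicate_count = ncol(fractions)),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course: %d time points (%.3g-%.3g min), %d replicate(s)\n",
              length(x$times), min(x$times), max(x$times), x$replicate_count))
  invisible(x)
}

#' Fraction cleaved from gel band volumes
#'
#' Converts per-lane band quantifications (supercoiled, nicked, linear) to
#' the fraction of supercoiled substrate cleaved. Within each lane the
#' supercoiled fraction SC/(SC+N+L) is computed first -- this cancels
#' lane-loading and scanner-gain differences -- and then normalised to the
#' zero-time lane of the same replicate:
#' fraction cleaved = 1 - \[SC/(SC+N+L)\]_t / \[SC/(SC+N+L)\]_0.
#' Alternatively `method = "sc_direct"` divides the supercoiled band volume
#' by the zero-time supercoiled volume without the within-lane ratio.
#'
#' @param band_volumes data frame with columns `time_min`, `replicate`,
#'   `sc`, `nicked`, `linear`; all volumes >= 0, one zero-time lane per
#'   replicate.
#' @param method `"within_lane"` (default) or `"sc_direct"`.
#' @return A [time_course].
#' @export
normalize_lanes <- function(band_volumes, method = c("within_lane", "sc_direct")) {
  method <- match.arg(method)
  need <- c("time_min", "replicate", "sc", "nicked", "linear")
  stopifnot(all(need %in% names(band_volumes)))
  bv <- band_volumes
  if (any(bv[c("sc", "nicked", "linear")] < 0))
    stop("band volumes must be non-negative")
  total <- bv$sc + bv$nicked + bv$linear
  if (any(total <= 0)) stop("zero total band volume in a lane")
  times <- sort(unique(bv$time_min))
  if (!0 %in% times) stop("no zero-time lane present")
  reps <- sort(unique(bv$replicate))
  frac <- matrix(NA_real_, length(times), length(reps))
  for (j in seq_along(reps)) {
    sub <- bv[bv$replicate == reps[j], ]
    ref <- sub[sub$time_min == 0, ]
    if (nrow(ref) != 1) stop("replicate ", reps[j], " lacks a unique zero-time lane")
    for (i in seq_along(times)) {
      lane <- sub[sub$time_min == times[i], ]
      if (nrow(lane) != 1) next
      if (method == "within_lane") {
        sc_t <- lane$sc / (lane$sc + lane$nicked + lane$linear)
        sc_0 <- ref$sc / (ref$sc + ref$nicked + ref$linear)
      } else {
        sc_t <- lane$sc; sc_0 <- ref$sc
      }
      frac[i, j] <- 1 - sc_t / sc_0
    }
  }
  time_course(times, pmin(pmax(frac, 0), 1))
}

#' Fit a single-exponential approach to completion
#'
#' Nonlinear least squares of f(t) = A (1 - exp(-k t)) to the replicate
#' means, the model for a single-turnover reaction whose observed rate
#' constant reflects the catalytic step. The curve is pinned to f(0) = 0
#' (quenched zero-time controls); set `offset = TRUE` to co-fit a constant
#' offset instead. With >= 2 replicates, points are weighted by the inverse
#' variance of the replicate mean; single series are fitted unweighted.
#'
#' @param tc a [time_course].
#' @param offset fit an additive offset term.
#' @return An object of class `exp_fit`: `k` (1/min), `amplitude`,
#'   `k_stderr`, `amp_stderr`, `residual_sd`, `offset` (when fitted),
#'   and the underlying `nls` fit.
#' @export
fit_single_exponential <- function(tc, offset = FALSE) {
  stopifnot(inherits(tc, "time_course"))
  t <- tc$times
  if (length(unique(t)) < 4) stop("need at least 4 distinct time points")
  y <- rowMeans(tc$fractions, na.rm = TRUE)
  w <- NULL
  if (tc$replicate_count >= 2) {
    sdr <- apply(tc$fractions, 1, stats::sd, na.rm = TRUE)
    sdr[!is.finite(sdr) | sdr <= 0] <- mean(sdr[sdr > 0], na.rm = TRUE)
    if (all(is.finite(sdr)) && all(sdr > 0))
      w <- tc$replicate_count / sdr^2     # variance of the mean
  }
  A0 <- max(y)
  t_half <- if (any(y >= A0 / 2)) t[which(y >= A0 / 2)[1]] else max(t) / 2
  k0 <- log(2) / max(t_half, min(t[t > 0]))
  dat <- data.frame(t = t, y = y)
  form <- if (offset) y ~ c0 + A * (1 - exp(-k * t)) else y ~ A * (1 - exp(-k * t))
  start <- if (offset) list(A = A0, k = k0, c0 = 0) else list(A = A0, k = k0)
  lower <- if (offset) c(A = 0, k = 1e-8, c0 = -1) else c(A = 0, k = 1e-8)
  args <- list(form, data = dat, start = start)
  if (!is.null(w)) args$weights <- w
  fit <- tryCatch(
    do.call(stats::nls, c(args, list(
      control = stats::nls.control(maxiter = 500, warnOnly = FALSE)))),
    error = function(e) do.call(minpack.lm::nlsLM, c(args, list(
      lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 500)))))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(cf)))
  if (cf[["k"]] <= 0) stop("fitted rate constant is non-positive")
  structure(list(k = cf[["k"]], amplitude = cf[["A"]],
                 k_stderr = se[["k"]], amp_stderr = se[["A"]],
                 offset = if (offset) cf[["c0"]],
                 residual_sd = stats::sd(stats::residuals(fit)),
                 fit = fit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Single-exponential fit: k = %.3f +/- %.3f 1/min, A = %.3f\n",
              x$k, x$k_stderr, x$amplitude))
  invisible(x)
}

#' @export
summary.exp_fit <- function(object, ...) summary(object$fit, ...)

#' @export
plot.exp_fit <- function(x, tc = NULL, ...) {
  env <- stats::fitted(x$fit)
  t <- x$fit$m$getEnv()$t
  graphics::plot(t, x$fit$m$getEnv()$y, xlab = "time (min)",
                 ylab = "fraction cleaved", ...)
  tt <- seq(0, max(t), length.out = 200)
  graphics::lines(tt, stats::predict(x$fit, newdata = data.frame(t = tt)))
  invisible(x)
}
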