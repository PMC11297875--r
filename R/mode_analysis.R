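#' Least-squares line through the origin
#'
#' Fits `y = s * x` with zero intercept; the closed form is
#' `s = sum(x*y) / sum(x^2)`. Used to summarize, per decay time, the linear
#' cloud of (effective integration interval, contributing spike count) points
#' by a single slope.
#'
#' @param x,y numeric vectors (interval in ms on x, contributing-spike count
#'   on y, by the package's axis convention).
#' @return the slope (contributing spikes per ms).
#' @export
origin_fit <- function(x, y) {
  .assert(length(x) == length(y) && length(x) >= 1, "x and y must match, n >= 1")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  .assert(any(x != 0),
          "slope through the origin is undefined: all x are 0",
          class = "spikemode_undefined_slope")
  sum(x * y) / sum(x * x)
}

#' Slope-versus-decay-time curve
#'
#' Groups measure points by decay time and fits an origin-constrained line to
#' each group's (mean interval, mean contributing-spike count) cloud. By this
#' axis convention (x = interval, y = count) coincidence detectors — short
#' decay times — produce *steeper* slopes: more near-simultaneous input spikes
#' per millisecond of integration. Groups whose slope is undefined (all
#' intervals zero) are skipped with a warning.
#'
#' @param measures a data.frame of measure points from [measure_model()].
#' @param x_col,y_col column names for the fit axes (switchable convention).
#' @return an object of class `slope_curve`: data.frame with `decay_time_ms`,
#'   `slope`, `n_points`.
#' @export
slope_curve <- function(measures, x_col = "mean_interval_ms",
                        y_col = "mean_n_contributing") {
  .assert(all(c("decay_time_ms", x_col, y_col) %in% names(measures)),
          "measures is missing required columns")
  groups <- split(measures, measures$decay_time_ms)
  rows <- lapply(groups, function(g) {
    s <- tryCatch(origin_fit(g[[x_col]], g[[y_col]]),
                  spikemode_undefined_slope = function(e) {
                    warning(sprintf(
                      "decay time %g ms: slope undefined (all intervals 0), skipped",
                      g$decay_time_ms[1]), call. = FALSE)
                    NULL
                  })
    if (is.null(s)) return(NULL)
    data.frame(decay_time_ms = g$decay_time_ms[1], slope = s, n_points = nrow(g))
  })
  out <- do.call(rbind, rows)
  .assert(!is.null(out) && nrow(out) >= 1, "no decay group yielded a valid slope")
  out <- out[order(out$decay_time_ms), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("slope_curve", "data.frame")
  out
}

#' Offset-plus-power-law fit of a slope curve
#'
#' Fits `s(t) = a * t^b + c` to the slope-versus-decay-time curve by
#' nonlinear least squares. The additive offset `c` absorbs the
#' brightness-driven vertical shift of the curve; after removing it the curve
#' is a pure power law (a straight line in double-logarithmic scale), whose
#' exponent `b` reflects the structure of the input data rather than its
#' brightness. The offset is estimated jointly (3-parameter fit) rather than
#' subtracted beforehand; initialization takes `c0` just below the minimum
#' slope and `(log a0, b0)` from a log-log regression of `s - c0`, with five
#' perturbed restarts, keeping the best residual. Deterministic given the
#' curve.
#'
#' @param curve a [slope_curve()] (or data.frame with `decay_time_ms`,
#'   `slope`); needs at least 4 decay values.
#' @return an object of class `powerlaw_fit`: list with `a`, `b`, `c`,
#'   `residual` (sum of squared residuals), `fitted`, and the initialization
#'   trace `starts`.
#' @export
powerlaw_fit <- function(curve) {
  .assert(all(c("decay_time_ms", "slope") %in% names(curve)),
          "curve needs decay_time_ms and slope columns")
  t <- curve$decay_time_ms; s <- curve$slope
  .assert(length(unique(t)) >= 4, "need at least 4 decay values for a power-law fit")
  sse <- function(p) {
    pred <- exp(p[1]) * t^p[2] + p[3]
    sum((s - pred)^2)
  }
  c0 <- min(s) - 1e-3 * max(abs(diff(range(s))), 1e-12)
  pos <- s - c0
  b0 <- stats::coef(stats::lm(log(pos) ~ log(t)))
  base <- c(b0[1], b0[2], c0)             # (log a, b, c)
  perturb <- list(c(0, 0, 0), c(0.2, -0.1, 0), c(-0.2, 0.1, 0),
                  c(0, 0.25, -0.05 * max(abs(s))), c(0.5, -0.25, 0.05 * max(abs(s))))
  best <- NULL; starts <- list()
  for (i in seq_along(perturb)) {
    p0 <- base + perturb[[i]]
    fit <- tryCatch(stats::optim(p0, sse, method = "BFGS",
                                 control = list(maxit = 2000, reltol = 1e-14)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(stats::optim(p0, sse, method = "Nelder-Mead",
                                   control = list(maxit = 5000)),
                      error = function(e) NULL)
    }
    starts[[i]] <- list(p0 = p0, value = if (is.null(fit)) NA else fit$value)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  .assert(!is.null(best),
          "power-law fit failed to converge from all starts",
          class = "spikemode_fit_failure")
  p <- best$par
  structure(list(a = exp(p[1]), b = p[2], c = p[3], residual = best$value,
                 fitted = exp(p[1]) * t^p[2] + p[3],
                 decay_time_ms = t, starts = starts),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> s(t) = %.4g * t^%.4g + %.4g  (SSE %.3g)\n",
              x$a, x$b, x$c, x$residual))
  invisible(x)
}
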