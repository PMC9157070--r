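# Hyperbolic (Michaelis-Menten-like) model of diversity accumulation:
#
#   log10 M(t*) = log10 M(0) + [log10 M]max * t* / (t*_1/2 + t*)
#
# where t* is time shifted so the first sampled timepoint is 0, [log10 M]max
# is the saturation amplitude and t*_1/2 the half-time in days.  The fit is
# nonlinear least squares on the log10 scale, launched from a fixed 54-point
# grid of starting values with a quasi-Newton (BFGS) optimizer.

hyper_curve <- function(tstar, b0, bmax, thalf) b0 + bmax * tstar / (thalf + tstar)

#' Fit the hyperbolic diversity-accumulation model
#'
#' Fits `log10 M(t*) = log10 M(0) + [log10 M]max t*/(t*_1/2 + t*)` by least
#' squares.  Time is shifted so the first sample is `t* = 0`.  Optimization
#' uses BFGS on `(intercept, amplitude, log half-time)` from a deterministic
#' factorial grid of 54 starting points: intercepts at the min/mean/max of
#' `log10 M`, amplitudes at 0.5/1/2 times the observed range, and 6
#' log-spaced half-times spanning the sampled window.  The generation-scale
#' half-time is `tau_1/2 = t*_1/2 * per_day_generations`.
#'
#' @param times_days Sampling times in days (>= 4 values).
#' @param M_values Corresponding `M(t)` values, all > 0.
#' @param per_day_generations Estimated minimum number of generations per
#'   day, used to convert the half-time to generations (default 1).
#' @return An object of class `diversity_fit` with components `coefficients`
#'   (`intercept`, `amplitude`, `half_time_days`), `tau_half`, `se`,
#'   `objective`, per-start `diagnostics`, `fitted`, `residuals` and
#'   `converged`.  If every start fails, a fit-failure object
#'   (`converged = FALSE`) is returned rather than an error.
#' @examples
#' t <- c(100, 200, 300, 400, 500, 600, 700)
#' M <- 10^(-0.5 + 1.2 * (t - 100) / (40 + (t - 100)))
#' fit <- fit_diversity_model(t, M, per_day_generations = 3.3)
#' coef(fit)
#' @export
fit_diversity_model <- function(times_days, M_values, per_day_generations = 1) {
  if (length(times_days) != length(M_values)) {
    stopf("times and M values must have equal length")
  }
  ok <- is.finite(times_days) & is.finite(M_values) & M_values > 0
  times_days <- times_days[ok]; M_values <- M_values[ok]
  if (length(times_days) < 4) stopf("need at least 4 (time, M > 0) pairs")
  o <- order(times_days)
  times_days <- times_days[o]; M_values <- M_values[o]
  tstar <- times_days - times_days[1]
  y <- log10(M_values)

  obj <- function(par) {
    r <- y - hyper_curve(tstar, par[1], par[2], exp(par[3]))
    sum(r * r)
  }
  rng <- diff(range(y))
  if (rng == 0) rng <- 1 # flat data: nonzero amplitude starts still probed
  window <- max(tstar)
  starts <- expand.grid(
    b0 = c(min(y), mean(y), max(y)),
    bmax = c(0.5, 1, 2) * rng,
    lth = seq(log(window / 50), log(window * 2), length.out = 6)
  )
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "BFGS",
                   control = list(reltol = 1e-12, maxit = 1000)),
      error = function(e) NULL
    )
  })
  okfit <- !vapply(fits, is.null, logical(1))
  diagnostics <- data.frame(
    start = seq_len(nrow(starts)),
    converged = vapply(fits, function(f) !is.null(f) && f$convergence == 0,
                       logical(1)),
    objective = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$value,
                       numeric(1))
  )
  if (!any(okfit)) {
    return(structure(
      list(converged = FALSE, coefficients = c(intercept = NA_real_,
                                               amplitude = NA_real_,
                                               half_time_days = NA_real_),
           tau_half = NA_real_, se = NULL, objective = NA_real_,
           diagnostics = diagnostics, data = data.frame(
             day = times_days, tstar = tstar, log10M = y),
           per_day_generations = per_day_generations),
      class = "diversity_fit"
    ))
  }
  best <- fits[[which.min(diagnostics$objective)]]
  b0 <- best$par[1]; bmax <- best$par[2]; thalf <- exp(best$par[3])
  fitted <- hyper_curve(tstar, b0, bmax, thalf)
  resid <- y - fitted
  # Gauss-Newton standard errors from the analytic Jacobian
  J <- cbind(1, tstar / (thalf + tstar), -bmax * tstar / (thalf + tstar)^2)
  dof <- length(y) - 3
  se <- rep(NA_real_, 3)
  if (dof > 0) {
    s2 <- sum(resid^2) / dof
    JtJ <- crossprod(J)
    cv <- tryCatch(solve(JtJ) * s2, error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  names(se) <- c("intercept", "amplitude", "half_time_days")
  structure(
    list(converged = TRUE,
         coefficients = c(intercept = b0, amplitude = bmax,
                          half_time_days = thalf),
         tau_half = thalf * per_day_generations,
         se = se, objective = best$value, diagnostics = diagnostics,
         fitted = fitted, residuals = resid,
         data = data.frame(day = times_days, tstar = tstar, log10M = y),
         per_day_generations = per_day_generations),
    class = "diversity_fit"
  )
}

#' @export
coef.diversity_fit <- function(object, ...) object$coefficients

#' @export
residuals.diversity_fit <- function(object, ...) object$residuals

#' @export
fitted.diversity_fit <- function(object, ...) object$fitted

#' @export
predict.diversity_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stopf("fit did not converge; no predictions")
  tstar <- if (is.null(newdata)) object$data$tstar else {
    if (is.list(newdata)) newdata$tstar else newdata
  }
  cf <- object$coefficients
  hyper_curve(tstar, cf[["intercept"]], cf[["amplitude"]],
              cf[["half_time_days"]])
}

#' @export
print.diversity_fit <- function(x, ...) {
  cat("Hyperbolic diversity-accumulation fit\n")
  if (!x$converged) {
    cat("  FIT FAILED: no optimizer start converged\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf("  log10 M(0)      = %.4f\n", cf[["intercept"]]))
  cat(sprintf("  [log10 M]max    = %.4f\n", cf[["amplitude"]]))
  cat(sprintf("  t*_1/2 (days)   = %.4f\n", cf[["half_time_days"]]))
  cat(sprintf("  tau_1/2 (gens)  = %.4f  (x %.3g generations/day)\n",
              x$tau_half, x$per_day_generations))
  cat(sprintf("  SSR = %.3g over %d points; %d/%d starts converged\n",
              x$objective, nrow(x$data), sum(x$diagnostics$converged),
              nrow(x$diagnostics)))
  invisible(x)
}

#' @export
summary.diversity_fit <- function(object, ...) {
  print(object)
  if (object$converged && !is.null(object$se)) {
    cat("  standard errors:\n")
    for (nm in names(object$se)) {
      cat(sprintf("    %-15s %.4g\n", nm, object$se[[nm]]))
    }
  }
  invisible(object)
}

#' @export
plot.diversity_fit <- function(x, ...) {
  graphics::plot(x$data$tstar, x$data$log10M, xlab = "t* (days)",
                 ylab = "log10 M(t*)", ...)
  if (x$converged) {
    tt <- seq(0, max(x$data$tstar), length.out = 200)
    graphics::lines(tt, predict(x, tt), col = "firebrick")
  }
  invisible(x)
}

#' Residual-bootstrap confidence intervals for a diversity fit
#'
#' Resamples residuals with replacement, refits from the fitted parameters,
#' and returns percentile confidence intervals for the three model
#' parameters.
#'
#' @param fit A converged `diversity_fit`.
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param level Confidence level (default 0.95).
#' @param seed Optional RNG seed.
#' @return A 3 x 2 matrix of lower/upper bounds.
#' @export
diversity_fit_ci <- function(fit, n_boot = 200, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "diversity_fit"), fit$converged)
  tstar <- fit$data$tstar
  cf <- fit$coefficients
  with_seed(seed, {
    draws <- vapply(seq_len(n_boot), function(b) {
      yb <- fit$fitted + sample(fit$residuals, replace = TRUE)
      objb <- function(par) {
        r <- yb - hyper_curve(tstar, par[1], par[2], exp(par[3]))
        sum(r * r)
      }
      ans <- tryCatch(
        stats::optim(c(cf[[1]], cf[[2]], log(cf[[3]])), objb,
                     method = "BFGS",
                     control = list(reltol = 1e-10, maxit = 500)),
        error = function(e) NULL
      )
      if (is.null(ans)) rep(NA_real_, 3)
      else c(ans$par[1], ans$par[2], exp(ans$par[3]))
    }, numeric(3))
    a <- (1 - level) / 2
    ci <- t(apply(draws, 1, stats::quantile, probs = c(a, 1 - a),
                  na.rm = TRUE))
    rownames(ci) <- c("intercept", "amplitude", "half_time_days")
    ci
  })
}
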