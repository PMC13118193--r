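# Least-squares estimation of diffusion parameters from a single decay curve.
#
# Both fits work on the log signal. The kurtosis model is log-quadratic in b,
#   ln S = c0 + c1 b + c2 b^2,  Dapp = -c1, K = 6 c2 / c1^2, S0 = exp(c0),
# so an ordinary degree-2 polynomial LS fit is exact under the model and
# serves as the reference algorithm; a bounded nonlinear refinement on the
# linear signal scale is available as an option.

logquad_coef <- function(b, logs) {
  X <- cbind(1, b, b * b)
  qr.coef(qr(X), logs)
}

loglin_coef <- function(b, logs) {
  X <- cbind(1, b)
  qr.coef(qr(X), logs)
}

usable_points <- function(signal, b) {
  ok <- is.finite(signal) & signal > 0 & is.finite(b)
  list(b = b[ok], logs = log(signal[ok]), n_dropped = sum(!ok))
}

#' Fit the diffusion-kurtosis model to a signal decay curve
#'
#' Estimates \code{(S0, Dapp, K)} from signal values measured at several
#' b-values by an exact closed-form least-squares fit of a degree-2 polynomial
#' to the log signal (\code{Dapp = -c1}, \code{K = 6 c2 / c1^2},
#' \code{S0 = exp(c0)}), optionally followed by a bounded nonlinear refinement
#' on the linear signal scale. Non-positive signal values (possible under
#' magnitude noise) are excluded before taking logs; their count is recorded.
#' Estimates are constrained to physiologically plausible ranges:
#' \code{Dapp} in (0, \code{dapp_max}], \code{K} in [0, \code{k_max}].
#'
#' @param signal numeric vector of signal values (arbitrary units).
#' @param b numeric vector of b-values in s/mm2, same length as \code{signal}.
#' @param refine logical; if \code{TRUE}, refine the closed-form estimate by
#'   bounded (L-BFGS-B) nonlinear least squares on the untransformed signal.
#' @param dapp_max,k_max upper constraint bounds for \code{Dapp}
#'   (1e-3 mm2/s) and \code{K}.
#' @return An object of class \code{dki_fit} with components
#'   \code{coefficients} (named vector \code{S0}, \code{Dapp}, \code{K};
#'   \code{Dapp} on the 1e-3 mm2/s scale), \code{valid} (logical: did the fit
#'   describe a decaying curve with enough usable points), \code{clamped}
#'   (logical: was any estimate constrained), \code{n_used}, \code{n_dropped},
#'   and the input data. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{residuals}, \code{fitted}, \code{plot}.
#' @examples
#' b <- c(0, 100, 500, 800, 1200, 2000)
#' s <- dki_signal(b, S0 = 1, Dapp = 0.914, K = 1.311)
#' coef(dki_fit(s, b))
#' @seealso \code{\link{adc_fit}}, \code{\link{fit_maps}}
#' @export
dki_fit <- function(signal, b, refine = FALSE, dapp_max = 4, k_max = 3) {
  if (length(signal) != length(b)) stopf("signal and b must have equal length")
  pts <- usable_points(signal, b)
  out <- list(coefficients = c(S0 = NA_real_, Dapp = NA_real_, K = NA_real_),
              valid = FALSE, clamped = FALSE,
              n_used = length(pts$b), n_dropped = pts$n_dropped,
              refined = FALSE, data = list(b = b, signal = signal),
              bounds = c(dapp_max = dapp_max, k_max = k_max))
  class(out) <- "dki_fit"
  if (length(pts$b) < 3 || length(unique(pts$b)) < 3) return(out)
  cf <- logquad_coef(pts$b, pts$logs)
  if (anyNA(cf) || cf[2] >= 0) return(out)   # non-decaying: voxel invalid
  dapp <- -cf[2] * 1e3                        # back to 1e-3 mm2/s scale
  k <- 6 * cf[3] / cf[2]^2
  s0 <- exp(cf[1])
  clamped <- FALSE
  if (dapp > dapp_max) { dapp <- dapp_max; clamped <- TRUE }
  if (k < 0) { k <- 0; clamped <- TRUE }
  if (k > k_max) { k <- k_max; clamped <- TRUE }
  out$coefficients <- c(S0 = unname(s0), Dapp = unname(dapp), K = unname(k))
  out$valid <- TRUE
  out$clamped <- clamped
  if (refine) {
    obj <- function(p) {
      pred <- dki_signal(pts$b, S0 = p[1], Dapp = p[2], K = p[3])
      sum((exp(pts$logs) - pred)^2)
    }
    start <- pmax(out$coefficients, c(1e-8, 1e-6, 0))
    opt <- try(stats::optim(start, obj, method = "L-BFGS-B",
                            lower = c(1e-8, 1e-6, 0),
                            upper = c(Inf, dapp_max, k_max)), silent = TRUE)
    # keep the refined estimate whenever it does not worsen the objective
    # (L-BFGS-B reports a line-search stall when started at the optimum)
    if (!inherits(opt, "try-error") && opt$value <= obj(start) + 1e-12) {
      out$coefficients <- c(S0 = opt$par[[1]], Dapp = opt$par[[2]], K = opt$par[[3]])
      out$refined <- TRUE
    }
  }
  out
}

#' Fit the monoexponential ADC model to a signal decay curve
#'
#' Estimates the apparent diffusion coefficient as the negated least-squares
#' slope of the log signal against b, restricted to b-values up to
#' \code{b_max} (1200 s/mm2 by default, the conventional upper limit for
#' Gaussian-diffusion ADC mapping). Non-positive signals are excluded before
#' the log; the estimate is clamped at zero.
#'
#' @inheritParams dki_fit
#' @param b_max largest b-value (s/mm2) entering the fit.
#' @return An object of class \code{adc_fit} with \code{coefficients}
#'   (\code{S0}, \code{ADC}; ADC in 1e-3 mm2/s), \code{valid}, \code{clamped},
#'   \code{n_used}, \code{n_dropped}, and the input data (full, unrestricted).
#' @examples
#' b <- c(0, 100, 500, 800, 1200, 2000)
#' s <- me_signal(b, S0 = 1, ADC = 0.761)
#' coef(adc_fit(s, b))
#' @export
adc_fit <- function(signal, b, b_max = 1200) {
  if (length(signal) != length(b)) stopf("signal and b must have equal length")
  keep <- b <= b_max
  pts <- usable_points(signal[keep], b[keep])
  out <- list(coefficients = c(S0 = NA_real_, ADC = NA_real_),
              valid = FALSE, clamped = FALSE,
              n_used = length(pts$b), n_dropped = pts$n_dropped,
              b_max = b_max, data = list(b = b, signal = signal))
  class(out) <- "adc_fit"
  if (length(pts$b) < 2 || length(unique(pts$b)) < 2) return(out)
  cf <- loglin_coef(pts$b, pts$logs)
  if (anyNA(cf)) return(out)
  adc <- -cf[2] * 1e3
  clamped <- FALSE
  if (adc < 0) { adc <- 0; clamped <- TRUE }
  out$coefficients <- c(S0 = unname(exp(cf[1])), ADC = unname(adc))
  out$valid <- TRUE
  out$clamped <- clamped
  out
}

#' @export
print.dki_fit <- function(x, digits = 4, ...) {
  cat("Diffusion-kurtosis model fit (log-quadratic LS",
      if (x$refined) "+ nonlinear refinement", ")\n")
  if (x$valid) {
    cat(sprintf("  S0 = %.*g, Dapp = %.*g x 1e-3 mm2/s, K = %.*g%s\n",
                digits, x$coefficients[["S0"]], digits, x$coefficients[["Dapp"]],
                digits, x$coefficients[["K"]],
                if (x$clamped) "  [constrained]" else ""))
  } else cat("  fit invalid (non-decaying signal or too few usable points)\n")
  cat(sprintf("  %d points used, %d dropped (non-positive signal)\n",
              x$n_used, x$n_dropped))
  invisible(x)
}

#' @export
print.adc_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Monoexponential ADC fit (log-linear LS, b <= %g s/mm2)\n", x$b_max))
  if (x$valid) {
    cat(sprintf("  S0 = %.*g, ADC = %.*g x 1e-3 mm2/s%s\n",
                digits, x$coefficients[["S0"]], digits, x$coefficients[["ADC"]],
                if (x$clamped) "  [clamped at 0]" else ""))
  } else cat("  fit invalid (too few usable points)\n")
  invisible(x)
}

#' @export
coef.dki_fit <- function(object, ...) object$coefficients

#' @export
coef.adc_fit <- function(object, ...) object$coefficients

#' @export
predict.dki_fit <- function(object, b = object$data$b, ...) {
  if (!object$valid) return(rep(NA_real_, length(b)))
  cf <- object$coefficients
  dki_signal(b, S0 = cf[["S0"]], Dapp = cf[["Dapp"]], K = cf[["K"]])
}

#' @export
predict.adc_fit <- function(object, b = object$data$b, ...) {
  if (!object$valid) return(rep(NA_real_, length(b)))
  cf <- object$coefficients
  me_signal(b, S0 = cf[["S0"]], ADC = cf[["ADC"]])
}

#' @export
fitted.dki_fit <- function(object, ...) predict(object)

#' @export
fitted.adc_fit <- function(object, ...) predict(object)

#' @export
residuals.dki_fit <- function(object, type = c("response", "log"), ...) {
  type <- match.arg(type)
  r <- object$data$signal - predict(object)
  if (type == "log") r <- log(object$data$signal) - log(predict(object))
  r
}

#' @export
residuals.adc_fit <- residuals.dki_fit

#' @export
summary.dki_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object,
                 rmse = if (object$valid) sqrt(mean(r^2, na.rm = TRUE)) else NA_real_),
            class = "summary.dki_fit")
}

#' @export
print.summary.dki_fit <- function(x, ...) {
  print(x$fit)
  if (x$fit$valid) cat(sprintf("  residual RMSE (signal units): %.4g\n", x$rmse))
  invisible(x)
}

#' @export
plot.dki_fit <- function(x, ...) {
  b <- x$data$b
  pos <- x$data$signal > 0
  graphics::plot(b[pos], log(x$data$signal[pos]),
                 xlab = "b (s/mm2)", ylab = "ln S", ...)
  if (x$valid) {
    bb <- seq(min(b), max(b), length.out = 200)
    graphics::lines(bb, log(predict(x, b = bb)))
  }
  invisible(x)
}

#' @export
plot.adc_fit <- plot.dki_fit
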