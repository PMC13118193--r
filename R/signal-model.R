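#' Multi-b-value acquisition scheme
#'
#' Describes the diffusion weighting of a multi-b DWI acquisition: the ordered
#' set of b-values and the number of signal averages per b-value. The default
#' is the six-b prostate protocol used throughout this package
#' (b = 0, 100, 500, 800, 1200, 2000 s/mm2 with five signal averages).
#'
#' @param bvalues numeric vector of b-values in s/mm2; must contain 0, be
#'   strictly increasing and non-negative.
#' @param n_averages number of signal averages per b-value (>= 1). Averaging
#'   reduces the effective noise standard deviation by \code{sqrt(n_averages)}.
#' @return An object of class \code{bvalue_scheme}.
#' @examples
#' sch <- bvalue_scheme()
#' sch$bvalues
#' @export
bvalue_scheme <- function(bvalues = c(0, 100, 500, 800, 1200, 2000),
                          n_averages = 5) {
  bvalues <- as.numeric(bvalues)
  if (length(bvalues) < 1 || anyNA(bvalues) || any(bvalues < 0))
    stopf("b-values must be non-negative and non-missing")
  if (!any(bvalues == 0))
    stopf("scheme must contain b = 0")
  if (is.unsorted(bvalues, strictly = TRUE))
    stopf("b-values must be strictly increasing")
  if (!is_count(n_averages))
    stopf("n_averages must be a positive integer")
  structure(list(bvalues = bvalues, n_averages = as.integer(n_averages)),
            class = "bvalue_scheme")
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("b-value scheme:", paste(x$bvalues, collapse = ", "), "s/mm2",
      sprintf("(%d signal averages)\n", x$n_averages))
  invisible(x)
}

#' Read / write FSL-style bval sidecar files
#'
#' A bval sidecar is a plain-text file whose first line holds one
#' whitespace-separated b-value per diffusion volume.
#'
#' @param path file path.
#' @param scheme a \code{\link{bvalue_scheme}} (for writing).
#' @return \code{read_bval} returns a numeric vector of b-values;
#'   \code{write_bval} returns \code{path} invisibly.
#' @export
read_bval <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  vals <- as.numeric(strsplit(trimws(line), "\\s+")[[1]])
  if (anyNA(vals)) stopf("could not parse b-values from %s", path)
  vals
}

#' @rdname read_bval
#' @export
write_bval <- function(scheme, path) {
  b <- if (inherits(scheme, "bvalue_scheme")) scheme$bvalues else as.numeric(scheme)
  writeLines(paste(format(b, trim = TRUE, scientific = FALSE), collapse = " "), path)
  invisible(path)
}

check_sig_params <- function(S0, b) {
  if (any(!is.finite(S0)) || any(S0 <= 0)) stopf("S0 must be positive")
  if (any(!is.finite(b)) || any(b < 0)) stopf("b-values must be non-negative")
}

#' Diffusion-kurtosis signal model
#'
#' Forward model for the orientation-averaged diffusion-kurtosis representation
#' \deqn{S(b) = S_0 \exp(-b D_{app} + b^2 D_{app}^2 K / 6)}
#' which reduces to the monoexponential model when \eqn{K = 0}. Diffusivities
#' are given on the conventional 1e-3 mm2/s scale and converted to mm2/s inside
#' the exponent, so that \code{b} is supplied directly in s/mm2.
#'
#' @param b b-value(s) in s/mm2, non-negative.
#' @param S0 signal at b = 0 (arbitrary units, > 0).
#' @param Dapp apparent diffusivity corrected for non-Gaussian behaviour,
#'   in 1e-3 mm2/s (> 0).
#' @param K apparent (excess) kurtosis, dimensionless (>= 0).
#' @return Signal value(s), same length as \code{b}.
#' @examples
#' dki_signal(800, S0 = 1, Dapp = 1.0, K = 0)    # exp(-0.8)
#' dki_signal(2000, S0 = 1, Dapp = 1.0, K = 1.0) # exp(-2 + 2/3)
#' @seealso \code{\link{me_signal}}, \code{\link{dki_fit}}
#' @export
dki_signal <- function(b, S0, Dapp, K) {
  check_sig_params(S0, b)
  if (any(!is.finite(Dapp)) || any(Dapp <= 0)) stopf("Dapp must be positive")
  if (any(!is.finite(K)) || any(K < 0)) stopf("K must be non-negative")
  d <- Dapp * 1e-3
  S0 * exp(-b * d + b^2 * d^2 * K / 6)
}

#' Monoexponential (ADC) signal model
#'
#' Standard Gaussian-diffusion decay \eqn{S(b) = S_0 \exp(-b \cdot ADC)} with
#' the ADC on the 1e-3 mm2/s scale.
#'
#' @inheritParams dki_signal
#' @param ADC apparent diffusion coefficient in 1e-3 mm2/s (>= 0).
#' @return Signal value(s), same length as \code{b}.
#' @examples
#' me_signal(800, S0 = 1, ADC = 0.891)
#' @export
me_signal <- function(b, S0, ADC) {
  check_sig_params(S0, b)
  if (any(!is.finite(ADC)) || any(ADC < 0)) stopf("ADC must be non-negative")
  S0 * exp(-b * ADC * 1e-3)
}

#' Evaluate a forward model over a whole acquisition scheme
#'
#' Convenience wrapper producing one signal value per b-value of a scheme,
#' under either the kurtosis or the monoexponential model. The log of a
#' kurtosis-model curve is exactly quadratic in b.
#'
#' @param scheme a \code{\link{bvalue_scheme}}.
#' @param S0,Dapp,K,ADC model parameters; supply \code{Dapp}/\code{K} for the
#'   kurtosis model or \code{ADC} for the monoexponential model.
#' @return A data.frame with columns \code{b} and \code{signal}.
#' @export
signal_curve <- function(scheme, S0 = 1, Dapp = NULL, K = NULL, ADC = NULL) {
  if (!inherits(scheme, "bvalue_scheme")) stopf("scheme must be a bvalue_scheme")
  b <- scheme$bvalues
  values <- if (!is.null(ADC)) {
    if (!is.null(Dapp) || !is.null(K)) stopf("supply either ADC or (Dapp, K), not both")
    me_signal(b, S0, ADC)
  } else {
    if (is.null(Dapp) || is.null(K)) stopf("supply either ADC or both Dapp and K")
    dki_signal(b, S0, Dapp, K)
  }
  data.frame(b = b, signal = values)
}
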