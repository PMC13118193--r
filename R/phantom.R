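# Synthetic multi-b DWI phantoms with known ground truth and Rician noise.

#' Specify an ellipsoidal lesion inside a phantom
#'
#' @param center voxel coordinates (x, y, z) of the lesion centre (1-based,
#'   may be fractional).
#' @param radii ellipsoid semi-axes in voxels (>= 1).
#' @param Dapp,K,S0 kurtosis-model parameters of the lesion tissue
#'   (\code{Dapp} in 1e-3 mm2/s).
#' @return A list of class \code{lesion_spec}.
#' @export
lesion_spec <- function(center, radii, Dapp, K, S0 = 1000) {
  if (length(center) != 3 || length(radii) != 3) stopf("center and radii must have length 3")
  if (any(radii < 1)) stopf("lesion radii must be at least 1 voxel")
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 Dapp = Dapp, K = K, S0 = S0), class = "lesion_spec")
}

#' Specify a DWI phantom
#'
#' Defines a rectangular lattice of background tissue containing ellipsoidal
#' lesions, each with its own kurtosis-model parameters, to be imaged under a
#' multi-b scheme at a given signal-to-noise ratio. Defaults emulate benign
#' peripheral-zone prostate tissue (high diffusivity, low kurtosis) containing
#' one tumour-like lesion with the low-Dapp / high-K profile typical of
#' clinically significant cancer.
#'
#' @param shape lattice extents in voxels.
#' @param spacing voxel size in mm.
#' @param background list with \code{S0}, \code{Dapp}, \code{K} for
#'   background tissue.
#' @param lesions list of \code{\link{lesion_spec}} objects.
#' @param snr ratio of voxel S0 to the per-measurement complex-channel noise
#'   SD; \code{Inf} disables noise. The effective magnitude-image noise is
#'   further reduced by \code{sqrt(n_averages)} of the scheme.
#' @param scheme a \code{\link{bvalue_scheme}}.
#' @return A list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(24, 24, 6),
                         spacing = c(2.2, 2.2, 3.5),
                         background = list(S0 = 1000, Dapp = 1.8, K = 0.6),
                         lesions = list(lesion_spec(center = c(12, 12, 3.5),
                                                    radii = c(5, 5, 2),
                                                    Dapp = 0.914, K = 1.311)),
                         snr = 50,
                         scheme = bvalue_scheme()) {
  if (length(shape) != 3 || any(shape < 1)) stopf("shape must be three positive extents")
  if (!is.numeric(snr) || length(snr) != 1 || snr <= 0) stopf("snr must be positive")
  for (l in lesions) {
    if (!inherits(l, "lesion_spec")) stopf("lesions must be lesion_spec objects")
    if (any(l$center - l$radii < 0.5) || any(l$center + l$radii > shape + 0.5))
      stopf("lesion extends outside the phantom grid")
  }
  structure(list(shape = as.integer(shape), spacing = spacing,
                 background = background, lesions = lesions,
                 snr = snr, scheme = scheme), class = "phantom_spec")
}

ellipsoid_mask <- function(shape, center, radii) {
  x <- (seq_len(shape[1]) - center[1]) / radii[1]
  y <- (seq_len(shape[2]) - center[2]) / radii[2]
  z <- (seq_len(shape[3]) - center[3]) / radii[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Simulate a multi-b DWI phantom
#'
#' Builds the ground-truth parameter fields from a \code{\link{phantom_spec}},
#' evaluates the kurtosis forward model at every voxel and b-value, and adds
#' Rician noise: the noiseless signal is perturbed in two Gaussian quadrature
#' channels of SD \code{S0 / (snr * sqrt(n_averages))} and the magnitude is
#' taken, as in averaged magnitude MRI. ROI masks are returned per lesion,
#' eroded by one voxel (semi-axes reduced by 1) to emulate margin-avoiding ROI
#' placement. The same seed always reproduces the identical volume.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param seed integer RNG seed (or \code{NULL} to use the current stream).
#' @return List with \code{volume} (a \code{\link{volume_set}}), \code{truth}
#'   (list of \code{S0}, \code{Dapp}, \code{K} ground-truth maps, valid
#'   everywhere), and \code{rois} (list of \code{\link{roi_mask}}).
#' @examples
#' ph <- generate_phantom(phantom_spec(snr = Inf))
#' maps <- fit_maps(ph$volume)
#' extract_roi_stats(maps$K, ph$rois[[1]])$mean
#' @export
generate_phantom <- function(spec, seed = NULL) {
  if (!inherits(spec, "phantom_spec")) stopf("spec must be a phantom_spec")
  shape <- spec$shape
  s0 <- array(spec$background$S0, shape)
  dapp <- array(spec$background$Dapp, shape)
  k <- array(spec$background$K, shape)
  rois <- list()
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    inside <- ellipsoid_mask(shape, l$center, l$radii)
    s0[inside] <- l$S0
    dapp[inside] <- l$Dapp
    k[inside] <- l$K
    core <- ellipsoid_mask(shape, l$center, pmax(l$radii - 1, 1))
    rois[[i]] <- roi_mask(which(core, arr.ind = TRUE), label = i)
  }
  if (length(rois)) names(rois) <- paste0("lesion_", seq_along(rois))

  b <- spec$scheme$bvalues
  nv <- prod(shape)
  sig <- matrix(0, nv, length(b))
  d <- as.vector(dapp) * 1e-3
  for (j in seq_along(b))
    sig[, j] <- as.vector(s0) * exp(-b[j] * d + b[j]^2 * d^2 * as.vector(k) / 6)

  if (is.finite(spec$snr)) {
    sigma <- as.vector(s0) / (spec$snr * sqrt(spec$scheme$n_averages))
    sig <- local_seed(seed, {
      n <- length(sig)
      sqrt((sig + sigma * stats::rnorm(n))^2 + (sigma * stats::rnorm(n))^2)
    })
  }

  truth_valid <- array(TRUE, shape)
  list(
    volume = volume_set(array(sig, c(shape, length(b))), spec$scheme, spec$spacing),
    truth = list(S0 = parameter_map("S0", s0, truth_valid),
                 Dapp = parameter_map("Dapp", dapp, truth_valid),
                 K = parameter_map("K", k, truth_valid)),
    rois = rois
  )
}
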