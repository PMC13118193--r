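# Voxelwise map fitting and ROI extraction for 4-D multi-b DWI volumes.

#' Multi-b DWI volume container
#'
#' Bundles a 4-D signal lattice (x, y, z, b-index) with its acquisition scheme
#' and voxel spacing. Parameter maps produced from it share the 3-D lattice.
#'
#' @param data 4-D numeric array; 4th extent must equal the number of b-values.
#' @param scheme a \code{\link{bvalue_scheme}}.
#' @param spacing voxel size in mm along x, y, z (all > 0).
#' @return An object of class \code{volume_set}.
#' @export
volume_set <- function(data, scheme, spacing = c(2.2, 2.2, 3.5)) {
  if (!inherits(scheme, "bvalue_scheme")) stopf("scheme must be a bvalue_scheme")
  if (length(dim(data)) != 4L) stopf("data must be a 4-D array")
  if (dim(data)[4] != length(scheme$bvalues))
    stopf("4th extent (%d) must equal the number of b-values (%d)",
          dim(data)[4], length(scheme$bvalues))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be three positive values (mm)")
  structure(list(data = data, scheme = scheme, spacing = spacing),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume set: %d x %d x %d voxels, %d b-values; spacing %s mm\n",
              d[1], d[2], d[3], d[4], paste(x$spacing, collapse = " x ")))
  print(x$scheme)
  invisible(x)
}

parameter_map <- function(name, data, valid) {
  structure(list(name = name, data = data, valid = valid),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("%s map: %s voxels, %d valid (%.1f%%)\n", x$name,
              paste(dim(x$data), collapse = " x "), sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Fit ADC and kurtosis parameter maps voxel by voxel
#'
#' Applies \code{\link{adc_fit}} (monoexponential, b-values up to
#' \code{b_max_adc}) and \code{\link{dki_fit}} (kurtosis model, all b-values)
#' independently at every voxel of a \code{\link{volume_set}}, assembling
#' \code{ADC}, \code{Dapp}, \code{K} and \code{S0} maps plus per-map validity
#' masks. Voxels where a fit fails (non-decaying signal, too few usable
#' points) are flagged invalid, never silently zeroed, and a failing voxel
#' never aborts the volume. Voxels whose signals are all positive are fitted
#' in a single vectorised least-squares solve; the remainder fall back to the
#' per-voxel path that excludes non-positive signals.
#'
#' @param vol a \code{\link{volume_set}}.
#' @param b_max_adc largest b-value used by the monoexponential fit (s/mm2).
#' @param dapp_max,k_max constraint bounds passed to the kurtosis fit.
#' @return A list of class \code{parameter_maps} with elements \code{ADC},
#'   \code{Dapp}, \code{K}, \code{S0} (each a \code{parameter_map}) and
#'   \code{n_dropped}, a 3-D array counting excluded non-positive signals per
#'   voxel.
#' @examples
#' sch <- bvalue_scheme()
#' sig <- dki_signal(sch$bvalues, S0 = 100, Dapp = 1.1, K = 1.0)
#' vol <- volume_set(array(rep(sig, each = 8), c(2, 2, 2, 6)), sch)
#' maps <- fit_maps(vol)
#' maps$K$data[1, 1, 1]
#' @export
fit_maps <- function(vol, b_max_adc = 1200, dapp_max = 4, k_max = 3) {
  if (!inherits(vol, "volume_set")) stopf("vol must be a volume_set")
  dims <- dim(vol$data)
  nb <- dims[4]
  nv <- prod(dims[1:3])
  M <- matrix(vol$data, nv, nb)
  b <- vol$scheme$bvalues
  ok <- is.finite(M) & M > 0

  dapp <- k <- s0 <- adc <- rep(NA_real_, nv)
  dki_valid <- adc_valid <- rep(FALSE, nv)

  # --- kurtosis model over all b ---
  full <- rowSums(ok) == nb
  if (any(full)) {
    cf <- qr.coef(qr(cbind(1, b, b * b)), t(log(M[full, , drop = FALSE])))
    c0 <- cf[1, ]; c1 <- cf[2, ]; c2 <- cf[3, ]
    v <- is.finite(c1) & c1 < 0
    idx <- which(full)[v]
    dki_valid[idx] <- TRUE
    dapp[idx] <- pmin(-c1[v] * 1e3, dapp_max)
    k[idx] <- pmin(pmax(6 * c2[v] / c1[v]^2, 0), k_max)
    s0[idx] <- exp(c0[v])
  }
  for (i in which(!full & rowSums(ok) >= 3)) {
    f <- dki_fit(M[i, ], b, dapp_max = dapp_max, k_max = k_max)
    if (f$valid) {
      dki_valid[i] <- TRUE
      s0[i] <- f$coefficients[["S0"]]
      dapp[i] <- f$coefficients[["Dapp"]]
      k[i] <- f$coefficients[["K"]]
    }
  }

  # --- monoexponential over b <= b_max_adc ---
  sub <- which(b <= b_max_adc)
  ok_me <- ok[, sub, drop = FALSE]
  full_me <- rowSums(ok_me) == length(sub)
  if (any(full_me)) {
    bm <- b[sub]
    cf <- qr.coef(qr(cbind(1, bm)), t(log(M[full_me, sub, drop = FALSE])))
    v <- is.finite(cf[2, ])
    idx <- which(full_me)[v]
    adc_valid[idx] <- TRUE
    adc[idx] <- pmax(-cf[2, v] * 1e3, 0)
  }
  for (i in which(!full_me & rowSums(ok_me) >= 2)) {
    f <- adc_fit(M[i, ], b, b_max = b_max_adc)
    if (f$valid) {
      adc_valid[i] <- TRUE
      adc[i] <- f$coefficients[["ADC"]]
    }
  }

  shape <- dims[1:3]
  as3d <- function(x) array(x, shape)
  structure(list(
    ADC  = parameter_map("ADC",  as3d(adc),  as3d(adc_valid)),
    Dapp = parameter_map("Dapp", as3d(dapp), as3d(dki_valid)),
    K    = parameter_map("K",    as3d(k),    as3d(dki_valid)),
    S0   = parameter_map("S0",   as3d(s0),   as3d(dki_valid)),
    n_dropped = as3d(nb - rowSums(ok))
  ), class = "parameter_maps")
}

#' Region-of-interest mask
#'
#' A set of voxel indices (1-based, rows of an n x 3 integer matrix) with a
#' lesion label and an optional prostate zone.
#'
#' @param voxels integer matrix with one row per voxel and columns x, y, z.
#' @param label lesion identifier.
#' @param zone \code{"peripheral"}, \code{"transition"} or \code{NA}.
#' @return An object of class \code{roi_mask}.
#' @export
roi_mask <- function(voxels, label = 1L, zone = NA_character_) {
  voxels <- as.matrix(voxels)
  if (nrow(voxels) < 1 || ncol(voxels) != 3) stopf("voxels must be a non-empty n x 3 matrix")
  if (any(voxels < 1) || any(voxels != round(voxels))) stopf("voxel indices must be positive integers")
  structure(list(voxels = voxels, label = label, zone = zone), class = "roi_mask")
}

#' Split a label volume into ROI masks
#'
#' @param labels 3-D integer array; 0 is background, each positive value one ROI.
#' @return Named list of \code{\link{roi_mask}} objects.
#' @export
rois_from_labels <- function(labels) {
  labs <- sort(unique(labels[labels > 0]))
  if (length(labs) == 0) stopf("label volume contains no foreground voxels")
  out <- lapply(labs, function(l) roi_mask(which(labels == l, arr.ind = TRUE), label = l))
  names(out) <- paste0("lesion_", labs)
  out
}

roi_linear_index <- function(roi, shape) {
  v <- roi$voxels
  if (any(v[, 1] > shape[1] | v[, 2] > shape[2] | v[, 3] > shape[3]))
    stopf("ROI '%s' has voxels outside the lattice", roi$label)
  v[, 1] + (v[, 2] - 1L) * shape[1] + (v[, 3] - 1L) * shape[1] * shape[2]
}

#' ROI summary statistics from a parameter map
#'
#' Arithmetic mean (with SD and count) of map values over the valid voxels of
#' an ROI. Invalid voxels are excluded and reduce \code{n}; an ROI with no
#' valid voxel is an error.
#'
#' @param map a \code{parameter_map} (element of \code{\link{fit_maps}} output).
#' @param roi a \code{\link{roi_mask}}.
#' @return List with \code{mean}, \code{sd}, \code{n} (valid voxels used) and
#'   \code{n_total} (ROI size).
#' @export
extract_roi_stats <- function(map, roi) {
  if (!inherits(map, "parameter_map")) stopf("map must be a parameter_map")
  if (!inherits(roi, "roi_mask")) stopf("roi must be an roi_mask")
  lin <- roi_linear_index(roi, dim(map$data))
  vals <- map$data[lin][map$valid[lin]]
  if (length(vals) == 0) stopf("ROI '%s' contains no valid voxels in the %s map",
                               roi$label, map$name)
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals),
       n_total = length(lin))
}

#' Tabulate ROI means across parameter maps
#'
#' Builds a long-format table (lesion_id, parameter, mean, sd, n_voxels) over
#' a set of ROIs and the \code{ADC}, \code{Dapp} and \code{K} maps (plus any
#' other maps present). The same voxel set -- voxels valid in every map -- is
#' used for all parameters of a lesion, mirroring ROI propagation across maps.
#'
#' @param maps a \code{parameter_maps} object from \code{\link{fit_maps}}.
#' @param rois list of \code{\link{roi_mask}} objects.
#' @param parameters which maps to tabulate.
#' @return A data.frame with one row per lesion x parameter.
#' @export
roi_stats_table <- function(maps, rois, parameters = c("ADC", "Dapp", "K")) {
  if (!inherits(maps, "parameter_maps")) stopf("maps must come from fit_maps()")
  if (inherits(rois, "roi_mask")) rois <- list(rois)
  rows <- lapply(rois, function(roi) {
    shape <- dim(maps[[parameters[1]]]$data)
    lin <- roi_linear_index(roi, shape)
    common <- Reduce(`&`, lapply(parameters, function(p) maps[[p]]$valid[lin]))
    if (!any(common)) stopf("ROI '%s' contains no voxel valid in all maps", roi$label)
    do.call(rbind, lapply(parameters, function(p) {
      vals <- maps[[p]]$data[lin][common]
      data.frame(lesion_id = roi$label, parameter = p, mean = mean(vals),
                 sd = stats::sd(vals), n_voxels = length(vals))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- NIfTI I/O -------------------------------------------------------------

nifti_with_spacing <- function(data, spacing) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- if (length(dim(data)) == 4L) c(spacing, 1) else spacing
  img
}

#' Read a 4-D DWI volume with its bval sidecar
#'
#' @param nii_path path to a 4-D NIfTI-1 image.
#' @param bval_path path to the FSL-style bval sidecar (one whitespace-
#'   separated line, one entry per diffusion volume).
#' @param n_averages signal averages per b-value (metadata not carried by the
#'   bval format).
#' @return A \code{\link{volume_set}}.
#' @export
read_dwi <- function(nii_path, bval_path, n_averages = 1) {
  img <- RNifti::readNifti(nii_path)
  b <- read_bval(bval_path)
  volume_set(array(as.numeric(img), dim(img)),
             bvalue_scheme(b, n_averages = n_averages),
             spacing = RNifti::pixdim(img)[1:3])
}

#' Write a DWI volume set as NIfTI plus bval sidecar
#'
#' @param vol a \code{\link{volume_set}}.
#' @param nii_path,bval_path output paths.
#' @return \code{nii_path}, invisibly.
#' @export
write_dwi <- function(vol, nii_path, bval_path) {
  RNifti::writeNifti(nifti_with_spacing(vol$data, vol$spacing), nii_path)
  write_bval(vol$scheme, bval_path)
  invisible(nii_path)
}

#' Write parameter maps (and a combined validity mask) as NIfTI
#'
#' Each map is written float-valued with invalid voxels set to NA-equivalent
#' zero in the mask file; \code{valid.nii.gz} holds the conjunction of the
#' ADC and kurtosis validity masks.
#'
#' @param maps output of \code{\link{fit_maps}}.
#' @param dir output directory (created if needed).
#' @param spacing voxel spacing in mm.
#' @return Character vector of files written, invisibly.
#' @export
write_maps <- function(maps, dir, spacing = c(2.2, 2.2, 3.5)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (p in c("ADC", "Dapp", "K", "S0")) {
    f <- file.path(dir, paste0(tolower(p), ".nii.gz"))
    dat <- maps[[p]]$data
    dat[!maps[[p]]$valid] <- 0
    RNifti::writeNifti(nifti_with_spacing(dat, spacing), f, datatype = "float")
    files <- c(files, f)
  }
  valid <- maps$ADC$valid & maps$Dapp$valid
  f <- file.path(dir, "valid.nii.gz")
  RNifti::writeNifti(nifti_with_spacing(array(as.integer(valid), dim(valid)),
                                        spacing), f, datatype = "uint8")
  invisible(c(files, f))
}

#' Read ROI masks from a NIfTI label volume
#'
#' @param path NIfTI integer label volume (0 = background).
#' @return Named list of \code{\link{roi_mask}} objects.
#' @export
read_roi_masks <- function(path) {
  img <- RNifti::readNifti(path)
  rois_from_labels(array(as.integer(round(as.numeric(img))), dim(img)))
}
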