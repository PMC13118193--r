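# Single-predictor diagnostic performance: empirical ROC, Mann-Whitney AUC,
# Youden operating point, and repeated cross-validated logistic regression.

#' Direction in which each lesion-level predictor marks upgrading
#'
#' Kurtosis, PSA and PSA density rise with tumour aggressiveness
#' (higher-positive); diffusivities fall (lower-positive). Fixing the
#' orientation a priori avoids artificially forcing AUC >= 0.5.
#'
#' @return Named character vector, values "higher" or "lower".
#' @export
predictor_orientation <- function() {
  c(K = "higher", D = "lower", ADC = "lower", PSA = "higher", PSAD = "higher")
}

check_labels <- function(labels) {
  labels <- as.integer(as.logical(labels))
  if (anyNA(labels)) stopf("labels must be logical or 0/1")
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  labels
}

oriented <- function(scores, orientation) {
  if (orientation == "lower") -scores else scores
}

#' Empirical ROC curve
#'
#' Standard empirical ROC with tied scores grouped into single operating
#' points; starts at (0, 0) and ends at (1, 1). The trapezoid area equals the
#' normalized Mann-Whitney U statistic exactly.
#'
#' @param scores numeric predictor values.
#' @param labels event indicator (logical or 0/1; 1 = positive class).
#' @param orientation \code{"higher"} if larger scores indicate the positive
#'   class, \code{"lower"} otherwise.
#' @return A data.frame of class \code{roc_points} with columns \code{fpr},
#'   \code{tpr} and attribute \code{auc} (trapezoid area).
#' @examples
#' r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' attr(r, "auc")  # 0.75
#' @export
roc_curve <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  s <- oriented(scores, orientation)
  ord <- order(s, decreasing = TRUE)
  ss <- s[ord]; ll <- labels[ord]
  grp_end <- cumsum(rle(ss)$lengths)
  n_pos <- sum(ll == 1); n_neg <- sum(ll == 0)
  tpr <- c(0, cumsum(ll == 1)[grp_end] / n_pos)
  fpr <- c(0, cumsum(ll == 0)[grp_end] / n_neg)
  out <- data.frame(fpr = fpr, tpr = tpr)
  attr(out, "auc") <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  class(out) <- c("roc_points", "data.frame")
  out
}

#' @export
plot.roc_points <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Mann-Whitney (rank) AUC
#'
#' AUC computed as the normalized Mann-Whitney U statistic (probability that
#' a random positive outranks a random negative, ties counting one half);
#' identical to the trapezoid area under \code{\link{roc_curve}}.
#'
#' @inheritParams roc_curve
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  labels <- check_labels(labels)
  s <- oriented(scores, orientation)
  r <- rank(s)
  n_pos <- as.numeric(sum(labels == 1)); n_neg <- as.numeric(sum(labels == 0))
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-index operating point
#'
#' Finds the cut-off maximizing J = sensitivity + specificity - 1 over all
#' midpoints between adjacent distinct score values. If several thresholds
#' attain the maximal J, the one with the higher specificity is chosen (and
#' among those, deterministically the most conservative, i.e. the one
#' classifying fewest lesions as positive). The threshold is reported in raw
#' predictor units; under \code{orientation = "lower"} a lesion is called
#' positive when its value falls below the threshold.
#'
#' @inheritParams roc_curve
#' @return List with \code{threshold}, \code{sensitivity}, \code{specificity},
#'   \code{J} and \code{degenerate} (TRUE when all scores are identical, in
#'   which case J = 0 and the threshold is undefined).
#' @examples
#' youden_threshold(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0), "lower")
#' @export
youden_threshold <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  labels <- check_labels(labels)
  s <- oriented(scores, orientation)
  if (length(unique(s)) == 1)
    return(list(threshold = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_, J = 0, degenerate = TRUE))
  o <- order(s)
  ss <- s[o]; ll <- labels[o]
  n_pos <- sum(ll == 1); n_neg <- sum(ll == 0)
  cum_pos <- cumsum(ll == 1); cum_neg <- cumsum(ll == 0)
  cut <- which(diff(ss) > 0)             # positive called when s > threshold
  sens <- (n_pos - cum_pos[cut]) / n_pos
  spec <- cum_neg[cut] / n_neg
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[spec[best] >= max(spec[best]) - 1e-12]
  i <- best[length(best)]                # most conservative of the remaining
  thr <- (ss[cut[i]] + ss[cut[i] + 1]) / 2
  list(threshold = if (orientation == "lower") -thr else thr,
       sensitivity = sens[i], specificity = spec[i], J = J[i],
       degenerate = FALSE)
}

#' Closed-form AUC of two normal populations
#'
#' For arms Normal(mu0, sd0) (negatives) and Normal(mu1, sd1) (positives) with
#' a known orientation, the population ROC AUC is
#' Phi(|mu1 - mu0| / sqrt(sd0^2 + sd1^2)) when the means are ordered
#' consistently with the orientation.
#'
#' @param mu0,sd0 moments of the negative arm.
#' @param mu1,sd1 moments of the positive arm.
#' @param orientation as in \code{\link{roc_curve}}.
#' @return Population AUC.
#' @export
binormal_auc <- function(mu0, sd0, mu1, sd1, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  delta <- if (orientation == "lower") mu0 - mu1 else mu1 - mu0
  stats::pnorm(delta / sqrt(sd0^2 + sd1^2))
}

stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

#' Cross-validated single-predictor logistic ROC analysis
#'
#' Evaluates one lesion-level predictor of Grade Group upgrading within a
#' biopsy-GG stratum by logistic regression with repeated stratified k-fold
#' cross-validation (5 repeats of 5-fold by default). Within each repeat the
#' out-of-fold predicted probabilities are pooled into one ROC; the reported
#' cross-validated AUC is the mean over repeats. The 95% CI is computed by
#' the DeLong method on each lesion's out-of-fold score averaged across
#' repeats; the full-sample empirical AUC of the raw predictor is also
#' reported (for a single monotone predictor the two agree closely). The
#' operating point is the Youden-optimal threshold of the raw predictor on
#' the full sample, in predictor units.
#'
#' @param records lesion-record data.frame (see \code{\link{generate_cohort}}).
#' @param stratum biopsy Grade Group to analyse.
#' @param predictor one of \code{"K"}, \code{"D"}, \code{"ADC"}, \code{"PSA"},
#'   \code{"PSAD"}.
#' @param folds,repeats cross-validation layout; folds are reduced (with a
#'   warning) if the smaller class cannot populate them.
#' @param seed integer seed making the fold assignment reproducible.
#' @param orientation predictor direction; defaults to the per-predictor
#'   convention of \code{\link{predictor_orientation}}.
#' @return An object of class \code{roc_result}: predictor, stratum,
#'   orientation, \code{auc} (cross-validated mean), \code{auc_full}
#'   (raw-predictor empirical AUC), \code{ci_lo}/\code{ci_hi},
#'   \code{threshold}, \code{sensitivity}, \code{specificity}, \code{J},
#'   per-repeat AUCs, class sizes and CV layout.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' cv_logistic_roc(coh, stratum = 2, predictor = "ADC", seed = 1)
#' @export
cv_logistic_roc <- function(records, stratum, predictor, folds = 5, repeats = 5,
                            seed = NULL, orientation = NULL) {
  if (!predictor %in% names(var_column)) stopf("unknown predictor '%s'", predictor)
  if (is.null(orientation)) orientation <- predictor_orientation()[[predictor]]
  col <- var_column[[predictor]]
  sel <- records$biopsy_gg == stratum & is.finite(records[[col]])
  x <- records[[col]][sel]
  y <- check_labels(records$upgrade[sel])
  n_min <- min(sum(y == 1), sum(y == 0))
  if (n_min < folds) {
    folds <- max(2L, n_min)
    warning(sprintf("reducing to %d folds: smaller class has %d lesions",
                    folds, n_min), call. = FALSE)
  }
  local_seed(seed, {
    rep_auc <- numeric(repeats)
    oof_sum <- numeric(length(y))
    for (r in seq_len(repeats)) {
      f <- stratified_folds(y, folds)
      oof <- numeric(length(y))
      for (k in seq_len(folds)) {
        train <- f != k
        fit <- suppressWarnings(
          stats::glm(y ~ x, family = stats::binomial(), subset = train))
        oof[!train] <- suppressWarnings(
          stats::predict(fit, newdata = data.frame(x = x[!train]),
                         type = "response"))
      }
      rep_auc[r] <- auc_mw(oof, y, "higher")
      oof_sum <- oof_sum + oof
    }
    mean_oof <- oof_sum / repeats
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(
      pROC::roc(response = y, predictor = mean_oof, levels = c(0, 1),
                direction = "<", quiet = TRUE), method = "delong")))
    yj <- youden_threshold(x, y, orientation)
    structure(list(predictor = predictor, stratum = stratum,
                   orientation = orientation,
                   auc = mean(rep_auc), auc_full = auc_mw(x, y, orientation),
                   ci_lo = ci[1], ci_hi = ci[3],
                   threshold = yj$threshold, sensitivity = yj$sensitivity,
                   specificity = yj$specificity, J = yj$J,
                   per_repeat_auc = rep_auc, folds = folds, repeats = repeats,
                   n_pos = sum(y == 1), n_neg = sum(y == 0)),
              class = "roc_result")
  })
}

#' @export
print.roc_result <- function(x, digits = 3, ...) {
  cat(sprintf("ROC analysis of %s (GG%s stratum, %s-positive), %d upgrade / %d no-upgrade\n",
              x$predictor, x$stratum, x$orientation, x$n_pos, x$n_neg))
  cat(sprintf("  cross-validated AUC (%d x %d-fold): %.*f  [95%% CI %.*f - %.*f]\n",
              x$repeats, x$folds, digits, x$auc, digits, x$ci_lo, digits, x$ci_hi))
  cat(sprintf("  full-sample AUC: %.*f\n", digits, x$auc_full))
  cat(sprintf("  Youden threshold %.*g: sensitivity %.*f, specificity %.*f\n",
              digits, x$threshold, digits, x$sensitivity, digits, x$specificity))
  invisible(x)
}

#' Per-stratum diagnostic performance table
#'
#' Runs \code{\link{cv_logistic_roc}} for each predictor within one stratum
#' and assembles a table with the columns threshold, AUC, CI bounds,
#' sensitivity and specificity.
#'
#' @inheritParams cv_logistic_roc
#' @param predictors predictors to evaluate.
#' @return A data.frame, one row per predictor.
#' @export
roc_table <- function(records, stratum,
                      predictors = c("K", "D", "ADC", "PSA", "PSAD"),
                      folds = 5, repeats = 5, seed = NULL) {
  rows <- lapply(predictors, function(p) {
    r <- cv_logistic_roc(records, stratum, p, folds = folds, repeats = repeats,
                         seed = seed)
    data.frame(predictor = p, threshold = r$threshold, auc = r$auc,
               ci_lo = r$ci_lo, ci_up = r$ci_hi, sens = r$sensitivity,
               spec = r$specificity, auc_full = r$auc_full,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
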