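# Per-stratum comparison of upgrade vs no-upgrade arms: test selection,
# effect size and Holm step-down adjustment.

#' Holm step-down adjustment of a family of p-values
#'
#' Classical Holm correction: the i-th smallest p-value is multiplied by
#' (m - i + 1), monotonicity is enforced along the sorted order and results
#' are capped at 1, returned in the original order. Delegates to
#' \code{stats::p.adjust(method = "holm")}.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.001, 0.063, 0.044, 0.35, 0.21))
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

pooled_sd <- function(s_a, n_a, s_b, n_b) {
  sqrt(((n_a - 1) * s_a^2 + (n_b - 1) * s_b^2) / (n_a + n_b - 2))
}

#' Cohen's d effect size (pooled-SD form)
#'
#' \code{cohens_d} works from the two samples, \code{cohens_d_stats} from
#' summary statistics. The sign convention is first argument minus second:
#' called with the upgrade arm first, positive d means higher values in
#' upgraded lesions.
#'
#' @param x,y numeric samples (first minus second in the numerator).
#' @return Signed effect size d.
#' @examples
#' cohens_d_stats(1.262, 0.146, 20, 1.086, 0.089, 7)  # about 1.31
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  cohens_d_stats(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' @rdname cohens_d
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b summary statistics of the two arms.
#' @export
cohens_d_stats <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stopf("Cohen's d requires at least 2 observations per arm")
  sp <- pooled_sd(sd_a, n_a, sd_b, n_b)
  if (!is.finite(sp) || sp == 0) stopf("pooled SD is zero; effect size undefined")
  (mean_a - mean_b) / sp
}

# Shapiro-Wilk normality gate at alpha; capped at the test's n = 5000 limit
# (first 5000 values used above that -- irrelevant at cohort scale).
arm_normal <- function(x, alpha) {
  if (length(x) > 5000) x <- x[1:5000]
  if (stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}

#' Compare one variable between upgrade and no-upgrade arms of a stratum
#'
#' Implements the either/or testing rule: each arm is screened for normality
#' with a Shapiro-Wilk test at \code{alpha}; if both arms pass, a two-sided
#' Welch t-test is used, otherwise a two-sided Mann-Whitney U test. The
#' effect size is the pooled-SD Cohen's d signed as upgrade minus no-upgrade.
#' Arms smaller than 3 (normality untestable) skip the test with an explicit
#' flag; arms that are jointly constant are flagged degenerate with p = 1.
#'
#' @param records lesion-record data.frame (see \code{\link{generate_cohort}}).
#' @param stratum biopsy Grade Group to analyse.
#' @param variable one of \code{"K"}, \code{"D"}, \code{"ADC"}, \code{"PSA"},
#'   \code{"PSAD"}.
#' @param alpha significance level of the normality gate.
#' @return A one-row data.frame: variable, per-arm n/mean/sd, \code{test}
#'   ("t", "mann-whitney", "skipped" or "degenerate"), \code{p},
#'   \code{cohens_d}.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' compare_groups(coh, stratum = 2, variable = "ADC")
#' @export
compare_groups <- function(records, stratum, variable, alpha = 0.05) {
  if (!variable %in% names(var_column)) stopf("unknown variable '%s'", variable)
  col <- var_column[[variable]]
  if (!col %in% names(records)) stopf("records lack column '%s'", col)
  sel <- records$biopsy_gg == stratum
  x <- records[[col]][sel & records$upgrade]     # upgrade arm
  y <- records[[col]][sel & !records$upgrade]    # no-upgrade arm
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0)
    stopf("both arms must be non-empty in stratum GG%s", stratum)
  res <- data.frame(variable = variable, stratum = stratum,
                    n_no_upgrade = length(y), mean_no_upgrade = mean(y),
                    sd_no_upgrade = stats::sd(y),
                    n_upgrade = length(x), mean_upgrade = mean(x),
                    sd_upgrade = stats::sd(x),
                    test = NA_character_, p = NA_real_,
                    cohens_d = NA_real_, stringsAsFactors = FALSE)
  if (length(x) >= 2 && length(y) >= 2 &&
      pooled_sd(stats::sd(x), length(x), stats::sd(y), length(y)) > 0)
    res$cohens_d <- cohens_d(x, y)
  if (length(x) < 3 || length(y) < 3) {
    res$test <- "skipped"
    return(res)
  }
  if (stats::sd(c(x, y)) == 0) {           # identical constant arms
    res$test <- "degenerate"
    res$p <- 1
    return(res)
  }
  if (arm_normal(x, alpha) && arm_normal(y, alpha)) {
    res$test <- "t"
    res$p <- stats::t.test(x, y)$p.value   # Welch, two-sided
  } else {
    res$test <- "mann-whitney"
    res$p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
  }
  res
}

#' Full per-stratum comparison table with Holm adjustment
#'
#' Runs \code{\link{compare_groups}} for every variable within each biopsy-GG
#' stratum and Holm-adjusts the raw p-values within the five-variable family
#' of each stratum.
#'
#' @inheritParams compare_groups
#' @param variables variables forming one Holm family per stratum.
#' @param strata biopsy Grade Groups to analyse (default: all observed).
#' @return A data.frame with one row per stratum x variable, including
#'   \code{p} and Holm-adjusted \code{p_adj}.
#' @export
comparison_table <- function(records, variables = c("K", "D", "ADC", "PSA", "PSAD"),
                             strata = sort(unique(records$biopsy_gg)),
                             alpha = 0.05) {
  out <- do.call(rbind, lapply(strata, function(g) {
    tab <- do.call(rbind, lapply(variables, function(v)
      compare_groups(records, g, v, alpha = alpha)))
    tab$p_adj <- NA_real_
    testable <- !is.na(tab$p) & tab$test != "degenerate"
    tab$p_adj[testable] <- holm_adjust(tab$p[testable])
    tab
  }))
  rownames(out) <- NULL
  out
}
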