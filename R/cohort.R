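# Lesion-level cohort simulation and upgrade bookkeeping.

#' Packaged group moments for the lesion-level cohort
#'
#' Per biopsy Grade Group (1-4) and arm (upgrade / no-upgrade), the sample
#' size, mean and SD of each of the five lesion-level variables: kurtosis K
#' (dimensionless), kurtosis-corrected diffusivity D and monoexponential ADC
#' (both 1e-3 mm2/s), PSA (ng/mL) and PSA density. These are the cohort study
#' conditions used by the default simulator; PSA/PSAD sample sizes are
#' slightly smaller than the diffusion ones in GG1/GG2 because the clinical
#' variables were not available for every lesion.
#'
#' @return A data.frame with columns \code{gg}, \code{arm}, \code{variable},
#'   \code{n}, \code{mean}, \code{sd}.
#' @export
default_group_moments <- function() {
  rows <- rbind(
    # gg, arm, variable, n, mean, sd
    c(1, "no_upgrade", "K",    7, 1.086, 0.089), c(1, "upgrade", "K",   20, 1.262, 0.146),
    c(1, "no_upgrade", "D",    7, 1.147, 0.204), c(1, "upgrade", "D",   20, 0.970, 0.101),
    c(1, "no_upgrade", "ADC",  7, 0.891, 0.134), c(1, "upgrade", "ADC", 20, 0.761, 0.095),
    c(1, "no_upgrade", "PSA",  6, 9.335, 3.995), c(1, "upgrade", "PSA", 20, 7.521, 3.658),
    c(1, "no_upgrade", "PSAD", 6, 0.282, 0.162), c(1, "upgrade", "PSAD",20, 0.185, 0.075),
    c(2, "no_upgrade", "K",   31, 1.152, 0.125), c(2, "upgrade", "K",   36, 1.311, 0.188),
    c(2, "no_upgrade", "D",   31, 1.115, 0.143), c(2, "upgrade", "D",   36, 0.914, 0.175),
    c(2, "no_upgrade", "ADC", 31, 0.862, 0.111), c(2, "upgrade", "ADC", 36, 0.712, 0.129),
    c(2, "no_upgrade", "PSA", 29, 8.703, 4.069), c(2, "upgrade", "PSA", 36, 10.216, 5.492),
    c(2, "no_upgrade", "PSAD",29, 0.255, 0.139), c(2, "upgrade", "PSAD",36, 0.284, 0.175),
    c(3, "no_upgrade", "K",   27, 1.266, 0.158), c(3, "upgrade", "K",    8, 1.342, 0.129),
    c(3, "no_upgrade", "D",   27, 0.961, 0.178), c(3, "upgrade", "D",    8, 0.913, 0.197),
    c(3, "no_upgrade", "ADC", 27, 0.753, 0.129), c(3, "upgrade", "ADC",  8, 0.698, 0.098),
    c(3, "no_upgrade", "PSA", 27, 10.384, 5.405),c(3, "upgrade", "PSA",  8, 9.862, 2.494),
    c(3, "no_upgrade", "PSAD",27, 0.289, 0.160), c(3, "upgrade", "PSAD", 8, 0.329, 0.120),
    c(4, "no_upgrade", "K",    9, 1.322, 0.211), c(4, "upgrade", "K",    4, 1.455, 0.246),
    c(4, "no_upgrade", "D",    9, 0.921, 0.223), c(4, "upgrade", "D",    4, 0.833, 0.225),
    c(4, "no_upgrade", "ADC",  9, 0.704, 0.144), c(4, "upgrade", "ADC",  4, 0.635, 0.135),
    c(4, "no_upgrade", "PSA",  9, 6.327, 2.121), c(4, "upgrade", "PSA",  4, 10.385, 5.725),
    c(4, "no_upgrade", "PSAD", 9, 0.199, 0.122), c(4, "upgrade", "PSAD", 4, 0.453, 0.265))
  data.frame(gg = as.integer(rows[, 1]), arm = rows[, 2], variable = rows[, 3],
             n = as.integer(rows[, 4]), mean = as.numeric(rows[, 5]),
             sd = as.numeric(rows[, 6]), stringsAsFactors = FALSE)
}

#' Cohort simulation specification
#'
#' Wraps a group-moments table (see \code{\link{default_group_moments}} for
#' the packaged defaults and the expected layout) after validating it.
#'
#' @param moments data.frame with columns \code{gg}, \code{arm} (one of
#'   \code{"upgrade"}, \code{"no_upgrade"}), \code{variable} (subset of K, D,
#'   ADC, PSA, PSAD), \code{n}, \code{mean}, \code{sd}.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(moments = default_group_moments()) {
  need <- c("gg", "arm", "variable", "n", "mean", "sd")
  if (!all(need %in% names(moments))) stopf("moments must have columns %s",
                                            paste(need, collapse = ", "))
  if (any(moments$n < 1)) stopf("all group sizes must be >= 1")
  if (any(moments$sd <= 0)) stopf("all SDs must be > 0")
  if (!all(moments$arm %in% c("upgrade", "no_upgrade"))) stopf("unknown arm label")
  if (!all(moments$variable %in% c("K", "D", "ADC", "PSA", "PSAD")))
    stopf("unknown variable name")
  if (anyDuplicated(moments[c("gg", "arm", "variable")]))
    stopf("duplicate (gg, arm, variable) rows")
  structure(list(moments = moments), class = "cohort_spec")
}

var_column <- c(K = "mean_k", D = "mean_d", ADC = "mean_adc",
                PSA = "psa", PSAD = "psad")

# normal draws truncated at zero by redraw (keeps the shape near-normal)
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a lesion-level cohort
#'
#' Draws one lesion record per subject from independent normal distributions
#' (truncated at zero by redraw) with the per-stratum, per-arm moments of a
#' \code{\link{cohort_spec}}. The arm size of a stratum is the largest n over
#' its variables; variables with a smaller printed n are filled for that many
#' records and left \code{NA} for the rest. The prostatectomy Grade Group is
#' assigned consistently with the arm: equal to the biopsy GG for no-upgrade
#' lesions, one tier above (capped at 5) for upgraded ones. Zone and PI-RADS
#' are drawn with the marginal frequencies of the packaged fixture.
#'
#' @param spec a \code{\link{cohort_spec}} (default: packaged moments).
#' @param seed integer RNG seed; the same seed reproduces the same cohort.
#' @return A data.frame of lesion records with columns \code{lesion_id},
#'   \code{biopsy_gg}, \code{prostatectomy_gg}, \code{upgrade},
#'   \code{mean_adc}, \code{mean_d}, \code{mean_k}, \code{psa}, \code{psad},
#'   \code{zone}, \code{pirads}.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' table(coh$biopsy_gg, coh$upgrade)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  m <- spec$moments
  local_seed(seed, {
    blocks <- list()
    for (gg in sort(unique(m$gg))) {
      for (arm in c("no_upgrade", "upgrade")) {
        sub <- m[m$gg == gg & m$arm == arm, , drop = FALSE]
        if (nrow(sub) == 0) next
        nrec <- max(sub$n)
        up <- arm == "upgrade"
        rec <- data.frame(
          lesion_id = NA_character_,
          biopsy_gg = gg,
          prostatectomy_gg = if (up) min(gg + 1L, 5L) else gg,
          upgrade = up,
          mean_adc = NA_real_, mean_d = NA_real_, mean_k = NA_real_,
          psa = NA_real_, psad = NA_real_,
          zone = sample(c("peripheral", "transition"), nrec, replace = TRUE,
                        prob = c(105, 37)),
          pirads = sample(c(3L, 4L, 5L), nrec, replace = TRUE,
                          prob = c(4, 71, 67)),
          stringsAsFactors = FALSE)
        for (i in seq_len(nrow(sub))) {
          col <- var_column[[sub$variable[i]]]
          rec[[col]][seq_len(sub$n[i])] <- rnorm_pos(sub$n[i], sub$mean[i], sub$sd[i])
        }
        blocks[[length(blocks) + 1L]] <- rec
      }
    }
    out <- do.call(rbind, blocks)
    out$lesion_id <- sprintf("L%03d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out
  })
}

#' Packaged 142-lesion reference table
#'
#' A deterministic lesion table reproducing the study-level bookkeeping of the
#' reference cohort: 142 lesions, biopsy GG strata of 27/67/35/13, a biopsy x
#' prostatectomy GG cross-table consistent with prostatectomy GG margins
#' 9/47/61/13/12 and per-stratum upgrade counts 20/36/8/4 (68 upgrades
#' overall, 47.9%), zone split 105 peripheral / 37 transition and PI-RADS
#' 3/4/5 counts of 4/71/67. Only these marginals are anchored to the
#' reference cohort; the joint completion, the row ordering and the
#' quantitative values (set to the arm means of
#' \code{\link{default_group_moments}}) are synthetic.
#'
#' @return A lesion-record data.frame (same columns as
#'   \code{\link{generate_cohort}}).
#' @export
fixture_lesion_table <- function() {
  # biopsy GG -> prostatectomy GG allocation (one consistent completion of
  # the published margins; includes the small number of downgrades)
  alloc <- list(
    `1` = c(`1` = 7, `2` = 16, `3` = 2, `5` = 2),
    `2` = c(`1` = 2, `2` = 29, `3` = 34, `5` = 2),
    `3` = c(`2` = 2, `3` = 25, `4` = 4, `5` = 4),
    `4` = c(`4` = 9, `5` = 4))
  bgg <- pgg <- integer(0)
  for (b in names(alloc)) for (p in names(alloc[[b]])) {
    bgg <- c(bgg, rep(as.integer(b), alloc[[b]][[p]]))
    pgg <- c(pgg, rep(as.integer(p), alloc[[b]][[p]]))
  }
  n <- length(bgg)
  up <- pgg > bgg
  m <- default_group_moments()
  val <- function(gg, upgraded, variable) {
    arm <- ifelse(upgraded, "upgrade", "no_upgrade")
    i <- match(paste(gg, arm, variable), paste(m$gg, m$arm, m$variable))
    m$mean[i]
  }
  data.frame(
    lesion_id = sprintf("F%03d", seq_len(n)),
    biopsy_gg = bgg, prostatectomy_gg = pgg, upgrade = up,
    mean_adc = val(bgg, up, "ADC"),
    mean_d = val(bgg, up, "D"),
    mean_k = val(bgg, up, "K"),
    psa = val(bgg, up, "PSA"),
    psad = val(bgg, up, "PSAD"),
    zone = rep(c("peripheral", "transition"), c(105, 37)),
    pirads = rep(c(3L, 4L, 5L), c(4, 71, 67)),
    stringsAsFactors = FALSE)
}

#' Upgrade counts and percentages per biopsy Grade Group
#'
#' A lesion counts as upgraded when its prostatectomy Grade Group exceeds its
#' biopsy Grade Group.
#'
#' @param records lesion-record data.frame with \code{biopsy_gg} and
#'   \code{prostatectomy_gg} columns.
#' @return A data.frame of class \code{upgrade_summary} with one row per
#'   observed biopsy-GG stratum plus an overall row: \code{stratum}, \code{n},
#'   \code{n_upgraded}, \code{pct_upgraded} (0-100 scale).
#' @examples
#' summarize_upgrades(fixture_lesion_table())
#' @export
summarize_upgrades <- function(records) {
  need <- c("biopsy_gg", "prostatectomy_gg")
  if (!all(need %in% names(records)))
    stopf("records must have biopsy_gg and prostatectomy_gg columns")
  if (anyNA(records$biopsy_gg) || anyNA(records$prostatectomy_gg))
    stopf("missing Grade Group values in records")
  up <- records$prostatectomy_gg > records$biopsy_gg
  strata <- sort(unique(records$biopsy_gg))
  rows <- lapply(strata, function(g) {
    sel <- records$biopsy_gg == g
    data.frame(stratum = paste0("GG", g), n = sum(sel),
               n_upgraded = sum(up[sel]),
               pct_upgraded = 100 * mean(up[sel]))
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    stratum = "overall", n = length(up), n_upgraded = sum(up),
    pct_upgraded = 100 * mean(up)))))
  rownames(out) <- NULL
  class(out) <- c("upgrade_summary", "data.frame")
  out
}

#' @export
print.upgrade_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$pct_upgraded <- sprintf("%.2f", y$pct_upgraded)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write / read a lesion-record cohort as CSV
#'
#' @param records lesion-record data.frame.
#' @param path CSV file path.
#' @return \code{write_cohort} returns \code{path} invisibly;
#'   \code{read_cohort} returns the data.frame.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
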