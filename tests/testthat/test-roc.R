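test_that("empirical ROC matches the exhaustive pair-counting oracle", {
  scores <- c(0.1, 0.4, 0.35, 0.8); labels <- c(0, 0, 1, 1)
  r <- roc_curve(scores, labels)
  expect_equal(attr(r, "auc"), 0.75)
  expect_equal(attr(r, "auc"), auc_pairs(scores, labels))
  expect_equal(auc_mw(scores, labels), 0.75)
  # curve anchors
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
})

test_that("trapezoid AUC equals the normalized Mann-Whitney U on tied data", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(10:80, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(attr(roc_curve(scores, labels), "auc"),
                 auc_mw(scores, labels), tolerance = 1e-12)
    expect_equal(auc_mw(scores, labels), auc_pairs(scores, labels),
                 tolerance = 1e-12)
    # independent cross-check against pROC
    expect_equal(auc_mw(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                levels = c(0, 1),
                                                direction = "<", quiet = TRUE))),
                 tolerance = 1e-10)
  }
})

test_that("orientation reversal mirrors the AUC and perfect separation gives 1", {
  set.seed(3)
  scores <- rnorm(200); labels <- rbinom(200, 1, 0.5)
  expect_equal(auc_mw(scores, labels, "lower"), 1 - auc_mw(scores, labels, "higher"))
  expect_equal(auc_mw(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0), "lower"), 1)
  # a single positive above all negatives puts (0, 1) on the curve
  r <- roc_curve(c(5, 1, 2, 3), c(1, 0, 0, 0))
  expect_true(any(r$fpr == 0 & r$tpr == 1))
  expect_error(roc_curve(1:5, rep(1, 5)), "both classes")
})

test_that("Youden thresholds maximize J with the high-specificity tie-break", {
  y <- youden_threshold(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0), "lower")
  expect_equal(y$threshold, 3.5)
  expect_equal(y$J, 1)
  expect_equal(y$sensitivity, 1); expect_equal(y$specificity, 1)
  # constant scores are degenerate with J = 0
  yd <- youden_threshold(rep(2, 10), rep(c(0, 1), 5))
  expect_true(yd$degenerate); expect_equal(yd$J, 0); expect_true(is.na(yd$threshold))
  # ties in J resolve toward higher specificity
  s <- c(1, 2, 3, 10); l <- c(0, 1, 0, 1)
  yt <- youden_threshold(s, l, "higher")
  grid <- sort(unique(s)); mids <- (grid[-1] + grid[-length(grid)]) / 2
  J <- vapply(mids, function(t) mean(s[l == 1] > t) + mean(s[l == 0] <= t) - 1,
              numeric(1))
  expect_equal(yt$J, max(J))
  best_spec <- max(vapply(mids[J == max(J)],
                          function(t) mean(s[l == 0] <= t), numeric(1)))
  expect_equal(yt$specificity, best_spec)
})

test_that("the binormal GG2 ADC operating point lands at the density crossing", {
  set.seed(14)
  n <- 5e4
  neg <- rnorm(n, 0.862, 0.111)   # no upgrade
  pos <- rnorm(n, 0.712, 0.129)   # upgrade
  y <- youden_threshold(c(pos, neg), rep(c(1, 0), each = n), "lower")
  # population oracle: maximize J(t) over a dense grid of the two normal CDFs
  grid <- seq(0.5, 1.1, by = 1e-4)
  Jpop <- pnorm(grid, 0.712, 0.129) - pnorm(grid, 0.862, 0.111)
  t_star <- grid[which.max(Jpop)]
  expect_gt(y$threshold, 0.77); expect_lt(y$threshold, 0.84)
  expect_equal(y$threshold, t_star, tolerance = 0.02)
})

test_that("empirical AUC matches the binormal closed form at large n", {
  set.seed(5)
  n <- 1e6
  scores <- c(rnorm(n, 1.311, 0.188), rnorm(n, 1.152, 0.125))
  labels <- rep(c(1, 0), each = n)
  expect_equal(auc_mw(scores, labels), binormal_auc(1.152, 0.125, 1.311, 0.188),
               tolerance = 0.002)
  expect_equal(binormal_auc(0.862, 0.111, 0.712, 0.129, "lower"),
               pnorm(0.15 / sqrt(0.111^2 + 0.129^2)))
})

test_that("cross-validated logistic AUC is reproducible and tracks the raw-predictor AUC", {
  set.seed(77)
  rec <- data.frame(biopsy_gg = 2, upgrade = rep(c(TRUE, FALSE), each = 150),
                    mean_adc = c(rnorm(150, 0.712, 0.129), rnorm(150, 0.862, 0.111)))
  a <- cv_logistic_roc(rec, 2, "ADC", seed = 42)
  b <- cv_logistic_roc(rec, 2, "ADC", seed = 42)
  expect_equal(a$auc, b$auc)
  expect_identical(a$per_repeat_auc, b$per_repeat_auc)
  # monotone single-predictor logistic map preserves the ranking
  expect_equal(a$auc, a$auc_full, tolerance = 0.01)
  expect_equal(a$orientation, "lower")
  expect_true(a$ci_lo <= a$auc_full && a$auc_full <= a$ci_hi)
  expect_true(a$ci_lo >= 0 && a$ci_hi <= 1)
})

test_that("cross-validation degrades gracefully on small or single-class strata", {
  set.seed(9)
  rec <- data.frame(biopsy_gg = 1, upgrade = rep(c(TRUE, FALSE), c(3, 20)),
                    mean_k = rnorm(23, 1.2, 0.1))
  expect_warning(r <- cv_logistic_roc(rec, 1, "K", seed = 1), "reducing to 3 folds")
  expect_equal(r$folds, 3)
  rec1 <- data.frame(biopsy_gg = 1, upgrade = rep(TRUE, 10), mean_k = rnorm(10))
  expect_error(cv_logistic_roc(rec1, 1, "K"), "both classes")
})

test_that("a null predictor scores near 0.5 and ROC tables carry all predictors", {
  set.seed(13)
  coh <- generate_cohort(seed = 13)
  coh$psa[coh$biopsy_gg == 2] <- rnorm(sum(coh$biopsy_gg == 2), 10, 3)
  tab <- roc_table(coh, 2, seed = 2)
  expect_equal(tab$predictor, c("K", "D", "ADC", "PSA", "PSAD"))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$ci_lo <= tab$ci_up))
  # the scrambled PSA column is uninformative
  expect_lt(abs(tab$auc_full[tab$predictor == "PSA"] - 0.5), 0.15)
  # diffusion predictors separate clearly at the packaged moments
  expect_gt(tab$auc_full[tab$predictor == "ADC"], 0.65)
})
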