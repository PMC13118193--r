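test_that("default cohort reproduces the stratum and arm sizes", {
  coh <- generate_cohort(seed = 1)
  expect_equal(nrow(coh), 142)
  expect_equal(sum(coh$biopsy_gg == 2), 67)
  expect_equal(sum(coh$biopsy_gg == 2 & coh$upgrade), 36)
  expect_equal(as.vector(table(coh$biopsy_gg)), c(27, 67, 35, 13))
  expect_equal(sum(coh$upgrade), 68)
  # upgrade flag consistent with the Grade Groups
  expect_equal(coh$upgrade, coh$prostatectomy_gg > coh$biopsy_gg)
  # clinical variables missing only where the printed n is smaller
  expect_equal(sum(is.na(coh$psa[coh$biopsy_gg == 1 & !coh$upgrade])), 1)
  expect_equal(sum(is.na(coh$mean_k)), 0)
})

test_that("cohort generation is deterministic and seed-sensitive", {
  expect_identical(generate_cohort(seed = 5), generate_cohort(seed = 5))
  expect_false(identical(generate_cohort(seed = 5)$mean_k,
                         generate_cohort(seed = 6)$mean_k))
})

test_that("empirical moments converge to the specified ones", {
  m <- data.frame(gg = 2, arm = c("no_upgrade", "upgrade"), variable = "ADC",
                  n = 1e5, mean = c(0.862, 0.712), sd = c(0.111, 0.129))
  coh <- generate_cohort(cohort_spec(m), seed = 2)
  expect_equal(mean(coh$mean_adc[!coh$upgrade]), 0.862, tolerance = 0.01)
  expect_equal(mean(coh$mean_adc[coh$upgrade]), 0.712, tolerance = 0.01)
  expect_equal(sd(coh$mean_adc[coh$upgrade]), 0.129, tolerance = 0.01)
})

test_that("degenerate and near-zero specifications behave sanely", {
  m <- data.frame(gg = 1, arm = "upgrade", variable = "K",
                  n = 50, mean = 1.2, sd = 1e-9)
  coh <- generate_cohort(cohort_spec(m), seed = 1)
  expect_equal(range(coh$mean_k), c(1.2, 1.2), tolerance = 1e-6)
  # truncation at zero keeps diffusion values positive even for wide spreads
  m2 <- data.frame(gg = 1, arm = "upgrade", variable = "ADC",
                   n = 2000, mean = 0.1, sd = 0.5)
  expect_true(all(generate_cohort(cohort_spec(m2), seed = 1)$mean_adc > 0))
})

test_that("malformed cohort specifications are rejected", {
  base <- default_group_moments()
  bad <- base; bad$sd[1] <- 0
  expect_error(cohort_spec(bad), "SD")
  bad <- base; bad$arm[1] <- "maybe"
  expect_error(cohort_spec(bad), "arm")
  expect_error(cohort_spec(rbind(base, base[1, ])), "duplicate")
})

test_that("the packaged 142-lesion table reproduces every published marginal", {
  fx <- fixture_lesion_table()
  expect_equal(nrow(fx), 142)
  expect_equal(as.vector(table(fx$biopsy_gg)), c(27, 67, 35, 13))
  expect_equal(as.vector(table(fx$prostatectomy_gg)), c(9, 47, 61, 13, 12))
  expect_equal(as.vector(table(fx$zone)), c(105, 37))
  expect_equal(as.vector(table(fx$pirads)), c(4, 71, 67))
  up_by_gg <- tapply(fx$prostatectomy_gg > fx$biopsy_gg, fx$biopsy_gg, sum)
  expect_equal(as.vector(up_by_gg), c(20, 36, 8, 4))
  expect_identical(fixture_lesion_table(), fx)  # fully deterministic
})

test_that("upgrade summaries count strictly increasing Grade Groups", {
  s <- summarize_upgrades(fixture_lesion_table())
  expect_equal(s$pct_upgraded[s$stratum == "overall"], 100 * 68 / 142)
  expect_equal(round(s$pct_upgraded[s$stratum == "GG1"], 2), 74.07)
  # downgrades never count as upgrades
  rec <- data.frame(biopsy_gg = c(3, 3), prostatectomy_gg = c(2, 3))
  expect_equal(summarize_upgrades(rec)$n_upgraded, c(0, 0))
  expect_error(summarize_upgrades(data.frame(biopsy_gg = 1)), "prostatectomy_gg")
  expect_error(summarize_upgrades(data.frame(biopsy_gg = NA, prostatectomy_gg = 2)),
               "missing")
})

test_that("cohorts round-trip through CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  coh <- generate_cohort(seed = 3)
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(back$mean_k, coh$mean_k)
  expect_equal(back$upgrade, coh$upgrade)
})
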