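# Synthetic registry generator: determinism, truth recovery, calibration.

test_that("simulation parameters are validated", {
  expect_error(sim_params(nsfs_allele_freq = 1.2), "probabilities")
  expect_error(sim_params(n_patients = 0), "n_patients")
  expect_error(sim_params(baseline_onset = list(
    DM = c(median = -1, sdlog = 0.4), OA = c(median = 12, sdlog = 0.35),
    DI = c(median = 13, sdlog = 0.3), HL = c(median = 14, sdlog = 0.4))),
    "positive")
  p <- sim_params(dose_group_n = c(10, 20, 30))
  expect_identical(p$n_patients, 60L)
})

test_that("the same seed reproduces the cohort byte for byte", {
  p <- sim_params(n_patients = 80L, seed = 314L)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(generate_cohort(p), d1)
  write_cohort(generate_cohort(p), d2)
  for (f in c("registry.tsv", "truth.tsv", "domains.tsv", "params.yaml"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # and a different seed changes it
  p2 <- sim_params(n_patients = 80L, seed = 315L)
  d3 <- tempfile()
  write_cohort(generate_cohort(p2), d3)
  expect_false(identical(readLines(file.path(d1, "registry.tsv")),
                         readLines(file.path(d3, "registry.tsv"))))
})

test_that("simulation parameters round-trip through the YAML config", {
  p <- sim_params(n_patients = 55L, nsfs_shift = 0.7, seed = 9L)
  path <- tempfile(fileext = ".yaml")
  write_sim_params(p, path)
  expect_equal(read_sim_params(path), p)
})

test_that("degenerate mixtures behave as specified", {
  # no missingness: every patient eligible for every manifestation
  p <- sim_params(n_patients = 60L, missing_rate = c(DM = 0, OA = 0,
                                                     DI = 0, HL = 0),
                  missing_allele_rate = 0, seed = 5L)
  sim <- generate_cohort(p)
  for (m in c("DM", "OA", "DI", "HL"))
    expect_identical(nrow(filter_eligible(sim$registry, m)), 60L)
  # all-NSFS alleles: everyone is dose 2
  p2 <- sim_params(n_patients = 40L, nsfs_allele_freq = 1, seed = 6L)
  expect_true(all(generate_cohort(p2)$truth$nsfs_dose == 2L))
})

test_that("allele-class frequencies converge to the generative settings", {
  p <- sim_params(n_patients = 10000L, missing_allele_rate = 0,
                  nsfs_allele_freq = 0.55, tm_fraction = 0.5, seed = 77L)
  sim <- generate_cohort(p)
  # allele-level NSFS frequency: binomial(2 * n, 0.55)
  freq <- mean(sim$truth$nsfs_dose) / 2
  se <- sqrt(0.55 * 0.45 / (2 * p$n_patients))
  expect_lt(abs(freq - 0.55), 3 * se)
  # TM fraction among in-frame alleles
  inf <- sim$truth[sim$truth$n_inframe > 0, ]
  tm_freq <- sum(inf$tm_dose) / sum(inf$n_inframe)
  se_tm <- sqrt(0.5 * 0.5 / sum(inf$n_inframe))
  expect_lt(abs(tm_freq - 0.5), 3 * se_tm)
})

test_that("group medians move by approximately the configured shift", {
  p <- sim_params(dose_group_n = c(2500, 0, 2500), nsfs_shift = 1.5,
                  tm_shift = 0, male_dm_shift = 0,
                  missing_rate = c(DM = 0, OA = 0, DI = 0, HL = 0),
                  missing_allele_rate = 0, seed = 404L)
  sim <- generate_cohort(p)
  reg <- sim$registry
  med0 <- median(reg$onset_dm[sim$truth$nsfs_dose == 0])
  med2 <- median(reg$onset_dm[sim$truth$nsfs_dose == 2])
  expect_equal(med0 - med2, 3, tolerance = 0.15)   # 2 alleles x 1.5 years
})

test_that("doubling the sample size does not reduce power beyond noise", {
  shifted <- function(n, seed) sim_params(
    dose_group_n = rep(n, 3), nsfs_shift = 1.2, tm_shift = 0,
    male_dm_shift = 0, missing_rate = c(DM = 0, OA = 0, DI = 0, HL = 0),
    missing_allele_rate = 0, seed = seed)
  pw <- function(n) {
    ps <- run_power_study(shifted(n, 1234L), n_replicates = 60L)
    r <- ps$rates
    r$reject_rate[r$comparison == "NSFS0 vs NSFS2"]
  }
  small <- pw(25L); big <- pw(50L)
  expect_gte(big, small - 0.15)   # binomial noise allowance at 60 replicates
})

test_that("sex effect: power at the generated male DM shift, calibration without it", {
  base <- function(shift, seed) sim_params(
    n_patients = 306L, nsfs_shift = 0, tm_shift = 0, male_dm_shift = shift,
    missing_rate = c(DM = 0, OA = 0, DI = 0, HL = 0),
    missing_allele_rate = 0, seed = seed)
  # ~150 per sex, 1.5-year male shift: the sex comparison should be
  # significant in the large majority of replicates
  ps <- run_power_study(base(1.5, 2024L), n_replicates = 100L,
                        grouping = "sex", gap_pair = c("male", "female"))
  expect_gte(ps$rates$reject_rate[1], 0.80)
  # no simulated effect: non-significant in >= 93% of replicates
  null <- run_power_study(base(0, 4048L), n_replicates = 100L,
                          grouping = "sex", gap_pair = c("male", "female"))
  expect_lte(null$rates$reject_rate[1], 0.07)
})
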