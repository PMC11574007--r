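test_that("identical config and seed give byte-identical cohorts", {
  c1 <- generate_cohort(small_config(seed = 11))
  c2 <- generate_cohort(small_config(seed = 11))
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$visits, c2$visits)
  expect_identical(truth_slopes(c1$truth, "csf"), truth_slopes(c2$truth, "csf"))
  c3 <- generate_cohort(small_config(seed = 12))
  expect_false(identical(c1$visits, c3$visits))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(sd_residual = -1), "sd_residual")
  expect_error(sim_config(dropout_prob = 1.5), "dropout_prob")
  expect_error(sim_config(n_families = 1000L, n_carriers = 10L,
                          n_noncarriers = 10L), "n_families")
  expect_error(sim_config(eyo_baseline_range = c(10, -30)),
               "eyo_baseline_range")
})

test_that("group counts and visit bookkeeping are exact", {
  coh <- generate_cohort(sim_config(n_carriers = 355L, n_noncarriers = 212L,
                                    seed = 2))
  expect_equal(nrow(coh$participants), 567L)
  tab <- table(coh$participants$mutation_status)
  expect_equal(unname(tab[["carrier"]]), 355L)
  expect_equal(unname(tab[["noncarrier"]]), 212L)
  # without dropout every participant has a full schedule within range
  coh0 <- generate_cohort(small_config(seed = 3, dropout_prob = 0))
  nv <- table(coh0$visits$participant_id)
  expect_true(all(nv >= 2 & nv <= 4))
  expect_equal(length(nv), nrow(coh0$participants))
})

test_that("noiseless generation reproduces the generating curve exactly", {
  coh <- generate_cohort(noiseless_config(seed = 4))
  vis <- apply_qc(coh$visits)
  for (fl in c("csf", "plasma")) {
    vcol <- paste0("log10_", fl, "_nfl")
    ok <- !is.na(vis[[vcol]])
    mu <- vapply(which(ok), function(k) {
      truth_mean(coh$truth, vis$participant_id[k], vis$eyo[k], fl)
    }, numeric(1))
    expect_lt(max(abs(vis[[vcol]][ok] - mu)), 1e-9)
  }
})

test_that("truth slopes equal a finite-difference oracle of the mean curve", {
  coh <- generate_cohort(noiseless_config(seed = 5))
  ts <- truth_slopes(coh$truth, "plasma")
  sub <- coh$truth$subjects
  for (id in names(sub)[seq(1, length(sub), by = 5)]) {
    s <- sub[[id]]
    if (s$eyo_last > s$eyo_first) {
      # chord slope of the generating curve over the observed window
      fd <- (truth_mean(coh$truth, id, s$eyo_last, "plasma") -
               truth_mean(coh$truth, id, s$eyo_first, "plasma")) /
        (s$eyo_last - s$eyo_first)
      expect_equal(ts$true_slope[ts$participant_id == id], fd,
                   tolerance = 1e-8)
    }
  }
  expect_error(truth_slopes(coh$truth, "serum"))
})

test_that("non-carriers with no age effect and no random slope have slope 0", {
  cfg <- noiseless_config(
    seed = 6,
    covariate_effects = list(csf = c(age = 0, male = 0.05, bmi = 0),
                             plasma = c(age = 0, male = 0, bmi = 0)))
  coh <- generate_cohort(cfg)
  ts <- truth_slopes(coh$truth, "csf")
  nc <- coh$participants$mutation_status == "noncarrier"
  expect_true(all(abs(ts$true_slope[nc]) < 1e-12))
})

test_that("plasma rate of change stops increasing after the plateau EYO while CSF keeps increasing", {
  cfg <- sim_config(seed = 1)
  p <- cfg$true_plateau_eyo
  eps <- 0.01
  rate <- function(e, fl) {
    (nfltraj:::disease_mean(e + eps, fl, cfg) -
       nfltraj:::disease_mean(e - eps, fl, cfg)) / (2 * eps)
  }
  # CSF rate strictly increasing well past the plateau
  expect_gt(rate(p + 4, "csf"), rate(p, "csf"))
  # plasma rate flat (default post-plateau acceleration 0) after the plateau
  expect_equal(rate(p + 4, "plasma"), rate(p + 1, "plasma"), tolerance = 1e-6)
  expect_gt(rate(p - 1, "plasma"), rate(p - 3, "plasma"))
})

test_that("empirical replicate CV converges to the configured mean", {
  coh <- generate_cohort(sim_config(n_carriers = 600L, n_noncarriers = 600L,
                                    n_families = 300L,
                                    n_visits_range = c(4L, 4L),
                                    dropout_prob = 0,
                                    analyte_missing_prob = 0,
                                    single_replicate_prob = 0, seed = 7))
  qc <- qc_pipeline(replicate_pairs(coh$visits))
  cvs <- qc$cv_percent / 100
  expect_gt(length(cvs[!is.na(cvs)]), 9000)
  rms_cv <- sqrt(mean(cvs^2, na.rm = TRUE))
  expect_lt(abs(rms_cv - 0.07) / 0.07, 0.10)
})
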