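test_that("expected onset age averages variant onsets with parental fallback", {
  expect_equal(expected_onset_age(c(43, 47), 50), 45)
  expect_equal(expected_onset_age(numeric(0), 50), 50)
  expect_equal(expected_onset_age(45, NA), 45)
  expect_error(expected_onset_age(numeric(0), NA), "staging error")
})

test_that("EYO is age minus expected onset, slope exactly 1 per year", {
  expect_equal(compute_eyo(45, 45), 0)
  expect_equal(compute_eyo(40, 45), -5)
  expect_equal(compute_eyo(61, 45), 16)
  ages <- seq(30, 70, by = 0.5)
  eyo <- compute_eyo(ages, 45)
  expect_equal(diff(eyo) / diff(ages), rep(1, length(ages) - 1))
})

test_that("stage classification follows the longitudinal CDR definitions", {
  expect_equal(classify_stage(c(0, 0, 0), "carrier"), "presymptomatic_MC")
  expect_equal(classify_stage(c(0, 0.5, 0.5), "carrier"), "converter_MC")
  expect_equal(classify_stage(c(0.5, 0), "carrier"), "reverter_excluded")
  expect_equal(classify_stage(c(0.5, 1, 2), "carrier"), "symptomatic_MC")
  expect_equal(classify_stage(c(0, 0), "noncarrier"), "NC")
  # single-visit carriers
  expect_equal(classify_stage(0, "carrier"), "presymptomatic_MC")
  expect_equal(classify_stage(1, "carrier"), "symptomatic_MC")
  expect_error(classify_stage(numeric(0), "carrier"), "staging error")
})

test_that("stage labels are invariant to appending an equal trailing CDR", {
  seqs <- list(c(0, 0), c(0, 0.5), c(0.5, 0.5), c(0, 0, 1))
  for (s in seqs) {
    lab <- classify_stage(s, "carrier")
    if (lab %in% c("presymptomatic_MC", "symptomatic_MC")) {
      expect_equal(classify_stage(c(s, s[length(s)]), "carrier"), lab)
    }
  }
})

test_that("exclusion rules match their definitions and log every removal", {
  participants <- data.frame(
    participant_id = c("A", "B", "C", "D"),
    mutation_status = c("noncarrier", "noncarrier", "carrier", "carrier"),
    competing_disorder = c(FALSE, FALSE, TRUE, FALSE),
    variant_class = "pathogenic",
    stringsAsFactors = FALSE)
  visits <- data.frame(
    participant_id = c("A", "A", "B", "C", "C", "D", "D"),
    visit_index = c(1, 2, 1, 1, 2, 1, 2),
    eyo = c(10, 15.0, 15.1, -5, -3, -5, -3),
    cdr_global = c(0, 0, 0, 0, 0, 0.5, 0),
    stringsAsFactors = FALSE)
  ex <- apply_exclusions(participants, visits)
  # NC visit at EYO exactly 15.0 retained; 15.1 removed (strict inequality)
  expect_true(any(ex$visits$participant_id == "A" & ex$visits$eyo == 15.0))
  expect_false("B" %in% ex$visits$participant_id)
  # competing disorder removes all visits; reverter excluded
  expect_false("C" %in% ex$visits$participant_id)
  expect_false("D" %in% ex$visits$participant_id)
  # log bookkeeping: every removed row/participant appears
  expect_equal(sum(ex$log$rule_id == "nc_eyo_gt15"), 1)
  expect_true("C" %in% ex$log$participant_id[ex$log$rule_id == "competing_disorder"])
  expect_true("D" %in% ex$log$participant_id[ex$log$rule_id == "reverter"])
  # idempotence
  ex2 <- apply_exclusions(ex$participants, ex$visits)
  expect_equal(ex2$participants, ex$participants)
  expect_equal(ex2$visits, ex$visits)
  expect_equal(nrow(ex2$log), 0)
})

test_that("stage_cohort partitions all retained participants", {
  coh <- generate_cohort(small_config(seed = 21, reverter_frac = 0.05))
  st <- stage_cohort(coh$participants, coh$visits)
  expect_true(all(st$participants$stage %in%
                    c("NC", "presymptomatic_MC", "converter_MC",
                      "symptomatic_MC")))
  # reverters are gone from the staged tables and logged (possibly under an
  # earlier rule if the same participant also hits, e.g., the
  # competing-disorder exclusion)
  expect_true(all(!coh$truth$reverters %in% st$participants$participant_id))
  expect_true(all(coh$truth$reverters %in% st$exclusion_log$participant_id))
  # competing-disorder defaults (3) are excluded
  cd <- coh$participants$participant_id[coh$participants$competing_disorder]
  expect_true(all(!cd %in% st$participants$participant_id))
})

test_that("weak and Dutch-type variant carriers are excluded when generated", {
  coh <- generate_cohort(small_config(seed = 22, n_dutch_variant = 3L,
                                      n_weak_variant = 2L))
  st <- stage_cohort(coh$participants, coh$visits)
  bad <- coh$participants$participant_id[
    coh$participants$variant_class != "pathogenic"]
  expect_equal(length(bad), 5L)
  expect_true(all(!bad %in% st$participants$participant_id))
})
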