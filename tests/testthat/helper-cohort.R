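# small cohort configurations and table builders shared across tests

small_config <- function(seed = 1, ...) {
  sim_config(n_carriers = 60L, n_noncarriers = 40L, n_families = 25L,
             n_visits_range = c(2L, 4L), seed = seed, ...)
}

noiseless_config <- function(seed = 1, ...) {
  sim_config(n_carriers = 30L, n_noncarriers = 20L, n_families = 12L,
             sd_family_intercept = 0, sd_subject_intercept = 0,
             sd_subject_slope = 0, sd_residual = 0, replicate_cv_mean = 0,
             single_replicate_prob = 0, dropout_prob = 0,
             analyte_missing_prob = 0, imaging_missing_prob = 0,
             n_outliers = 0L, reverter_frac = 0,
             variant_onset_missing_frac = 0, seed = seed, ...)
}

# baseline analysis table (first visit with the analyte) for trajectory fits
baseline_table <- function(coh, fluid = "csf") {
  st <- stage_cohort(coh$participants, coh$visits)
  vis <- apply_qc(st$visits)
  pp <- st$participants
  vcol <- paste0("log10_", fluid, "_nfl")
  v <- vis[!is.na(vis[[vcol]]), ]
  b <- v[!duplicated(v$participant_id), ]
  i <- match(b$participant_id, pp$participant_id)
  data.frame(value = b[[vcol]], eyo = b$eyo, status = pp$mutation_status[i],
             age = pp$baseline_age[i], sex = pp$sex[i],
             bmi = pp$baseline_bmi[i], family_id = pp$family_id[i],
             participant_id = b$participant_id, stringsAsFactors = FALSE)
}

# long per-visit table for slope extraction
long_table <- function(coh, fluid = "csf") {
  st <- stage_cohort(coh$participants, coh$visits)
  vis <- apply_qc(st$visits)
  pp <- st$participants
  vcol <- paste0("log10_", fluid, "_nfl")
  v <- vis[!is.na(vis[[vcol]]), ]
  t0 <- tapply(v$age_at_visit, v$participant_id, min)
  data.frame(participant_id = v$participant_id,
             family_id = pp$family_id[match(v$participant_id,
                                            pp$participant_id)],
             time = v$age_at_visit - unname(t0[v$participant_id]),
             value = v[[vcol]], eyo = v$eyo, stringsAsFactors = FALSE)
}

# exhaustive profile-RSS grid search: the independent breakpoint oracle
segmented_grid_oracle <- function(x, y, res = 0.01) {
  cand <- seq(quantile(x, 0.02), quantile(x, 0.98), by = res)
  rss <- vapply(cand, function(p)
    sum(.lm.fit(cbind(1, x, pmax(x - p, 0)), y)$residuals^2), numeric(1))
  cand[which.min(rss)]
}
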