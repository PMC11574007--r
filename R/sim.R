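#' Configuration for a synthetic ADAD-like cohort
#'
#' Builds a validated configuration object for [generate_cohort()]. Defaults
#' describe a cohort of 355 mutation carriers and 212 non-carrier family
#' members followed every two years (annually once symptomatic), with
#' EYO-anchored log10 NfL trajectories in CSF and plasma, family-clustered
#' random effects, duplicate assay replicates, CDR conversion around EYO 0,
#' and precuneus MRI volume / PiB-PET SUVR summaries.
#'
#' The carrier disease component of the mean log10 NfL trajectory is a
#' smooth monotone curve: flat before the divergence EYO `d`, then
#' accelerating, with mean
#' \deqn{D(e) = \tfrac{1}{2}\,a\, g(e-d)^2, \qquad g(u) = s\log(1+e^{u/s}),}
#' so the annual rate of change \eqn{D'(e) \approx a (e-d)_+} grows roughly
#' linearly after divergence. For plasma only, the rate stops increasing at
#' the plateau EYO `p` (`true_plateau_eyo`): beyond `p` the curve continues
#' with constant (or, if `post_plateau_accel < 0`, decreasing) rate. CSF has
#' no plateau, so its rate of change keeps increasing across the disease
#' course.
#'
#' @param n_carriers,n_noncarriers number of mutation carriers / non-carrier
#'   family members.
#' @param n_families number of families; must not exceed the cohort size.
#' @param visit_interval_years scheduled visit interval (years) while CDR = 0.
#' @param symptomatic_interval_years visit interval once CDR > 0 (annual
#'   follow-up of symptomatic participants).
#' @param n_visits_range integer pair: min/max scheduled visits per person.
#' @param eyo_baseline_range range (years) of baseline EYO, e.g. -30..+10.
#' @param true_divergence_eyo EYO (years) at which carrier trajectories start
#'   to leave the non-carrier course.
#' @param true_plateau_eyo EYO (years) after which the plasma rate of change
#'   stops increasing.
#' @param carrier_slope_params per-fluid trajectory coefficients: for each of
#'   `csf` and `plasma`, a list with `accel` (log10 pg/ml per year^2 growth of
#'   the rate after divergence), `smooth_years` (softplus smoothing scale) and
#'   for plasma `post_plateau_accel` (rate slope after the plateau; 0 = flat).
#' @param covariate_effects per-fluid named vectors `c(age=, male=, bmi=)` on
#'   log10 pg/ml (age per year, BMI per kg/m2).
#' @param base_levels per-fluid log10 pg/ml at the covariate reference
#'   (age 40, female, BMI 27).
#' @param sd_family_intercept,sd_subject_intercept,sd_subject_slope,sd_residual
#'   standard deviations (log10 units; slope per year) of the generating
#'   random effects and visit-level residual.
#' @param subject_intercept_cor,subject_slope_cor correlation of a subject's
#'   CSF and plasma random intercepts / slopes.
#' @param replicate_cv_mean mean coefficient of variation of duplicate assay
#'   replicates (proportion, e.g. 0.07 for 7%).
#' @param single_replicate_prob probability a visit yields only one replicate.
#' @param onset_sd_years SD of actual CDR conversion age around the expected
#'   onset age.
#' @param imaging_coupling precuneus-volume slope (mm3/year) per unit NfL
#'   slope (log10/year), applied in symptomatic carriers only.
#' @param imaging_coupling_fluid which fluid's true slope drives the volume
#'   coupling (`"csf"` or `"plasma"`).
#' @param pib_coupling like `imaging_coupling` but for the PiB-PET SUVR
#'   slope; the default 0 generates amyloid change independent of NfL change.
#' @param pib_amplitude height (SUVR units) of the sigmoid amyloid rise in
#'   carriers (half-maximum at EYO -12); 0 generates PiB fully independent
#'   of disease stage and of NfL.
#' @param dropout_prob probability a scheduled non-baseline visit is missed
#'   (missing completely at random).
#' @param analyte_missing_prob per-visit probability that a fluid sample is
#'   unavailable.
#' @param imaging_missing_prob per-visit probability an imaging summary is
#'   unavailable.
#' @param reverter_frac fraction of carriers given an injected CDR sequence
#'   that reverts to 0 (exercises the exclusion rule).
#' @param n_outliers number of participants flagged with a competing
#'   neurological disorder and given extreme NfL values.
#' @param n_dutch_variant,n_weak_variant carriers assigned a Dutch-type CAA /
#'   weakly pathogenic variant class (excluded downstream).
#' @param variant_onset_missing_frac fraction of variants with no reported
#'   mean onset age (forces the parental-onset fallback).
#' @param mean_onset_age,sd_onset_age_between_variants distribution of the
#'   variant-specific expected onset age (years).
#' @param seed integer seed controlling all generation randomness.
#' @return object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_carriers = 355L,
                       n_noncarriers = 212L,
                       n_families = 140L,
                       visit_interval_years = 2,
                       symptomatic_interval_years = 1,
                       n_visits_range = c(2L, 6L),
                       eyo_baseline_range = c(-30, 10),
                       true_divergence_eyo = -20,
                       true_plateau_eyo = 3.6,
                       carrier_slope_params = list(
                         csf = list(accel = 0.0020, smooth_years = 2.5),
                         plasma = list(accel = 0.0015, smooth_years = 2.5,
                                       post_plateau_accel = 0)
                       ),
                       covariate_effects = list(
                         csf = c(age = 0.010, male = 0.05, bmi = 0),
                         plasma = c(age = 0.010, male = 0, bmi = -0.008)
                       ),
                       base_levels = c(csf = 2.35, plasma = 0.72),
                       sd_family_intercept = 0.05,
                       sd_subject_intercept = 0.08,
                       sd_subject_slope = 0.005,
                       sd_residual = 0.05,
                       subject_intercept_cor = 0.6,
                       subject_slope_cor = 0.5,
                       replicate_cv_mean = 0.07,
                       single_replicate_prob = 0.01,
                       onset_sd_years = 2,
                       imaging_coupling = -2500,
                       imaging_coupling_fluid = "csf",
                       pib_coupling = 0,
                       pib_amplitude = 1.3,
                       dropout_prob = 0.08,
                       analyte_missing_prob = 0.08,
                       imaging_missing_prob = 0.15,
                       reverter_frac = 0.02,
                       n_outliers = 3L,
                       n_dutch_variant = 0L,
                       n_weak_variant = 0L,
                       variant_onset_missing_frac = 0.05,
                       mean_onset_age = 46,
                       sd_onset_age_between_variants = 5,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop_field(field, "must be a single nonnegative number")
  }
  for (f in c("sd_family_intercept", "sd_subject_intercept",
              "sd_subject_slope", "sd_residual", "replicate_cv_mean",
              "onset_sd_years")) chk_nonneg(f)
  for (f in c("dropout_prob", "analyte_missing_prob", "imaging_missing_prob",
              "single_replicate_prob", "reverter_frac",
              "variant_onset_missing_frac")) {
    chk_nonneg(f)
    if (cfg[[f]] > 1) stop_field(f, "must lie in [0, 1]")
  }
  for (f in c("n_carriers", "n_noncarriers", "n_families", "n_outliers")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop_field(f, "must be a single nonnegative integer")
  }
  if (cfg$n_carriers + cfg$n_noncarriers < 1L)
    stop_field("n_carriers", "cohort must contain at least one participant")
  if (cfg$n_families > cfg$n_carriers + cfg$n_noncarriers)
    stop_field("n_families", "cannot exceed the number of participants")
  if (length(cfg$eyo_baseline_range) != 2L ||
      diff(cfg$eyo_baseline_range) <= 0)
    stop_field("eyo_baseline_range", "must be an ordered pair (lo < hi)")
  if (length(cfg$n_visits_range) != 2L ||
      cfg$n_visits_range[1] > cfg$n_visits_range[2] ||
      cfg$n_visits_range[1] < 1)
    stop_field("n_visits_range", "must be an ordered integer pair >= 1")
  for (fl in c("csf", "plasma")) {
    if (is.null(cfg$carrier_slope_params[[fl]]))
      stop_field("carrier_slope_params", paste("missing fluid", fl))
    if (is.null(cfg$covariate_effects[[fl]]))
      stop_field("covariate_effects", paste("missing fluid", fl))
  }
  if (!cfg$imaging_coupling_fluid %in% c("csf", "plasma"))
    stop_field("imaging_coupling_fluid", "must be 'csf' or 'plasma'")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ADAD cohort configuration\n")
  cat(sprintf("  %d carriers, %d non-carriers, %d families, seed %d\n",
              x$n_carriers, x$n_noncarriers, x$n_families, x$seed))
  cat(sprintf("  baseline EYO %g..%g, divergence %g, plasma plateau %g\n",
              x$eyo_baseline_range[1], x$eyo_baseline_range[2],
              x$true_divergence_eyo, x$true_plateau_eyo))
  invisible(x)
}

# Disease component of the mean log10 NfL trajectory (carriers only).
# Flat-then-accelerating; plasma rate capped after the plateau EYO.
disease_mean <- function(eyo, fluid, cfg) {
  pp <- cfg$carrier_slope_params[[fluid]]
  a <- pp$accel; s <- pp$smooth_years
  d <- cfg$true_divergence_eyo
  g <- function(u) softplus(u, s)
  base <- function(e) 0.5 * a * g(e - d)^2
  rate <- function(e) a * g(e - d) * sigmoid((e - d) / s)
  if (identical(fluid, "plasma")) {
    p <- cfg$true_plateau_eyo
    c2 <- pp$post_plateau_accel %||% 0
    out <- ifelse(eyo <= p,
                  base(eyo),
                  base(p) + rate(p) * (eyo - p) + 0.5 * c2 * (eyo - p)^2)
  } else {
    out <- base(eyo)
  }
  out
}

# Analytic derivative of disease_mean: annual rate of change (log10/yr).
disease_rate <- function(eyo, fluid, cfg) {
  pp <- cfg$carrier_slope_params[[fluid]]
  a <- pp$accel; s <- pp$smooth_years
  d <- cfg$true_divergence_eyo
  rate <- function(e) a * softplus(e - d, s) * sigmoid((e - d) / s)
  if (identical(fluid, "plasma")) {
    p <- cfg$true_plateau_eyo
    c2 <- pp$post_plateau_accel %||% 0
    ifelse(eyo <= p, rate(eyo), rate(p) + c2 * (eyo - p))
  } else {
    rate(eyo)
  }
}

# Full generating mean log10 concentration for one subject at given EYO
# (vectorized over eyo). `subj` is a row of the internal subject frame.
subject_mean_log10 <- function(eyo, fluid, subj, cfg) {
  ce <- cfg$covariate_effects[[fluid]]
  age <- subj$expected_onset + eyo
  m <- cfg$base_levels[[fluid]] +
    ce[["age"]] * (age - 40) +
    ce[["male"]] * as.numeric(subj$sex == "male") +
    ce[["bmi"]] * (subj$baseline_bmi - 27) +
    subj[[paste0("u_", fluid)]] +
    subj[[paste0("b_", fluid)]] * (eyo - subj$baseline_eyo) +
    subj$u_family
  if (subj$mutation_status == "carrier") m <- m + disease_mean(eyo, fluid, cfg)
  m
}

#' Generate a synthetic ADAD-like cohort
#'
#' Draws a complete longitudinal cohort (participant table, visit table, and
#' the generating truth) under a [sim_config()]. Identical config and seed
#' give identical output. The truth object records every realized random
#' effect and per-subject generating slope and is intended only for
#' evaluating downstream estimates, never as an input to them.
#'
#' @param config a [sim_config()] object.
#' @return object of class `nfl_cohort`: list with `participants` (one row
#'   per person), `visits` (long format, one row per visit, duplicate assay
#'   replicates in `*_rep1`/`*_rep2` columns, CSF remeasurements in
#'   `csf_nfl_rep1_rm`/`csf_nfl_rep2_rm`), and `truth` (class `sim_truth`).
#' @examples
#' coh <- generate_cohort(sim_config(n_carriers = 30, n_noncarriers = 20,
#'                                   n_families = 12, seed = 7))
#' nrow(coh$participants)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be a sim_config object", call. = FALSE)
  }
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_carriers + cfg$n_noncarriers

  ## ---- families and variants ------------------------------------------
  n_var <- max(1L, as.integer(round(cfg$n_families * 0.7)))
  variant_onset <- pmin(pmax(rnorm(n_var, cfg$mean_onset_age,
                                   cfg$sd_onset_age_between_variants), 32), 62)
  variant_gene <- sample(c("PSEN1", "APP", "PSEN2"), n_var, replace = TRUE,
                         prob = c(0.75, 0.16, 0.09))
  variant_reported <- ifelse(
    runif(n_var) < cfg$variant_onset_missing_frac, NA_real_, variant_onset)
  fam_variant <- c(seq_len(min(n_var, cfg$n_families)),
                   sample(n_var, max(0L, cfg$n_families - n_var),
                          replace = TRUE))
  fam_variant <- fam_variant[sample.int(cfg$n_families)]
  u_family <- rnorm(cfg$n_families, 0, cfg$sd_family_intercept)

  ## ---- participants ----------------------------------------------------
  family_id <- c(seq_len(cfg$n_families),
                 sample.int(cfg$n_families, n - cfg$n_families,
                            replace = TRUE))
  family_id <- family_id[sample.int(n)]
  status <- rep(c("carrier", "noncarrier"),
                c(cfg$n_carriers, cfg$n_noncarriers))
  variant <- fam_variant[family_id]
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.55, 0.45))
  bmi <- pmax(rnorm(n, 27.7, 5.5), 16)

  # correlated per-subject random intercepts and slopes across fluids
  draw_pair <- function(sd, rho) {
    z1 <- rnorm(n); z2 <- rnorm(n)
    cbind(sd * z1, sd * (rho * z1 + sqrt(1 - rho^2) * z2))
  }
  ui <- draw_pair(cfg$sd_subject_intercept, cfg$subject_intercept_cor)
  bi <- draw_pair(cfg$sd_subject_slope, cfg$subject_slope_cor)

  expected_onset <- variant_onset[variant]
  conversion_age <- ifelse(status == "carrier",
                           expected_onset + rnorm(n, 0, cfg$onset_sd_years),
                           Inf)
  baseline_eyo <- runif(n, cfg$eyo_baseline_range[1], cfg$eyo_baseline_range[2])
  baseline_age <- expected_onset + baseline_eyo

  variant_class <- rep("pathogenic", n)
  carr_idx <- which(status == "carrier")
  special <- sample_vec(carr_idx,
                    min(length(carr_idx),
                        cfg$n_dutch_variant + cfg$n_weak_variant))
  if (cfg$n_dutch_variant > 0)
    variant_class[special[seq_len(min(cfg$n_dutch_variant, length(special)))]] <-
      "dutch_caa"
  if (cfg$n_weak_variant > 0 && length(special) > cfg$n_dutch_variant)
    variant_class[special[(cfg$n_dutch_variant + 1):length(special)]] <- "weak"

  competing <- rep(FALSE, n)
  if (cfg$n_outliers > 0)
    competing[sample.int(n, min(cfg$n_outliers, n))] <- TRUE

  parental_onset <- expected_onset + rnorm(n, 0, 2)

  participants <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    family_id = sprintf("F%03d", family_id),
    mutation_status = status,
    gene = ifelse(status == "carrier", variant_gene[variant], "none"),
    variant_id = sprintf("V%03d", variant),
    variant_class = variant_class,
    variant_reported_onset = variant_reported[variant],
    parental_onset_age = parental_onset,
    sex = sex,
    baseline_age = baseline_age,
    baseline_bmi = bmi,
    competing_disorder = competing,
    stringsAsFactors = FALSE
  )

  subj <- data.frame(
    participant_id = participants$participant_id,
    mutation_status = status,
    sex = sex,
    baseline_bmi = bmi,
    expected_onset = expected_onset,
    conversion_age = conversion_age,
    baseline_eyo = baseline_eyo,
    u_family = u_family[family_id],
    u_csf = ui[, 1], u_plasma = ui[, 2],
    b_csf = bi[, 1], b_plasma = bi[, 2],
    stringsAsFactors = FALSE
  )

  # reverter injection: carriers given a CDR>0 visit followed by 0
  reverters <- character(0)
  if (cfg$reverter_frac > 0) {
    n_rev <- round(cfg$reverter_frac * cfg$n_carriers)
    pre_idx <- which(status == "carrier" & baseline_age < conversion_age)
    if (n_rev > 0 && length(pre_idx) > 0)
      reverters <- participants$participant_id[
        sample_vec(pre_idx, min(n_rev, length(pre_idx)))]
  }

  ## ---- visits ----------------------------------------------------------
  sd_rep_log <- sqrt(log1p(cfg$replicate_cv_mean^2))
  draw_reps <- function(conc) {
    # multiplicative lognormal replicate noise with mean conc and CV ~= target
    z <- matrix(rnorm(2 * length(conc)), ncol = 2)
    conc * exp(sd_rep_log * z - 0.5 * sd_rep_log^2)
  }

  mean_icv <- 1.45e6
  icv <- rnorm(n, mean_icv, 1.2e5)
  vol0 <- 9800 + 0.006 * (icv - mean_icv) - 25 * (baseline_age - 40) +
    rnorm(n, 0, 600)
  vol_slope <- -25 + rnorm(n, 0, 12)
  pib_noise <- rnorm(n, 0, 0.08)
  pib_slope_noise <- rnorm(n, 0, 0.01)

  rows <- vector("list", n)
  injected_reverters <- character(0)
  for (i in seq_len(n)) {
    si <- subj[i, ]
    nv <- sample_vec(seq(cfg$n_visits_range[1], cfg$n_visits_range[2]), 1L)
    ages <- numeric(nv); ages[1] <- baseline_age[i]
    cdr_of_age <- function(a) {
      if (a < conversion_age[i]) return(0)
      dt <- a - conversion_age[i]
      if (dt < 3) 0.5 else if (dt < 6) 1 else if (dt < 9) 2 else 3
    }
    if (nv > 1) {
      for (k in 2:nv) {
        intv <- if (cdr_of_age(ages[k - 1]) > 0)
          cfg$symptomatic_interval_years else cfg$visit_interval_years
        ages[k] <- ages[k - 1] + intv
      }
    }
    keep <- c(TRUE, runif(nv - 1) >= cfg$dropout_prob)
    ages <- ages[keep]
    nv <- length(ages)
    eyo <- ages - expected_onset[i]
    cdr <- vapply(ages, cdr_of_age, numeric(1))
    if (participants$participant_id[i] %in% reverters && nv >= 2) {
      cdr[] <- 0
      cdr[1] <- 0.5  # injected transient impairment that later reverts
      injected_reverters <- c(injected_reverters,
                              participants$participant_id[i])
    }

    mmse <- ifelse(cdr == 0,
                   pmin(30, round(29.5 - 0.02 * (ages - 40) + rnorm(nv, 0, 0.7))),
                   pmax(0, round(29 - 2.2 * (ages - conversion_age[i]) +
                                   rnorm(nv, 0, 1.5))))

    m_csf <- subject_mean_log10(eyo, "csf", si, cfg) +
      rnorm(nv, 0, cfg$sd_residual)
    m_pla <- subject_mean_log10(eyo, "plasma", si, cfg) +
      rnorm(nv, 0, cfg$sd_residual)
    if (competing[i]) { m_csf <- m_csf + log10(8); m_pla <- m_pla + log10(8) }
    conc_csf <- 10^m_csf
    conc_pla <- 10^m_pla
    rep_csf <- draw_reps(conc_csf)
    rep_pla <- draw_reps(conc_pla)
    single_c <- runif(nv) < cfg$single_replicate_prob
    single_p <- runif(nv) < cfg$single_replicate_prob
    rep_csf[single_c, 2] <- NA
    rep_pla[single_p, 2] <- NA
    miss_c <- runif(nv) < cfg$analyte_missing_prob
    miss_p <- runif(nv) < cfg$analyte_missing_prob
    rep_csf[miss_c, ] <- NA
    rep_pla[miss_p, ] <- NA

    # CSF remeasurement available where initial pair is flagged
    cv_c <- 100 * abs(rep_csf[, 1] - rep_csf[, 2]) / sqrt(2) /
      rowMeans(rep_csf)
    need_rm <- (!miss_c) & ((is.na(rep_csf[, 2]) & !is.na(rep_csf[, 1])) |
                              (!is.na(cv_c) & cv_c > 20))
    rm_csf <- matrix(NA_real_, nv, 2)
    if (any(need_rm)) rm_csf[need_rm, ] <- draw_reps(conc_csf[need_rm])

    vol_meas <- vol0[i] + vol_slope[i] * (ages - ages[1]) +
      rnorm(nv, 0, 150)
    if (status[i] == "carrier" && cdr[1] > 0) {
      fl <- cfg$imaging_coupling_fluid
      true_rate <- cfg$covariate_effects[[fl]][["age"]] +
        si[[paste0("b_", fl)]] +
        disease_rate(mean(eyo), fl, cfg)
      vol_meas <- vol_meas + cfg$imaging_coupling * true_rate * (ages - ages[1])
    }
    pib_level <- if (status[i] == "carrier")
      1.2 + cfg$pib_amplitude * sigmoid((eyo + 12) / 4) else rep(1.2, nv)
    pib_meas <- pib_level + pib_noise[i] + pib_slope_noise[i] * (ages - ages[1]) +
      rnorm(nv, 0, 0.05)
    if (cfg$pib_coupling != 0 && status[i] == "carrier" && cdr[1] > 0) {
      fl <- cfg$imaging_coupling_fluid
      true_rate <- cfg$covariate_effects[[fl]][["age"]] +
        si[[paste0("b_", fl)]] + disease_rate(mean(eyo), fl, cfg)
      pib_meas <- pib_meas + cfg$pib_coupling * true_rate * (ages - ages[1])
    }
    miss_img <- runif(nv) < cfg$imaging_missing_prob
    vol_meas[miss_img] <- NA
    miss_pib <- runif(nv) < cfg$imaging_missing_prob
    pib_meas[miss_pib] <- NA

    rows[[i]] <- data.frame(
      participant_id = participants$participant_id[i],
      visit_index = seq_len(nv),
      age_at_visit = ages,
      eyo = eyo,
      cdr_global = cdr,
      mmse = mmse,
      plasma_nfl_rep1 = rep_pla[, 1],
      plasma_nfl_rep2 = rep_pla[, 2],
      csf_nfl_rep1 = rep_csf[, 1],
      csf_nfl_rep2 = rep_csf[, 2],
      csf_nfl_rep1_rm = rm_csf[, 1],
      csf_nfl_rep2_rm = rm_csf[, 2],
      precuneus_volume = vol_meas,
      icv = icv[i],
      precuneus_pib_suvr = pib_meas,
      stringsAsFactors = FALSE
    )
  }
  visits <- do.call(rbind, rows)
  rownames(visits) <- NULL

  ## ---- truth -----------------------------------------------------------
  subjects <- vector("list", n)
  names(subjects) <- participants$participant_id
  for (i in seq_len(n)) {
    vi <- rows[[i]]
    e1 <- vi$eyo[1]; e2 <- vi$eyo[nrow(vi)]
    sl <- lapply(c(csf = "csf", plasma = "plasma"), function(fl) {
      b <- subj[[paste0("b_", fl)]][i]
      age_eff <- cfg$covariate_effects[[fl]][["age"]]
      dis <- if (subj$mutation_status[i] == "carrier") {
        if (e2 > e1) {
          (disease_mean(e2, fl, cfg) - disease_mean(e1, fl, cfg)) / (e2 - e1)
        } else disease_rate(e1, fl, cfg)
      } else 0
      age_eff + b + dis
    })
    subjects[[i]] <- list(
      u_family = subj$u_family[i],
      u_csf = subj$u_csf[i], u_plasma = subj$u_plasma[i],
      b_csf = subj$b_csf[i], b_plasma = subj$b_plasma[i],
      expected_onset = subj$expected_onset[i],
      conversion_age = subj$conversion_age[i],
      baseline_eyo = subj$baseline_eyo[i],
      eyo_first = e1, eyo_last = e2,
      true_slope_csf = sl$csf, true_slope_plasma = sl$plasma
    )
  }
  truth <- structure(list(config = cfg,
                          subject_frame = subj,
                          subjects = subjects,
                          reverters = injected_reverters),
                     class = "sim_truth")

  structure(list(participants = participants, visits = visits, truth = truth),
            class = "nfl_cohort")
}

#' @export
print.nfl_cohort <- function(x, ...) {
  tab <- table(x$participants$mutation_status)
  cat(sprintf("Synthetic ADAD cohort: %d participants (%d carriers, %d non-carriers), %d visits\n",
              nrow(x$participants), tab[["carrier"]], tab[["noncarrier"]],
              nrow(x$visits)))
  invisible(x)
}

#' True per-subject annualized slopes from the generating truth
#'
#' Returns, for every participant, the slope of the generating mean log10
#' trajectory over that participant's observed EYO window (chord slope, i.e.
#' the time-weighted average of the instantaneous generating rates), including
#' the age trend and the subject's own random slope. Subjects with a single
#' visit get the instantaneous generating rate at that visit.
#'
#' @param truth a `sim_truth` object from [generate_cohort()].
#' @param fluid `"csf"` or `"plasma"`.
#' @return data.frame with `participant_id` and `true_slope` (log10/year).
#' @export
truth_slopes <- function(truth, fluid = c("csf", "plasma")) {
  if (!inherits(truth, "sim_truth")) stop("'truth' must be a sim_truth object",
                                          call. = FALSE)
  fluid <- match.arg(fluid)
  data.frame(
    participant_id = names(truth$subjects),
    true_slope = vapply(truth$subjects,
                        function(s) s[[paste0("true_slope_", fluid)]],
                        numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Generating mean log10 concentration for a participant
#'
#' Evaluates the noiseless generating curve (fixed covariate effects, disease
#' component and the participant's realized random effects) at given EYO
#' values. Useful for checking estimates against the truth.
#'
#' @param truth a `sim_truth` object.
#' @param participant_id single participant id.
#' @param eyo numeric vector of EYO values (years).
#' @param fluid `"csf"` or `"plasma"`.
#' @return numeric vector of mean log10 pg/ml.
#' @export
truth_mean <- function(truth, participant_id, eyo, fluid = c("csf", "plasma")) {
  fluid <- match.arg(fluid)
  sf <- truth$subject_frame
  i <- match(participant_id, sf$participant_id)
  if (is.na(i)) stop("unknown participant_id", call. = FALSE)
  subject_mean_log10(eyo, fluid, sf[i, ], truth$config)
}

#' Write / read a synthetic cohort as delimited text
#'
#' `write_cohort()` writes `participants.csv` and `visits.csv` (comma
#' separated, header row, UTF-8) and, unless `truth = FALSE`, the generating
#' truth as `truth.yaml` (nested key-value, one block per subject).
#' `read_cohort()` reads them back.
#'
#' @param cohort an `nfl_cohort` object.
#' @param dir output directory (created if needed).
#' @param truth whether to also serialize the generating truth.
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` an
#'   `nfl_cohort` (with `truth = NULL` if no truth file is present).
#' @export
write_cohort <- function(cohort, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  if (isTRUE(truth) && !is.null(cohort$truth)) {
    tr <- cohort$truth
    ser <- list(config = unclass(tr$config),
                reverters = as.list(tr$reverters),
                subjects = tr$subjects)
    yaml::write_yaml(ser, file.path(dir, "truth.yaml"), precision = 15)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            stringsAsFactors = FALSE)
  truth <- NULL
  tf <- file.path(dir, "truth.yaml")
  if (file.exists(tf)) {
    raw <- yaml::read_yaml(tf)
    cfg <- raw$config
    class(cfg) <- "sim_config"
    truth <- structure(list(config = cfg, subject_frame = NULL,
                            subjects = raw$subjects,
                            reverters = unlist(raw$reverters)),
                       class = "sim_truth")
  }
  structure(list(participants = participants, visits = visits, truth = truth),
            class = "nfl_cohort")
}
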