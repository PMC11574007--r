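#' Adjust regional volumes for total intracranial volume
#'
#' Residual-method adjustment: the slope of volume on ICV is estimated in a
#' reference group (typically the non-carriers), and
#' `adjusted = volume - b * (icv - mean(icv[reference]))`, so adjusted
#' volume is uncorrelated with ICV within the reference group. With
#' constant ICV the data are returned unchanged.
#'
#' @param volume regional volumes (mm3).
#' @param icv total intracranial volumes (mm3).
#' @param reference logical vector marking the reference-group rows
#'   (at least 10 required).
#' @return adjusted volumes (mm3).
#' @export
adjust_volume_for_icv <- function(volume, icv, reference) {
  stopifnot(length(volume) == length(icv), length(reference) == length(icv))
  ref <- reference & !is.na(volume) & !is.na(icv)
  if (sum(ref) < 10) {
    stop("reference group must contain at least 10 complete observations",
         call. = FALSE)
  }
  if (any(volume <= 0, na.rm = TRUE) || any(icv <= 0, na.rm = TRUE)) {
    stop("volumes must be positive", call. = FALSE)
  }
  m_icv <- mean(icv[ref])
  if (sd(icv[ref]) == 0) return(volume)
  b <- coef(lm(volume[ref] ~ icv[ref]))[[2]]
  volume - b * (icv - m_icv)
}

#' Coupling of NfL rate of change with imaging rate of change
#'
#' Tests, within one clinical group, whether the per-person extracted NfL
#' rate of change predicts the rate of change of a time-varying imaging
#' outcome. The mixed model regresses the imaging outcome on time with
#' baseline age x time, sex x time, baseline BMI x time and NfL-slope x time
#' interactions (plus their main effects), random slope and intercept per
#' participant, and a random intercept for family. The NfL-slope x time
#' interaction is the coefficient of interest: imaging units per year per
#' unit NfL slope. When the random-slope model cannot be estimated (small
#' groups), the model falls back to random intercepts only, with a warning.
#'
#' @param data long-format data.frame with columns `outcome_col`, `time`
#'   (years from baseline), `nfl_slope` (per-participant extracted slope,
#'   constant within participant), `age`, `sex`, `bmi`, `participant_id`,
#'   `family_id`.
#' @param outcome_col name of the imaging outcome column (ICV-adjusted
#'   precuneus volume in mm3, or PiB SUVR).
#' @return object of class `nfl_coupling`: `estimate` (interaction), `se`,
#'   `df`, `p`, `n` (participants), `outcome`, and the fitted model.
#' @export
fit_imaging_coupling <- function(data, outcome_col) {
  need <- c(outcome_col, "time", "nfl_slope", "age", "sex", "bmi",
            "participant_id", "family_id")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[, need]), need]
  names(d)[1] <- "y"
  d$male <- sex_indicator(d$sex)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  fml <- y ~ time + age + male + bmi + nfl_slope +
    age:time + male:time + bmi:time + nfl_slope:time +
    (time | participant_id) + (1 | family_id)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lmerTest::lmer(fml, data = d, control = ctrl))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("random-slope model failed; falling back to random intercepts")
    fml2 <- y ~ time + age + male + bmi + nfl_slope +
      age:time + male:time + bmi:time + nfl_slope:time +
      (1 | participant_id) + (1 | family_id)
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(fml2, data = d, control = ctrl)))
  }
  sm <- suppressWarnings(summary(fit))$coefficients
  row <- grep("nfl_slope:time|time:nfl_slope", rownames(sm))
  if (length(row) != 1) {
    stop("the NfL-slope x time interaction was dropped from the model ",
         "(rank deficiency: the slope is collinear with other covariates)",
         call. = FALSE)
  }
  est <- sm[row, "Estimate"]; se <- sm[row, "Std. Error"]
  df <- if ("df" %in% colnames(sm)) sm[row, "df"] else NA_real_
  p <- if ("Pr(>|t|)" %in% colnames(sm)) sm[row, "Pr(>|t|)"] else
    2 * pnorm(-abs(est / se))
  structure(list(estimate = unname(est), se = unname(se), df = unname(df),
                 p = unname(p), n = length(unique(d$participant_id)),
                 outcome = outcome_col, model = fit),
            class = "nfl_coupling")
}

#' @export
print.nfl_coupling <- function(x, ...) {
  cat(sprintf("NfL-slope x time coupling — %s\n", x$outcome))
  cat(sprintf("  estimate %.4g (SE %.4g), p = %.4g, n = %d participants\n",
              x$estimate, x$se, x$p, x$n))
  invisible(x)
}
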