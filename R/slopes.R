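#' Extract within-person annualized rates of change (empirical Bayes)
#'
#' Fits a linear mixed model of the outcome on time from baseline (years)
#' with a random intercept for family and random slope and intercept per
#' participant, and extracts each participant's annualized slope as the
#' fixed time effect plus the participant's empirical-Bayes (BLUP) random
#' slope. The same operation serves log10 NfL, precuneus volume, and
#' PiB-PET SUVR outcomes.
#'
#' @param data long-format data.frame.
#' @param outcome name of the outcome column (e.g. `"log10_csf_nfl"`).
#' @param id,time,family column names for participant id, time from
#'   baseline (years), and family id.
#' @return object of class `nfl_slopes` (a data.frame): `participant_id`,
#'   `outcome`, `annualized_slope`, `n_visits_used`. The fitted `lme4` model
#'   is kept in attribute `model`.
#' @export
extract_subject_slopes <- function(data, outcome, id = "participant_id",
                                   time = "time", family = "family_id") {
  need <- c(outcome, id, time, family)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[, need]), need]
  names(d) <- c("y", "id", "time", "family")
  if (nrow(d) < 3) stop("too few rows to fit the slope model", call. = FALSE)

  fml <- y ~ time + (time | id) + (1 | family)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = d,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             check.conv.grad = "ignore",
                                             check.conv.hess = "ignore")))),
    error = function(e) {
      stop("slope model did not converge: ", conditionMessage(e),
           "\n  rows: ", nrow(d), ", participants: ", length(unique(d$id)),
           call. = FALSE)
    })
  fe <- lme4::fixef(fit)[["time"]]
  re <- lme4::ranef(fit)$id
  slopes <- fe + re[, "time"]
  nv <- table(d$id)[rownames(re)]
  out <- data.frame(participant_id = rownames(re),
                    outcome = outcome,
                    annualized_slope = slopes,
                    n_visits_used = as.integer(nv),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "model") <- fit
  class(out) <- c("nfl_slopes", "data.frame")
  out
}

#' Cross-sectional / longitudinal association of CSF and plasma NfL
#'
#' For each group separately, reports the unadjusted Pearson correlation
#' (`r2`, two-sided `p`) between the CSF and plasma quantities (log10
#' baseline values, or extracted annualized slopes) and, when covariates are
#' supplied, a linear model of CSF on plasma plus age, sex and BMI with the
#' full-model `r2` and the partial `r2` of the plasma term.
#'
#' @param data data.frame with columns `csf`, `plasma`, `group`, and
#'   (optionally) `age`, `sex`, `bmi`.
#' @param adjust include age/sex/BMI-adjusted regression (default TRUE if
#'   the covariate columns are present).
#' @return data.frame, one row per group: `group`, `n`, `r2`, `p`,
#'   `adj_r2`, `partial_r2`, `slope` (regression coefficient of plasma).
#' @export
relate_csf_plasma <- function(data, adjust = all(c("age", "sex", "bmi") %in%
                                                   names(data))) {
  stopifnot(all(c("csf", "plasma", "group") %in% names(data)))
  out <- lapply(split(data, data$group), function(d) {
    d <- d[stats::complete.cases(d[, c("csf", "plasma")]), ]
    if (nrow(d) < 3) {
      stop("fewer than 3 complete pairs in group ", d$group[1], call. = FALSE)
    }
    ct <- cor.test(d$plasma, d$csf)
    row <- data.frame(group = d$group[1], n = nrow(d),
                      r2 = unname(ct$estimate)^2, p = ct$p.value,
                      adj_r2 = NA_real_, partial_r2 = NA_real_,
                      slope = NA_real_, stringsAsFactors = FALSE)
    if (adjust) {
      d$male <- sex_indicator(d$sex)
      full <- lm(csf ~ plasma + age + male + bmi, data = d)
      red <- lm(csf ~ age + male + bmi, data = d)
      row$adj_r2 <- summary(full)$r.squared
      rss_f <- sum(resid(full)^2); rss_r <- sum(resid(red)^2)
      row$partial_r2 <- (rss_r - rss_f) / rss_r
      row$slope <- coef(full)[["plasma"]]
    } else {
      row$slope <- coef(lm(csf ~ plasma, data = d))[["plasma"]]
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' AIC model selection over candidate covariate sets
#'
#' Fits one linear model per candidate covariate set (all on the same rows),
#' and ranks them by AIC with Akaike weights
#' \eqn{w_i = \exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)} and cumulative
#' weights in ascending-AIC order. The default candidate set is all eight
#' subsets of \{age, sex, BMI\}.
#'
#' @param data data.frame containing the outcome, the base predictors and
#'   the candidate covariates.
#' @param outcome outcome column name.
#' @param base character vector of predictors present in every candidate
#'   (may be empty).
#' @param candidates list of character vectors (covariate sets). Default:
#'   all subsets of `c("age", "sex", "bmi")`.
#' @return object of class `nfl_aic_table` (a data.frame sorted by AIC):
#'   `covariates`, `k` (parameters), `aic`, `delta`, `weight`,
#'   `cum_weight`.
#' @export
aic_select <- function(data, outcome, base = "plasma", candidates = NULL) {
  if (is.null(candidates)) {
    vars <- c("age", "sex", "bmi")
    candidates <- unlist(lapply(0:3, function(k)
      utils::combn(vars, k, simplify = FALSE)), recursive = FALSE)
  }
  if (length(candidates) < 2) stop("need at least 2 candidate models",
                                   call. = FALSE)
  all_vars <- unique(c(outcome, base, unlist(candidates)))
  d <- data[stats::complete.cases(data[, all_vars, drop = FALSE]),
            all_vars, drop = FALSE]
  if ("sex" %in% names(d)) d$sex <- sex_indicator(d$sex)
  fits <- lapply(candidates, function(cv) {
    rhs <- c(base, cv)
    if (length(rhs) == 0) rhs <- "1"
    lm(as.formula(paste(outcome, "~", paste(rhs, collapse = " + "))),
       data = d)
  })
  ns <- vapply(fits, function(f) length(resid(f)), numeric(1))
  if (length(unique(ns)) != 1) {
    stop("candidate models use different case sets; AIC not comparable",
         call. = FALSE)
  }
  aic <- vapply(fits, AIC, numeric(1))
  delta <- aic - min(aic)
  w <- exp(-delta / 2); w <- w / sum(w)
  tab <- data.frame(
    covariates = vapply(candidates, function(cv)
      if (length(cv) == 0) "(none)" else paste(cv, collapse = "+"),
      character(1)),
    k = vapply(fits, function(f) length(coef(f)) + 1, numeric(1)),
    aic = aic, delta = delta, weight = w, stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic), ]
  tab$delta <- tab$aic - tab$aic[1]
  tab$cum_weight <- cumsum(tab$weight)
  rownames(tab) <- NULL
  class(tab) <- c("nfl_aic_table", "data.frame")
  tab
}

#' Pairwise clinical-group comparison of extracted rates of change
#'
#' Fits a linear mixed model of a per-participant quantity (extracted NfL
#' slope, or plasma/CSF ratio) on clinical group with fixed effects for
#' baseline age, sex and baseline BMI and a random intercept for family,
#' then reports all pairwise group contrasts with Satterthwaite degrees of
#' freedom and Holm-adjusted p-values (configurable).
#'
#' @param data data.frame, one row per participant: `value`, `stage`,
#'   `age`, `sex`, `bmi`, `family_id`.
#' @param adjust multiple-comparison method passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @param stage_levels contrast ordering; levels absent from the data (or
#'   with fewer than 2 members, dropped with a warning) are omitted.
#' @return object of class `nfl_group_comparison` (a data.frame):
#'   `contrast`, `estimate`, `se`, `df`, `p_raw`, `p_adj`, plus attribute
#'   `method`.
#' @export
compare_groups <- function(data, adjust = "holm",
                           stage_levels = c("NC", "presymptomatic_MC",
                                            "converter_MC", "symptomatic_MC")) {
  need <- c("value", "stage", "age", "sex", "bmi", "family_id")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[, need]), need]
  d <- d[d$stage %in% stage_levels, ]
  cnt <- table(d$stage)
  small <- names(cnt)[cnt < 2]
  if (length(small) > 0) {
    warning("omitting group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    d <- d[!d$stage %in% small, ]
  }
  d$stage <- factor(d$stage, levels = intersect(stage_levels,
                                                unique(d$stage)))
  d$male <- sex_indicator(d$sex)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lmerTest::lmer(value ~ stage + age + male + bmi + (1 | family_id),
                     data = d,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore")))),
    error = function(e) lm(value ~ stage + age + male + bmi, data = d))
  emm <- emmeans::emmeans(fit, "stage", lmer.df = "satterthwaite")
  prs <- as.data.frame(graphics::pairs(emm, adjust = "none"))
  out <- data.frame(contrast = as.character(prs$contrast),
                    estimate = prs$estimate,
                    se = prs$SE, df = prs$df,
                    p_raw = prs$p.value,
                    p_adj = p.adjust(prs$p.value, method = adjust),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- adjust
  attr(out, "model") <- fit
  attr(out, "group_n") <- table(d$stage)
  class(out) <- c("nfl_group_comparison", "data.frame")
  out
}

#' Plasma/CSF NfL ratio
#'
#' Per-visit ratio of absolute (untransformed pg/ml) plasma NfL to CSF NfL,
#' computed only at visits where both analytes are present. Absolute values
#' rather than log-transformed or rate-of-change values keep the ratio
#' interpretable.
#'
#' @param visits visit table with final `plasma_nfl` and `csf_nfl` columns
#'   (see [apply_qc()]).
#' @return data.frame `participant_id`, `visit_index`, `ratio`.
#' @export
plasma_csf_ratio <- function(visits) {
  stopifnot(all(c("plasma_nfl", "csf_nfl") %in% names(visits)))
  ok <- !is.na(visits$plasma_nfl) & !is.na(visits$csf_nfl)
  if (any(visits$csf_nfl[ok] <= 0)) {
    stop("ratio error: nonpositive CSF NfL value(s)", call. = FALSE)
  }
  data.frame(participant_id = visits$participant_id[ok],
             visit_index = visits$visit_index[ok],
             ratio = visits$plasma_nfl[ok] / visits$csf_nfl[ok],
             row.names = NULL, stringsAsFactors = FALSE)
}
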