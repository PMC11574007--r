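#' Format a percentage the way cohort descriptive tables print them
#'
#' Percentages of 10% or more are rounded to the nearest integer ("96%");
#' percentages below 10% get one decimal ("3.8%"). Percentages are always
#' recomputed from counts, never stored.
#'
#' @param count numerator count(s).
#' @param total denominator count.
#' @return character vector like `"96%"` or `"3.8%"`.
#' @examples
#' format_pct(204, 212)  # "96%"
#' format_pct(8, 212)    # "3.8%"
#' @export
format_pct <- function(count, total) {
  pct <- 100 * count / total
  ifelse(pct >= 10 | pct == 0,
         paste0(round(pct), "%"),
         paste0(formatC(round(pct, 1), format = "f", digits = 1), "%"))
}

#' Baseline descriptive table with group tests
#'
#' Summarizes the baseline visit per participant by mutation-carrier group:
#' mean (SD) for continuous variables with a two-sided Wilcoxon rank-sum
#' test, and n (%) for categorical variables with a two-sided Pearson
#' chi-squared test (no continuity correction; documented behaviour for all
#' table sizes).
#'
#' @param participants staged participant table (needs `mutation_status`;
#'   uses `sex`, `gene`, `baseline_age`, `baseline_bmi` when present).
#' @param visits visit table with QC'd `plasma_nfl`/`csf_nfl` columns (run
#'   [apply_qc()] first) and `eyo`.
#' @return object of class `nfl_table1` (a data.frame): `variable`, `level`,
#'   `NC`, `MC`, `p`.
#' @export
descriptive_table <- function(participants, visits) {
  if (!"plasma_nfl" %in% names(visits)) visits <- apply_qc(visits)
  grp <- ifelse(participants$mutation_status == "carrier", "MC", "NC")
  if (!all(c("MC", "NC") %in% grp)) stop("empty group", call. = FALSE)
  base <- visits[!duplicated(visits$participant_id), ]
  base <- base[match(participants$participant_id, base$participant_id), ]

  rows <- list()
  cont <- function(label, x) {
    s <- function(g) sprintf("%.1f (%.1f)", mean(x[grp == g], na.rm = TRUE),
                             sd(x[grp == g], na.rm = TRUE))
    p <- tryCatch(suppressWarnings(
      wilcox.test(x[grp == "NC"], x[grp == "MC"])$p.value),
      error = function(e) NA_real_)
    rows[[length(rows) + 1]] <<- data.frame(
      variable = label, level = "", NC = s("NC"), MC = s("MC"), p = p,
      stringsAsFactors = FALSE)
  }
  catg <- function(label, x) {
    x <- factor(x)
    tab <- table(x, grp)
    p <- tryCatch(suppressWarnings(
      chisq.test(tab, correct = FALSE)$p.value), error = function(e) NA_real_)
    hdr <- data.frame(variable = label, level = "", NC = "", MC = "", p = p,
                      stringsAsFactors = FALSE)
    lv <- do.call(rbind, lapply(levels(x), function(l) data.frame(
      variable = label, level = l,
      NC = sprintf("%d (%s)", tab[l, "NC"],
                   format_pct(tab[l, "NC"], sum(grp == "NC"))),
      MC = sprintf("%d (%s)", tab[l, "MC"],
                   format_pct(tab[l, "MC"], sum(grp == "MC"))),
      p = NA_real_, stringsAsFactors = FALSE)))
    rows[[length(rows) + 1]] <<- rbind(hdr, lv)
  }

  cont("Age (yrs)", participants$baseline_age)
  catg("Sex", participants$sex)
  if ("eyo" %in% names(base)) cont("EYO (yrs)", base$eyo)
  cont("BMI", participants$baseline_bmi)
  if ("mmse" %in% names(base)) cont("MMSE", base$mmse)
  if ("cdr_global" %in% names(base)) {
    catg("CDR global", ifelse(base$cdr_global == 0, "CDR 0",
                              ifelse(base$cdr_global == 0.5, "CDR 0.5",
                                     "CDR 1+")))
  }
  if ("gene" %in% names(participants)) {
    gn <- participants$gene
    catg("Family mutation", ifelse(gn == "none", NA, gn))
  }
  if ("precuneus_volume" %in% names(base))
    cont("Precuneus volume (mm3)", base$precuneus_volume)
  if ("precuneus_pib_suvr" %in% names(base))
    cont("Precuneus PiB-PET (SUVR)", base$precuneus_pib_suvr)
  cont("Plasma NfL (pg/ml)", base$plasma_nfl)
  cont("CSF NfL (pg/ml)", base$csf_nfl)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nfl_table1", "data.frame")
  out
}

#' @export
print.nfl_table1 <- function(x, ...) {
  y <- as.data.frame(x)
  y$p <- ifelse(is.na(y$p), "", format(signif(y$p, 3)))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Run the full analysis pipeline on a synthetic or on-disk cohort
#'
#' Orchestrates simulate -> stage -> QC -> trajectory fits and divergence
#' points -> slope extraction and group comparison -> plasma/CSF ratio ->
#' breakpoint detection -> imaging coupling -> report, writing all outputs
#' as delimited text under `out_dir` (`tables/`, `fits/`, `report.txt`,
#' `manifest.yaml`). Stages can be toggled off; later stages that need a
#' disabled stage are skipped.
#'
#' @param config a [sim_config()] (used when `input_dir` is NULL).
#' @param out_dir output directory.
#' @param input_dir optional directory with `participants.csv`/`visits.csv`
#'   to analyse instead of simulating.
#' @param seed overrides `config$seed` when not NULL.
#' @param fluids analytes to analyse (`"plasma"`, `"csf"`).
#' @param stages character vector of stage toggles.
#' @param mcmc list of MCMC settings for [nfl_trajectory()]
#'   (`chains`, `warmup`, `draws`).
#' @param sym_includes_converters merge converters into the symptomatic
#'   group for the imaging analysis (default TRUE).
#' @param breakpoint_min_eyo earliest baseline EYO entering the bifurcation
#'   search (default -10: the breakpoint of interest is the post-onset
#'   plateau of the plasma rate, not the much earlier divergence bend).
#' @return object of class `nfl_run`: list of stage results plus `out_dir`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, input_dir = NULL,
                         seed = NULL, fluids = c("plasma", "csf"),
                         stages = c("simulate", "stage", "qc",
                                    "fit_trajectory", "slopes", "compare",
                                    "breakpoint", "imaging", "report"),
                         mcmc = list(chains = 4, warmup = 500, draws = 1000),
                         sym_includes_converters = TRUE,
                         breakpoint_min_eyo = -10) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_sim_config(config)
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "fits"), showWarnings = FALSE)
  res <- list(out_dir = out_dir, config = config)
  wtab <- function(df, name) {
    utils::write.csv(as.data.frame(df), file.path(out_dir, "tables",
                                                  paste0(name, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }

  ## cohort
  if (!is.null(input_dir)) {
    coh <- read_cohort(input_dir)
  } else {
    if (!"simulate" %in% stages) stop("no input_dir and simulate disabled",
                                      call. = FALSE)
    coh <- generate_cohort(config)
    wtab(coh$participants, "participants")
    wtab(coh$visits, "visits")
  }
  res$cohort <- coh

  if ("stage" %in% stages) {
    st <- stage_cohort(coh$participants, coh$visits)
    res$staged <- st
    wtab(st$exclusion_log, "exclusion_log")
    wtab(st$participants, "participants_staged")
  }

  if ("qc" %in% stages && !is.null(res$staged)) {
    vis <- apply_qc(res$staged$visits)
    res$visits_qc <- vis
    wtab(attr(vis, "qc"), "qc")
    wtab(vis, "visits_qc")
  }

  have_qc <- !is.null(res$visits_qc)
  pp <- if (have_qc) res$staged$participants else NULL

  analysis_table <- function(fluid) {
    vcol <- paste0("log10_", fluid, "_nfl")
    v <- res$visits_qc
    v <- v[!is.na(v[[vcol]]), ]
    b <- v[!duplicated(v$participant_id), ]
    i <- match(b$participant_id, pp$participant_id)
    data.frame(value = b[[vcol]], eyo = b$eyo,
               status = pp$mutation_status[i], age = pp$baseline_age[i],
               sex = pp$sex[i], bmi = pp$baseline_bmi[i],
               family_id = pp$family_id[i],
               participant_id = b$participant_id,
               stringsAsFactors = FALSE)
  }

  long_table <- function(fluid) {
    vcol <- paste0("log10_", fluid, "_nfl")
    v <- res$visits_qc
    v <- v[!is.na(v[[vcol]]), ]
    t0 <- tapply(v$age_at_visit, v$participant_id, min)
    i <- match(v$participant_id, pp$participant_id)
    data.frame(participant_id = v$participant_id,
               family_id = pp$family_id[i],
               time = v$age_at_visit - unname(t0[v$participant_id]),
               value = v[[vcol]], eyo = v$eyo,
               stringsAsFactors = FALSE)
  }

  ## slope extraction (needed by several later stages)
  if ("slopes" %in% stages && have_qc) {
    res$slopes <- list()
    for (fl in fluids) {
      lt <- long_table(fl)
      sl <- extract_subject_slopes(lt, "value")
      sl$outcome <- paste0("log10_", fl, "_nfl")
      res$slopes[[fl]] <- sl
      wtab(sl, paste0("slopes_", fl))
    }
    # cross-fluid association, baseline and longitudinal
    if (all(c("plasma", "csf") %in% fluids)) {
      ab <- analysis_table("csf"); bp <- analysis_table("plasma")
      i <- match(ab$participant_id, bp$participant_id)
      pair <- data.frame(csf = ab$value, plasma = bp$value[i],
                         group = ifelse(ab$status == "carrier", "MC", "NC"),
                         age = ab$age, sex = ab$sex, bmi = ab$bmi)
      res$assoc_baseline <- relate_csf_plasma(pair)
      wtab(res$assoc_baseline, "assoc_baseline")
      sc <- res$slopes$csf; sp <- res$slopes$plasma
      i <- match(sc$participant_id, sp$participant_id)
      j <- match(sc$participant_id, pp$participant_id)
      pair2 <- data.frame(csf = sc$annualized_slope,
                          plasma = sp$annualized_slope[i],
                          group = ifelse(pp$mutation_status[j] == "carrier",
                                         "MC", "NC"),
                          age = pp$baseline_age[j], sex = pp$sex[j],
                          bmi = pp$baseline_bmi[j])
      res$assoc_slopes <- relate_csf_plasma(pair2)
      wtab(res$assoc_slopes, "assoc_slopes")
      res$aic_baseline <- aic_select(
        stats::na.omit(pair[pair$group == "MC", ]), "csf")
      wtab(res$aic_baseline, "aic_baseline_mc")
    }
  }

  ## trajectory fits and divergence points
  if ("fit_trajectory" %in% stages && have_qc) {
    res$trajectory <- list(); res$divergence <- list(); res$gam <- list()
    for (fl in fluids) {
      at <- analysis_table(fl)
      fit <- nfl_trajectory(at, "value", chains = mcmc$chains,
                            warmup = mcmc$warmup, draws = mcmc$draws,
                            seed = config$seed)
      dv <- divergence_point(fit, force = TRUE)
      res$trajectory[[fl]] <- fit
      res$divergence[[fl]] <- dv
      wtab(dv$difference_curve, paste0("difference_curve_", fl))
      sink(file.path(out_dir, "fits", paste0("trajectory_", fl, ".txt")))
      print(summary(fit)); print(dv)
      sink()
      res$gam[[fl]] <- gam_trajectory(at, "value")
      # rate-of-change trajectory over EYO, when slopes were extracted
      if (!is.null(res$slopes[[fl]])) {
        sl <- res$slopes[[fl]]
        at2 <- at[match(sl$participant_id, at$participant_id), ]
        at2$value <- sl$annualized_slope
        at2 <- at2[stats::complete.cases(at2), ]
        fit2 <- nfl_trajectory(at2, "value", chains = mcmc$chains,
                               warmup = mcmc$warmup, draws = mcmc$draws,
                               seed = config$seed + 1L)
        dv2 <- divergence_point(fit2, force = TRUE)
        res$trajectory[[paste0(fl, "_rate")]] <- fit2
        res$divergence[[paste0(fl, "_rate")]] <- dv2
        wtab(dv2$difference_curve, paste0("difference_curve_", fl, "_rate"))
      }
    }
  }

  ## stage labels merged with slopes; group comparisons and ratio
  slope_stage_table <- function(fl) {
    sl <- res$slopes[[fl]]
    i <- match(sl$participant_id, pp$participant_id)
    data.frame(participant_id = sl$participant_id,
               value = sl$annualized_slope,
               stage = pp$stage[i], age = pp$baseline_age[i],
               sex = pp$sex[i], bmi = pp$baseline_bmi[i],
               family_id = pp$family_id[i], stringsAsFactors = FALSE)
  }
  if ("compare" %in% stages && !is.null(res$slopes)) {
    res$group_comparison <- list()
    for (fl in fluids) {
      cmp <- compare_groups(slope_stage_table(fl))
      res$group_comparison[[fl]] <- cmp
      wtab(cmp, paste0("group_comparison_", fl))
    }
    # plasma/CSF ratio on absolute values, compared across stages
    rat <- plasma_csf_ratio(res$visits_qc)
    subj_ratio <- aggregate(ratio ~ participant_id, rat, mean)
    i <- match(subj_ratio$participant_id, pp$participant_id)
    rt <- data.frame(participant_id = subj_ratio$participant_id,
                     value = subj_ratio$ratio, stage = pp$stage[i],
                     age = pp$baseline_age[i], sex = pp$sex[i],
                     bmi = pp$baseline_bmi[i], family_id = pp$family_id[i],
                     stringsAsFactors = FALSE)
    res$ratio <- rat
    res$ratio_comparison <- compare_groups(rt)
    wtab(rat, "plasma_csf_ratio")
    wtab(res$ratio_comparison, "ratio_comparison")
  }

  ## breakpoints in rate-of-change vs EYO (carriers, later disease course:
  ## the post-onset plateau is the target, not the early divergence bend)
  if ("breakpoint" %in% stages && !is.null(res$slopes)) {
    res$bifurcation <- list()
    for (fl in fluids) {
      sl <- res$slopes[[fl]]
      i <- match(sl$participant_id, pp$participant_id)
      eyo_b <- res$visits_qc$eyo[
        match(sl$participant_id, res$visits_qc$participant_id)]
      keep <- pp$mutation_status[i] == "carrier" &
        !is.na(eyo_b) & eyo_b >= breakpoint_min_eyo
      bf <- detect_bifurcation(eyo_b[keep], sl$annualized_slope[keep])
      res$bifurcation[[fl]] <- bf
      wtab(data.frame(fluid = fl, detected = bf$detected, psi = bf$psi,
                      psi_se = bf$fit$psi_se,
                      p_slope_change = bf$fit$slope_change_test$p),
           paste0("bifurcation_", fl))
    }
  }

  ## imaging coupling per group x analyte x outcome
  if ("imaging" %in% stages && !is.null(res$slopes)) {
    v <- res$visits_qc
    i <- match(v$participant_id, pp$participant_id)
    nc_ref <- pp$mutation_status[i] == "noncarrier"
    v$vol_adj <- tryCatch(
      adjust_volume_for_icv(v$precuneus_volume, v$icv, nc_ref),
      error = function(e) v$precuneus_volume)
    t0 <- tapply(v$age_at_visit, v$participant_id, min)
    v$time <- v$age_at_visit - unname(t0[v$participant_id])
    stage_of <- pp$stage[i]
    grp <- ifelse(pp$mutation_status[i] == "noncarrier", "NC",
                  ifelse(stage_of == "presymptomatic_MC", "presym",
                         ifelse(stage_of %in% c("symptomatic_MC",
                                                if (sym_includes_converters)
                                                  "converter_MC"),
                                "sym", NA)))
    res$coupling <- list()
    rows <- list()
    for (fl in fluids) {
      sl <- res$slopes[[fl]]
      v$nfl_slope <- sl$annualized_slope[
        match(v$participant_id, sl$participant_id)]
      v$age <- pp$baseline_age[i]; v$sex <- pp$sex[i]
      v$bmi <- pp$baseline_bmi[i]
      for (oc in c("vol_adj", "precuneus_pib_suvr")) {
        for (g in c("NC", "presym", "sym")) {
          sub <- v[!is.na(grp) & grp == g, ]
          cp <- tryCatch(fit_imaging_coupling(sub, oc),
                         error = function(e) NULL)
          if (is.null(cp)) next
          key <- paste(fl, oc, g, sep = ".")
          res$coupling[[key]] <- cp
          rows[[key]] <- data.frame(fluid = fl, outcome = oc, group = g,
                                    estimate = cp$estimate, se = cp$se,
                                    p = cp$p, n = cp$n,
                                    stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) > 0) wtab(do.call(rbind, rows), "imaging_coupling")
  }

  ## report + manifest
  if ("report" %in% stages && have_qc) {
    res$table1 <- descriptive_table(pp, res$visits_qc)
    wtab(res$table1, "descriptives")
    write_report(res, file.path(out_dir, "report.txt"))
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path, precision = 15)
  manifest <- list(
    package = "nfltraj",
    version = as.character(utils::packageVersion("nfltraj")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = stages, fluids = fluids)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  class(res) <- "nfl_run"
  invisible(res)
}

write_report <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("NfL trajectory pipeline report")
  w("==============================")
  w("")
  w("Cohort: %d participants (%d visits) after exclusions",
    nrow(res$staged$participants), nrow(res$staged$visits))
  w("Exclusions logged: %d", nrow(res$staged$exclusion_log))
  if (!is.null(res$table1)) {
    w(""); w("Baseline descriptives (mean (SD) / n (%%)):")
    tab <- utils::capture.output(print(res$table1))
    writeLines(tab, con)
  }
  if (!is.null(res$divergence)) {
    w(""); w("Divergence points (first EYO where the 95%% credible band of")
    w("the carrier - non-carrier difference excludes 0):")
    for (nm in names(res$divergence)) {
      d <- res$divergence[[nm]]
      w("  %-14s %s", nm,
        if (is.na(d$first_divergence_eyo)) "none"
        else sprintf("%+.1f yrs (persistent: %s)", d$first_divergence_eyo,
                     d$persistence_flag))
    }
  }
  if (!is.null(res$group_comparison)) {
    for (nm in names(res$group_comparison)) {
      w(""); w("Pairwise group contrasts, %s rate of change (Holm):", nm)
      writeLines(utils::capture.output(
        print(as.data.frame(res$group_comparison[[nm]]), digits = 3)), con)
    }
  }
  if (!is.null(res$bifurcation)) {
    w(""); w("Bifurcation points (rate of change vs EYO, carriers):")
    for (nm in names(res$bifurcation)) {
      b <- res$bifurcation[[nm]]
      w("  %-8s %s", nm,
        if (b$detected) sprintf("psi = %+.2f yrs (SE %.2f)", b$psi,
                                b$fit$psi_se) else "none detected")
    }
  }
  invisible(path)
}

#' @export
print.nfl_run <- function(x, ...) {
  cat("nfltraj pipeline run ->", x$out_dir, "\n")
  if (!is.null(x$divergence)) {
    for (nm in names(x$divergence)) {
      cat(sprintf("  divergence %-12s %s\n", nm,
                  format(x$divergence[[nm]]$first_divergence_eyo)))
    }
  }
  invisible(x)
}
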