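#' Coefficient of variation of a duplicate assay measurement
#'
#' CV of a duplicate pair, in percent, using the n-1 sample standard
#' deviation: `100 * sd(c(rep1, rep2)) / mean(c(rep1, rep2))`. For two
#' points the SD reduces to `|rep1 - rep2| / sqrt(2)`. The CV is symmetric
#' in the replicates and invariant to rescaling both by a common factor.
#'
#' @param rep1,rep2 replicate concentrations (pg/ml), both positive.
#'   Vectorized.
#' @return CV in percent.
#' @examples
#' replicate_cv(80, 120)  # 28.28%
#' @export
replicate_cv <- function(rep1, rep2) {
  bad <- (!is.na(rep1) & rep1 <= 0) | (!is.na(rep2) & rep2 <= 0)
  if (any(bad)) {
    stop("QC error: nonpositive replicate value(s) at row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  100 * (abs(rep1 - rep2) / sqrt(2)) / ((rep1 + rep2) / 2)
}

#' Log10 transform of concentrations
#'
#' @param values concentrations (pg/ml), all positive (NA allowed).
#' @return elementwise log base 10.
#' @export
log10_transform <- function(values) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad) > 0) {
    stop("transform error: nonpositive value(s) at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  log10(values)
}

#' Replicate-level assay QC
#'
#' Computes per-measurement duplicate CVs, flags pairs with CV > 20% and
#' single-replicate measurements, and resolves the final reported value.
#' For CSF, a flagged measurement with a remeasured pair available uses the
#' remeasured values (`remeasured_used`); for plasma no remeasurement is
#' performed and the initial values are kept (`initial_used`), carrying the
#' flags. The final value is the mean of the available replicates (a single
#' replicate is its own value). No rows are ever dropped.
#'
#' @param pairs data.frame with columns `participant_id`, `visit_index`,
#'   `analyte` (`"plasma_nfl"` or `"csf_nfl"`), `rep1`, `rep2` and optionally
#'   `rep1_rm`, `rep2_rm` (remeasured pair, `NA` when unavailable).
#' @param cv_threshold CV flagging threshold in percent (default 20).
#' @return object of class `nfl_qc`: the input with added columns
#'   `cv_percent`, `flags` (comma-separated subset of `cv_gt_20`,
#'   `single_replicate`, `remeasured_used`, `initial_used`) and
#'   `final_value`; attribute `summary` holds flag counts per analyte.
#' @export
qc_pipeline <- function(pairs, cv_threshold = 20) {
  need <- c("participant_id", "visit_index", "analyte", "rep1", "rep2")
  if (!all(need %in% names(pairs))) {
    stop("pairs must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(pairs)
  if (!"rep1_rm" %in% names(pairs)) pairs$rep1_rm <- NA_real_
  if (!"rep2_rm" %in% names(pairs)) pairs$rep2_rm <- NA_real_

  pair_mean <- function(a, b) ifelse(is.na(b), a, (a + b) / 2)
  cv <- rep(NA_real_, n)
  both <- !is.na(pairs$rep1) & !is.na(pairs$rep2)
  cv[both] <- replicate_cv(pairs$rep1[both], pairs$rep2[both])

  single <- !is.na(pairs$rep1) & is.na(pairs$rep2)
  high_cv <- !is.na(cv) & cv > cv_threshold
  has_rm <- !is.na(pairs$rep1_rm)
  is_csf <- pairs$analyte == "csf_nfl"
  use_rm <- is_csf & (high_cv | single) & has_rm

  final <- pair_mean(pairs$rep1, pairs$rep2)
  final[use_rm] <- pair_mean(pairs$rep1_rm[use_rm], pairs$rep2_rm[use_rm])

  flags <- vapply(seq_len(n), function(i) {
    f <- character(0)
    if (high_cv[i]) f <- c(f, "cv_gt_20")
    if (single[i]) f <- c(f, "single_replicate")
    if (use_rm[i]) f <- c(f, "remeasured_used")
    if ((high_cv[i] || single[i]) && !use_rm[i] && !is.na(pairs$rep1[i])) {
      f <- c(f, "initial_used")
    }
    paste(f, collapse = ",")
  }, character(1))

  out <- pairs
  out$cv_percent <- cv
  out$flags <- flags
  out$final_value <- final

  summ <- do.call(rbind, lapply(split(seq_len(n), pairs$analyte), function(ix) {
    data.frame(
      analyte = pairs$analyte[ix[1]],
      n = length(ix),
      n_cv_gt_20 = sum(high_cv[ix]),
      n_single_replicate = sum(single[ix]),
      n_remeasured_used = sum(use_rm[ix]),
      n_missing = sum(is.na(pairs$rep1[ix]) & is.na(pairs$rep2[ix])),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  class(out) <- c("nfl_qc", "data.frame")
  out
}

#' @export
print.nfl_qc <- function(x, ...) {
  cat("Duplicate-assay QC:", nrow(x), "measurements\n")
  print(attr(x, "summary"))
  invisible(x)
}

#' Long-format replicate table from a visit table
#'
#' Reshapes the wide per-visit replicate columns of a cohort visit table into
#' the long replicate-pair format consumed by [qc_pipeline()].
#'
#' @param visits cohort visit table (columns `plasma_nfl_rep1` etc.).
#' @return replicate-pair data.frame.
#' @export
replicate_pairs <- function(visits) {
  mk <- function(analyte, r1, r2, r1rm = NA_real_, r2rm = NA_real_) {
    data.frame(participant_id = visits$participant_id,
               visit_index = visits$visit_index,
               analyte = analyte,
               rep1 = r1, rep2 = r2, rep1_rm = r1rm, rep2_rm = r2rm,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("plasma_nfl", visits$plasma_nfl_rep1, visits$plasma_nfl_rep2),
    mk("csf_nfl", visits$csf_nfl_rep1, visits$csf_nfl_rep2,
       visits$csf_nfl_rep1_rm %||% NA_real_,
       visits$csf_nfl_rep2_rm %||% NA_real_)
  )
}

#' Attach QC'd final NfL values to a visit table
#'
#' Runs [qc_pipeline()] on the replicate pairs of a visit table and returns
#' the visit table with `plasma_nfl` and `csf_nfl` columns (final pg/ml
#' values) plus their log10 transforms.
#'
#' @param visits cohort visit table.
#' @return the visit table with `plasma_nfl`, `csf_nfl`, `log10_plasma_nfl`,
#'   `log10_csf_nfl` columns; QC table in attribute `qc`.
#' @export
apply_qc <- function(visits) {
  qc <- qc_pipeline(replicate_pairs(visits))
  key <- function(df) paste(df$participant_id, df$visit_index)
  for (an in c("plasma_nfl", "csf_nfl")) {
    sub <- qc[qc$analyte == an, ]
    visits[[an]] <- sub$final_value[match(key(visits), key(sub))]
    visits[[paste0("log10_", an)]] <- log10_transform(visits[[an]])
  }
  attr(visits, "qc") <- qc
  visits
}
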