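#' Expected age at symptom onset
#'
#' The mutation-specific expected onset age is the arithmetic mean of the
#' reported onset ages across individuals with the same variant. When no
#' variant-level onset information exists, the parental (first-degree
#' relative) onset age is used instead.
#'
#' @param variant_onsets numeric vector of reported onset ages for the
#'   variant (possibly empty).
#' @param parental_onset parental onset age in years, or `NA`.
#' @return expected onset age in years.
#' @examples
#' expected_onset_age(c(43, 47), 50)  # 45
#' expected_onset_age(numeric(0), 50) # 50
#' @export
expected_onset_age <- function(variant_onsets, parental_onset = NA_real_) {
  variant_onsets <- variant_onsets[is.finite(variant_onsets)]
  if (length(variant_onsets) > 0) return(mean(variant_onsets))
  if (length(parental_onset) == 1L && is.finite(parental_onset)) {
    return(parental_onset)
  }
  stop("staging error: no variant-level onset ages and no parental onset age",
       call. = FALSE)
}

#' Estimated years to symptom onset (EYO)
#'
#' EYO is the participant's age at the visit minus the expected onset age;
#' negative values are years before expected onset. It is computed
#' identically for carriers and non-carriers.
#'
#' @param age_at_visit age in years.
#' @param expected_onset expected onset age in years.
#' @return EYO in years.
#' @export
compute_eyo <- function(age_at_visit, expected_onset) {
  age_at_visit - expected_onset
}

#' Classify a participant's clinical stage from longitudinal CDR
#'
#' Non-carriers are labelled `NC`. Carriers with global CDR 0 at every visit
#' are `presymptomatic_MC`; CDR 0 at baseline and > 0 at all subsequent
#' visits is `converter_MC`; CDR > 0 at every visit is `symptomatic_MC`.
#' Any CDR > 0 followed by a later 0 marks a reverter, which is excluded
#' from analyses. A carrier with a single visit is presymptomatic (CDR 0) or
#' symptomatic (CDR > 0); converting requires at least two visits.
#'
#' @param cdr_sequence ordered vector of global CDR scores (0, 0.5, 1, 2, 3).
#' @param mutation_status `"carrier"` or `"noncarrier"`.
#' @return one of `"NC"`, `"presymptomatic_MC"`, `"converter_MC"`,
#'   `"symptomatic_MC"`, `"reverter_excluded"`.
#' @export
classify_stage <- function(cdr_sequence, mutation_status) {
  cdr_sequence <- cdr_sequence[!is.na(cdr_sequence)]
  if (length(cdr_sequence) == 0L) {
    stop("staging error: empty CDR sequence", call. = FALSE)
  }
  pos <- cdr_sequence > 0
  # a CDR > 0 followed by any later 0 implies an adjacent TRUE -> FALSE step
  if (any(diff(pos) < 0)) return("reverter_excluded")
  if (identical(mutation_status, "noncarrier")) return("NC")
  if (!any(pos)) return("presymptomatic_MC")
  if (all(pos)) return("symptomatic_MC")
  # monotone 0 -> >0 switch: converter
  "converter_MC"
}

#' Apply cohort exclusion rules
#'
#' Applies, in order: (`variant_class`) exclusion of participants whose
#' variant is Dutch-type CAA or weakly/non-pathogenic; (`competing_disorder`)
#' exclusion of participants with a competing neurological disorder;
#' (`reverter`) exclusion of carriers whose CDR sequence reverts to 0;
#' (`nc_eyo_gt15`) visit-level removal of non-carrier visits with EYO
#' strictly greater than 15 years (the participant is retained when earlier
#' visits remain). The operation is idempotent and every removal is logged.
#'
#' @param participants participant table (with `eyo` already present in
#'   `visits`).
#' @param visits visit table containing an `eyo` column.
#' @return list with filtered `participants`, `visits`, and `log` (columns
#'   `participant_id`, `visit_index` (`NA` = all visits), `rule_id`).
#' @export
apply_exclusions <- function(participants, visits) {
  if (!"eyo" %in% names(visits)) {
    stop("visits must contain an 'eyo' column; run staging first",
         call. = FALSE)
  }
  log <- data.frame(participant_id = character(0),
                    visit_index = integer(0),
                    rule_id = character(0), stringsAsFactors = FALSE)
  drop_participants <- function(ids, rule) {
    if (length(ids) == 0) return()
    log <<- rbind(log, data.frame(participant_id = ids, visit_index = NA,
                                  rule_id = rule, stringsAsFactors = FALSE))
    participants <<- participants[!participants$participant_id %in% ids, ,
                                  drop = FALSE]
    visits <<- visits[!visits$participant_id %in% ids, , drop = FALSE]
  }

  if ("variant_class" %in% names(participants)) {
    bad <- participants$participant_id[
      !participants$variant_class %in% "pathogenic"]
    drop_participants(bad, "variant_class")
  }
  if ("competing_disorder" %in% names(participants)) {
    drop_participants(
      participants$participant_id[isTRUE_vec(participants$competing_disorder)],
      "competing_disorder")
  }

  # reverters from longitudinal CDR
  if ("cdr_global" %in% names(visits)) {
    ids <- unique(visits$participant_id)
    status <- participants$mutation_status[
      match(ids, participants$participant_id)]
    rev_ids <- ids[vapply(seq_along(ids), function(k) {
      cdr <- visits$cdr_global[visits$participant_id == ids[k]]
      cdr <- cdr[!is.na(cdr)]
      length(cdr) > 0 &&
        classify_stage(cdr, status[k]) == "reverter_excluded"
    }, logical(1))]
    drop_participants(rev_ids, "reverter")
  }

  # NC visits beyond EYO +15 (strict inequality, per visit)
  nc_ids <- participants$participant_id[
    participants$mutation_status == "noncarrier"]
  hit <- visits$participant_id %in% nc_ids & !is.na(visits$eyo) &
    visits$eyo > 15
  if (any(hit)) {
    log <- rbind(log, data.frame(participant_id = visits$participant_id[hit],
                                 visit_index = visits$visit_index[hit],
                                 rule_id = "nc_eyo_gt15",
                                 stringsAsFactors = FALSE))
    visits <- visits[!hit, , drop = FALSE]
    gone <- setdiff(nc_ids, visits$participant_id)
    participants <- participants[!participants$participant_id %in% gone, ,
                                 drop = FALSE]
  }
  rownames(participants) <- rownames(visits) <- NULL
  list(participants = participants, visits = visits, log = log)
}

isTRUE_vec <- function(x) !is.na(x) & x %in% c(TRUE, "TRUE", "true")

#' Stage a cohort: expected onset, EYO, exclusions, clinical labels
#'
#' Convenience wrapper running the full staging pass on raw cohort tables:
#' computes the expected onset age per participant (variant-level mean onset
#' with parental fallback, frozen on the pre-exclusion input), derives EYO
#' for every visit, applies the exclusion rules, and labels every remaining
#' participant's clinical stage from their longitudinal CDR.
#'
#' @param participants participant table as produced by [generate_cohort()].
#' @param visits visit table.
#' @return list with `participants` (plus `expected_onset` and `stage`
#'   columns), `visits` (plus `eyo`), and `exclusion_log`.
#' @export
stage_cohort <- function(participants, visits) {
  onset <- vapply(seq_len(nrow(participants)), function(i) {
    expected_onset_age(participants$variant_reported_onset[i],
                       participants$parental_onset_age[i])
  }, numeric(1))
  participants$expected_onset <- onset
  visits$eyo <- compute_eyo(
    visits$age_at_visit,
    onset[match(visits$participant_id, participants$participant_id)])

  ex <- apply_exclusions(participants, visits)
  participants <- ex$participants
  visits <- ex$visits

  participants$stage <- vapply(seq_len(nrow(participants)), function(i) {
    id <- participants$participant_id[i]
    cdr <- visits$cdr_global[visits$participant_id == id]
    cdr <- cdr[!is.na(cdr)]
    if (length(cdr) == 0) return(NA_character_)
    classify_stage(cdr, participants$mutation_status[i])
  }, character(1))

  list(participants = participants, visits = visits, exclusion_log = ex$log)
}
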