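# Offsets (months relative to index, closed) of the named analysis windows.
WINDOW_OFFSETS <- list(
  index = c(0L, 0L),
  pre_index = c(-6L, 0L),   # the 6-month pre-index period includes the index month
  M10_12 = c(10L, 12L)
)

# Diagnosis claims of the given members restricted to a per-member month
# window, annotated with cough category and disease label.
member_dx_in_window <- function(members, diagnoses, codebooks, offsets) {
  dx <- diagnoses[diagnoses$beneficiary_id %in% members$beneficiary_id]
  idx <- members$index[match(dx$beneficiary_id, members$beneficiary_id)]
  dx <- dx[dx$month >= idx + offsets[1L] & dx$month <= idx + offsets[2L]]
  dx[, category := classify_cough_claim(icd10, standard_name, codebooks)]
  dx[, disease := classify_disease(icd10, codebooks)]
  dx
}

#' Members evaluable at Months 10-12
#'
#' The denominator for all Months 10-12 analyses: members with at least one
#' diagnosis claim in months index+10 .. index+12 carrying either a cough
#' code or a cough-related disease code. Members with only prescription
#' claims in the window are not evaluable. Enrolled members not evaluable at
#' Months 10-12 are regarded as having left the cohort.
#'
#' @param members assignment rows (`beneficiary_id`, `index`), e.g. from
#'   [population_subset()].
#' @param bundle the claims bundle.
#' @param codebooks a [load_codebooks()] object.
#' @return character vector of evaluable beneficiary ids.
#' @export
evaluable_at_m10_12 <- function(members, bundle, codebooks) {
  dx <- member_dx_in_window(members, bundle$diagnoses, codebooks,
                            WINDOW_OFFSETS$M10_12)
  unique(dx$beneficiary_id[!is.na(dx$category) |
                             (!is.na(dx$disease) & dx$disease %in% DISEASE_LABELS)])
}

#' Cough-category counts in an analysis window
#'
#' Counts, per cough category, the members with at least one claim of that
#' category in the window (participant-level counting: claim multiplicity is
#' ignored; categories are not mutually exclusive). For the index window the
#' denominator is the number of enrolled members; for Months 10-12 it is the
#' evaluable members ([evaluable_at_m10_12()]) and counts are restricted to
#' them.
#'
#' @inheritParams evaluable_at_m10_12
#' @param window `"index"` or `"M10_12"`.
#' @return a list with `window`, `denominator`, and `counts` (named integer
#'   vector over the six cough categories).
#' @export
cough_categories_in <- function(members, bundle, codebooks,
                                window = c("index", "M10_12")) {
  window <- match.arg(window)
  if (window == "M10_12") {
    ev <- evaluable_at_m10_12(members, bundle, codebooks)
    members <- members[members$beneficiary_id %in% ev]
  }
  dx <- member_dx_in_window(members, bundle$diagnoses, codebooks,
                            WINDOW_OFFSETS[[window]])
  dx <- dx[!is.na(dx$category)]
  counts <- vapply(COUGH_CATEGORIES, function(cat_) {
    length(unique(dx$beneficiary_id[dx$category == cat_]))
  }, 0L)
  list(window = window, denominator = nrow(members), counts = counts)
}

#' Cough-related disease counts in an analysis window
#'
#' Counts, per cough-related disease, the members with at least one claim of
#' that disease in the window (participant-level; diseases are not mutually
#' exclusive). Windows: `"index"` (the index month), `"pre_index"` (the six
#' months up to and including the index month, denominator = enrolled
#' members) and `"M10_12"` (denominator = evaluable members).
#'
#' @inheritParams evaluable_at_m10_12
#' @param window `"index"`, `"pre_index"` or `"M10_12"`.
#' @return a list with `window`, `denominator`, and `counts` (named integer
#'   vector over the ten disease labels).
#' @export
diseases_in <- function(members, bundle, codebooks,
                        window = c("index", "pre_index", "M10_12")) {
  window <- match.arg(window)
  if (window == "M10_12") {
    ev <- evaluable_at_m10_12(members, bundle, codebooks)
    members <- members[members$beneficiary_id %in% ev]
  }
  dx <- member_dx_in_window(members, bundle$diagnoses, codebooks,
                            WINDOW_OFFSETS[[window]])
  dx <- dx[!is.na(dx$disease) & dx$disease %in% DISEASE_LABELS]
  counts <- vapply(DISEASE_LABELS, function(d) {
    length(unique(dx$beneficiary_id[dx$disease == d]))
  }, 0L)
  list(window = window, denominator = nrow(members), counts = counts)
}

#' Day bounds of a drug-utilisation window
#'
#' The index-month window is the whole index calendar month (prescriptions
#' "for the index month" are month-scoped because the index day within the
#' month is unknown). Post-index time points k = 1, 2, 3, 6, 9, 12 use a
#' four-week window: two weeks before and after an anchor set to day 15 of
#' calendar month index + k.
#'
#' @param index integer index month.
#' @param k `"index"` or an integer month offset >= 1.
#' @return Date vector `c(start, end)`, closed on both ends.
#' @examples
#' medication_window(ym(2018, 5), 1)  # 2018-06-01 .. 2018-06-29
#' @export
medication_window <- function(index, k) {
  if (identical(k, "index")) {
    start <- ym_date(index, 1L)
    end <- ym_date(index + 1L, 1L) - 1L
  } else {
    k <- as.integer(k)
    stopifnot(k >= 1L)
    anchor <- ym_date(index + k, 15L)
    start <- anchor - 14L
    end <- anchor + 14L
  }
  c(start, end)
}

# Distinct (beneficiary_id, class) pairs of prescriptions of the given
# members falling inside the time-point-k window, classes of interest only.
member_classes_in_window <- function(members, prescriptions, codebooks, k) {
  rx <- prescriptions[prescriptions$beneficiary_id %in% members$beneficiary_id]
  if (!nrow(rx)) {
    return(data.table::data.table(beneficiary_id = character(0), class = character(0)))
  }
  rx <- data.table::copy(rx)
  rx[, class := classify_atc(atc, codebooks)]
  rx <- rx[!is.na(class) & class %in% MED_CLASSES_OF_INTEREST]
  idx <- members$index[match(rx$beneficiary_id, members$beneficiary_id)]
  if (identical(k, "index")) {
    keep <- date_ym(rx$date) == idx
  } else {
    anchor <- ym_date(idx + as.integer(k), 15L)
    keep <- rx$date >= anchor - 14L & rx$date <= anchor + 14L
  }
  unique(rx[keep, .(beneficiary_id, class)])
}

#' Medication-class summary at a drug-utilisation time point
#'
#' For the window at time point `k` (see [medication_window()]):
#' the denominator `n` is the number of members with at least one
#' prescription of a medication class of interest in the window (ACE
#' inhibitors are not of interest: their users were excluded upstream).
#' Each class row counts members with that class in the window, split by
#' whether a central antitussive also falls in the same window. Members
#' using an ICS/LABA combination are not counted under other
#' bronchodilators. `antitussive_alone` counts members whose window
#' contains only central antitussives.
#'
#' @inheritParams evaluable_at_m10_12
#' @param k `"index"` or an integer in 1..12.
#' @return a list with `time_point`, `n_enrolled`, `n` (any-medication
#'   denominator), `antitussive_alone`, and `classes`: a data.table
#'   (`class`, `total`, `with_antitussive`, `without_antitussive`).
#' @export
medication_summary <- function(members, bundle, codebooks, k) {
  pairs <- member_classes_in_window(members, bundle$prescriptions, codebooks, k)
  ids <- unique(pairs$beneficiary_id)
  with_ct <- unique(pairs$beneficiary_id[pairs$class == "central_antitussive"])
  n_classes <- if (nrow(pairs)) table(pairs$beneficiary_id) else integer(0)
  alone <- sum(names(n_classes) %in% with_ct & n_classes == 1L)

  ics_ids <- unique(pairs$beneficiary_id[pairs$class == "ICS_LABA"])
  classes <- data.table::rbindlist(lapply(MED_CLASSES_OF_INTEREST, function(cl) {
    users <- unique(pairs$beneficiary_id[pairs$class == cl])
    if (cl == "bronchodilator_other") users <- setdiff(users, ics_ids)
    w <- sum(users %in% with_ct)
    data.table::data.table(class = cl, total = length(users),
                           with_antitussive = w,
                           without_antitussive = length(users) - w)
  }))
  list(time_point = k, n_enrolled = nrow(members), n = length(ids),
       antitussive_alone = alone, classes = classes)
}
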