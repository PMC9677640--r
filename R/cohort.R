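#' Population 1 index month
#'
#' Population 1 is defined by an explicit chronic-cough code: the index month
#' is the earliest selection-period month carrying a diagnosis claim whose
#' (ICD-10, standard name) pair classifies as `CHRONIC`.
#'
#' @param claims diagnosis claims of one beneficiary (columns `month`,
#'   `icd10`, `standard_name`).
#' @param codebooks a [load_codebooks()] object.
#' @param periods a [study_periods()] object.
#' @return integer index month, or `NA` if no selection-period chronic-cough
#'   claim exists.
#' @export
find_pop1_index <- function(claims, codebooks, periods) {
  cat_ <- classify_cough_claim(claims$icd10, claims$standard_name, codebooks)
  m <- claims$month[!is.na(cat_) & cat_ == "CHRONIC" &
                      claims$month >= periods$selection_start &
                      claims$month <= periods$selection_end]
  if (length(m)) min(m) else NA_integer_
}

# Window search over distinct months carrying a Population-2 cough code.
# A window starting at s qualifies when [s, s+2] holds cough codes in >= 2
# distinct months and the post-window [s+3, s+5] holds >= 1; the index is
# the earliest post-window cough month and must fall inside the selection
# period. Candidate starts run from study_start (the first cough diagnosis
# may precede the index by up to six months) in calendar order; the first
# qualifying window wins.
pop2_search <- function(months, periods) {
  months <- sort(unique(months))
  if (length(months) < 3L) return(NULL)
  months <- months[months >= periods$study_start]
  if (length(months) < 3L) return(NULL)
  for (s in seq.int(periods$study_start, periods$selection_end - 3L)) {
    n_eval <- sum(months >= s & months <= s + 2L)
    if (n_eval < 2L) next
    post <- months[months >= s + 3L & months <= s + 5L]
    if (!length(post)) next
    idx <- post[1L]
    if (idx > periods$selection_end) return(NULL)  # only grows with s
    if (idx >= periods$selection_start) {
      # report the first cough diagnosis of the qualifying window as its
      # start: months of [s, s+2] before it carry no cough code, so this
      # only normalises the label (and the subgroup lower bound)
      return(list(index = idx, window_start = min(months[months >= s])))
    }
  }
  NULL
}

#' Population 2 index month and qualifying window
#'
#' Population 2 captures chronic cough coded under other cough types: at
#' least two cough codes in two different months within three consecutive
#' months (the evaluation window), followed by at least one further cough
#' code in the subsequent three months (the post-evaluation window). With
#' month-granular diagnoses this pattern guarantees a cough span exceeding
#' eight weeks. The index month is the earliest post-window month with a
#' cough code and must fall inside the selection period.
#'
#' Candidate evaluation windows are enumerated from the study start (the
#' first cough diagnosis may precede the index by up to six months) and the
#' earliest qualifying window wins; the reported `window_start` is that
#' window's first cough-coded month, i.e. the first diagnosis of cough that
#' opens the qualifying pattern.
#'
#' @inheritParams find_pop1_index
#' @return `NULL`, or a list with `index` (integer month) and `window_start`
#'   (first cough-coded month of the qualifying evaluation window).
#' @export
find_pop2_index <- function(claims, codebooks, periods) {
  cat_ <- classify_cough_claim(claims$icd10, claims$standard_name, codebooks)
  m <- claims$month[!is.na(cat_) & cat_ %in% P2_CATEGORIES]
  pop2_search(m, periods)
}

#' Eligibility screening at a candidate index month
#'
#' Applies the non-phenotype eligibility rules: age at index >= 20 years
#' (age is the floor of whole years between birth month and index month,
#' the finest resolution the data permit); no ACE-inhibitor prescription
#' (ATC C9A/C9B) anywhere in the study period, since ACE inhibitors cause
#' drug-induced cough; no organic respiratory disease or cancer code
#' anywhere in the study period; a database history of at least six months
#' before the index (proxied by first-ever claim month, as enrolment spells
#' are not recorded); and at least one claim of any kind in the twelve
#' post-index months.
#'
#' @param beneficiary one-row data.frame with `id`, `birth`, `gender`.
#' @param claims this beneficiary's diagnosis claims.
#' @param prescriptions this beneficiary's prescription claims.
#' @param index candidate index month (integer).
#' @param codebooks a [load_codebooks()] object.
#' @param periods a [study_periods()] object.
#' @return character vector of exclusion reasons (empty when eligible),
#'   a subset of `under_20`, `ace_inhibitor`,
#'   `organic_respiratory_or_cancer`, `insufficient_history`,
#'   `no_postindex_claim`.
#' @export
screen_eligibility <- function(beneficiary, claims, prescriptions, index,
                               codebooks, periods) {
  reasons <- character(0)
  if ((index - beneficiary$birth) %/% 12L < 20L) reasons <- c(reasons, "under_20")
  if (nrow(prescriptions)) {
    cls <- classify_atc(prescriptions$atc, codebooks)
    if (any(!is.na(cls) & cls == "ACE_inhibitor")) {
      reasons <- c(reasons, "ace_inhibitor")
    }
  }
  if (nrow(claims)) {
    lab <- classify_disease(claims$icd10, codebooks)
    if (any(!is.na(lab) & lab %in% EXCL_LABELS)) {
      reasons <- c(reasons, "organic_respiratory_or_cancer")
    }
  }
  first_claim <- suppressWarnings(min(
    c(claims$month, if (nrow(prescriptions)) date_ym(prescriptions$date))
  ))
  if (!is.finite(first_claim) || first_claim > index - 6L) {
    reasons <- c(reasons, "insufficient_history")
  }
  post <- c(claims$month, if (nrow(prescriptions)) date_ym(prescriptions$date))
  if (!any(post >= index + 1L & post <= index + 12L)) {
    reasons <- c(reasons, "no_postindex_claim")
  }
  reasons
}

#' Population 2 cough subtype subgroups
#'
#' A Population 2 member is assigned every cough category documented between
#' the start of the qualifying evaluation window and the index month
#' inclusive (so subgroups are not mutually exclusive). With
#' `subgroup_end = "post_window"` the bound is instead the end of the
#' post-evaluation window (`window_start + 5`), an alternative reading of
#' the subtype definition retained as a switch.
#'
#' @inheritParams find_pop1_index
#' @param window_start first month of the qualifying evaluation window.
#' @param index index month.
#' @param subgroup_end `"index"` (default) or `"post_window"`.
#' @return character vector of categories, a non-empty subset of
#'   `INFECTION`, `ATOPIC_ALLERGIC`, `CVA`, `POSTINFECTIOUS`, `OTHER`.
#' @export
assign_subgroups <- function(claims, codebooks, window_start, index,
                             subgroup_end = c("index", "post_window")) {
  subgroup_end <- match.arg(subgroup_end)
  hi <- if (subgroup_end == "index") index else window_start + 5L
  cat_ <- classify_cough_claim(claims$icd10, claims$standard_name, codebooks)
  keep <- !is.na(cat_) & cat_ %in% P2_CATEGORIES &
    claims$month >= window_start & claims$month <= hi
  sort(unique(cat_[keep]))
}

# Facility size where the member was seen at index: mode over index-month
# diagnosis claims, ties broken toward the larger category, none -> unknown.
facility_at_index <- function(fac) {
  fac <- fac[!is.na(fac) & fac != "unknown"]
  if (!length(fac)) return("unknown")
  sizes <- c("beds_1_19", "beds_20_199", "beds_200_plus")
  tab <- table(factor(fac, levels = sizes))
  sizes[max(which(tab == max(tab)))]
}

#' Build the chronic-cough cohort
#'
#' Runs the full two-population identification over a claims bundle:
#' classifies every diagnosis claim, derives a Population 1 index (earliest
#' selection-period chronic-cough claim) or, failing that, a Population 2
#' index (repeated cough codes over more than eight weeks; see
#' [find_pop2_index()]), screens eligibility, and assigns Population 2
#' subgroups. A beneficiary eligible for both populations is assigned to
#' Population 1, making the populations mutually exclusive.
#'
#' @param bundle a claims bundle ([read_claims()] / [claims_bundle()]).
#' @param codebooks a [load_codebooks()] object.
#' @param periods a [study_periods()] object.
#' @param subgroup_end see [assign_subgroups()].
#' @return a list of class `"cohort"`:
#'   \describe{
#'     \item{assignments}{data.table with one row per enrolled member:
#'       `beneficiary_id`, `population` ("P1"/"P2"), `index`,
#'       `window_start` (NA for P1), `subgroups` (comma-joined, "" for P1),
#'       `age_at_index`, `gender`, `facility_size`.}
#'     \item{exclusions}{data.table `beneficiary_id`, `reasons`
#'       (comma-joined) for beneficiaries with a selection-period cough claim
#'       who were not enrolled (`no_qualifying_cough` when no index exists).}
#'     \item{flow}{named integer vector of attrition steps: beneficiaries
#'       with any claim, adults with a selection-period claim, of whom with a
#'       cough code, of whom meeting the phenotype + age criteria, excluded
#'       by the other eligibility rules, and enrolled.}
#'   }
#' @export
build_cohort <- function(bundle, codebooks, periods,
                         subgroup_end = c("index", "post_window")) {
  subgroup_end <- match.arg(subgroup_end)
  ben <- bundle$beneficiaries
  dx <- data.table::copy(bundle$diagnoses)
  rx <- bundle$prescriptions

  dx[, category := classify_cough_claim(icd10, standard_name, codebooks)]
  dx[, disease := classify_disease(icd10, codebooks)]
  rx_month <- if (nrow(rx)) date_ym(rx$date) else integer(0)
  rx_class <- if (nrow(rx)) classify_atc(rx$atc, codebooks) else character(0)

  in_sel <- function(m) m >= periods$selection_start & m <= periods$selection_end

  # ---- flow steps -------------------------------------------------------
  ids_any <- unique(c(dx$beneficiary_id, rx$beneficiary_id))
  sel_ids <- unique(c(dx$beneficiary_id[in_sel(dx$month)],
                      rx$beneficiary_id[in_sel(rx_month)]))
  # age >= 20 by the end of the selection period
  adult <- ben$id[(periods$selection_end - ben$birth) %/% 12L >= 20L]
  ids_adult_sel <- intersect(sel_ids, adult)
  cough_sel_ids <- unique(dx$beneficiary_id[!is.na(dx$category) & in_sel(dx$month)])
  ids_cough <- intersect(ids_adult_sel, cough_sel_ids)

  # ---- candidate indices ------------------------------------------------
  # Population 1: earliest selection-period CHRONIC claim per beneficiary.
  p1_claims <- dx[!is.na(category) & category == "CHRONIC" & in_sel(month)]
  p1 <- if (nrow(p1_claims)) {
    p1_claims[, .(index = min(month)), by = beneficiary_id]
  } else {
    data.table::data.table(beneficiary_id = character(0), index = integer(0))
  }

  # Population 2: window search over distinct cough months, only for
  # beneficiaries without a P1 index.
  p2_claims <- dx[!is.na(category) & category %in% P2_CATEGORIES &
                    !beneficiary_id %in% p1$beneficiary_id]
  p2_months <- split(p2_claims$month, p2_claims$beneficiary_id)
  p2_hits <- lapply(p2_months, pop2_search, periods = periods)
  p2_ok <- !vapply(p2_hits, is.null, TRUE)
  p2 <- data.table::data.table(
    beneficiary_id = names(p2_hits)[p2_ok],
    index = vapply(p2_hits[p2_ok], `[[`, 0L, "index"),
    window_start = vapply(p2_hits[p2_ok], `[[`, 0L, "window_start")
  )

  cand <- data.table::rbindlist(list(
    data.table::data.table(beneficiary_id = p1$beneficiary_id, population = "P1",
                           index = p1$index, window_start = NA_integer_),
    data.table::data.table(beneficiary_id = p2$beneficiary_id, population = "P2",
                           index = p2$index, window_start = p2$window_start)
  ))

  # ---- vectorised screening --------------------------------------------
  birth <- ben$birth[match(cand$beneficiary_id, ben$id)]
  under_20 <- (cand$index - birth) %/% 12L < 20L

  ace_ids <- unique(rx$beneficiary_id[!is.na(rx_class) & rx_class == "ACE_inhibitor"])
  excl_ids <- unique(dx$beneficiary_id[!is.na(dx$disease) & dx$disease %in% EXCL_LABELS])

  all_claim_months <- data.table::rbindlist(list(
    dx[, .(beneficiary_id, month)],
    if (nrow(rx)) data.table::data.table(beneficiary_id = rx$beneficiary_id,
                                         month = rx_month)
  ))
  first_claim <- if (nrow(all_claim_months)) {
    all_claim_months[, .(first = min(month)), by = beneficiary_id]
  } else {
    data.table::data.table(beneficiary_id = character(0), first = integer(0))
  }
  cand_first <- first_claim$first[match(cand$beneficiary_id, first_claim$beneficiary_id)]
  insufficient <- is.na(cand_first) | cand_first > cand$index - 6L

  cm <- all_claim_months[cand, on = "beneficiary_id", allow.cartesian = TRUE]
  post_ids <- unique(cm[month >= index + 1L & month <= index + 12L]$beneficiary_id)

  reasons <- mapply(function(id, u20, ins) {
    r <- character(0)
    if (u20) r <- c(r, "under_20")
    if (id %in% ace_ids) r <- c(r, "ace_inhibitor")
    if (id %in% excl_ids) r <- c(r, "organic_respiratory_or_cancer")
    if (ins) r <- c(r, "insufficient_history")
    if (!id %in% post_ids) r <- c(r, "no_postindex_claim")
    r
  }, cand$beneficiary_id, under_20, insufficient, SIMPLIFY = FALSE)
  excluded <- lengths(reasons) > 0L

  n_criteria_met <- sum(!under_20)
  other_reason <- vapply(reasons, function(r) length(setdiff(r, "under_20")) > 0L, TRUE)
  n_excluded_other <- sum(!under_20 & other_reason)

  # ---- assignments ------------------------------------------------------
  keep <- which(!excluded)
  asg <- cand[keep]
  asg[, age_at_index := (index - ben$birth[match(beneficiary_id, ben$id)]) %/% 12L]
  asg[, gender := ben$gender[match(beneficiary_id, ben$id)]]

  idx_fac <- dx[asg[, .(beneficiary_id, index)], on = c("beneficiary_id", month = "index"),
                nomatch = NULL][, .(facility_size = facility_at_index(facility_size)),
                                by = beneficiary_id]
  asg[, facility_size := idx_fac$facility_size[match(beneficiary_id, idx_fac$beneficiary_id)]]
  asg[is.na(facility_size), facility_size := "unknown"]

  asg[, subgroups := ""]
  if (any(asg$population == "P2")) {
    p2_rows <- which(asg$population == "P2")
    dx_split <- split(dx[beneficiary_id %in% asg$beneficiary_id[p2_rows]],
                      by = "beneficiary_id")
    asg$subgroups[p2_rows] <- vapply(p2_rows, function(i) {
      cl <- dx_split[[asg$beneficiary_id[i]]]
      paste(assign_subgroups(cl, codebooks, asg$window_start[i], asg$index[i],
                             subgroup_end), collapse = ",")
    }, "")
  }
  data.table::setorder(asg, beneficiary_id)

  # ---- exclusion reports -----------------------------------------------
  excl_dt <- data.table::rbindlist(list(
    data.table::data.table(
      beneficiary_id = cand$beneficiary_id[excluded],
      reasons = vapply(reasons[excluded], paste, "", collapse = ",")
    ),
    data.table::data.table(
      beneficiary_id = setdiff(ids_cough, cand$beneficiary_id),
      reasons = "no_qualifying_cough"
    )
  ))
  data.table::setorder(excl_dt, beneficiary_id)

  flow <- c(
    any_claim = length(ids_any),
    adults_selection_claim = length(ids_adult_sel),
    cough_code_selection = length(ids_cough),
    criteria_met = n_criteria_met,
    excluded_other = n_excluded_other,
    enrolled = nrow(asg)
  )

  structure(list(assignments = asg[], exclusions = excl_dt, flow = flow),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n1 <- sum(x$assignments$population == "P1")
  n2 <- sum(x$assignments$population == "P2")
  cat(sprintf("cohort: %d enrolled (P1 %d, P2 %d), %d exclusion reports\n",
              nrow(x$assignments), n1, n2, nrow(x$exclusions)))
  invisible(x)
}

#' Members of an analysis population
#'
#' The analyses report six populations: everyone (`"All"`), Population 1,
#' Population 2, and the Population 2 cough subtype subgroups (by category
#' name). Subgroups are not mutually exclusive.
#'
#' @param cohort a [build_cohort()] result.
#' @param population `"All"`, `"P1"`, `"P2"`, or a Population 2 category
#'   name (e.g. `"CVA"`).
#' @return the matching rows of `cohort$assignments`.
#' @export
population_subset <- function(cohort, population) {
  a <- cohort$assignments
  pop <- population  # local copy: `population` is also a column of `a`
  if (pop == "All") return(a)
  if (pop %in% c("P1", "P2")) {
    sel <- a$population == pop
  } else if (pop %in% P2_CATEGORIES) {
    sel <- vapply(strsplit(a$subgroups, ",", fixed = TRUE),
                  function(s) pop %in% s, TRUE)
  } else {
    stop("unknown population: ", pop, call. = FALSE)
  }
  a[which(sel)]
}
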