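#' Percentage with half-up rounding to one decimal
#'
#' All reported proportions are percentages rounded half-up to one decimal
#' (so 470/1284 prints as 36.6). A zero denominator yields `NA` rather than
#' an error, matching the use of an undefined marker in sparse subgroup
#' cells.
#'
#' @param count,denominator numeric vectors.
#' @return numeric vector of percentages.
#' @examples
#' percent(194, 4860)  # 4.0
#' @export
percent <- function(count, denominator) {
  out <- rep(NA_real_, length(count))
  ok <- denominator > 0
  # half-up at the third significant position of count/denom*1000; the tiny
  # epsilon guards against binary representation of exact halves
  out[ok] <- floor(count[ok] / denominator[ok] * 1000 + 0.5 + 1e-9) / 10
  out
}

fmt_count_pct <- function(count, denominator) {
  p <- percent(count, denominator)
  ifelse(is.na(p), sprintf("%d (-)", count), sprintf("%d (%.1f%%)", count, p))
}

#' Participant-flow reconciliation
#'
#' Given an initial count and the number excluded at each successive step,
#' returns the remaining count after each step. Remainders must stay
#' non-negative or the step counts are inconsistent.
#'
#' @param initial starting count.
#' @param excluded named integer vector of per-step exclusion counts.
#' @return named integer vector of remainders after each step.
#' @examples
#' flow_reconciliation(12467, c(other_eligibility = 6429))  # 6038
#' @export
flow_reconciliation <- function(initial, excluded) {
  remaining <- initial - cumsum(excluded)
  if (any(remaining < 0)) {
    stop("flow inconsistency: more participants excluded than remaining",
         call. = FALSE)
  }
  remaining
}

#' Persistence partition from per-member code sets
#'
#' Classifies each Months 10-12 evaluable member by priority: members whose
#' window contains their original cough category code retain it
#' (`retained_original`); otherwise any other cough category code counts as
#' `other_cough`; otherwise the member is evaluable through a cough-related
#' disease code only (`disease_only`). Enrolled members not evaluable at
#' Months 10-12 have `left_cohort`. The four counts partition the enrolled
#' population exactly.
#'
#' @param enrolled number of enrolled members.
#' @param member_categories list of character vectors: the cough categories
#'   coded in Months 10-12 for each evaluable member (possibly empty for
#'   disease-only members).
#' @param original_category the cohort-defining category (`"CHRONIC"` for
#'   Population 1, the subgroup category for a subgroup).
#' @return a list with `enrolled`, `evaluable`, `retained_original`,
#'   `other_cough`, `disease_only`, `left_cohort`.
#' @export
persistence_from_codes <- function(enrolled, member_categories, original_category) {
  enrolled <- as.integer(enrolled)
  evaluable <- length(member_categories)
  stopifnot(evaluable <= enrolled)
  retained <- vapply(member_categories, function(s) original_category %in% s, TRUE)
  other <- !retained & lengths(member_categories) > 0L
  list(
    enrolled = enrolled,
    evaluable = evaluable,
    retained_original = sum(retained),
    other_cough = sum(other),
    disease_only = evaluable - sum(retained) - sum(other),
    left_cohort = enrolled - evaluable
  )
}

#' Persistence of the cohort-defining cough code at Months 10-12
#'
#' Computes the [persistence_from_codes()] partition for a population or
#' subgroup directly from claims: evaluability and per-member Months 10-12
#' cough category sets are derived from the diagnosis claims.
#'
#' @inheritParams evaluable_at_m10_12
#' @param original_category see [persistence_from_codes()].
#' @export
persistence_partition <- function(members, bundle, codebooks, original_category) {
  ev <- evaluable_at_m10_12(members, bundle, codebooks)
  mem_ev <- members[members$beneficiary_id %in% ev]
  dx <- member_dx_in_window(mem_ev, bundle$diagnoses, codebooks,
                            WINDOW_OFFSETS$M10_12)
  dx <- dx[!is.na(dx$category)]
  sets <- lapply(mem_ev$beneficiary_id, function(id) {
    unique(dx$category[dx$beneficiary_id == id])
  })
  persistence_from_codes(nrow(members), sets, original_category)
}

# Display order and labels used in the emitted tables.
CATEGORY_LABELS <- c(
  CHRONIC = "Chronic cough", INFECTION = "Cough associated with infection",
  ATOPIC_ALLERGIC = "Atopic/allergic cough", CVA = "Cough-variant asthma",
  POSTINFECTIOUS = "Postinfectious cough", OTHER = "Other coughs"
)

# Top Population 2 subgroups by member count (largest first).
top_subgroups <- function(cohort, n_top = 3L) {
  p2 <- cohort$assignments[cohort$assignments$population == "P2"]
  counts <- vapply(P2_CATEGORIES, function(cat_) {
    sum(vapply(strsplit(p2$subgroups, ",", fixed = TRUE),
               function(s) cat_ %in% s, TRUE))
  }, 0L)
  names(sort(counts, decreasing = TRUE))[seq_len(min(n_top, sum(counts > 0)))]
}

long_rows <- function(table, population, label, count, denominator, flag = NA) {
  data.table::data.table(
    table = table, population = population, label = label,
    count = as.integer(count), denominator = as.integer(denominator),
    pct = percent(count, denominator),
    display = fmt_count_pct(count, denominator),
    flag = flag
  )
}

#' Assemble the analysis tables and figure series
#'
#' Builds the study's descriptive outputs over the six analysis populations
#' (All, Population 1, Population 2, and the three largest Population 2
#' subgroups): participant flow; cough diagnoses during the index month
#' (T2); participant characteristics and cough-related diseases at index
#' (T3); cough diagnoses at Months 10-12 over the evaluable denominator
#' (T4); cough-related diseases pre-index versus Months 10-12, flagging
#' rows whose proportion changes by more than 5 percentage points (T5);
#' index-month medication classes split by central-antitussive
#' co-prescription (T6); central antitussives alone by time point (T7); the
#' per-class antitussive-combination proportion at index versus Month 12
#' (fig3); and per-class medication share per time point (fig4). Every
#' printed percentage recomputes from the count and denominator carried on
#' its row. Statistics are purely descriptive (counts, proportions, mean and
#' SD, median and IQR); no hypothesis tests are computed.
#'
#' @param cohort a [build_cohort()] result.
#' @param bundle the claims bundle.
#' @param codebooks a [load_codebooks()] object.
#' @param time_points drug-utilisation time points (months after index) in
#'   addition to the index month.
#' @return a named list of data.tables (`flow`, `T2` .. `T7`, `fig3`,
#'   `fig4`, `characteristics`), each in long format with columns `table`,
#'   `population`, `label`, `count`, `denominator`, `pct`, `display`,
#'   `flag`.
#' @export
build_tables <- function(cohort, bundle, codebooks,
                         time_points = c(1L, 2L, 3L, 6L, 9L, 12L)) {
  pops <- c("All", "P1", "P2", top_subgroups(cohort))
  pop_members <- lapply(pops, population_subset, cohort = cohort)
  names(pop_members) <- pops

  flow_excl <- c(
    no_selection_claim_or_minor = unname(cohort$flow["any_claim"] -
                                           cohort$flow["adults_selection_claim"]),
    no_cough_code = unname(cohort$flow["adults_selection_claim"] -
                             cohort$flow["cough_code_selection"]),
    criteria_not_met = unname(cohort$flow["cough_code_selection"] -
                                cohort$flow["criteria_met"]),
    other_eligibility = unname(cohort$flow["excluded_other"])
  )
  remaining <- flow_reconciliation(unname(cohort$flow["any_claim"]), flow_excl)
  flow_dt <- data.table::data.table(
    table = "flow",
    step = c("any_claim", names(flow_excl)),
    excluded = c(NA_integer_, as.integer(flow_excl)),
    remaining = as.integer(c(cohort$flow["any_claim"], remaining))
  )
  if (utils::tail(remaining, 1L) != cohort$flow[["enrolled"]]) {
    stop("flow reconciliation does not match enrolled cohort size", call. = FALSE)
  }

  tab <- function(f) data.table::rbindlist(lapply(pops, f), fill = TRUE)

  t2 <- tab(function(p) {
    s <- cough_categories_in(pop_members[[p]], bundle, codebooks, "index")
    long_rows("T2", p, CATEGORY_LABELS, s$counts[names(CATEGORY_LABELS)],
              s$denominator)
  })

  chars <- data.table::rbindlist(lapply(pops, function(p) {
    m <- pop_members[[p]]
    fac_known <- m$facility_size[m$facility_size != "unknown"]
    data.table::data.table(
      table = "characteristics", population = p, n = nrow(m),
      age_mean = mean(m$age_at_index), age_sd = stats::sd(m$age_at_index),
      age_median = stats::median(as.numeric(m$age_at_index)),
      age_q1 = unname(stats::quantile(as.numeric(m$age_at_index), 0.25)),
      age_q3 = unname(stats::quantile(as.numeric(m$age_at_index), 0.75)),
      n_60_plus = sum(m$age_at_index >= 60L),
      n_women = sum(m$gender == "female"),
      n_men = sum(m$gender == "male"),
      facility_denominator = length(fac_known),
      beds_1_19 = sum(fac_known == "beds_1_19"),
      beds_20_199 = sum(fac_known == "beds_20_199"),
      beds_200_plus = sum(fac_known == "beds_200_plus")
    )
  }))

  t3 <- tab(function(p) {
    s <- diseases_in(pop_members[[p]], bundle, codebooks, "index")
    long_rows("T3", p, DISEASE_LABELS, s$counts[DISEASE_LABELS], s$denominator)
  })

  t4 <- tab(function(p) {
    s <- cough_categories_in(pop_members[[p]], bundle, codebooks, "M10_12")
    long_rows("T4", p, CATEGORY_LABELS, s$counts[names(CATEGORY_LABELS)],
              s$denominator)
  })

  t5 <- tab(function(p) {
    pre <- diseases_in(pop_members[[p]], bundle, codebooks, "pre_index")
    m10 <- diseases_in(pop_members[[p]], bundle, codebooks, "M10_12")
    pre_rows <- long_rows("T5", p, paste0(DISEASE_LABELS, " (pre-index)"),
                          pre$counts[DISEASE_LABELS], pre$denominator)
    m10_rows <- long_rows("T5", p, paste0(DISEASE_LABELS, " (M10-12)"),
                          m10$counts[DISEASE_LABELS], m10$denominator)
    # flag a disease when the proportion moves by more than 5 points
    delta <- abs(percent(pre$counts[DISEASE_LABELS], pre$denominator) -
                   percent(m10$counts[DISEASE_LABELS], m10$denominator))
    flagged <- !is.na(delta) & delta > 5
    pre_rows$flag <- flagged
    m10_rows$flag <- flagged
    rbind(pre_rows, m10_rows)
  })

  med_index <- lapply(pop_members, medication_summary, bundle = bundle,
                      codebooks = codebooks, k = "index")
  t6 <- tab(function(p) {
    s <- med_index[[p]]
    cl <- s$classes[s$classes$class != "central_antitussive"]
    rbind(
      long_rows("T6", p, "Any medication of interest", s$n, s$n_enrolled),
      long_rows("T6", p, "Central antitussives only", s$antitussive_alone, s$n),
      long_rows("T6", p, paste0(cl$class, " (all)"), cl$total, s$n),
      long_rows("T6", p, paste0(cl$class, " (without central antitussives)"),
                cl$without_antitussive, s$n),
      long_rows("T6", p, paste0(cl$class, " (with central antitussives)"),
                cl$with_antitussive, s$n)
    )
  })

  med_tp <- lapply(time_points, function(k) {
    lapply(pop_members, medication_summary, bundle = bundle,
           codebooks = codebooks, k = k)
  })
  names(med_tp) <- paste0("M", time_points)
  all_tp <- c(list(index = med_index), med_tp)

  t7 <- data.table::rbindlist(lapply(names(all_tp), function(tp) {
    tab(function(p) {
      s <- all_tp[[tp]][[p]]
      long_rows("T7", p, paste0("Central antitussives only (", tp, ")"),
                s$antitussive_alone, s$n)
    })
  }))

  last_tp <- names(all_tp)[length(all_tp)]
  fig3 <- tab(function(p) {
    rbind_pts <- lapply(c("index", last_tp), function(tp) {
      s <- all_tp[[tp]][[p]]
      cl <- s$classes[s$classes$class != "central_antitussive"]
      long_rows("fig3", p, paste0(cl$class, " (", tp, ")"),
                cl$with_antitussive, cl$total)
    })
    data.table::rbindlist(rbind_pts)
  })

  fig4 <- data.table::rbindlist(lapply(names(all_tp), function(tp) {
    tab(function(p) {
      s <- all_tp[[tp]][[p]]
      long_rows("fig4", p, paste0(s$classes$class, " (", tp, ")"),
                s$classes$total, s$n)
    })
  }))

  list(flow = flow_dt, T2 = t2, characteristics = chars, T3 = t3, T4 = t4,
       T5 = t5, T6 = t6, T7 = t7, fig3 = fig3, fig4 = fig4)
}

#' Write tables to disk
#'
#' @param tables a [build_tables()] result.
#' @param dir output directory.
#' @param format `"tsv"` (one file per table) or `"json"` (one file).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(tables, dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "tsv") {
    for (nm in names(tables)) {
      data.table::fwrite(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE)
    }
  } else {
    jsonlite::write_json(tables, file.path(dir, "tables.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
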