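cb <- default_cb
p <- default_periods

# Enrolled two-member cohort used across window tests: M1 is P1 (index
# 2018-03), M2 is P2 (index 2018-04).
two_member_cohort <- function(extra_dx = NULL, extra_rx = NULL) {
  dx <- rbind(
    dx_row("M1", "2017-08", "J30.4", "arni"),
    dx_row("M1", "2018-03", "R05", "chronic cough"),
    dx_row("M1", "2018-07", "J30.4", "arni"),
    dx_row("M2", "2017-08", "J30.4", "arni"),
    dx_row("M2", "2018-01", "R05", "cough"),
    dx_row("M2", "2018-02", "R05", "cough"),
    dx_row("M2", "2018-04", "R05", "cough"),
    dx_row("M2", "2018-08", "J30.4", "arni"),
    extra_dx
  )
  rx <- rbind(empty_rx(), extra_rx)
  bundle <- claims_bundle(ben_row(c("M1", "M2")), dx, rx)
  list(bundle = bundle, cohort = build_cohort(bundle, cb, p))
}

test_that("evaluability at Months 10-12 requires a diagnosis code", {
  # M1 (index 2018-03): ARNI claim at index+11 makes it evaluable;
  # M2 (index 2018-04): only a prescription in the window does not
  tc <- two_member_cohort(
    extra_dx = dx_row("M1", "2019-02", "J30.4", "arni"),
    extra_rx = rx_row("M2", "2019-03-10", "R05CB01")
  )
  ev <- evaluable_at_m10_12(tc$cohort$assignments, tc$bundle, cb)
  expect_identical(ev, "M1")
  # a cough code in the window also evaluates
  tc2 <- two_member_cohort(extra_dx = dx_row("M2", "2019-02", "R05", "dry cough"))
  expect_setequal(evaluable_at_m10_12(tc2$cohort$assignments, tc2$bundle, cb),
                  "M2")
})

test_that("cough categories count members once per category per window", {
  tc <- two_member_cohort()
  s <- cough_categories_in(tc$cohort$assignments, tc$bundle, cb, "index")
  expect_identical(s$denominator, 2L)
  expect_identical(unname(s$counts["CHRONIC"]), 1L)  # M1 at index
  expect_identical(unname(s$counts["OTHER"]), 1L)    # M2 at index
  # a P2 member is never counted under chronic cough at index
  p1 <- population_subset(tc$cohort, "P2")
  s2 <- cough_categories_in(p1, tc$bundle, cb, "index")
  expect_identical(unname(s2$counts["CHRONIC"]), 0L)
})

test_that("disease windows separate index, pre-index and Months 10-12", {
  # GERD three months before index counts pre-index but not at index;
  # duplicated ARNI claims in one window count the member once
  tc <- two_member_cohort(extra_dx = rbind(
    dx_row("M1", "2017-12", "K21.0", "gerd"),
    dx_row("M1", "2018-03", "J30.4", "arni"),
    dx_row("M1", "2018-03", "J30.9", "arni again")
  ))
  at_index <- diseases_in(tc$cohort$assignments, tc$bundle, cb, "index")
  pre <- diseases_in(tc$cohort$assignments, tc$bundle, cb, "pre_index")
  expect_identical(unname(at_index$counts["GERD"]), 0L)
  expect_identical(unname(pre$counts["GERD"]), 1L)
  expect_identical(unname(at_index$counts["ARNI"]), 1L)
  expect_identical(pre$denominator, 2L)
})

test_that("window extraction equals a per-member brute-force recount", {
  sim <- simulate_claims(sim_config(n_beneficiaries = 1200, seed = 31,
                                    planted = c(p1 = 40L, p2 = 25L)))
  co <- build_cohort(sim$bundle, cb, p)
  a <- co$assignments
  dx <- as.data.frame(sim$bundle$diagnoses)
  dx$category <- classify_cough_claim(dx$icd10, dx$standard_name, cb)
  dx$disease <- classify_disease(dx$icd10, cb)

  recount <- function(ids, idx, lo, hi, col, val) {
    sum(vapply(seq_along(ids), function(i) {
      rows <- dx$beneficiary_id == ids[i] & dx$month >= idx[i] + lo &
        dx$month <= idx[i] + hi
      any(rows & !is.na(dx[[col]]) & dx[[col]] == val)
    }, TRUE))
  }

  s <- cough_categories_in(a, sim$bundle, cb, "index")
  for (cat_ in names(s$counts)) {
    expect_identical(unname(s$counts[cat_]),
                     recount(a$beneficiary_id, a$index, 0L, 0L, "category", cat_),
                     info = cat_)
  }
  d <- diseases_in(a, sim$bundle, cb, "pre_index")
  for (dd in c("ARNI", "asthma", "GERD")) {
    expect_identical(unname(d$counts[dd]),
                     recount(a$beneficiary_id, a$index, -6L, 0L, "disease", dd),
                     info = dd)
  }
  # M10-12 with the evaluable denominator
  ev <- evaluable_at_m10_12(a, sim$bundle, cb)
  ev_naive <- a$beneficiary_id[vapply(seq_len(nrow(a)), function(i) {
    rows <- dx$beneficiary_id == a$beneficiary_id[i] &
      dx$month >= a$index[i] + 10L & dx$month <= a$index[i] + 12L
    any(rows & (!is.na(dx$category) |
                  (!is.na(dx$disease) & !startsWith(dx$disease, "EXCL"))))
  }, TRUE)]
  expect_setequal(ev, ev_naive)
  s10 <- cough_categories_in(a, sim$bundle, cb, "M10_12")
  expect_identical(s10$denominator, length(ev_naive))
})

test_that("drug windows are four weeks around day 15, whole month at index", {
  # index month 2018-05, time point k = 1 -> anchor 2018-06-15
  w <- medication_window(ym(2018, 5), 1)
  expect_identical(w, as.Date(c("2018-06-01", "2018-06-29")))
  expect_true(as.Date("2018-06-02") >= w[1])        # 13 days before anchor
  expect_false(as.Date("2018-05-30") >= w[1])       # 16 days before anchor
  wi <- medication_window(ym(2018, 5), "index")
  expect_identical(wi, as.Date(c("2018-05-01", "2018-05-31")))
})

test_that("medication summaries split classes by antitussive co-prescription", {
  tc <- two_member_cohort(extra_rx = rbind(
    rx_row("M1", "2018-03-05", "R05CB01"),   # expectorant, index month
    rx_row("M1", "2018-03-20", "R05DA09"),   # central antitussive, same window
    rx_row("M2", "2018-04-10", "R05DA09")    # antitussive only
  ))
  s <- medication_summary(tc$cohort$assignments, tc$bundle, cb, "index")
  expect_identical(s$n, 2L)
  cl <- as.data.frame(s$classes)
  exp_row <- cl[cl$class == "expectorant", ]
  expect_identical(exp_row$total, 1L)
  expect_identical(exp_row$with_antitussive, 1L)
  expect_identical(exp_row$without_antitussive, 0L)
  # M2's window holds only a central antitussive
  expect_identical(s$antitussive_alone, 1L)
  # M1 is not antitussive-alone despite having an antitussive
  expect_true(all(cl$with_antitussive + cl$without_antitussive == cl$total))
})

test_that("ICS/LABA users are not counted among other bronchodilators", {
  tc <- two_member_cohort(extra_rx = rbind(
    rx_row("M1", "2018-03-05", "R03AK06"),   # ICS/LABA
    rx_row("M1", "2018-03-06", "R03AC02"),   # plain bronchodilator
    rx_row("M2", "2018-04-10", "R03AC02")
  ))
  s <- medication_summary(tc$cohort$assignments, tc$bundle, cb, "index")
  cl <- as.data.frame(s$classes)
  expect_identical(cl$total[cl$class == "ICS_LABA"], 1L)
  expect_identical(cl$total[cl$class == "bronchodilator_other"], 1L)  # M2 only
})

test_that("index-month capture is calendar-scoped; day windows are not", {
  tc <- two_member_cohort(extra_rx = rx_row("M1", "2018-03-30", "R05CB01"))
  s0 <- medication_summary(tc$cohort$assignments, tc$bundle, cb, "index")
  # shifting all prescriptions by one day keeps them inside the calendar month
  shift <- data.table::copy(tc$bundle$prescriptions)
  shift$date <- shift$date + 1L
  b2 <- claims_bundle(tc$bundle$beneficiaries, tc$bundle$diagnoses, shift)
  s1 <- medication_summary(tc$cohort$assignments, b2, cb, "index")
  expect_identical(s0$classes, s1$classes)

  # a +/-14-day window is day-sensitive at its boundary: anchor for M1 at
  # k = 1 is 2018-04-15, so 2018-04-29 is inside but 2018-04-30 is not
  tcb <- two_member_cohort(extra_rx = rx_row("M1", "2018-04-29", "R05CB01"))
  sb0 <- medication_summary(tcb$cohort$assignments, tcb$bundle, cb, 1)
  shiftb <- data.table::copy(tcb$bundle$prescriptions)
  shiftb$date <- shiftb$date + 1L
  bb2 <- claims_bundle(tcb$bundle$beneficiaries, tcb$bundle$diagnoses, shiftb)
  sb1 <- medication_summary(tcb$cohort$assignments, bb2, cb, 1)
  expect_identical(sb0$classes$total[sb0$classes$class == "expectorant"], 1L)
  expect_identical(sb1$classes$total[sb1$classes$class == "expectorant"], 0L)
})

test_that("medication totals equal an oracle recount on simulated data", {
  sim <- simulate_claims(sim_config(n_beneficiaries = 800, seed = 37,
                                    planted = c(p1 = 30L, p2 = 15L)))
  co <- build_cohort(sim$bundle, cb, p)
  a <- co$assignments
  rx <- as.data.frame(sim$bundle$prescriptions)
  rx$class <- classify_atc(rx$atc, cb)
  for (k in list("index", 3L, 12L)) {
    s <- medication_summary(a, sim$bundle, cb, k)
    naive_sets <- lapply(seq_len(nrow(a)), function(i) {
      w <- medication_window(a$index[i], k)
      rows <- rx$beneficiary_id == a$beneficiary_id[i] &
        rx$date >= w[1] & rx$date <= w[2] & !is.na(rx$class) &
        rx$class != "ACE_inhibitor"
      unique(rx$class[rows])
    })
    expect_identical(s$n, sum(lengths(naive_sets) > 0L))
    expect_identical(s$antitussive_alone,
                     sum(vapply(naive_sets, function(x)
                       identical(x, "central_antitussive"), TRUE)))
    cl <- s$classes
    expect_true(all(cl$with_antitussive + cl$without_antitussive == cl$total))
    for (j in seq_len(nrow(cl))) {
      has <- vapply(naive_sets, function(x) cl$class[j] %in% x, TRUE)
      if (cl$class[j] == "bronchodilator_other") {
        has <- has & !vapply(naive_sets, function(x) "ICS_LABA" %in% x, TRUE)
      }
      expect_identical(cl$total[j], sum(has), info = paste(k, cl$class[j]))
    }
  }
})
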