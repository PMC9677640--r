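cb <- default_cb
p <- default_periods

test_that("Population 1 index is the earliest selection-period chronic claim", {
  cl <- rbind(dx_row("B1", "2017-09", "R05", "chronic cough"),
              dx_row("B1", "2018-01", "R05", "chronic cough"))
  expect_identical(find_pop1_index(cl, cb, p), ym(2017, 9))
  # a chronic claim before the selection period does not index
  expect_true(is.na(find_pop1_index(dx_row("B1", "2017-03", "R05", "chronic cough"),
                                    cb, p)))
  expect_true(is.na(find_pop1_index(dx_row("B1", "2018-01", "R05", "dry cough"),
                                    cb, p)))
})

test_that("Population 2 window search finds the first qualifying pattern", {
  cl <- rbind(dx_row("B1", "2018-01", "R05", "cough"),
              dx_row("B1", "2018-02", "R05", "cough"),
              dx_row("B1", "2018-04", "R05", "cough"))
  hit <- find_pop2_index(cl, cb, p)
  expect_identical(hit$index, ym(2018, 4))
  expect_identical(hit$window_start, ym(2018, 1))
  # no post-window code
  expect_null(find_pop2_index(rbind(dx_row("B1", "2018-01", "R05", "cough"),
                                    dx_row("B1", "2018-03", "R05", "cough")),
                              cb, p))
  # three codes in one month: "two different months" unmet
  expect_null(find_pop2_index(rbind(dx_row("B1", "2018-01", "R05", "cough"),
                                    dx_row("B1", "2018-01", "R05", "dry cough"),
                                    dx_row("B1", "2018-01", "R05", "wet cough")),
                              cb, p))
  # evaluation window may start before the selection period if the index
  # falls inside it
  early <- rbind(dx_row("B1", "2017-05", "R05", "cough"),
                 dx_row("B1", "2017-06", "R05", "cough"),
                 dx_row("B1", "2017-08", "R05", "cough"))
  hit2 <- find_pop2_index(early, cb, p)
  expect_identical(hit2$index, ym(2017, 8))
  expect_identical(hit2$window_start, ym(2017, 5))
  # but an index before the selection start cannot enrol
  too_early <- rbind(dx_row("B1", "2017-01", "R05", "cough"),
                     dx_row("B1", "2017-02", "R05", "cough"),
                     dx_row("B1", "2017-04", "R05", "cough"))
  expect_null(find_pop2_index(too_early, cb, p))
})

test_that("eligibility screening reports each exclusion reason", {
  ben <- data.frame(id = "B1", birth = ym(1999, 6), gender = "male")
  idx <- ym(2018, 5)
  cl <- rbind(dx_row("B1", "2017-09", "J30.4", "x"),
              dx_row("B1", "2018-08", "J30.4", "x"))
  expect_identical(
    screen_eligibility(ben, cl, empty_rx(), idx, cb, p), "under_20")

  adult <- data.frame(id = "B1", birth = ym(1980, 1), gender = "female")
  # one C9B prescription anywhere in the study period excludes
  rx <- rx_row("B1", "2020-02-01", "C9B1X")
  expect_true("ace_inhibitor" %in%
                screen_eligibility(adult, cl, rx, idx, cb, p))
  # cancer code anywhere in the study period excludes
  cl2 <- rbind(cl, dx_row("B1", "2019-12", "C50.9", "x"))
  expect_true("organic_respiratory_or_cancer" %in%
                screen_eligibility(adult, cl2, empty_rx(), idx, cb, p))
  # first claim only two months before the index
  cl3 <- rbind(dx_row("B1", "2018-03", "J30.4", "x"),
               dx_row("B1", "2018-08", "J30.4", "x"))
  expect_identical(screen_eligibility(adult, cl3, empty_rx(), idx, cb, p),
                   "insufficient_history")
  # no claim in the 12 post-index months
  cl4 <- dx_row("B1", "2017-09", "J30.4", "x")
  expect_identical(screen_eligibility(adult, cl4, empty_rx(), idx, cb, p),
                   "no_postindex_claim")
  # a prescription claim alone satisfies the post-index continuity rule
  rx2 <- rx_row("B1", "2018-09-10", "R06AE07")
  expect_identical(screen_eligibility(adult, cl4, rx2, idx, cb, p),
                   character(0))
})

test_that("age at index uses completed years from birth month", {
  # born 1998-06, index 2018-05: 239 months = 19 completed years -> excluded
  ben <- data.frame(id = "B1", birth = ym(1998, 6), gender = "male")
  cl <- rbind(dx_row("B1", "2017-09", "J30.4", "x"),
              dx_row("B1", "2018-08", "J30.4", "x"))
  expect_identical(screen_eligibility(ben, cl, empty_rx(), ym(2018, 5), cb, p),
                   "under_20")
  # one month later they turn 20
  expect_identical(screen_eligibility(ben, cl, empty_rx(), ym(2018, 6), cb, p),
                   character(0))
})

test_that("subgroups collect every category between window start and index", {
  cl <- rbind(dx_row("B1", "2018-01", "J45.9", "cough-variant asthma"),
              dx_row("B1", "2018-02", "R05", "cough"),
              dx_row("B1", "2018-04", "R05", "atopic cough"))
  expect_identical(assign_subgroups(cl, cb, ym(2018, 1), ym(2018, 4)),
                   c("ATOPIC_ALLERGIC", "CVA", "OTHER"))
  only_other <- rbind(dx_row("B1", "2018-01", "R05", "cough"),
                      dx_row("B1", "2018-02", "R05", "dry cough"),
                      dx_row("B1", "2018-04", "R05", "wet cough"))
  expect_identical(assign_subgroups(only_other, cb, ym(2018, 1), ym(2018, 4)),
                   "OTHER")
  # a category coded after the index month is not a subgroup under the
  # default bound, but is under the post-window bound
  late <- rbind(cl, dx_row("B1", "2018-05", "R05", "post-infectious cough"))
  expect_false("POSTINFECTIOUS" %in%
                 assign_subgroups(late, cb, ym(2018, 1), ym(2018, 4)))
  expect_true("POSTINFECTIOUS" %in%
                assign_subgroups(late, cb, ym(2018, 1), ym(2018, 4),
                                 subgroup_end = "post_window"))
})

test_that("fixtures produce their documented cohort outcomes", {
  co <- build_cohort(make_fixture("single-P1"), cb, p)
  expect_identical(co$assignments$population, "P1")
  expect_identical(co$assignments$index, ym(2018, 3))

  co2 <- build_cohort(make_fixture("single-P2-minimal"), cb, p)
  expect_identical(co2$assignments$population, "P2")
  expect_identical(co2$assignments$index, ym(2018, 4))
  expect_identical(co2$assignments$subgroups, "OTHER")

  # a member meeting both definitions goes to Population 1
  co3 <- build_cohort(make_fixture("overlap-case"), cb, p)
  expect_identical(co3$assignments$population, "P1")
  expect_identical(co3$assignments$index, ym(2018, 5))

  for (fx in c("excluded-by-ACE", "excluded-by-age", "short-history",
               "no-postindex-claim")) {
    cofx <- build_cohort(make_fixture(fx), cb, p)
    expect_identical(nrow(cofx$assignments), 0L)
    expect_identical(nrow(cofx$exclusions), 1L)
  }
  expect_match(build_cohort(make_fixture("excluded-by-ACE"), cb, p)$exclusions$reasons,
               "ace_inhibitor")
})

test_that("the cohort partitions into mutually exclusive populations", {
  sim <- simulate_claims(sim_config(n_beneficiaries = 2000, seed = 21,
                                    planted = c(p1 = 30L, p2 = 20L)))
  co <- build_cohort(sim$bundle, cb, p)
  a <- co$assignments
  expect_false(anyDuplicated(a$beneficiary_id) > 0)
  expect_setequal(unique(a$population), c("P1", "P2"))
  expect_identical(nrow(a), sum(a$population == "P1") + sum(a$population == "P2"))
  # every P2 member: non-empty subgroups, >= 3 distinct cough months, and
  # index at least 2 months after the earliest evaluation cough month
  p2 <- a[a$population == "P2"]
  expect_true(all(nzchar(p2$subgroups)))
  # the index is at least two months after the earliest evaluation-window
  # cough month (the month-granular guarantee of an > 8-week span)
  expect_true(all(p2$index - p2$window_start >= 2L))
  dxc <- sim$bundle$diagnoses
  dxc$category <- classify_cough_claim(dxc$icd10, dxc$standard_name, cb)
  for (i in seq_len(nrow(p2))) {
    m <- unique(dxc$month[dxc$beneficiary_id == p2$beneficiary_id[i] &
                            !is.na(dxc$category) & dxc$category != "CHRONIC"])
    expect_gte(length(m), 3L)
  }
  # flow identities
  fl <- co$flow
  expect_identical(unname(fl["enrolled"]),
                   unname(fl["criteria_met"] - fl["excluded_other"]))
  expect_true(all(diff(fl[c("any_claim", "adults_selection_claim",
                            "cough_code_selection", "criteria_met")]) <= 0))
})

test_that("engine assignments equal the brute-force oracle on random bundles", {
  for (i in 1:40) {
    n <- sample(c(3:30, 80, 200), 1)
    b <- random_bundle(n, seed = 5000 + i)
    expect_true(isTRUE(engine_matches_oracle(b)), label = paste("trial", i))
  }
})

test_that("adding claims never ejects a member; chronic claims move P2 to P1", {
  b <- make_fixture("single-P2-minimal")
  co <- build_cohort(b, cb, p)
  expect_identical(co$assignments$population, "P2")
  # adding a benign disease claim keeps membership and index unchanged
  b_plus <- claims_bundle(b$beneficiaries,
                          rbind(b$diagnoses, dx_row("F1", "2018-08", "K21.0", "gerd")),
                          b$prescriptions)
  co_plus <- build_cohort(b_plus, cb, p)
  expect_identical(co_plus$assignments$population, "P2")
  expect_identical(co_plus$assignments$index, co$assignments$index)
  # adding a selection-period chronic claim moves the member to P1
  b_chronic <- claims_bundle(b$beneficiaries,
                             rbind(b$diagnoses,
                                   dx_row("F1", "2018-06", "R05", "chronic cough")),
                             b$prescriptions)
  co_chr <- build_cohort(b_chronic, cb, p)
  expect_identical(co_chr$assignments$population, "P1")
  expect_identical(co_chr$assignments$index, ym(2018, 6))

  # property over random bundles: members stay enrolled when a benign claim
  # is added, and P1 membership is monotone in selection-period chronic claims
  for (i in 1:10) {
    rb <- random_bundle(20, seed = 7000 + i)
    base <- build_cohort(rb, cb, p)$assignments
    if (!nrow(base)) next
    id <- base$beneficiary_id[1]
    add <- dx_row(id, base$index[1] + 3L, "J30.4", "benign claim")
    rb2 <- claims_bundle(rb$beneficiaries, rbind(rb$diagnoses, add),
                         rb$prescriptions)
    after <- build_cohort(rb2, cb, p)$assignments
    expect_true(id %in% after$beneficiary_id)
    # a chronic claim at the member's own index month turns it into (or
    # keeps it) a P1 index without touching the screening conditions
    chr <- dx_row(id, base$index[1], "R05", "chronic cough")
    rb3 <- claims_bundle(rb$beneficiaries, rbind(rb$diagnoses, chr),
                         rb$prescriptions)
    after3 <- build_cohort(rb3, cb, p)$assignments
    expect_identical(after3$population[after3$beneficiary_id == id], "P1")
    expect_identical(after3$index[after3$beneficiary_id == id], base$index[1])
  }
})

test_that("noise-free planted bundles are recovered exactly", {
  cfg <- sim_config_noise_free(300, seed = 17, planted = c(p1 = 40L, p2 = 25L))
  sim <- simulate_claims(cfg)
  co <- build_cohort(sim$bundle, cb, p)
  tr <- sim$ground_truth[sim$ground_truth$label != "non_case", ]
  m <- merge(as.data.frame(co$assignments), as.data.frame(tr),
             by = "beneficiary_id")
  expect_identical(nrow(co$assignments), nrow(tr))
  expect_identical(nrow(m), nrow(tr))
  expect_true(all(m$population == m$label))
  expect_true(all(m$index.x == m$index.y))
  expect_true(all(m$subgroups.x == m$subgroups.y))
  # non-cases with zeroed cough rates never phenotype
  non <- sim$ground_truth$beneficiary_id[sim$ground_truth$label == "non_case"]
  expect_length(intersect(non, co$assignments$beneficiary_id), 0L)
})

test_that("facility size at index is the mode with ties toward larger", {
  dx <- rbind(
    dx_row("B1", "2017-08", "J30.4", "x"),
    dx_row("B1", "2018-03", "R05", "chronic cough", "beds_1_19"),
    dx_row("B1", "2018-03", "J30.4", "x", "beds_200_plus"),
    dx_row("B1", "2018-06", "J30.4", "x")
  )
  co <- build_cohort(claims_bundle(ben_row("B1"), dx, empty_rx()), cb, p)
  expect_identical(co$assignments$facility_size, "beds_200_plus")
})
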