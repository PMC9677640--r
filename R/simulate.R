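# Representative codes used by the generator. Disease and prescription
# claims carry one representative leaf code per label; cough claims sample
# (icd10, standard_name) pairs from the cough codebook rows of the category.
SIM_DISEASE_CODES <- c(
  ARNI = "J30.4", asthma = "J45.0", GERD = "K21.0",
  paranasal_sinusitis = "J32.9", CAID = "J44.8", chronic_rhinitis = "J31.0",
  postnasal_drip = "R09.8", vocal_cord_dysfunction = "J38.3",
  emphysema = "J43.9", nasal_polyps = "J33.9",
  EXCL_organic_respiratory = "J84.9", EXCL_cancer = "C34.9"
)
SIM_ATC_CODES <- c(
  central_antitussive = "R05DA09", expectorant = "R05CB01",
  antiallergic = "R06AE07", antimicrobial_restricted = "J01FA10",
  ICS_LABA = "R03AK06", herbal = "V90A01", corticosteroid = "H02AB07",
  bronchodilator_other = "R03AC02", peptic_ulcer = "A02BC01",
  GI_motility = "A03FA01", ACE_inhibitor = "C9A0A"
)

# Which condition makes a consult month eligible for a prescription of each
# class: "cough" = a cough claim that month; otherwise a held disease.
SIM_MED_CONDITION <- list(
  central_antitussive = "cough", expectorant = "cough",
  antimicrobial_restricted = "cough", herbal = "cough",
  antiallergic = "ARNI", ICS_LABA = "asthma", corticosteroid = "asthma",
  bronchodilator_other = "asthma", peptic_ulcer = "GERD", GI_motility = "GERD"
)

#' Synthetic claims simulation configuration
#'
#' Defaults emulate the structure of the source database: mean age 43.7 (SD
#' 12.2) years, 61.8% women, about 14% of beneficiaries leaving within any
#' one-year period (modelled as geometric monthly dropout with per-month
#' leave probability `1 - (1 - a)^(1/12)`), consultation months drawn per
#' beneficiary-month, per-consultation cough-category rates, per-beneficiary
#' cough-related disease prevalences in the range of the reported index-month
#' proportions, and conditional prescription probabilities per consult
#' month. Planted members carry an exactly qualifying Population 1 or 2
#' claim pattern for recovery testing.
#'
#' @param n_beneficiaries number of beneficiaries.
#' @param seed integer seed; generation is deterministic given the config.
#' @param female_fraction probability a beneficiary is female.
#' @param age_mean,age_sd age distribution (years) at selection start,
#'   truncated to 1..74 (the database covers beneficiaries under 75).
#' @param annual_attrition probability of leaving the database within one
#'   year.
#' @param monthly_consult_prob probability an active beneficiary consults in
#'   a given month.
#' @param cough_category_rates named per-consultation probabilities for the
#'   six cough categories.
#' @param disease_rates named per-beneficiary prevalences for the ten
#'   cough-related diseases.
#' @param disease_document_prob probability a held disease is coded at a
#'   consultation.
#' @param med_class_given_disease named per-consult-month prescription
#'   probabilities, conditional on the class's trigger (a same-month cough
#'   claim, or a held linked disease).
#' @param ace_user_rate per-beneficiary probability of being an
#'   ACE-inhibitor user (such beneficiaries are excluded by screening).
#' @param excl_rates per-beneficiary prevalences of the exclusion diseases.
#' @param facility_probs sampling probabilities of the three facility sizes.
#' @param planted named counts `c(p1 = ..., p2 = ...)` of guaranteed
#'   Population 1 / Population 2 members.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_beneficiaries = 1000L,
                       seed = 1L,
                       female_fraction = 0.618,
                       age_mean = 43.7,
                       age_sd = 12.2,
                       annual_attrition = 0.14,
                       monthly_consult_prob = 0.12,
                       cough_category_rates = c(
                         CHRONIC = 0.015, INFECTION = 0.001,
                         ATOPIC_ALLERGIC = 0.002, CVA = 0.02,
                         POSTINFECTIOUS = 0.002, OTHER = 0.03
                       ),
                       disease_rates = c(
                         ARNI = 0.50, asthma = 0.35, GERD = 0.15,
                         paranasal_sinusitis = 0.12, CAID = 0.08,
                         chronic_rhinitis = 0.03, postnasal_drip = 0.01,
                         vocal_cord_dysfunction = 0.01, emphysema = 0.01,
                         nasal_polyps = 0.002
                       ),
                       disease_document_prob = 0.5,
                       med_class_given_disease = c(
                         central_antitussive = 0.15, expectorant = 0.40,
                         antiallergic = 0.50, antimicrobial_restricted = 0.20,
                         ICS_LABA = 0.50, herbal = 0.15, corticosteroid = 0.15,
                         bronchodilator_other = 0.15, peptic_ulcer = 0.50,
                         GI_motility = 0.20
                       ),
                       ace_user_rate = 0.02,
                       excl_rates = c(EXCL_organic_respiratory = 0.005,
                                      EXCL_cancer = 0.03),
                       facility_probs = c(beds_1_19 = 0.699,
                                          beds_20_199 = 0.087,
                                          beds_200_plus = 0.214),
                       planted = c(p1 = 0L, p2 = 0L)) {
  cfg <- list(
    n_beneficiaries = as.integer(n_beneficiaries), seed = as.integer(seed),
    female_fraction = female_fraction, age_mean = age_mean, age_sd = age_sd,
    annual_attrition = annual_attrition,
    monthly_consult_prob = monthly_consult_prob,
    cough_category_rates = cough_category_rates,
    disease_rates = disease_rates,
    disease_document_prob = disease_document_prob,
    med_class_given_disease = med_class_given_disease,
    ace_user_rate = ace_user_rate, excl_rates = excl_rates,
    facility_probs = facility_probs,
    planted = c(p1 = as.integer(planted[["p1"]]), p2 = as.integer(planted[["p2"]]))
  )
  probs <- c(cfg$female_fraction, cfg$annual_attrition, cfg$monthly_consult_prob,
             cfg$cough_category_rates, cfg$disease_rates,
             cfg$disease_document_prob, cfg$med_class_given_disease,
             cfg$ace_user_rate, cfg$excl_rates, cfg$facility_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sum(cfg$planted) > cfg$n_beneficiaries) {
    stop("config error: planted counts exceed n_beneficiaries", call. = FALSE)
  }
  if (cfg$n_beneficiaries < 0) stop("config error: negative n_beneficiaries", call. = FALSE)
  stopifnot(setequal(names(cfg$cough_category_rates), COUGH_CATEGORIES),
            setequal(names(cfg$disease_rates), DISEASE_LABELS))
  structure(cfg, class = "sim_config")
}

empty_bundle <- function() {
  claims_bundle(
    data.table::data.table(id = character(0), birth = integer(0),
                           gender = character(0)),
    data.table::data.table(beneficiary_id = character(0), month = integer(0),
                           icd10 = character(0), standard_name = character(0),
                           facility_size = character(0)),
    data.table::data.table(beneficiary_id = character(0), date = as.Date(character(0)),
                           atc = character(0))
  )
}

# Sample one cough-codebook row per hit of a given category.
sample_cough_rows <- function(ids, months, cough_cat, codebooks) {
  rows <- codebooks$cough[which(codebooks$cough$category == cough_cat)]
  pick <- if (nrow(rows) == 1L) rep(1L, length(ids)) else
    sample.int(nrow(rows), length(ids), replace = TRUE)
  data.table::data.table(beneficiary_id = ids, month = months,
                         icd10 = rows$icd10[pick],
                         standard_name = rows$standard_name[pick])
}

# Uniform random day-of-month dates within given year-months (days 1..28 so
# every month length is valid).
random_dates <- function(months) {
  ym_date(months, sample.int(28L, length(months), replace = TRUE))
}

#' Generate a synthetic claims bundle
#'
#' Draws beneficiaries, monthly consultation patterns, cough and disease
#' diagnosis claims and day-stamped prescriptions under a [sim_config()],
#' plants the requested number of exactly qualifying Population 1 and
#' Population 2 members, and truncates each beneficiary's claims at a
#' geometric dropout month. Output is deterministic given the config (the
#' caller's RNG state is left untouched).
#'
#' Planted Population 1 members carry a chronic-cough claim at the intended
#' index month inside the selection period; planted Population 2 members
#' carry cough claims in months s, s+1 and s+3 of a qualifying window, never
#' a chronic-cough claim; both carry a history claim six months before the
#' index and a post-index claim, are aged >= 21, and are free of exclusion
#' codes. Their intended labels, index months and subgroup sets are returned
#' as ground truth (exact recovery holds when background noise is disabled;
#' with noise, background claims may legitimately shift an index earlier).
#'
#' @param config a [sim_config()].
#' @param periods a [study_periods()] object.
#' @return a list with `bundle` (a claims bundle), `ground_truth`
#'   (data.table: `beneficiary_id`, `label` in P1/P2/non_case, `index`,
#'   `subgroups`, `dropout` = last active month) and `config`.
#' @export
simulate_claims <- function(config = sim_config(), periods = study_periods()) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_beneficiaries
  if (n == 0L) {
    return(list(
      bundle = empty_bundle(),
      ground_truth = data.table::data.table(
        beneficiary_id = character(0), label = character(0),
        index = integer(0), subgroups = character(0), dropout = integer(0)),
      config = config
    ))
  }
  span <- periods$observation_end - periods$study_start + 1L

  ids <- sprintf("B%06d", seq_len(n))
  gender <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 1), 74)
  birth <- periods$selection_start - as.integer(round(age * 12))
  facility <- sample(names(config$facility_probs), n, replace = TRUE,
                     prob = config$facility_probs)

  # geometric dropout calibrated to the annual attrition rate: with monthly
  # leave probability p = 1 - (1 - a)^(1/12), the chance of leaving within
  # any 12 active months is exactly a
  p_month <- 1 - (1 - config$annual_attrition)^(1 / 12)
  active_n <- if (p_month > 0) 1L + stats::rgeom(n, p_month) else rep(span, n)
  active_n <- pmin(active_n, span)

  # planted members: assigned ids at the head of the roster; forced adult
  # age, full-span enrolment, and no exclusion codes
  n_p1 <- config$planted[["p1"]]
  n_p2 <- config$planted[["p2"]]
  planted_idx <- seq_len(n_p1 + n_p2)
  if (length(planted_idx)) {
    age_p <- pmin(pmax(stats::rnorm(length(planted_idx), config$age_mean,
                                    config$age_sd), 21), 74)
    birth[planted_idx] <- periods$selection_start - as.integer(round(age_p * 12))
    active_n[planted_idx] <- span
  }
  last_active <- periods$study_start + active_n - 1L

  # monthly consultations over each beneficiary's active span
  grid <- data.table::data.table(
    beneficiary_id = rep(ids, active_n),
    month = periods$study_start +
      unlist(lapply(active_n, seq_len), use.names = FALSE) - 1L
  )
  consult <- grid[stats::runif(nrow(grid)) < config$monthly_consult_prob]

  codebooks <- load_codebooks()

  # cough claims per consult month and category
  cough_claims <- data.table::rbindlist(lapply(COUGH_CATEGORIES, function(cat_) {
    r <- config$cough_category_rates[[cat_]]
    if (r <= 0 || !nrow(consult)) return(NULL)
    hit <- stats::runif(nrow(consult)) < r
    if (!any(hit)) return(NULL)
    sample_cough_rows(consult$beneficiary_id[hit], consult$month[hit],
                      cat_, codebooks)
  }))
  # planted Population 2 members must never carry a chronic-cough code
  planted_p2_ids <- ids[seq_len(n_p2) + n_p1]
  if (nrow(cough_claims) && length(planted_p2_ids)) {
    chronic <- classify_cough_claim(cough_claims$icd10,
                                    cough_claims$standard_name, codebooks) == "CHRONIC"
    cough_claims <- cough_claims[!(chronic & beneficiary_id %in% planted_p2_ids)]
  }

  # per-beneficiary held diseases, documented at consultations
  all_rates <- c(config$disease_rates, config$excl_rates)
  held <- data.table::rbindlist(lapply(names(all_rates), function(d) {
    has <- stats::runif(n) < all_rates[[d]]
    if (d %in% names(config$excl_rates)) has[planted_idx] <- FALSE
    data.table::data.table(beneficiary_id = ids[has], disease = d)
  }))
  disease_claims <- if (nrow(held) && nrow(consult)) {
    dc <- held[consult, on = "beneficiary_id", allow.cartesian = TRUE,
               nomatch = NULL]
    dc <- dc[stats::runif(nrow(dc)) < config$disease_document_prob]
    data.table::data.table(beneficiary_id = dc$beneficiary_id, month = dc$month,
                           icd10 = unname(SIM_DISEASE_CODES[dc$disease]),
                           standard_name = dc$disease)
  } else NULL

  # prescriptions: class-specific triggers per consult month
  cough_months <- if (nrow(cough_claims)) {
    unique(cough_claims[, c("beneficiary_id", "month")])
  } else {
    data.table::data.table(beneficiary_id = character(0), month = integer(0))
  }
  held_of <- function(d) held$beneficiary_id[held$disease == d]
  rx <- data.table::rbindlist(lapply(names(SIM_MED_CONDITION), function(cl) {
    p <- config$med_class_given_disease[[cl]]
    if (is.null(p) || p <= 0) return(NULL)
    cond <- SIM_MED_CONDITION[[cl]]
    elig <- if (cond == "cough") {
      cough_months
    } else {
      consult[consult$beneficiary_id %in% held_of(cond),
              c("beneficiary_id", "month")]
    }
    if (!nrow(elig)) return(NULL)
    hit <- stats::runif(nrow(elig)) < p
    if (!any(hit)) return(NULL)
    data.table::data.table(beneficiary_id = elig$beneficiary_id[hit],
                           date = random_dates(elig$month[hit]),
                           atc = unname(SIM_ATC_CODES[cl]))
  }))
  # background ACE-inhibitor users (excluded downstream by screening)
  ace_user <- stats::runif(n) < config$ace_user_rate
  ace_user[planted_idx] <- FALSE
  if (any(ace_user) && nrow(consult)) {
    ec <- consult[consult$beneficiary_id %in% ids[ace_user]]
    hit <- stats::runif(nrow(ec)) < 0.3
    if (any(hit)) {
      rx <- data.table::rbindlist(list(rx, data.table::data.table(
        beneficiary_id = ec$beneficiary_id[hit],
        date = random_dates(ec$month[hit]),
        atc = unname(SIM_ATC_CODES[["ACE_inhibitor"]])
      )))
    }
  }

  # ---- planted qualifying patterns -------------------------------------
  truth_label <- rep("non_case", n)
  truth_index <- rep(NA_integer_, n)
  truth_sub <- rep("", n)
  planted_dx <- NULL
  if (n_p1 > 0L) {
    i <- seq_len(n_p1)
    idx <- periods$selection_start +
      sample.int(periods$selection_end - periods$selection_start + 1L,
                 n_p1, replace = TRUE) - 1L
    truth_label[i] <- "P1"
    truth_index[i] <- idx
    chronic_row <- codebooks$cough[codebooks$cough$category == "CHRONIC"][1L]
    planted_dx <- data.table::rbindlist(list(
      data.table::data.table(beneficiary_id = ids[i], month = idx,
                             icd10 = chronic_row$icd10,
                             standard_name = chronic_row$standard_name),
      # history and post-index anchor claims
      data.table::data.table(beneficiary_id = ids[i], month = idx - 6L,
                             icd10 = SIM_DISEASE_CODES[["ARNI"]],
                             standard_name = "ARNI"),
      data.table::data.table(beneficiary_id = ids[i], month = idx + 2L,
                             icd10 = SIM_DISEASE_CODES[["ARNI"]],
                             standard_name = "ARNI")
    ))
  }
  if (n_p2 > 0L) {
    i <- seq_len(n_p2) + n_p1
    s <- (periods$selection_start - 3L) +
      sample.int(periods$selection_end - periods$selection_start + 1L,
                 n_p2, replace = TRUE) - 1L
    idx <- s + 3L
    p2_w <- config$cough_category_rates[P2_CATEGORIES]
    if (all(p2_w <= 0)) p2_w <- stats::setNames(rep(1, length(P2_CATEGORIES)),
                                                P2_CATEGORIES)
    cat3 <- matrix(sample(P2_CATEGORIES, 3L * n_p2, replace = TRUE,
                          prob = p2_w), nrow = n_p2)
    truth_label[i] <- "P2"
    truth_index[i] <- idx
    truth_sub[i] <- apply(cat3, 1L, function(cc) paste(sort(unique(cc)), collapse = ","))
    # one claim per (member, pattern month), of the drawn category
    p2_dx <- data.table::rbindlist(lapply(1:3, function(j) {
      m <- switch(j, s, s + 1L, s + 3L)
      data.table::rbindlist(lapply(seq_len(n_p2), function(b) {
        sample_cough_rows(ids[i][b], m[b], cat3[b, j], codebooks)
      }))
    }))
    planted_dx <- data.table::rbindlist(list(
      planted_dx, p2_dx,
      data.table::data.table(beneficiary_id = ids[i], month = idx - 6L,
                             icd10 = SIM_DISEASE_CODES[["ARNI"]],
                             standard_name = "ARNI"),
      data.table::data.table(beneficiary_id = ids[i], month = idx + 2L,
                             icd10 = SIM_DISEASE_CODES[["ARNI"]],
                             standard_name = "ARNI")
    ))
  }

  dx <- data.table::rbindlist(list(cough_claims, disease_claims, planted_dx),
                              use.names = TRUE, fill = TRUE)
  if (!nrow(dx)) {
    dx <- empty_bundle()$diagnoses
  } else {
    dx[, facility_size := facility[match(beneficiary_id, ids)]]
    data.table::setorder(dx, beneficiary_id, month, icd10, standard_name)
  }
  if (is.null(rx) || !nrow(rx)) {
    rx <- empty_bundle()$prescriptions
  } else {
    data.table::setorder(rx, beneficiary_id, date, atc)
  }

  ben <- data.table::data.table(id = ids, birth = birth, gender = gender)
  truth <- data.table::data.table(
    beneficiary_id = ids, label = truth_label, index = truth_index,
    subgroups = truth_sub, dropout = last_active
  )
  list(bundle = claims_bundle(ben, dx, rx), ground_truth = truth,
       config = config)
}

#' Noise-free simulation configuration
#'
#' Convenience wrapper: all background consultation, cough, disease,
#' exclusion and prescription rates set to zero, so the only claims are the
#' planted qualifying patterns. Under this config the cohort engine must
#' recover the planted members exactly.
#'
#' @param n_beneficiaries,seed,planted see [sim_config()].
#' @param ... further overrides passed to [sim_config()].
#' @export
sim_config_noise_free <- function(n_beneficiaries, seed = 1L,
                                  planted = c(p1 = 0L, p2 = 0L), ...) {
  sim_config(
    n_beneficiaries = n_beneficiaries, seed = seed, planted = planted,
    monthly_consult_prob = 0,
    cough_category_rates = stats::setNames(rep(0, 6L), COUGH_CATEGORIES),
    disease_rates = stats::setNames(rep(0, 10L), DISEASE_LABELS),
    ace_user_rate = 0,
    excl_rates = c(EXCL_organic_respiratory = 0, EXCL_cancer = 0),
    ...
  )
}
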