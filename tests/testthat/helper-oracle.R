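# Naive brute-force re-implementation of the phenotyping algorithm, kept
# deliberately independent of the engine: per-beneficiary loops, its own
# codebook lookups, and explicit enumeration of candidate evaluation
# windows. Used to check engine equivalence on random bundles.

oracle_cough_category <- function(icd10, standard_name, cb) {
  hit <- which(cb$cough$icd10 == icd10 & cb$cough$standard_name == standard_name)
  if (length(hit)) cb$cough$category[hit] else NA_character_
}

oracle_prefix_label <- function(code, prefixes, labels) {
  best <- NA_character_; blen <- -1L
  for (j in seq_along(prefixes)) {
    if (startsWith(code, prefixes[j]) && nchar(prefixes[j]) > blen) {
      best <- labels[j]; blen <- nchar(prefixes[j])
    }
  }
  best
}

# Full naive cohort: returns a data.frame of assignments (beneficiary_id,
# population, index, window_start, subgroups) for eligible members.
oracle_cohort <- function(bundle, cb, periods) {
  out <- list()
  for (i in seq_len(nrow(bundle$beneficiaries))) {
    id <- bundle$beneficiaries$id[i]
    birth <- bundle$beneficiaries$birth[i]
    dxb <- bundle$diagnoses[bundle$diagnoses$beneficiary_id == id, ]
    rxb <- bundle$prescriptions[bundle$prescriptions$beneficiary_id == id, ]

    cats <- character(nrow(dxb))
    for (r in seq_len(nrow(dxb))) {
      cats[r] <- oracle_cough_category(dxb$icd10[r], dxb$standard_name[r], cb)
    }
    in_sel <- dxb$month >= periods$selection_start &
      dxb$month <= periods$selection_end

    population <- NA_character_; index <- NA_integer_; wstart <- NA_integer_
    chronic_sel <- dxb$month[!is.na(cats) & cats == "CHRONIC" & in_sel]
    if (length(chronic_sel)) {
      population <- "P1"
      index <- min(chronic_sel)
    } else {
      p2m <- sort(unique(dxb$month[!is.na(cats) & cats != "CHRONIC"]))
      for (s in periods$study_start:(periods$selection_end - 3L)) {
        ev <- unique(p2m[p2m >= s & p2m <= s + 2L])
        post <- p2m[p2m >= s + 3L & p2m <= s + 5L]
        if (length(ev) >= 2L && length(post) >= 1L) {
          cand <- min(post)
          if (cand >= periods$selection_start && cand <= periods$selection_end) {
            population <- "P2"; index <- cand
            wstart <- min(p2m[p2m >= s])  # first cough diagnosis of the window
            break
          }
        }
      }
    }
    if (is.na(population)) next

    # eligibility screening, spelled out
    ok <- TRUE
    if ((index - birth) %/% 12L < 20L) ok <- FALSE
    if (ok && nrow(rxb)) {
      for (r in seq_len(nrow(rxb))) {
        lab <- oracle_prefix_label(rxb$atc[r], cb$medication$prefix,
                                   cb$medication$class)
        if (!is.na(lab) && lab == "ACE_inhibitor") { ok <- FALSE; break }
      }
    }
    if (ok && nrow(dxb)) {
      for (r in seq_len(nrow(dxb))) {
        lab <- oracle_prefix_label(dxb$icd10[r], cb$disease$prefix,
                                   cb$disease$label)
        if (!is.na(lab) && lab %in% c("EXCL_organic_respiratory", "EXCL_cancer")) {
          ok <- FALSE; break
        }
      }
    }
    all_months <- c(dxb$month,
                    if (nrow(rxb)) date_ym(rxb$date) else integer(0))
    if (ok && min(all_months) > index - 6L) ok <- FALSE
    if (ok && !any(all_months >= index + 1L & all_months <= index + 12L)) ok <- FALSE
    if (!ok) next

    subgroups <- ""
    if (population == "P2") {
      sg <- unique(cats[!is.na(cats) & cats != "CHRONIC" &
                          dxb$month >= wstart & dxb$month <= index])
      subgroups <- paste(sort(sg), collapse = ",")
    }
    out[[length(out) + 1L]] <- data.frame(
      beneficiary_id = id, population = population, index = index,
      window_start = wstart, subgroups = subgroups,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(beneficiary_id = character(0), population = character(0),
                      index = integer(0), window_start = integer(0),
                      subgroups = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$beneficiary_id), , drop = FALSE]
}

# Random scatter bundle, independent of the package generator: claims are
# thrown uniformly over a 36-month span with a mix of cough codebook rows,
# disease codes, junk codes and occasional ACE prescriptions.
random_bundle <- function(n, seed, cb = default_cb, periods = default_periods) {
  set.seed(seed)
  span <- periods$study_start:(periods$study_start + 35L)
  ids <- sprintf("R%03d", seq_len(n))
  ben <- data.table::data.table(
    id = ids,
    birth = ym(sample(1950:2001, n, replace = TRUE), sample.int(12L, n, replace = TRUE)),
    gender = sample(c("female", "male"), n, replace = TRUE)
  )
  disease_codes <- c("J30.4", "K21.0", "J45.0", "J84.9", "C34.9", "J43.9")
  dx <- data.table::rbindlist(lapply(ids, function(id) {
    k <- stats::rpois(1L, 6L)
    if (!k) return(NULL)
    kind <- stats::runif(k)
    row <- sample.int(nrow(cb$cough), k, replace = TRUE)
    icd <- ifelse(kind < 0.55, cb$cough$icd10[row],
                  ifelse(kind < 0.85, sample(disease_codes, k, replace = TRUE),
                         "Z99"))
    nm <- ifelse(kind < 0.55, cb$cough$standard_name[row], "non-cough claim")
    data.table::data.table(
      beneficiary_id = id, month = sample(span, k, replace = TRUE),
      icd10 = icd, standard_name = nm,
      facility_size = sample(c("beds_1_19", "beds_20_199", "beds_200_plus"),
                             k, replace = TRUE)
    )
  }))
  rx <- data.table::rbindlist(lapply(ids, function(id) {
    k <- stats::rpois(1L, 1.5)
    if (!k) return(NULL)
    data.table::data.table(
      beneficiary_id = id,
      date = ym_date(sample(span, k, replace = TRUE),
                     sample.int(28L, k, replace = TRUE)),
      atc = sample(c("R05DA09", "R05CB01", "R06AE07", "C9A0A", "X00"), k,
                   replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.05, 0.05))
    )
  }))
  if (is.null(dx) || !nrow(dx)) {
    dx <- data.table::data.table(beneficiary_id = character(0),
                                 month = integer(0), icd10 = character(0),
                                 standard_name = character(0),
                                 facility_size = character(0))
  }
  if (is.null(rx) || !nrow(rx)) rx <- empty_rx()
  claims_bundle(ben, dx, rx)
}

# Compare engine and oracle assignments on one bundle; returns TRUE or a
# description of the first difference.
engine_matches_oracle <- function(bundle, cb = default_cb,
                                  periods = default_periods) {
  eng <- build_cohort(bundle, cb, periods)$assignments
  ora <- oracle_cohort(bundle, cb, periods)
  if (nrow(eng) != nrow(ora)) {
    return(sprintf("size mismatch: engine %d vs oracle %d", nrow(eng), nrow(ora)))
  }
  if (!nrow(eng)) return(TRUE)
  eng <- eng[order(eng$beneficiary_id)]
  for (col in c("beneficiary_id", "population", "index", "subgroups")) {
    if (!identical(as.vector(eng[[col]]), as.vector(ora[[col]]))) {
      return(paste("mismatch in", col))
    }
  }
  w_eng <- ifelse(is.na(eng$window_start), -1L, eng$window_start)
  w_ora <- ifelse(is.na(ora$window_start), -1L, ora$window_start)
  if (!identical(as.integer(w_eng), as.integer(w_ora))) {
    return("mismatch in window_start")
  }
  TRUE
}
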