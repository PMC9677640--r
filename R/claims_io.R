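FACILITY_LEVELS <- c("beds_1_19", "beds_20_199", "beds_200_plus", "unknown")

# Required columns per table; order is also the serialisation order.
CLAIMS_SCHEMA <- list(
  beneficiaries = c("id", "birth_ym", "gender"),
  diagnoses = c("beneficiary_id", "ym", "icd10", "standard_name", "facility_size"),
  prescriptions = c("beneficiary_id", "date", "atc")
)

read_tsv_checked <- function(path, table) {
  if (!file.exists(path)) stop("claims file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          header = TRUE, na.strings = NULL, quote = "")
  missing <- setdiff(CLAIMS_SCHEMA[[table]], names(dt))
  if (length(missing)) {
    stop("schema error in ", basename(path), ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dt
}

row_error <- function(path, lines, what) {
  # +1 converts data row numbers to file line numbers (header is line 1)
  stop(sprintf("%s: %s at line(s) %s", basename(path), what,
               paste(utils::head(lines + 1L, 10L), collapse = ", ")),
       call. = FALSE)
}

#' Read a claims bundle from tab-delimited files
#'
#' Reads the three study tables: beneficiary records (id, year-month of
#' birth, gender), month-stamped diagnosis claims carrying an ICD-10 code
#' plus a standard disease name, and day-stamped prescription claims carrying
#' an ATC class code. Files are tab-delimited UTF-8 with a header row; months
#' are serialized as "YYYY-MM" and days as "YYYY-MM-DD". All rows are
#' validated; unparseable rows are reported with their file line numbers.
#'
#' @param dir directory holding `beneficiaries.tsv`, `diagnoses.tsv` and
#'   `prescriptions.tsv` (individual paths may be overridden).
#' @param beneficiaries,diagnoses,prescriptions optional explicit file paths.
#' @return a list of class `"claims_bundle"` with data.tables
#'   `beneficiaries` (id, birth, gender), `diagnoses` (beneficiary_id, month,
#'   icd10, standard_name, facility_size) and `prescriptions`
#'   (beneficiary_id, date, atc); months are [ym()] integers, dates are Date.
#' @export
read_claims <- function(dir = NULL,
                        beneficiaries = file.path(dir, "beneficiaries.tsv"),
                        diagnoses = file.path(dir, "diagnoses.tsv"),
                        prescriptions = file.path(dir, "prescriptions.tsv")) {
  ben_raw <- read_tsv_checked(beneficiaries, "beneficiaries")
  dx_raw <- read_tsv_checked(diagnoses, "diagnoses")
  rx_raw <- read_tsv_checked(prescriptions, "prescriptions")

  if (anyDuplicated(ben_raw$id)) {
    row_error(beneficiaries, which(duplicated(ben_raw$id)),
              "duplicate beneficiary id")
  }
  birth <- ym_parse(ben_raw$birth_ym)
  if (anyNA(birth) && nrow(ben_raw)) {
    row_error(beneficiaries, which(is.na(birth)), "unparsable birth month")
  }
  if (nrow(ben_raw) && !all(ben_raw$gender %in% c("male", "female"))) {
    row_error(beneficiaries, which(!ben_raw$gender %in% c("male", "female")),
              "gender must be 'male' or 'female'")
  }
  ben <- data.table::data.table(id = ben_raw$id, birth = birth,
                                gender = ben_raw$gender)

  month <- ym_parse(dx_raw$ym)
  if (anyNA(month) && nrow(dx_raw)) {
    row_error(diagnoses, which(is.na(month)), "unparsable claim month")
  }
  if (nrow(dx_raw) && any(dx_raw$icd10 == "")) {
    row_error(diagnoses, which(dx_raw$icd10 == ""), "empty icd10 code")
  }
  fac <- dx_raw$facility_size
  if (nrow(dx_raw) && !all(fac %in% FACILITY_LEVELS)) {
    row_error(diagnoses, which(!fac %in% FACILITY_LEVELS),
              paste("facility_size must be one of",
                    paste(FACILITY_LEVELS, collapse = "/")))
  }
  dx <- data.table::data.table(
    beneficiary_id = dx_raw$beneficiary_id, month = month,
    icd10 = dx_raw$icd10, standard_name = dx_raw$standard_name,
    facility_size = fac
  )

  date <- as.Date(rx_raw$date, format = "%Y-%m-%d")
  if (anyNA(date) && nrow(rx_raw)) {
    row_error(prescriptions, which(is.na(date)), "unparsable prescription date")
  }
  rx <- data.table::data.table(beneficiary_id = rx_raw$beneficiary_id,
                               date = date, atc = rx_raw$atc)

  claims_bundle(ben, dx, rx)
}

#' Construct a claims bundle from in-memory tables
#'
#' @param beneficiaries,diagnoses,prescriptions data.frames with the columns
#'   documented in [read_claims()].
#' @export
claims_bundle <- function(beneficiaries, diagnoses, prescriptions) {
  structure(
    list(beneficiaries = data.table::as.data.table(beneficiaries),
         diagnoses = data.table::as.data.table(diagnoses),
         prescriptions = data.table::as.data.table(prescriptions)),
    class = "claims_bundle"
  )
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat(sprintf("claims bundle: %d beneficiaries, %d diagnosis claims, %d prescription claims\n",
              nrow(x$beneficiaries), nrow(x$diagnoses), nrow(x$prescriptions)))
  invisible(x)
}

#' Write a claims bundle to tab-delimited files
#'
#' Inverse of [read_claims()]: `read_claims(write_claims(b, dir))` returns a
#' bundle identical to `b`.
#'
#' @param bundle a claims bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ben <- data.table::data.table(
    id = bundle$beneficiaries$id,
    birth_ym = ym_format(bundle$beneficiaries$birth),
    gender = bundle$beneficiaries$gender
  )
  dx <- data.table::data.table(
    beneficiary_id = bundle$diagnoses$beneficiary_id,
    ym = ym_format(bundle$diagnoses$month),
    icd10 = bundle$diagnoses$icd10,
    standard_name = bundle$diagnoses$standard_name,
    facility_size = bundle$diagnoses$facility_size
  )
  rx <- data.table::data.table(
    beneficiary_id = bundle$prescriptions$beneficiary_id,
    date = format(bundle$prescriptions$date, "%Y-%m-%d"),
    atc = bundle$prescriptions$atc
  )
  data.table::fwrite(ben, file.path(dir, "beneficiaries.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(dx, file.path(dir, "diagnoses.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(rx, file.path(dir, "prescriptions.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}

#' Validate bundle-level invariants against study periods
#'
#' Checks that every claim month and prescription date falls inside the
#' study period and that each beneficiary's birth precedes their claims.
#'
#' @param bundle a claims bundle.
#' @param periods a [study_periods()] object.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_bundle <- function(bundle, periods) {
  dxm <- bundle$diagnoses$month
  if (length(dxm) && (min(dxm) < periods$study_start || max(dxm) > periods$observation_end)) {
    stop("diagnosis claim month outside the study period", call. = FALSE)
  }
  if (nrow(bundle$prescriptions)) {
    rxm <- date_ym(bundle$prescriptions$date)
    if (min(rxm) < periods$study_start || max(rxm) > periods$observation_end) {
      stop("prescription date outside the study period", call. = FALSE)
    }
  }
  if (nrow(bundle$diagnoses)) {
    birth <- bundle$beneficiaries$birth[
      match(bundle$diagnoses$beneficiary_id, bundle$beneficiaries$id)]
    if (any(!is.na(birth) & birth >= dxm)) {
      stop("beneficiary birth month does not precede a claim month", call. = FALSE)
    }
  }
  invisible(TRUE)
}
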