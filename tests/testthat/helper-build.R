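# Small builders shared across tests.

dx_row <- function(id, month, icd10, standard_name, facility = "beds_1_19") {
  data.table::data.table(
    beneficiary_id = id,
    month = if (is.character(month)) ym_parse(month) else as.integer(month),
    icd10 = icd10, standard_name = standard_name, facility_size = facility
  )
}

rx_row <- function(id, date, atc) {
  data.table::data.table(beneficiary_id = id, date = as.Date(date), atc = atc)
}

ben_row <- function(id, birth = ym(1980, 1), gender = "female") {
  data.table::data.table(id = id, birth = birth, gender = gender)
}

empty_rx <- function() {
  data.table::data.table(beneficiary_id = character(0),
                         date = as.Date(character(0)), atc = character(0))
}

# One-beneficiary bundle with history + post-index anchor claims around a
# given set of cough claims (standard names from the default codebook).
one_member_bundle <- function(cough, history = "2017-08", postindex = "2018-12",
                              birth = ym(1980, 1), rx = empty_rx()) {
  dx <- data.table::rbindlist(c(
    if (!is.null(history)) list(dx_row("B1", history, "J30.4", "arni claim")),
    list(cough),
    if (!is.null(postindex)) list(dx_row("B1", postindex, "J30.4", "arni claim"))
  ))
  claims_bundle(ben_row("B1", birth), dx, rx)
}

default_cb <- load_codebooks()
default_periods <- study_periods()
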