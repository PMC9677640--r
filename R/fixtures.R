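#' Hand-built minimal claims fixtures
#'
#' Small single-beneficiary bundles with documented expected outcomes,
#' used for boundary testing of the cohort engine:
#' \describe{
#'   \item{single-P1}{one chronic-cough claim in 2018-03 with sufficient
#'     history and a post-index claim; expected Population 1, index 2018-03.}
#'   \item{single-P2-minimal}{cough codes in exactly 2018-01, 2018-02 and
#'     2018-04 (the minimal qualifying pattern); expected Population 2,
#'     window start 2018-01, index 2018-04, subgroup OTHER.}
#'   \item{overlap-case}{the Population 2 pattern plus a chronic-cough claim
#'     in the selection period; meets both definitions, expected Population
#'     1 (overlaps resolve to Population 1).}
#'   \item{excluded-by-ACE}{single-P1 plus one ACE-inhibitor (ATC C9A)
#'     prescription in 2020-02; expected excluded, reason `ace_inhibitor`.}
#'   \item{excluded-by-age}{born 1999-06, index 2018-05 (age 18); expected
#'     excluded, reason `under_20`.}
#'   \item{short-history}{first-ever claim two months before the index;
#'     expected excluded, reason `insufficient_history`.}
#'   \item{no-postindex-claim}{no claim of any kind in the twelve months
#'     after the index; expected excluded, reason `no_postindex_claim`.}
#' }
#'
#' @param name one of the fixture names above.
#' @return a claims bundle.
#' @export
make_fixture <- function(name) {
  dx_row <- function(month, icd10, standard_name, id = "F1") {
    data.table::data.table(beneficiary_id = id, month = ym_parse(month),
                           icd10 = icd10, standard_name = standard_name,
                           facility_size = "beds_1_19")
  }
  adult <- data.table::data.table(id = "F1", birth = ym(1980, 1),
                                  gender = "female")
  no_rx <- data.table::data.table(beneficiary_id = character(0),
                                  date = as.Date(character(0)),
                                  atc = character(0))
  history <- dx_row("2017-08", "J30.4", "ARNI")   # first claim, >= 6 mo pre-index
  postindex <- dx_row("2018-07", "J30.4", "ARNI") # post-index continuity claim

  switch(
    name,
    "single-P1" = claims_bundle(
      adult,
      rbind(history, dx_row("2018-03", "R05", "chronic cough"), postindex),
      no_rx
    ),
    "single-P2-minimal" = claims_bundle(
      adult,
      rbind(history,
            dx_row("2018-01", "R05", "cough"),
            dx_row("2018-02", "R05", "dry cough"),
            dx_row("2018-04", "R05", "cough"),
            postindex),
      no_rx
    ),
    "overlap-case" = claims_bundle(
      adult,
      rbind(history,
            dx_row("2018-01", "R05", "cough"),
            dx_row("2018-02", "R05", "dry cough"),
            dx_row("2018-04", "R05", "cough"),
            dx_row("2018-05", "R05", "chronic cough"),
            postindex),
      no_rx
    ),
    "excluded-by-ACE" = claims_bundle(
      adult,
      rbind(history, dx_row("2018-03", "R05", "chronic cough"), postindex),
      data.table::data.table(beneficiary_id = "F1",
                             date = as.Date("2020-02-10"), atc = "C9A0A")
    ),
    "excluded-by-age" = claims_bundle(
      data.table::data.table(id = "F1", birth = ym(1999, 6), gender = "male"),
      rbind(dx_row("2017-09", "J30.4", "ARNI"),
            dx_row("2018-05", "R05", "chronic cough"),
            dx_row("2018-09", "J30.4", "ARNI")),
      no_rx
    ),
    "short-history" = claims_bundle(
      adult,
      rbind(dx_row("2018-01", "J30.4", "ARNI"),  # only 2 months before index
            dx_row("2018-03", "R05", "chronic cough"),
            postindex),
      no_rx
    ),
    "no-postindex-claim" = claims_bundle(
      adult,
      rbind(history, dx_row("2018-03", "R05", "chronic cough")),
      no_rx
    ),
    stop("unknown fixture name: ", name, call. = FALSE)
  )
}
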