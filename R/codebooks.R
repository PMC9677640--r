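#' @import data.table
NULL

# Category and label vocabularies. CHRONIC defines Population 1; the other
# five cough categories define Population 2 and its subgroups.
COUGH_CATEGORIES <- c("CHRONIC", "INFECTION", "ATOPIC_ALLERGIC", "CVA",
                      "POSTINFECTIOUS", "OTHER")
P2_CATEGORIES <- setdiff(COUGH_CATEGORIES, "CHRONIC")

DISEASE_LABELS <- c("ARNI", "asthma", "GERD", "paranasal_sinusitis", "CAID",
                    "chronic_rhinitis", "postnasal_drip",
                    "vocal_cord_dysfunction", "emphysema", "nasal_polyps")
EXCL_LABELS <- c("EXCL_organic_respiratory", "EXCL_cancer")

MED_CLASSES <- c("central_antitussive", "expectorant", "antiallergic",
                 "antimicrobial_restricted", "ICS_LABA", "herbal",
                 "corticosteroid", "bronchodilator_other", "peptic_ulcer",
                 "GI_motility", "ACE_inhibitor")
# "any medication of interest" denominators exclude ACE inhibitors: their
# users are excluded from the cohort upstream.
MED_CLASSES_OF_INTEREST <- setdiff(MED_CLASSES, "ACE_inhibitor")

#' Load diagnosis and medication codebooks
#'
#' Three lookup structures drive the pipeline: the cough codebook maps exact
#' (ICD-10, standard disease name) pairs to one of six cough categories
#' (`CHRONIC` alone defines Population 1); the disease codebook maps ICD-10
#' code prefixes to ten cough-related disease labels plus two exclusion
#' labels (organic respiratory disease, cancer); the medication codebook maps
#' ATC code prefixes to eleven medication classes. Standard disease names are
#' matched as opaque strings: in Japanese claims they disambiguate cough
#' subtypes that share one ICD-10 code (e.g. the R05 variants).
#'
#' @param path path to a yaml file with `cough`, `disease` and `medication`
#'   sections; defaults to the bundled codebook, whose cough section is the
#'   published 17-row cough codebook and whose disease/medication sections are
#'   documented synthetic stand-ins.
#' @return a list of class `"codebooks"` with data.tables `cough`
#'   (icd10, standard_name, category), `disease` (prefix, label) and
#'   `medication` (prefix, class).
#' @examples
#' cb <- load_codebooks()
#' classify_cough_claim("R05", "chronic cough", cb)  # "CHRONIC"
#' @export
load_codebooks <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codebooks.yaml", package = "coughcohort")
  }
  if (!file.exists(path)) stop("codebook file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (sec in c("cough", "disease", "medication")) {
    if (is.null(cfg[[sec]])) stop("codebook file lacks section '", sec, "'", call. = FALSE)
  }

  cough <- data.table::rbindlist(lapply(cfg$cough, function(e) {
    data.table::data.table(
      icd10 = as.character(e$icd10),
      standard_name = as.character(e$standard_name),
      category = as.character(e$category)
    )
  }))
  bad <- setdiff(cough$category, COUGH_CATEGORIES)
  if (length(bad)) {
    stop("unknown cough category label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cough[, c("icd10", "standard_name")])) {
    dup <- cough[duplicated(cough[, c("icd10", "standard_name")])]
    stop("duplicate (icd10, standard_name) pair(s) in cough codebook: ",
         paste(paste0("(", dup$icd10, ", ", dup$standard_name, ")"), collapse = ", "),
         call. = FALSE)
  }
  if (!any(cough$category == "CHRONIC")) {
    stop("cough codebook has no CHRONIC entry; Population 1 would be undefined",
         call. = FALSE)
  }

  disease <- data.table::rbindlist(lapply(cfg$disease, function(e) {
    data.table::data.table(prefix = as.character(e$prefix), label = as.character(e$label))
  }))
  bad <- setdiff(disease$label, c(DISEASE_LABELS, EXCL_LABELS))
  if (length(bad)) {
    stop("unknown disease label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(disease$prefix)) {
    stop("duplicate prefix in disease codebook (one label per code required)",
         call. = FALSE)
  }

  medication <- data.table::rbindlist(lapply(cfg$medication, function(e) {
    data.table::data.table(prefix = as.character(e$prefix), class = as.character(e$class))
  }))
  bad <- setdiff(medication$class, MED_CLASSES)
  if (length(bad)) {
    stop("unknown medication class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(medication$prefix)) {
    stop("duplicate prefix in medication codebook", call. = FALSE)
  }
  # The ACE-inhibitor exclusion is defined on ATC classes C9A/C9B; any
  # codebook must preserve that mapping.
  ace <- classify_prefix(c("C9A", "C9B"), medication$prefix, medication$class)
  if (!all(ace == "ACE_inhibitor", na.rm = FALSE) || anyNA(ace)) {
    stop("medication codebook must map ATC prefixes C9A and C9B to ACE_inhibitor",
         call. = FALSE)
  }

  structure(list(cough = cough, disease = disease, medication = medication),
            class = "codebooks")
}

#' @export
print.codebooks <- function(x, ...) {
  cat(sprintf("codebooks: %d cough pairs, %d disease prefixes, %d medication prefixes\n",
              nrow(x$cough), nrow(x$disease), nrow(x$medication)))
  invisible(x)
}

# Longest-prefix classification of codes against (prefix, label) rules.
# Returns NA for codes matching no prefix.
classify_prefix <- function(codes, prefixes, labels) {
  out <- rep(NA_character_, length(codes))
  best <- rep(-1L, length(codes))
  for (i in seq_along(prefixes)) {
    hit <- startsWith(codes, prefixes[i]) & nchar(prefixes[i]) > best
    if (any(hit)) {
      out[hit] <- labels[i]
      best[hit] <- nchar(prefixes[i])
    }
  }
  out
}

#' Classify a diagnosis claim against the cough codebook
#'
#' Matching is exact on the (ICD-10, standard name) pair: the standard
#' disease name is what separates, say, chronic cough from dry cough under
#' the shared R05 code.
#'
#' @param icd10,standard_name character vectors (recycled to equal length).
#' @param codebooks a [load_codebooks()] object.
#' @return character vector of cough categories, `NA` for unlisted pairs.
#' @export
classify_cough_claim <- function(icd10, standard_name, codebooks) {
  key <- paste(icd10, standard_name, sep = "\r")
  cb <- codebooks$cough
  cb_key <- paste(cb$icd10, cb$standard_name, sep = "\r")
  cb$category[match(key, cb_key)]
}

#' Classify ICD-10 codes against the cough-related disease codebook
#'
#' @param icd10 character vector of ICD-10 codes.
#' @param codebooks a [load_codebooks()] object.
#' @return character vector of disease / exclusion labels, `NA` if unmatched.
#' @export
classify_disease <- function(icd10, codebooks) {
  classify_prefix(icd10, codebooks$disease$prefix, codebooks$disease$label)
}

#' Classify ATC codes against the medication codebook
#'
#' @param atc character vector of ATC class codes.
#' @param codebooks a [load_codebooks()] object.
#' @return character vector of medication classes, `NA` if unmatched.
#' @export
classify_atc <- function(atc, codebooks) {
  classify_prefix(atc, codebooks$medication$prefix, codebooks$medication$class)
}
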