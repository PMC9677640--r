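#' Study periods
#'
#' The analysis is anchored on a 26-month selection period during which
#' participants can be enrolled. The study period starts 6 months earlier
#' (so every index month has a full pre-index window) and observation ends
#' 12 months after the selection period (so every index month has a full
#' post-index window). Defaults: study 2017-01, selection 2017-07..2019-08,
#' observation end 2020-08.
#'
#' @param selection_start,selection_end integer year-months ([ym()]) bounding
#'   the enrolment window, inclusive.
#' @return a list of class `"study_periods"` with `study_start`,
#'   `selection_start`, `selection_end`, `observation_end`.
#' @examples
#' p <- study_periods()
#' ym_format(p$observation_end)  # "2020-08"
#' @export
study_periods <- function(selection_start = ym(2017, 7),
                          selection_end = ym(2019, 8)) {
  stopifnot(selection_start <= selection_end)
  structure(
    list(
      study_start = selection_start - 6L,
      selection_start = selection_start,
      selection_end = selection_end,
      observation_end = selection_end + 12L
    ),
    class = "study_periods"
  )
}

#' @export
print.study_periods <- function(x, ...) {
  cat(sprintf(
    "study period %s..%s | selection %s..%s | observation ends %s\n",
    ym_format(x$study_start), ym_format(x$observation_end),
    ym_format(x$selection_start), ym_format(x$selection_end),
    ym_format(x$observation_end)
  ))
  invisible(x)
}

#' Read study periods from a yaml file
#'
#' The file carries `selection_start` and `selection_end` as "YYYY-MM"
#' strings; the derived bounds are recomputed, not trusted from the file.
#'
#' @param path path to a yaml file.
#' @export
read_periods <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("selection_start", "selection_end")) {
    if (is.null(cfg[[f]])) stop("periods file lacks field '", f, "'", call. = FALSE)
  }
  ss <- ym_parse(cfg$selection_start)
  se <- ym_parse(cfg$selection_end)
  if (is.na(ss) || is.na(se)) {
    stop("periods file has unparsable year-month (expected YYYY-MM)", call. = FALSE)
  }
  study_periods(ss, se)
}
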