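#' De-duplicate AERS reports
#'
#' The FDA's recommended rule for collapsing follow-up reports: among
#' all reports (ISRs) sharing one CASE number, keep the one with the
#' latest FDA receipt date (`FDA_DT`); when dates tie, keep the highest
#' ISR. A missing or unparseable date never beats a dated report; if
#' every report of a case lacks a date, the highest ISR wins.
#'
#' @param demo a DEMO table as returned by [read_demo()] (columns `isr`,
#'   `case_id`, `fda_dt`).
#' @return An object of class `keep_set`: a list with `retained_isrs`
#'   (integer vector, sorted), `provenance` (a `data.table` mapping each
#'   `case_id` to its retained `isr` and `fda_dt`), and counts
#'   `input_reports`, `retained_reports`, `distinct_cases`.
#' @export
#' @examples
#' demo <- data.table::data.table(
#'   isr     = c(4269368L, 4275741L, 7637789L, 7637797L),
#'   case_id = c(4047837L, 4047837L, 8468457L, 8468457L),
#'   fda_dt  = c(20040113L, 20040121L, 20110720L, 20110720L))
#' deduplicate(demo)$retained_isrs
deduplicate <- function(demo) {
  demo <- data.table::as.data.table(demo)
  stopifnot(all(c("isr", "case_id", "fda_dt") %in% names(demo)))
  if (nrow(demo) == 0L) {
    keep <- data.table::data.table(case_id = integer(), isr = integer(),
                                   fda_dt = integer())
  } else {
    d <- unique(demo[, list(isr, case_id, fda_dt)])
    # missing dates sort before any valid date
    d[, `:=`(.dt_key = data.table::fifelse(is.na(fda_dt), -1L, fda_dt))]
    data.table::setorder(d, case_id, .dt_key, isr)
    keep <- d[, utils::tail(.SD, 1L), by = case_id][, list(case_id, isr, fda_dt)]
  }
  structure(
    list(
      retained_isrs = sort(keep$isr),
      provenance = keep,
      input_reports = length(unique(demo$isr)),
      retained_reports = nrow(keep),
      distinct_cases = nrow(keep)
    ),
    class = "keep_set"
  )
}

#' @export
print.keep_set <- function(x, ...) {
  cat(sprintf(
    "keep_set: %d of %d reports retained (%d distinct cases)\n",
    x$retained_reports, x$input_reports, x$distinct_cases))
  invisible(x)
}

#' Filter an AERS table to the retained reports
#'
#' Propagates a de-duplication keep-set to any table keyed by `isr`
#' (DEMO, DRUG or REAC). Row order is preserved; rows whose ISR is not
#' retained are removed. ISRs absent from the DEMO-derived keep-set are
#' dropped here too — the keep-set is defined solely on DEMO.
#'
#' @param records a `data.table` with an `isr` column
#' @param keep a `keep_set` from [deduplicate()]
#' @return the retained rows, order preserved; attribute `dropped_count`
#'   records how many rows were removed.
#' @export
filter_table <- function(records, keep) {
  stopifnot(inherits(keep, "keep_set"), "isr" %in% names(records))
  records <- data.table::as.data.table(records)
  out <- records[isr %in% keep$retained_isrs]
  data.table::setattr(out, "dropped_count", nrow(records) - nrow(out))
  out
}
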