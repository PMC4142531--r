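#' AERS quarterly ASCII table input
#'
#' Readers for the three AERS/FAERS tables the pipeline consumes: DEMO
#' (report identity: ISR, CASE, FDA_DT), DRUG (verbatim drug text per
#' report) and REAC (MedDRA Preferred Terms per report). Files are plain
#' ASCII with one header line; the historical AERS distribution uses `$`
#' as the field delimiter, which is the default here and configurable per
#' file. Files are decoded as UTF-8 with a Latin-1 fallback per line, as
#' legacy quarters are not UTF-8 clean.
#'
#' Malformed data lines (too few fields to supply the required columns,
#' or unparseable ISR/CASE) are counted and reported via the
#' `malformed_count` attribute, never silently dropped from the
#' accounting: `nrow(result) + attr(result, "malformed_count")` equals
#' the number of data lines.
#'
#' @name aers_io
NULL

read_aers_lines <- function(path) {
  if (!file.exists(path)) {
    stop_aersdm(sprintf("AERS table not found: %s", path), "aersdm_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  bad <- !validUTF8(lines)
  if (any(bad)) {
    lines[bad] <- iconv(lines[bad], from = "latin1", to = "UTF-8")
  }
  lines
}

# Split header + data lines against a required/optional column contract.
# Returns a list of character matrices-worth of fields plus bookkeeping.
parse_aers_table <- function(path, required, optional = character(), delim = "$") {
  lines <- read_aers_lines(path)
  if (length(lines) == 0L) {
    stop_aersdm(sprintf("empty file (no header line): %s", path),
                "aersdm_io_error")
  }
  header <- toupper(squish(strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]]))
  idx <- match(required, header)
  if (anyNA(idx)) {
    stop_aersdm(sprintf("missing required column(s) %s in %s",
                        paste(required[is.na(idx)], collapse = ", "), path),
                "aersdm_config_error")
  }
  opt_idx <- match(optional, header)
  data_lines <- lines[-1L]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  # short rows are not rejected here: trailing empty fields are legal
  # (strsplit drops them); the readers demote rows whose required
  # identifier fields fail to parse
  fields <- strsplit(data_lines, delim, fixed = TRUE)
  list(
    fields = fields,
    malformed = 0L,
    n_data_lines = length(data_lines),
    idx = stats::setNames(as.list(idx), required),
    opt_idx = stats::setNames(as.list(opt_idx), optional),
    column_map = header
  )
}

pick_field <- function(fields, i) {
  if (is.na(i)) return(rep("", length(fields)))
  vapply(fields, function(f) if (length(f) >= i) f[[i]] else "", character(1))
}

finish_aers_table <- function(dt, parsed, extra_malformed = 0L) {
  malformed <- parsed$malformed + extra_malformed
  data.table::setattr(dt, "malformed_count", as.integer(malformed))
  data.table::setattr(dt, "data_line_count", as.integer(parsed$n_data_lines))
  data.table::setattr(dt, "column_map", parsed$column_map)
  dt
}

# FDA_DT is encoded YYYYMMDD; returns integer, NA when not a valid
# calendar date. Integer order equals lexicographic YYYYMMDD order.
parse_fda_dt <- function(x) {
  x <- trimws(x)
  out <- rep(NA_integer_, length(x))
  cand <- grepl("^[0-9]{8}$", x)
  if (any(cand)) {
    d <- as.Date(x[cand], format = "%Y%m%d")
    ok <- !is.na(d)
    out[which(cand)[ok]] <- as.integer(x[cand][ok])
  }
  out
}

#' Read an AERS DEMO table
#'
#' @param path path to a delimiter-separated DEMO file with a header line
#'   naming at least `ISR`, `CASE` and `FDA_DT` (case-insensitive).
#' @param delim field delimiter, default `"$"`.
#' @return A `data.table` with columns `isr`, `case_id` (integer) and
#'   `fda_dt` (integer `YYYYMMDD`, `NA` when missing or not a valid
#'   calendar date). Attributes `malformed_count` and `data_line_count`
#'   carry the line accounting; `column_map` records the header as read.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("ISR$CASE$FDA_DT", "4275741$4047837$20040121"), f)
#' read_demo(f)
read_demo <- function(path, delim = "$") {
  p <- parse_aers_table(path, required = c("ISR", "CASE", "FDA_DT"),
                        delim = delim)
  isr <- suppressWarnings(as.integer(trimws(pick_field(p$fields, p$idx$ISR))))
  case_id <- suppressWarnings(as.integer(trimws(pick_field(p$fields, p$idx$CASE))))
  fda_dt <- parse_fda_dt(pick_field(p$fields, p$idx$FDA_DT))
  ok <- !is.na(isr) & !is.na(case_id)
  dt <- data.table::data.table(isr = isr[ok], case_id = case_id[ok],
                               fda_dt = fda_dt[ok])
  finish_aers_table(dt, p, extra_malformed = sum(!ok))
}

#' Read an AERS DRUG table
#'
#' @inheritParams read_demo
#' @return A `data.table` with columns `isr`, `drug_seq` (integer),
#'   `drugname`, `route`, `dose_vbm` (verbatim character; empty string
#'   when the optional `ROUTE`/`DOSE_VBM` columns are absent). Line
#'   accounting attributes as in [read_demo()].
#' @export
read_drug <- function(path, delim = "$") {
  p <- parse_aers_table(path, required = c("ISR", "DRUG_SEQ", "DRUGNAME"),
                        optional = c("ROUTE", "DOSE_VBM"), delim = delim)
  isr <- suppressWarnings(as.integer(trimws(pick_field(p$fields, p$idx$ISR))))
  drug_seq <- suppressWarnings(as.integer(trimws(pick_field(p$fields, p$idx$DRUG_SEQ))))
  ok <- !is.na(isr) & !is.na(drug_seq)
  dt <- data.table::data.table(
    isr = isr[ok],
    drug_seq = drug_seq[ok],
    drugname = trimws(pick_field(p$fields, p$idx$DRUGNAME))[ok],
    route = trimws(pick_field(p$fields, p$opt_idx$ROUTE))[ok],
    dose_vbm = trimws(pick_field(p$fields, p$opt_idx$DOSE_VBM))[ok]
  )
  finish_aers_table(dt, p, extra_malformed = sum(!ok))
}

#' Read an AERS REAC table
#'
#' @inheritParams read_demo
#' @return A `data.table` with columns `isr` (integer) and `pt_term`
#'   (whitespace-trimmed verbatim MedDRA Preferred Term). Rows whose PT
#'   is empty after trimming are counted as malformed. Line accounting
#'   attributes as in [read_demo()].
#' @export
read_reac <- function(path, delim = "$") {
  p <- parse_aers_table(path, required = c("ISR", "PT"), delim = delim)
  isr <- suppressWarnings(as.integer(trimws(pick_field(p$fields, p$idx$ISR))))
  pt_term <- squish(pick_field(p$fields, p$idx$PT))
  ok <- !is.na(isr) & nzchar(pt_term)
  dt <- data.table::data.table(isr = isr[ok], pt_term = pt_term[ok])
  finish_aers_table(dt, p, extra_malformed = sum(!ok))
}

#' Write an AERS-style delimited table
#'
#' Inverse of the readers, used by the fixture generator and for
#' persisting filtered tables. Column names are upper-cased to the AERS
#' header convention (`isr` -> `ISR`, `case_id` -> `CASE`,
#' `pt_term` -> `PT`).
#'
#' @param x a `data.table`/data.frame as produced by the readers
#' @param path output path
#' @param delim field delimiter, default `"$"`
#' @return `path`, invisibly
#' @export
write_aers_table <- function(x, path, delim = "$") {
  hdr_map <- c(isr = "ISR", case_id = "CASE", fda_dt = "FDA_DT",
               drug_seq = "DRUG_SEQ", drugname = "DRUGNAME",
               route = "ROUTE", dose_vbm = "DOSE_VBM", pt_term = "PT")
  hdr <- ifelse(names(x) %in% names(hdr_map), hdr_map[names(x)],
                toupper(names(x)))
  cols <- lapply(x, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  body <- do.call(paste, c(cols, sep = delim))
  writeLines(c(paste(hdr, collapse = delim), body), path)
  invisible(path)
}
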