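#' MedDRA PT and SOC mapping
#'
#' AERS REAC entries are MedDRA Preferred Terms (PTs) in verbatim text.
#' This module maps PT terms to PT codes and rolls PT codes up to their
#' primary System Organ Class (SOC). MedDRA is a licensed terminology
#' and is never shipped with this package: the tables are consumed from
#' a user-supplied TSV (columns `pt_term`, `pt_code`, `soc_code`,
#' `soc_name`, `primary_flag`), one row per (PT, SOC) link.
#'
#' Each PT is rolled up to exactly one (primary) SOC rather than fanned
#' out over all linked SOCs, so SOC-level aggregation partitions the
#' record set and percentages sum to 100.
#'
#' @name meddra_map
NULL

#' Load MedDRA PT/SOC tables from TSV
#'
#' @param path TSV with header columns `pt_term`, `pt_code`, `soc_code`,
#'   and optionally `soc_name` (defaults to the code) and `primary_flag`
#'   (`Y`/`N`; when absent, the first SOC row of each PT is primary).
#' @return object of class `meddra_tables`: list with `pt_lexicon`
#'   (keyed `data.table` case-folded term -> `pt_code`), `pt_to_soc`
#'   (`data.table` `pt_code`, `soc_code`, `is_primary`), `soc_names`
#'   (`data.table` `soc_code`, `soc_name`).
#' @export
load_meddra <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", showProgress = FALSE)
  need <- c("pt_term", "pt_code", "soc_code")
  if (!all(need %in% names(dt))) {
    stop_aersdm("MedDRA TSV must have columns pt_term, pt_code, soc_code",
                "aersdm_config_error")
  }
  dt[, pt_code := as.integer(pt_code)]
  dt[, soc_code := as.integer(soc_code)]
  if (!"soc_name" %in% names(dt)) dt[, soc_name := as.character(soc_code)]
  dt[!nzchar(soc_name), soc_name := as.character(soc_code)]
  if (!"primary_flag" %in% names(dt)) {
    dt[, primary_flag := c("Y", rep("N", .N - 1L)), by = pt_code]
  }
  dt <- unique(dt, by = c("pt_code", "soc_code"))
  if (any(is.na(dt$pt_code) | is.na(dt$soc_code))) {
    stop_aersdm("non-numeric pt_code/soc_code in MedDRA TSV",
                "aersdm_config_error")
  }
  n_primary <- dt[, list(n = sum(primary_flag == "Y")), by = pt_code]
  if (any(n_primary$n != 1L)) {
    stop_aersdm("every pt_code must have exactly one primary SOC row",
                "aersdm_config_error")
  }
  pt_lexicon <- unique(dt[, list(term_key = canonical_pt_term(pt_term),
                                 pt_code)])
  if (anyDuplicated(pt_lexicon$term_key)) {
    stop_aersdm("a PT term maps to more than one pt_code",
                "aersdm_config_error")
  }
  data.table::setkey(pt_lexicon, term_key)
  pt_to_soc <- dt[, list(pt_code, soc_code, is_primary = primary_flag == "Y")]
  data.table::setkey(pt_to_soc, pt_code)
  soc_names <- unique(dt[, list(soc_code, soc_name)], by = "soc_code")
  structure(list(pt_lexicon = pt_lexicon, pt_to_soc = pt_to_soc,
                 soc_names = soc_names),
            class = "meddra_tables")
}

#' @export
print.meddra_tables <- function(x, ...) {
  cat(sprintf("meddra_tables: %d PTs, %d SOCs\n",
              nrow(x$pt_lexicon), nrow(x$soc_names)))
  invisible(x)
}

#' Map a verbatim PT term to its MedDRA PT code
#'
#' Exact match after case folding and whitespace normalization; the
#' REAC table already uses MedDRA PTs, so fuzzy matching is neither
#' needed nor safe. A miss returns `NA`.
#'
#' @param term character vector of PT terms
#' @param tables a `meddra_tables`
#' @return integer vector of PT codes (`NA` for unmapped terms)
#' @export
map_pt <- function(term, tables) {
  keys <- canonical_pt_term(term)
  tables$pt_lexicon[list(keys), pt_code]
}

#' Primary SOC of a PT code
#'
#' @param pt_code integer vector of PT codes
#' @param tables a `meddra_tables`
#' @return integer vector of primary SOC codes (`NA` for unknown PTs)
#' @export
pt_to_soc <- function(pt_code, tables) {
  codes <- pt_code
  prim <- tables$pt_to_soc[is_primary == TRUE]
  data.table::setkey(prim, pt_code)
  prim[list(codes), soc_code]
}
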