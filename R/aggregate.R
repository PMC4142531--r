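#' Drug-ADE table construction and aggregation
#'
#' The end product is a pair of flat tables: the normalized record
#' table, one row per (report, RxNorm drug concept, MedDRA PT)
#' co-occurrence, and the aggregated table of class-level drug/event
#' pair counts. The two connect through the RxNorm codes.
#'
#' A Drug-ADE record is defined as the within-report cross product of a
#' report's matched drug mentions and its mapped reactions: every drug
#' reported on an ISR co-occurs with every adverse event reported on
#' that ISR. Unmatched drug mentions and unmapped PTs contribute
#' nothing (their counts are reported as attributes).
#'
#' @name aggregate
NULL

#' Build the normalized Drug-ADE record table
#'
#' @param drug_mentions mention table from [normalize_drug_table()] or
#'   [import_medex_output()] joined back to `isr` (columns `isr`,
#'   `rxcui`, `status`)
#' @param reac_records REAC table from [read_reac()] (columns `isr`,
#'   `pt_term`)
#' @param keep a `keep_set` from [deduplicate()]; both inputs are
#'   filtered to the retained reports
#' @param meddra a `meddra_tables` from [load_meddra()]
#' @param distinct if `TRUE`, collapse repeated (rxcui, pt_code) pairs
#'   within one report to a single record; default `FALSE` (occurrence
#'   pairs)
#' @return `data.table` with columns `isr`, `rxcui`, `pt_code`,
#'   `soc_code`. Attributes `unmatched_drug_count` and
#'   `unmapped_pt_count` report what was excluded.
#' @export
build_drug_ade_records <- function(drug_mentions, reac_records, keep, meddra,
                                   distinct = FALSE) {
  mentions <- filter_table(data.table::as.data.table(drug_mentions), keep)
  reac <- filter_table(data.table::as.data.table(reac_records), keep)
  unmatched <- sum(mentions$status != "matched" | is.na(mentions$rxcui))
  drugs <- mentions[status == "matched" & !is.na(rxcui), list(isr, rxcui)]
  reac[, pt_code := map_pt(pt_term, meddra)]
  unmapped <- sum(is.na(reac$pt_code))
  events <- reac[!is.na(pt_code), list(isr, pt_code)]
  events[, soc_code := pt_to_soc(pt_code, meddra)]
  out <- merge(drugs, events, by = "isr", allow.cartesian = TRUE)
  if (distinct) out <- unique(out, by = c("isr", "rxcui", "pt_code"))
  data.table::setcolorder(out, c("isr", "rxcui", "pt_code", "soc_code"))
  data.table::setattr(out, "unmatched_drug_count", unmatched)
  data.table::setattr(out, "unmapped_pt_count", unmapped)
  out[]
}

#' Count distinct drug/event pairs
#'
#' @param records Drug-ADE records from [build_drug_ade_records()]
#' @param level `"PT"` or `"SOC"`
#' @return integer: number of distinct (rxcui, event-code) pairs at the
#'   requested level
#' @export
count_unique_pairs <- function(records, level = c("PT", "SOC")) {
  level <- match.arg(level)
  records <- data.table::as.data.table(records)
  if (level == "PT") {
    nrow(unique(records[, list(rxcui, pt_code)]))
  } else {
    nrow(unique(records[, list(rxcui, soc_code)]))
  }
}

#' Aggregate Drug-ADE records to class-level pair counts
#'
#' Joins each record to the class memberships of its drug concept on
#' the chosen axis; a drug belonging to several classes on that axis
#' increments every one of them (fan-out semantics). Counts are
#' co-occurrence totals over records.
#'
#' @param records Drug-ADE records from [build_drug_ade_records()]
#' @param classifications memberships from [classify_concepts()]
#'   (columns `rxcui`, `axis`, `class_code`, `class_name`)
#' @param axis one of the nine class-axis labels ([ndfrt_axes()])
#' @param level `"PT"` or `"SOC"`
#' @return `data.table` ordered by `count` descending: `axis`,
#'   `class_code`, `class_name`, `ade_level`, `ade_code`, `count`
#' @export
aggregate_pairs <- function(records, classifications, axis,
                            level = c("PT", "SOC")) {
  level <- match.arg(level)
  axis_label <- axis
  records <- data.table::as.data.table(records)
  cls <- data.table::as.data.table(classifications)
  cls <- unique(cls[axis == axis_label,
                    list(rxcui, class_code, class_name)])
  records[, ade_code := if (level == "PT") pt_code else soc_code]
  joined <- merge(records[, list(rxcui, ade_code)], cls, by = "rxcui",
                  allow.cartesian = TRUE)
  out <- joined[, list(count = .N), by = list(class_code, class_name, ade_code)]
  out[, `:=`(axis = axis_label, ade_level = level)]
  data.table::setcolorder(out, c("axis", "class_code", "class_name",
                                 "ade_level", "ade_code", "count"))
  data.table::setorder(out, -count, class_code, ade_code)
  records[, ade_code := NULL]
  out[]
}

#' Distribution of Drug-ADE records over System Organ Classes
#'
#' Primary-SOC rollup partitions the record set, so the percentage
#' column sums to 100 (up to rounding). Percentages are rounded
#' half-up to one decimal.
#'
#' @param records Drug-ADE records from [build_drug_ade_records()]
#' @param meddra a `meddra_tables` (for SOC labels)
#' @return `data.table` ordered by `n_records` descending: `soc_code`,
#'   `soc_name`, `n_pt_codes`, `n_records`, `pct`
#' @export
soc_distribution <- function(records, meddra) {
  records <- data.table::as.data.table(records)
  total <- nrow(records)
  out <- records[, list(n_pt_codes = length(unique(pt_code)),
                        n_records = .N), by = soc_code]
  out <- merge(out, meddra$soc_names, by = "soc_code", all.x = TRUE)
  out[is.na(soc_name), soc_name := as.character(soc_code)]
  out[, pct := if (total > 0) round_half_up(100 * n_records / total, 1)
      else NA_real_]
  data.table::setorder(out, -n_records, soc_code)
  data.table::setcolorder(out, c("soc_code", "soc_name", "n_pt_codes",
                                 "n_records", "pct"))
  out[]
}

#' Report and drug counts per class
#'
#' Profile of one class axis: for each class, the number of distinct
#' retained reports containing at least one drug of that class and the
#' number of distinct drug concepts of that class seen in the records.
#' Classes with many reports but few drugs stand out as candidates for
#' further disproportionality mining.
#'
#' @inheritParams aggregate_pairs
#' @return `data.table` ordered by `n_reports` descending:
#'   `class_code`, `class_name`, `n_reports`, `n_drugs`
#' @export
class_profile <- function(records, classifications, axis) {
  axis_label <- axis
  records <- data.table::as.data.table(records)
  cls <- data.table::as.data.table(classifications)
  cls <- unique(cls[axis == axis_label, list(rxcui, class_code, class_name)])
  joined <- merge(unique(records[, list(isr, rxcui)]), cls, by = "rxcui",
                  allow.cartesian = TRUE)
  out <- joined[, list(n_reports = length(unique(isr)),
                       n_drugs = length(unique(rxcui))),
                by = list(class_code, class_name)]
  data.table::setorder(out, -n_reports, class_code)
  out[]
}
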