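#' Drug-name normalization to RxNorm
#'
#' AERS drug entries are free text. Following the pipeline's design, the
#' `DRUGNAME`, `DOSE_VBM` and `ROUTE` fields are concatenated into one
#' input string, which is then normalized to an RxNorm concept (RxCUI)
#' either by the built-in lexicon matcher or by ingesting the output of
#' an external medication-extraction tool (MedEx) via
#' [import_medex_output()].
#'
#' The built-in matcher is deliberately transparent: input and lexicon
#' strings are case-folded, punctuation-stripped and
#' whitespace-collapsed. A lexicon entry is a candidate when its first
#' token equals the input's first token (the match is anchored at the
#' drug-name head) and every one of its tokens occurs somewhere in the
#' input; the concatenated dose and route text supplies strength and
#' form tokens out of their lexicon order, so containment rather than
#' token-by-token prefix equality is required. The longest candidate
#' (most tokens) wins; a full-string exact match always wins outright;
#' remaining ties are broken by term-type priority (clinical drug over
#' brand over ingredient), then lowest rxcui. Anchoring at the head
#' avoids the class of false positives where an inner token such as a
#' salt name ("sodium") is matched instead of the drug.
#'
#' @name drug_normalizer
NULL

TTY_PRIORITY <- c(SCD = 1, SBD = 2, SCDC = 3, GPCK = 4, BPCK = 5,
                  BN = 6, IN = 7, PIN = 8, MIN = 9)

tty_rank <- function(tty) {
  r <- TTY_PRIORITY[tty]
  r[is.na(r)] <- 50
  unname(r)
}

#' Build a normalization lexicon from a concept graph
#'
#' One entry per distinct canonical string; when several concepts share
#' a string, the tie is broken by term-type priority (semantic clinical
#' drug over brand over ingredient), then by lowest rxcui, so lookup is
#' deterministic. Suppressed atoms are excluded.
#'
#' @param graph an `rx_graph` from [load_rrf()]
#' @return object of class `rx_lexicon`: a `data.table` keyed by
#'   `first_token` with columns `key` (canonical string), `rxcui`,
#'   `tty`, `name` (the original lexicon string), `rank` (term-type
#'   priority) and `n_tokens`
#' @export
build_lexicon <- function(graph) {
  atoms <- graph$atoms[!(suppress %in% c("Y", "E", "O"))]
  entries <- atoms[, list(key = canonical_drug_string(name),
                          rxcui, tty, name)]
  entries <- entries[nzchar(key)]
  entries[, rank := tty_rank(tty)]
  data.table::setorder(entries, key, rank, rxcui)
  entries <- entries[, utils::head(.SD, 1L), by = key]
  entries[, n_tokens := lengths(strsplit(key, " ", fixed = TRUE))]
  entries[, first_token := sub(" .*", "", key)]
  data.table::setkey(entries, first_token)
  structure(entries, class = c("rx_lexicon", class(entries)))
}

#' Concatenate the DRUG-table fields into the normalization input
#'
#' Fields are joined in the order `DRUGNAME`, `DOSE_VBM`, `ROUTE` with
#' single spaces; empty fields are skipped and internal whitespace is
#' collapsed. The dose and route text add form/route tokens (e.g.
#' "TABLET", "ORAL") that help the match reach a specific clinical-drug
#' concept.
#'
#' @param drugname,route,dose_vbm character vectors (recycled per row)
#' @return character vector of concatenated input strings
#' @export
#' @examples
#' build_input_string("ASPIRIN", "", "")
build_input_string <- function(drugname, route = "", dose_vbm = "") {
  n <- max(length(drugname), length(route), length(dose_vbm))
  drugname <- rep_len(squish(drugname), n)
  route <- rep_len(squish(route), n)
  dose_vbm <- rep_len(squish(dose_vbm), n)
  out <- character(n)
  for (i in seq_len(n)) {
    parts <- c(drugname[i], dose_vbm[i], route[i])
    out[i] <- paste(parts[nzchar(parts)], collapse = " ")
  }
  out
}

# Head-anchored containment match of `tokens` against the lexicon.
# Returns a one-row data.table (rxcui, name) or NULL.
match_tokens <- function(tokens, lexicon) {
  cands <- lexicon[list(tokens[1L]), nomatch = NULL]
  if (nrow(cands) == 0L) return(NULL)
  contained <- vapply(strsplit(cands$key, " ", fixed = TRUE),
                      function(kt) all(kt %in% tokens), logical(1))
  cands <- cands[contained]
  if (nrow(cands) == 0L) return(NULL)
  full <- paste(tokens, collapse = " ")
  exact <- cands[key == full]
  if (nrow(exact)) return(exact[1L, list(rxcui, name)])
  data.table::setorder(cands, -n_tokens, rank, rxcui)
  cands[1L, list(rxcui, name)]
}

#' Normalize one drug string against a lexicon
#'
#' @param text input string (typically from [build_input_string()])
#' @param lexicon an `rx_lexicon`
#' @return list with `matched_rxcui` (integer or `NA`), `matched_name`
#'   (character or `NA`) and `status` (`"matched"` / `"unmatched"`)
#' @export
normalize_mention <- function(text, lexicon) {
  tokens <- strsplit(canonical_drug_string(text), " ", fixed = TRUE)[[1L]]
  hit <- if (length(tokens) && nzchar(tokens[1L])) {
    match_tokens(tokens, lexicon)
  }
  if (is.null(hit)) {
    list(matched_rxcui = NA_integer_, matched_name = NA_character_,
         status = "unmatched")
  } else {
    list(matched_rxcui = hit$rxcui, matched_name = hit$name,
         status = "matched")
  }
}

#' Normalize a whole DRUG table
#'
#' Builds the concatenated input string for every row and matches it
#' against the lexicon. Rows with an empty `DRUGNAME` are flagged
#' unmatched without a lookup.
#'
#' @param drug a DRUG table from [read_drug()]
#' @param lexicon an `rx_lexicon`
#' @return `data.table` of drug mentions: `isr`, `drug_seq`,
#'   `input_string`, `rxcui`, `matched_name`, `status`
#' @export
normalize_drug_table <- function(drug, lexicon) {
  drug <- data.table::as.data.table(drug)
  input_string <- build_input_string(drug$drugname, drug$route, drug$dose_vbm)
  uniq <- unique(input_string)
  res <- lapply(uniq, function(s) {
    if (!nzchar(squish(s))) {
      return(list(matched_rxcui = NA_integer_,
                  matched_name = NA_character_, status = "unmatched"))
    }
    normalize_mention(s, lexicon)
  })
  lut <- data.table::data.table(
    input_string = uniq,
    rxcui = vapply(res, `[[`, integer(1), "matched_rxcui"),
    matched_name = vapply(res, `[[`, character(1), "matched_name"),
    status = vapply(res, `[[`, character(1), "status")
  )
  out <- data.table::data.table(isr = drug$isr, drug_seq = drug$drug_seq,
                                input_string = input_string)
  lut[out, on = "input_string"][
    , list(isr, drug_seq, input_string, rxcui, matched_name, status)]
}

#' Import externally produced MedEx normalization output
#'
#' Adapter for runs where normalization was done by the MedEx tool
#' outside this package. Expected format: tab-separated lines
#' `input_string<TAB>rxcui` (empty rxcui = unmatched). RxCUIs are
#' validated against the loaded graph; codes absent from the graph are
#' demoted to unmatched and counted in the `invalid_rxcui_count`
#' attribute.
#'
#' @param path TSV path
#' @param graph an `rx_graph` used for code validation
#' @return `data.table` of mentions: `input_string`, `rxcui`,
#'   `matched_name`, `status`
#' @export
import_medex_output <- function(path, graph) {
  if (!file.exists(path)) {
    stop_aersdm(sprintf("MedEx output not found: %s", path), "aersdm_io_error")
  }
  lines <- read_aers_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  dt <- data.table::data.table(
    input_string = vapply(parts, function(p) p[1] %||% "", character(1)),
    rxcui = suppressWarnings(as.integer(vapply(
      parts, function(p) if (length(p) >= 2) p[2] else "", character(1))))
  )
  dt <- dt[nzchar(input_string)]
  invalid <- !is.na(dt$rxcui) & !(dt$rxcui %in% graph$concepts$rxcui)
  if (any(invalid)) {
    warning(sprintf("%d MedEx rxcui(s) absent from the concept graph; demoted to unmatched",
                    sum(invalid)))
    dt[invalid, rxcui := NA_integer_]
  }
  dt <- merge(dt, graph$concepts[, list(rxcui, matched_name = name)],
              by = "rxcui", all.x = TRUE, sort = FALSE)
  dt[, status := data.table::fifelse(is.na(rxcui), "unmatched", "matched")]
  out <- dt[, list(input_string, rxcui, matched_name, status)]
  data.table::setattr(out, "invalid_rxcui_count", sum(invalid))
  out
}

#' Summary statistics of a normalization run
#'
#' @param mentions a mention table (from [normalize_drug_table()] or
#'   [import_medex_output()])
#' @return list: `n_unique_input_strings`, `n_unique_matched_strings`,
#'   `n_unique_rxcuis`, `pct_matched` (unique matched strings / unique
#'   input strings as a percent, rounded half-up to an integer; `NA`
#'   when there are no mentions)
#' @export
normalization_stats <- function(mentions) {
  mentions <- data.table::as.data.table(mentions)
  n_in <- length(unique(mentions$input_string))
  matched <- mentions[status == "matched"]
  n_ok <- length(unique(matched$input_string))
  list(
    n_unique_input_strings = n_in,
    n_unique_matched_strings = n_ok,
    n_unique_rxcuis = length(unique(matched$rxcui)),
    pct_matched = if (n_in == 0L) NA_real_ else round_half_up(100 * n_ok / n_in)
  )
}
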