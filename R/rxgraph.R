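#' RxNorm concept graph
#'
#' Loads the two Rich Release Format (RRF) tables the pipeline needs —
#' the concept/atom table (`RXNCONSO.RRF` layout) and the relationship
#' table (`RXNREL.RRF` layout) — into a typed concept graph. Each
#' concept (RxCUI) carries its names, term types (TTY: IN, PIN, BN, SCD,
#' SBD, SCDC, ...) and source vocabularies (SAB); edges carry the RELA
#' relationship label (has_ingredient, tradename_of, consists_of, ...).
#'
#' @name rxgraph
NULL

RXNCONSO_COLS <- c("RXCUI", "LAT", "TS", "LUI", "STT", "SUI", "ISPREF",
                   "RXAUI", "SAUI", "SCUI", "SDUI", "SAB", "TTY", "CODE",
                   "STR", "SRL", "SUPPRESS", "CVF")
RXNREL_COLS <- c("RXCUI1", "RXAUI1", "STYPE1", "REL", "RXCUI2", "RXAUI2",
                 "STYPE2", "RELA", "RUI", "SRUI", "SAB", "SL", "RG", "DIR",
                 "SUPPRESS", "CVF")

read_rrf <- function(path, cols) {
  empty <- data.table::as.data.table(
    stats::setNames(rep(list(character()), length(cols)), cols))
  if (!file.exists(path)) {
    stop_aersdm(sprintf("RRF file not found: %s", path), "aersdm_io_error")
  }
  if (file.size(path) == 0L) return(empty)
  dt <- data.table::fread(path, sep = "|", header = FALSE, quote = "",
                          fill = TRUE, colClasses = "character",
                          showProgress = FALSE)
  if (nrow(dt) == 0L) return(empty)
  # RRF lines end with a trailing "|", producing one empty extra column
  if (ncol(dt) > length(cols)) dt <- dt[, seq_along(cols), with = FALSE]
  while (ncol(dt) < length(cols)) {
    data.table::set(dt, j = paste0("pad", ncol(dt) + 1L), value = "")
  }
  data.table::setnames(dt, cols)
  dt
}

#' Load RxNorm RRF files into a concept graph
#'
#' @param conso_path path to a pipe-delimited concept file with the
#'   `RXNCONSO.RRF` column layout (no header line).
#' @param rel_path path to a pipe-delimited relationship file with the
#'   `RXNREL.RRF` column layout.
#' @return An object of class `rx_graph`: a list with
#'   \describe{
#'     \item{atoms}{`data.table` of atoms: `rxcui`, `name`, `tty`,
#'       `sab`, `suppress`.}
#'     \item{concepts}{one row per rxcui with a preferred `name`.}
#'     \item{edges}{deduplicated RELA-labelled edges `from`, `to`,
#'       `rela`, as directed in the file.}
#'     \item{adjacency}{undirected adjacency index (the edge list plus
#'       its transpose) used for traversal.}
#'   }
#'   Relationship rows referencing an rxcui absent from the concept
#'   table, or lacking a RELA label, are dropped; their counts are kept
#'   in `dropped_edges` / `rela_less_edges`.
#' @export
load_rrf <- function(conso_path, rel_path) {
  conso <- read_rrf(conso_path, RXNCONSO_COLS)
  rel <- read_rrf(rel_path, RXNREL_COLS)

  atoms <- conso[, list(
    rxcui = suppressWarnings(as.integer(RXCUI)),
    name = STR, tty = TTY, sab = SAB,
    suppress = SUPPRESS
  )]
  atoms <- atoms[!is.na(rxcui) & nzchar(name)]
  concepts <- atoms[, list(name = name[1L]), by = rxcui]
  data.table::setkey(concepts, rxcui)

  edges <- rel[, list(
    from = suppressWarnings(as.integer(RXCUI1)),
    to = suppressWarnings(as.integer(RXCUI2)),
    rela = RELA, sab = SAB
  )]
  edges <- edges[!is.na(from) & !is.na(to)]
  rela_less <- edges[!nzchar(rela)]
  edges <- edges[nzchar(rela)]
  known <- edges$from %in% concepts$rxcui & edges$to %in% concepts$rxcui
  dropped <- sum(!known)
  if (dropped > 0L) {
    warning(sprintf("%d relationship row(s) reference unknown rxcuis; dropped",
                    dropped))
  }
  edges <- unique(edges[known])

  adjacency <- unique(data.table::rbindlist(list(
    edges[, list(a = from, b = to, rela)],
    edges[, list(a = to, b = from, rela)]
  )))
  data.table::setkey(adjacency, a)

  structure(
    list(atoms = atoms, concepts = concepts, edges = edges,
         adjacency = adjacency,
         dropped_edges = dropped, rela_less_edges = nrow(rela_less)),
    class = "rx_graph"
  )
}

#' @export
print.rx_graph <- function(x, ...) {
  cat(sprintf("rx_graph: %d concepts (%d atoms), %d RELA edges\n",
              nrow(x$concepts), nrow(x$atoms), nrow(x$edges)))
  invisible(x)
}

#' Does a concept carry the NDF-RT source vocabulary?
#'
#' A concept counts as an NDF-RT concept when at least one of its atoms
#' is sourced from the NDF-RT vocabulary (SAB matched case-insensitively
#' against `NDFRT`).
#'
#' @param graph an `rx_graph`
#' @param rxcui integer vector of concept identifiers
#' @return logical vector, one element per input rxcui
#' @export
is_ndfrt_concept <- function(graph, rxcui) {
  ndfrt_cuis <- ndfrt_concepts(graph)
  rxcui %in% ndfrt_cuis
}

ndfrt_concepts <- function(graph) {
  unique(graph$atoms[toupper(sab) == "NDFRT", rxcui])
}

#' Term types of concepts
#'
#' @param graph an `rx_graph`
#' @param rxcui integer vector
#' @return list of character vectors of term types, one per rxcui
#' @export
concept_term_types <- function(graph, rxcui) {
  tt <- graph$atoms[, list(ttys = list(unique(tty))), by = rxcui]
  data.table::setkey(tt, rxcui)
  res <- tt[data.table::data.table(rxcui = rxcui), ttys]
  lapply(res, function(v) if (is.null(v)) character() else v)
}

#' Default mapping from NDF-RT role relationship labels to class axes
#'
#' Used when deriving a class-membership table from RRF relationship
#' rows sourced to NDF-RT (see [extract_class_table()]). The nine axis
#' labels form the closed set used throughout the package. The mapping
#' is a plain named character vector so callers can supply their own.
#'
#' @return named character vector: RELA label -> axis label
#' @export
default_axis_map <- function() {
  c(
    has_ingredients            = "Generic Ingredient Combinations",
    has_chemical_structure     = "Chemical Ingredients Class",
    may_treat                  = "Therapeutic Intent",
    has_mechanism_of_action    = "Mechanism of Action",
    has_physiologic_effect     = "Physiologic Effect",
    has_va_class               = "VA Class",
    has_epc                    = "FDA Established Pharmacologic Class",
    has_therapeutic_class      = "Therapeutic Category",
    has_pk                     = "Pharmacokinetics"
  )
}

#' The nine NDF-RT class axis labels
#' @return character vector of the closed axis set
#' @export
ndfrt_axes <- function() unname(default_axis_map())

#' Derive an NDF-RT class-membership table from the loaded graph
#'
#' Scans NDF-RT-sourced relationship rows whose RELA labels appear in
#' the axis map and emits one class membership per (concept, axis,
#' class) triple. The class code is the class concept's rxcui and the
#' class name its preferred name.
#'
#' @param graph an `rx_graph`
#' @param axis_map named character vector RELA -> axis label; defaults
#'   to [default_axis_map()]
#' @return `data.table` with columns `ndfrt_rxcui`, `axis`,
#'   `class_code`, `class_name`
#' @export
extract_class_table <- function(graph, axis_map = default_axis_map()) {
  ed <- graph$edges[toupper(sab) == "NDFRT" & rela %in% names(axis_map)]
  out <- ed[, list(ndfrt_rxcui = from,
                   axis = unname(axis_map[rela]),
                   class_cui = to)]
  out <- merge(out, graph$concepts[, list(class_cui = rxcui,
                                          class_name = name)],
               by = "class_cui", all.x = TRUE)
  out[is.na(class_name), class_name := as.character(class_cui)]
  unique(out[, list(ndfrt_rxcui, axis, class_code = as.character(class_cui),
                    class_name)])
}

#' Load a class-membership table from TSV
#'
#' Alternative to [extract_class_table()] for users who hold an NDF-RT
#' distribution outside RxNorm. Expected columns: `ndfrt_rxcui`, `axis`,
#' `class_code`, `class_name` (tab-separated, header line).
#'
#' @param path TSV path
#' @return `data.table` with those four columns; axes are validated
#'   against the closed nine-label set.
#' @export
load_class_table <- function(path) {
  ct <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("class_code",
                                                          "class_name")),
                          showProgress = FALSE)
  need <- c("ndfrt_rxcui", "axis", "class_code", "class_name")
  if (!all(need %in% names(ct))) {
    stop_aersdm("class table must have columns ndfrt_rxcui, axis, class_code, class_name",
                "aersdm_config_error")
  }
  bad <- setdiff(unique(ct$axis), ndfrt_axes())
  if (length(bad)) {
    stop_aersdm(sprintf("unknown class axis label(s): %s",
                        paste(bad, collapse = ", ")),
                "aersdm_config_error")
  }
  ct[, ndfrt_rxcui := as.integer(ndfrt_rxcui)]
  unique(ct[, need, with = FALSE])
}
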