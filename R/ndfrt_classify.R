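#' NDF-RT classification by greedy graph traversal
#'
#' An AERS drug normalized to an RxCUI is classified by finding the
#' NDF-RT concepts that stand for it. If the concept itself carries the
#' NDF-RT source, it is its own anchor. Otherwise the RxNorm
#' relationship graph is traversed breadth-first over the
#' ingredient/clinical-drug pathway (tradename, ingredient, component
#' and dose-form relations, both directions), stopping at the first
#' depth at which one or more NDF-RT-sourced ingredient-like (IN/PIN)
#' or clinical-drug-like (SCD/SCDC) concepts are reached; all concepts
#' at that minimal depth become anchors ("greedy" = minimal hop count,
#' collect all, for maximum class recall). Class memberships on the nine
#' NDF-RT axes are then read off a class-membership table for the
#' anchors, with clinical-drug anchors additionally inheriting the
#' classes of their ingredients.
#'
#' @name ndfrt_classify
NULL

ANCHOR_TTYS <- c("IN", "PIN", "SCD", "SCDC")
CLINICAL_TTYS <- c("SCD", "SCDC")
INGREDIENT_RELAS <- c("has_ingredient", "ingredient_of",
                      "has_precise_ingredient", "precise_ingredient_of")

#' Default relationship labels followed during traversal
#'
#' The ingredient / clinical-drug pathway of the RxNorm relation model.
#' Both members of each inverse pair are listed because traversal is
#' bidirectional. Supplied as a configuration value so users can widen
#' or narrow the pathway.
#'
#' @return character vector of RELA labels
#' @export
default_traversal_relations <- function() {
  c("has_ingredient", "ingredient_of",
    "has_precise_ingredient", "precise_ingredient_of",
    "tradename_of", "has_tradename",
    "consists_of", "constitutes",
    "has_form", "form_of",
    "isa", "inverse_isa")
}

anchor_eligible_cuis <- function(graph) {
  nd <- ndfrt_concepts(graph)
  tt <- graph$atoms[rxcui %in% nd & tty %in% ANCHOR_TTYS, unique(rxcui)]
  tt
}

#' Find NDF-RT anchor concepts for an RxCUI
#'
#' @param graph an `rx_graph`
#' @param rxcui a single concept identifier present in the graph
#' @param max_depth maximum number of hops to explore (default 3)
#' @param relations RELA labels the traversal may follow; default
#'   [default_traversal_relations()]
#' @return object of class `traversal_result`: list with `query_rxcui`,
#'   `anchors` (sorted integer vector, empty when classification is
#'   unavailable), `depth` (hop count at which anchors were found, 0
#'   when the query is itself NDF-RT-sourced, `NA` when none found) and
#'   `path_log` (RELA labels walked).
#' @export
find_ndfrt_anchors <- function(graph, rxcui, max_depth = 3L,
                               relations = default_traversal_relations()) {
  stopifnot(length(rxcui) == 1L, max_depth >= 1L)
  if (!(rxcui %in% graph$concepts$rxcui)) {
    stop_aersdm(sprintf("rxcui %s not present in the concept graph", rxcui),
                "aersdm_unknown_rxcui")
  }
  result <- function(anchors, depth, path_log) {
    structure(list(query_rxcui = rxcui, anchors = sort(anchors),
                   depth = depth, path_log = path_log),
              class = "traversal_result")
  }
  if (is_ndfrt_concept(graph, rxcui)) {
    return(result(rxcui, 0L, character()))
  }
  eligible <- anchor_eligible_cuis(graph)
  adj <- graph$adjacency[rela %in% relations]
  data.table::setkey(adj, a)
  visited <- rxcui
  frontier <- rxcui
  path_log <- character()
  for (d in seq_len(max_depth)) {
    step <- adj[list(frontier), nomatch = NULL]
    if (nrow(step) == 0L) break
    path_log <- union(path_log, step$rela)
    frontier <- setdiff(unique(step$b), visited)
    if (length(frontier) == 0L) break
    visited <- c(visited, frontier)
    hits <- intersect(frontier, eligible)
    if (length(hits)) return(result(hits, d, path_log))
  }
  result(integer(), NA_integer_, path_log)
}

#' @export
print.traversal_result <- function(x, ...) {
  if (length(x$anchors)) {
    cat(sprintf("traversal_result: rxcui %d -> %d anchor(s) at depth %d\n",
                x$query_rxcui, length(x$anchors), x$depth))
  } else {
    cat(sprintf("traversal_result: rxcui %d -> no NDF-RT anchors\n",
                x$query_rxcui))
  }
  invisible(x)
}

#' Class memberships for a set of anchors
#'
#' Unions the class rows of all anchors. When `inherit = TRUE`,
#' clinical-drug anchors (SCD/SCDC) also contribute the class rows of
#' their ingredient neighbours (one hop over ingredient relations),
#' mirroring the inheritance of role relationships from ingredients
#' into the clinical drugs that contain them.
#'
#' @param graph an `rx_graph`
#' @param anchors integer vector of anchor rxcuis (e.g.
#'   `find_ndfrt_anchors(...)$anchors`)
#' @param class_table `data.table` with columns `ndfrt_rxcui`, `axis`,
#'   `class_code`, `class_name` ([extract_class_table()] or
#'   [load_class_table()])
#' @param inherit honour ingredient-to-clinical-drug inheritance
#'   (default `TRUE`)
#' @return `data.table` of memberships, unique on
#'   `(anchor_rxcui, axis, class_code)`
#' @export
classify <- function(graph, anchors, class_table, inherit = TRUE) {
  empty <- data.table::data.table(anchor_rxcui = integer(),
                                  axis = character(),
                                  class_code = character(),
                                  class_name = character())
  if (length(anchors) == 0L) return(empty)
  ct <- data.table::as.data.table(class_table)
  direct <- ct[ndfrt_rxcui %in% anchors,
               list(anchor_rxcui = ndfrt_rxcui, axis, class_code, class_name)]
  pieces <- list(direct)
  if (inherit) {
    clinical <- graph$atoms[rxcui %in% anchors & tty %in% CLINICAL_TTYS,
                            unique(rxcui)]
    if (length(clinical)) {
      ing <- graph$adjacency[rela %in% INGREDIENT_RELAS & a %in% clinical]
      if (nrow(ing)) {
        inh <- merge(ing[, list(anchor_rxcui = a, ndfrt_rxcui = b)],
                     ct, by = "ndfrt_rxcui", allow.cartesian = TRUE)
        pieces <- c(pieces, list(
          inh[, list(anchor_rxcui, axis, class_code, class_name)]))
      }
    }
  }
  unique(data.table::rbindlist(pieces))
}

#' Classify many concepts end to end
#'
#' Runs [find_ndfrt_anchors()] + [classify()] for every concept and
#' binds the results. Concepts with no anchors, or absent from the
#' graph, contribute no rows.
#'
#' @param graph an `rx_graph`
#' @param rxcuis integer vector of query concepts
#' @inheritParams find_ndfrt_anchors
#' @inheritParams classify
#' @return `data.table`: `rxcui` (query), `anchor_rxcui`, `depth`,
#'   `axis`, `class_code`, `class_name`, unique on
#'   `(rxcui, axis, class_code)` per anchor
#' @export
classify_concepts <- function(graph, rxcuis, class_table, max_depth = 3L,
                              relations = default_traversal_relations(),
                              inherit = TRUE) {
  rxcuis <- unique(rxcuis[!is.na(rxcuis)])
  rows <- lapply(rxcuis, function(q) {
    if (!(q %in% graph$concepts$rxcui)) return(NULL)
    tr <- find_ndfrt_anchors(graph, q, max_depth = max_depth,
                             relations = relations)
    if (length(tr$anchors) == 0L) return(NULL)
    m <- classify(graph, tr$anchors, class_table, inherit = inherit)
    if (nrow(m) == 0L) return(NULL)
    m[, `:=`(rxcui = q, depth = tr$depth)]
    m
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.table::data.table(rxcui = integer(), anchor_rxcui = integer(),
                                  depth = integer(), axis = character(),
                                  class_code = character(),
                                  class_name = character()))
  }
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("rxcui", "anchor_rxcui", "depth", "axis",
                                 "class_code", "class_name"))
  out
}

#' Per-axis coverage of classified drugs
#'
#' For each class axis reports the number of distinct classes and
#' classified concepts, the share of all classified concepts
#' (`a_pct`) and the share of reports containing at least one drug
#' classified on the axis among reports containing at least one
#' classified drug (`b_pct`). Percentages are rounded half-up to
#' integers, matching the conventional presentation of such coverage
#' tables.
#'
#' @param classified memberships from [classify_concepts()] (needs
#'   columns `rxcui`, `axis`, `class_code`)
#' @param records normalized drug records linking reports to concepts
#'   (columns `isr`, `rxcui`); may be `NULL`, in which case `b_pct` is
#'   `NA`
#' @return `data.table` with one row per axis: `axis`, `n_classes`,
#'   `n_rxcuis`, `a_pct`, `b_pct`, ordered by `n_rxcuis` descending.
#'   Attributes `total_classified_rxcuis` and
#'   `total_reports_with_classified_drug` carry the denominators.
#' @export
coverage_report <- function(classified, records = NULL) {
  classified <- data.table::as.data.table(classified)
  total_rxcuis <- length(unique(classified$rxcui))
  per_axis <- classified[, list(n_classes = length(unique(class_code)),
                                n_rxcuis = length(unique(rxcui))),
                         by = axis]
  per_axis[, a_pct := if (total_rxcuis > 0)
    round_half_up(100 * n_rxcuis / total_rxcuis) else NA_real_]
  total_reports <- NA_integer_
  if (!is.null(records)) {
    records <- data.table::as.data.table(records)[!is.na(rxcui)]
    rep_cls <- merge(records[, list(isr, rxcui)],
                     unique(classified[, list(rxcui, axis)]),
                     by = "rxcui", allow.cartesian = TRUE)
    total_reports <- length(unique(rep_cls$isr))
    b <- rep_cls[, list(n_reports = length(unique(isr))), by = axis]
    per_axis <- merge(per_axis, b, by = "axis", all.x = TRUE)
    per_axis[, b_pct := if (total_reports > 0)
      round_half_up(100 * data.table::fifelse(is.na(n_reports), 0L, n_reports) /
                      total_reports) else NA_real_]
    per_axis[, n_reports := NULL]
  } else {
    per_axis[, b_pct := NA_real_]
  }
  data.table::setorder(per_axis, -n_rxcuis, axis)
  data.table::setattr(per_axis, "total_classified_rxcuis", total_rxcuis)
  data.table::setattr(per_axis, "total_reports_with_classified_drug",
                      total_reports)
  per_axis[]
}
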