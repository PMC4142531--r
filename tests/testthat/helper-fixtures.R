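library(data.table)

# One shared default fixture set per test run; regenerating it for every
# test file would dominate the suite's runtime.
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(seed = 42L, ...) {
  key <- paste(seed, ..., sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  bp <- fixture_blueprint(seed = seed, ...)
  dir <- file.path(tempdir(), paste0("aersdm_fx_", key))
  fx <- generate_fixture_set(bp, dir)
  fx$graph <- load_rrf(fx$rxnorm$conso, fx$rxnorm$rel)
  fx$lexicon <- build_lexicon(fx$graph)
  fx$meddra_tables <- load_meddra(fx$meddra$tsv)
  fx$class_tbl <- load_class_table(fx$rxnorm$class_tsv)
  .fixture_cache[[key]] <- fx
  fx
}

# Build a tiny rx_graph from explicit concept/edge specs (writes RRF to
# a temp dir). concepts: data.table(rxcui, name, tty, sab); edges:
# data.table(from, to, rela, sab).
build_test_graph <- function(concepts, edges) {
  dir <- tempfile("graph")
  dir.create(dir)
  conso <- concepts[, paste(rxcui, "ENG", "", "", "", "", "",
                            paste0("A", .I), "", "", "", sab, tty, rxcui,
                            name, "", "N", "", "", sep = "|")]
  writeLines(conso, file.path(dir, "RXNCONSO.RRF"))
  if (nrow(edges) > 0) {
    rel <- edges[, paste(from, "", "CUI", "RO", to, "", "CUI", rela,
                         paste0("R", .I), "", sab, "", "", "", "N", "", "",
                         sep = "|")]
  } else rel <- character()
  writeLines(rel, file.path(dir, "RXNREL.RRF"))
  load_rrf(file.path(dir, "RXNCONSO.RRF"), file.path(dir, "RXNREL.RRF"))
}

# Independent shortest-path oracle for the greedy traversal, built on
# igraph: minimal depth d <= max_depth at which an NDF-RT-sourced
# IN/PIN/SCD/SCDC concept is reachable over the allowed relations, all
# such concepts at depth d.
igraph_anchor_oracle <- function(graph, max_depth = 3L,
                                 relations = default_traversal_relations()) {
  cuis <- graph$concepts$rxcui
  ed <- graph$edges[rela %in% relations]
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$from), to = as.character(ed$to)),
    directed = FALSE, vertices = data.frame(name = as.character(cuis)))
  dmat <- igraph::distances(ig)
  nd <- unique(graph$atoms[toupper(sab) == "NDFRT", rxcui])
  eligible <- unique(graph$atoms[
    rxcui %in% nd & tty %in% c("IN", "PIN", "SCD", "SCDC"), rxcui])
  function(q) {
    if (q %in% nd) return(list(anchors = q, depth = 0L))
    if (length(eligible) == 0L) return(list(anchors = integer(), depth = NA_integer_))
    d <- dmat[as.character(q), as.character(eligible)]
    d <- d[is.finite(d) & d <= max_depth & d >= 1]
    if (length(d) == 0L) return(list(anchors = integer(), depth = NA_integer_))
    dmin <- min(d)
    list(anchors = sort(as.integer(names(d)[d == dmin])),
         depth = as.integer(dmin))
  }
}

# Random DEMO table for de-duplication property tests: cases with 1-4
# reports each, dates sometimes tied, sometimes missing.
random_demo <- function(n_cases, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_cases), function(i) {
    k <- sample(1:4, 1)
    dts <- sample(c(20040101L, 20050615L, 20050615L, 20110720L, NA), k,
                  replace = TRUE)
    data.table(case_id = 1000L + i, fda_dt = dts)
  })
  demo <- rbindlist(rows)
  demo[, isr := sample(seq_len(.N) * 7L)]
  demo[, list(isr, case_id, fda_dt)]
}

# Reference implementation of the keep rule in plain base R.
base_r_keep <- function(demo) {
  demo <- as.data.frame(demo)
  out <- integer(0)
  for (cid in unique(demo$case_id)) {
    g <- demo[demo$case_id == cid, ]
    key <- ifelse(is.na(g$fda_dt), -1, g$fda_dt)
    best <- g[order(key, g$isr, decreasing = TRUE), ][1, "isr"]
    out <- c(out, best)
  }
  sort(out)
}
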