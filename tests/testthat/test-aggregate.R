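# Small end-to-end state shared by the aggregation tests.
pipeline_state <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- get_fixture()
    keep <- deduplicate(read_demo(fx$aers$demo))
    mentions <- normalize_drug_table(
      filter_table(read_drug(fx$aers$drug), keep), fx$lexicon)
    reac <- read_reac(fx$aers$reac)
    records <- build_drug_ade_records(mentions, reac, keep, fx$meddra_tables)
    cls <- classify_concepts(fx$graph, unique(mentions$rxcui), fx$class_tbl)
    cache <<- list(fx = fx, keep = keep, mentions = mentions, reac = reac,
                   records = records, cls = cls)
    cache
  }
})

test_that("a report's records are the cross product of its matched drugs and mapped events", {
  fx <- get_fixture()
  tables <- fx$meddra_tables
  prim <- fx$meddra$table[primary_flag == "Y"]
  keep <- deduplicate(data.table(isr = c(1L, 2L), case_id = c(1L, 2L),
                                 fda_dt = 20100101L))
  mentions <- data.table(isr = c(1L, 1L, 2L), drug_seq = c(1L, 2L, 1L),
                         input_string = "x",
                         rxcui = c(101L, 102L, NA_integer_),
                         matched_name = NA_character_,
                         status = c("matched", "matched", "unmatched"))
  reac <- data.table(isr = c(1L, 1L, 1L, 2L),
                     pt_term = c(prim$pt_term[1:3], prim$pt_term[1]))
  records <- build_drug_ade_records(mentions, reac, keep, tables)
  expect_equal(nrow(records), 6L)  # 2 drugs x 3 events
  expect_equal(sort(unique(records$rxcui)), c(101L, 102L))
  # report 2 had no matched drugs: zero records
  expect_equal(nrow(records[isr == 2L]), 0L)
  expect_equal(attr(records, "unmatched_drug_count"), 1L)
})

test_that("unmapped PTs contribute nothing and are counted", {
  fx <- get_fixture()
  keep <- deduplicate(data.table(isr = 1L, case_id = 1L, fda_dt = 20100101L))
  mentions <- data.table(isr = 1L, drug_seq = 1L, input_string = "x",
                         rxcui = 101L, matched_name = "n", status = "matched")
  reac <- data.table(isr = 1L, pt_term = c("No such term here",
                                           fx$meddra$table$pt_term[1]))
  records <- build_drug_ade_records(mentions, reac, keep, fx$meddra_tables)
  expect_equal(nrow(records), 1L)
  expect_equal(attr(records, "unmapped_pt_count"), 1L)
})

test_that("fixture record multiset equals the generator's planted pair list", {
  st <- pipeline_state()
  expected <- st$fx$aers$expected
  expect_equal(nrow(st$records), expected$n_records)
  expect_equal(count_unique_pairs(st$records, "PT"), expected$n_pt_pairs)
  expect_equal(count_unique_pairs(st$records, "SOC"), expected$n_soc_pairs)
})

test_that("distinct pair counting collapses repeats; SOC pairs never exceed PT pairs", {
  records <- data.table(isr = c(1L, 1L, 1L), rxcui = 5L,
                        pt_code = c(101L, 101L, 102L),
                        soc_code = c(900L, 900L, 900L))
  expect_equal(count_unique_pairs(records, "PT"), 2L)
  expect_equal(count_unique_pairs(records, "SOC"), 1L)
  st <- pipeline_state()
  expect_lte(count_unique_pairs(st$records, "SOC"),
             count_unique_pairs(st$records, "PT"))
})

test_that("aggregation equals a brute-force group-by and is shuffle invariant", {
  st <- pipeline_state()
  for (level in c("PT", "SOC")) {
    agg <- aggregate_pairs(st$records, st$cls, axis = "VA Class",
                           level = level)
    # brute force: join records x memberships in base R, then table()
    cls <- unique(as.data.frame(st$cls[axis == "VA Class",
                                       list(rxcui, class_code)]))
    recs <- as.data.frame(st$records)
    recs$ade <- if (level == "PT") recs$pt_code else recs$soc_code
    joined <- merge(recs, cls, by = "rxcui")
    want <- as.data.frame(table(joined$class_code, joined$ade),
                          stringsAsFactors = FALSE)
    want <- want[want$Freq > 0, ]
    got <- agg[, list(class_code, ade_code = as.character(ade_code), count)]
    m <- merge(got, want,
               by.x = c("class_code", "ade_code"), by.y = c("Var1", "Var2"),
               all = TRUE)
    expect_equal(nrow(m), nrow(got))
    expect_equal(m$count, m$Freq)
    # shuffle invariance
    shuffled <- st$records[sample(nrow(st$records))]
    agg2 <- aggregate_pairs(shuffled, st$cls, axis = "VA Class",
                            level = level)
    expect_equal(agg2, agg)
  }
})

test_that("a drug in two classes on the axis increments both pairs", {
  records <- data.table(isr = 1L, rxcui = 5L, pt_code = 101L, soc_code = 900L)
  cls <- data.table(rxcui = 5L, axis = "VA Class",
                    class_code = c("c1", "c2"), class_name = c("C1", "C2"))
  agg <- aggregate_pairs(records, cls, axis = "VA Class", level = "PT")
  expect_equal(nrow(agg), 2L)
  expect_equal(agg$count, c(1L, 1L))
})

test_that("SOC distribution partitions the records and rounds to one decimal", {
  st <- pipeline_state()
  dist <- soc_distribution(st$records, st$fx$meddra_tables)
  expect_equal(sum(dist$n_records), nrow(st$records))
  expect_equal(dist$pct, round_half_up(100 * dist$n_records /
                                         nrow(st$records), 1))
  expect_equal(dist$n_records, sort(dist$n_records, decreasing = TRUE))
  # single-SOC corpus saturates at 100.0
  one <- soc_distribution(st$records[soc_code == st$records$soc_code[1]],
                          st$fx$meddra_tables)
  expect_equal(one$pct, 100)
})

test_that("class profile counts distinct reports and drugs per class", {
  st <- pipeline_state()
  prof <- class_profile(st$records, st$cls, axis = "Pharmacokinetics")
  cls <- unique(as.data.frame(st$cls[axis == "Pharmacokinetics",
                                     list(rxcui, class_code)]))
  joined <- merge(unique(as.data.frame(st$records[, list(isr, rxcui)])),
                  cls, by = "rxcui")
  for (cc in prof$class_code) {
    sub <- joined[joined$class_code == cc, ]
    expect_equal(prof[class_code == cc, n_reports],
                 length(unique(sub$isr)))
    expect_equal(prof[class_code == cc, n_drugs],
                 length(unique(sub$rxcui)))
  }
  expect_equal(nrow(class_profile(st$records[0], st$cls,
                                  axis = "Pharmacokinetics")), 0L)
})

test_that("a class with fewer drugs but more reports ranks higher by reports", {
  records <- data.table(
    isr = c(1L, 2L, 3L, 4L, 5L, 6L),
    rxcui = c(10L, 10L, 10L, 10L, 20L, 21L),
    pt_code = 101L, soc_code = 900L)
  cls <- data.table(rxcui = c(10L, 20L, 21L), axis = "Pharmacokinetics",
                    class_code = c("hepatic", "fecal", "fecal"),
                    class_name = c("Hepatic excretion", "Fecal excretion",
                                   "Fecal excretion"))
  prof <- class_profile(records, cls, axis = "Pharmacokinetics")
  expect_equal(prof$class_code, c("hepatic", "fecal"))
  expect_lt(prof[class_code == "hepatic", n_drugs],
            prof[class_code == "fecal", n_drugs])
})

test_that("the distinct-pairs flag collapses within-report repeats", {
  fx <- get_fixture()
  keep <- deduplicate(data.table(isr = 1L, case_id = 1L, fda_dt = 20100101L))
  mentions <- data.table(isr = 1L, drug_seq = 1:2, input_string = "x",
                         rxcui = 101L, matched_name = "n", status = "matched")
  reac <- data.table(isr = 1L, pt_term = fx$meddra$table$pt_term[1])
  occ <- build_drug_ade_records(mentions, reac, keep, fx$meddra_tables)
  dis <- build_drug_ade_records(mentions, reac, keep, fx$meddra_tables,
                                distinct = TRUE)
  expect_equal(nrow(occ), 2L)
  expect_equal(nrow(dis), 1L)
})
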