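test_that("input string concatenates DRUGNAME, DOSE_VBM, ROUTE, skipping empties", {
  expect_equal(
    build_input_string("POTASSIUM CHLORIDE EXTENDED RELEASE TABLET",
                       route = "ORAL",
                       dose_vbm = "EXTENDED RELEASE TABLET ORAL 20 MEQ BID"),
    "POTASSIUM CHLORIDE EXTENDED RELEASE TABLET EXTENDED RELEASE TABLET ORAL 20 MEQ BID ORAL")
  expect_equal(build_input_string("ASPIRIN", "", ""), "ASPIRIN")
  expect_equal(build_input_string("  A   B ", "ORAL", ""), "A B ORAL")
})

test_that("fixture concatenations equal the generator's recorded strings", {
  fx <- get_fixture()
  log <- fx$aers$mention_log
  expect_equal(build_input_string(log$drugname, log$route, log$dose_vbm),
               log$input_string)
})

test_that("every lexicon string fed verbatim maps to its own concept", {
  fx <- get_fixture()
  lex <- fx$lexicon
  for (i in seq_len(nrow(lex))) {
    res <- normalize_mention(lex$name[i], lex)
    expect_equal(res$status, "matched")
    expect_equal(res$matched_rxcui, lex$rxcui[i])
  }
})

test_that("text sharing no token with the lexicon is unmatched", {
  fx <- get_fixture()
  res <- normalize_mention("QWXJ ZPLV 123", fx$lexicon)
  expect_equal(res$status, "unmatched")
  expect_true(is.na(res$matched_rxcui))
})

test_that("matcher equals a brute-force scorer over every entry and prefix span", {
  fx <- get_fixture()
  lex <- fx$lexicon
  prio <- function(tty) {
    p <- c(SCD = 1, SBD = 2, SCDC = 3, GPCK = 4, BPCK = 5, BN = 6,
           IN = 7, PIN = 8, MIN = 9)[tty]
    ifelse(is.na(p), 50, p)
  }
  brute <- function(text) {
    toks <- strsplit(toupper(gsub("[^A-Za-z0-9 ]+", " ", text)), "[ ]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) return(NULL)
    cand <- integer(0); len <- integer(0); pr <- numeric(0)
    for (i in seq_len(nrow(lex))) {
      ktoks <- strsplit(lex$key[i], " ", fixed = TRUE)[[1]]
      if (identical(ktoks[1], toks[1]) && all(ktoks %in% toks)) {
        if (identical(lex$key[i], paste(toks, collapse = " "))) {
          return(lex$rxcui[i])  # exact match wins outright
        }
        cand <- c(cand, lex$rxcui[i])
        len <- c(len, length(ktoks))
        pr <- c(pr, prio(lex$tty[i]))
      }
    }
    if (length(cand) == 0) return(NULL)
    ord <- order(-len, pr, cand)
    cand[ord[1]]
  }
  strings <- unique(fx$aers$mention_log$input_string)[1:150]
  for (s in strings) {
    res <- normalize_mention(s, lex)
    expect_equal(res$matched_rxcui,
                 brute(s) %||% NA_integer_,
                 ignore_attr = TRUE, label = s)
  }
})

test_that("adding lexicon entries never turns a matched mention unmatched", {
  fx <- get_fixture()
  g <- fx$graph
  # rebuild the lexicon from a graph with extra concepts appended
  extra <- data.table(rxcui = 99991L:99993L,
                      name = c("Zzyqum Extra", "Borol Extra Plus", "Qix"),
                      tty = "IN", sab = "RXNORM")
  g2 <- build_test_graph(
    rbind(g$atoms[suppress == "N", list(rxcui, name, tty, sab)], extra),
    g$edges[0])
  lex2 <- build_lexicon(g2)
  log <- unique(fx$aers$mention_log[status == "matched", input_string])[1:50]
  for (s in log) {
    expect_equal(normalize_mention(s, lex2)$status, "matched", label = s)
  }
})

test_that("ties among equally long matches prefer clinical drug over brand over ingredient, then lowest rxcui", {
  concepts <- data.table(
    rxcui = c(10L, 20L, 30L, 40L),
    name = c("Dupra", "Dupra", "Dupra", "Dupra"),
    tty = c("IN", "BN", "SCD", "SCD"),
    sab = "RXNORM")
  g <- build_test_graph(concepts, data.table(from = integer(),
                                             to = integer(),
                                             rela = character(),
                                             sab = character()))
  lex <- build_lexicon(g)
  res <- normalize_mention("DUPRA", lex)
  expect_equal(res$matched_rxcui, 30L)  # SCD beats BN/IN; 30 < 40
})

test_that("normalize_drug_table flags empty drug names unmatched without lookup", {
  fx <- get_fixture()
  drug <- data.table(isr = 1L, drug_seq = 1:2,
                     drugname = c("", fx$lexicon$name[1]),
                     route = "", dose_vbm = "")
  out <- normalize_drug_table(drug, fx$lexicon)
  expect_equal(out$status, c("unmatched", "matched"))
})

test_that("MedEx adapter agrees with the built-in matcher on fixture strings", {
  fx <- get_fixture()
  drug <- read_drug(fx$aers$drug)
  mentions <- normalize_drug_table(drug, fx$lexicon)
  # export the matcher's verdicts in MedEx output format, re-import
  f <- tempfile()
  lut <- unique(mentions[, list(input_string, rxcui)])
  writeLines(paste0(lut$input_string, "\t",
                    ifelse(is.na(lut$rxcui), "", lut$rxcui)), f)
  imported <- import_medex_output(f, fx$graph)
  m <- merge(lut, imported, by = "input_string", suffixes = c("", ".imp"))
  expect_equal(nrow(m), nrow(lut))
  expect_equal(m$rxcui, m$rxcui.imp)
})

test_that("MedEx rxcuis absent from the graph are demoted to unmatched with a warning", {
  fx <- get_fixture()
  f <- tempfile()
  writeLines(c("ASPIRIN\t999999", paste0(fx$lexicon$name[1], "\t",
                                         fx$lexicon$rxcui[1])), f)
  expect_warning(out <- import_medex_output(f, fx$graph),
                 "absent from the concept graph")
  expect_equal(out[input_string == "ASPIRIN", status], "unmatched")
  expect_equal(attr(out, "invalid_rxcui_count"), 1L)
})

test_that("normalization stats report the planted match fraction", {
  fx <- get_fixture()
  drug <- read_drug(fx$aers$drug)
  keep <- deduplicate(read_demo(fx$aers$demo))
  mentions <- normalize_drug_table(filter_table(drug, keep), fx$lexicon)
  st <- normalization_stats(mentions)
  expect_equal(st$pct_matched, fx$aers$expected$pct_matched)
  # empty input: all counts 0, fraction undefined
  st0 <- normalization_stats(mentions[0])
  expect_equal(st0$n_unique_input_strings, 0L)
  expect_true(is.na(st0$pct_matched))
})

test_that("percent-matched arithmetic rounds half-up to integers", {
  # 1,125,045 matched of 1,517,811 unique strings prints as 74
  expect_equal(round_half_up(100 * 1125045 / 1517811), 74)
})
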