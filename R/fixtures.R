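#' Deterministic synthetic fixtures
#'
#' Generates miniature, fully synthetic stand-ins for the three external
#' inputs of the pipeline — an RxNorm-style RRF pair (concepts +
#' relationships) with a known ingredient / clinical-drug / brand
#' structure, AERS-style DEMO/DRUG/REAC tables with injected duplicate
#' cases and corrupted drug strings, and a MedDRA-style PT/SOC TSV —
#' together with a blueprint of planted ground truth (true rxcui per
#' drug string, class memberships, retained ISRs, expected pair counts)
#' sufficient to predict every pipeline output exactly. Identical seeds
#' give identical outputs.
#'
#' These fixtures emulate the *structure* the pipeline depends on
#' (relation wiring, tie-breaks, multi-axial classes, PT/SOC rollup),
#' not the statistics of real spontaneous-report data: drug and event
#' frequencies are uniform, names are invented words, and the free-text
#' noise is limited to head-token corruption.
#'
#' @name fixtures
NULL

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# pronounceable unique uppercase-ish words; never starting with "ZZ",
# which is reserved for deliberate corruption
make_words <- function(n, n_syllables = 3) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "x")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    w <- replicate(n * 2, paste0(
      paste0(sample(cons, n_syllables, replace = TRUE),
             sample(vow, n_syllables, replace = TRUE), collapse = ""),
      sample(c("ib", "ol", "ine", "ax", "um"), 1)))
    w <- paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Fixture blueprint
#'
#' Bundles the sizes, rates and seed that define one synthetic study
#' corpus. Defaults give roughly 200 drug concepts and 500 cases: large
#' enough to exercise tie-breaks, brand fan-out and multi-axis classes,
#' small enough for sub-second tests.
#'
#' @param seed integer RNG seed; everything downstream is a pure
#'   function of the blueprint
#' @param n_ingredients,n_clinical_drugs,n_brands concept counts
#' @param n_cases number of distinct AERS cases
#' @param duplicate_rate fraction of cases receiving a follow-up report
#'   (half of the duplicates share the exact FDA_DT to exercise the
#'   highest-ISR tie-break)
#' @param unmatched_rate fraction of drug mentions corrupted beyond
#'   lexicon reach
#' @param ndfrt_rate fraction of ingredients and clinical drugs carrying
#'   the NDF-RT source flag (and hence class rows)
#' @return object of class `fixture_blueprint`
#' @export
fixture_blueprint <- function(seed = 1L, n_ingredients = 40L,
                              n_clinical_drugs = 90L, n_brands = 70L,
                              n_cases = 500L, duplicate_rate = 0.2,
                              unmatched_rate = 0.2, ndfrt_rate = 0.7) {
  stopifnot(n_ingredients >= 0, n_clinical_drugs >= 0, n_brands >= 0,
            n_cases >= 0, duplicate_rate >= 0, duplicate_rate <= 1,
            unmatched_rate >= 0, unmatched_rate <= 1,
            ndfrt_rate >= 0, ndfrt_rate <= 1)
  structure(list(seed = as.integer(seed),
                 n_ingredients = as.integer(n_ingredients),
                 n_clinical_drugs = as.integer(n_clinical_drugs),
                 n_brands = as.integer(n_brands),
                 n_cases = as.integer(n_cases),
                 duplicate_rate = duplicate_rate,
                 unmatched_rate = unmatched_rate,
                 ndfrt_rate = ndfrt_rate),
            class = "fixture_blueprint")
}

#' Generate a miniature RxNorm-style fixture
#'
#' Ingredients (IN), clinical drugs (SCD, wired `has_ingredient` to 1-2
#' ingredients, some with an SCDC component via `consists_of`) and
#' brands (BN, `tradename_of` a clinical drug). A blueprint-controlled
#' fraction of ingredients and clinical drugs carries an NDF-RT-sourced
#' atom; each NDF-RT concept receives class rows on a random subset of
#' the nine axes, written both as NDF-RT role-relationship rows in the
#' relationship file and as a class TSV. A few suppressed alias atoms
#' are included to exercise lexicon exclusion.
#'
#' @param blueprint a [fixture_blueprint()]
#' @param dir output directory (created if needed)
#' @return list with file paths (`conso`, `rel`, `class_tsv`) and
#'   planted truth: `concepts` (rxcui, name, tty, ndfrt), `edges`,
#'   `class_table`, `lexicon` (name -> rxcui)
#' @export
generate_rxnorm_fixture <- function(blueprint, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(blueprint$seed + 101L, {
    n_ing <- blueprint$n_ingredients
    n_scd <- blueprint$n_clinical_drugs
    n_bn <- blueprint$n_brands
    words <- make_words(n_ing + n_bn)
    ing <- if (n_ing > 0) data.table::data.table(
      rxcui = 1000L + seq_len(n_ing), name = words[seq_len(n_ing)],
      tty = "IN") else
      data.table::data.table(rxcui = integer(), name = character(),
                             tty = character())
    scd <- if (n_scd > 0 && n_ing > 0) {
      # unique (ingredient, strength, form) combos so names never collide
      combos <- data.table::CJ(
        base_ing = ing$rxcui,
        strength = c(5L, 10L, 25L, 50L, 100L),
        form = c("Oral Tablet", "Oral Capsule", "Injectable Solution"))
      if (nrow(combos) < n_scd) {
        stop_aersdm("n_clinical_drugs too large for the ingredient pool",
                    "aersdm_fixture_error")
      }
      combos <- combos[sample(nrow(combos), n_scd)]
      data.table::data.table(
        rxcui = 2000L + seq_len(n_scd),
        name = paste(ing[match(combos$base_ing, rxcui), name],
                     combos$strength, "MG", combos$form),
        tty = "SCD", base_ing = combos$base_ing)
    } else data.table::data.table(rxcui = integer(), name = character(),
                                  tty = character(), base_ing = integer())
    bn <- if (n_bn > 0 && nrow(scd) > 0) data.table::data.table(
      rxcui = 3000L + seq_len(n_bn),
      name = words[n_ing + seq_len(n_bn)],
      tty = "BN",
      of_scd = sample(scd$rxcui, n_bn, replace = TRUE)) else
      data.table::data.table(rxcui = integer(), name = character(),
                             tty = character(), of_scd = integer())

    edges <- list()
    if (nrow(scd) > 0) {
      edges$scd_ing <- data.table::data.table(
        from = scd$rxcui, to = scd$base_ing, rela = "has_ingredient",
        sab = "RXNORM")
      # a third of clinical drugs get a second ingredient
      extra <- scd[seq_len(nrow(scd)) %% 3L == 0L]
      if (nrow(extra) > 0 && n_ing > 1) {
        second <- vapply(extra$base_ing, function(b)
          sample(setdiff(ing$rxcui, b), 1L), integer(1))
        edges$scd_ing2 <- data.table::data.table(
          from = extra$rxcui, to = second, rela = "has_ingredient",
          sab = "RXNORM")
      }
    }
    # SCDC components for a quarter of clinical drugs
    scdc <- data.table::data.table(rxcui = integer(), name = character(),
                                   tty = character())
    if (nrow(scd) >= 4) {
      comp_of <- scd[seq_len(nrow(scd)) %% 4L == 0L]
      scdc <- data.table::data.table(
        rxcui = 4000L + seq_len(nrow(comp_of)),
        name = paste(comp_of$name, "Component"),
        tty = "SCDC")
      edges$consists <- data.table::data.table(
        from = comp_of$rxcui, to = scdc$rxcui, rela = "consists_of",
        sab = "RXNORM")
      edges$scdc_ing <- data.table::data.table(
        from = scdc$rxcui, to = comp_of$base_ing, rela = "has_ingredient",
        sab = "RXNORM")
    }
    if (nrow(bn) > 0) {
      edges$trade <- data.table::data.table(
        from = bn$rxcui, to = bn$of_scd, rela = "tradename_of", sab = "RXNORM")
    }

    concepts <- data.table::rbindlist(list(
      ing[, list(rxcui, name, tty)],
      scd[, list(rxcui, name, tty)],
      bn[, list(rxcui, name, tty)],
      scdc[, list(rxcui, name, tty)]))

    # NDF-RT source flags on ingredients and clinical drugs
    flaggable <- concepts[tty %in% c("IN", "SCD"), rxcui]
    n_flag <- round(blueprint$ndfrt_rate * length(flaggable))
    ndfrt_cuis <- sort(sample(flaggable, n_flag))
    concepts[, ndfrt := rxcui %in% ndfrt_cuis]

    # class axes: three classes per axis, assigned to NDF-RT concepts
    axes <- ndfrt_axes()
    rela_of_axis <- stats::setNames(names(default_axis_map()),
                                    unname(default_axis_map()))
    class_concepts <- data.table::data.table(
      rxcui = 9000L + seq_len(3L * length(axes)),
      axis = rep(axes, each = 3L),
      k = rep(1:3, times = length(axes)))
    class_concepts[, name := paste(axis, "class", k)]
    class_rows <- list()
    for (cui in ndfrt_cuis) {
      on_axes <- axes[stats::runif(length(axes)) < 0.5]
      if (length(on_axes) == 0L) on_axes <- sample(axes, 1L)
      for (ax in on_axes) {
        cand <- class_concepts[axis == ax]
        pick <- cand[sample(.N, 1L)]
        class_rows[[length(class_rows) + 1L]] <- data.table::data.table(
          ndfrt_rxcui = cui, axis = ax,
          class_code = as.character(pick$rxcui), class_name = pick$name,
          rela = rela_of_axis[[ax]])
      }
    }
    class_table <- if (length(class_rows)) data.table::rbindlist(class_rows)
      else data.table::data.table(ndfrt_rxcui = integer(),
                                  axis = character(),
                                  class_code = character(),
                                  class_name = character(),
                                  rela = character())

    # atoms: RXNORM atom per concept, NDFRT atom for flagged concepts
    # and class concepts, a sprinkling of suppressed aliases
    atoms <- concepts[, list(rxcui, name, tty, sab = "RXNORM",
                             suppress = "N")]
    atoms <- data.table::rbindlist(list(
      atoms,
      concepts[ndfrt == TRUE,
               list(rxcui, name, tty, sab = "NDFRT", suppress = "N")],
      class_concepts[, list(rxcui, name, tty = "PT", sab = "NDFRT",
                            suppress = "N")]))
    supp_idx <- which(seq_len(nrow(concepts)) %% 20L == 0L)
    if (length(supp_idx)) {
      atoms <- data.table::rbindlist(list(atoms, concepts[supp_idx, list(
        rxcui, name = paste(name, "SUPPRESSED ALIAS"), tty,
        sab = "RXNORM", suppress = "Y")]))
    }

    rel_edges <- if (length(edges)) data.table::rbindlist(edges)
      else data.table::data.table(from = integer(), to = integer(),
                                  rela = character(), sab = character())
    if (nrow(class_table) > 0) {
      rel_edges <- data.table::rbindlist(list(rel_edges, class_table[, list(
        from = ndfrt_rxcui, to = as.integer(class_code), rela,
        sab = "NDFRT")]))
    }
    class_table[, rela := NULL]

    conso_path <- file.path(dir, "RXNCONSO.RRF")
    rel_path <- file.path(dir, "RXNREL.RRF")
    class_path <- file.path(dir, "ndfrt_classes.tsv")
    conso_lines <- if (nrow(atoms)) atoms[, paste(
      rxcui, "ENG", "", "", "", "", "", paste0("A", .I), "", "", "", sab,
      tty, rxcui, name, "", suppress, "", "", sep = "|")] else character()
    writeLines(conso_lines, conso_path)
    rel_lines <- if (nrow(rel_edges)) rel_edges[, paste(
      from, "", "CUI", "RO", to, "", "CUI", rela, paste0("R", .I), "", sab,
      "", "", "", "N", "", "", sep = "|")] else character()
    writeLines(rel_lines, rel_path)
    utils::write.table(class_table, class_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)

    lexicon <- concepts[, list(name, rxcui, tty)]
    list(conso = conso_path, rel = rel_path, class_tsv = class_path,
         concepts = concepts, edges = rel_edges, class_table = class_table,
         lexicon = lexicon)
  })
}

#' Generate a miniature MedDRA-style PT/SOC fixture
#'
#' Eight SOCs, each with 3-6 PTs (so the rollup collapses several PTs
#' into one SOC); a fifth of the PTs also carry a non-primary secondary
#' SOC link. Every PT has exactly one primary SOC.
#'
#' @inheritParams generate_rxnorm_fixture
#' @return list with `tsv` (path) and `table` (the planted rows:
#'   `pt_term`, `pt_code`, `soc_code`, `soc_name`, `primary_flag`)
#' @export
generate_meddra_fixture <- function(blueprint, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(blueprint$seed + 202L, {
    n_soc <- 8L
    soc_words <- make_words(n_soc, n_syllables = 2)
    socs <- data.table::data.table(
      soc_code = 30000000L + seq_len(n_soc),
      soc_name = paste(soc_words, "system disorders"))
    n_pts <- pmax(3L, sample(3:6, n_soc, replace = TRUE))
    pt_words <- make_words(sum(n_pts), n_syllables = 2)
    pts <- data.table::data.table(
      pt_code = 20000000L + seq_len(sum(n_pts)),
      pt_term = paste(pt_words, "disorder"),
      soc_code = rep(socs$soc_code, times = n_pts))
    rows <- merge(pts, socs, by = "soc_code")[
      , list(pt_term, pt_code, soc_code, soc_name, primary_flag = "Y")]
    sec_idx <- which(seq_len(nrow(rows)) %% 5L == 0L)
    if (length(sec_idx)) {
      sec <- rows[sec_idx]
      other <- vapply(sec$soc_code, function(s)
        sample(setdiff(socs$soc_code, s), 1L), integer(1))
      sec[, `:=`(soc_code = other,
                 soc_name = socs[match(other, soc_code), soc_name],
                 primary_flag = "N")]
      rows <- data.table::rbindlist(list(rows, sec))
    }
    data.table::setorder(rows, pt_code, -primary_flag)
    path <- file.path(dir, "meddra_pt_soc.tsv")
    utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    list(tsv = path, table = rows)
  })
}

#' Generate miniature AERS-style DEMO/DRUG/REAC fixtures
#'
#' Each case gets one base report; a `duplicate_rate` fraction receive a
#' follow-up with a higher ISR, half of those with a strictly later
#' FDA_DT and half with the identical date (exercising the highest-ISR
#' tie-break). Drug strings are lexicon names decorated with dose/route
#' text; an `unmatched_rate` fraction are corrupted at the head token
#' (typo-style scrambles and foreign-brand-style renames) so that no
#' lexicon entry can match — verified at generation time by an
#' exhaustive prefix scan of the lexicon. REAC PTs are drawn from the
#' MedDRA fixture.
#'
#' @inheritParams generate_rxnorm_fixture
#' @param rxnorm_fixture result of [generate_rxnorm_fixture()]
#' @param meddra_fixture result of [generate_meddra_fixture()]
#' @return list with paths (`demo`, `drug`, `reac`) and planted truth:
#'   `demo_table`, `mention_log` (per DRUG row: `isr`, `drug_seq`,
#'   `input_string`, `true_rxcui`, `status`), `reac_log`, `retained`
#'   (case -> retained isr), and `expected` (distinct_cases,
#'   n_records, n_pt_pairs, n_soc_pairs, pct_matched computed from the
#'   planted logs alone)
#' @export
generate_aers_fixture <- function(blueprint, rxnorm_fixture, meddra_fixture,
                                  dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lex <- rxnorm_fixture$lexicon
  med <- meddra_fixture$table[primary_flag == "Y"]
  with_local_seed(blueprint$seed + 303L, {
    n_cases <- blueprint$n_cases
    case_ids <- 500000L + seq_len(n_cases)
    dup <- stats::runif(n_cases) < blueprint$duplicate_rate
    tie <- dup & (stats::runif(n_cases) < 0.5)

    rand_date <- function(n) {
      y <- sample(2004:2011, n, replace = TRUE)
      m <- sample(1:12, n, replace = TRUE)
      d <- sample(1:28, n, replace = TRUE)
      as.integer(y * 10000L + m * 100L + d)
    }
    base_dt <- rand_date(n_cases)
    later_dt <- function(dt) {
      # strictly later valid date: bump the day within the safe 1..28 range,
      # rolling into the next month/year when needed
      d <- dt %% 100L; m <- (dt %/% 100L) %% 100L; y <- dt %/% 10000L
      d <- d + 1L
      roll <- d > 28L
      d[roll] <- 1L; m[roll] <- m[roll] + 1L
      roll2 <- m > 12L
      m[roll2] <- 1L; y[roll2] <- y[roll2] + 1L
      as.integer(y * 10000L + m * 100L + d)
    }

    # base reports get ISRs in case order; follow-ups get strictly
    # higher ISRs, mirroring the chronology of real submissions
    demo <- data.table::data.table(isr = 7000000L + seq_len(n_cases),
                                   case_id = case_ids, fda_dt = base_dt)
    n_dup <- sum(dup)
    if (n_dup > 0) {
      dup_rows <- data.table::data.table(
        isr = 7000000L + n_cases + seq_len(n_dup),
        case_id = case_ids[dup],
        fda_dt = data.table::fifelse(tie[dup], base_dt[dup],
                                     later_dt(base_dt[dup])))
      demo <- data.table::rbindlist(list(demo, dup_rows))
    }
    retained <- demo[order(case_id, fda_dt, isr),
                     list(isr = isr[.N]), by = case_id]

    # drug mentions: 1-3 per report, lexicon names decorated; a fraction
    # corrupted at the head token so no entry can match
    # decoration vocabularies are disjoint from lexicon strength/form
    # tokens so dose text can never complete a different concept's name
    routes <- c("", "ORAL", "INTRAVENOUS")
    doses <- c("", "1 CAP QD", "AS NEEDED", "TWICE DAILY")
    mention_rows <- vector("list", nrow(demo))
    for (i in seq_len(nrow(demo))) {
      k <- sample(1:3, 1L)
      pick <- lex[sample(nrow(lex), k, replace = TRUE)]
      route <- sample(routes, k, replace = TRUE)
      dose <- sample(doses, k, replace = TRUE)
      corrupt <- stats::runif(k) < blueprint$unmatched_rate
      drugname <- pick$name
      true_rxcui <- pick$rxcui
      if (any(corrupt)) {
        style <- sample(c("typo", "foreign"), sum(corrupt), replace = TRUE)
        mangled <- paste0("ZZ",
                          ifelse(style == "typo",
                                 vapply(drugname[corrupt], function(w) {
                                   s <- strsplit(w, "")[[1]]
                                   paste(rev(s), collapse = "")
                                 }, character(1)),
                                 paste0("Q", toupper(drugname[corrupt]))))
        first_gone <- sub("^\\S+", "", drugname[corrupt])
        drugname[corrupt] <- squish(paste0(mangled, first_gone))
        true_rxcui[corrupt] <- NA_integer_
      }
      mention_rows[[i]] <- data.table::data.table(
        isr = demo$isr[i], drug_seq = seq_len(k), drugname = drugname,
        route = route, dose_vbm = dose, true_rxcui = true_rxcui)
    }
    drug <- data.table::rbindlist(mention_rows)
    drug[, input_string := {
      parts <- cbind(drugname, dose_vbm, route)
      apply(parts, 1L, function(p) paste(p[nzchar(p)], collapse = " "))
    }]
    drug[, status := data.table::fifelse(is.na(true_rxcui),
                                         "unmatched", "matched")]

    # closure check: among lexicon entries anchored at each input
    # string's head token with all their tokens contained in the input,
    # there must be a unique longest one and it must be the planted
    # name (and none may exist for corrupted strings)
    canon_keys <- canonical_drug_string(lex$name)
    key_tokens <- strsplit(canon_keys, " ", fixed = TRUE)
    key_len <- lengths(key_tokens)
    check_one <- function(s) {
      toks <- strsplit(canonical_drug_string(s), " ", fixed = TRUE)[[1]]
      hits <- which(vapply(seq_along(canon_keys), function(j) {
        kt <- key_tokens[[j]]
        identical(kt[1], toks[1]) && all(kt %in% toks)
      }, logical(1)))
      if (length(hits) == 0L) return(NA_integer_)
      best <- hits[key_len[hits] == max(key_len[hits])]
      if (length(best) != 1L) {
        stop_aersdm(sprintf("ambiguous fixture drug string: %s", s),
                    "aersdm_fixture_error")
      }
      lex$rxcui[best]
    }
    uniq <- unique(drug[, list(input_string, true_rxcui)])
    scan <- vapply(uniq$input_string, check_one, integer(1))
    if (!identical(unname(scan), uniq$true_rxcui)) {
      stop_aersdm("fixture closure violated: lexicon scan disagrees with planted rxcuis",
                  "aersdm_fixture_error")
    }

    # reactions: 1-3 distinct PTs per report
    reac_rows <- vector("list", nrow(demo))
    for (i in seq_len(nrow(demo))) {
      k <- sample(1:3, 1L)
      pick <- med[sample(nrow(med), min(k, nrow(med)))]
      reac_rows[[i]] <- data.table::data.table(
        isr = demo$isr[i], pt_term = pick$pt_term, pt_code = pick$pt_code,
        soc_code = pick$soc_code)
    }
    reac <- data.table::rbindlist(reac_rows)

    demo_path <- file.path(dir, "DEMO.txt")
    drug_path <- file.path(dir, "DRUG.txt")
    reac_path <- file.path(dir, "REAC.txt")
    write_aers_table(demo, demo_path)
    write_aers_table(drug[, list(isr, drug_seq, drugname, route, dose_vbm)],
                     drug_path)
    write_aers_table(reac[, list(isr, pt_term)], reac_path)

    # expected end-to-end quantities from the planted logs alone
    kept <- retained$isr
    kd <- drug[isr %in% kept]
    kr <- reac[isr %in% kept]
    n_drugs_per <- kd[status == "matched", list(nd = .N), by = isr]
    n_pts_per <- kr[, list(np = .N), by = isr]
    per <- merge(n_drugs_per, n_pts_per, by = "isr")
    pairs <- merge(kd[status == "matched", list(isr, true_rxcui)],
                   kr[, list(isr, pt_code, soc_code)],
                   by = "isr", allow.cartesian = TRUE)
    expected <- list(
      distinct_cases = n_cases,
      n_input_reports = nrow(demo),
      n_records = sum(per$nd * per$np),
      n_pt_pairs = nrow(unique(pairs[, list(true_rxcui, pt_code)])),
      n_soc_pairs = nrow(unique(pairs[, list(true_rxcui, soc_code)])),
      pct_matched = if (nrow(kd) == 0) NA_real_ else round_half_up(
        100 * length(unique(kd[status == "matched", input_string])) /
          length(unique(kd$input_string)))
    )
    list(demo = demo_path, drug = drug_path, reac = reac_path,
         demo_table = demo,
         mention_log = drug[, list(isr, drug_seq, drugname, route, dose_vbm,
                                   input_string, true_rxcui, status)],
         reac_log = reac, retained = retained, expected = expected)
  })
}

#' Generate the complete fixture set
#'
#' Convenience wrapper running the three generators into one directory
#' and writing the blueprint parameters and expected quantities to
#' `blueprint.json`.
#'
#' @inheritParams generate_rxnorm_fixture
#' @return list with elements `rxnorm`, `meddra`, `aers` (the three
#'   generator results) and `blueprint`
#' @export
generate_fixture_set <- function(blueprint, dir) {
  rx <- generate_rxnorm_fixture(blueprint, dir)
  md <- generate_meddra_fixture(blueprint, dir)
  ae <- generate_aers_fixture(blueprint, rx, md, dir)
  jsonlite::write_json(
    list(parameters = unclass(blueprint), expected = ae$expected),
    file.path(dir, "blueprint.json"), auto_unbox = TRUE, digits = NA)
  list(rxnorm = rx, meddra = md, aers = ae, blueprint = blueprint)
}
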