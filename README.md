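# aersdm

Standardize and aggregate FDA adverse-event reports with RxNorm, NDF-RT
and MedDRA.

## The problem

The FDA Adverse Event Reporting System (AERS/FAERS) is the main public
resource for post-marketing drug-safety surveillance, but its raw
quarterly files resist large-scale mining: the same patient case appears
as multiple follow-up reports, drug names are free text (trade names,
abbreviations, typos, foreign brands), and adverse events are coded only
at the MedDRA Preferred Term (PT) level. `aersdm` builds a normalized,
aggregated Drug-ADE data set from those files for pharmacovigilance
researchers who want to run class-level analyses or feed clean
drug-event pairs into disproportionality methods (which are themselves
out of scope here).

The pipeline has three stages:

1. **De-duplication.** Among reports (ISRs) sharing a CASE number, keep
   the one with the latest FDA receipt date `FDA_DT`; on date ties, keep
   the highest ISR. The retained ISR set is propagated to the DRUG and
   REAC tables.
2. **Normalization.** Each DRUG row's `DRUGNAME`, `DOSE_VBM` and `ROUTE`
   fields are concatenated and mapped to an RxNorm concept (RxCUI),
   either by the built-in head-anchored lexicon matcher or by ingesting
   output of the external MedEx tool. REAC PT terms are mapped to MedDRA
   PT codes and rolled up to their primary System Organ Class (SOC).
3. **Classification and aggregation.** Each RxCUI is classified into the
   nine multi-axial NDF-RT drug-class axes (Mechanism of Action,
   Physiologic Effect, Therapeutic Intent, VA Class, Pharmacokinetics,
   ...) by a greedy breadth-first traversal of the RxNorm relationship
   graph: if the concept itself carries the NDF-RT source it is its own
   anchor; otherwise the ingredient/clinical-drug pathway
   (`tradename_of`, `has_ingredient`, `consists_of`, ... in both
   directions) is walked to the first depth at which NDF-RT ingredients
   or clinical drugs are found, and all anchors at that depth
   contribute their class memberships. The result is two flat tables —
   normalized (ISR, RxCUI, PT, SOC) records and aggregated
   (class, event) co-occurrence counts — joined by the RxNorm codes.

Evaluation helpers compute precision `P = TP/(TP+FP)`, recall
`R = TP/(TP+FN)` and `F = 2PR/(P+R)` against a gold standard of manually
coded drug names.

MedDRA is licensed and is **not** shipped; it is consumed as a simple
TSV (`pt_term`, `pt_code`, `soc_code`, `soc_name`, `primary_flag`).
RxNorm is read directly from its Rich Release Format (RRF) files. A
deterministic generator of miniature synthetic RxNorm/AERS/MedDRA-style
fixtures with recorded ground truth makes the whole pipeline testable
offline.

## Worked example

Entirely self-contained on synthetic fixtures (500 cases, ~200 drug
concepts, 20% duplicate cases, 20% corrupted drug strings):

```r
library(aersdm)

fx <- generate_fixture_set(fixture_blueprint(seed = 42),
                           file.path(tempdir(), "aersdm-demo"))
graph  <- load_rrf(fx$rxnorm$conso, fx$rxnorm$rel)
meddra <- load_meddra(fx$meddra$tsv)

keep <- deduplicate(read_demo(fx$aers$demo))
keep
#> keep_set: 500 of 608 reports retained (500 distinct cases)

mentions <- normalize_drug_table(
  filter_table(read_drug(fx$aers$drug), keep), build_lexicon(graph))
str(normalization_stats(mentions))
#> List of 4
#>  $ n_unique_input_strings  : int 886
#>  $ n_unique_matched_strings: int 686
#>  $ n_unique_rxcuis         : int 214
#>  $ pct_matched             : num 77

records <- build_drug_ade_records(mentions, read_reac(fx$aers$reac),
                                  keep, meddra)
nrow(records)                        # 1607 Drug-ADE records
count_unique_pairs(records, "PT")    # 1453 distinct (RxCUI, PT) pairs
count_unique_pairs(records, "SOC")   # 996 distinct (RxCUI, SOC) pairs

cls <- classify_concepts(graph, unique(mentions$rxcui),
                         load_class_table(fx$rxnorm$class_tsv))
head(coverage_report(cls, mentions[mentions$status == "matched", ]), 2)
#>                    axis n_classes n_rxcuis a_pct b_pct
#> 1: Therapeutic Category         3      155    72    86
#> 2:     Pharmacokinetics         3      150    70    84
```

Reading the output: 108 of the 608 raw reports were follow-ups of an
existing case and were dropped; 77% of the unique concatenated drug
strings resolved to an RxNorm concept (the planted corruption rate plus
string reuse accounts for the rest); every retained report then
contributes the cross product of its matched drugs and mapped events to
the record table. In the coverage table, `a_pct` is the share of all
classified concepts covered by that axis and `b_pct` the share of
reports containing at least one drug classified on it.

A thin command-line front end over the same functions is installed as
`exec/aersdm` with subcommands `dedup`, `normalize`, `classify`,
`aggregate`, `evaluate` and `fixtures`:

```sh
Rscript "$(Rscript -e 'cat(find.package("aersdm"))')/exec/aersdm" \
  dedup --demo DEMO.txt --drug DRUG.txt --reac REAC.txt --out-dir out/
```

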