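---
title: "Methods: standardizing and aggregating adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardizing and aggregating adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aersdm)
library(data.table)
```

`aersdm` turns raw AERS/FAERS quarterly files into a normalized and
aggregated Drug-ADE data set. This vignette documents the procedure,
the design decisions taken where the problem is genuinely
underdetermined, the synthetic-fixture machinery behind the test
suite, and the package's known limitations.

## De-duplication

AERS stores every follow-up submission of a patient case as a separate
report (ISR) under a shared CASE number. The FDA's recommended rule is
applied verbatim: within a CASE, retain the report with the latest
`FDA_DT`; when dates tie, retain the highest ISR. Two choices had to be
made beyond the rule itself:

* **Missing dates.** A report whose `FDA_DT` is absent or not a valid
  calendar date never beats a dated report; if every report of a case
  lacks a date, the highest ISR wins. This lets the rule degrade
  gracefully to its own tie-breaker instead of inventing an ordering on
  missing values.
* **Orphan ISRs.** The keep-set is defined solely on the DEMO table.
  DRUG/REAC rows whose ISR never appears in DEMO are dropped and
  counted (`dropped_count` attribute) — they cannot be assigned to a
  case, so no retention decision is possible for them.

Dates are stored as `YYYYMMDD` integers; integer order equals the
lexicographic order of the date strings, so no date arithmetic is
needed for the comparison.

## Drug-name normalization

The normalization input is the concatenation `DRUGNAME`, `DOSE_VBM`,
`ROUTE` (empty fields skipped, whitespace collapsed). The dose and
route fields contribute strength and form tokens ("20 MEQ",
"TABLET", "ORAL") that let a match reach a specific clinical-drug
concept rather than a bare ingredient. `DOSE_VBM` is placed before
`ROUTE` because dose text customarily carries the form/strength tokens
that immediately qualify the drug name.

The built-in matcher is a transparent lexicon scorer, not a
re-implementation of a medication NLP system; an adapter
(`import_medex_output()`) ingests externally produced MedEx output for
users who run that tool, and validates its codes against the loaded
concept graph. The matcher's semantics:

1. Input and lexicon strings are upper-cased, punctuation-stripped and
   whitespace-collapsed.
2. A lexicon entry is a *candidate* when its first token equals the
   input's first token **and** every one of its tokens occurs in the
   input. Head anchoring matters: unanchored substring matching maps
   strings like "... (CARBAZOCROME SODIUM SULFONATE)" to the salt
   ingredient "sodium", a known false-positive class. Containment
   (rather than token-by-token prefix equality) matters because the
   concatenation appends dose and route tokens out of their lexicon
   order: "POTASSIUM CHLORIDE EXTENDED RELEASE TABLET ... 20 MEQ BID
   ORAL" must still reach "Potassium Chloride 20 MEQ Extended Release
   Tablet".
3. The candidate with the most tokens wins; an exact full-string match
   wins outright; remaining ties are broken by term-type priority
   (semantic clinical drug > branded drug > component > brand >
   ingredient) and then lowest rxcui. Preferring the clinical drug
   keeps the most specific concept; the rxcui tie-break makes the
   result deterministic.
4. Suppressed RRF atoms are excluded from the lexicon (standard RRF
   practice) but retained in the graph.

The matcher is deterministic by construction, monotone under lexicon
growth (adding entries can never unmatch a string), and complete on
exact names (every lexicon string fed verbatim maps to its own
concept) — each of these is enforced by a property test. One
simplifying assumption is carried through the pipeline: at most one
RxCUI per mention.

## NDF-RT classification

RxNorm embeds NDF-RT: some concepts carry the NDF-RT source
vocabulary, and those concepts hold multi-axial class memberships
(Mechanism of Action, Physiologic Effect, Therapeutic Intent, VA
Class, Chemical Ingredients, Generic Ingredient Combinations, FDA
Established Pharmacologic Class, Therapeutic Category,
Pharmacokinetics — the closed nine-axis set used throughout). A
normalized RxCUI is classified as follows:

* If the concept itself is NDF-RT-sourced, it is its own anchor
  (depth 0) and never traverses.
* Otherwise a breadth-first traversal walks the
  ingredient/clinical-drug pathway of the RxNorm relation model —
  `has_ingredient`/`ingredient_of`,
  `has_precise_ingredient`/`precise_ingredient_of`,
  `tradename_of`/`has_tradename`, `consists_of`/`constitutes`,
  `has_form`/`form_of`, `isa` — in both edge directions, stopping at
  the **first** depth at which at least one NDF-RT-sourced
  ingredient-like (IN/PIN) or clinical-drug-like (SCD/SCDC) concept is
  reached. All concepts at that minimal depth become anchors.

"Greedy" is interpreted as *minimal hop count, collect all anchors at
that depth*: minimal depth keeps anchors semantically closest to the
query, while collecting all of them maximizes class recall (a
combination brand can legitimately resolve to several ingredients).
The default `max_depth = 3` covers the longest standard chain
(brand → clinical drug → component → ingredient); both the depth and
the relation set are plain arguments, so users can widen the pathway.
Traversal uses a visited set, so relation cycles are safe, and edges
without a RELA label are ignored. Querying a concept absent from the
graph raises a distinct error — it is not the same situation as "no
anchors found", which is a legitimate empty result.

Class memberships are read off a class table — either derived from
NDF-RT-labelled role-relationship rows in the RRF (the
`has_mechanism_of_action`, `has_va_class`, ... labels mapped to axes by
a configurable dictionary, `default_axis_map()`) or supplied as a TSV
for users holding NDF-RT outside RxNorm. The mapping from role labels
to the nine axis names is a documented default, not an assertion about
any particular release; it is deliberately configurable because
different NDF-RT distributions label these hierarchies differently.
Clinical-drug anchors additionally inherit the class rows of their
ingredient neighbours (`inherit = TRUE`), mirroring the inheritance of
role relationships from ingredients into the clinical drugs that
contain them.

The traversal is verified against an independent shortest-path oracle
(igraph distances restricted to the allowed relations) on every node
of dozens of randomly wired fixture graphs.

In the per-axis coverage report, `a_pct` is computed over concepts
with at least one membership on *any* axis, and `b_pct` over reports
containing at least one *classified* drug (not all retained reports):
both denominators describe the classified subpopulation, which is the
population the axis shares are meant to partition.

## MedDRA rollup

REAC entries are already MedDRA PTs, so PT mapping is exact after case
folding and whitespace normalization — fuzzy matching would risk
silent miscoding for no recall gain. Each PT rolls up to exactly one
*primary* SOC rather than fanning out over all linked SOCs: the
primary-SOC rollup makes SOC-level aggregation a partition of the
record set, so SOC percentages sum to 100 and records are never
double-counted. The TSV input abstracts how the user's MedDRA
distribution designates the primary link. Loading validates that every
PT has exactly one primary SOC and fails otherwise.

## The Drug-ADE tables

A Drug-ADE record is the within-report cross product: every matched
drug of a retained report co-occurs with every mapped event of that
report. Record counts therefore grow as (drugs per report) × (events
per report); this is the only join consistent with tens of millions of
records arising from a few million reports, and it is isolated in one
operation (`build_drug_ade_records()`) with a `distinct` flag for the
collapsed per-report variant. Unmatched drugs and unmapped PTs
contribute nothing and are counted in attributes.

Aggregation joins each record to the class memberships of its drug on
one axis; a drug in several classes increments every one (fan-out).
The aggregation is tested against a brute-force group-by over the
joined record × membership list and is invariant under record
shuffling.

Percentages are rounded half away from zero (`round_half_up()`) — one
decimal for SOC-distribution tables, integers for coverage tables —
matching the conventional presentation of such tables;
`base::round()`'s half-to-even rule would differ on exact halves. All
internal arithmetic is at full precision; the F-measure is computed
from unrounded precision and recall.

## Evaluation metrics

`score_against_gold()` compares predicted mentions with a
reviewer-coded gold standard at the unique-string level. A prediction
whose code differs from gold counts as one FP *and* one FN (the gold
string was not recovered); a gold-coded string left unmatched is an
FN. Degenerate cases raise a typed "undefined metric" error rather
than returning 0, except `F` when `P + R = 0`, which is 0 by
convention.

## Synthetic fixtures: what they do and do not show

`generate_fixture_set()` produces a miniature RxNorm-style RRF pair, a
MedDRA-style PT/SOC TSV, and AERS-style DEMO/DRUG/REAC files, all
deterministic per seed, with a blueprint of planted ground truth
sufficient to predict every pipeline output exactly. Defaults — 40
ingredients, 90 clinical drugs, 70 brands (≈200 drug concepts plus 27
class concepts), 500 cases, 20% duplicated cases (half of the
duplicates on exact-date ties), 20% corrupted drug strings, 70% of
ingredients/clinical drugs NDF-RT-flagged — are chosen to exercise
every branch (tie-breaks, brand fan-out, multi-axis classes,
suppressed atoms, corruption) while keeping a full pipeline run
sub-second. Corruptions follow the two dominant real-world failure
modes, typographical scrambles and foreign-brand-style renames, by
mangling the head token beyond lexicon reach; an exhaustive
generation-time scan proves no corrupted string can match and every
clean string resolves to its planted concept (the generator aborts
otherwise, rather than shipping an ambiguous corpus).

What the fixtures deliberately do **not** emulate: the Zipf-like
frequency distribution of real drug names, MedDRA's intermediate
HLGT/HLT levels, MedDRA version drift across years, real RxNorm's
scale and its occasional relation irregularities, and free-text noise
beyond head-token corruption (dose-text parsing, spelling variants
inside the name). Passing tests therefore demonstrate correctness of
the pipeline's logic under controlled structure, not the coverage
percentages one would obtain on real AERS quarters — those depend on
the user's RxNorm release, MedDRA version and corpus years.

## Test problem sizes

The suite runs the full pipeline on the default 500-case corpus;
sweeps duplicate and corruption rates over {0, 0.1, 0.3} with
150-case corpora; and checks traversal/oracle agreement on 50 random
graphs of up to a few hundred nodes each — sizes chosen to exercise
all code paths many times while keeping the whole suite around two
minutes on one CPU.

## Limitations

* The built-in matcher is a lexicon scorer: it does not parse dose,
  frequency or duration, correct spelling, or resolve foreign brand
  names. Users wanting NLP-grade normalization should run MedEx and
  import its output.
* Classification quality is bounded by the NDF-RT embedding in the
  user's RxNorm release; coverage gaps in NDF-RT itself are not
  repaired.
* Only the DEMO/DRUG/REAC tables are read; OUTC, RPSR, THER and INDI
  are not used by this pipeline.
* Disproportionality statistics (PRR, ROR, IC, EBGM) are downstream of
  this package's output and intentionally not implemented.
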