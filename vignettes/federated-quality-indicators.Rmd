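---
title: "Federated quality indicators over FAIR data stations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated quality indicators over FAIR data stations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedqi)
```

## The problem and the approach

Surgical quality registries compare hospitals on indicators such as the
waiting time between cancer diagnosis and the start of therapy, or the
postoperative complication rate. Computing these centrally requires every
hospital to export patient-level records — slow, duplicative and
privacy-sensitive. `fedqi` implements the federated alternative: data stay
inside each hospital as a FAIR (Findable, Accessible, Interoperable,
Reusable) RDF graph behind a query-only *station*; an analysis *train*
(a SPARQL retrieval query plus a local algorithm and its parameters)
travels to each station; only aggregate counts travel back; a master step
combines them. The package reproduces this architecture in-process with a
hard interface boundary rather than over a network: transport, tokens and
containers are deployment concerns, not part of the method, and the
station/train/payload contracts are what carry the privacy property.

## Indicator definitions and their approximations

Both indicators are crude proportions `numerator / denominator` per center.
The registry that defines them does not publish its exact algorithm, so the
package states its approximations explicitly and makes each one a
parameter:

* **First therapy date.** The variable set for the waiting-time indicator
  contains both a neoadjuvant-therapy start date and a surgery date but no
  combination rule. `fedqi` takes the earlier of the two
  (`first_therapy_date()`); records missing a diagnosis date are dropped
  from the denominator with a logged count.
* **"< 5 weeks" is strict.** Waiting time is the whole-day difference
  between diagnosis and first therapy; membership requires `< 35` days,
  never `<= 35`. A patient at exactly 35 days is outside the numerator.
* **Referral.** Both indicators exclude referred patients by default
  (`exclude_referred = TRUE`), since the referred flag appears in both
  variable lists; the complication indicator's published condition text
  does not mention referral, so the flag can be turned off.
* **Localization is a parameter.** The published indicator definition
  states both indicators on the rectum population, while the published
  per-center results table reports the waiting-time counts on the colon
  population. Defaults follow the results table (colon for 2b, rectum
  for 8); neither reading is asserted as correct.
* **Resection.** Every retrieved record is treated as a resection case; a
  resection-type filter can be layered on the cohort by editing the
  retrieval query, but no value-based filtering is applied by default
  because no value list is published.
* **No case-mix adjustment.** Age, BMI, Charlson score, ASA class and
  preoperative complications are retrieved and carried through untouched;
  the complication rate is crude.

The master statistics are the cross-center mean ratio, per-center expected
events (mean ratio × center denominator) and per-center rate-of-mean
(center ratio ÷ mean ratio). The mean is **unweighted** across centers by
default: the audit-style plots draw a mean line against per-center
percentages, and with very unequal centers a pooled mean would collapse
onto the largest center. The pooled reading (`Σ numerators / Σ
denominators`) is available via `mean_mode = "pooled"`. With equal weights
the rate-of-mean values average to exactly 1 — a property the tests assert.

## The synthetic-EHR generator

The generator (`generate_center()`) emulates one center's extracted flat
table: one row per patient with identification, tumor localization,
referral flag, the three dates, resection type and the case-mix variables.
It has two sampling modes:

* **Bernoulli mode** draws every marginal independently from configured
  probabilities and distribution specs.
* **Quota mode** fixes exact marginal counts — per localization a
  `(denominator, numerator)` pair, where the numerator is the
  short-waiting-time count for the colon group and the complication count
  for the rectum group, mirroring the audit's per-localization report
  columns. Events are assigned by shuffling within the group, and any
  records beyond the quota denominators are generated as *referred*, so
  they populate the table without entering the indicator cohorts. Quota
  mode exists because published audit tables are exact integer ratios; it
  is how the shipped two-center demo reproduces them digit for digit.

Waiting time is realized structurally: an integer day offset from the
diagnosis date to the first therapy. When a record receives neoadjuvant
therapy (probability `neoadjuvant_fraction`, default 0.25), the neoadjuvant
start sits at that offset and surgery follows 21–70 days later; otherwise
surgery itself sits at the offset. When a short-wait status is fixed (quota
or `short_wait_fraction`), short waits are drawn uniformly from 7–34 days
and long waits from 35–90 days — the boundary day 35 is reachable, and the
strict inequality is exercised by dedicated boundary tests.

The registries publish no distributions for the case-mix variables, so the
defaults — age from a truncated normal (mean 68, sd 10, 18–95 years), BMI
log-normal (median 26 kg/m², 14–55), Charlson truncated Poisson (λ = 1.5),
ASA categorical over classes 1–4 (0.15/0.55/0.27/0.03), preoperative
complications Bernoulli(0.2), waiting time truncated normal (mean 28, sd
14 days) — are plausible fixtures for a colorectal-surgery population, not
estimates. They ship in `inst/extdata/generator_defaults.json` and are
fully overridable. The shipped small-center demo config generates 40
patients whose two indicator cohorts (10 colon, 7 rectum) cover only 17
records; the other 23 are referred. Consequently, passing tests demonstrate
the *pipeline's* correctness on controlled marginals; they say nothing
about clinical correlations (e.g. ASA vs. complications), which the
generator deliberately does not model.

Every stochastic call requires an explicit integer seed in the config; the
generator uses no hidden global state, and the same config yields a
byte-identical CSV.

## The FAIR data model

The published architecture specifies "flat table → RDF triples with
terminology annotations" without reproducing its schema, so the package
defines a minimal star schema and documents it: one subject IRI per patient
(`{base}/patient/{center}/{patient_id}`) with one `rdf:type` triple and one
typed-literal triple per mapped, non-missing cell. Missing data is an
absent triple — no nulls, no blank nodes (which also makes graph
isomorphism plain set equality, used by the round-trip tests). Dates are
`xsd:date`, booleans `xsd:boolean`, and the CSV convention "yes"/"no" is
declared in the mapping's `value_codes`. Terminology anchoring is
vocabulary-level: each predicate links to its SNOMED CT code via an
annotation triple rather than using the code as the predicate, keeping the
graph readable while leaving the exact codes in the editable mapping file —
the shipped codes are placeholders. One dataset-level triple records the
center id as provenance.

The mapping covers all 14 table columns (the patient identifier is itself a
mapped column), so a complete record contributes exactly 15
patient-subject triples; the triple-count tests enumerate this directly.
`flat_view()` inverts `triplify()` up to record order and ignores unmapped
triples; the identity holds on 200 randomized generated tables per test
run.

## The embedded SPARQL engine and the station boundary

No R SPARQL engine fits an in-process station, so the package includes one
covering the fragment the shipped retrieval queries need: PREFIX, `SELECT`
with a variable list or `*`, basic graph patterns with `;`/`,`
abbreviations and `a`, `OPTIONAL` groups and `FILTER` (typed comparisons,
`&&`, `||`, `!`, `BOUND`). Solutions are computed relationally: each
triple pattern yields a binding table, tables join on shared variables,
`OPTIONAL` left-joins, filters evaluate on typed values (dates as dates,
numbers as numbers, booleans as booleans) — the station hands the local
algorithm typed rows, keeping indicator code free of serialization
concerns. Queries against unknown predicates return empty results, not
errors; syntax errors report the offending token. The engine is
cross-checked in the test suite against an independent standards-conformant
RDF stack (Python `rdflib`) running the identical query files on the
identical serialized Turtle, and against a direct in-memory filter oracle
on every generated fixture.

A station exposes exactly two capabilities to an orchestrator:
`accept_train()` and `return_payload()`. The graph lives in a private
closure environment — the station object has no graph field, which a
surface-enumeration test asserts. Payloads crossing the boundary must
conform to a closed-world schema (`validate_payload()`): exactly the six
aggregate fields, correct types, `0 ≤ numerator ≤ denominator`, exact
ratio. Unknown fields are violations, so a compromised train smuggling
patient identifiers is rejected by the master (`run_federated()` validates
every payload); an adversarial test exercises this. Small-cell suppression
is available (`station_policy(min_cell_size = k)` replaces sub-threshold
counts with an explicit suppressed marker) but defaults to off so that
small-center counts such as 4/7 remain reproducible.

## Numerical and degenerate-input choices

* Counts are exact integers; ratios are exact machine doubles. Rounding is
  display-only (percentage as integer, rate to three decimals), applied in
  print methods and figure labels, never in stored results.
* A zero denominator yields an undefined ratio with a warning, not an
  exception; undefined centers are excluded from the mean with a message,
  and a run where no center is computable is an error.
* Ties: a neoadjuvant date equal to the surgery date is simply that date;
  day differences ignore time of day by construction (calendar dates only).
* Truncated distributions resample up to a bounded number of rounds, then
  clamp; the bound is unreachable for the shipped parameterizations.
* Plots embed no timestamps; rendering the same result twice gives
  byte-identical SVG output.

## Problem sizes

The test suite and acceptance script run the full pipeline at the demo's
natural scale — 4699 records (~70k triples) for the large center, 40 for
the small one, which completes in roughly a second per federated run —
plus property suites over hundreds of small randomized tables (up to 30
records each). These sizes were chosen because the demo cohorts *are* the
study conditions being reproduced; nothing in the method depends on them,
and the generator scales linearly.

## Known limitations

* The indicator definitions are documented approximations of an
  undisclosed registry algorithm; agreement with any official calculation
  cannot be claimed.
* The SPARQL subset is deliberately small (no UNION, property paths,
  aggregates or subqueries); queries outside it fail to parse.
* The generator models marginals only — no clinical correlation structure,
  no missingness mechanisms beyond the optional neoadjuvant date.
* The in-process boundary demonstrates the contracts, not network
  security; deploying against real hospitals requires the transport,
  authentication and governance layers this package deliberately omits.
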