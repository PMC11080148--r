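# fedqi — federated surgical quality indicators over FAIR data stations

National surgical audits such as the Dutch ColoRectal Audit (DCRA) compare
hospitals on quality indicators, but the conventional route — copying
patient-level data out of every hospital's EHR into a central registry — is
slow, error-prone and privacy-sensitive. `fedqi` implements the alternative
end to end, at desk scale: each center's flat patient table is converted to
an RDF graph annotated with clinical terminology codes (the FAIRification
step), hosted behind a query-only *data station*, and visited by a *train*
that carries a SPARQL retrieval query plus a local indicator algorithm.
Only aggregate counts leave a station; a master step combines them across
centers and renders the audit-style comparison plots. A configurable
synthetic-EHR generator stands in for hospital data, so the entire pipeline
is testable and reproducible without any patient records.

## The indicators

For a center *c* with indicator cohort size (denominator) `d_c` and event
count (numerator) `k_c`, each indicator is the crude proportion
`r_c = k_c / d_c`:

* **Indicator 2b (short waiting time).** Cohort: non-referred patients with
  the configured tumor localization and a known diagnosis date. Event:
  strictly fewer than 35 whole days (5 weeks) between the diagnosis date and
  the *first therapy date* — the earlier of the neoadjuvant-therapy start
  and the surgery date. Reported as a percentage.
* **Indicator 8 (postoperative complications).** Cohort: the (non-referred)
  rectum-resection population. Event: a postoperative complication.
  Reported as a rate, unadjusted for case mix.

The master statistics are the unweighted cross-center mean
`m = mean(r_c)` (a pooled `Σk_c / Σd_c` mode is available), the *expected
events* per center `m × d_c`, and each center's *rate of the mean*
`r_c / m` — the quantities behind the two comparison figures (indicator
percentage vs. cohort size with a mean line; rate-of-mean vs. expected
events with a reference line at 1).

## Worked example

The shipped demo reproduces a two-center audit: a large center with 4699
patients and a small center represented by a 40-patient simulated cohort,
both generated in *quota mode* (exact marginal counts) from configs under
`inst/extdata/`.

```r
library(fedqi)
globals <- run_demo()   # generate -> triplify -> stations -> trains -> aggregate
print(globals$qi2b)
print(globals$qi8)
```

```
<global_result> qi2b over 2 center(s); mean ratio 0.8500 (unweighted)
<local_result> qi2b @ center1: 546/546 = 100%
<local_result> qi2b @ center2: 7/10 = 70%
<global_result> qi8 over 2 center(s); mean ratio 0.5438 (unweighted)
<local_result> qi8 @ center1: 2144/4153 = 0.516
<local_result> qi8 @ center2: 4/7 = 0.571
```

Reading: at center 1 all 546 colon-cohort patients started therapy within
5 weeks (100%); center 2 managed 7 of 10 (70%), so the mean line sits at
85%. Center 1 recorded complications in 2144 of 4153 rectum resections
(rate 0.516), center 2 in 4 of 7 (0.571); with the mean rate 0.544 the
expected events are 0.544 × 4153 ≈ 2258.6 and 0.544 × 7 ≈ 3.8, and the
rates-of-mean 0.949 and 1.051. `run_demo(outdir = "demo")` additionally
writes `results.json` and both figures (PNG and SVG).

Each stage is also scriptable individually — see `generate_center()`,
`triplify()`, `host_station()`, `build_train()`, `run_federated()`,
`plot_qi2b()`/`plot_qi8()` — or from a shell through the thin CLI:

```sh
inst/cli/fedqi generate --config inst/extdata/center2_config.json --out t.csv
inst/cli/fedqi fairify  --in t.csv --out s.ttl
inst/cli/fedqi demo     --outdir demo/
```

## Scope

The package implements the federated method, not a deployment: there is no
HTTP endpoint, authentication, or container orchestration, and no case-mix
adjustment (the case-mix variables are retrieved and carried through
untouched). The default mapping's SNOMED CT codes are editable placeholders,
not asserted terminology bindings. See the methods vignette
(`vignettes/federated-quality-indicators.Rmd`) for the design rationale and
limitations.
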