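---
title: "Methods: ARI phenotyping and surveillance with ariphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ARI phenotyping and surveillance with ariphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ariphen)
```

`ariphen` implements a rule-based phenotyping algorithm for acute
respiratory infection (ARI) in coded primary-care records, together with
the surveillance arithmetic built on top of it and a synthetic data
generator used to validate every stage. This vignette documents the
model, the parameters that matter, the numerical conventions, and the
design decisions taken where more than one reasonable choice existed.

## Terminology and the ECL subset

The terminology model is a polyhierarchical is-a graph: concepts are
opaque coded nodes, edges run child → parent, a node may have several
parents, and cycles are rejected at construction. Codes are not validated
as genuine SNOMED CT identifiers: synthetic terminologies use readable
codes, and real SNOMED codes pass through unchanged.

Codelists are defined *intensionally* with a small core of SNOMED's
Expression Constraint Language: `<<C` (descendant-or-self), `<C` (strict
descendants), bare `C`, and infix `AND`, `OR`, `MINUS` with parentheses.
This subset is exactly what descendant-plus-exclusion codelist rules
need; full ECL (attribute refinements, member-of, cardinality) is out of
scope. Two grammar conventions are worth stating:

* unary constraints bind tightest;
* the three binary operators share one precedence level and associate
  left-to-right. The subset is small enough that explicit parentheses are
  encouraged, and the canonical printer (`format()`) always fully
  parenthesizes, so a printed rule re-parses to the same tree.

Reachability over the graph is delegated to igraph and computed against a
cache built once per (immutable) graph; `graph_add_edges()` /
`graph_add_concepts()` return a *new* validated graph, so a stale
descendant set can never be observed after a mutation.

## The indicator hierarchy

ARI is modelled as a 3-level hierarchy. Level 1 is the umbrella ARI
indicator. Level 2 holds five groups: ILI (influenza-like illness), ECLD
(exacerbation of chronic lung disease), LRTI, URTI, and ARI-NOS, the
residual "coded as ARI without further detail, or suspected COVID-19"
group. Each level-2 group owns one or more level-3 indicators — 16 in the
standard model, split 1 (ILI) / 3 (ECLD) / 4 (LRTI) / 6 (URTI) / 2
(ARI-NOS) — and only level-3 indicators carry ECL rules. Level-2 and
level-1 codelists are inferred as unions of their children; because the
terminology is polyhierarchical, one code may legitimately resolve into
several level-3 codelists. That ambiguity is deliberately *not* removed
from the codelists; it is resolved at case classification.

## Case detection

Detection proceeds: filter events to the level-1 codelist → group by
patient → sort deterministically (date, then the code's best level-2
priority, then code) → group into episodes → classify each episode.

**The 28-day window.** An event opens a new case iff it falls strictly
more than `window_days` (default 28 days) after the previous ARI event.
Two semantics are plausible and the published descriptions of such rules
rarely distinguish them:

* **rolling** (default): the window restarts at every event, so a chain
  of recordings at ≤ 28-day gaps stays one episode however long it runs.
  This is the literal reading of "more than 28 days from the previous
  recorded event".
* **fixed**: the window is anchored at the episode's opening (index)
  event; a recording more than 28 days after the *index* starts a new
  episode even if it is close to the previous recording.

Both are implemented (`dedup_mode`), rolling is the default, and the
synthetic generator draws within-episode gaps of 1–21 days specifically
so that crafted configurations can make the two modes disagree and the
switch can be tested. "More than" is strict: a gap of exactly 28 days
joins the episode.

**Classification.** An episode may contain events matching several
level-3 indicators. The episode takes the indicator whose level-2 parent
ranks highest in the priority order ILI > ECLD > LRTI > URTI > ARI-NOS;
within a group the earliest-dated matching event decides, then the
lexicographically first level-3 id. The rationale for the default order:
ILI is kept as its own level-2 group precisely because of its primacy in
influenza surveillance, so it must win; ARI-NOS is by definition the
"no specific information" residual, so it must lose. The order is
configurable (`level2_priority`), and because no published convention
exists for which indicator a multi-indicator episode is counted under,
sensitivity analyses should vary it.

Events before registration or after deregistration are *not* filtered at
detection time; denominator-quality handling lives entirely in the
surveillance layer, so case extraction and rate computation can be
audited independently.

## Surveillance arithmetic

Weeks are ISO-8601 weeks (Monday-start; week 1 contains the year's first
Thursday), and the default reporting period is the influenza surveillance
year, ISO week 39 to week 38 of the following year (52 weeks). Age bands
are 0–17, 18–69 and 70+ completed years, evaluated at the case's index
date (not at season start): per-event stratification is the convention in
weekly reporting, and both choices are defensible, so the reference date
is an argument.

**Reliable denominators.** Practice list sizes are not always
trustworthy, and rate computation must exclude practices whose
denominator cannot be reliably established. No published operational
definition of "reliable" exists for this setting, so the rule here is an
invented, configurable stand-in, stated prominently: a practice is
reliable over a period iff it reports a positive list size for *every*
week and no week-on-week relative change exceeds `max_jump` (default
20%). Both numerator and denominator exclude unreliable practices.

**Denominators by stratum.** The weekly "all" denominator is the summed
reported list size of included practices. Age-band and risk-group
denominators count roster patients in the stratum (age at the week's
Monday). When reported list sizes equal roster sizes the strata sum
exactly to the total; when they diverge the reported list size is taken
as authoritative for the overall rate. Case counts, unlike denominators,
always partition exactly across strata and across level-2 groups — these
conservation identities are asserted in the test suite.

**Rounding.** Rates are `100000 * cases / denominator` at full precision;
medians and percentage changes are rounded half-up (half away from zero)
to one decimal *at presentation only*, matching surveillance-table
convention. `percent_change(old, new)` is `100 * (new − old) / old` and
requires `old > 0`; a comparison against an empty baseline is flagged as
undefined rather than silently returned as infinite. Published
comparison tables are sometimes computed on unrounded internal values, so
re-deriving a printed percentage from printed rounded inputs can differ
in the last decimal; `ariphen` always computes on the quantities actually
supplied.

## The validation reports

`run_part1` is the codelist set analysis: sizes, intersection, and codes
unique to each list, with the size identities `|a| = |a∩b| + |a\b|`
checked by construction. `code_frequency_coverage` supports the
concentration analysis ("how many codes account for 90% of recorded
events?"): codes are ranked by descending count with lexicographic
tie-break, and `k` is the smallest covering prefix.

`run_part2` detects cases twice over the same stream — legacy flat
codelist vs rule-based hierarchy — and matches cases on
(patient, index date). Newly included/excluded cases are the unmatched
sets, which makes `new_total = old_total + included − excluded` an exact
identity on every run. Matching on index date is deliberately strict: an
episode whose first visible event differs between algorithms counts as
one exclusion plus one inclusion, which is what a surveillance consumer
comparing the two case tables would observe.

`run_part3` applies the reliability filter once, computes both weekly
rate tables over the shared included practices, and summarises totals,
median weekly rates (even week counts average the two central values) and
percentage changes per indicator and stratum.

## The synthetic data generator

The generator stands in for an inaccessible national primary-care record
system, and its defaults are the package's reference study conditions:

* **Terminology** (~130–150 concepts): one anchor concept per level-3
  indicator with a small descendant subtree; a few extra is-a edges give
  concepts second parents within the same level-2 group (polyhierarchy);
  three anchors carry chronic/recurrent exclusion subtrees removed by
  `MINUS` rules; standalone branches hold chronic, non-infective and
  recurrent decoy concepts. The legacy ("old") codelist contains every
  decoy and — in the default `realistic` style — misses ~15% of the new
  codes (`p_new_only_code`), emulating symptom codes a legacy list never
  contained. The `superset` style (old = new ∪ decoys) isolates
  miscoding as the only difference between algorithms, which is what the
  exact exclusion-count check requires. Decoy codes are disjoint from
  the resolved new level-1 codelist by construction.
* **Population**: 20 practices × 500 patients by default; ages drawn
  0.21 / 0.655 / 0.135 across the three bands (roughly an English
  population); risk-group prevalence 0.25; practices drop register weeks
  with probability 0.15, exercising the reliability filter.
* **Events**: per patient-week episode onsets from a seasonal intensity
  per level-2 group — baseline plus a Gaussian winter peak,
  `rate(w) = b·(1 + (m−1)·exp(−(w−w0)²/2σ²))` per 100,000 per week, with
  defaults (URTI 110×2.2, LRTI 55×2.8, ARI-NOS 14×2, ECLD 8×3, ILI 2×8
  peaking weeks 13–16 of the season) chosen to give a realistic overall
  weekly ARI rate in the low hundreds per 100,000. Each episode emits
  1 + Geometric(mean `repeat_mean_extra` = 1) codings at uniform 1–21-day
  gaps truncated to the 28-day window. Onsets are greedily thinned to a
  minimum inter-episode gap (`min_episode_gap_days` = 60 >
  28 + 21), which guarantees distinct true episodes can never merge
  under the window rule — so ground-truth recovery is exact when
  repeat coding is the only corruption. Miscoded decoy events are
  injected at `miscode_rate_per_100k` = 5 per week (≈2% of true case
  volume, matching the false-positive share a legacy algorithm
  plausibly carries) and then thinned so no decoy falls within
  window + 1 days of a true event of the same patient.

All draws come from R's generator seeded from `sim_config(seed)` (with
fixed stage offsets), so identical configurations are byte-identical;
no wall-clock entropy enters anywhere.

**What the generator does not emulate.** Real coded records have
registration churn, practice-level coding-style heterogeneity,
multi-pathogen co-circulation, recording delays, and miscodes that are
temporally *entangled* with true illness (e.g. a chronic code recorded
at an acute consultation). The temporal guard that separates decoys from
true events is a deliberate idealisation: it makes the false-positive
accounting exact and testable, at the cost of understating how messy
real exclusion analyses are. Passing the synthetic validation therefore
demonstrates correctness of the *logic*, not field performance of any
particular codelist.

## Test and validation problem sizes

The property suites run on 200 random DAGs (≤ 40 nodes, ≤ 60 edges) with
random depth-≤3 ECL expressions, and 500 random per-patient event streams
(≤ 30 events, 0–60-day gaps) in both deduplication modes, each against
independent brute-force oracles kept in the test helpers. End-to-end
validation simulates 10,000 patients over 52 weeks: detected weekly ARI
counts are tested against the configured seasonal curve with a chi-square
goodness-of-fit (conditioning on the season total; rejection level 0.01),
detected case counts against ground-truth episode counts, and the
old-vs-new exclusion count against the injected decoy case count exactly.
These sizes give each weekly cell an expected count well above the
chi-square small-cell regime while keeping the whole suite fast on a
single CPU.

## Known limitations

* The ECL subset omits refinements and member-of; rules needing them
  must be rewritten in descendant/exclusion form.
* The reliability rule is a stand-in; a production deployment should
  replace it with the network's actual denominator quality checks.
* Classification priority is a convention, not an estimate; multi-group
  episodes are sensitive to it and should be examined with the priority
  reordered.
* Stratified denominators rely on the patient roster; if the roster and
  the reported list sizes disagree, stratified rates and the overall
  rate are computed from different denominators.
* No baseline/threshold machinery (e.g. moving epidemic method) is
  included; the output is the weekly rate table itself.
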