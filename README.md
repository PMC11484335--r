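# ariphen

Rule-based phenotyping of acute respiratory infection (ARI) for
primary-care sentinel surveillance, in R.

Sentinel surveillance networks estimate community rates of indicators such
as influenza-like illness (ILI) and ARI from coded electronic health
records. Doing that well needs three things: **codelists** that map a
clinical terminology onto a case definition, **clinical logic** that turns
a stream of date-stamped coded events into deduplicated infection
episodes, and **rate computation** over practice denominators.
`ariphen` implements that full chain for an ARI indicator, plus the
validation analyses used when a surveillance system replaces an old
codelist-based algorithm with a new rule-based one, and a seeded synthetic
data generator so every stage can be exercised and tested without access
to patient records. It is aimed at epidemiologists and health-data
scientists who build or audit syndromic surveillance pipelines.

## The model

**Terminology and rules.** Concepts live in a polyhierarchy (a concept may
have several is-a parents, as in SNOMED CT). Codelists are not enumerated
but *derived* by evaluating rules in a core subset of SNOMED's Expression
Constraint Language (ECL):

```
<<C          descendant-or-self of C
<C           strict descendants of C
C            C itself
X AND|OR|MINUS Y    set intersection / union / difference
```

**Indicator hierarchy.** ARI is a 3-level indicator: level 1 is ARI
itself; level 2 comprises ILI, ECLD (exacerbation of chronic lung
disease), LRTI, URTI and a residual ARI-NOS group; each level-2 group
owns level-3 indicators (16 in the standard model: 1/3/4/6/2 per group),
each bound to one ECL rule. Level-2 and level-1 codelists are unions of
their children.

**Case detection.** Events matching the level-1 codelist are scanned per
patient in date order; an event opens a new case iff it falls strictly
more than 28 days (configurable) after the previous ARI event — a rolling
window, so closely spaced recordings collapse into one episode. Each
episode is assigned a level-3/level-2 indicator using the priority order
ILI > ECLD > LRTI > URTI > ARI-NOS.

**Rates.** Cases are binned by ISO week of index date and divided by the
registered population of practices with reliable weekly denominators,
reported per 100,000 overall and stratified by age band
(0–17, 18–69, 70+) and risk group.

## Worked example

```r
library(ariphen)

# ECL against a small terminology
g <- concept_graph(
  tibble::tibble(
    code  = c("uri", "sinusitis", "acute_sinusitis", "chronic_sinusitis"),
    label = c("Upper respiratory infection", "Sinusitis",
              "Acute sinusitis", "Chronic sinusitis")
  ),
  tibble::tibble(
    child  = c("sinusitis", "acute_sinusitis", "chronic_sinusitis"),
    parent = c("uri", "sinusitis", "sinusitis")
  )
)
evaluate_ecl(g, "<<sinusitis MINUS <<chronic_sinusitis")
#> [1] "acute_sinusitis" "sinusitis"

# a full synthetic surveillance season: 20 practices x 500 patients
sim   <- simulate_surveillance_data(sim_config(seed = 1))
cases <- detect_cases(sim$events, sim$codelists)
dplyr::count(cases, level2)
#>   level2      n
#> 1 ARI-NOS    99
#> 2 ECLD       59
#> 3 ILI        25
#> 4 LRTI      413
#> 5 URTI      740

# old (flat legacy codelist) vs new (rule-based hierarchy)
run_part2(sim$events, sim$old_codelist, sim$codelists)
#> Part 2: case comparison
#>   old total: 1285   new total: 1336
#>   newly included: 136   newly excluded: 85
#>   percent change: 4

old_cases <- detect_cases(sim$events, sim$old_codelist)
run_part3(old_cases, cases,
          list(practices = sim$practices, patients = sim$patients),
          sim$period)
#> Part 3: weekly rate comparison
#>   reliable practices: 18
#>   season totals (all): old 1145, new 1196 (additional 51)
```

Reading the output: the new rule-based algorithm picks up 136 episodes
the legacy codelist missed (symptom codes outside the old list) and drops
85 false-positive episodes arising from injected chronic/recurrent/
non-infective miscodes; two practices fail the denominator reliability
rule, so the weekly-rate comparison runs over the remaining 18. The
season's median weekly ARI rate rises from 216.7 to 233.3 per 100,000
(`rate_percent_change` 7.7 in `run_part3(...)$summary`).

A thin command-line front end over the same functions lives in
`inst/cli/ariphen.R` (subcommands `simulate`, `build-codelists`,
`detect-cases`, `compare-codelists`, `compute-rates`).

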