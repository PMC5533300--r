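# ironavail

Population-level estimation of dietary iron bioavailability (percent
absorption) from nutrition-survey data: individual iron intakes, serum
ferritin (SF) concentrations, and a percentile distribution of absorbed-iron
requirements.

**Who it is for.** Risk managers, nutrition epidemiologists and anyone
setting dietary reference values who has representative iron-intake and
iron-status data for an adult population and needs a transparent
bioavailability factor at a chosen target ferritin concentration.

## The model

For a group stratified by sex and menopausal status, with intakes
$x_1,\dots,x_n$ (mg/d) and an absorbed-iron requirement distribution given
as a quantile function $R(p)$ on the half-percentile grid
$p \in \{0.5, 1.0, \dots, 99.5\}$:

* at an assumed absorption $a$ (percent, grid 1–40 by 0.5), individual $i$
  absorbs $x_i a / 100$ mg/d, and their probability of inadequacy is the
  fraction of grid percentiles with $R(p) > x_i a / 100$ (full-probability
  approach);
* the predicted prevalence of inadequate intakes is
  $\pi(a) = \frac{100}{n}\sum_i \Pr[\text{inadequate}_i \mid a]$,
  non-increasing in $a$;
* the observed prevalence of iron insufficiency at an SF cutoff $s$ is
  $P_{\mathrm{obs}}(s) = 100 \cdot \#\{ \mathrm{SF}_i < s \} / n$;
* the estimated dietary absorption at $s$ solves
  $\pi(a) = P_{\mathrm{obs}}(s)$, found by linear interpolation along the
  absorption grid.

Cohorts are filtered first: individuals with raised inflammation markers
(hs-CRP > 5 mg/L or α-1-antichymotrypsin > 0.65 g/L; ferritin is an
acute-phase reactant), iron-supplement users, and records without SF are
excluded sequentially.

## Worked example

```r
library(ironavail)

# n-weighted pooling of published per-study summaries
tab <- survey_reference_table()
men <- tab[tab$group == "men", ]
pooled_mean(men$iron_intake_mean, men$n)                      # 13.6 mg/d
pooled_sd(men$iron_intake_mean, men$iron_intake_sd, men$n)    # 5.2 mg/d

# a synthetic premenopausal cohort at the pooled survey conditions
coh  <- generate_group(reference_group_spec("premenopausal", seed = 1))
dist <- generate_requirement_distribution(requirement_spec("premenopausal"))

predicted_prevalence(cohort_intakes(coh), dist, 18)
#> 37.8   — percent of the group whose intake is inadequate at 18% absorption

absorption_profile(coh, dist, sf_cutoffs = c(15, 30, 60))
#>   sf_cutoff absorption observed_prevalence clamped
#> 1        15   28.93890            12.32143   FALSE
#> 2        30   16.59046            43.39286   FALSE
#> 3        60   10.49215            74.28571   FALSE
```

Reading the profile: 12.3 % of this cohort has SF below 15 μg/L; for the
predicted prevalence of inadequacy to equal that, dietary absorption must
be 28.9 %. At a more generous definition of sufficiency (SF 60), the
matched absorption drops to 10.5 % — low iron stores imply upregulated
absorption.

Real data enter through `read_cohort()` (CSV, arbitrary headers via a
column map) and `load_requirement_table()`; the same computations are
exposed as commands (`cmd_filter`, `cmd_summarize`, `cmd_prevalence`,
`cmd_absorption`, `cmd_simulate`) driven by a JSON/YAML config, and from a
shell via the thin dispatcher `inst/cli/ironavail`.

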