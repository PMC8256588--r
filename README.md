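# eosmask

Estimating the true prevalence of airway luminal eosinophilia from
quantitative sputum cytometry.

## The problem

On Wright-stained sputum cytospins, an intact eosinophil differential of
≥ 1.2% is abnormal and ≥ 2.3% defines a clinically relevant eosinophilic
(Th2-high) endotype — the phenotype that predicts response to
corticosteroids and anti-IL-5 biologics. A single intact cell count,
however, misses two kinds of evidence:

* **free eosinophil granules (FEG)** left by eosinophil cytolysis, graded
  semi-quantitatively (none / few / moderate / many clumps per 400× field)
  and countable even when the sample is too degenerated for an intact
  differential; and
* **masking** — eosinophilia suppressed by corticosteroids or obscured by
  neutrophilia that *re-emerges* on a later examination when the dose is
  weaned, bronchitis is treated, or the disease flares.

`eosmask` implements the staged estimate that corrects for both. For a
longitudinal cohort of sputum examinations and a threshold specification
(cutoff `c`, qualifying FEG grade set `Q`), with `n` samples of which `a`
are intact-positive, `b` FEG-positive with an intact differential below
the cutoff, and `d` FEG-positive without an intact differential:

```
p_intact = a / n
p_feg    = (a + b + d) / n
p_total  = p_feg + (1 - p_feg) * q        # q = re-emergence fraction
```

where `q` is the fraction of multi-sample patients showing at least one
non-eosinophilic → eosinophilic transition between consecutive
examinations. Each re-emergence event is attributed an etiology
(treated neutrophilia / steroid decrease / both / flare), and a two-state
discrete-time Markov chain over the per-sample calls — transition
probabilities estimated by pooled row-normalized pair counts, stationary
occupancy `π_E = p_NE / (p_NE + p_EN)` — serves as a sensitivity analysis
of the same longitudinal information. Because clinical sputum databases
are not publicly deposited, the package also ships a first-class
synthetic cohort generator with a latent eosinophilic state, dose- and
neutrophilia-driven masking, and a ground-truth ledger, calibrated so its
defaults reproduce the cohort structure and staged prevalences of a large
published clinical database.

For whom: respirologists and biostatisticians analyzing sputum cytometry
databases, and methodologists studying prevalence estimation under
intermittently masked disease states.

## Worked example

```r
library(eosmask)

cohort <- generate_cohort(generator_config(seed = 1))$cohort
res <- run_full_analysis(cohort, tally_mode = "paper_tally")
res
```

```
<eos_analysis> 17789 samples, 9570 patients (paper_tally tallies)

<prevalence_estimate> eos_1.2 (paper_tally tallies, n = 17789)
  intact-only:   35.3%  (6272 samples)
  FEG-augmented: 44.7%  (+573 with differential, +1101 without)
  extrapolated:  59.7%  (emergence fraction 27.2%)
  underestimation by intact-only tier: 41.0%
  emergence: 803/2954 patients (27.2%), 0.313 events/patient
  Markov: p_NE = 0.220, p_EN = 0.224, pi_E = 0.495

<prevalence_estimate> eos_2.3 (paper_tally tallies, n = 17789)
  intact-only:   25.8%  (4592 samples)
  FEG-augmented: 30.0%  (+145 with differential, +602 without)
  extrapolated:  48.2%  (emergence fraction 26.0%)
  underestimation by intact-only tier: 46.5%
  emergence: 769/2954 patients (26.0%), 0.319 events/patient
  Markov: p_NE = 0.166, p_EN = 0.379, pi_E = 0.304
```

Reading the 1.2% block: 35.3% of samples are eosinophilic on the intact
differential alone; granules raise that to 44.7% (573 samples with a
differential below the cutoff but qualifying FEG, 1101 degenerated
samples rescued by FEG alone); extrapolating the 27.2% re-emergence
fraction over the not-yet-positive remainder gives an estimated true
prevalence of 59.7%, i.e. the single intact count underestimates by 41%.
The Markov stationary occupancy (49.5% at 1.2%) is the chain's
independent reading of the same longitudinal data.

The same pipeline runs on real data via `read_cohort("records.csv")`
(schema in `?cohort_schema`; invalid rows are quarantined with reasons,
see `rejects()`). Individual stages are exported — `classify_cohort()`,
`find_emergence()`, `estimate_prevalence()`, `estimate_transitions()`,
`euler_composition()` — and `closed_form_expectations()` gives analytic
expectations under a generator configuration for validation.

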