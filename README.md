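# nkaml — genomic classification and outcome analysis for normal-karyotype AML

Acute myeloid leukemia with a normal karyotype (NK-AML) has no chromosomal
lesion to anchor risk stratification, so prognosis rests on somatic driver
mutations found by targeted deep sequencing. `nkaml` is an R package for
hematology research groups analysing such cohorts. It implements, end to
end:

* **Somatic driver retention** — for each candidate variant with tumour
  ref/alt depths *(r_T, a_T)* and control depths *(r_N, a_N)*: retain iff
  the gene is on the driver panel, VAF = a_T/(r_T + a_T) ≥ 0.03, no
  germline-database flag, and the two-sided Fisher exact test on the 2×2
  table [(r_T, a_T), (r_N, a_N)] gives p < 0.001 (a control-free caller
  flag substitutes when no control exists).
* **Eight-way genomic classification** — class-defining lesions are NPM1
  mutation; any mutation in RUNX1, ASXL1, BCOR, STAG2, EZH2, SRSF2, SF3B1,
  U2AF1 or ZRSR2 (chromatin/spliceosome); TP53 mutation; biallelic CEBPA;
  and IDH2-R172 with no other class-defining lesion. One lesion gives that
  class; ≥2 give the multi-class bin; none gives driver-no-class or
  no-driver depending on whether any driver was retained.
* **Subgroup statistics** — per-class rates with Wald intervals
  (100·k/n ± z·100·√(p(1−p)/n)), Woolf odds-ratio intervals
  (exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d))), Pearson χ².
* **Survival machinery** — Kaplan–Meier Ŝ(t) = ∏(1 − d_j/n_j) with
  Greenwood variance; log-rank; Aalen–Johansen cumulative incidence
  CIF_k(t) = Σ_{s≤t} Ŝ(s−)·d_k(s)/n(s) for relapse with death-without-
  relapse competing; Gray's test; Cox partial likelihood on start–stop
  intervals with allogeneic transplantation as a time-dependent covariate.
  Endpoints follow the clinical definitions: OS and EFS from induction
  start, relapse from CR, transplantation never censors.
* **A calibrated synthetic cohort generator** — emulates the published
  393-patient cohort (subgroup prevalences, CR and transplant rates,
  5-year OS and relapse per class, co-mutation frequencies) so the whole
  pipeline is testable without patient-level data.

See `vignettes/nkaml-methods.Rmd` for the model details and design
decisions.

## Worked example

```r
library(nkaml)

# published-count arithmetic
proportion_with_ci(118, 136)
#> proportion (%): 86.765 (95% CI 81.069-92.460)
odds_ratio(50, 3, 275, 65)
#> odds ratio: 3.939 (95% CI 1.191-13.027), p = 0.016

# synthetic cohort -> full pipeline
co <- generate_cohort(sim_config(seed = 42), dir = "demo")
run <- run_pipeline("demo/mutations.tsv", "demo/clinical.csv",
                    out_dir = "demo/out")
run
#> NK-AML pipeline run: 393 patients
#>
#> Genomic classification of 393 patients
#>                                               label   n  pct
#>                                       NPM1 mutation 139 35.4
#>        Chromatin and/or RNA-splicing genes mutation  36  9.2
#>                                       TP53 mutation   3  0.8
#>                           Biallelic CEBPA mutations  50 12.7
#>  IDH2-R172 mutation, no other class-defining lesion   9  2.3
#>          Driver mutations, no class-defining lesion 116 29.5
#>                         No detected driver mutation  19  4.8
#>                              More than one subgroup  21  5.3
#>
#> 5-year outcome summary (%):
#>             label   n  os5 efs5 relapse5
#>              NPM1 139 50.4 12.9     49.6
#>  CHROMATIN_SPLICE  36 16.7  0.0     47.8
#>              TP53   3 33.3 33.3      0.0
#>   BIALLELIC_CEBPA  50 56.0 48.0     16.3
#>         IDH2_R172   9 44.4 11.1     42.9
#>   DRIVER_NO_CLASS 116 19.8  1.7     42.0
#>         NO_DRIVER  19 15.8  0.0     47.4
#>       MULTI_CLASS  21 38.1 14.3     22.2
```

The first two calls reproduce published figures exactly (the CR rate of
the biallelic-CEBPA subgroup versus the rest, odds ratio 3.939). The
pipeline run classifies a simulated cohort — class shares land near the
configured prevalences (35.4% vs 34.6% for NPM1), and the 5-year columns
scatter around the configured class targets with n-of-393 Monte-Carlo
noise. `demo/out/` then contains the filter decisions, per-patient labels,
subgroup statistics, survival summaries, test results and a Table-1-style
report plus run log.

A thin command-line wrapper ships in `exec/`:

```sh
nkaml simulate --seed 1 --n 393 --out cohort/
nkaml run --mutations cohort/mutations.tsv --clinical cohort/clinical.csv --out results/
```

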