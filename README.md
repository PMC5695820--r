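# admixscan

Admixture mapping of quantitative traits in admixed cohorts.

In populations descended from several ancestral groups — such as US
Hispanics/Latinos, admixed between European, African and Amerindian
ancestors — each genomic segment of each chromosome copy has an ancestral
origin. **Admixture mapping** regresses a trait on the per-interval count
(0/1/2) of copies inherited from a given ancestry. In the simplest
two-ancestry setting with per-allele effects β₁, β₂ and effect-allele
frequencies p₁, p₂, the interval-count slope is

    β_adm = β₁ p₁ − β₂ p₂   (= β (p₁ − p₂) for a shared effect size)

so the scan detects loci whose causal alleles differ in frequency *or* in
effect between ancestral populations, at a multiple-testing burden of
thousands of intervals rather than millions of variants. `admixscan` is
aimed at statistical geneticists who want a tested, reproducible version
of that workflow for blood-pressure-like quantitative traits:

* **synthetic cohorts** with known truth: Poisson-process ancestry tracts,
  Dirichlet admixture proportions per analysis group, ancestry-conditional
  genotypes, household/block clustering, sibling kinship and BP phenotypes
  with planted causal variants;
* **phenotype preparation**: medication adjustment (+10/+5 mmHg),
  measurement-inconsistency, missingness and range exclusions with a full
  audit log, PP winsorization at mean + 6 SD;
* **linear mixed models** with kinship, household and block random effects
  (sparse REML), and 1-df / 2-df Wald scans of local ancestry counts at
  the genome-wide admixture threshold 5.68×10⁻⁵;
* **fine-mapping**: the candidate-variant p-value/EAF-difference ladder,
  correlation pruning at |r| ≤ 0.4, conditional scans, and an
  explained-signal classification;
* **ancestry-specific allele frequencies** by EM from unphased genotypes
  and local ancestry;
* **power theory** (admixture vs association testing by exact enumeration)
  and **one-sided replication testing** with Bonferroni thresholds.

See `vignette("admixture-mapping")` for the models, defaults and design
choices.

## Worked example

Simulate a two-group cohort (Mainland-like and Caribbean-like admixture)
with one planted causal variant that is common on Amerindian background
(frequency 0.9) and rare elsewhere (0.1), then run the whole pipeline:

```r
library(admixscan)

cfg <- pipeline_config(seed = 31, groups = default_groups(250, 250),
                       vs = variance_spec(10, 8, 2, 60),
                       n_intervals = 60, traits = "SBP",
                       replication_n = 250L)
res <- run_pipeline(cfg, outdir = "demo_run")

res$regions[, c("trait", "ancestry", "chrom", "start", "end", "n_lai", "lead_p")]
#>  trait   ancestry chrom start       end n_lai       lead_p
#>    SBP Amerindian     1 1e+08 103333333     1 2.469486e-06
```

One Amerindian-ancestry region crosses the genome-wide admixture threshold
(lead interval p = 2.5×10⁻⁶). Fine-mapping admits the planted variant at
the strictest ladder rung and pruning selects it as the lead:

```r
fm <- res$finemap[[1]]
fm$leads[, c("variant", "p_min", "delta", "rung_p", "effect_overall")]
#>    variant        p_min     delta rung_p effect_overall
#>  rs_causal 2.953986e-09 0.3272688  1e-06       3.726501
```

`delta` is the effect-allele frequency difference between the high- and
low-Amerindian analysis groups; `effect_overall` is the per-allele
association estimate (mmHg). Conditioning the interval scan on this
variant abolishes the region signal, so it is classified as fully
explaining the admixture association:

```r
fm$summary[, c("lead_p", "p_conditional", "explained")]
#>        lead_p p_conditional explained
#>  2.469486e-06     0.5115715      full
```

The EM estimator recovers the planted ancestry-specific frequencies
(truth 0.1 / 0.1 / 0.9) from unphased dosages:

```r
fm$ancestry_eaf[, c("variant", "ancestry", "eaf")]
#>    variant   ancestry        eaf
#>  rs_causal   European 0.09353371
#>  rs_causal    African 0.15545589
#>  rs_causal Amerindian 0.89291838
```

and a one-sided replication test in an independently simulated
high-Amerindian cohort (direction fixed by the discovery sign) confirms
the association:

```r
res$replication[, c("variant", "trait", "rep_freq", "rep_effect",
                    "p_one_sided", "significant")]
#>    variant trait  rep_freq rep_effect  p_one_sided significant
#>  rs_causal   SBP 0.8714859   4.921394 6.396861e-05        TRUE
```

All stage outputs (local-ancestry, dosage, trait and scan tables; region
BED; conditional scans; plots; JSON manifest with the seed and a
configuration hash) are written under `outdir`, and a rerun with the same
configuration and seed reproduces them byte for byte.

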