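# hmcquant

Quantification and comparative analysis of 5-hydroxymethylcytosine
(5hmC) from paired bisulfite (BS) and oxidative-bisulfite (oxBS)
Illumina-450K-style methylation arrays.

Standard BS conversion cannot distinguish 5-methylcytosine (5mC) from
5hmC: a BS beta value reads their sum. oxBS conversion oxidises 5hmC
before conversion so that only true 5mC survives as methylated signal.
Profiling both chemistries on the same DNA gives, per probe and sample,

    delta_beta = beta_BS - beta_oxBS  ~  5hmC level,

with technical noise producing *negative* delta-beta at 5hmC-free
probes. The package turns that negative tail into an empirical null:
the detection threshold tau is the absolute 5 % quantile of the pooled
strictly-negative delta-beta values, and a probe has "detectable" 5hmC
in a tissue when its tissue-mean delta-beta strictly exceeds tau.

For whom: analysts working with paired BS/oxBS beta matrices (e.g. GEO
series of brain or other tissue panels) who need the full downstream
battery — QC, 5hmC calling, tissue-specific and variable-site ranking,
genomic-feature enrichment, confounder-controlled pathway analysis,
metagene profiles, genome-browser export — plus a synthetic-data
generator with known truth to validate every stage offline.

## What is implemented

* **core_io** — TSV/CSV beta and detection-p matrices, sample sheets,
  probe annotation, gene models; BS/oxBS pairing per donor and tissue;
  BED6 export (1-based annotation in, 0-based half-open out).
* **qc** — detection-p filtering (samples then probes, 5 % of sites at
  p < 0.05), SNP/cross-reactive masking, BS-kit concordance (R² per
  tissue), donor identity from rs genotyping probes.
* **hmc_calling** — delta-beta, empirical threshold (negative-tail or
  all-values quantile), detectable calls with inclusion-exclusion
  summaries, ranking by level / inter-individual variability /
  cross-tissue difference (TS-HMPs).
* **enrichment** — Fisher's exact test across CpG-island context, gene
  features, TFBS, DHS and alternative-transcription events; Woolf 95 %
  CIs; inclusive-background convention reproducing the published
  tables, exclusive option for effect-size inference.
* **tissue_comparison** — cross-tissue correlation at detectable sites,
  discovery/validation concordance with replication counts, exact
  decomposition of BS tissue differences into 5mC and 5hmC components.
* **pathway_enrichment** — GMT input, ancestor propagation, logistic
  regression of pathway membership on a test gene list controlling for
  probes-per-gene, Firth fallback under separation, iterative
  redundancy grouping.
* **metagene_profile** — strand-aware normalised gene axis (flanks
  [-10,0) and (100,110], body [0,100]), overlapping 1-unit windows.
* **synthetic_data** — annotation/truth/beta/pathway generators with
  configurable effect sizes, feature odds, confounding and seeds.
* **cli_pipeline** — `run_pipeline()` / `hmc_main()` staged execution
  with file hand-off, JSON manifest and checksums; YAML or JSON config.

## Worked example

```r
library(hmcquant)

sim <- simulate_hmc_experiment(n_probes = 20000,
                               n_donors = c(discovery = 8L,
                                            validation = 18L),
                               seed = 1)
qc    <- mask_probes(pfilter(sim$betas, sim$detp)$betas, sim$annotation)
pairs <- pair_samples(sim$sheet[sim$sheet$cohort == "discovery", ],
                      qc$betas)
delta <- compute_delta_beta(qc$betas, pairs)
tau   <- estimate_threshold(delta)
cs    <- call_detectable(delta, tau, betas = qc$betas)
print(cs)
#> hmc_callset: 18983 probes, 16 pairs, tau = 0.06950949
#> detectable per tissue:
#>        cerebellum prefrontal_cortex
#>              4700              4714
```

tau lands at 0.0695, in line with the analytic null for beta noise of
0.025 (`qnorm(0.975) * sqrt(2) * 0.025 = 0.0693`); about a quarter of
probes carry detectable 5hmC, matching the generator's injected 20 %
baseline plus the gene-body odds multiplier of 2.

```r
det_cbl <- rownames(cs$detectable)[cs$detectable[, "cerebellum"]]
enrich(det_cbl, rownames(cs$detectable), sim$annotation, "gene")
#>             feature    a    n    A     N odds_ratio ci_low ci_high  p_value
#> 1        intergenic  531 4700 2659 18983      0.782  0.708   0.863 7.70e-07
#> 3 proximal_promoter 1504 4700 7339 18983      0.747  0.698   0.799 1.70e-17
#> 4         gene_body 2315 4700 7282 18983      1.560  1.463   1.663 1.18e-41
#> ...
```

The injected gene-body enrichment is recovered (inclusive-background
OR 1.56; the exclusive mode estimates the injected odds ratio of 2),
with depletion elsewhere — the same shape the published tables show for
real brain data.

```r
ts <- rank_sites(cs, "tissue_difference", n = 1000)
mean(ts$direction == "cerebellum")
#> [1] 0.96
```

96 % of the top tissue-specific positions are higher in cerebellum,
mirroring the generator's 0.965 direction probability.

The same chain runs as a pipeline with persisted artifacts:

```r
run_pipeline("all",
             config = list(simulate = list(n_probes = 20000)),
             run_dir = "hmc_run/demo")
```

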