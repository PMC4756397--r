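---
title: "Quantifying 5-hydroxymethylcytosine from paired BS/oxBS arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 5-hydroxymethylcytosine from paired BS/oxBS arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcquant)
```

## The measurement model

Bisulfite (BS) conversion leaves both 5-methylcytosine (5mC) and
5-hydroxymethylcytosine (5hmC) unconverted, so a BS beta value reads
their sum. Oxidative bisulfite (oxBS) first oxidises 5hmC to
5-formylcytosine, which converts like unmodified cytosine, so an oxBS
beta reads 5mC alone. Running both chemistries on aliquots of the same
DNA and hybridising both to 450K-style arrays gives, per probe \(p\) and
sample \(i\),

\[
\beta^{BS}_{pi} \approx m_{pi} + h_{pi}, \qquad
\beta^{oxBS}_{pi} \approx m_{pi}, \qquad
\Delta\beta_{pi} = \beta^{BS}_{pi} - \beta^{oxBS}_{pi} \approx h_{pi},
\]

with \(m\) the 5mC and \(h\) the 5hmC fraction. `compute_delta_beta()`
is exactly this subtraction; missing values in either arm propagate.

Because the two arms carry independent technical error,
\(\Delta\beta\) at a probe with no 5hmC is centred at zero with
standard deviation \(\sqrt{2}\,\sigma\) (\(\sigma\) the per-array beta
noise). The strictly negative \(\Delta\beta\) values are therefore an
empirical null sample: `estimate_threshold()` pools them across all
probes and samples and takes the absolute 5 % quantile as the detection
threshold \(\tau\). A probe is called "detectable" in a tissue when its
tissue-mean \(\Delta\beta\) strictly exceeds \(\tau\)
(`call_detectable()`). Under Gaussian noise the analytic counterpart is
\(\tau \approx z_{0.975}\sqrt{2}\sigma\); the acceptance suite verifies
the estimator recovers it within 10 % on a 50,000-probe null
simulation.

Two threshold conventions circulate for this design: a quantile of the
negative tail only (the default, `mode = "negative_tail"`) and a
quantile of all pooled values (`mode = "all_values"`). Both are
implemented and are deliberately not reconciled; the negative-tail
reading is the default because it is the one consistent with an
empirical-null interpretation. Quantiles use linear interpolation at
position \(q(n-1)\) (R type 7); no convention is canonical in the
literature, so one had to be fixed for reproducibility.

## Ranking, enrichment and comparison

`rank_sites()` orders the detectable probes by tissue-mean
\(\Delta\beta\) (level), by the standard deviation of \(\Delta\beta\)
across donors within a tissue (variability; the statistic is a plain SD
because nothing in the design motivates shrinkage at n = 8–18 donors),
or by the absolute difference of the two tissue means
(tissue-specific hydroxymethylated positions, TS-HMPs). Ties break by
probe id so output is deterministic.

`enrich()` tests feature enrichment with Fisher's exact test on the
**inclusive-background** 2x2 table \([a, n-a; A, N-A]\): the foreground
is counted inside the background. This is the convention that
reproduces the published tables this package mirrors, and it is the
default. It is, however, an attenuated measure of association when the
foreground is a sizeable share of the background, so parameter-recovery
work should use `background_mode = "exclusive"`, which forms the
standard \([a, n-a; A-a, (N-n)-(A-a)]\) table. Confidence intervals are
Woolf logit intervals; with a zero cell the table is flagged
`degenerate`, the OR reported as 0 or Inf, and a one-sided interval
derived from the 0.5-corrected table. Two-sided Fisher p-values sum all
hypergeometric outcomes no more probable than the observed one
(relative tolerance 1e-7, the convention shared by standard
implementations); p-values are reported unadjusted, as in the tables
the package mirrors.

`decompose_bs_differences()` exploits the identity
\(\Delta\beta^{BS}_{tissue} = \Delta\beta^{oxBS}_{tissue} +
\Delta(\Delta\beta)_{tissue}\): a cross-tissue difference seen by a
BS-only assay splits exactly into a 5mC and a 5hmC component, and the
larger absolute component labels the driver. The identity is exact by
construction and asserted to 1e-9.

For discovery/validation comparison, `validate_concordance()` reports
Pearson r, the median absolute difference in percentage points
(\(\Delta\beta \times 100\), matching the scale on which such
differences are usually quoted), and — for TS-HMP lists — the number of
probes whose cross-tissue difference replicates by an unpaired
two-sided t-test at alpha 0.05. The source analysis named no test; the
t-test on per-donor \(\Delta\beta\) is the least-structured choice
consistent with the design.

## Pathway testing with probe-count control

Genes tile the array unevenly (~17 probes per gene on average, with a
long tail), and any probe-level selection therefore over-samples
heavily-probed genes. `test_pathway()` regresses per-gene pathway
membership on test-list membership plus the probes-per-gene count
(logistic regression; Wald p on the list coefficient; enrichment
requires a positive coefficient). The covariate enters as the raw count
by default (`covariate = "log"` is available); the confounding injected
by the synthetic generator is linear on the logit scale in the raw
count, so the raw-count adjustment is exactly correct there, and the
acceptance suite shows the adjusted test is calibrated (rejection rate
within the binomial 99 % band of 0.05 over 1,000 confounded null
pathways) while the unadjusted test is wildly anticonservative.

Perfect separation (e.g. a pathway identical to the test list) is
detected from non-convergence or runaway estimates and refitted with a
Firth-penalised likelihood (Jeffreys prior, implemented in-package);
such rows are flagged `separated`.

`group_redundant()` implements the iterative conditioning algorithm:
take the most significant ungrouped pathway as leader, refit every
remaining significant pathway with the leader's membership as an extra
covariate, and mark pathways whose list term drops below significance
as `explained_by` the leader; repeat until every significant pathway is
a leader or explained. The result is a partition; ties in p break by
pathway id. The significance gate is the Wald p at 0.05 (a
likelihood-ratio gate would change little at these sizes but is not what
the grouping algorithm's description implies).

`build_universe()` accepts GMT gene sets plus an optional child→parent
edge list; memberships propagate transitively to ancestors (cycles are
an error), genes without probes or pathways are dropped, and pathways
outside 10–2,000 member genes (inclusive) are discarded.

## Metagene profiles

`map_probe_to_axis()` maps each probe onto a normalised gene axis:
5 kb upstream flank → [-10, 0), gene body TSS→TES → [0, 100],
5 kb downstream flank → (100, 110], strand-aware so the TSS is always
at 0. The flank-to-body scaling (10/100/10) is a declared convention:
the body is measured in per-cent-of-gene-length units so that "1 %
windows" are 1 axis unit, and 5 kb flanks get 10 units each.
`metagene_profile()` averages any per-probe signal over windows
\([x, x+w)\) with width 1 and step 0.5 by default (the final window is
right-closed so the endpoint is covered). Probes assigned to several
genes contribute once per assignment; empty windows are reported with
n = 0 and NA, never interpolated. Strand-mirroring all genes and
reflecting probe positions reproduces the profile exactly, which the
tests assert.

## The synthetic world

The generator emulates the study design the pipeline was built for:
two brain tissues (prefrontal cortex, cerebellum) from 8 discovery and
18 validation donors, three treatment arms per sample. Defaults, chosen
once:

| parameter | default | rationale |
|---|---|---|
| `n_probes` | 50,000 | desk-scale stand-in for a 450K analysis set |
| feature marginals | islands 32.3 %, shores 23.3 %, shelves 8.8 %, gene body 37.7 %, TFBS 49.2 %, DHS 13.3 %, alt-annotated 37.1 %, unannotated 2.4 % | background composition of a QC-passing array |
| `f` | 0.2 | baseline hydroxymethylation rate (see below) |
| `hmc_range` | U(0.10, 0.35) | detectable-but-modest true 5hmC, matching the scale of reported brain levels |
| `tissue_effect` | 0.05 | mean cerebellum increment; per-probe magnitude U(0, 0.1), directed to cerebellum with probability 0.965 |
| `noise_sd` | 0.025 | per-array beta noise giving a negative Δβ tail at ~0.069, the same order as the published threshold |
| `true_mc` | 0.5·Beta(10,40) + 0.5·Beta(40,10) | the standard bimodal beta-value landscape, kept clear of the clip boundaries |

Noise is Gaussian with clipping to [0, 1] rather than beta-distributed:
the null \(\Delta\beta \sim N(0, 2\sigma^2)\) is then analytic, which
is what makes the threshold criterion checkable. `f` is the baseline
rate at reference features; with `feature_rr` multipliers above 1 the
marginal hydroxymethylated fraction exceeds `f` (0.26 at the defaults)
— the generator satisfies the feature-odds contract exactly and the
marginal only approximately, not the other way round. The constraint
5mC + 5hmC ≤ 1 is enforced by truncating 5hmC, which slightly thins
true levels at heavily methylated probes; tests that need exact
injected amplitudes fix `true_mc` away from 1. rs genotyping probes get
donor-specific trimodal betas (0.05/0.5/0.95 ± 0.02) shared across a
donor's samples, which is what the genotype-concordance check consumes.

What the generator does **not** emulate: Infinium I/II probe chemistry
and dye bias, batch structure, cell-composition heterogeneity, spatial
correlation along the genome, and beta-value heteroscedasticity near
the boundaries. A green synthetic suite therefore establishes that the
estimators implement their definitions and recover known truth under
idealised noise — not that the defaults reproduce any particular
tissue's biology.

For pathway calibration the stated world is: 2,000 genes with
probes-per-gene ~ NegBin(mu 17, size 2), 1,000 pathways with sizes
log-uniform on [10, 500], confounding strength 1 (logit scale) applied
identically to membership and test list, list fraction 0.3. Sizes were
fixed from a calibration pre-study before the acceptance test was
written; very small pathways (< 10 positives) make the Wald test
erratic, and 450K-style gene universes at desk scale support ~500-gene
sets at most.

## Numerical choices and degenerate inputs

* Quantile type 7 everywhere; strict `>` at the threshold (a mean
  exactly at \(\tau\) is not detectable).
* Pairwise-complete deletion for all means and correlations; a probe
  missing in one arm is missing in \(\Delta\beta\).
* Fisher p by enumeration with relative tolerance 1e-7 on the density
  comparison; verified against exhaustive enumeration for every table
  with N ≤ 60 to 1e-10.
* Deterministic order everywhere: ranking ties by probe id, pathway
  ties by pathway id, BED sorted by (chrom, start).
* `pfilter` removes samples first, then probes, both at 5 % of sites
  with detection p < 0.05; all four numbers configurable.
* Sub-seeds in `simulate_hmc_experiment()` are derived as
  `(seed mod 1e6) * 1000 + k`, keeping every seed below 2^31.

## Known limitations

* The inclusive-background OR is descriptive, not an association
  estimate; use the exclusive mode for inference about effect sizes.
* Woolf CIs are poor at cell counts below ~5; degenerate tables are
  flagged rather than silently corrected.
* The Wald gate in pathway grouping can differ from a likelihood-ratio
  gate for near-separated refits; such refits fall back to Firth fits.
* No normalisation is performed or checked: the package consumes
  normalised betas by contract.
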