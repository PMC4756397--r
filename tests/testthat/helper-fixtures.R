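# Shared fixture builders.  Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# probes x samples matrix with dimnames
mk_beta <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(probes)) probes <- sprintf("cg%03d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(probes, samples)
  m
}

# sample sheet for n donors x 2 tissues x given arms
mk_sheet <- function(n_donors = 2L, arms = c("bs_cegx", "oxbs_cegx"),
                     cohort = "discovery") {
  rows <- expand.grid(donor_id = sprintf("d%02d", seq_len(n_donors)),
                      tissue = TISSUES, treatment = arms,
                      stringsAsFactors = FALSE)
  rows$cohort <- cohort
  rows$sample_id <- paste(rows$donor_id, substr(rows$tissue, 1, 3),
                          rows$treatment, sep = "_")
  rows[, c("sample_id", "donor_id", "tissue", "treatment", "cohort")]
}

# betas for a sheet from per-(probe,tissue) truth, Gaussian noise, clipping
mk_betas_from_truth <- function(sheet, mc, hmc_pfc, hmc_cbl,
                                noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  n <- length(mc)
  probes <- sprintf("cg%03d", seq_len(n))
  m <- sapply(seq_len(nrow(sheet)), function(j) {
    h <- if (sheet$tissue[j] == "prefrontal_cortex") hmc_pfc else hmc_cbl
    mu <- if (sheet$treatment[j] == "oxbs_cegx") mc else mc + h
    pmin(1, pmax(0, mu + rnorm(n, 0, noise_sd)))
  })
  mk_beta(m, probes, sheet$sample_id)
}

# a small complete callset used by several suites (memoised per session)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_hmc_experiment(
      n_probes = 4000L, n_donors = c(discovery = 8L, validation = 6L),
      seed = 20160216L)
  }
  .sim_cache$sim
}

cached_callset <- function() {
  if (is.null(.sim_cache$cs)) {
    sim <- cached_sim()
    mk <- mask_probes(pfilter(sim$betas, sim$detp)$betas, sim$annotation)
    pairs <- pair_samples(sim$sheet[sim$sheet$cohort == "discovery", ],
                          mk$betas)
    delta <- compute_delta_beta(mk$betas, pairs)
    tau <- estimate_threshold(delta)
    .sim_cache$betas_qc <- mk$betas
    .sim_cache$cs <- call_detectable(delta, tau, betas = mk$betas)
  }
  .sim_cache$cs
}

cached_betas_qc <- function() { cached_callset(); .sim_cache$betas_qc }

# minimal probe annotation data.frame
mk_ann <- function(probe_id,
                   chrom = "chr1",
                   pos = seq_along(probe_id) * 100L,
                   cgi_feature = "outside", gene_feature = "gene_body",
                   tfbs = FALSE, dhs = FALSE, alt_events = "",
                   genes = "", is_snp_probe = FALSE, masked = FALSE) {
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
             cgi_feature = cgi_feature, gene_feature = gene_feature,
             tfbs = tfbs, dhs = dhs, alt_events = alt_events,
             genes = genes, is_snp_probe = is_snp_probe, masked = masked,
             stringsAsFactors = FALSE)
}

# independent two-sided Fisher p by explicit hypergeometric enumeration
# (kept deliberately separate from the package implementation)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(k, m)
  dens <- choose(m, xs) * choose(n2, k - xs) / choose(m + n2, k)
  obs <- dens[xs == a]
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}
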