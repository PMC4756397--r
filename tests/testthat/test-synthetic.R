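test_that("generators are deterministic in the seed", {
  a1 <- generate_annotation(n_probes = 500L, seed = 5L)
  a2 <- generate_annotation(n_probes = 500L, seed = 5L)
  a3 <- generate_annotation(n_probes = 500L, seed = 6L)
  expect_identical(a1, a2)
  expect_false(identical(a1$annotation, a3$annotation))

  t1 <- generate_truth(a1$annotation, seed = 5L)
  expect_identical(t1, generate_truth(a1$annotation, seed = 5L))
  b1 <- generate_betas(t1, n_donors = c(discovery = 2L), seed = 5L)
  b2 <- generate_betas(t1, n_donors = c(discovery = 2L), seed = 5L)
  expect_identical(b1$betas, b2$betas)
})

test_that("degenerate feature probabilities are honoured", {
  fp <- DEFAULT_FEATURE_PROBS
  fp$cgi <- c(island = 1, shore = 0, shelf = 0, outside = 0)
  fp$unannotated <- 0
  a <- generate_annotation(n_probes = 300L, feature_probs = fp, n_rs = 0L,
                           seed = 9L)
  expect_true(all(a$annotation$cgi_feature == "island"))
  fp$cgi <- c(island = -1, shore = 2, shelf = 0, outside = 0)
  expect_error(generate_annotation(300L, feature_probs = fp),
               "probability")
})

test_that("default feature marginals land near their targets", {
  a <- generate_annotation(n_probes = 20000L, n_rs = 0L, seed = 13L)
  ann <- a$annotation
  p0 <- 0.323 * (1 - 0.0239)   # island prob after the unannotated gate
  expect_lt(abs(mean(ann$cgi_feature == "island") - p0),
            3 * sqrt(p0 * (1 - p0) / 20000))
  # alt-annotated probes always carry at least one event
  alt <- ann$alt_events[ann$alt_events != ""]
  expect_true(all(lengths(strsplit(alt, ",")) >= 1))
})

test_that("truth generation respects constraints and switches", {
  a <- generate_annotation(n_probes = 2000L, seed = 17L)
  # f = 0: no 5hmC anywhere
  t0 <- generate_truth(a$annotation, f = 0, seed = 17L)
  expect_true(all(t0$true_hmc_prefrontal_cortex == 0))
  expect_true(all(t0$true_hmc_cerebellum == 0))
  # tissue_effect = 0: identical across tissues
  t1 <- generate_truth(a$annotation, tissue_effect = 0, seed = 17L)
  expect_equal(t1$true_hmc_prefrontal_cortex, t1$true_hmc_cerebellum)
  # feasibility: mc + hmc never exceeds 1
  t2 <- generate_truth(a$annotation, seed = 18L)
  expect_true(all(t2$true_mc + t2$true_hmc_prefrontal_cortex <= 1 + 1e-12))
  expect_true(all(t2$true_mc + t2$true_hmc_cerebellum <= 1 + 1e-12))
  # rs probes never carry 5hmC
  expect_true(all(!t2$is_hmc[grepl("^rs", t2$probe_id)]))
})

test_that("injected feature odds are recovered from the truth table", {
  a <- generate_annotation(n_probes = 20000L, seed = 19L)
  tr <- generate_truth(a$annotation, feature_rr = c(gene_body = 2),
                       seed = 19L)
  gb <- a$annotation$gene_feature == "gene_body"
  tab <- table(gb, tr$is_hmc)
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[1, 2] * tab[2, 1]))
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(lor - log(2)), 2 * se)
})

test_that("the noiseless limit returns the truth exactly", {
  a <- generate_annotation(n_probes = 300L, n_rs = 0L, seed = 23L)
  tr <- generate_truth(a$annotation, seed = 23L)
  b <- generate_betas(tr, n_donors = c(discovery = 2L), noise_sd = 1e-9,
                      include_zymo = FALSE, seed = 23L)
  pairs <- pair_samples(b$sheet, b$betas)
  d <- compute_delta_beta(b$betas, pairs)
  away <- tr$true_mc + tr$true_hmc_cerebellum < 0.999 & tr$true_mc > 0.001
  cbl <- pairs$pair_id[pairs$tissue == "cerebellum"]
  expect_equal(unname(d[away, cbl[1]]),
               tr$true_hmc_cerebellum[away], tolerance = 1e-6)
})

test_that("a null simulation yields a symmetric delta-beta distribution", {
  a <- generate_annotation(n_probes = 4000L, n_rs = 0L, seed = 29L)
  tr <- generate_truth(a$annotation, f = 0, seed = 29L)
  b <- generate_betas(tr, n_donors = c(discovery = 8L), noise_sd = 0.025,
                      include_zymo = FALSE, seed = 29L)
  d <- compute_delta_beta(b$betas, pair_samples(b$sheet, b$betas))
  expect_lt(abs(mean(d)), 0.002)
  expect_lt(abs(skewness <- mean((d - mean(d))^3) / sd(d)^3), 0.2)
  # |5th percentile of negatives| matches the analytic N(0, sqrt(2) sd)
  # tail value within Monte-Carlo error
  tau <- estimate_threshold(d)
  expect_lt(abs(tau - qnorm(0.975) * sqrt(2) * 0.025) /
              (qnorm(0.975) * sqrt(2) * 0.025), 0.05)
})

test_that("generate_pathways honours sizes, signals and confounding", {
  genes <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                      n_probes = rpois(1000, 10) + 1L)
  # a single pathway of exactly the minimum size
  pw1 <- generate_pathways(genes, n_pathways = 1L, size_range = c(10L, 10L),
                           seed = 31L)
  expect_length(pw1$pathways, 1L)
  expect_gte(length(pw1$pathways[[1]]), 10L)
  expect_error(generate_pathways(genes, size_range = c(10L, 5000L)),
               "infeasible")

  # a strong signal pathway is detected by the adjusted test
  pw <- generate_pathways(genes, n_pathways = 20L, size_range = c(50L, 300L),
                          n_signal = 1L, signal_odds = 6, seed = 37L)
  uni <- structure(list(
    genes = transform(genes, in_test_list = gene_id %in% pw$test_genes),
    pathways = pw$pathways), class = "gene_universe")
  res <- test_pathway(uni, pw$signal_pathways)
  expect_true(res$significant)
})

test_that("simulate_hmc_experiment wires the pieces together", {
  sim <- cached_sim()
  expect_setequal(names(sim), c("annotation", "genes", "truth", "betas",
                                "detp", "sheet", "genotypes"))
  expect_equal(nrow(sim$betas), nrow(sim$annotation))
  expect_identical(colnames(sim$betas), sim$sheet$sample_id)
  validate_beta_matrix(sim$betas)
  validate_sample_sheet(sim$sheet)
  # three arms per (donor, tissue)
  expect_equal(nrow(sim$sheet),
               (8 + 6) * 2 * 3)
})
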