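test_that("delta-beta is BS minus oxBS, missing-propagating, antisymmetric", {
  sheet <- mk_sheet(n_donors = 2L)
  betas <- mk_beta(matrix(0.5, 3, nrow(sheet)), samples = sheet$sample_id)
  bs <- sheet$treatment == "bs_cegx"
  betas[, bs] <- c(0.80, 0.50, 0.30)
  betas[, !bs] <- c(0.65, 0.50, 0.40)
  betas[1, which(!bs)[1]] <- NA
  pairs <- pair_samples(sheet, betas)
  d <- compute_delta_beta(betas, pairs)
  expect_equal(dim(d), c(3L, 4L))
  expect_equal(unname(d[2, ]), rep(0, 4))           # BS == oxBS
  expect_equal(unname(d[3, ]), rep(-0.10, 4))       # negatives retained
  # missing propagates (the NA sits in d01's prefrontal-cortex pair)
  na_pair <- pairs$pair_id[pairs$donor_id == "d01" &
                             pairs$tissue == "prefrontal_cortex"]
  expect_true(is.na(d[1, na_pair]))
  expect_equal(unname(d[1, setdiff(colnames(d), na_pair)]), rep(0.15, 3))

  # swapping the arms negates delta exactly
  swapped <- pairs
  tmp <- swapped$bs_sample
  swapped$bs_sample <- swapped$oxbs_sample; swapped$oxbs_sample <- tmp
  d2 <- compute_delta_beta(betas, swapped)
  expect_equal(as.vector(d2), as.vector(-d))
})

test_that("estimate_threshold implements the interpolated tail quantile", {
  # constant negatives
  d <- mk_beta(matrix(c(-0.1, -0.1, 0.3, 0.5), 2, 2))
  expect_equal(estimate_threshold(d), 0.1)

  # frozen from the linear-interpolation definition: position
  # q*(n-1) = 0.2 between -0.20 and -0.15 -> -0.19
  d2 <- mk_beta(matrix(c(-0.20, -0.15, -0.10, -0.05, -0.01, 0.4), 3, 2))
  expect_equal(estimate_threshold(d2, q = 0.05), 0.19)
  # independent quantile oracle on the pooled negative multiset
  negs <- sort(c(-0.20, -0.15, -0.10, -0.05, -0.01))
  pos <- 0.05 * (length(negs) - 1)
  oracle <- abs(negs[floor(pos) + 1] * (1 - pos %% 1) +
                negs[floor(pos) + 2] * (pos %% 1))
  expect_equal(estimate_threshold(d2, q = 0.05), oracle)

  # all_values mode pools everything
  expect_equal(estimate_threshold(d2, mode = "all_values", q = 0.5),
               abs(quantile(c(-0.20, -0.15, -0.10, -0.05, -0.01, 0.4),
                            0.5, names = FALSE)))

  # no negatives in negative_tail mode is an error with advice
  d3 <- mk_beta(matrix(c(0.1, 0.2), 1, 2))
  expect_error(estimate_threshold(d3), "all_values")
})

test_that("tau never decreases when more-extreme negatives are added", {
  set.seed(21)
  for (i in 1:20) {
    vals <- c(-runif(50), runif(50))
    d <- mk_beta(matrix(vals, 20, 5))
    tau <- estimate_threshold(d)
    extra <- matrix(-runif(20, min(vals) * 1.5, -abs(min(vals))), 4, 5)
    d2 <- mk_beta(rbind(d, extra), probes = sprintf("p%03d", 1:24))
    expect_gte(estimate_threshold(d2), tau)
  }
})

test_that("call_detectable uses strict inequality on tissue means", {
  sheet <- mk_sheet(n_donors = 2L)
  betas <- mk_beta(matrix(0.4, 2, nrow(sheet)), samples = sheet$sample_id)
  bs <- sheet$treatment == "bs_cegx"
  pfc <- sheet$tissue == "prefrontal_cortex"
  # probe 1: pfc delta rows (0.12, 0.14); probe 2: (0.02, 0.04); cbl zero
  betas[, bs & pfc] <- 0.4 + cbind(c(0.12, 0.02), c(0.14, 0.04))
  pairs <- pair_samples(sheet, betas)
  d <- compute_delta_beta(betas, pairs)
  cs <- call_detectable(d, tau = 0.0916)
  expect_true(cs$detectable["cg001", "prefrontal_cortex"])
  expect_false(cs$detectable["cg002", "prefrontal_cortex"])
  expect_false(any(cs$detectable[, "cerebellum"]))
  expect_equal(cs$tissue_mean_delta["cg001", "prefrontal_cortex"], 0.13)

  # boundary: mean exactly tau is NOT detectable
  cs2 <- call_detectable(d, tau = 0.13)
  expect_false(cs2$detectable["cg001", "prefrontal_cortex"])
})

test_that("summarize_sets obeys inclusion-exclusion on random callsets", {
  cs <- cached_callset()
  s <- summarize_sets(cs)
  expect_equal(s$n_union,
               s$n_prefrontal_cortex + s$n_cerebellum - s$n_both)
  expect_equal(s$n_prefrontal_cortex_only,
               s$n_prefrontal_cortex - s$n_both)

  # disjoint and identical corner cases through inclusion_exclusion()
  expect_equal(inclusion_exclusion(10, 20, n_both = 0)$n_union, 30)
  ie <- inclusion_exclusion(5, 5, n_both = 5)
  expect_equal(ie$n_union, 5)
  expect_equal(ie$n_a_only, 0)
  expect_error(inclusion_exclusion(5, 5, n_both = 6), "infeasible")
  expect_error(inclusion_exclusion(5, 5, n_both = 2, n_union = 9),
               "inconsistent")
})

test_that("rank_sites orders by the documented statistics with stable ties", {
  sheet <- mk_sheet(n_donors = 4L)
  n <- 6L
  diffs <- c(0.40, 0.35, 0.30, 0.10, 0.05, 0)
  betas <- mk_beta(matrix(0.2, n, nrow(sheet)), samples = sheet$sample_id)
  bs <- sheet$treatment == "bs_cegx"
  pfc <- sheet$tissue == "prefrontal_cortex"
  betas[, bs & pfc] <- 0.2 + 0.12            # constant pfc 5hmC
  betas[, bs & !pfc] <- 0.2 + 0.12 + diffs   # cbl higher by `diffs`
  pairs <- pair_samples(sheet, betas)
  cs <- call_detectable(compute_delta_beta(betas, pairs), tau = 0.09)

  # tissue_difference: top-3 equals the sorted top-3, min included >=
  # max excluded (sorting oracle)
  ts <- rank_sites(cs, "tissue_difference", n = 3)
  expect_equal(ts$probe_id, c("cg001", "cg002", "cg003"))
  expect_gte(min(ts$statistic), max(diffs[4:6]))
  expect_true(all(ts$direction == "cerebellum"))
  expect_equal(abs(ts$signed_difference), c(0.40, 0.35, 0.30))

  # constant delta across donors: variability 0, order by probe id
  v <- rank_sites(cs, "variability", tissue = "prefrontal_cortex", n = 6)
  expect_equal(v$statistic, rep(0, nrow(v)))
  expect_equal(v$probe_id, sort(v$probe_id))

  # n beyond the pool returns the pool with a warning
  expect_warning(rank_sites(cs, "level", tissue = "cerebellum", n = 1e4),
                 "exceeds pool")
})

test_that("null data yields detectable fractions within the tail mass", {
  # zero true 5hmC, symmetric noise: detectable fraction should not
  # exceed the q-implied noise-tail mass by more than binomial error
  set.seed(314)
  n <- 3000L; n_donors <- 8L
  sheet <- mk_sheet(n_donors = n_donors)
  betas <- mk_betas_from_truth(sheet, mc = rep(0.5, n),
                               hmc_pfc = rep(0, n), hmc_cbl = rep(0, n),
                               noise_sd = 0.025, seed = 314)
  pairs <- pair_samples(sheet, betas)
  d <- compute_delta_beta(betas, pairs)
  tau <- estimate_threshold(d)
  cs <- call_detectable(d, tau)
  # tissue mean of n_donors pairs ~ N(0, sqrt(2)*sd/sqrt(8)); tail mass
  # above tau (which sits at ~2.77 sds of the mean distribution)
  p_tail <- pnorm(tau, 0, sqrt(2) * 0.025 / sqrt(n_donors),
                  lower.tail = FALSE)
  frac <- mean(cs$detectable)
  expect_lte(frac, p_tail + 3 * sqrt(p_tail * (1 - p_tail) / n))
})
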