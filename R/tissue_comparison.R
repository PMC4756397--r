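## Cross-tissue correlation, discovery/validation concordance, and the
## decomposition of BS tissue differences into 5mC and 5hmC components.

#' Correlation of 5hmC levels between tissues at detectable sites
#'
#' Simple linear fit of the other tissue's mean delta-beta on the anchor
#' tissue's, over the anchor's detectable probes.  Reports Pearson r,
#' R-squared, adjusted R-squared `1 - (1 - R2)(n - 1)/(n - 2)` and the
#' t-transform p-value.
#'
#' @param callset An `hmc_callset` with two tissues.
#' @param anchor_tissue Tissue whose detectable set defines the loci.
#' @return List of class `concordance_result`: r, r_squared,
#'   adjusted_r_squared, p_value, n, slope, intercept.
#' @export
cross_tissue_correlation <- function(callset, anchor_tissue) {
  stopifnot(inherits(callset, "hmc_callset"))
  tm <- callset$tissue_mean_delta
  if (!anchor_tissue %in% colnames(tm))
    stop("unknown tissue: ", anchor_tissue)
  other <- setdiff(colnames(tm), anchor_tissue)[1L]
  keep <- callset$detectable[, anchor_tissue]
  x <- tm[keep, anchor_tissue]; y <- tm[keep, other]
  ct <- .cor_test(x, y)
  r2 <- ct$r^2
  fit <- stats::coef(stats::lm(y ~ x))
  structure(list(r = ct$r, r_squared = r2,
                 adjusted_r_squared = 1 - (1 - r2) * (ct$n - 1) / (ct$n - 2),
                 p_value = ct$p, n = ct$n,
                 slope = unname(fit[2L]), intercept = unname(fit[1L]),
                 anchor_tissue = anchor_tissue, other_tissue = other),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance over %d loci: r = %.3f, R2 = %.3f (adj %.3f), p = %.3g\n",
              x$n, x$r, x$r_squared, x$adjusted_r_squared, x$p_value))
  if (!is.null(x$median_abs_difference_pct))
    cat(sprintf("median |difference| = %.2f percentage points\n",
                x$median_abs_difference_pct))
  invisible(x)
}

#' Concordance of a discovery ranked list in a validation cohort
#'
#' Correlates discovery and validation tissue-mean delta-beta at the
#' listed probes, reports the median absolute difference in percentage
#' points (delta-beta x 100), and - when the list carries signed tissue
#' differences (a TS-HMP list) - counts listed probes whose cross-tissue
#' difference is significant in validation by an unpaired two-sided
#' t-test on per-donor delta-beta at `alpha`.
#'
#' @param ranked data.frame from [rank_sites()] (needs `probe_id`; for
#'   the TS-HMP replication count, ranked by `"tissue_difference"`).
#' @param discovery_callset,validation_callset `hmc_callset`s sharing
#'   probe ids.
#' @param tissue Tissue whose mean levels are compared; for TS-HMP lists
#'   use `tissue = NULL` to compare signed tissue differences instead.
#' @param alpha Significance level for the per-probe validation t-test.
#' @return `concordance_result` with additionally
#'   `median_abs_difference_pct`, and for TS-HMP lists `n_replicated`
#'   (significant in validation) of `n`.
#' @export
validate_concordance <- function(ranked, discovery_callset,
                                 validation_callset, tissue = NULL,
                                 alpha = 0.05) {
  stopifnot(inherits(discovery_callset, "hmc_callset"),
            inherits(validation_callset, "hmc_callset"))
  probes <- intersect(ranked$probe_id,
                      rownames(validation_callset$tissue_mean_delta))
  if (length(probes) < 3L) stop("fewer than 3 shared probes")
  dtm <- discovery_callset$tissue_mean_delta
  vtm <- validation_callset$tissue_mean_delta
  if (is.null(tissue)) {
    tis <- colnames(dtm)[1:2]
    x <- dtm[probes, tis[1L]] - dtm[probes, tis[2L]]
    y <- vtm[probes, tis[1L]] - vtm[probes, tis[2L]]
  } else {
    x <- dtm[probes, tissue]
    y <- vtm[probes, tissue]
  }
  ct <- .cor_test(x, y)
  res <- structure(
    list(r = ct$r, r_squared = ct$r^2,
         adjusted_r_squared = 1 - (1 - ct$r^2) * (ct$n - 1) / (ct$n - 2),
         p_value = ct$p, n = ct$n,
         median_abs_difference_pct = stats::median(abs(x - y),
                                                   na.rm = TRUE) * 100),
    class = "concordance_result")
  if (is.null(tissue)) {
    pairs <- validation_callset$pairs
    tis <- unique(pairs$tissue)[1:2]
    cols_a <- pairs$pair_id[pairs$tissue == tis[1L]]
    cols_b <- pairs$pair_id[pairs$tissue == tis[2L]]
    d <- validation_callset$delta_beta
    pvals <- vapply(probes, function(p) {
      xa <- d[p, cols_a]; xb <- d[p, cols_b]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      if (length(xa) < 2L || length(xb) < 2L) return(NA_real_)
      stats::t.test(xa, xb)$p.value
    }, numeric(1L))
    res$n_replicated <- sum(pvals < alpha, na.rm = TRUE)
    res$replication_p <- pvals
  }
  res
}

#' Decompose top BS tissue differences into 5mC and 5hmC components
#'
#' Because the BS beta reads 5mC + 5hmC, a cross-tissue difference in BS
#' signal splits exactly into an oxBS (5mC) component and a delta-beta
#' (5hmC) component: `bs_diff = mc_diff + hmc_diff`.  Probes are ranked
#' by |bs_diff| descending, the top `n` taken, and each classified by the
#' larger absolute component.
#'
#' @param betas Beta matrix holding the BS and oxBS arms of `pairs`.
#' @param pairs `hmc_pairs` covering two tissues.
#' @param n Number of top BS differences to decompose (default 1000).
#' @return data.frame `probe_id`, `bs_diff`, `mc_diff`, `hmc_diff`,
#'   `driver` ("mc" or "hmc"), ordered by |bs_diff|; attributes
#'   `n_hmc_driven` and `bs_vs_mc_r` (Pearson correlation of bs_diff with
#'   mc_diff over the top set).
#' @export
decompose_bs_differences <- function(betas, pairs, n = 1000L) {
  stopifnot(inherits(pairs, "hmc_pairs"))
  tissues <- unique(pairs$tissue)
  if (length(tissues) < 2L) stop("need two tissues")
  mean_arm <- function(cols) rowMeans(betas[, cols, drop = FALSE],
                                      na.rm = TRUE)
  bs_a <- mean_arm(pairs$bs_sample[pairs$tissue == tissues[1L]])
  bs_b <- mean_arm(pairs$bs_sample[pairs$tissue == tissues[2L]])
  ox_a <- mean_arm(pairs$oxbs_sample[pairs$tissue == tissues[1L]])
  ox_b <- mean_arm(pairs$oxbs_sample[pairs$tissue == tissues[2L]])
  bs_diff <- bs_a - bs_b
  mc_diff <- ox_a - ox_b
  hmc_diff <- bs_diff - mc_diff
  ord <- order(-abs(bs_diff), rownames(betas))
  top <- ord[seq_len(min(n, sum(!is.na(bs_diff))))]
  out <- data.frame(probe_id = rownames(betas)[top],
                    bs_diff = bs_diff[top], mc_diff = mc_diff[top],
                    hmc_diff = hmc_diff[top],
                    driver = ifelse(abs(hmc_diff[top]) > abs(mc_diff[top]),
                                    "hmc", "mc"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_hmc_driven") <- sum(out$driver == "hmc")
  attr(out, "bs_vs_mc_r") <- stats::cor(out$bs_diff, out$mc_diff,
                                        use = "complete.obs")
  out
}
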