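## Delta-beta computation, empirical detection threshold, detectable calls
## and site ranking.  This is the analytic core: BS beta minus oxBS beta
## estimates 5hmC per probe; technical noise produces negative values at
## 5hmC-free probes, and the negative tail supplies an empirical null from
## which the detection threshold tau is taken.

#' Compute the BS-minus-oxBS delta-beta matrix
#'
#' `delta[p, i] = beta_BS[p, i] - beta_oxBS[p, i]` for every probe p and
#' pair i; missing if either arm is missing.  Negative values are
#' retained: they carry the technical-noise null used by
#' [estimate_threshold()].
#'
#' @param betas Beta matrix containing both arms of every pair.
#' @param pairs `hmc_pairs` from [pair_samples()].
#' @return Numeric matrix probes x pairs (columns named by `pair_id`),
#'   values in \[-1, 1\], with `pairs` attached as attribute `"pairs"`.
#' @export
compute_delta_beta <- function(betas, pairs) {
  stopifnot(inherits(pairs, "hmc_pairs"))
  validate_beta_matrix(betas)
  missing <- setdiff(c(pairs$bs_sample, pairs$oxbs_sample), colnames(betas))
  if (length(missing))
    stop("pair references sample absent from beta matrix: ", missing[1L])
  delta <- betas[, pairs$bs_sample, drop = FALSE] -
    betas[, pairs$oxbs_sample, drop = FALSE]
  colnames(delta) <- pairs$pair_id
  attr(delta, "pairs") <- pairs
  delta
}

#' Estimate the empirical 5hmC detection threshold
#'
#' In `negative_tail` mode (default), tau is the absolute value of the
#' q-quantile of the pooled multiset of strictly negative delta-beta
#' values across all probes and samples: the negative tail is taken as an
#' empirical null for technical noise.  In `all_values` mode the quantile
#' is over all pooled delta-beta values.  Quantiles use linear
#' interpolation between order statistics at position `q * (n - 1)`
#' (R type 7).
#'
#' @param delta Delta-beta matrix from [compute_delta_beta()].
#' @param mode `"negative_tail"` (default) or `"all_values"`.
#' @param q Tail quantile, default 0.05.
#' @return Threshold tau (non-negative scalar).
#' @export
estimate_threshold <- function(delta, mode = c("negative_tail", "all_values"),
                               q = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1)
  vals <- delta[!is.na(delta)]
  if (mode == "negative_tail") {
    vals <- vals[vals < 0]
    if (!length(vals))
      stop("no negative delta-beta values; consider mode = \"all_values\"")
  }
  abs(unname(stats::quantile(vals, probs = q, type = 7)))
}

#' Call probes with detectable 5hmC per tissue
#'
#' Averages delta-beta over each tissue's pairs (pairwise-complete) and
#' flags probes whose tissue mean strictly exceeds tau.  When `betas` is
#' supplied, tissue-mean oxBS betas (true 5mC) are recorded alongside.
#'
#' @param delta Delta-beta matrix from [compute_delta_beta()].
#' @param tau Detection threshold (see [estimate_threshold()]).
#' @param pairs Optional `hmc_pairs`; defaults to `attr(delta, "pairs")`.
#' @param betas Optional beta matrix for tissue-mean oxBS levels.
#' @return Object of class `hmc_callset`: list with `delta_beta`, `tau`,
#'   `tissue_mean_delta` (probes x tissues), `tissue_mean_oxbs` (or NULL),
#'   `detectable` (logical probes x tissues), `pairs`, and `counts`
#'   (per-tissue and union/intersection detectable counts).
#' @export
call_detectable <- function(delta, tau, pairs = attr(delta, "pairs"),
                            betas = NULL) {
  if (is.null(pairs)) stop("pairs not supplied and not attached to delta")
  stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0)
  tissues <- unique(pairs$tissue)
  if (!length(tissues)) stop("no tissues in pairs")
  tm <- vapply(tissues, function(tis) {
    cols <- pairs$pair_id[pairs$tissue == tis]
    rowMeans(delta[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(delta)))
  tm[is.nan(tm)] <- NA_real_
  det <- !is.na(tm) & tm > tau
  ox <- NULL
  if (!is.null(betas)) {
    ox <- vapply(tissues, function(tis) {
      cols <- pairs$oxbs_sample[pairs$tissue == tis]
      rowMeans(betas[, cols, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(delta)))
    rownames(ox) <- rownames(delta)
  }
  cs <- structure(list(delta_beta = delta, tau = tau,
                       tissue_mean_delta = tm, tissue_mean_oxbs = ox,
                       detectable = det, pairs = pairs),
                  class = "hmc_callset")
  cs$counts <- summarize_sets(cs)
  cs
}

#' @export
print.hmc_callset <- function(x, ...) {
  cat("hmc_callset:", nrow(x$delta_beta), "probes,",
      ncol(x$delta_beta), "pairs, tau =", format(x$tau), "\n")
  cat("detectable per tissue:\n")
  print(colSums(x$detectable))
  invisible(x)
}

#' Detectable-set counts with inclusion-exclusion
#'
#' For a two-tissue callset, returns per-tissue detectable counts, the
#' intersection, union, and tissue-unique counts; the identities
#' `n_union = n_a + n_b - n_both` and `n_a_only = n_a - n_both` hold
#' exactly.
#'
#' @param callset An `hmc_callset` covering (at least) two tissues; extra
#'   tissues beyond the first two are ignored for the pairwise fields.
#' @return Named list: `n_<tissue>` for each tissue, plus `n_both`,
#'   `n_union`, `n_<tissue>_only`.
#' @export
summarize_sets <- function(callset) {
  stopifnot(inherits(callset, "hmc_callset"))
  det <- callset$detectable
  out <- as.list(colSums(det))
  names(out) <- paste0("n_", colnames(det))
  if (ncol(det) >= 2L) {
    a <- det[, 1L]; b <- det[, 2L]
    out$n_both  <- sum(a & b)
    out$n_union <- sum(a | b)
    out[[paste0("n_", colnames(det)[1L], "_only")]] <- sum(a & !b)
    out[[paste0("n_", colnames(det)[2L], "_only")]] <- sum(b & !a)
  }
  out
}

#' Complete two-set counts by inclusion-exclusion
#'
#' Given any three of `n_a`, `n_b`, `n_both`, `n_union`, fills in the
#' rest: `n_union = n_a + n_b - n_both`, uniques `n_a - n_both` and
#' `n_b - n_both`.
#'
#' @param n_a,n_b Set sizes.
#' @param n_both Intersection size (optional if `n_union` given).
#' @param n_union Union size (optional if `n_both` given).
#' @return Named list with `n_a`, `n_b`, `n_both`, `n_union`, `n_a_only`,
#'   `n_b_only`.
#' @export
inclusion_exclusion <- function(n_a, n_b, n_both = NULL, n_union = NULL) {
  if (is.null(n_both) && is.null(n_union))
    stop("supply n_both or n_union")
  if (is.null(n_both)) n_both <- n_a + n_b - n_union
  if (is.null(n_union)) n_union <- n_a + n_b - n_both
  if (n_union != n_a + n_b - n_both)
    stop("inconsistent counts: union does not match inclusion-exclusion")
  if (n_both < 0 || n_both > min(n_a, n_b))
    stop("infeasible intersection size")
  list(n_a = n_a, n_b = n_b, n_both = n_both, n_union = n_union,
       n_a_only = n_a - n_both, n_b_only = n_b - n_both)
}

#' Rank probes by 5hmC level, variability or tissue difference
#'
#' Candidate pools: probes detectable in `tissue` for `level` and
#' `variability`; detectable in either tissue for `tissue_difference`
#' (tissue-specific hydroxymethylated positions, TS-HMPs).  Statistics:
#' tissue-mean delta-beta (level); standard deviation of delta-beta
#' across donors within tissue (variability); absolute difference of the
#' two tissue means (tissue_difference, with the signed difference and
#' direction retained).  Ties break by probe id ascending.
#'
#' @param callset An `hmc_callset`.
#' @param by `"level"`, `"variability"` or `"tissue_difference"`.
#' @param tissue Tissue name (required for level/variability).
#' @param n Number of top sites (default 1000); if larger than the pool,
#'   the full pool is returned with a warning.
#' @return data.frame `probe_id`, `statistic`, and for tissue_difference
#'   also `signed_difference` and `direction` (which tissue is higher),
#'   ordered by decreasing statistic.
#' @export
rank_sites <- function(callset,
                       by = c("level", "variability", "tissue_difference"),
                       tissue = NULL, n = 1000L) {
  by <- match.arg(by)
  stopifnot(inherits(callset, "hmc_callset"))
  tm <- callset$tissue_mean_delta
  if (by %in% c("level", "variability")) {
    if (is.null(tissue) || !tissue %in% colnames(tm))
      stop("a tissue present in the callset is required for by = '", by, "'")
    pool <- rownames(tm)[callset$detectable[, tissue]]
    if (by == "level") {
      stat <- tm[pool, tissue]
    } else {
      cols <- callset$pairs$pair_id[callset$pairs$tissue == tissue]
      sub <- callset$delta_beta[pool, cols, drop = FALSE]
      stat <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    }
    res <- data.frame(probe_id = pool, statistic = unname(stat))
  } else {
    if (ncol(tm) < 2L) stop("tissue_difference needs two tissues")
    pool <- rownames(tm)[rowSums(callset$detectable[, 1:2, drop = FALSE]) > 0]
    d <- tm[pool, 1L] - tm[pool, 2L]
    res <- data.frame(probe_id = pool, statistic = abs(unname(d)),
                      signed_difference = unname(d),
                      direction = ifelse(d >= 0, colnames(tm)[1L],
                                         colnames(tm)[2L]))
  }
  res <- res[order(-res$statistic, res$probe_id), , drop = FALSE]
  if (n > nrow(res)) {
    warning("requested n = ", n, " exceeds pool size ", nrow(res),
            "; returning full pool")
    n <- nrow(res)
  }
  res <- res[seq_len(n), , drop = FALSE]
  rownames(res) <- NULL
  res
}
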