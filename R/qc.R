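## Sample/probe filtering and concordance checks preceding 5hmC calling.

.qc_report <- function(removed_samples = data.frame(sample_id = character(),
                                                    reason = character()),
                       removed_probes = integer(), extra = list()) {
  rep <- c(list(removed_samples = removed_samples,
                removed_probes = removed_probes), extra)
  class(rep) <- "qc_report"
  rep
}

#' Detection p-value filter for samples then probes
#'
#' Removes any sample in which more than `fail_fraction` of sites have
#' detection p >= `site_alpha`, then any probe failing (p >= `site_alpha`)
#' in more than `fail_fraction` of the remaining samples.  Defaults follow
#' the customary 5 percent of sites at p < 0.05.
#'
#' @param betas Beta matrix (probes x samples).
#' @param detp Detection p-value matrix, same dimnames.
#' @param site_alpha Per-site detection p cut-off (default 0.05).
#' @param fail_fraction Maximum tolerated failing fraction (default 0.05).
#' @return List with `betas` (filtered matrix) and `report` (a
#'   `qc_report`: removed samples with reasons, removed-probe counts by
#'   reason).
#' @export
pfilter <- function(betas, detp, site_alpha = 0.05, fail_fraction = 0.05) {
  validate_beta_matrix(betas)
  validate_beta_matrix(detp, what = "detection p")
  if (!identical(dim(betas), dim(detp)) ||
      !identical(rownames(betas), rownames(detp)) ||
      !identical(colnames(betas), colnames(detp)))
    stop("beta and detection-p matrices are not aligned")
  fail <- !is.na(detp) & detp >= site_alpha
  samp_frac <- colMeans(fail)
  bad_samples <- colnames(betas)[samp_frac > fail_fraction]
  keep_s <- setdiff(colnames(betas), bad_samples)
  if (!length(keep_s))
    stop("pfilter removed all samples (fail_fraction = ", fail_fraction, ")")
  probe_frac <- rowMeans(fail[, keep_s, drop = FALSE])
  bad_probes <- probe_frac > fail_fraction
  out <- betas[!bad_probes, keep_s, drop = FALSE]
  report <- .qc_report(
    removed_samples = data.frame(
      sample_id = bad_samples,
      reason = rep("detection-p", length(bad_samples))),
    removed_probes = c(`detection-p` = sum(bad_probes)),
    extra = list(n_probes_in = nrow(betas), n_probes_out = nrow(out)))
  list(betas = out, report = report)
}

#' Mask SNP-affected, cross-reactive and genotyping probes
#'
#' Drops probes flagged `masked` (common-SNP / cross-reactive /
#' non-specific) or `is_snp_probe` (rs genotyping probes); the remainder
#' is the analysis set.
#'
#' @param betas Beta matrix.
#' @param ann Probe annotation table covering the probes.
#' @param unannotated What to do with probes absent from `ann`:
#'   `"keep"` (default, with a warning) or `"error"`.
#' @return List with `betas` and `report` (removal counts by reason).
#' @export
mask_probes <- function(betas, ann, unannotated = c("keep", "error")) {
  unannotated <- match.arg(unannotated)
  validate_beta_matrix(betas)
  idx <- match(rownames(betas), ann$probe_id)
  if (anyNA(idx)) {
    n_un <- sum(is.na(idx))
    if (unannotated == "error")
      stop(n_un, " probe(s) missing from annotation")
    warning(n_un, " probe(s) missing from annotation; kept")
  }
  snp  <- !is.na(idx) & ann$is_snp_probe[idx] %in% TRUE
  mask <- !is.na(idx) & !snp & ann$masked[idx] %in% TRUE
  out <- betas[!(snp | mask), , drop = FALSE]
  report <- .qc_report(
    removed_probes = c(`rs-probe` = sum(snp), masked = sum(mask)),
    extra = list(n_probes_in = nrow(betas), n_probes_out = nrow(out)))
  list(betas = out, report = report)
}

# Pearson r with the t-transform p-value on n - 2 df
.cor_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 complete observations")
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

#' Concordance between two BS conversion kits
#'
#' For each tissue, correlates probe-wise mean beta values between the
#' Zymo-BS and CEGX-BS arms of the same donors and reports squared
#' Pearson correlation with its t-transform p-value.
#'
#' @param betas Beta matrix holding both arms.
#' @param sheet Sample sheet; tissues are taken from it.
#' @return data.frame with one row per tissue: `tissue`, `r_squared`,
#'   `p_value`, `n_probes`, `n_pairs`.
#' @export
kit_concordance <- function(betas, sheet) {
  validate_sample_sheet(sheet)
  res <- lapply(unique(sheet$tissue), function(tis) {
    s <- sheet[sheet$tissue == tis, ]
    zy <- intersect(s$sample_id[s$treatment == "bs_zymo"], colnames(betas))
    bc <- intersect(s$sample_id[s$treatment == "bs_cegx"], colnames(betas))
    if (!length(zy) || !length(bc))
      stop("tissue '", tis, "' lacks matched bs_zymo/bs_cegx samples")
    mz <- rowMeans(betas[, zy, drop = FALSE], na.rm = TRUE)
    mc <- rowMeans(betas[, bc, drop = FALSE], na.rm = TRUE)
    ct <- .cor_test(mz, mc)
    data.frame(tissue = tis, r_squared = ct$r^2, p_value = ct$p,
               n_probes = ct$n, n_pairs = min(length(zy), length(bc)))
  })
  do.call(rbind, res)
}

#' Donor identity check from rs genotyping probes
#'
#' Correlates rs-probe beta profiles between samples; same-donor pairs
#' are expected to exceed all cross-donor pairs.  The donor-level matrix
#' correlates per-donor mean profiles.
#'
#' @param betas Beta matrix restricted to (or containing) rs probes.
#' @param sheet Sample sheet.
#' @param rs_probes Optional character vector of rs probe ids; defaults to
#'   rownames starting with "rs".
#' @return List: `donor_cor` (donor x donor Pearson matrix), `sample_cor`,
#'   `min_same_donor`, `max_cross_donor`, `violations` (data.frame of
#'   cross-donor sample pairs correlating at least as strongly as the
#'   weakest same-donor pair).
#' @export
genotype_concordance <- function(betas, sheet, rs_probes = NULL) {
  validate_sample_sheet(sheet)
  if (is.null(rs_probes))
    rs_probes <- grep("^rs", rownames(betas), value = TRUE)
  rs_probes <- intersect(rs_probes, rownames(betas))
  if (length(rs_probes) < 5L)
    stop("need at least 5 rs probes, got ", length(rs_probes))
  samples <- intersect(sheet$sample_id, colnames(betas))
  m <- betas[rs_probes, samples, drop = FALSE]
  sample_cor <- stats::cor(m, use = "pairwise.complete.obs")
  donor_of <- sheet$donor_id[match(samples, sheet$sample_id)]
  donors <- unique(donor_of)
  dm <- vapply(donors, function(d)
    rowMeans(m[, donor_of == d, drop = FALSE], na.rm = TRUE),
    numeric(length(rs_probes)))
  donor_cor <- stats::cor(dm, use = "pairwise.complete.obs")
  same <- outer(donor_of, donor_of, "==") & upper.tri(sample_cor)
  cross <- !outer(donor_of, donor_of, "==") & upper.tri(sample_cor)
  min_same  <- if (any(same)) min(sample_cor[same]) else NA_real_
  max_cross <- if (any(cross)) max(sample_cor[cross]) else NA_real_
  viol <- data.frame(sample_a = character(), sample_b = character(),
                     r = numeric())
  if (!is.na(min_same) && !is.na(max_cross)) {
    bad <- which(cross & sample_cor >= min_same, arr.ind = TRUE)
    if (nrow(bad))
      viol <- data.frame(sample_a = samples[bad[, 1L]],
                         sample_b = samples[bad[, 2L]],
                         r = sample_cor[bad])
  }
  list(donor_cor = donor_cor, sample_cor = sample_cor,
       min_same_donor = min_same, max_cross_donor = max_cross,
       violations = viol)
}
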