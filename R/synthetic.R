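## Synthetic-data generator with known per-probe truth.  The stated world
## mirrors the study design it stands in for: two brain tissues
## (prefrontal cortex, cerebellum) from 8 discovery and 18 validation
## donors, three treatment arms per sample, ~20 percent of probes
## carrying 5hmC at levels 0.10-0.35, cerebellum running higher, and
## Gaussian technical noise (sd 0.025) on betas so that 5hmC-free probes
## show the negative delta-beta tail the empirical threshold is built on.

DEFAULT_FEATURE_PROBS <- list(
  # background composition of a QC-passing 450K-style array
  unannotated = 0.0239,
  cgi  = c(island = 0.323, shore = 0.233, shelf = 0.088, outside = 0.331),
  gene = c(intergenic = 0.140, distal_promoter = 0.045,
           proximal_promoter = 0.396, gene_body = 0.377,
           downstream = 0.018),
  tfbs = 0.492, dhs = 0.133,
  alt_annotated = 0.371,
  alt  = c(A3SS = 0.024, A5SS = 0.024, AFE = 0.418, ALE = 0.065,
           CE = 0.434, CNE = 0.149, EI = 0.001, II = 0.200, IR = 0.117,
           MXE = 0.094))

#' Generate a synthetic probe annotation and gene models
#'
#' Lays genes along a synthetic genome (round-robin over chromosomes,
#' 30 kb intergenic gaps) and places probes according to sampled genomic
#' features: the exclusive CpG-island and gene-feature strata are drawn
#' categorically with the supplied marginals, TFBS/DHS/alternative-event
#' flags as Bernoullis, and probe positions realised consistently with
#' the gene feature (promoter probes near the strand-aware TSS, body
#' probes inside the gene, intergenic probes in the gaps).  A block of
#' rs genotyping probes and a masked (SNP/cross-reactive) subset are
#' appended to exercise the QC stage.
#'
#' @param n_probes Number of CpG probes (default 50000).
#' @param feature_probs Nested list of feature probabilities; see
#'   `DEFAULT_FEATURE_PROBS` for the shape and defaults.
#' @param n_genes Number of genes (default `round(n_probes / 25)`).
#' @param n_rs Number of rs genotyping probes appended (default 65).
#' @param masked_frac Fraction of CpG probes flagged masked (default
#'   0.05).
#' @param seed Integer seed; same seed reproduces the tables exactly.
#' @return List with `annotation` (probe annotation data.frame) and
#'   `genes` (gene models).
#' @export
generate_annotation <- function(n_probes = 50000L,
                                feature_probs = DEFAULT_FEATURE_PROBS,
                                n_genes = max(50L, round(n_probes / 25)),
                                n_rs = 65L, masked_frac = 0.05,
                                seed = 1L) {
  fp <- feature_probs
  for (nm in c("cgi", "gene"))
    if (any(fp[[nm]] < 0) || abs(sum(fp[[nm]]) - 1) > 0.05)
      stop("feature_probs$", nm, " must be a probability vector summing to 1")
  set.seed(seed)
  # genome layout: genes round-robin over 20 chromosomes, 30 kb gaps
  gap <- 30000L
  glen <- round(stats::runif(n_genes, 2000, 50000))
  chrom_of <- paste0("chr", rep_len(1:20, n_genes))
  starts <- integer(n_genes)
  offs <- stats::setNames(rep(50000L, 20L), paste0("chr", 1:20))
  for (i in seq_len(n_genes)) {
    starts[i] <- offs[[chrom_of[i]]]
    offs[[chrom_of[i]]] <- starts[i] + glen[i] + gap
  }
  genes <- data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
                      chrom = chrom_of,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      tx_start = starts, tx_end = starts + glen,
                      stringsAsFactors = FALSE)

  unann <- stats::runif(n_probes) < fp$unannotated
  cgi <- ifelse(unann, "unannotated",
                sample(names(fp$cgi), n_probes, replace = TRUE,
                       prob = fp$cgi / sum(fp$cgi)))
  gfeat <- ifelse(unann, "unannotated",
                  sample(names(fp$gene), n_probes, replace = TRUE,
                         prob = fp$gene / sum(fp$gene)))
  host <- sample.int(n_genes, n_probes, replace = TRUE)
  tss <- ifelse(genes$strand[host] == "+", genes$tx_start[host],
                genes$tx_end[host])
  dirn <- ifelse(genes$strand[host] == "+", 1L, -1L)  # +1 means TSS at left
  tes <- ifelse(genes$strand[host] == "+", genes$tx_end[host],
                genes$tx_start[host])
  u <- stats::runif(n_probes)
  pos <- integer(n_probes)
  place <- function(sel, lo, hi)       # uniform integer offset in [lo, hi]
    round(lo[sel] + u[sel] * (hi[sel] - lo[sel]))
  sel <- gfeat == "proximal_promoter"; pos[sel] <- tss[sel] - dirn[sel] *
    place(sel, rep(1, n_probes), rep(2000, n_probes))
  sel <- gfeat == "distal_promoter"; pos[sel] <- tss[sel] - dirn[sel] *
    place(sel, rep(2001, n_probes), rep(5000, n_probes))
  sel <- gfeat == "gene_body" | unann
  pos[sel] <- round(genes$tx_start[host][sel] +
                    u[sel] * (genes$tx_end[host][sel] -
                              genes$tx_start[host][sel]))
  sel <- gfeat == "downstream"; pos[sel] <- tes[sel] + dirn[sel] *
    place(sel, rep(1, n_probes), rep(5000, n_probes))
  sel <- gfeat == "intergenic"
  pos[sel] <- genes$tx_end[host][sel] +
    place(sel, rep(6000, n_probes), rep(20000, n_probes))

  near <- gfeat %in% c("distal_promoter", "proximal_promoter", "gene_body",
                       "downstream") | unann
  gene_sym <- ifelse(near, genes$gene_id[host], "")

  alt_ann <- stats::runif(n_probes) < fp$alt_annotated
  alt_mat <- vapply(names(fp$alt), function(ev)
    alt_ann & stats::runif(n_probes) < fp$alt[[ev]], logical(n_probes))
  none <- alt_ann & rowSums(alt_mat) == 0
  alt_mat[none, "CE"] <- TRUE            # keep alt-annotated probes non-empty
  alt_str <- apply(alt_mat, 1L, function(r)
    paste(names(fp$alt)[r], collapse = ","))

  ann <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n_probes)),
    chrom = genes$chrom[host], pos = pos,
    cgi_feature = cgi, gene_feature = gfeat,
    tfbs = stats::runif(n_probes) < fp$tfbs,
    dhs = stats::runif(n_probes) < fp$dhs,
    alt_events = alt_str, genes = gene_sym,
    is_snp_probe = FALSE,
    masked = stats::runif(n_probes) < masked_frac,
    stringsAsFactors = FALSE)
  if (n_rs > 0L) {
    rs <- data.frame(
      probe_id = sprintf("rs%07d", seq_len(n_rs)),
      chrom = sample(paste0("chr", 1:20), n_rs, replace = TRUE),
      pos = round(stats::runif(n_rs, 1e6, 2e6)),
      cgi_feature = "unannotated", gene_feature = "unannotated",
      tfbs = FALSE, dhs = FALSE, alt_events = "", genes = "",
      is_snp_probe = TRUE, masked = FALSE, stringsAsFactors = FALSE)
    ann <- rbind(ann, rs)
  }
  list(annotation = ann, genes = genes)
}

#' Generate per-probe true 5mC and 5hmC levels
#'
#' A fraction `f` of CpG probes carries 5hmC, with feature-dependent odds
#' (`feature_rr`, e.g. `c(gene_body = 2)` doubles the odds for gene-body
#' probes).  True 5hmC is uniform on `hmc_range`, with a cerebellum
#' increment of mean `tissue_effect` (per-probe magnitude uniform on
#' \[0, 2 x tissue_effect\], directed toward cerebellum with probability
#' `cbl_higher_frac`).  True 5mC is a bimodal Beta mixture; the
#' constraint 5mC + 5hmC <= 1 is enforced by truncating 5hmC.
#'
#' @param ann Annotation from [generate_annotation()].
#' @param f Fraction of probes hydroxymethylated (default 0.2).
#' @param tissue_effect Mean cerebellum-minus-cortex true 5hmC increment
#'   at hydroxymethylated probes (default 0.05).
#' @param feature_rr Named numeric: odds multipliers on hydroxymethylation
#'   by feature (names matched against CpG-island features, gene
#'   features, "tfbs", "dhs").
#' @param hmc_range Range of true 5hmC at positive probes (default
#'   c(0.10, 0.35)).
#' @param cbl_higher_frac Probability the tissue increment favours
#'   cerebellum (default 0.965).
#' @param seed Integer seed.
#' @return data.frame of class `synthetic_truth`: probe_id, is_hmc,
#'   true_mc, true_hmc_prefrontal_cortex, true_hmc_cerebellum.
#'   Parameters are attached as attribute `params`.
#' @export
generate_truth <- function(ann, f = 0.2, tissue_effect = 0.05,
                           feature_rr = c(gene_body = 2),
                           hmc_range = c(0.10, 0.35),
                           cbl_higher_frac = 0.965, seed = 1L) {
  stopifnot(f >= 0, f <= 1, all(feature_rr >= 0))
  set.seed(seed)
  n <- nrow(ann)
  eta <- rep(stats::qlogis(max(f, 1e-12)), n)
  for (nm in names(feature_rr)) {
    has <- if (nm %in% CGI_FEATURES) ann$cgi_feature == nm
    else if (nm %in% GENE_FEATURES) ann$gene_feature == nm
    else if (nm == "tfbs") ann$tfbs
    else if (nm == "dhs") ann$dhs
    else stop("unknown feature in feature_rr: ", nm)
    eta <- eta + log(feature_rr[[nm]]) * has
  }
  is_hmc <- if (f == 0) rep(FALSE, n) else
    stats::runif(n) < stats::plogis(eta)
  is_hmc[ann$is_snp_probe] <- FALSE
  mix <- stats::runif(n) < 0.5
  true_mc <- ifelse(mix, stats::rbeta(n, 10, 40), stats::rbeta(n, 40, 10))
  base <- ifelse(is_hmc, stats::runif(n, hmc_range[1L], hmc_range[2L]), 0)
  mag <- stats::runif(n, 0, 2 * tissue_effect)
  sgn <- ifelse(stats::runif(n) < cbl_higher_frac, 1, -1)
  hmc_pfc <- base
  hmc_cbl <- pmax(0, base + ifelse(is_hmc, sgn * mag, 0))
  # feasibility: 5mC + 5hmC must not exceed 1
  hmc_pfc <- pmin(hmc_pfc, 1 - true_mc)
  hmc_cbl <- pmin(hmc_cbl, 1 - true_mc)
  if (any(is_hmc) && all(hmc_pfc[is_hmc] <= 0 & hmc_cbl[is_hmc] <= 0))
    stop("infeasible truth: 5mC leaves no room for 5hmC at any probe")
  out <- data.frame(probe_id = ann$probe_id, is_hmc = is_hmc,
                    true_mc = true_mc,
                    true_hmc_prefrontal_cortex = hmc_pfc,
                    true_hmc_cerebellum = hmc_cbl,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(f = f, tissue_effect = tissue_effect,
                              feature_rr = feature_rr,
                              hmc_range = hmc_range,
                              cbl_higher_frac = cbl_higher_frac,
                              seed = seed)
  class(out) <- c("synthetic_truth", "data.frame")
  out
}

#' Generate beta matrices, detection p-values and a sample sheet
#'
#' Per sample: `beta_oxBS = clip(mc + e1)`, `beta_BS = clip(mc + hmc +
#' e2)` with independent Gaussian noise `N(0, noise_sd^2)` and clipping
#' to \[0, 1\]; the optional Zymo-BS arm is an independent BS replicate.
#' rs genotyping probes get donor-specific trimodal betas (0.05/0.5/0.95
#' plus N(0, 0.02) noise) shared across that donor's samples.  Detection
#' p-values are near zero with an optional injected failure rate.
#'
#' @param truth `synthetic_truth` from [generate_truth()].
#' @param n_donors Named integer vector of donors per cohort, default
#'   `c(discovery = 8, validation = 18)`.
#' @param noise_sd Technical noise SD on betas (default 0.025).
#' @param detp_fail_rate Per-entry probability of an injected detection
#'   failure (p drawn uniform on \[0.05, 1\]; default 0).
#' @param include_zymo Generate the Zymo-BS arm too (default TRUE).
#' @param seed Integer seed; regeneration is bit-identical.
#' @return List: `betas` (matrix), `detp`, `sheet`, `genotypes` (donor x
#'   rs-probe truth used for rs betas).
#' @export
generate_betas <- function(truth, n_donors = c(discovery = 8L,
                                               validation = 18L),
                           noise_sd = 0.025, detp_fail_rate = 0,
                           include_zymo = TRUE, seed = 1L) {
  stopifnot(noise_sd > 0)
  if (is.null(names(n_donors)))
    names(n_donors) <- COHORTS[seq_along(n_donors)]
  set.seed(seed)
  arms <- c("bs_cegx", "oxbs_cegx", if (include_zymo) "bs_zymo")
  rows <- list(); k <- 0L
  for (co in names(n_donors)) {
    for (d in seq_len(n_donors[[co]])) {
      donor <- sprintf("%s%02d", substr(co, 1L, 1L), d)
      for (tis in TISSUES) for (arm in arms) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample_id = paste(donor, substr(tis, 1L, 3L), arm, sep = "_"),
          donor_id = donor, tissue = tis, treatment = arm, cohort = co,
          stringsAsFactors = FALSE)
      }
    }
  }
  sheet <- do.call(rbind, rows)
  n <- nrow(truth)
  rs <- grepl("^rs", truth$probe_id)
  donors <- unique(sheet$donor_id)
  geno <- matrix(sample(c(0.05, 0.5, 0.95), length(donors) * sum(rs),
                        replace = TRUE),
                 nrow = sum(rs), ncol = length(donors),
                 dimnames = list(truth$probe_id[rs], donors))
  betas <- matrix(NA_real_, n, nrow(sheet),
                  dimnames = list(truth$probe_id, sheet$sample_id))
  hmc_col <- paste0("true_hmc_", sheet$tissue)
  for (j in seq_len(nrow(sheet))) {
    mu <- if (sheet$treatment[j] == "oxbs_cegx") truth$true_mc
    else truth$true_mc + truth[[hmc_col[j]]]
    v <- mu + stats::rnorm(n, 0, noise_sd)
    if (any(rs))
      v[rs] <- geno[, sheet$donor_id[j]] + stats::rnorm(sum(rs), 0, 0.02)
    betas[, j] <- pmin(1, pmax(0, v))
  }
  detp <- matrix(stats::runif(n * nrow(sheet), 0, 0.01), n, nrow(sheet),
                 dimnames = dimnames(betas))
  if (detp_fail_rate > 0) {
    fail <- stats::runif(length(detp)) < detp_fail_rate
    detp[fail] <- stats::runif(sum(fail), 0.05, 1)
  }
  list(betas = betas, detp = detp, sheet = sheet, genotypes = geno)
}

#' Generate synthetic gene sets with optional probe-count confounding
#'
#' Pathway target sizes are log-uniform on `size_range`; gene membership
#' probability is the target fraction, odds-shifted by
#' `confounding_strength` times the standardised probe count (so heavily
#' probed genes land in more pathways).  The test gene list is drawn with
#' base odds `list_fraction`, the same probe-count confounding, and an
#' odds multiplier `signal_odds` for genes in designated signal pathways.
#'
#' @param genes data.frame with `gene_id` and `n_probes` (e.g.
#'   `build_universe()$genes` or tallied from an annotation).
#' @param n_pathways Number of gene sets (default 1000).
#' @param size_range Target size bounds (default c(10, 2000)).
#' @param confounding_strength Log-odds shift per SD of probe count
#'   applied to both membership and the test list (default 0 = none).
#' @param n_signal Number of designated signal pathways (default 0).
#' @param signal_odds Odds multiplier for test-list membership of genes
#'   in a signal pathway (default 4).
#' @param list_fraction Base test-list fraction (default 0.3).
#' @param seed Integer seed.
#' @return List: `pathways` (named list), `test_genes`,
#'   `signal_pathways` (character), `genes` (the input frame).
#' @export
generate_pathways <- function(genes, n_pathways = 1000L,
                              size_range = c(10L, 2000L),
                              confounding_strength = 0, n_signal = 0L,
                              signal_odds = 4, list_fraction = 0.3,
                              seed = 1L) {
  n <- nrow(genes)
  if (size_range[1L] < 1L || size_range[2L] > n)
    stop("size_range infeasible for ", n, " genes")
  set.seed(seed)
  z <- as.numeric(scale(genes$n_probes))
  if (all(is.na(z))) z <- rep(0, n)      # constant probe counts
  sizes <- round(exp(stats::runif(n_pathways, log(size_range[1L]),
                                  log(size_range[2L]))))
  pathways <- vector("list", n_pathways)
  names(pathways) <- sprintf("PW%04d", seq_len(n_pathways))
  for (j in seq_len(n_pathways)) {
    p <- stats::plogis(stats::qlogis(sizes[j] / n) +
                       confounding_strength * z)
    member <- stats::runif(n) < p
    # guarantee the minimum size so the set survives universe filtering
    if (sum(member) < size_range[1L])
      member[sample.int(n, size_range[1L])] <- TRUE
    pathways[[j]] <- genes$gene_id[member]
  }
  signal <- names(pathways)[seq_len(n_signal)]
  in_signal <- genes$gene_id %in% unique(unlist(pathways[signal]))
  pl <- stats::plogis(stats::qlogis(list_fraction) +
                      confounding_strength * z +
                      log(signal_odds) * in_signal)
  test_genes <- genes$gene_id[stats::runif(n) < pl]
  list(pathways = pathways, test_genes = test_genes,
       signal_pathways = signal, genes = genes)
}

#' One-call synthetic experiment
#'
#' Chains [generate_annotation()], [generate_truth()] and
#' [generate_betas()] with a single master seed (sub-seeds are derived
#' deterministically below 2^31).
#'
#' @param n_probes,n_genes,n_rs,masked_frac Passed to the annotation
#'   generator.
#' @param f,tissue_effect,feature_rr,hmc_range Passed to the truth
#'   generator.
#' @param n_donors,noise_sd,detp_fail_rate,include_zymo Passed to the
#'   beta generator.
#' @param seed Master seed.
#' @return List: annotation, genes, truth, betas, detp, sheet.
#' @export
simulate_hmc_experiment <- function(n_probes = 50000L,
                                    n_genes = max(50L, round(n_probes / 25)),
                                    n_rs = 65L, masked_frac = 0.05,
                                    f = 0.2, tissue_effect = 0.05,
                                    feature_rr = c(gene_body = 2),
                                    hmc_range = c(0.10, 0.35),
                                    n_donors = c(discovery = 8L,
                                                 validation = 18L),
                                    noise_sd = 0.025, detp_fail_rate = 0,
                                    include_zymo = TRUE, seed = 1L) {
  s <- (as.integer(seed) %% 1000000L) * 1000L
  geno <- generate_annotation(n_probes, n_genes = n_genes, n_rs = n_rs,
                              masked_frac = masked_frac, seed = s + 1L)
  truth <- generate_truth(geno$annotation, f = f,
                          tissue_effect = tissue_effect,
                          feature_rr = feature_rr, hmc_range = hmc_range,
                          seed = s + 2L)
  sim <- generate_betas(truth, n_donors = n_donors, noise_sd = noise_sd,
                        detp_fail_rate = detp_fail_rate,
                        include_zymo = include_zymo, seed = s + 3L)
  c(list(annotation = geno$annotation, genes = geno$genes, truth = truth),
    sim)
}
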