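## Orchestration: run configuration, staged execution with file-based
## hand-off between stages, a JSON manifest with checksums, and a thin
## command-line entry point.

#' Read a run configuration
#'
#' YAML (requires the `yaml` package) or JSON, by file extension.  See
#' [default_run_config()] for recognised fields.
#'
#' @param path Config file path.
#' @return Named list merged over the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  utils::modifyList(default_run_config(), cfg)
}

#' Default run configuration
#'
#' @return Nested list of defaults: `simulate` (generator parameters or
#'   NULL to use `inputs` paths), `inputs`, `qc`, `threshold`, `ranking`,
#'   `pathway`, `metagene`, `seed`.
#' @export
default_run_config <- function() {
  list(
    simulate = NULL,
    inputs = list(betas = NULL, detp = NULL, sample_sheet = NULL,
                  annotation = NULL, genes = NULL, gene_sets = NULL),
    qc = list(site_alpha = 0.05, fail_fraction = 0.05),
    threshold = list(mode = "negative_tail", q = 0.05),
    ranking = list(n = 1000L),
    pathway = list(alpha = 0.05, size_min = 10L, size_max = 2000L),
    metagene = list(flank = 5000, window_width = 1, step = 0.5),
    seed = 1L)
}

.validate_config <- function(cfg) {
  if (is.null(cfg$simulate)) {
    need <- c("betas", "detp", "sample_sheet", "annotation")
    for (nm in need) {
      p <- cfg$inputs[[nm]]
      if (is.null(p)) stop("config: inputs$", nm,
                           " required when not simulating")
      if (!file.exists(p)) stop("config: input path does not exist: ", p)
    }
  }
  stopifnot(cfg$threshold$q > 0, cfg$threshold$q < 1,
            cfg$ranking$n >= 1,
            cfg$pathway$size_min >= 1,
            cfg$pathway$size_min <= cfg$pathway$size_max)
  invisible(cfg)
}

.stage_log <- function(run_dir, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  cat(line, "\n", file = file.path(run_dir, "pipeline.log"), append = TRUE)
}

.art <- function(run_dir, ...) file.path(run_dir, ...)

# load shared inputs (from the simulate stage's files or external paths)
.load_inputs <- function(cfg, run_dir) {
  src <- function(nm, fallback)
    if (!is.null(cfg$inputs[[nm]])) cfg$inputs[[nm]]
    else .art(run_dir, "inputs", fallback)
  list(betas = read_beta_matrix(src("betas", "betas.tsv")),
       detp = read_detection_p(src("detp", "detp.tsv")),
       sheet = read_sample_sheet(src("sample_sheet", "sample_sheet.tsv")),
       ann = read_probe_annotation(src("annotation", "annotation.tsv")),
       genes = {
         p <- if (!is.null(cfg$inputs$genes)) cfg$inputs$genes
         else .art(run_dir, "inputs", "genes.tsv")
         if (file.exists(p)) read_gene_models(p) else NULL
       },
       gene_sets = {
         p <- if (!is.null(cfg$inputs$gene_sets)) cfg$inputs$gene_sets
         else .art(run_dir, "inputs", "pathways.gmt")
         if (file.exists(p)) read_gmt(p) else NULL
       })
}

.stage_simulate <- function(cfg, run_dir) {
  sim_cfg <- cfg$simulate
  if (is.null(sim_cfg)) sim_cfg <- list()
  sim_cfg$seed <- if (!is.null(sim_cfg$seed)) sim_cfg$seed else cfg$seed
  if (!is.null(sim_cfg$n_donors))
    sim_cfg$n_donors <- unlist(sim_cfg$n_donors)
  if (!is.null(sim_cfg$feature_rr))
    sim_cfg$feature_rr <- unlist(sim_cfg$feature_rr)
  pw_cfg <- sim_cfg$pathways
  if (!is.null(pw_cfg$size_range))
    pw_cfg$size_range <- unlist(pw_cfg$size_range)
  sim_cfg$pathways <- NULL
  sim <- do.call(simulate_hmc_experiment, sim_cfg)
  dir.create(.art(run_dir, "inputs"), showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(sim$betas, .art(run_dir, "inputs", "betas.tsv"))
  write_beta_matrix(sim$detp, .art(run_dir, "inputs", "detp.tsv"))
  wtsv <- function(df, f) data.table::fwrite(df, .art(run_dir, "inputs", f),
                                             sep = "\t", quote = FALSE)
  wtsv(sim$sheet, "sample_sheet.tsv")
  wtsv(sim$annotation, "annotation.tsv")
  wtsv(sim$genes, "genes.tsv")
  wtsv(as.data.frame(sim$truth), "truth.tsv")
  genes_df <- data.frame(gene_id = sim$genes$gene_id,
                         n_probes = as.integer(
                           table(factor(sim$annotation$genes,
                                        levels = sim$genes$gene_id))))
  genes_df <- genes_df[genes_df$n_probes > 0, ]
  pw <- do.call(generate_pathways,
                c(list(genes = genes_df,
                       seed = sim_cfg$seed), pw_cfg))
  write_gmt(pw$pathways, .art(run_dir, "inputs", "pathways.gmt"))
  .stage_log(run_dir, "simulate",
             sprintf("%d probes, %d samples, %d gene sets",
                     nrow(sim$betas), ncol(sim$betas), length(pw$pathways)))
  invisible(NULL)
}

.stage_qc <- function(cfg, run_dir) {
  inp <- .load_inputs(cfg, run_dir)
  pf <- pfilter(inp$betas, inp$detp, cfg$qc$site_alpha,
                cfg$qc$fail_fraction)
  mk <- mask_probes(pf$betas, inp$ann)
  qc <- list(pfilter = unclass(pf$report), mask = unclass(mk$report))
  kc <- tryCatch(kit_concordance(inp$betas, inp$sheet),
                 error = function(e) NULL)
  if (!is.null(kc)) qc$kit_concordance <- kc
  gc_ <- tryCatch(genotype_concordance(inp$betas, inp$sheet),
                  error = function(e) NULL)
  if (!is.null(gc_))
    qc$genotype <- list(min_same_donor = gc_$min_same_donor,
                        max_cross_donor = gc_$max_cross_donor,
                        n_violations = nrow(gc_$violations))
  write_beta_matrix(mk$betas, .art(run_dir, "betas_qc.tsv"))
  jsonlite::write_json(qc, .art(run_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  .stage_log(run_dir, "qc", sprintf("%d -> %d probes, %d -> %d samples",
                                    nrow(inp$betas), nrow(mk$betas),
                                    ncol(inp$betas), ncol(mk$betas)))
  invisible(NULL)
}

.load_callset <- function(cfg, run_dir) {
  betas <- read_beta_matrix(.art(run_dir, "betas_qc.tsv"))
  sheet <- .load_inputs(cfg, run_dir)$sheet
  sheet_d <- sheet[sheet$cohort == "discovery", ]
  pairs <- pair_samples(sheet_d, betas)
  delta <- compute_delta_beta(betas, pairs)
  tau <- estimate_threshold(delta, mode = cfg$threshold$mode,
                            q = cfg$threshold$q)
  call_detectable(delta, tau, betas = betas)
}

.stage_call <- function(cfg, run_dir) {
  cs <- .load_callset(cfg, run_dir)
  out <- data.frame(probe_id = rownames(cs$delta_beta),
                    cs$tissue_mean_delta,
                    detectable = cs$detectable, cs$delta_beta,
                    check.names = FALSE)
  data.table::fwrite(out, .art(run_dir, "callset.tsv"), sep = "\t")
  jsonlite::write_json(c(list(tau = cs$tau), cs$counts),
                       .art(run_dir, "callset_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  n <- cfg$ranking$n
  for (spec in list(c("level", TISSUES[1L]), c("level", TISSUES[2L]),
                    c("variability", TISSUES[1L]),
                    c("variability", TISSUES[2L]),
                    c("tissue_difference", NA))) {
    by <- spec[1L]; tis <- spec[2L]
    rk <- suppressWarnings(
      rank_sites(cs, by, tissue = if (is.na(tis)) NULL else tis, n = n))
    fn <- if (is.na(tis)) "ranked_tshmp.tsv"
    else sprintf("ranked_%s_%s.tsv", by, tis)
    data.table::fwrite(rk, .art(run_dir, fn), sep = "\t")
  }
  .stage_log(run_dir, "call",
             sprintf("tau = %.6f; detectable: %s", cs$tau,
                     paste(names(cs$counts), unlist(cs$counts),
                           collapse = ", ", sep = "=")))
  invisible(NULL)
}

.stage_enrich <- function(cfg, run_dir) {
  cs <- .load_callset(cfg, run_dir)
  ann <- .load_inputs(cfg, run_dir)$ann
  tabs <- suppressWarnings(enrichment_tables(cs, ann, n_top = cfg$ranking$n))
  for (nm in names(tabs))
    data.table::fwrite(tabs[[nm]],
                       .art(run_dir, sprintf("enrichment_%s.tsv", nm)),
                       sep = "\t")
  .stage_log(run_dir, "enrich", "wrote 4 enrichment tables")
  invisible(NULL)
}

.stage_compare <- function(cfg, run_dir) {
  inp <- .load_inputs(cfg, run_dir)
  betas <- read_beta_matrix(.art(run_dir, "betas_qc.tsv"))
  cs <- .load_callset(cfg, run_dir)
  res <- list()
  for (tis in unique(cs$pairs$tissue))
    res[[paste0("cross_tissue_", tis)]] <-
      unclass(cross_tissue_correlation(cs, tis))
  sheet_v <- inp$sheet[inp$sheet$cohort == "validation", ]
  sheet_v <- sheet_v[sheet_v$sample_id %in% colnames(betas), ]
  if (nrow(sheet_v)) {
    pairs_v <- pair_samples(sheet_v, betas)
    delta_v <- compute_delta_beta(betas, pairs_v)
    cs_v <- call_detectable(delta_v, cs$tau)
    ts <- rank_sites(cs, "tissue_difference", n = cfg$ranking$n)
    vc <- validate_concordance(ts, cs, cs_v)
    res$validation_tshmp <- list(r = vc$r, p_value = vc$p_value,
                                 median_abs_difference_pct =
                                   vc$median_abs_difference_pct,
                                 n_replicated = vc$n_replicated, n = vc$n)
    for (tis in unique(cs$pairs$tissue)) {
      lv <- rank_sites(cs, "level", tissue = tis, n = cfg$ranking$n)
      vl <- validate_concordance(lv, cs, cs_v, tissue = tis)
      res[[paste0("validation_level_", tis)]] <-
        list(r = vl$r, p_value = vl$p_value,
             median_abs_difference_pct = vl$median_abs_difference_pct,
             n = vl$n)
    }
  }
  dec <- decompose_bs_differences(betas, cs$pairs, n = cfg$ranking$n)
  data.table::fwrite(dec, .art(run_dir, "bs_decomposition.tsv"), sep = "\t")
  res$bs_decomposition <- list(
    n_hmc_driven = attr(dec, "n_hmc_driven"),
    bs_vs_mc_r = attr(dec, "bs_vs_mc_r"))
  jsonlite::write_json(res, .art(run_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  .stage_log(run_dir, "compare", "wrote comparison.json")
  invisible(NULL)
}

.stage_pathways <- function(cfg, run_dir) {
  inp <- .load_inputs(cfg, run_dir)
  if (is.null(inp$gene_sets)) {
    .stage_log(run_dir, "pathways", "no gene sets supplied; skipped")
    return(invisible(NULL))
  }
  cs <- .load_callset(cfg, run_dir)
  det <- rownames(cs$detectable)[rowSums(cs$detectable) > 0]
  idx <- match(det, inp$ann$probe_id)
  test_genes <- unique(unlist(strsplit(inp$ann$genes[idx], ",")))
  test_genes <- test_genes[nzchar(test_genes)]
  uni <- build_universe(inp$ann, inp$gene_sets, test_genes,
                        size_range = c(cfg$pathway$size_min,
                                       cfg$pathway$size_max))
  res <- test_pathways(uni, alpha = cfg$pathway$alpha)
  res <- group_redundant(res, uni, alpha = cfg$pathway$alpha)
  data.table::fwrite(res, .art(run_dir, "pathways.tsv"), sep = "\t")
  .stage_log(run_dir, "pathways",
             sprintf("%d pathways tested, %d significant",
                     nrow(res), sum(res$significant)))
  invisible(NULL)
}

.stage_metagene <- function(cfg, run_dir) {
  inp <- .load_inputs(cfg, run_dir)
  if (is.null(inp$genes)) stop("metagene stage requires gene models")
  cs <- .load_callset(cfg, run_dir)
  det <- rownames(cs$detectable)[rowSums(cs$detectable) > 0]
  sub_ann <- inp$ann[inp$ann$probe_id %in% det, ]
  sigs <- list()
  for (tis in colnames(cs$tissue_mean_delta))
    sigs[[paste0("hmc_", tis)]] <- cs$tissue_mean_delta[, tis]
  if (!is.null(cs$tissue_mean_oxbs))
    for (tis in colnames(cs$tissue_mean_oxbs))
      sigs[[paste0("mc_", tis)]] <- cs$tissue_mean_oxbs[, tis]
  prof <- metagene_profile(sigs, ann = sub_ann, genes = inp$genes,
                           window_width = cfg$metagene$window_width,
                           step = cfg$metagene$step,
                           flank = cfg$metagene$flank)
  data.table::fwrite(prof, .art(run_dir, "metagene_profile.tsv"),
                     sep = "\t")
  .stage_log(run_dir, "metagene", "wrote metagene_profile.tsv")
  invisible(NULL)
}

.stage_export_bed <- function(cfg, run_dir) {
  inp <- .load_inputs(cfg, run_dir)
  cs <- .load_callset(cfg, run_dir)
  suppressWarnings(write_bed(cs, inp$ann, .art(run_dir, "hmc_calls.bed")))
  .stage_log(run_dir, "export-bed", "wrote hmc_calls.bed")
  invisible(NULL)
}

PIPELINE_STAGES <- c("simulate", "qc", "call", "enrich", "compare",
                     "pathways", "metagene", "export-bed")

#' Run the 5hmC pipeline
#'
#' Executes one stage or the full chain.  Stages communicate only
#' through files in `run_dir`, so any stage can be re-run from persisted
#' upstream artifacts.  A JSON manifest with parameters, package/R
#' versions, seed and md5 checksums of all artifacts is written at the
#' end.
#'
#' @param stage One of `"simulate"`, `"qc"`, `"call"`, `"enrich"`,
#'   `"compare"`, `"pathways"`, `"metagene"`, `"export-bed"`, `"all"`.
#' @param config Run configuration: a list (see [default_run_config()])
#'   or a path to a YAML/JSON file.
#' @param run_dir Output directory (created if needed); default a
#'   timestamped directory under the working directory.
#' @return `run_dir`, invisibly.
#' @export
run_pipeline <- function(stage = "all", config = list(),
                         run_dir = file.path("hmc_run",
                                             format(Sys.time(),
                                                    "%Y%m%d_%H%M%S"))) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  stage <- match.arg(stage, c(PIPELINE_STAGES, "all"))
  .validate_config(cfg)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") {
    st <- PIPELINE_STAGES
    if (is.null(cfg$simulate)) st <- setdiff(st, "simulate")
    st
  } else stage
  for (st in stages) {
    fun <- switch(st, simulate = .stage_simulate, qc = .stage_qc,
                  call = .stage_call, enrich = .stage_enrich,
                  compare = .stage_compare, pathways = .stage_pathways,
                  metagene = .stage_metagene,
                  `export-bed` = .stage_export_bed)
    ok <- tryCatch({ fun(cfg, run_dir); TRUE },
                   error = function(e) {
                     .stage_log(run_dir, st, paste("ERROR:",
                                                   conditionMessage(e)))
                     stop("stage '", st, "' failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
  }
  arts <- setdiff(list.files(run_dir, recursive = TRUE),
                  c("manifest.json", "pipeline.log"))
  checks <- as.list(tools::md5sum(file.path(run_dir, arts)))
  names(checks) <- arts
  manifest <- list(package = "hmcquant",
                   version = as.character(utils::packageVersion("hmcquant")),
                   r_version = R.version.string,
                   stages = stages, seed = cfg$seed, config = cfg,
                   checksums = checks)
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE, null = "null")
  invisible(run_dir)
}

#' Command-line entry point
#'
#' `Rscript -e 'hmcquant::hmc_main()' <stage> --config cfg.yaml --out dir`
#'
#' @param args Character vector of arguments (default: command line).
#' @return Exit status, invisibly (0 on success).
#' @export
hmc_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0("usage: hmc_main(c(stage, '--config', path, '--out', dir))\n",
                  "stage: ", paste(c(PIPELINE_STAGES, "all"),
                                   collapse = " | "))
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  stage <- args[1L]
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  config <- get_opt("--config")
  out <- get_opt("--out",
                 file.path("hmc_run", format(Sys.time(), "%Y%m%d_%H%M%S")))
  status <- tryCatch({
    run_pipeline(stage,
                 config = if (is.null(config)) list() else config,
                 run_dir = out)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
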