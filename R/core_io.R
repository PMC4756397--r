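## Readers, validators, sample pairing and BED export.
##
## Conventions: beta/detection-p matrices are plain numeric matrices with
## probe ids as rownames and sample ids as colnames; annotation, sample
## sheets and gene models are plain data.frames.  Annotation coordinates
## are 1-based (array-manifest convention); BED output is 0-based
## half-open.  TSV is the canonical dialect; commas are accepted on read.

TISSUES    <- c("prefrontal_cortex", "cerebellum")
TREATMENTS <- c("bs_zymo", "bs_cegx", "oxbs_cegx")
COHORTS    <- c("discovery", "validation")

CGI_FEATURES  <- c("island", "shore", "shelf", "outside", "unannotated")
GENE_FEATURES <- c("intergenic", "distal_promoter", "proximal_promoter",
                   "gene_body", "downstream", "unannotated")
ALT_EVENTS    <- c("A3SS", "A5SS", "AFE", "ALE", "CE", "CNE", "EI", "II",
                   "IR", "MXE")

#' Validate a beta-value (or detection-p) matrix
#'
#' Checks the invariants shared by beta and detection-p matrices: a numeric
#' matrix, unique non-empty probe and sample identifiers, and every
#' non-missing value in \[0, 1\].
#'
#' @param m Numeric matrix, probes in rows, samples in columns.
#' @param what Label used in error messages ("beta" or "detection p").
#' @return `m`, invisibly, if valid; otherwise an error is thrown naming
#'   the offending probe and sample.
#' @export
validate_beta_matrix <- function(m, what = "beta") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate probe id: ", rownames(m)[duplicated(rownames(m))][1L])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id: ", colnames(m)[duplicated(colnames(m))][1L])
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("%s value %g out of [0,1] at probe '%s', sample '%s'",
                 what, m[bad[1L, 1L], bad[1L, 2L]],
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  invisible(m)
}

# sniff tab vs comma from the header line
.sniff_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0) "\t" else ","
}

#' Read a probes-by-samples beta matrix from TSV/CSV
#'
#' First column holds probe ids, header row holds sample ids, body is
#' numeric.  Values outside \[0, 1\] raise a validation error naming probe
#' and sample; duplicated probe or sample ids raise a format error.
#'
#' @param path Path to a tab- or comma-separated file (dialect sniffed).
#' @param missing_token String(s) treated as missing, default `"NA"`.
#' @param what Passed to [validate_beta_matrix()] for error messages.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path, missing_token = "NA", what = "beta") {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = .sniff_sep(path),
                          na.strings = missing_token, header = TRUE,
                          colClasses = list(character = 1L),
                          data.table = FALSE)
  if (ncol(dt) < 2L) stop("format error: expected probe id column plus samples")
  ids <- dt[[1L]]
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("format error: non-numeric body in ", path)
  rownames(m) <- ids
  validate_beta_matrix(m, what = what)
  m
}

#' Read a detection p-value matrix
#'
#' Same layout and constraints as [read_beta_matrix()]; values are
#' per-probe detection p-values in \[0, 1\].
#'
#' @inheritParams read_beta_matrix
#' @return Numeric matrix of detection p-values.
#' @export
read_detection_p <- function(path, missing_token = "NA") {
  read_beta_matrix(path, missing_token, what = "detection p")
}

#' Write a beta matrix as TSV
#'
#' Inverse of [read_beta_matrix()]; round-trips values and orderings.
#'
#' @param m Matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @export
write_beta_matrix <- function(m, path) {
  validate_beta_matrix(m)
  dt <- data.table::data.table(probe_id = rownames(m), m)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Validate a sample sheet
#'
#' Required columns: `sample_id`, `donor_id`, `tissue`, `treatment`,
#' `cohort`.  Sample ids must be unique and each (donor, tissue, cohort)
#' may carry at most one sample per treatment arm.
#'
#' @param sheet data.frame.
#' @return `sheet`, invisibly.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "donor_id", "tissue", "treatment", "cohort")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!all(sheet$tissue %in% TISSUES))
    stop("unknown tissue: ", setdiff(sheet$tissue, TISSUES)[1L])
  if (!all(sheet$treatment %in% TREATMENTS))
    stop("unknown treatment: ", setdiff(sheet$treatment, TREATMENTS)[1L])
  if (!all(sheet$cohort %in% COHORTS))
    stop("unknown cohort: ", setdiff(sheet$cohort, COHORTS)[1L])
  key <- paste(sheet$donor_id, sheet$tissue, sheet$cohort, sheet$treatment)
  if (anyDuplicated(key))
    stop("more than one sample for a (donor, tissue, treatment) combination")
  invisible(sheet)
}

#' Read a sample sheet from TSV
#'
#' @param path TSV with columns sample_id, donor_id, tissue, treatment,
#'   cohort.
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- data.table::fread(path, sep = .sniff_sep(path), header = TRUE,
                             colClasses = "character", data.table = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' Read a probe annotation table from TSV
#'
#' Expected columns: probe_id, chrom, pos (1-based), cgi_feature,
#' gene_feature, tfbs, dhs, alt_events (comma-separated event codes, empty
#' for not alt-annotated), genes (comma-separated symbols, possibly
#' empty), is_snp_probe, masked.
#'
#' @param path TSV path.
#' @return data.frame with logical tfbs/dhs/is_snp_probe/masked columns.
#' @export
read_probe_annotation <- function(path) {
  ann <- data.table::fread(path, sep = .sniff_sep(path), header = TRUE,
                           data.table = FALSE, na.strings = "NA")
  validate_probe_annotation(ann)
}

#' Validate a probe annotation table
#'
#' @param ann data.frame as described in [read_probe_annotation()].
#' @return `ann` with coerced column types.
#' @export
validate_probe_annotation <- function(ann) {
  need <- c("probe_id", "chrom", "pos", "cgi_feature", "gene_feature",
            "tfbs", "dhs", "alt_events", "genes", "is_snp_probe", "masked")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop("duplicate probe_id in annotation")
  for (col in c("tfbs", "dhs", "is_snp_probe", "masked"))
    ann[[col]] <- as.logical(ann[[col]])
  ann$alt_events <- ifelse(is.na(ann$alt_events), "", ann$alt_events)
  ann$genes <- ifelse(is.na(ann$genes), "", ann$genes)
  bad <- setdiff(ann$cgi_feature, CGI_FEATURES)
  if (length(bad)) stop("unknown cgi_feature: ", bad[1L])
  bad <- setdiff(ann$gene_feature, GENE_FEATURES)
  if (length(bad)) stop("unknown gene_feature: ", bad[1L])
  ann
}

#' Read gene models from TSV
#'
#' Columns: gene_id, chrom, strand (+/-), tx_start, tx_end (1-based
#' inclusive, tx_start <= tx_end).
#'
#' @param path TSV path.
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  g <- data.table::fread(path, sep = .sniff_sep(path), header = TRUE,
                         data.table = FALSE)
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("gene models missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(g$tx_start > g$tx_end)) stop("gene with tx_start > tx_end")
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  g
}

#' Pair BS and oxBS arms per donor and tissue
#'
#' Builds one pair per (donor, tissue, cohort) possessing both a
#' `bs_cegx` and an `oxbs_cegx` sample; the optional `bs_zymo` arm is
#' attached when present.  Incomplete pairs are dropped and recorded in
#' the `unpaired` attribute.
#'
#' @param sheet Sample sheet data.frame (see [read_sample_sheet()]).
#' @param betas Optional beta matrix; when given, every sheet sample id
#'   must be one of its columns.
#' @return data.frame of class `hmc_pairs` with columns `pair_id`,
#'   `donor_id`, `tissue`, `cohort`, `bs_sample`, `oxbs_sample`,
#'   `zymo_sample` (NA when absent), ordered by cohort, tissue, donor.
#'   Attribute `unpaired` lists samples not in any complete pair.
#' @export
pair_samples <- function(sheet, betas = NULL) {
  validate_sample_sheet(sheet)
  if (!is.null(betas)) {
    unknown <- setdiff(sheet$sample_id, colnames(betas))
    if (length(unknown))
      stop("sample sheet references unknown sample_id: ", unknown[1L])
  }
  key <- interaction(sheet$donor_id, sheet$tissue, sheet$cohort, drop = TRUE)
  rows <- lapply(split(sheet, key), function(s) {
    bs  <- s$sample_id[s$treatment == "bs_cegx"]
    ox  <- s$sample_id[s$treatment == "oxbs_cegx"]
    zy  <- s$sample_id[s$treatment == "bs_zymo"]
    if (length(bs) != 1L || length(ox) != 1L) return(NULL)
    data.frame(donor_id = s$donor_id[1L], tissue = s$tissue[1L],
               cohort = s$cohort[1L], bs_sample = bs, oxbs_sample = ox,
               zymo_sample = if (length(zy)) zy else NA_character_,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || !nrow(pairs))
    stop("no complete BS/oxBS pairs in sample sheet")
  pairs <- pairs[order(pairs$cohort, pairs$tissue, pairs$donor_id), ,
                 drop = FALSE]
  pairs$pair_id <- paste(pairs$donor_id, pairs$tissue, pairs$cohort,
                         sep = ".")
  rownames(pairs) <- NULL
  pairs <- pairs[, c("pair_id", "donor_id", "tissue", "cohort",
                     "bs_sample", "oxbs_sample", "zymo_sample")]
  used <- c(pairs$bs_sample, pairs$oxbs_sample,
            pairs$zymo_sample[!is.na(pairs$zymo_sample)])
  attr(pairs, "unpaired") <- setdiff(sheet$sample_id, used)
  class(pairs) <- c("hmc_pairs", "data.frame")
  pairs
}

#' Export tissue-mean 5hmC calls as a BED track
#'
#' Writes one BED6 line per probe with coordinates for the CpG
#' dinucleotide (0-based half-open: `pos - 1` to `pos + 1`), the probe id
#' plus per-tissue mean delta-beta in the name field, and the first
#' tissue's mean (scaled to 0-1000, clamped) as score.  Probes without
#' coordinates are skipped and counted.
#'
#' @param callset An `hmc_callset` (see [call_detectable()]).
#' @param ann Probe annotation covering the callset probes.
#' @param path Output path.
#' @param which One of "detectable" (default: union of detectable probes)
#'   or "all".
#' @return `path`, invisibly; attribute `n_skipped` gives the count of
#'   probes lacking coordinates.
#' @export
write_bed <- function(callset, ann, path, which = c("detectable", "all")) {
  which <- match.arg(which)
  stopifnot(inherits(callset, "hmc_callset"))
  tm <- callset$tissue_mean_delta
  keep <- if (which == "detectable")
    rownames(tm)[rowSums(callset$detectable, na.rm = TRUE) > 0]
  else rownames(tm)
  idx <- match(keep, ann$probe_id)
  missing_coord <- is.na(idx) | is.na(ann$pos[idx]) | is.na(ann$chrom[idx])
  n_skipped <- sum(missing_coord)
  if (n_skipped) warning(n_skipped, " probe(s) without coordinates skipped")
  keep <- keep[!missing_coord]; idx <- idx[!missing_coord]
  hdr <- sprintf("track name=hmc_mean_delta_beta description=\"tissue mean delta-beta (%s)\"",
                 paste(colnames(tm), collapse = "/"))
  if (!length(keep)) {
    writeLines(hdr, path)
    out <- path; attr(out, "n_skipped") <- n_skipped
    return(invisible(out))
  }
  vals <- tm[keep, , drop = FALSE]
  name <- paste0(keep, "|",
                 apply(vals, 1L, function(v)
                   paste(sprintf("%s=%.4f", colnames(tm), v), collapse = ";")))
  score <- pmin(1000L, pmax(0L, as.integer(round(vals[, 1L] * 1000))))
  score[is.na(score)] <- 0L
  bed <- data.frame(chrom = ann$chrom[idx], start = ann$pos[idx] - 1L,
                    end = ann$pos[idx] + 1L, name = name, score = score,
                    strand = ".", stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start), ]
  writeLines(hdr, path)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE,
                     append = TRUE, quote = FALSE)
  out <- path; attr(out, "n_skipped") <- n_skipped
  invisible(out)
}
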