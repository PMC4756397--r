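## Canonical-gene ("metagene") sliding-window profiles.  Every gene is
## mapped to a common normalised axis: 5 kb upstream flank -> [-10, 0),
## gene body (TSS to TES, strand-aware) -> [0, 100], 5 kb downstream
## flank -> (100, 110].  One axis unit over the body corresponds to 1
## percent of gene length, so 1-unit windows are "1 percent windows".

#' Map a probe position onto the normalised gene axis
#'
#' Strand-aware: minus-strand genes are coordinate-flipped so the TSS is
#' always at 0 and the TES at 100.  Positions outside gene +/- flank map
#' to NA.
#'
#' @param pos Integer vector of probe positions (1-based).
#' @param gene One-row gene model (gene_id, chrom, strand, tx_start,
#'   tx_end); chromosome agreement is the caller's responsibility.
#' @param flank Flank width in bp (default 5000), mapped to 10 axis
#'   units on each side.
#' @return Numeric vector of axis coordinates in \[-10, 110\] or NA.
#' @export
map_probe_to_axis <- function(pos, gene, flank = 5000) {
  start <- gene$tx_start; end <- gene$tx_end
  if (end <= start) stop("zero-length gene: ", gene$gene_id)
  len <- end - start
  if (gene$strand == "+") {
    up   <- pos >= start - flank & pos < start
    body <- pos >= start & pos <= end
    down <- pos > end & pos <= end + flank
    ax <- rep(NA_real_, length(pos))
    ax[up]   <- -10 + 10 * (pos[up] - (start - flank)) / flank
    ax[body] <- 100 * (pos[body] - start) / len
    ax[down] <- 100 + 10 * (pos[down] - end) / flank
  } else {
    up   <- pos > end & pos <= end + flank
    body <- pos >= start & pos <= end
    down <- pos >= start - flank & pos < start
    ax <- rep(NA_real_, length(pos))
    ax[up]   <- -10 + 10 * ((end + flank) - pos[up]) / flank
    ax[body] <- 100 * (end - pos[body]) / len
    ax[down] <- 100 + 10 * (start - pos[down]) / flank
  }
  ax
}

#' Assign probes to genes on the normalised axis
#'
#' Each probe is assigned to every gene on the same chromosome within
#' gene +/- flank; probes hitting several genes contribute one assignment
#' per gene.
#'
#' @param ann Probe annotation (probe_id, chrom, pos).
#' @param genes Gene-model data.frame.
#' @param flank Flank width in bp (default 5000).
#' @return data.frame `probe_id`, `gene_id`, `axis`.
#' @export
map_probes_to_genes <- function(ann, genes, flank = 5000) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    on_chr <- which(ann$chrom == g$chrom &
                    ann$pos >= g$tx_start - flank &
                    ann$pos <= g$tx_end + flank)
    if (!length(on_chr)) return(NULL)
    ax <- map_probe_to_axis(ann$pos[on_chr], g, flank)
    keep <- !is.na(ax)
    if (!any(keep)) return(NULL)
    data.frame(probe_id = ann$probe_id[on_chr][keep], gene_id = g$gene_id,
               axis = ax[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(probe_id = character(),
                                      gene_id = character(),
                                      axis = numeric())
  out
}

#' Sliding-window metagene profile
#'
#' Averages one or more per-probe signals (e.g. tissue-mean delta-beta
#' for 5hmC, tissue-mean oxBS beta for 5mC) over overlapping windows of
#' the normalised gene axis.  Window \[x, x + width) for starts x from
#' -10 in steps of `step`; the final window is closed on the right so the
#' axis endpoint 110 is covered.  Empty windows are reported with n = 0
#' and NA mean, never interpolated.
#'
#' @param signals Named list of numeric vectors (or a matrix with probe
#'   rownames and trace colnames): per-probe signal per trace.
#' @param assignments data.frame from [map_probes_to_genes()], or `ann`
#'   and `genes` to compute it.
#' @param ann,genes Used when `assignments` is NULL.
#' @param window_width Window width in axis units (default 1 = 1 percent
#'   of gene length).
#' @param step Window step in axis units (default 0.5, overlapping).
#' @param flank Flank width in bp when assignments are computed here.
#' @return data.frame: `window_start`, `window_end`, `trace`, `mean`,
#'   `n` (probe-gene assignments in window).
#' @export
metagene_profile <- function(signals, assignments = NULL, ann = NULL,
                             genes = NULL, window_width = 1, step = 0.5,
                             flank = 5000) {
  if (is.matrix(signals))
    signals <- stats::setNames(
      lapply(seq_len(ncol(signals)), function(j)
        stats::setNames(signals[, j], rownames(signals))),
      colnames(signals))
  if (is.null(assignments)) {
    if (is.null(ann) || is.null(genes))
      stop("supply assignments, or ann and genes")
    assignments <- map_probes_to_genes(ann, genes, flank)
  }
  if (!nrow(assignments)) stop("no probe-gene assignments")
  starts <- seq(-10, 110 - window_width, by = step)
  last <- length(starts)
  rows <- lapply(names(signals), function(tr) {
    sig <- signals[[tr]][assignments$probe_id]
    res <- vapply(seq_along(starts), function(i) {
      lo <- starts[i]; hi <- starts[i] + window_width
      inw <- assignments$axis >= lo &
        (if (i == last) assignments$axis <= hi else assignments$axis < hi)
      v <- sig[inw]
      v <- v[!is.na(v)]
      c(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
    }, numeric(2L))
    data.frame(window_start = starts, window_end = starts + window_width,
               trace = tr, mean = res["mean", ], n = as.integer(res["n", ]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
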