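## Gene-set (GO-style) enrichment by logistic regression.  For each
## pathway, per-gene membership (0/1) is regressed on membership of the
## test gene list plus the number of array probes annotated to the gene;
## the probe-count covariate removes the bias whereby heavily-probed
## genes are more likely both to enter the test list and to sit in large
## pathways.  Redundant significant pathways are grouped by iterative
## conditioning on the best remaining term.

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated: id, description, then
#' member genes.
#'
#' @param path GMT path.
#' @return Named list mapping pathway id to a character vector of genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1L), 1L)
  if (anyDuplicated(ids)) stop("duplicate pathway id in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (pathway id to genes).
#' @param path Output path.
#' @param description Optional per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- mapply(function(id, genes, desc)
    paste(c(id, desc, genes), collapse = "\t"),
    names(sets), sets, rep_len(description, length(sets)))
  writeLines(unname(lines), path)
  invisible(path)
}

# transitive propagation of pathway membership to ancestor terms;
# edges: data.frame(child, parent).  Errors on cycles.
.propagate_parents <- function(sets, edges) {
  nodes <- unique(c(edges$child, edges$parent, names(sets)))
  # Kahn topological order: children must be processed before parents so
  # that propagation is transitive in a single pass
  dep_count <- table(factor(edges$parent, levels = nodes))
  deg <- as.integer(dep_count); names(deg) <- nodes
  order <- character(0)
  queue <- nodes[deg == 0L]
  parents_of <- split(edges$parent, edges$child)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (p in parents_of[[v]]) {
      deg[p] <- deg[p] - 1L
      if (deg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order) < length(nodes))
    stop("cyclic parent graph in ontology edges")
  for (v in order) {
    for (p in parents_of[[v]]) {
      sets[[p]] <- unique(c(sets[[p]], sets[[v]]))
    }
  }
  sets
}

#' Build the gene universe for pathway testing
#'
#' Tallies probes per gene from the annotation, optionally propagates
#' pathway memberships to ancestor terms through a child-parent edge
#' list, drops genes without probes or without any pathway, and filters
#' pathways to those with `size_range` member genes (inclusive bounds)
#' within the universe.
#'
#' @param ann Probe annotation (the `genes` column, comma-separated
#'   symbols, supplies probe counts).
#' @param gene_sets Named list: pathway id to character vector of genes
#'   (e.g. from [read_gmt()]).
#' @param test_genes Character vector, the test gene list (e.g. genes
#'   annotated to detectable-5hmC probes).
#' @param parent_edges Optional data.frame with columns `child`,
#'   `parent`; memberships are propagated transitively to ancestors
#'   before size filtering.  A cyclic graph is an error.
#' @param size_range Inclusive pathway-size bounds, default c(10, 2000).
#' @return Object of class `gene_universe`: list with `genes`
#'   (data.frame gene_id, n_probes, in_test_list) and `pathways` (named
#'   list of gene-id vectors restricted to the universe).
#' @export
build_universe <- function(ann, gene_sets, test_genes,
                           parent_edges = NULL,
                           size_range = c(10L, 2000L)) {
  if (!length(gene_sets)) stop("empty gene sets")
  gl <- strsplit(ann$genes, ",", fixed = TRUE)
  tab <- table(unlist(gl))
  counts <- data.frame(gene_id = names(tab), n_probes = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[nzchar(counts$gene_id) & counts$n_probes >= 1L, ]
  if (!is.null(parent_edges))
    gene_sets <- .propagate_parents(gene_sets, parent_edges)
  with_pathway <- unique(unlist(gene_sets))
  genes <- counts[counts$gene_id %in% with_pathway, , drop = FALSE]
  pathways <- lapply(gene_sets, intersect, y = genes$gene_id)
  sizes <- lengths(pathways)
  pathways <- pathways[sizes >= size_range[1L] & sizes <= size_range[2L]]
  genes$in_test_list <- genes$gene_id %in% test_genes
  rownames(genes) <- NULL
  structure(list(genes = genes, pathways = pathways),
            class = "gene_universe")
}

# Firth-penalised logistic regression (Jeffreys prior): Newton iteration
# on the modified score U(b) = X'(y - p + h (0.5 - p)).  Used as the
# fallback when the ML fit separates.
.firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(info_inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(info_inv))
  list(coef = beta, se = se)
}

.wald_row <- function(coef, se) {
  z <- coef / se
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

# core fit: membership ~ in_test_list + n_probes [+ extra member column]
.fit_pathway <- function(universe, pathway_id, covariate = "raw",
                         condition_on = NULL, alpha = 0.05) {
  g <- universe$genes
  y <- as.integer(g$gene_id %in% universe$pathways[[pathway_id]])
  np <- if (covariate == "log") log(g$n_probes) else g$n_probes
  df <- data.frame(y = y, in_list = as.integer(g$in_test_list),
                   n_probes = np)
  form <- y ~ in_list + n_probes
  if (!is.null(condition_on)) {
    df$leader <- as.integer(g$gene_id %in% universe$pathways[[condition_on]])
    form <- y ~ in_list + n_probes + leader
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = df))
  sm <- summary(fit)$coefficients
  if (!"in_list" %in% rownames(sm)) {
    # the test-list indicator is constant (or aliased): no information
    return(list(coefficient = 0, se = NA_real_, p_value = 1,
                separated = FALSE))
  }
  coef <- sm["in_list", "Estimate"]
  se <- sm["in_list", "Std. Error"]
  separated <- !fit$converged || abs(coef) > 15 || se > 100
  if (separated) {
    X <- stats::model.matrix(form, df)
    ff <- .firth_logistic(X, df$y)
    i <- match("in_list", colnames(X))
    coef <- ff$coef[i]; se <- ff$se[i]
  }
  list(coefficient = coef, se = se, p_value = .wald_row(coef, se),
       separated = separated)
}

#' Test one pathway for enrichment of the test gene list
#'
#' Logistic regression of per-gene pathway membership on test-list
#' membership and probe count; the Wald p-value of the test-list
#' coefficient measures enrichment (requiring a positive coefficient).
#' Perfect separation is detected and refitted by a Firth
#' penalised-likelihood fallback, flagged in the result.
#'
#' @param universe A `gene_universe` from [build_universe()].
#' @param pathway_id Pathway to test.
#' @param covariate `"raw"` (default) or `"log"` probe count.
#' @param alpha Significance level used for the `significant` flag.
#' @return One-row data.frame: pathway_id, n_genes, coefficient
#'   (log-odds), se, p_value, significant (p < alpha and coefficient >
#'   0), separated.
#' @export
test_pathway <- function(universe, pathway_id, covariate = c("raw", "log"),
                         alpha = 0.05) {
  covariate <- match.arg(covariate)
  stopifnot(inherits(universe, "gene_universe"))
  if (!pathway_id %in% names(universe$pathways))
    stop("pathway not in universe: ", pathway_id)
  f <- .fit_pathway(universe, pathway_id, covariate)
  data.frame(pathway_id = pathway_id,
             n_genes = length(universe$pathways[[pathway_id]]),
             coefficient = f$coefficient, se = f$se, p_value = f$p_value,
             significant = f$p_value < alpha & f$coefficient > 0,
             separated = f$separated, stringsAsFactors = FALSE)
}

#' Test every pathway in the universe
#'
#' @inheritParams test_pathway
#' @return data.frame, one row per pathway, sorted by p-value ascending
#'   (ties broken by pathway id).
#' @export
test_pathways <- function(universe, covariate = c("raw", "log"),
                          alpha = 0.05) {
  covariate <- match.arg(covariate)
  res <- do.call(rbind, lapply(names(universe$pathways), function(p)
    test_pathway(universe, p, covariate, alpha)))
  res <- res[order(res$p_value, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Group redundant significant pathways
#'
#' Iteratively takes the most significant ungrouped pathway as leader and
#' retests every remaining ungrouped significant pathway while
#' additionally conditioning on membership of the leader; pathways whose
#' test-list term is no longer significant (p >= alpha) are marked
#' `explained_by` the leader.  Repeats with the next ungrouped leader
#' until every significant pathway is a leader or explained.
#'
#' @param results data.frame from [test_pathways()].
#' @param universe The `gene_universe` the results came from.
#' @param covariate `"raw"` or `"log"` probe count, as in the first pass.
#' @param alpha Significance gate (default 0.05).
#' @return `results` with added columns `group_leader` (leader id for
#'   every significant pathway, itself for leaders) and `explained_by`
#'   (NA for leaders and non-significant pathways).
#' @export
group_redundant <- function(results, universe,
                            covariate = c("raw", "log"), alpha = 0.05) {
  covariate <- match.arg(covariate)
  results <- results[order(results$p_value, results$pathway_id), ,
                     drop = FALSE]
  results$group_leader <- NA_character_
  results$explained_by <- NA_character_
  sig <- which(results$significant)
  open <- sig
  while (length(open)) {
    lead_i <- open[1L]
    leader <- results$pathway_id[lead_i]
    results$group_leader[lead_i] <- leader
    open <- open[-1L]
    if (!length(open)) break
    still <- logical(length(open))
    for (j in seq_along(open)) {
      pid <- results$pathway_id[open[j]]
      f <- tryCatch(
        .fit_pathway(universe, pid, covariate, condition_on = leader),
        error = function(e) NULL)
      if (is.null(f)) { still[j] <- TRUE; next }   # fit failure: stays open
      if (f$p_value >= alpha || f$coefficient <= 0) {
        results$group_leader[open[j]] <- leader
        results$explained_by[open[j]] <- leader
      } else {
        still[j] <- TRUE
      }
    }
    open <- open[still]
  }
  rownames(results) <- NULL
  results
}
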