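# deliberately independent logistic-regression oracle: plain IRLS
oracle_logistic <- function(X, y, max_iter = 100L) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    p <- plogis(drop(X %*% beta))
    W <- p * (1 - p)
    info <- crossprod(X, X * W)
    step <- solve(info, crossprod(X, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  list(coef = beta, se = se, p = 2 * pnorm(abs(z), lower.tail = FALSE))
}

mk_universe <- function(genes, pathways, test_genes) {
  genes$in_test_list <- genes$gene_id %in% test_genes
  structure(list(genes = genes, pathways = pathways),
            class = "gene_universe")
}

test_that("build_universe tallies probes, propagates parents, filters", {
  ann <- mk_ann(sprintf("cg%02d", 1:12),
                genes = c("g1", "g1", "g1,g2", "g2", "g3", "g3", "g4",
                          "g5", "g6", "g7", "g8", ""))
  sets <- list(T = c("g1"), P = c("g2"),
               big = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8"),
               small9 = paste0("g", 1:8))   # will fall below min size
  edges <- data.frame(child = "T", parent = "P")
  uni <- build_universe(ann, sets, test_genes = c("g1", "g3"),
                        parent_edges = edges, size_range = c(2L, 8L))
  # g1 was propagated from child T into parent P
  expect_setequal(uni$pathways$P, c("g1", "g2"))
  # probe counts tallied from comma-separated annotation
  expect_equal(uni$genes$n_probes[uni$genes$gene_id == "g1"], 3L)
  expect_equal(uni$genes$n_probes[uni$genes$gene_id == "g2"], 2L)
  # T (1 gene) dropped below min size 2; sets within [2, 8] kept
  expect_false("T" %in% names(uni$pathways))
  expect_true(all(c("P", "big") %in% names(uni$pathways)))

  # inclusive size bounds: exactly min kept, min - 1 dropped
  uni2 <- build_universe(ann, sets, test_genes = "g1",
                         size_range = c(8L, 10L))
  expect_true("big" %in% names(uni2$pathways))   # size 8 == lower bound
  expect_false("P" %in% names(uni2$pathways))

  # cyclic ontology is an error
  cyc <- data.frame(child = c("T", "P"), parent = c("P", "T"))
  expect_error(build_universe(ann, sets, "g1", parent_edges = cyc),
               "cyclic")
})

test_that("parent propagation equals a brute-force reachability oracle", {
  # 3-level chain A -> B -> C with memberships only at the leaf
  sets <- list(A = c("g1", "g2"), B = character(0), C = character(0))
  edges <- data.frame(child = c("A", "B"), parent = c("B", "C"))
  ann <- mk_ann(sprintf("cg%02d", 1:4),
                genes = c("g1", "g2", "g3", "g3"))
  uni <- build_universe(ann, c(sets, list(other = c("g1", "g2", "g3"))),
                        test_genes = "g1", parent_edges = edges,
                        size_range = c(1L, 10L))
  # DFS closure oracle
  reach <- function(node, e) {
    out <- node
    repeat {
      nxt <- unique(e$parent[e$child %in% out])
      if (all(nxt %in% out)) return(out)
      out <- unique(c(out, nxt))
    }
  }
  for (g in c("g1", "g2")) {
    holds <- names(uni$pathways)[vapply(uni$pathways, function(s)
      g %in% s, logical(1))]
    expect_setequal(setdiff(holds, "other"), reach("A", edges))
  }
})

test_that("test_pathway is null on balanced designs and matches the oracle", {
  # 100 genes, 50 in pathway, 50 in list, overlap exactly 25, equal
  # probe counts: exact independence, coefficient 0
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      n_probes = 5L, stringsAsFactors = FALSE)
  pw <- list(pw1 = genes$gene_id[1:50])
  test_list <- genes$gene_id[c(1:25, 51:75)]
  uni <- mk_universe(genes, pw, test_list)
  res <- test_pathway(uni, "pw1")
  expect_lt(abs(res$coefficient), 1e-8)
  expect_gt(res$p_value, 0.99)
  expect_false(res$significant)

  # oracle comparison on an unbalanced random design
  set.seed(61)
  genes$n_probes <- rpois(100, 10) + 1L
  test_list <- sample(genes$gene_id, 40)
  pw <- list(pw1 = sample(genes$gene_id, 30))
  uni <- mk_universe(genes, pw, test_list)
  res <- test_pathway(uni, "pw1")
  X <- cbind(1, as.integer(uni$genes$in_test_list), uni$genes$n_probes)
  y <- as.integer(genes$gene_id %in% pw$pw1)
  orc <- oracle_logistic(X, y)
  expect_equal(res$coefficient, orc$coef[2], tolerance = 1e-6)
  expect_equal(res$p_value, orc$p[2], tolerance = 1e-6)
})

test_that("the probe-count covariate removes confounded false positives", {
  # membership and list membership both driven solely by probe count
  set.seed(67)
  n <- 1500L
  genes <- data.frame(gene_id = sprintf("g%04d", 1:n),
                      n_probes = pmax(1L, rnbinom(n, mu = 17, size = 2)))
  z <- as.numeric(scale(genes$n_probes))
  member <- runif(n) < plogis(qlogis(0.15) + 1.2 * z)
  test_list <- genes$gene_id[runif(n) < plogis(qlogis(0.3) + 1.2 * z)]
  uni <- mk_universe(genes, list(pw1 = genes$gene_id[member]), test_list)

  adjusted <- test_pathway(uni, "pw1")
  # naive fit without the covariate, via the independent IRLS oracle
  X0 <- cbind(1, as.integer(uni$genes$in_test_list))
  naive <- oracle_logistic(X0, as.integer(member))
  expect_lt(naive$p[2], 0.05)          # confounding fools the naive test
  expect_gt(adjusted$p_value, 0.05)    # covariate control rescues it
})

test_that("perfect separation falls back to a penalised fit", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60),
                      n_probes = rep(c(3L, 7L), 30))
  pw <- list(pw1 = genes$gene_id[1:20])
  uni <- mk_universe(genes, pw, genes$gene_id[1:20])  # list == pathway
  res <- test_pathway(uni, "pw1")
  expect_true(res$separated)
  expect_true(is.finite(res$coefficient))
  expect_true(is.finite(res$p_value))
  expect_true(res$significant)
})

test_that("group_redundant collapses duplicates and keeps independent hits", {
  set.seed(71)
  n <- 800L
  genes <- data.frame(gene_id = sprintf("g%04d", 1:n),
                      n_probes = rpois(n, 10) + 1L)
  # two disjoint true signals + an exact duplicate of the first
  sig1 <- genes$gene_id[1:80]
  sig2 <- genes$gene_id[101:180]
  test_list <- c(sample(sig1, 48), sample(sig2, 48),
                 sample(genes$gene_id[201:n], 120))
  pw <- list(alpha = sig1, alpha_copy = sig1, beta = sig2,
             noise1 = sample(genes$gene_id, 60),
             noise2 = sample(genes$gene_id, 200))
  uni <- mk_universe(genes, pw, test_list)
  res <- test_pathways(uni)
  res <- group_redundant(res, uni)

  sig <- res[res$significant, ]
  expect_true(all(c("alpha", "alpha_copy", "beta") %in% sig$pathway_id))
  # identical twin is absorbed by the better-ranked copy
  twin <- sig[sig$pathway_id %in% c("alpha", "alpha_copy"), ]
  expect_equal(sum(is.na(twin$explained_by)), 1L)
  expect_equal(twin$explained_by[!is.na(twin$explained_by)],
               twin$pathway_id[is.na(twin$explained_by)])
  # the disjoint signal stays its own leader
  expect_true(is.na(res$explained_by[res$pathway_id == "beta"]))
  # grouping is a partition over significant pathways
  expect_true(all(!is.na(sig$group_leader)))
  # a single significant pathway is its own leader
  uni1 <- mk_universe(genes, pw["alpha"], test_list)
  r1 <- group_redundant(test_pathways(uni1), uni1)
  expect_equal(r1$group_leader[r1$pathway_id == "alpha"], "alpha")
})

test_that("GMT round-trips", {
  sets <- list(pw1 = c("g1", "g2", "g3"), pw2 = c("g4"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_identical(read_gmt(f), sets)
})
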