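# Group-average (UPGMA) hierarchical clustering with SIMPROF
# significance testing of cluster structure.

#' Group-average (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering in which the distance between two clusters
#' is the arithmetic mean of all cross-pair dissimilarities.  Samples
#' are ordered lexicographically by label before clustering so that
#' tied merges resolve deterministically regardless of input order.
#'
#' @param d a [dissimilarity_matrix] or symmetric matrix.
#' @return An object of class `upgma_dendrogram`: the underlying
#'   `hclust` object (`hc`), `sample_ids`, and `node_sets` — for each
#'   internal node, its merge `height` and the sample labels beneath it
#'   (root last).
#' @export
upgma <- function(d) {
  dv <- as_dissim_values(d)
  if (nrow(dv) < 2L) stop("clustering needs at least 2 samples")
  ids <- rownames(dv)
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(dv)))
  ord <- order(ids)
  dvo <- dv[ord, ord]
  hc <- stats::hclust(stats::as.dist(dvo), method = "average")
  sets <- vector("list", nrow(hc$merge))
  members <- function(k) {
    if (k < 0) hc$labels[-k] else sets[[k]]$samples
  }
  for (i in seq_len(nrow(hc$merge))) {
    sets[[i]] <- list(
      height = hc$height[i],
      children = lapply(hc$merge[i, ], members),
      samples = sort(c(members(hc$merge[i, 1L]),
                       members(hc$merge[i, 2L]))))
  }
  structure(list(hc = hc, sample_ids = ids, node_sets = sets),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram over", length(x$sample_ids), "samples; root height",
      signif(max(x$hc$height), 4), "\n")
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths position each node at its merge height.
#'
#' @param dend an `upgma_dendrogram` from [upgma()].
#' @param path optional file path; if `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

# Sorted vector of within-subset pairwise dissimilarities of an
# abundance matrix (the "similarity profile" on the dissimilarity
# scale).
profile_of <- function(ab) {
  d <- bc_dissim(ab, warn = FALSE)
  sort(d[lower.tri(d)])
}

#' SIMPROF test for multivariate structure
#'
#' Tests whether a set of samples contains multivariate structure
#' beyond what independent taxa would produce.  The observed profile is
#' the sorted vector of all within-set pairwise Bray-Curtis
#' dissimilarities; null profiles are generated by independently
#' permuting each taxon's values across the samples.  The statistic
#' `pi = sum_k |s_(k) - sbar_(k)|` measures departure from the mean
#' null profile (from `n_perm_mean` permutations); its p-value comes
#' from `n_perm_test` further permutations compared against the same
#' mean profile, with the `(1 + x)/(1 + B)` convention.
#'
#' The permutation stream is consumed in sorted-label order, so
#' reordering input rows or columns cannot change the result.
#'
#' @param m a [community_matrix], already transformed as for the
#'   dissimilarities under study.
#' @param subset sample ids or indices to test (default: all samples);
#'   sets of fewer than 3 samples are untestable and return the verdict
#'   `"no structure"` without a test.
#' @param n_perm_mean permutations used for the mean null profile
#'   (default 1000).
#' @param n_perm_test permutations used for the p-value (default 999).
#' @param alpha significance level in (0, 1) (default 0.05).
#' @param seed integer seed.
#' @return An object of class `simprof_result`: `pi`, `P_perm`,
#'   `n_perm`, `verdict` (`"structure"` / `"no structure"`), `tested`,
#'   `samples`, `alpha`.
#' @export
simprof_test <- function(m, subset = NULL, n_perm_mean = 1000,
                         n_perm_test = 999, alpha = 0.05, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  ab <- m$abundance
  if (is.null(subset)) subset <- rownames(ab)
  idx <- resolve_idx(subset, rownames(ab))
  samples <- rownames(ab)[idx]
  if (length(idx) < 3L) {
    return(structure(list(pi = NA_real_, P_perm = NA_real_, n_perm = 0L,
                          verdict = "no structure", tested = FALSE,
                          samples = samples, alpha = alpha),
                     class = "simprof_result"))
  }
  # label-keyed ordering: the RNG stream is tied to sorted labels, not
  # input positions
  X <- ab[idx[order(samples)], order(colnames(ab)), drop = FALSE]
  n <- nrow(X)
  obs <- profile_of(X)

  res <- with_seed(seed, {
    perm_profile <- function() {
      Xp <- X
      for (k in seq_len(ncol(X))) Xp[, k] <- X[sample.int(n), k]
      profile_of(Xp)
    }
    mean_prof <- rowMeans(vapply(seq_len(n_perm_mean),
                                 function(i) perm_profile(),
                                 numeric(length(obs))))
    pi_obs <- sum(abs(obs - mean_prof))
    cnt <- 0L
    for (b in seq_len(n_perm_test)) {
      pi_b <- sum(abs(perm_profile() - mean_prof))
      if (pi_b >= pi_obs - stat_tol(pi_obs)) cnt <- cnt + 1L
    }
    list(pi = pi_obs, p = (1 + cnt) / (1 + n_perm_test))
  })

  structure(list(pi = res$pi, P_perm = res$p, n_perm = n_perm_test,
                 verdict = if (res$p <= alpha) "structure" else "no structure",
                 tested = TRUE, samples = samples, alpha = alpha),
            class = "simprof_result")
}

#' @export
print.simprof_result <- function(x, ...) {
  if (!x$tested) {
    cat("SIMPROF: untestable set of", length(x$samples),
        "sample(s) -> no structure\n")
  } else {
    cat(sprintf("SIMPROF: pi = %.4g, P(perm) = %.4g (%d perms) -> %s\n",
                x$pi, x$P_perm, x$n_perm, x$verdict))
  }
  invisible(x)
}

#' SIMPROF-validated cluster assignment
#'
#' Traverses the UPGMA tree top-down: the root's sample set is tested
#' with [simprof_test()]; where structure is significant the traversal
#' recurses into both children, and it stops at nodes whose test is
#' non-significant — those sample sets (and untestable sets of fewer
#' than 3 samples) are the output clusters, interpreted as internally
#' homogeneous groups.
#'
#' @param m a transformed [community_matrix].
#' @param d optional [dissimilarity_matrix] derived from `m` (computed
#'   with [bray_curtis()] if missing).
#' @param alpha significance level (default 0.05).
#' @param n_perm_mean,n_perm_test,seed passed to [simprof_test()]; each
#'   node receives a deterministic sub-seed keyed on its sample labels.
#' @return An object of class `simprof_clusters`: `cluster` (named
#'   assignment per sample), `tests` (per-node results), `tree`.
#' @export
significant_clusters <- function(m, d = NULL, alpha = 0.05,
                                 n_perm_mean = 1000, n_perm_test = 999,
                                 seed = NULL) {
  if (is.null(d)) d <- suppressWarnings(bray_curtis(m))
  tree <- upgma(d)
  tests <- list()
  clusters <- list()
  visit <- function(samples) {
    res <- simprof_test(m, subset = samples, n_perm_mean = n_perm_mean,
                        n_perm_test = n_perm_test, alpha = alpha,
                        seed = subseed(seed, paste(sort(samples),
                                                   collapse = "|")))
    tests[[length(tests) + 1L]] <<- res
    if (identical(res$verdict, "structure")) {
      node <- find_node(tree, samples)
      for (child in node$children) visit(child)
    } else {
      clusters[[length(clusters) + 1L]] <<- samples
    }
  }
  root <- tree$node_sets[[length(tree$node_sets)]]$samples
  visit(root)
  assign <- character(length(tree$sample_ids))
  names(assign) <- tree$sample_ids
  for (k in seq_along(clusters))
    assign[clusters[[k]]] <- paste0("cluster", k)
  structure(list(cluster = assign, tests = tests, tree = tree,
                 alpha = alpha),
            class = "simprof_clusters")
}

find_node <- function(tree, samples) {
  key <- paste(sort(samples), collapse = "|")
  for (ns in tree$node_sets)
    if (identical(paste(ns$samples, collapse = "|"), key)) return(ns)
  # a set of size 1 or an unmatched set has no internal node
  stop("internal: no dendrogram node for the given sample set")
}

#' @export
print.simprof_clusters <- function(x, ...) {
  k <- length(unique(x$cluster))
  cat("SIMPROF-validated clusters at alpha =", x$alpha, ":", k,
      "cluster(s)\n")
  print(table(x$cluster))
  invisible(x)
}
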