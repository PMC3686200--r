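# Gower centering, principal coordinates, and centroid-distance
# identities.  These let PERMANOVA, PERMDISP and the control charts work
# directly in (possibly semimetric) Bray-Curtis space without an
# explicit ordination of the data.

as_dissim_values <- function(d) {
  if (inherits(d, "dissimilarity_matrix")) d$values
  else {
    d <- as.matrix(d)
    if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity input is not symmetric")
    d
  }
}

#' Gower-centred inner-product matrix of a dissimilarity matrix
#'
#' Computes `G = -1/2 J A J` with `A_ij = d_ij^2` and
#' `J = I - 11'/N`.  `G` hosts the centroid geometry of the samples:
#' its trace is the total sum of squares `(1/N) sum_{i<j} d_ij^2`.
#'
#' @param d a [dissimilarity_matrix] (or symmetric matrix).
#' @return An object of class `gower_matrix` with components `G` and
#'   `sample_ids`.
#' @export
gower_center <- function(d) {
  dv <- as_dissim_values(d)
  n <- nrow(dv)
  A <- -0.5 * dv^2
  rm <- rowMeans(A)
  G <- A - outer(rm, rm, "+") + mean(A)
  G <- (G + t(G)) / 2
  structure(list(G = G,
                 sample_ids = if (inherits(d, "dissimilarity_matrix"))
                   d$sample_ids else rownames(dv)),
            class = "gower_matrix")
}

#' Principal coordinates of a Gower matrix
#'
#' Eigen-decomposition of `G`; axes are eigenvectors scaled by
#' `sqrt(|lambda|)`.  Semimetric dissimilarities yield negative
#' eigenvalues, whose axes are kept separately ("imaginary" axes) so the
#' signed squared-distance convention can subtract their contribution.
#' Axes with `|lambda| < 1e-9 * max|lambda|` are treated as numerical
#' noise and dropped.
#'
#' @param g a `gower_matrix` from [gower_center()], or a
#'   [dissimilarity_matrix] (centred on the fly).
#' @return An object of class `pcoa_result`: `eigenvalues` (descending),
#'   `pos` (n x p real-axis coordinates), `neg` (n x q imaginary-axis
#'   coordinates), `sample_ids`.
#' @export
pcoa <- function(g) {
  if (inherits(g, "dissimilarity_matrix")) g <- gower_center(g)
  e <- eigen(g$G, symmetric = TRUE)
  lam <- e$values
  cut <- 1e-9 * max(abs(lam), 0)
  keep <- abs(lam) > cut
  lam_k <- lam[keep]
  vec_k <- e$vectors[, keep, drop = FALSE]
  pos_i <- lam_k > 0
  pos <- vec_k[, pos_i, drop = FALSE] %*% diag(sqrt(lam_k[pos_i]),
                                               nrow = sum(pos_i))
  neg <- vec_k[, !pos_i, drop = FALSE] %*% diag(sqrt(-lam_k[!pos_i]),
                                                nrow = sum(!pos_i))
  rownames(pos) <- rownames(neg) <- g$sample_ids
  structure(list(eigenvalues = lam, pos = pos, neg = neg,
                 sample_ids = g$sample_ids),
            class = "pcoa_result")
}

# Raw (unclipped) squared distance between the centroids of two index
# multisets, straight from the D^2 identity.  Duplicate indices are
# legitimate (bootstrap resampling) and weight samples by multiplicity.
csd_raw <- function(D2, A, B) {
  nA <- length(A); nB <- length(B)
  sum(D2[A, B]) / (nA * nB) -
    sum(D2[A, A]) / (2 * nA^2) -
    sum(D2[B, B]) / (2 * nB^2)
}

#' Squared distance between group centroids in dissimilarity space
#'
#' Uses the identity
#' `||c_A - c_B||^2 = (1/(n_A n_B)) sum_{i in A, j in B} d_ij^2
#'  - (1/n_A^2) sum_{i<j in A} d_ij^2 - (1/n_B^2) sum_{i<j in B} d_ij^2`,
#' which equals the squared Euclidean distance between the group
#' centroids in the principal-coordinate embedding.  For semimetric
#' dissimilarities the identity can return a (typically tiny) negative
#' value; it is clipped to zero, the event recorded in
#' [clip_diagnostics()], and the raw value kept in the `"unclipped"`
#' attribute.
#'
#' @param d a [dissimilarity_matrix] or symmetric matrix.
#' @param setA,setB non-empty index vectors (positions or sample ids);
#'   they may overlap, repeat, or be singletons.
#' @return Non-negative squared centroid distance with attribute
#'   `"unclipped"`.
#' @export
centroid_sq_distance <- function(d, setA, setB) {
  dv <- as_dissim_values(d)
  setA <- resolve_idx(setA, rownames(dv))
  setB <- resolve_idx(setB, rownames(dv))
  if (!length(setA) || !length(setB)) stop("index sets must be non-empty")
  raw <- csd_raw(dv^2, setA, setB)
  val <- raw
  if (val < 0) {
    note_clip(val)
    warning(sprintf("negative squared centroid distance (%.3g) clipped to 0",
                    val), call. = FALSE)
    val <- 0
  }
  structure(val, unclipped = raw)
}

resolve_idx <- function(idx, ids) {
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown sample id(s): ",
                         paste(idx[is.na(pos)], collapse = ", "))
    pos
  } else as.integer(idx)
}

#' Distance of each sample to its own group centroid
#'
#' Computes the PERMDISP deviations `z_i`: the distance from sample `i`
#' to the centroid of its group, using the signed squared-distance
#' convention for semimetric input — real (positive-eigenvalue) axis
#' contributions minus imaginary (negative-eigenvalue) axis
#' contributions in the principal-coordinate embedding.  Negative signed
#' squares clip to 0 (recorded in [clip_diagnostics()]).  Singleton
#' groups give `z = 0`.
#'
#' @param d a [dissimilarity_matrix] or symmetric matrix.
#' @param groups group label per sample.
#' @return Numeric vector of deviations, named by sample id.
#' @export
distances_to_own_centroid <- function(d, groups) {
  dv <- as_dissim_values(d)
  n <- nrow(dv)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  pc <- pcoa(gower_center(d))
  z <- z_from_coords(pc$pos, pc$neg, groups)
  names(z) <- if (!is.null(rownames(dv))) rownames(dv) else NULL
  z
}

# Signed PERMDISP deviations from a fixed embedding; shared with the
# permutation loop of permdisp().
z_from_coords <- function(pos, neg, groups) {
  n <- nrow(pos)
  z2 <- numeric(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) == 1L) { z2[idx] <- 0; next }
    cp <- colMeans(pos[idx, , drop = FALSE])
    cn <- colMeans(neg[idx, , drop = FALSE])
    dp <- sweep(pos[idx, , drop = FALSE], 2L, cp)
    dn <- sweep(neg[idx, , drop = FALSE], 2L, cn)
    z2[idx] <- rowSums(dp^2) - rowSums(dn^2)
  }
  bad <- z2 < 0
  if (any(bad)) for (v in z2[bad]) note_clip(v)
  sqrt(pmax(z2, 0))
}
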