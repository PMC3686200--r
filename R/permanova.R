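# Distance-based permutational ANOVA: one-way and two-way crossed mixed
# designs with Type III sums of squares, pseudo-F from expected mean
# squares, permutation p-values (raw-data permutation or permutation of
# residuals under a reduced model), pairwise comparisons and
# method-of-moments components of variation.

# ---- permutation enumeration -------------------------------------------

# All distinct arrangements of a label vector (multiset permutations),
# one row per arrangement.
multiset_perms <- function(labels) {
  labels <- as.character(labels)
  u <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = u)))
  rec <- function(counts) {
    if (sum(counts) == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
    blocks <- list()
    for (i in seq_along(counts)) {
      if (counts[i] > 0L) {
        c2 <- counts
        c2[i] <- c2[i] - 1L
        blocks[[length(blocks) + 1L]] <- cbind(i, rec(c2), deparse.level = 0)
      }
    }
    do.call(rbind, blocks)
  }
  idx <- rec(counts)
  matrix(u[idx], nrow = nrow(idx))
}

# All n! permutations of 1..n (rows); intended for small n only.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    blocks <- vector("list", length(v))
    for (k in seq_along(v))
      blocks[[k]] <- cbind(v[k], rec(v[-k]), deparse.level = 0)
    do.call(rbind, blocks)
  }
  rec(seq_len(n))
}

n_distinct_label_perms <- function(f) {
  counts <- table(f)
  exp(lfactorial(sum(counts)) - sum(lfactorial(counts)))
}

# Tolerance used when counting permuted statistics >= observed, so exact
# ties (common in small enumerations) are counted as exceedances.
stat_tol <- function(obs) 1e-12 + 1e-8 * abs(obs)

# ---- one-way ------------------------------------------------------------

# Among-group SS tr(HG) for centred G: sum over groups of the group
# submatrix total divided by group size.
ss_among_oneway <- function(G, group_idx, ord) {
  s <- 0
  for (ix in group_idx) {
    o <- ord[ix]
    s <- s + sum(G[o, o]) / length(ix)
  }
  s
}

#' One-way distance-based PERMANOVA
#'
#' Partitions a dissimilarity matrix by a single factor.  The
#' among-group sum of squares is `tr(HGH)` with `H` the hat matrix of
#' the group design and `G` the Gower-centred matrix;
#' `pseudo-F = (SS_among/(a-1)) / (SS_res/(N-a))`.  The p-value uses
#' unrestricted permutation of raw data (whole-sample relabelling) with
#' `P = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`; when the number of
#' distinct relabellings does not exceed `n_perm` the permutation space
#' is enumerated exhaustively and the exact p-value reported.
#'
#' @param d a [dissimilarity_matrix] or symmetric matrix.
#' @param f group label per sample (at least two groups).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param factor_name label used for the term in the output table.
#' @return An object of class `permanova` with an ANOVA-style table
#'   (`tab`), components of variation (`components`, balanced designs),
#'   the permutation scheme, seed, and design metadata.
#' @export
permanova_oneway <- function(d, f, n_perm = 9999, seed = NULL,
                             factor_name = "factor") {
  dv <- as_dissim_values(d)
  N <- nrow(dv)
  f <- factor(as.character(f))
  if (length(f) != N) stop("one group label per sample required")
  a <- nlevels(f)
  if (a < 2L) stop("need at least 2 groups")
  if (any(table(f) == N)) stop("a group equal to the whole sample set")
  if (N - a < 1L) stop("no residual degrees of freedom (N - a = 0)")
  if (n_perm < 1L) stop("n_perm must be >= 1")

  G <- gower_center(d)$G
  sst <- sum(diag(G))
  group_idx <- split(seq_len(N), f)
  df1 <- a - 1L
  df2 <- N - a

  if (sst <= 1e-12) {
    # all samples identical: define pseudo-F = 0, P = 1
    return(permanova_build(
      terms = factor_name, df = df1, SS = 0, MS = 0, F = 0, P = 1,
      n_perm_used = 0L, ss_res = 0, df_res = df2, sst = 0,
      scheme = "unrestricted permutation of raw data", seed = seed,
      exhaustive = FALSE,
      design = list(type = "oneway", a = a, n = unname(table(f))[1L],
                    balanced = length(unique(table(f))) == 1L, N = N,
                    ems = NA_character_)))
  }

  ssa <- ss_among_oneway(G, group_idx, seq_len(N))
  ssr <- sst - ssa
  f_obs <- (ssa / df1) / (ssr / df2)
  tol <- stat_tol(f_obs)
  f_of_ord <- function(ord) {
    sa <- ss_among_oneway(G, group_idx, ord)
    (sa / df1) / ((sst - sa) / df2)
  }

  n_dist <- n_distinct_label_perms(f)
  if (n_dist <= n_perm) {
    labs <- multiset_perms(as.character(f))
    fs <- apply(labs, 1L, function(lab) {
      gi <- split(seq_len(N), factor(lab, levels = levels(f)))
      sa <- ss_among_oneway(G, gi, seq_len(N))
      (sa / df1) / ((sst - sa) / df2)
    })
    p <- mean(fs >= f_obs - tol)
    used <- nrow(labs)
    exhaustive <- TRUE
  } else {
    cnt <- with_seed(seed, {
      x <- 0L
      for (b in seq_len(n_perm)) {
        ord <- sample.int(N)
        if (f_of_ord(ord) >= f_obs - tol) x <- x + 1L
      }
      x
    })
    p <- (1 + cnt) / (1 + n_perm)
    used <- n_perm
    exhaustive <- FALSE
  }

  permanova_build(
    terms = factor_name, df = df1, SS = ssa, MS = ssa / df1, F = f_obs,
    P = p, n_perm_used = used, ss_res = ssr, df_res = df2, sst = sst,
    scheme = "unrestricted permutation of raw data", seed = seed,
    exhaustive = exhaustive,
    design = list(type = "oneway", a = a, n = unname(table(f))[1L],
                  balanced = length(unique(table(f))) == 1L, N = N,
                  ems = NA_character_))
}

# Assemble the permanova S3 object and, where the design is balanced,
# the components of variation.
permanova_build <- function(terms, df, SS, MS, F, P, n_perm_used,
                            ss_res, df_res, sst, scheme, seed, exhaustive,
                            design) {
  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, sum(df) + df_res),
    SS = c(SS, ss_res, sst),
    MS = c(MS, if (df_res > 0) ss_res / df_res else NA_real_, NA_real_),
    pseudo_F = c(F, NA_real_, NA_real_),
    P_perm = c(P, NA_real_, NA_real_),
    n_perm = c(n_perm_used, NA_integer_, NA_integer_),
    stringsAsFactors = FALSE)
  res <- structure(list(tab = tab, scheme = scheme, seed = seed,
                        exhaustive = exhaustive, design = design,
                        components = NULL),
                   class = "permanova")
  if (isTRUE(design$balanced))
    res$components <- compute_components(res)
  res
}

#' @export
print.permanova <- function(x, ...) {
  cat("Permutational multivariate analysis of variance\n")
  cat("Permutation scheme:", x$scheme,
      if (x$exhaustive) "(exhaustive enumeration)" else "", "\n")
  tab <- x$tab
  tab$SS <- signif(tab$SS, 6)
  tab$MS <- signif(tab$MS, 6)
  tab$pseudo_F <- signif(tab$pseudo_F, 5)
  print(tab, row.names = FALSE)
  if (!is.null(x$components)) {
    cat("\nComponents of variation:\n")
    print(x$components, row.names = FALSE)
  }
  invisible(x)
}

# ---- two-way crossed mixed ----------------------------------------------

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Two-way crossed mixed-model distance-based PERMANOVA
#'
#' Fits `fixed + random + fixed:random` to a dissimilarity matrix with
#' Type III sums of squares (each term adjusted for all others, via
#' sum-to-zero contrasts).  Pseudo-F denominators follow mixed-model
#' expected mean squares: by default (`ems = "restricted"`) the fixed
#' main effect is tested over the interaction MS while the random main
#' effect and the interaction are tested over the residual MS;
#' `ems = "unrestricted"` tests both main effects over the interaction
#' MS.  P-values come from permutation of residuals under the reduced
#' model: for each term the Gower matrix is residualised by the
#' reduced-model hat matrix, rows/columns are co-permuted, and the full
#' statistic recomputed.  If the permutation space (N!) does not exceed
#' `n_perm` it is enumerated exhaustively.
#'
#' @param d a [dissimilarity_matrix] or symmetric matrix.
#' @param fixed fixed-factor label per sample (e.g. year).
#' @param random random-factor label per sample (e.g. plot).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @param ems `"restricted"` (default) or `"unrestricted"` expected mean
#'   squares convention.
#' @param fixed_name,random_name term labels for the output table.
#' @return An object of class `permanova`; see [permanova_oneway()].
#' @export
permanova_twoway_mixed <- function(d, fixed, random, n_perm = 9999,
                                   seed = NULL,
                                   ems = c("restricted", "unrestricted"),
                                   fixed_name = "fixed",
                                   random_name = "random") {
  ems <- match.arg(ems)
  dv <- as_dissim_values(d)
  N <- nrow(dv)
  A <- factor(as.character(fixed))
  B <- factor(as.character(random))
  if (length(A) != N || length(B) != N)
    stop("one fixed and one random label per sample required")
  a <- nlevels(A); b <- nlevels(B)
  if (a < 2L || b < 2L) stop("both factors need at least 2 levels")
  ct <- table(A, B)
  if (all(rowSums(ct > 0) == 1L) && all(colSums(ct > 0) == 1L))
    stop("fixed and random factors are aliased (identical partitions)")
  if (any(ct == 0L))
    stop("incomplete crossing: empty cell(s) in fixed x random layout")
  df_res <- N - a * b
  if (df_res < 1L) stop("no residual degrees of freedom (no replication)")
  if (n_perm < 1L) stop("n_perm must be >= 1")

  dat <- data.frame(A = A, B = B)
  X <- stats::model.matrix(~ A * B, dat,
                           contrasts.arg = list(A = "contr.sum",
                                                B = "contr.sum"))
  asgn <- attr(X, "assign")
  Hf <- hat_matrix(X)
  H_wo <- lapply(1:3, function(t)
    hat_matrix(X[, asgn != t, drop = FALSE]))
  M_term <- lapply(H_wo, function(h) Hf - h)

  G <- gower_center(d)$G
  sst <- sum(diag(G))
  dfs <- c(a - 1L, b - 1L, (a - 1L) * (b - 1L))
  term_names <- c(fixed_name, random_name,
                  paste0(fixed_name, ":", random_name))
  n_rep <- unname(ct[1L, 1L])
  balanced <- length(unique(c(ct))) == 1L

  if (sst <= 1e-12) {
    return(permanova_build(
      terms = term_names, df = dfs, SS = rep(0, 3), MS = rep(0, 3),
      F = rep(0, 3), P = rep(1, 3), n_perm_used = rep(0L, 3),
      ss_res = 0, df_res = df_res, sst = 0,
      scheme = "permutation of residuals under a reduced model",
      seed = seed, exhaustive = FALSE,
      design = list(type = "twoway_mixed", a = a, b = b, n = n_rep,
                    balanced = balanced, N = N, ems = ems)))
  }

  ss <- vapply(M_term, function(M) sum(M * G), 0)
  ss_res <- sst - sum(Hf * G)
  ms <- ss / dfs
  ms_res <- ss_res / df_res
  # EMS denominators: index 3 = interaction MS, 0 = residual MS
  denom_idx <- if (ems == "restricted") c(3L, 0L, 0L) else c(3L, 3L, 0L)
  den_ms <- ifelse(denom_idx == 0L, ms_res, ms[3L])
  f_obs <- ms / den_ms
  f_obs[!is.finite(f_obs)] <- 0

  exhaustive <- factorial(N) <= n_perm
  perms <- if (exhaustive) all_perms(N) else NULL
  n_used <- if (exhaustive) nrow(perms) else n_perm

  pvals <- numeric(3)
  for (t in 1:3) {
    Ht <- H_wo[[t]]
    R <- diag(N) - Ht
    Gres <- R %*% G %*% R
    Gres <- (Gres + t(Gres)) / 2
    tr_res <- sum(diag(Gres))
    Mnum <- M_term[[t]]
    Mden <- if (denom_idx[t] == 0L) NULL else M_term[[3L]]
    df_num <- dfs[t]
    df_den <- if (denom_idx[t] == 0L) df_res else dfs[3L]
    tol <- stat_tol(f_obs[t])
    # numerator and denominator SS are projection norms (>= 0 exactly);
    # values below eps are structural zeros of the permuted design
    eps <- 1e-12 * max(tr_res, .Machine$double.xmin)
    f_perm <- function(ord) {
      Gp <- Gres[ord, ord]
      num <- sum(Mnum * Gp)
      den <- if (is.null(Mden)) (tr_res - sum(Hf * Gp))
             else sum(Mden * Gp)
      if (den <= eps) return(if (num <= eps) 0 else Inf)
      (num / df_num) / (den / df_den)
    }
    if (exhaustive) {
      fs <- apply(perms, 1L, f_perm)
      pvals[t] <- mean(fs >= f_obs[t] - tol)
    } else {
      cnt <- with_seed(subseed(seed, paste0("term", t)), {
        x <- 0L
        for (bb in seq_len(n_perm))
          if (f_perm(sample.int(N)) >= f_obs[t] - tol) x <- x + 1L
        x
      })
      pvals[t] <- (1 + cnt) / (1 + n_perm)
    }
  }

  permanova_build(
    terms = term_names, df = dfs, SS = ss, MS = ms, F = f_obs, P = pvals,
    n_perm_used = rep(n_used, 3), ss_res = ss_res, df_res = df_res,
    sst = sst,
    scheme = "permutation of residuals under a reduced model",
    seed = seed, exhaustive = exhaustive,
    design = list(type = "twoway_mixed", a = a, b = b, n = n_rep,
                  balanced = balanced, N = N, ems = ems))
}

# ---- components of variation -------------------------------------------

compute_components <- function(res) {
  d <- res$design
  tab <- res$tab
  ms_res <- tab$MS[tab$term == "Residual"]
  if (d$type == "oneway") {
    raw <- c((tab$MS[1L] - ms_res) / d$n, ms_res)
    terms <- c(tab$term[1L], "Residual")
  } else {
    ms <- tab$MS[1:3]
    if (identical(d$ems, "unrestricted")) {
      raw <- c((ms[1L] - ms[3L]) / (d$n * d$b),   # fixed, over interaction
               (ms[2L] - ms[3L]) / (d$n * d$a),   # random, over interaction
               (ms[3L] - ms_res) / d$n,           # interaction
               ms_res)
    } else {
      raw <- c((ms[1L] - ms[3L]) / (d$n * d$b),
               (ms[2L] - ms_res) / (d$n * d$a),
               (ms[3L] - ms_res) / d$n,
               ms_res)
    }
    terms <- c(tab$term[1:3], "Residual")
  }
  est <- pmax(raw, 0)
  pct <- if (sum(est) > 0) 100 * est / sum(est) else rep(0, length(est))
  data.frame(term = terms, estimate = est, raw_estimate = raw,
             pct = pct, stringsAsFactors = FALSE)
}

#' Components of variation from expected mean squares
#'
#' Method-of-moments variance components obtained by equating observed
#' mean squares to their expectations, e.g. for a balanced mixed two-way
#' design with `n` replicates, `a` fixed and `b` random levels:
#' `sigma2_interaction = (MS_AB - MS_res)/n`,
#' `sigma2_random = (MS_B - MS_res)/(n a)` and the fixed-effect
#' component `(MS_A - MS_AB)/(n b)`.  Negative estimates are reported as
#' 0 with the raw value retained; percentages are taken over the sum of
#' the non-negative estimates plus the residual.  These let the relative
#' importance of model terms be compared on a common scale.
#'
#' @param res a `permanova` result from a balanced design.
#' @return Data frame with columns `term`, `estimate`, `raw_estimate`,
#'   `pct`.
#' @export
components_of_variation <- function(res) {
  stopifnot(inherits(res, "permanova"))
  if (!isTRUE(res$design$balanced))
    stop("components of variation are only supported for balanced designs")
  if (is.null(res$components)) res$components <- compute_components(res)
  res$components
}

# ---- pairwise comparisons ----------------------------------------------

#' Pairwise PERMANOVA comparison between two levels of the fixed factor
#'
#' Subsets the dissimilarity matrix to samples at the two levels and
#' reruns the same design restricted to the pair; `t = sqrt(pseudo-F)`
#' for the fixed term, with the p-value from the same permutation scheme
#' on the subset.
#'
#' @param d a [dissimilarity_matrix] or symmetric matrix.
#' @param fixed fixed-factor label per sample.
#' @param pair character vector of the two levels to compare.
#' @param random optional random-factor label per sample; `NULL` runs a
#'   one-way comparison.
#' @param n_perm,seed,ems as in [permanova_twoway_mixed()].
#' @return An object of class `pairwise_result`: `pair`, `t`, `P_perm`,
#'   `n_perm`, `exhaustive`.
#' @export
pairwise_fixed <- function(d, fixed, pair, random = NULL, n_perm = 9999,
                           seed = NULL, ems = "restricted") {
  dv <- as_dissim_values(d)
  fixed <- as.character(fixed)
  if (length(pair) != 2L) stop("pair must name exactly two levels")
  if (!all(pair %in% fixed)) stop("both levels must be present in the data")
  idx <- which(fixed %in% pair)
  dsub <- dv[idx, idx, drop = FALSE]
  fsub <- fixed[idx]
  if (is.null(random)) {
    res <- permanova_oneway(dsub, fsub, n_perm = n_perm, seed = seed)
  } else {
    rsub <- as.character(random)[idx]
    ctab <- table(fsub, rsub)
    solo <- rowSums(ctab > 0) == 1L
    if (any(solo))
      stop("fixed level '", rownames(ctab)[solo][1L],
           "' has all samples in one cell of the random factor")
    res <- permanova_twoway_mixed(dsub, fsub, rsub, n_perm = n_perm,
                                  seed = seed, ems = ems)
  }
  f <- res$tab$pseudo_F[1L]
  structure(list(pair = pair, t = sqrt(max(f, 0)), F = f,
                 P_perm = res$tab$P_perm[1L],
                 n_perm = res$tab$n_perm[1L],
                 exhaustive = res$exhaustive),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("Pairwise PERMANOVA %s vs %s: t = %.4g, P(perm) = %.4g (%d perms)\n",
              x$pair[1L], x$pair[2L], x$t, x$P_perm, x$n_perm))
  invisible(x)
}

#' All pairwise comparisons between levels of the fixed factor
#'
#' @inheritParams pairwise_fixed
#' @param levels optional ordering of levels (default: time-aware sort).
#' @return Data frame with one row per level pair (`level1`, `level2`,
#'   `t`, `P_perm`, `n_perm`).
#' @export
pairwise_table <- function(d, fixed, random = NULL, n_perm = 9999,
                           seed = NULL, ems = "restricted", levels = NULL) {
  fixed <- as.character(fixed)
  if (is.null(levels)) levels <- order_time_labels(fixed)
  prs <- utils::combn(levels, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    pr <- prs[, k]
    r <- pairwise_fixed(d, fixed, pr, random = random, n_perm = n_perm,
                        seed = subseed(seed, paste(pr, collapse = "|")),
                        ems = ems)
    data.frame(level1 = pr[1L], level2 = pr[2L], t = r$t,
               P_perm = r$P_perm, n_perm = r$n_perm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- PERMDISP -----------------------------------------------------------

disp_anova_F <- function(z, groups) {
  gm <- tapply(z, groups, mean)
  counts <- table(groups)
  grand <- mean(z)
  ssb <- sum(counts * (gm - grand)^2)
  ssw <- sum((z - gm[groups])^2)
  df1 <- length(gm) - 1L
  df2 <- length(z) - length(gm)
  if (ssw <= 1e-14 * max(1, ssb)) {
    if (ssb <= 1e-14) 0 else Inf
  } else (ssb / df1) / (ssw / df2)
}

#' Permutational test of homogeneity of multivariate dispersions
#'
#' Tests whether groups differ in their spread around their own
#' centroids (as opposed to in location), so that significant PERMANOVA
#' terms can be attributed to differences in species abundances rather
#' than dispersion.  Deviations `z_i` come from
#' [distances_to_own_centroid()] (signed semimetric convention); the
#' statistic is the classical one-way ANOVA F on the `z_i`, with the
#' p-value from permuting group labels and recomputing the deviations.
#'
#' @param d a [dissimilarity_matrix] or symmetric matrix.
#' @param groups group label per sample; every group needs >= 2 samples.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return An object of class `permdisp`: `group_means`, `F`, `P_perm`,
#'   `z`, `n_perm`, `seed`.
#' @export
permdisp <- function(d, groups, n_perm = 9999, seed = NULL) {
  dv <- as_dissim_values(d)
  N <- nrow(dv)
  groups <- as.character(groups)
  if (length(groups) != N) stop("one group label per sample required")
  counts <- table(groups)
  if (length(counts) < 2L) stop("need at least 2 groups")
  if (any(counts < 2L))
    stop("group of size 1: '", names(counts)[counts < 2L][1L], "'")
  if (n_perm < 1L) stop("n_perm must be >= 1")

  pc <- pcoa(gower_center(d))
  z <- z_from_coords(pc$pos, pc$neg, groups)
  f_obs <- disp_anova_F(z, groups)
  tol <- stat_tol(if (is.finite(f_obs)) f_obs else 0)

  n_dist <- n_distinct_label_perms(groups)
  if (n_dist <= n_perm) {
    labs <- multiset_perms(groups)
    fs <- apply(labs, 1L, function(g)
      disp_anova_F(z_from_coords(pc$pos, pc$neg, g), g))
    p <- mean(fs >= f_obs - tol)
    used <- nrow(labs)
    exhaustive <- TRUE
  } else {
    cnt <- with_seed(seed, {
      x <- 0L
      for (b in seq_len(n_perm)) {
        g <- groups[sample.int(N)]
        if (disp_anova_F(z_from_coords(pc$pos, pc$neg, g), g) >=
              f_obs - tol) x <- x + 1L
      }
      x
    })
    p <- (1 + cnt) / (1 + n_perm)
    used <- n_perm
    exhaustive <- FALSE
  }
  structure(list(group_means = tapply(z, groups, mean), F = f_obs,
                 P_perm = p, z = z, n_perm = used, seed = seed,
                 exhaustive = exhaustive),
            class = "permdisp")
}

#' @export
print.permdisp <- function(x, ...) {
  cat("Permutational test of homogeneity of multivariate dispersions\n")
  cat(sprintf("F = %.4g, P(perm) = %.4g (%d permutations%s)\n",
              x$F, x$P_perm, x$n_perm,
              if (x$exhaustive) ", exhaustive" else ""))
  cat("Mean distance to centroid by group:\n")
  print(round(x$group_means, 4))
  invisible(x)
}
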