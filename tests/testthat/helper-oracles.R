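# Shared fixtures and independent oracles for the test suite.

# Random Euclidean configuration: n points in p dimensions, plus the
# Euclidean distance matrix they induce.
rand_euclid <- function(n, p = 2, seed = NULL, offset = 0) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * p), n, p) + offset
  rownames(x) <- paste0("s", seq_len(n))
  list(coords = x, D = as.matrix(dist(x)))
}

# Hand evaluation of the Bray-Curtis formula, independent of vegdist.
bc_hand <- function(ab) {
  n <- nrow(ab)
  d <- matrix(0, n, n, dimnames = list(rownames(ab), rownames(ab)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    den <- sum(ab[i, ] + ab[j, ])
    d[i, j] <- if (den == 0) 0 else sum(abs(ab[i, ] - ab[j, ])) / den
  }
  d
}

# Classical one-way ANOVA F from group means/variances (univariate).
anova_F_hand <- function(y, f) {
  f <- factor(f)
  gm <- tapply(y, f, mean)
  n <- table(f)
  ssb <- sum(n * (gm - mean(y))^2)
  ssw <- sum((y - gm[f])^2)
  (ssb / (nlevels(f) - 1)) / (ssw / (length(y) - nlevels(f)))
}

# Exhaustive one-way permutation p-value by brute force over all
# distinct group labellings (chosen via combn), computed on univariate
# data with the classical F.
oneway_exact_P_hand <- function(y, f) {
  f <- factor(f)
  N <- length(y)
  f_obs <- anova_F_hand(y, f)
  # enumerate all assignments of positions to groups, respecting sizes
  sizes <- table(f)
  labels <- levels(f)
  assignments <- list(list(remaining = seq_len(N), lab = character(N)))
  for (g in labels[-length(labels)]) {
    nxt <- list()
    for (a in assignments) {
      picks <- utils::combn(a$remaining, sizes[[g]], simplify = FALSE)
      for (p in picks) {
        lab <- a$lab
        lab[p] <- g
        nxt[[length(nxt) + 1L]] <- list(remaining = setdiff(a$remaining, p),
                                        lab = lab)
      }
    }
    assignments <- nxt
  }
  fs <- vapply(assignments, function(a) {
    lab <- a$lab
    lab[a$remaining] <- labels[length(labels)]
    anova_F_hand(y, lab)
  }, 0)
  mean(fs >= f_obs - 1e-10)
}

# Heap's algorithm: all n! permutations of 1..n (independent of the
# package's enumerator).
heap_perms <- function(n) {
  out <- matrix(NA_integer_, factorial(n), n)
  row <- 0L
  a <- seq_len(n)
  gen <- function(k) {
    if (k == 1L) {
      row <<- row + 1L
      out[row, ] <<- a
    } else {
      for (i in seq_len(k)) {
        gen(k - 1L)
        if (i < k) {
          j <- if (k %% 2L == 0L) i else 1L
          tmp <- a[j]; a[j] <<- a[k]; a[k] <<- tmp
        }
      }
    }
  }
  gen(n)
  out
}

# Small structured community: two groups of samples with disjoint
# dominant taxa plus uniform background noise.
two_group_community <- function(n_per = 6, n_taxa = 10, hi = 50, seed = 1) {
  set.seed(seed)
  mu <- rbind(
    matrix(rep(c(rep(hi, 3), rep(1, n_taxa - 3)), each = n_per), n_per),
    matrix(rep(c(rep(1, n_taxa - 3), rep(hi, 3)), each = n_per), n_per))
  ab <- matrix(rpois(length(mu), mu), nrow(mu))
  rownames(ab) <- paste0("s", seq_len(nrow(ab)))
  colnames(ab) <- paste0("t", seq_len(n_taxa))
  md <- data.frame(sample_id = rownames(ab), site = "x", plot = "p",
                   time = "1", replicate = rownames(ab),
                   stringsAsFactors = FALSE)
  community_matrix(ab, md)
}

# Minimal community matrix from an abundance matrix, generating
# distinct replicate labels.
quick_community <- function(ab, site = "s", plot = "p", time = "1") {
  if (is.null(rownames(ab))) rownames(ab) <- paste0("x", seq_len(nrow(ab)))
  if (is.null(colnames(ab))) colnames(ab) <- paste0("t", seq_len(ncol(ab)))
  md <- data.frame(sample_id = rownames(ab), site = site, plot = plot,
                   time = time, replicate = rownames(ab),
                   stringsAsFactors = FALSE)
  community_matrix(ab, md)
}

# Metadata for a single-site plot x time x replicate layout, in the
# order plots > times > replicates (matching simulate_community).
grid_metadata <- function(n_plots, n_times, n_reps, site = "site1") {
  rows <- expand.grid(r = seq_len(n_reps), t = seq_len(n_times),
                      p = seq_len(n_plots))
  rows <- rows[order(rows$p, rows$t, rows$r), ]
  data.frame(sample_id = sprintf("p%d_t%d_r%d", rows$p, rows$t, rows$r),
             site = site, plot = paste0("plot", rows$p),
             time = as.character(rows$t), replicate = paste0("r", rows$r),
             stringsAsFactors = FALSE)
}
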