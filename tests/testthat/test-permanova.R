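test_that("one-way PERMANOVA reduces to classical ANOVA on Euclidean data", {
  # worked example: {0,1} vs {2,3} -> F = 8, exact P = 1/3
  y <- c(0, 1, 2, 3)
  D <- as.matrix(dist(y))
  r <- permanova_oneway(D, c("a", "a", "b", "b"), n_perm = 999, seed = 1)
  expect_equal(r$tab$pseudo_F[1], 8, tolerance = 1e-12)
  expect_true(r$exhaustive)
  expect_equal(r$tab$P_perm[1], 1 / 3, tolerance = 1e-12)
  # random instances vs aov
  for (k in 1:20) {
    set.seed(200 + k)
    f <- rep(c("a", "b", "c"), times = c(4, 5, 3))
    yy <- rnorm(12)
    rr <- permanova_oneway(as.matrix(dist(yy)), f, n_perm = 1, seed = 1)
    a <- anova(lm(yy ~ f))
    expect_equal(rr$tab$SS[1], a$`Sum Sq`[1], tolerance = 1e-10)
    expect_equal(rr$tab$SS[2], a$`Sum Sq`[2], tolerance = 1e-10)
    expect_equal(rr$tab$pseudo_F[1], a$`F value`[1], tolerance = 1e-10)
  }
})

test_that("one-way permutation P matches brute-force enumeration", {
  layouts <- list(rep(c("a", "b"), each = 4),
                  rep(c("a", "b"), times = c(3, 4)),
                  rep(c("a", "b", "c"), times = c(3, 3, 2)))
  for (k in seq_along(layouts)) {
    f <- layouts[[k]]
    set.seed(40 + k)
    y <- rnorm(length(f))
    r <- permanova_oneway(as.matrix(dist(y)), f, n_perm = 9999, seed = 1)
    expect_true(r$exhaustive)
    expect_equal(r$tab$P_perm[1], oneway_exact_P_hand(y, f),
                 tolerance = 1e-12)
  }
})

test_that("degenerate and invalid one-way inputs are handled", {
  D0 <- matrix(0, 4, 4)
  r <- permanova_oneway(D0, c("a", "a", "b", "b"), n_perm = 99, seed = 1)
  expect_equal(r$tab$pseudo_F[1], 0)
  expect_equal(r$tab$P_perm[1], 1)
  D <- as.matrix(dist(1:4))
  expect_error(permanova_oneway(D, rep("a", 4)), "at least 2 groups")
  expect_error(permanova_oneway(D, c("a", "b", "c", "d")),
               "residual degrees of freedom")
})

test_that("scaling dissimilarities leaves pseudo-F and P unchanged", {
  set.seed(5)
  m <- quick_community(matrix(rpois(120, 5), 12))
  d <- bray_curtis(m)$values
  f <- rep(c("a", "b", "c"), each = 4)
  r1 <- permanova_oneway(d, f, n_perm = 199, seed = 7)
  r2 <- permanova_oneway(3.7 * d, f, n_perm = 199, seed = 7)
  expect_equal(r1$tab$pseudo_F[1], r2$tab$pseudo_F[1], tolerance = 1e-10)
  expect_equal(r1$tab$P_perm[1], r2$tab$P_perm[1])
  # cross-check observed pseudo-F against vegan::adonis2
  ad <- vegan::adonis2(as.dist(d) ~ f, permutations = 2)
  expect_equal(r1$tab$pseudo_F[1], ad$F[1], tolerance = 1e-10)
  expect_equal(r1$tab$SS[1], ad$SumOfSqs[1], tolerance = 1e-10)
})

test_that("two-way mixed PERMANOVA recovers classical two-way SS", {
  for (k in 1:20) {
    set.seed(300 + k)
    md <- grid_metadata(3, 4, 2)      # 3 plots x 4 times x 2 reps
    y <- rnorm(nrow(md))
    r <- permanova_twoway_mixed(as.matrix(dist(y)), md$time, md$plot,
                                n_perm = 1, seed = 1)
    a <- anova(lm(y ~ time * plot, data = md))
    expect_equal(r$tab$SS[1:4], a$`Sum Sq`, tolerance = 1e-10)
    expect_equal(r$tab$df[1:4], a$Df)
    # EMS pseudo-F: fixed over interaction MS, others over residual MS
    ms <- a$`Mean Sq`
    expect_equal(r$tab$pseudo_F[1], ms[1] / ms[3], tolerance = 1e-10)
    expect_equal(r$tab$pseudo_F[2], ms[2] / ms[4], tolerance = 1e-10)
    expect_equal(r$tab$pseudo_F[3], ms[3] / ms[4], tolerance = 1e-10)
    # balanced additivity
    expect_equal(sum(r$tab$SS[1:4]), r$tab$SS[5], tolerance = 1e-8)
  }
})

test_that("unrestricted EMS switch changes the random-effect denominator", {
  set.seed(77)
  md <- grid_metadata(2, 3, 2)
  y <- rnorm(nrow(md))
  D <- as.matrix(dist(y))
  rr <- permanova_twoway_mixed(D, md$time, md$plot, n_perm = 1, seed = 1)
  ru <- permanova_twoway_mixed(D, md$time, md$plot, n_perm = 1, seed = 1,
                               ems = "unrestricted")
  expect_equal(ru$tab$pseudo_F[2], rr$tab$MS[2] / rr$tab$MS[3],
               tolerance = 1e-10)
  expect_equal(ru$tab$pseudo_F[1], rr$tab$pseudo_F[1], tolerance = 1e-12)
})

test_that("two-way residual permutation matches exhaustive enumeration", {
  # 2 x 2 with 2 replicates: N = 8, 8! = 40320 permutations enumerable
  set.seed(88)
  md <- grid_metadata(2, 2, 2)
  y <- rnorm(nrow(md))
  D <- as.matrix(dist(y))
  r <- permanova_twoway_mixed(D, md$time, md$plot, n_perm = 45000, seed = 1)
  expect_true(r$exhaustive)

  # independent oracle: quadratic forms in the permuted reduced-model
  # residual vector, over Heap-generated permutations
  A <- factor(md$time); B <- factor(md$plot)
  X <- model.matrix(~ A * B, contrasts.arg = list(A = "contr.sum",
                                                  B = "contr.sum"))
  asgn <- attr(X, "assign")
  proj <- function(M) M %*% solve(crossprod(M)) %*% t(M)
  Hf <- proj(X)
  yc <- y - mean(y)
  perms <- heap_perms(8)
  for (t in 1:3) {
    Hr <- proj(X[, asgn != t, drop = FALSE])
    Mt <- Hf - Hr
    M3 <- Hf - proj(X[, asgn != 3, drop = FALSE])
    r_red <- as.numeric((diag(8) - Hr) %*% yc)
    df_num <- r$tab$df[t]
    use_int <- t == 1
    f_obs <- r$tab$pseudo_F[t]
    eps <- 1e-12 * sum(r_red^2)
    fs <- apply(perms, 1, function(p) {
      rp <- r_red[p]
      num <- as.numeric(t(rp) %*% Mt %*% rp)
      den <- if (use_int) as.numeric(t(rp) %*% M3 %*% rp)
             else as.numeric(t(rp) %*% (diag(8) - Hf) %*% rp)
      if (den <= eps) (if (num <= eps) 0 else Inf)
      else (num / df_num) / (den / (if (use_int) r$tab$df[3] else 4))
    })
    expect_equal(r$tab$P_perm[t], mean(fs >= f_obs - 1e-8 * f_obs - 1e-12),
                 tolerance = 1e-12)
  }
})

test_that("two-way input validation catches bad designs", {
  D <- as.matrix(dist(1:8))
  expect_error(permanova_twoway_mixed(D, rep(c("a", "b"), 4),
                                      rep(c("x", "y"), 4), n_perm = 9),
               "aliased")
  expect_error(permanova_twoway_mixed(D, rep("a", 8),
                                      rep(c("x", "y"), 4), n_perm = 9),
               "at least 2 levels")
  expect_error(
    permanova_twoway_mixed(D, c("a", "a", "a", "a", "b", "b", "b", "b"),
                           c("x", "x", "y", "y", "x", "x", "x", "x"),
                           n_perm = 9),
    "incomplete crossing|empty cell")
})

test_that("components of variation follow the EMS formulas", {
  # MS_A = MS_AB -> fixed component 0; equal MS -> only residual left
  md <- grid_metadata(3, 4, 2)
  set.seed(12)
  y <- rnorm(nrow(md))
  r <- permanova_twoway_mixed(as.matrix(dist(y)), md$time, md$plot,
                              n_perm = 1, seed = 1)
  comp <- components_of_variation(r)
  ms <- r$tab$MS
  n <- 2; a <- 4; b <- 3
  expect_equal(comp$raw_estimate[1], (ms[1] - ms[3]) / (n * b),
               tolerance = 1e-12)
  expect_equal(comp$raw_estimate[2], (ms[2] - ms[4]) / (n * a),
               tolerance = 1e-12)
  expect_equal(comp$raw_estimate[3], (ms[3] - ms[4]) / n,
               tolerance = 1e-12)
  expect_equal(comp$estimate, pmax(comp$raw_estimate, 0))
  expect_equal(sum(comp$pct), 100, tolerance = 1e-9)
  # unbalanced designs refuse
  r$design$balanced <- FALSE
  expect_error(components_of_variation(r), "balanced")
})

test_that("pairwise t equals the square root of the pairwise pseudo-F", {
  # one-way {0,1} vs {2,3}: t = sqrt(8)
  y <- c(0, 1, 2, 3)
  pw <- pairwise_fixed(as.matrix(dist(y)), c("a", "a", "b", "b"),
                       c("a", "b"), n_perm = 99, seed = 2)
  expect_equal(pw$t, sqrt(8), tolerance = 1e-10)
  expect_equal(pw$t^2, pw$F, tolerance = 1e-10)
  # identical communities in both levels -> t = 0, P = 1
  D0 <- matrix(0, 6, 6)
  pw0 <- pairwise_fixed(D0, rep(c("a", "b"), each = 3), c("a", "b"),
                        n_perm = 9, seed = 1)
  expect_equal(pw0$t, 0)
  expect_equal(pw0$P_perm, 1)
  # two-way pairwise with a level confined to one random cell errors
  expect_error(
    pairwise_fixed(as.matrix(dist(1:6)),
                   c("a", "a", "a", "a", "b", "b"), c("a", "b"),
                   random = c("x", "x", "y", "y", "x", "x")),
    "one cell of the random factor")
  # full pairwise table covers all level pairs
  md <- grid_metadata(2, 3, 2)
  set.seed(6)
  D <- as.matrix(dist(rnorm(nrow(md))))
  tab <- pairwise_table(D, md$time, random = md$plot, n_perm = 19, seed = 3)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$t >= 0))
})

test_that("PERMDISP matches hand ANOVA on deviations", {
  # equal dispersion by symmetry: {0,2} and {10,12} -> all z = 1, F = 0
  D <- as.matrix(dist(c(0, 2, 10, 12)))
  g <- rep(c("a", "b"), each = 2)
  r <- permdisp(D, g, n_perm = 99, seed = 1)
  expect_equal(unname(r$z), rep(1, 4), tolerance = 1e-10)
  expect_equal(r$F, 0, tolerance = 1e-10)
  expect_equal(r$P_perm, 1)
  # {0,2} vs {10,30}: z = (1,1) vs (10,10), SSW = 0 -> F infinite,
  # matching the hand ANOVA on those z values
  D2 <- as.matrix(dist(c(0, 2, 10, 30)))
  r2 <- permdisp(D2, g, n_perm = 99, seed = 1)
  expect_equal(unname(r2$z), c(1, 1, 10, 10), tolerance = 1e-10)
  expect_equal(r2$F, anova_F_hand(c(1, 1, 10, 10), g))
  # duplicated group -> F = 0
  D3 <- as.matrix(dist(c(0, 2, 0, 2)))
  expect_equal(permdisp(D3, g, n_perm = 9, seed = 1)$F, 0,
               tolerance = 1e-10)
  expect_error(permdisp(D, c("a", "a", "a", "b")), "size 1")
  # cross-check F against vegan on community data
  set.seed(21)
  m <- quick_community(matrix(rpois(160, 7), 16))
  d <- bray_curtis(m)
  grp <- rep(c("u", "v"), each = 8)
  r3 <- permdisp(d, grp, n_perm = 19, seed = 5)
  bd <- vegan::betadisper(as.dist(d$values), grp, type = "centroid")
  av <- anova(bd)
  expect_equal(r3$F, av$`F value`[1], tolerance = 1e-8)
})
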