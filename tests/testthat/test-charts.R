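simple_series_md <- function(ids, times) {
  data.frame(sample_id = ids, site = "s", plot = "p1",
             time = as.character(times), replicate = "r1",
             stringsAsFactors = FALSE)
}

test_that("plot-time observation sets use replicate centroids", {
  # 2 replicates at 1-D positions 0 and 2 behave as a point at 1
  y <- c(0, 2, 5)
  D <- as.matrix(dist(y))
  md <- data.frame(sample_id = paste0("s", 1:3), site = "x", plot = "p",
                   time = c("1", "1", "2"), replicate = c("r1", "r2", "r1"))
  pts <- plot_time_points(md)
  expect_equal(length(pts), 1)
  expect_equal(pts[[1]]$cells[[1]], 1:2)
  expect_equal(sqrt(as.numeric(centroid_sq_distance(D, pts[[1]]$cells[[1]],
                                                    3))), 4)
  # 4 identical replicates: centroid at common position, dispersion 0
  D0 <- matrix(0, 4, 4)
  expect_equal(as.numeric(centroid_sq_distance(D0, 1:4, 1)), 0)
  # missing (plot, time) cells are skipped with a warning
  md2 <- data.frame(sample_id = paste0("s", 1:5), site = "x",
                    plot = c("p1", "p1", "p1", "p2", "p2"),
                    time = c("1", "2", "3", "1", "3"), replicate = "r1")
  expect_warning(pts2 <- plot_time_points(md2), "skipped")
  expect_equal(pts2[[2]]$times, c("1", "3"))
})

test_that("baseline chart matches the Euclidean centroid oracle", {
  y <- c(0, 2, 5)
  D <- as.matrix(dist(y))
  md <- simple_series_md(paste0("s", 1:3), 1:3)
  ch <- chart_baseline(D, md, chart_spec("baseline", m = 2, B = 1, seed = 1))
  expect_equal(ch$points$deviation, c(1, 1, 4), tolerance = 1e-12)
  # m = 1: deviation at the baseline time is 0 (point vs itself)
  ch1 <- chart_baseline(D, md, chart_spec("baseline", m = 1, B = 1, seed = 1))
  expect_equal(ch1$points$deviation[1], 0, tolerance = 1e-12)
  # constant community -> all deviations 0
  Dc <- matrix(0, 3, 3)
  chc <- chart_baseline(Dc, md, chart_spec("baseline", m = 2, B = 1, seed = 1))
  expect_true(all(chc$points$deviation == 0))
  # plot with too few times errors by name
  md2 <- simple_series_md(paste0("s", 1:2), 1:2)
  expect_error(chart_baseline(as.matrix(dist(c(0, 1))), md2,
                              chart_spec("baseline", m = 3, B = 1)),
               "baseline needs")
})

test_that("sequential chart tracks the running centroid", {
  y <- c(0, 2, 5)
  D <- as.matrix(dist(y))
  md <- simple_series_md(paste0("s", 1:3), 1:3)
  ch <- chart_sequential(D, md, chart_spec("sequential", B = 1, seed = 1))
  expect_equal(ch$points$deviation, c(2, 4), tolerance = 1e-12)
  expect_equal(ch$points$unstable, c(TRUE, FALSE))
  # single aberrant final time -> maximum deviation at the final time
  y2 <- c(1, 1.1, 0.9, 1, 9)
  ch2 <- chart_sequential(as.matrix(dist(y2)),
                          simple_series_md(paste0("s", 1:5), 1:5),
                          chart_spec("sequential", B = 1, seed = 1))
  expect_equal(which.max(ch2$points$deviation), nrow(ch2$points))
})

test_that("both chart types agree with explicit coordinate centroids", {
  for (k in 1:30) {
    set.seed(700 + k)
    coords <- matrix(rnorm(10 * 2), 10, 2)
    D <- as.matrix(dist(coords))
    md <- data.frame(sample_id = paste0("s", 1:10), site = "x", plot = "p",
                     time = as.character(rep(1:5, each = 2)),
                     replicate = rep(c("r1", "r2"), 5))
    rownames(D) <- colnames(D) <- md$sample_id
    cell_cent <- t(sapply(1:5, function(t)
      colMeans(coords[md$time == t, , drop = FALSE])))
    base_cent <- colMeans(coords[md$time %in% c("1", "2"), , drop = FALSE])
    exp_base <- sqrt(rowSums(sweep(cell_cent, 2, base_cent)^2))
    ch <- chart_baseline(D, md, chart_spec("baseline", m = 2, B = 1, seed = 1))
    expect_equal(ch$points$deviation, exp_base, tolerance = 1e-10)
    exp_seq <- sapply(2:5, function(t) {
      ref <- colMeans(coords[md$time %in% as.character(1:(t - 1)), ,
                             drop = FALSE])
      sqrt(sum((cell_cent[t, ] - ref)^2))
    })
    cs <- chart_sequential(D, md, chart_spec("sequential", B = 1, seed = 1))
    expect_equal(cs$points$deviation, exp_seq, tolerance = 1e-10)
  }
})

test_that("bootstrap limits honour their degenerate identities", {
  # constant communities in two plots -> limits 0
  md <- data.frame(sample_id = paste0("s", 1:6), site = "x",
                   plot = rep(c("p1", "p2"), each = 3),
                   time = as.character(rep(1:3, 2)), replicate = "r1")
  D0 <- matrix(0, 6, 6, dimnames = list(md$sample_id, md$sample_id))
  lim <- bootstrap_limits(D0, md, chart_spec("baseline", B = 25, seed = 1))
  expect_equal(unname(lim$limits), c(0, 0))
  # single plot, sequential: pooled cross-section is one value per time,
  # so the 50th and 95th limits coincide
  md1 <- simple_series_md(paste0("s", 1:4), 1:4)
  D <- as.matrix(dist(c(0, 3, 1, 7)))
  dimnames(D) <- list(md1$sample_id, md1$sample_id)
  lims <- bootstrap_limits(D, md1, chart_spec("sequential", B = 40, seed = 2))
  expect_equal(lims$limits[-1, "p50"], lims$limits[-1, "p95"],
               tolerance = 1e-12)
  # identical seed -> identical limits; B >= 1 enforced
  l1 <- bootstrap_limits(D, md1, chart_spec("sequential", B = 30, seed = 9))
  l2 <- bootstrap_limits(D, md1, chart_spec("sequential", B = 30, seed = 9))
  expect_identical(l1$limits, l2$limits)
  expect_error(chart_spec("baseline", B = 0), "B must be")
})

test_that("scaling dissimilarities scales deviations and limits, not flags", {
  set.seed(15)
  cfg <- simulation_config(n_plots = 2, n_times = 4, n_replicates = 2,
                           n_taxa = 10, seed = 33)
  sim <- simulate_community(cfg)
  d <- bray_curtis(fourth_root_transform(sim$community))
  md <- sim$community$metadata
  spec <- chart_spec("sequential", B = 60, seed = 4)
  ch1 <- chart_sequential(d$values, md, spec)
  lim1 <- bootstrap_limits(d$values, md, spec)
  c_scale <- 2.5
  ch2 <- chart_sequential(c_scale * d$values, md, spec)
  lim2 <- bootstrap_limits(c_scale * d$values, md, spec)
  expect_equal(ch2$points$deviation, c_scale * ch1$points$deviation,
               tolerance = 1e-10)
  expect_equal(lim2$limits[-1, ], c_scale * lim1$limits[-1, ],
               tolerance = 1e-10)
  f1 <- flag_out_of_control(ch1, lim1)
  f2 <- flag_out_of_control(ch2, lim2)
  expect_identical(f1$flag, f2$flag)
})

test_that("flagging compares deviations to the 95th limit", {
  # all deviations at the 50th limit -> no flags
  md <- simple_series_md(paste0("s", 1:3), 1:3)
  ch <- chart_baseline(matrix(0, 3, 3), md,
                       chart_spec("baseline", m = 2, B = 5, seed = 1))
  lim <- structure(list(limits = c(p50 = 0, p95 = 0), type = "baseline",
                        percentiles = c(50, 95), B = 5, seed = 1),
                   class = "control_limits")
  fl <- flag_out_of_control(ch, lim)
  expect_false(any(fl$flag))
  # constructed pulse: exactly one exceedance, at the pulse time
  y <- c(1, 1.2, 0.8, 1.1, 6)
  md5 <- simple_series_md(paste0("s", 1:5), 1:5)
  D <- as.matrix(dist(y)); dimnames(D) <- list(md5$sample_id, md5$sample_id)
  chs <- chart_sequential(D, md5, chart_spec("sequential", B = 200, seed = 3))
  lims <- bootstrap_limits(D, md5, chart_spec("sequential", B = 200, seed = 3))
  fls <- flag_out_of_control(chs, lims)
  expect_equal(sum(fls$flag & !fls$unstable), 1)
  expect_equal(fls$time[fls$flag & !fls$unstable], "5")
  # mismatched chart/limit types refuse
  expect_error(flag_out_of_control(chs, lim), "does not match")
  # baseline-time flags are suppressed by default
  expect_false(any(fl$flag[fl$time_index <= 2]))
})

test_that("self-exceedance of the baseline chart limits is near 5%", {
  cfg <- simulation_config(n_plots = 3, n_times = 20, n_replicates = 4,
                           n_taxa = 20, seed = 11)
  sim <- simulate_community(cfg)
  d <- bray_curtis(fourth_root_transform(sim$community))
  md <- sim$community$metadata
  exceed <- sapply(1:3, function(k) {
    sim_k <- simulate_community(simulation_config(
      n_plots = 3, n_times = 20, n_replicates = 4, n_taxa = 20,
      seed = 10 + k))
    d_k <- bray_curtis(fourth_root_transform(sim_k$community))
    md_k <- sim_k$community$metadata
    spec_k <- chart_spec("baseline", B = 300, seed = 3)
    tab_k <- flag_out_of_control(chart_baseline(d_k, md_k, spec_k),
                                 bootstrap_limits(d_k, md_k, spec_k),
                                 flag_baseline_times = TRUE)
    mean(tab_k$deviation > tab_k$cl95)
  })
  expect_gte(mean(exceed), 0.02)
  expect_lte(mean(exceed), 0.08)
  # sequential limits from a 3-plot cross-section are coarser (the
  # per-time 95th percentile of 3 values is a near-max order
  # statistic); assert only that the limit bounds are ordered and the
  # exceedance stays below the cross-section ceiling
  spec2 <- chart_spec("sequential", B = 400, seed = 3)
  lim2 <- bootstrap_limits(d, md, spec2)
  expect_true(all(lim2$limits[-1, "p95"] >= lim2$limits[-1, "p50"]))
  tab2 <- flag_out_of_control(chart_sequential(d, md, spec2), lim2)
  expect_lte(mean(tab2$deviation > tab2$cl95), 1 / 3)
})

test_that("pseudo-plot assignment is balanced and seed-stable", {
  lab <- assign_pseudo_plots(paste0("s", 1:12), 3, seed = 4)
  expect_equal(as.vector(sort(table(lab))), c(4, 4, 4))
  expect_identical(lab, assign_pseudo_plots(paste0("s", 1:12), 3, seed = 4))
  lab10 <- assign_pseudo_plots(paste0("s", 1:10), 3, seed = 5)
  expect_equal(as.vector(sort(table(lab10))), c(3, 3, 4))
  expect_error(assign_pseudo_plots(paste0("s", 1:2), 3), "fewer samples")
  # per-time application keeps labels stable across times
  md <- data.frame(sample_id = paste0("s", 1:24),
                   time = rep(c("1", "2"), each = 12))
  lab_all <- assign_pseudo_plots_by_time(md, 3, seed = 6)
  expect_setequal(unique(lab_all), paste0("pseudo-", 1:3))
  expect_equal(unname(table(lab_all[md$time == "1"])), rep(4L, 3),
               ignore_attr = TRUE)
})
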