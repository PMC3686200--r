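# Multivariate control charts: per-plot time series of centroid
# deviations under two measures (distance to a fixed baseline centroid,
# and distance to the running centroid of all previous times), with
# bootstrapped percentile control limits and out-of-control flagging.

#' Control chart specification
#'
#' @param type `"baseline"` — deviation of each plot-time community from
#'   the centroid of that plot's first `m` times (sensitive to gradual
#'   "press" change) — or `"sequential"` — deviation from the centroid
#'   of all times up to `t - 1` (sensitive to one-off "pulse" change).
#' @param m baseline size in time points (default 2, i.e. the first two
#'   survey years).
#' @param percentiles control-limit percentiles in (0, 100)
#'   (default 50 and 95).
#' @param B bootstrap samples for the control limits (default 10000).
#' @param seed integer seed for the bootstrap.
#' @param replicate_level if `TRUE`, chart every replicate sample
#'   instead of the replicate centroid of each plot-time.
#' @return An object of class `chart_spec`.
#' @export
chart_spec <- function(type = c("baseline", "sequential"), m = 2,
                       percentiles = c(50, 95), B = 10000, seed = NULL,
                       replicate_level = FALSE) {
  type <- match.arg(type)
  if (m < 1) stop("baseline size m must be >= 1")
  if (B < 1) stop("B must be >= 1")
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie in (0, 100)")
  structure(list(type = type, m = as.integer(m),
                 percentiles = sort(percentiles), B = as.integer(B),
                 seed = seed, replicate_level = isTRUE(replicate_level)),
            class = "chart_spec")
}

#' Plot-time observation sets
#'
#' Groups samples into (site, plot, time) cells.  Each cell's community
#' is represented by the centroid of its replicate samples (a singleton
#' cell reduces to the sample itself); all chart distances are computed
#' with the centroid identity of [centroid_sq_distance()].  Plots with
#' missing time points keep their available times (skipped cells are
#' reported with a warning).
#'
#' @param metadata data frame with columns `site`, `plot`, `time` (and
#'   `sample_id`), one row per sample, rows aligned with the
#'   dissimilarity matrix.
#' @return A list of per-plot records: `site`, `plot`, `times` (ordered
#'   time labels) and `cells` (list of replicate index vectors, one per
#'   time).
#' @export
plot_time_points <- function(metadata) {
  md <- as.data.frame(metadata)
  time_levels <- order_time_labels(md$time)
  plot_key <- paste(md$site, md$plot, sep = "\r")
  out <- list()
  for (pk in unique(plot_key)) {
    rows <- which(plot_key == pk)
    cells <- list()
    times <- character(0)
    missing <- character(0)
    for (tl in time_levels) {
      ix <- rows[md$time[rows] == tl]
      if (length(ix) == 0L) { missing <- c(missing, tl); next }
      times <- c(times, tl)
      cells[[length(cells) + 1L]] <- ix
    }
    if (length(missing) && length(missing) < length(time_levels))
      warning(sprintf("plot %s/%s: no samples at time(s) %s; skipped",
                      md$site[rows[1L]], md$plot[rows[1L]],
                      paste(missing, collapse = ", ")), call. = FALSE)
    out[[length(out) + 1L]] <- list(site = md$site[rows[1L]],
                                    plot = md$plot[rows[1L]],
                                    times = times, cells = cells)
  }
  out
}

# Deviation series for one plot given its list of cells (index
# vectors), from the squared-distance matrix.  Returns NA at
# positions that are not charted (t = 1 for sequential charts).
plot_deviations <- function(D2, cells, type, m) {
  T_ <- length(cells)
  d <- rep(NA_real_, T_)
  if (type == "baseline") {
    if (T_ < m) return(NULL)
    base <- unlist(cells[seq_len(m)])
    for (t in seq_len(T_)) {
      v <- csd_raw(D2, cells[[t]], base)
      if (v < 0) note_clip(v)
      d[t] <- sqrt(max(v, 0))
    }
  } else {
    if (T_ < 2L) return(NULL)
    for (t in 2:T_) {
      ref <- unlist(cells[seq_len(t - 1L)])
      v <- csd_raw(D2, cells[[t]], ref)
      if (v < 0) note_clip(v)
      d[t] <- sqrt(max(v, 0))
    }
  }
  d
}

expand_replicate_cells <- function(pts) {
  lapply(pts, function(p) {
    reps <- lapply(seq_along(p$cells), function(t)
      lapply(p$cells[[t]], function(i) i))
    p$rep_cells <- reps
    p
  })
}

chart_build <- function(d, metadata, spec) {
  dv <- as_dissim_values(d)
  D2 <- dv^2
  pts <- plot_time_points(metadata)
  rows <- list()
  provenance <- list()
  for (p in pts) {
    T_ <- length(p$times)
    if (spec$type == "baseline" && T_ < spec$m)
      stop(sprintf("plot %s/%s has %d time point(s); baseline needs >= %d",
                   p$site, p$plot, T_, spec$m))
    if (spec$type == "sequential" && T_ < 2L)
      stop(sprintf("plot %s/%s has %d time point(s); sequential chart needs >= 2",
                   p$site, p$plot, T_))
    if (spec$replicate_level) {
      # chart every replicate against the reference centroid
      for (t in seq_len(T_)) {
        if (spec$type == "sequential" && t == 1L) next
        ref <- if (spec$type == "baseline") unlist(p$cells[seq_len(spec$m)])
               else unlist(p$cells[seq_len(t - 1L)])
        for (i in p$cells[[t]]) {
          v <- csd_raw(D2, i, ref)
          if (v < 0) note_clip(v)
          rows[[length(rows) + 1L]] <- data.frame(
            site = p$site, plot = p$plot, time = p$times[t],
            time_index = t, deviation = sqrt(max(v, 0)),
            unstable = spec$type == "sequential" && t == 2L,
            stringsAsFactors = FALSE)
        }
      }
    } else {
      dev <- plot_deviations(D2, p$cells, spec$type, spec$m)
      for (t in seq_len(T_)) {
        if (is.na(dev[t])) next
        rows[[length(rows) + 1L]] <- data.frame(
          site = p$site, plot = p$plot, time = p$times[t],
          time_index = t, deviation = dev[t],
          unstable = spec$type == "sequential" && t == 2L,
          stringsAsFactors = FALSE)
      }
    }
    provenance[[paste(p$site, p$plot, sep = "/")]] <-
      list(times = p$times, cells = p$cells)
  }
  structure(list(points = do.call(rbind, rows), type = spec$type,
                 spec = spec, provenance = provenance),
            class = "control_chart")
}

#' Baseline ("press") control chart
#'
#' For each plot, the baseline set is the union of all replicate
#' samples from the plot's first `m` time points; the charted deviation
#' at time `t` is the distance from the plot-time centroid to the
#' baseline centroid (on the dissimilarity scale, i.e. the square root
#' of the squared centroid distance).  Deviations are charted at every
#' time, including the baseline times themselves.
#'
#' @param d a [dissimilarity_matrix] or symmetric matrix.
#' @param metadata per-sample metadata (`site`, `plot`, `time`), rows
#'   aligned with `d`.
#' @param spec a [chart_spec()] with `type = "baseline"`.
#' @return An object of class `control_chart` with a tidy `points` data
#'   frame (`site`, `plot`, `time`, `time_index`, `deviation`,
#'   `unstable`) and per-plot provenance.
#' @export
chart_baseline <- function(d, metadata, spec = chart_spec("baseline")) {
  if (spec$type != "baseline") stop("spec$type must be 'baseline'")
  chart_build(d, metadata, spec)
}

#' Sequential ("pulse") control chart
#'
#' For each plot and each time `t >= 2`, the charted deviation is the
#' distance from the plot-time-`t` centroid to the centroid of all the
#' plot's observations at times `1 ... t-1`.  The reference moves with
#' the series, so one-off shocks stand out.  The first charted point
#' (`t = 2`, a single-time reference) is annotated `unstable`: the
#' chart typically needs time to stabilise and early exceedances are
#' more likely artifacts.
#'
#' @inheritParams chart_baseline
#' @param spec a [chart_spec()] with `type = "sequential"`.
#' @return A `control_chart`; see [chart_baseline()].
#' @export
chart_sequential <- function(d, metadata, spec = chart_spec("sequential")) {
  if (spec$type != "sequential") stop("spec$type must be 'sequential'")
  chart_build(d, metadata, spec)
}

#' @export
print.control_chart <- function(x, ...) {
  cat(sprintf("%s control chart: %d plotted points over %d plot(s)\n",
              x$type, nrow(x$points), length(x$provenance)))
  invisible(x)
}

#' Bootstrapped percentile control limits
#'
#' For each of `B` bootstrap iterations, the time-point observation
#' sets of every plot are independently resampled with replacement
#' (each (plot, time) cell travels with its full replicate set, and the
#' resampled cells fill time positions `1 ... T` in draw order), all
#' deviations are recomputed for the chart type, deviations are pooled
#' across all plots (and sites), and the requested percentiles recorded
#' — pooled over all charted times for the baseline chart, separately
#' per time index for the sequential chart (whose deviation
#' distribution changes as the reference accumulates).  The plotted
#' control limit is the mean of the `B` bootstrap percentile values.
#' Percentiles use the linear-interpolation empirical quantile
#' (type 7).
#'
#' @inheritParams chart_baseline
#' @param spec a [chart_spec()]; `spec$B` bootstrap samples,
#'   `spec$percentiles` limits, `spec$seed` stream.
#' @return An object of class `control_limits`: for baseline charts,
#'   `limits` is a named vector (one value per percentile, global over
#'   time); for sequential charts a matrix (time index x percentile).
#' @export
bootstrap_limits <- function(d, metadata, spec) {
  dv <- as_dissim_values(d)
  D2 <- dv^2
  pts <- plot_time_points(metadata)
  if (!length(pts)) stop("no plots found")
  Ts <- vapply(pts, function(p) length(p$times), 0L)
  if (any(Ts < 2L)) stop("every plot needs >= 2 time points")
  B <- spec$B
  qs <- spec$percentiles / 100
  max_T <- max(Ts)

  draw_stats <- with_seed(spec$seed, {
    if (spec$type == "baseline") {
      acc <- matrix(NA_real_, B, length(qs))
      for (bb in seq_len(B)) {
        pooled <- numeric(0)
        for (p in pts) {
          T_ <- length(p$times)
          cells <- p$cells[sample.int(T_, T_, replace = TRUE)]
          pooled <- c(pooled, plot_deviations(D2, cells, "baseline", spec$m))
        }
        acc[bb, ] <- stats::quantile(pooled, qs, type = 7, names = FALSE)
      }
      acc
    } else {
      acc <- array(NA_real_, c(B, max_T, length(qs)))
      for (bb in seq_len(B)) {
        per_time <- vector("list", max_T)
        for (p in pts) {
          T_ <- length(p$times)
          cells <- p$cells[sample.int(T_, T_, replace = TRUE)]
          dev <- plot_deviations(D2, cells, "sequential", spec$m)
          for (t in 2:T_)
            per_time[[t]] <- c(per_time[[t]], dev[t])
        }
        for (t in 2:max_T)
          if (length(per_time[[t]]))
            acc[bb, t, ] <- stats::quantile(per_time[[t]], qs, type = 7,
                                            names = FALSE)
      }
      acc
    }
  })

  if (spec$type == "baseline") {
    limits <- colMeans(draw_stats)
    names(limits) <- paste0("p", spec$percentiles)
  } else {
    limits <- apply(draw_stats, c(2L, 3L), mean)
    dimnames(limits) <- list(seq_len(max_T), paste0("p", spec$percentiles))
  }
  structure(list(limits = limits, type = spec$type,
                 percentiles = spec$percentiles, B = B, seed = spec$seed),
            class = "control_limits")
}

#' @export
print.control_limits <- function(x, ...) {
  cat(sprintf("%s control limits (B = %d bootstrap samples)\n", x$type, x$B))
  print(round(if (is.matrix(x$limits)) x$limits else x$limits, 4))
  invisible(x)
}

#' Flag out-of-control observations
#'
#' An observation is out of control when its deviation exceeds the 95th
#' percentile control limit (time-index-matched for sequential charts).
#' Flagging is suppressed at baseline times (`t <= m`) of baseline
#' charts by default, and sequential `t = 2` points keep their
#' `unstable` annotation — exceedances are 'alarm signals' that require
#' further investigation, not attributions of cause.
#'
#' @param chart a `control_chart`.
#' @param limits a `control_limits` of the same type.
#' @param flag_baseline_times chart baseline times too (default FALSE).
#' @return The chart's `points` data frame with columns `cl50`, `cl95`,
#'   `flag` and `unstable` added.
#' @export
flag_out_of_control <- function(chart, limits, flag_baseline_times = FALSE) {
  if (!identical(chart$type, limits$type))
    stop("chart type '", chart$type, "' does not match limits type '",
         limits$type, "'")
  pts <- chart$points
  if (is.null(pts) || nrow(pts) == 0L) {
    return(cbind(pts, data.frame(cl50 = numeric(0), cl95 = numeric(0),
                                 flag = logical(0))))
  }
  pcols <- paste0("p", limits$percentiles)
  if (!all(c("p50", "p95") %in% pcols))
    stop("limits must include the 50th and 95th percentiles")
  if (chart$type == "baseline") {
    pts$cl50 <- unname(limits$limits["p50"])
    pts$cl95 <- unname(limits$limits["p95"])
  } else {
    pts$cl50 <- limits$limits[pts$time_index, "p50"]
    pts$cl95 <- limits$limits[pts$time_index, "p95"]
  }
  pts$flag <- pts$deviation > pts$cl95
  if (chart$type == "baseline" && !flag_baseline_times)
    pts$flag[pts$time_index <= chart$spec$m] <- FALSE
  pts
}

#' Randomly assign replicates to pseudo-sample plots
#'
#' Where a site is sampled without distinct plots, the replicates
#' collected at one time are randomly partitioned into `k`
#' pseudo-plots (sizes differing by at most 1) so that a plot-based
#' control chart can still be constructed.  Labels are stable
#' (`"pseudo-1" ... "pseudo-k"`) so that assignments at different times
#' line up into series.
#'
#' @param sample_ids sample ids at one site-time.
#' @param k number of pseudo-plots.
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return Named character vector of pseudo-plot labels.
#' @export
assign_pseudo_plots <- function(sample_ids, k, seed = NULL) {
  if (k < 1) stop("k must be >= 1")
  n <- length(sample_ids)
  if (n < k)
    stop("fewer samples (", n, ") than pseudo-plots (", k, ")")
  lab <- with_seed(seed, {
    ord <- sample.int(n)
    rep_len(paste0("pseudo-", seq_len(k)), n)[order(ord)]
  })
  names(lab) <- sample_ids
  lab
}

#' Assign pseudo-plots across an entire site
#'
#' Applies [assign_pseudo_plots()] independently at each time of one
#' site, with per-time sub-seeds derived from `seed`.
#'
#' @param metadata per-sample metadata (`sample_id`, `time`).
#' @param k number of pseudo-plots.
#' @param seed integer master seed.
#' @return Character vector of pseudo-plot labels aligned with
#'   `metadata` rows.
#' @export
assign_pseudo_plots_by_time <- function(metadata, k, seed = NULL) {
  md <- as.data.frame(metadata)
  out <- character(nrow(md))
  for (tl in unique(md$time)) {
    ix <- which(md$time == tl)
    out[ix] <- assign_pseudo_plots(md$sample_id[ix], k,
                                   seed = subseed(seed, paste0("t", tl)))
  }
  out
}

#' Plot a control chart
#'
#' One panel per site: deviation series per plot (distinct symbols)
#' with dashed 50th and long-dashed 95th percentile control limits.
#'
#' @param x a flagged chart table from [flag_out_of_control()] (or a
#'   `control_chart`, plotted without limits).
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the plotted table.
#' @export
plot_control_chart <- function(x, ...) {
  pts <- if (inherits(x, "control_chart")) x$points else x
  sites <- unique(pts$site)
  op <- graphics::par(mfrow = c(length(sites), 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in sites) {
    sub <- pts[pts$site == s, ]
    plots <- unique(sub$plot)
    tix <- sort(unique(sub$time_index))
    ylim <- c(0, max(sub$deviation,
                     if ("cl95" %in% names(sub)) sub$cl95 else 0) * 1.1)
    graphics::plot(NA, xlim = range(tix), ylim = ylim, xaxt = "n",
                   xlab = "time", ylab = "deviation", main = s, ...)
    graphics::axis(1, at = tix,
                   labels = sub$time[match(tix, sub$time_index)])
    for (k in seq_along(plots)) {
      pp <- sub[sub$plot == plots[k], ]
      pp <- pp[order(pp$time_index), ]
      graphics::lines(pp$time_index, pp$deviation, type = "b", pch = k,
                      lty = 1)
      if ("flag" %in% names(pp) && any(pp$flag))
        graphics::points(pp$time_index[pp$flag], pp$deviation[pp$flag],
                         pch = 8, cex = 1.6)
    }
    if ("cl50" %in% names(sub)) {
      o <- order(sub$time_index)
      graphics::lines(sub$time_index[o], sub$cl50[o], lty = 2)
      graphics::lines(sub$time_index[o], sub$cl95[o], lty = 5)
    }
  }
  invisible(pts)
}
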