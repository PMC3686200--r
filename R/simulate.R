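# Synthetic lagoon-community generator: replicated plot-by-year survey
# designs with log-scale spatial/temporal effects, overdispersed
# (negative binomial) counts, strong numerical dominance gradients, and
# optional injected press or pulse disturbances, plus a ground-truth
# record so every downstream stage is testable without field data.

#' Disturbance specifications
#'
#' `disturbance_pulse()` multiplies the expected abundance of a random
#' fraction of taxa by `multiplier` at a single time (a one-off shock,
#' e.g. an extreme cold event).  `disturbance_press()` applies a
#' compounding per-step multiplicative trend `exp(log_trend)` to the
#' affected taxa from `start_time` onward (a sustained gradual change).
#'
#' @param time,start_time 1-based time index of the shock / trend onset.
#' @param taxon_fraction fraction of taxa affected (default 0.5).
#' @param multiplier multiplicative change in expectation (> 0).
#' @param log_trend per-step change on the log-abundance scale.
#' @return A disturbance spec list for [simulation_config()].
#' @export
disturbance_pulse <- function(time, taxon_fraction = 0.5, multiplier = 5) {
  if (multiplier <= 0) stop("multiplier must be > 0")
  list(kind = "pulse", time = as.integer(time),
       taxon_fraction = taxon_fraction, multiplier = multiplier)
}

#' @rdname disturbance_pulse
#' @export
disturbance_press <- function(start_time, taxon_fraction = 0.5,
                              log_trend = 0.2) {
  list(kind = "press", start_time = as.integer(start_time),
       taxon_fraction = taxon_fraction, log_trend = log_trend)
}

#' Simulation configuration
#'
#' Defaults mirror a replicated lagoon survey: 1 site with 3 plots
#' sampled over 5 years with 4 replicate samples per plot-year, 30
#' taxa, and expected abundances of the most and least abundant taxa
#' spanning 3 orders of magnitude.  Effects act multiplicatively on
#' expectations (log scale) so the fourth-root / Bray-Curtis pipeline
#' behaves as with real abundance data; counts are negative binomial
#' (gamma-Poisson) with a single dispersion shared across taxa.
#'
#' @param n_sites,n_plots,n_times,n_replicates design dimensions.
#' @param n_taxa taxa per site.
#' @param dominance_span orders of magnitude between the most and least
#'   abundant expected taxa (default 3); base expectations form a
#'   geometric ladder over this span.
#' @param base_min expected abundance of the rarest taxon (default 0.3
#'   individuals per sample).
#' @param plot_sd,time_sd,interaction_sd standard deviations of the
#'   per-taxon-per-level normal effects on the log-abundance scale.
#' @param dispersion negative binomial size parameter (variance
#'   `mu + mu^2/dispersion`); `Inf` gives the Poisson limit.
#' @param disturbance `NULL`, [disturbance_pulse()] or
#'   [disturbance_press()].
#' @param seed integer seed; the config plus seed fully determine the
#'   emitted matrix.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 1, n_plots = 3, n_times = 5,
                              n_replicates = 4, n_taxa = 30,
                              dominance_span = 3, base_min = 0.3,
                              plot_sd = 0.5, time_sd = 0.3,
                              interaction_sd = 0.2, dispersion = 2,
                              disturbance = NULL, seed = 1) {
  cfg <- list(n_sites = as.integer(n_sites), n_plots = as.integer(n_plots),
              n_times = as.integer(n_times),
              n_replicates = as.integer(n_replicates),
              n_taxa = as.integer(n_taxa),
              dominance_span = dominance_span, base_min = base_min,
              plot_sd = plot_sd, time_sd = time_sd,
              interaction_sd = interaction_sd, dispersion = dispersion,
              disturbance = disturbance, seed = seed)
  with(cfg, {
    if (any(c(n_sites, n_plots, n_times, n_replicates, n_taxa) < 1L))
      stop("design counts must all be >= 1")
    if (any(c(plot_sd, time_sd, interaction_sd) < 0))
      stop("effect sizes must be >= 0")
    if (dominance_span < 0) stop("dominance_span must be >= 0")
    if (base_min <= 0) stop("base_min must be > 0")
    if (dispersion <= 0) stop("dispersion must be > 0")
    if (!is.null(disturbance)) {
      if (identical(disturbance$kind, "pulse") &&
          (disturbance$time < 1L || disturbance$time > n_times))
        stop("pulse time outside the simulated series")
      if (identical(disturbance$kind, "press") &&
          (disturbance$start_time < 1L || disturbance$start_time > n_times))
        stop("press start time outside the simulated series")
      if (disturbance$taxon_fraction < 0 || disturbance$taxon_fraction > 1)
        stop("taxon_fraction must be in [0, 1]")
    }
  })
  structure(cfg, class = "simulation_config")
}

# log-scale disturbance offset for taxon set `affected` at time index t
disturbance_offset <- function(dist, affected, t, n_taxa) {
  off <- numeric(n_taxa)
  if (is.null(dist)) return(off)
  if (dist$kind == "pulse") {
    if (t == dist$time) off[affected] <- log(dist$multiplier)
  } else {
    if (t >= dist$start_time)
      off[affected] <- dist$log_trend * (t - dist$start_time + 1L)
  }
  off
}

#' Simulate a replicated community survey
#'
#' Taxon base expectations form a geometric ladder over the dominance
#' span; the cell expectation is
#' `base * exp(plot effect + time effect + interaction + disturbance)`,
#' with per-taxon effects drawn normal at each factor level (fixed
#' across replicates), and counts drawn negative binomial with the
#' configured dispersion.  Deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @return A list of class `community_simulation`: `community` (a
#'   [community_matrix]) and `truth` (expected abundances per cell,
#'   realised effect draws, disturbance incidence map, and the config).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  # effects, disturbance-taxon selection and count draws use separate
  # named sub-streams of the master seed, so injecting a disturbance
  # into an existing simulation never shifts the other draws
  {
    K <- cf$n_taxa
    bases <- if (K == 1L) cf$base_min else
      cf$base_min * 10^(cf$dominance_span * (seq_len(K) - 1L) / (K - 1L))
    n_samp <- cf$n_sites * cf$n_plots * cf$n_times * cf$n_replicates
    mu <- matrix(NA_real_, n_samp, K)
    meta <- data.frame(sample_id = character(n_samp), site = "",
                       plot = "", time = "", replicate = "",
                       stringsAsFactors = FALSE)
    effects <- list()
    dist_map <- matrix(FALSE, n_samp, K)
    row <- 0L
    eff_draws <- with_seed(subseed(cf$seed, "effects"), {
      lapply(seq_len(cf$n_sites), function(s) list(
        plot = matrix(stats::rnorm(K * cf$n_plots, 0, cf$plot_sd),
                      K, cf$n_plots),
        time = matrix(stats::rnorm(K * cf$n_times, 0, cf$time_sd),
                      K, cf$n_times),
        interaction = array(stats::rnorm(K * cf$n_plots * cf$n_times, 0,
                                         cf$interaction_sd),
                            c(K, cf$n_plots, cf$n_times))))
    })
    aff_draws <- with_seed(subseed(cf$seed, "disturbance"), {
      lapply(seq_len(cf$n_sites), function(s)
        if (!is.null(cf$disturbance))
          sort(sample.int(K, round(cf$disturbance$taxon_fraction * K)))
        else integer(0))
    })
    for (s in seq_len(cf$n_sites)) {
      plot_eff <- eff_draws[[s]]$plot
      time_eff <- eff_draws[[s]]$time
      int_eff <- eff_draws[[s]]$interaction
      affected <- aff_draws[[s]]
      effects[[s]] <- list(plot = plot_eff, time = time_eff,
                           interaction = int_eff, affected_taxa = affected)
      for (p in seq_len(cf$n_plots)) for (t in seq_len(cf$n_times)) {
        off <- disturbance_offset(cf$disturbance, affected, t, K)
        cell_mu <- bases * exp(plot_eff[, p] + time_eff[, t] +
                                 int_eff[, p, t] + off)
        for (r in seq_len(cf$n_replicates)) {
          row <- row + 1L
          mu[row, ] <- cell_mu
          dist_map[row, ] <- off != 0
          meta$sample_id[row] <- sprintf("s%d_p%d_t%d_r%d", s, p, t, r)
          meta$site[row] <- paste0("site", s)
          meta$plot[row] <- paste0("plot", p)
          meta$time[row] <- as.character(t)
          meta$replicate[row] <- paste0("r", r)
        }
      }
    }
    counts <- with_seed(subseed(cf$seed, "counts"), {
      if (is.infinite(cf$dispersion))
        stats::rpois(length(mu), lambda = mu)
      else stats::rnbinom(length(mu), mu = mu, size = cf$dispersion)
    })
    counts <- matrix(as.double(counts), n_samp, K)
    taxa <- sprintf("taxon%02d", seq_len(K))
    dimnames(counts) <- list(meta$sample_id, taxa)
    dimnames(mu) <- dimnames(dist_map) <- dimnames(counts)
    structure(list(
      community = community_matrix(counts, meta),
      truth = list(expected = mu, effects = effects, bases = bases,
                   disturbed = dist_map, config = cf)),
      class = "community_simulation")
  }
}

#' Re-simulate with a disturbance injected
#'
#' Rebuilds the same simulated survey (same seed, hence the same
#' realised effect draws and disturbance-taxon selection) with the
#' given disturbance applied to the cell expectations before the count
#' draws.  The returned ground truth records exactly which cells
#' changed.  A pulse with `multiplier = 1` or a press with
#' `log_trend = 0` leaves the distribution unchanged.
#'
#' @param sim a `community_simulation` from [simulate_community()].
#' @param disturbance a [disturbance_pulse()] or [disturbance_press()].
#' @return A new `community_simulation`.
#' @export
inject_disturbance <- function(sim, disturbance) {
  stopifnot(inherits(sim, "community_simulation"))
  cf <- sim$truth$config
  cf$disturbance <- disturbance
  simulate_community(do.call(simulation_config, unclass(cf)))
}

#' @export
print.community_simulation <- function(x, ...) {
  cf <- x$truth$config
  cat(sprintf("community_simulation: %d site(s) x %d plot(s) x %d time(s) x %d replicate(s), %d taxa\n",
              cf$n_sites, cf$n_plots, cf$n_times, cf$n_replicates, cf$n_taxa))
  if (!is.null(cf$disturbance))
    cat("  disturbance:", cf$disturbance$kind, "\n")
  invisible(x)
}

#' Write a simulated survey to disk
#'
#' Emits the standard community CSV (embedded metadata columns), a
#' companion metadata CSV, and the ground truth as JSON.
#'
#' @param sim a `community_simulation`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_lagoon_survey <- function(sim, dir) {
  if (inherits(sim, "simulation_config")) sim <- simulate_community(sim)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(community = file.path(dir, "community.csv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.json"))
  write_community_csv(sim$community, paths[["community"]])
  utils::write.csv(sim$community$metadata, paths[["metadata"]],
                   row.names = FALSE)
  truth <- sim$truth
  truth$config$disturbance <- truth$config$disturbance  # keep NULL as absent
  jsonlite::write_json(
    list(expected = truth$expected, bases = truth$bases,
         disturbed_cells = which(truth$disturbed, arr.ind = TRUE),
         seed = truth$config$seed),
    paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
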