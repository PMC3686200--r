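# End-to-end monitoring workflow: transform -> Bray-Curtis -> clustering
# with SIMPROF -> PERMANOVA (+ pairwise, components) -> PERMDISP ->
# control charts with bootstrapped limits, with file export and a run
# manifest.  A single master seed fans out to named sub-streams so
# toggling one stage never shifts another's randomness.

#' Run the community monitoring workflow
#'
#' Executes the full analysis on a community matrix (or a simulation
#' config): fourth-root transform, Bray-Curtis dissimilarities,
#' SIMPROF-validated clustering, per-site PERMANOVA (two-way crossed
#' mixed with time fixed and plot random where a site has several
#' plots, one-way on time otherwise), pairwise year comparisons,
#' PERMDISP on each main effect, and both control chart types with
#' bootstrapped 50th/95th percentile limits and out-of-control flags.
#'
#' @param community a [community_matrix], or `NULL` to simulate from
#'   `config`.
#' @param config optional [simulation_config()] used when `community`
#'   is `NULL`.
#' @param n_perm permutations for all tests (default 9999).
#' @param B bootstrap samples for control limits (default 10000).
#' @param alpha significance level (default 0.05).
#' @param baseline_m baseline size for the press chart (default 2).
#' @param seed master seed; sub-streams are derived per stage.
#' @param do_cluster,do_permanova,do_permdisp,do_charts stage toggles.
#' @param out_dir optional directory; when given, term tables, the
#'   pairwise table, cluster assignments, tidy chart CSVs, a Newick
#'   dendrogram and a JSON run manifest (seeds, parameters, file
#'   hashes) are written there.
#' @return An object of class `community_workflow` collecting all stage
#'   results.
#' @export
run_community_workflow <- function(community = NULL, config = NULL,
                                   n_perm = 9999, B = 10000, alpha = 0.05,
                                   baseline_m = 2, seed = 1,
                                   do_cluster = TRUE, do_permanova = TRUE,
                                   do_permdisp = TRUE, do_charts = TRUE,
                                   out_dir = NULL) {
  if (n_perm < 1 || B < 1 || alpha <= 0 || alpha >= 1)
    stop("invalid workflow parameters")
  sim <- NULL
  if (is.null(community)) {
    if (is.null(config)) stop("supply a community matrix or a simulation config")
    sim <- simulate_community(config)
    community <- sim$community
  }
  stopifnot(inherits(community, "community_matrix"))

  trans <- fourth_root_transform(community)
  d <- suppressWarnings(bray_curtis(trans))
  md <- community$metadata
  res <- list(community = community, transformed = trans, dissimilarity = d,
              simulation = sim,
              params = list(n_perm = n_perm, B = B, alpha = alpha,
                            baseline_m = baseline_m, seed = seed))

  if (do_cluster) {
    res$clusters <- significant_clusters(
      trans, d, alpha = alpha,
      n_perm_mean = min(1000, n_perm + 1), n_perm_test = min(999, n_perm),
      seed = subseed(seed, "simprof"))
  }

  if (do_permanova) {
    res$permanova <- list()
    res$pairwise <- list()
    for (s in unique(md$site)) {
      ix <- which(md$site == s)
      dv <- d$values[ix, ix, drop = FALSE]
      if (length(unique(md$plot[ix])) > 1L) {
        res$permanova[[s]] <- permanova_twoway_mixed(
          dv, fixed = md$time[ix], random = md$plot[ix], n_perm = n_perm,
          seed = subseed(seed, paste0("permanova_", s)),
          fixed_name = "time", random_name = "plot")
        res$pairwise[[s]] <- pairwise_table(
          dv, fixed = md$time[ix], random = md$plot[ix], n_perm = n_perm,
          seed = subseed(seed, paste0("pairwise_", s)))
      } else {
        res$permanova[[s]] <- permanova_oneway(
          dv, md$time[ix], n_perm = n_perm,
          seed = subseed(seed, paste0("permanova_", s)),
          factor_name = "time")
        res$pairwise[[s]] <- pairwise_table(
          dv, fixed = md$time[ix], n_perm = n_perm,
          seed = subseed(seed, paste0("pairwise_", s)))
      }
    }
  }

  if (do_permdisp) {
    res$permdisp <- list()
    for (s in unique(md$site)) {
      ix <- which(md$site == s)
      dv <- d$values[ix, ix, drop = FALSE]
      res$permdisp[[s]] <- list()
      for (fac in c("time", "plot")) {
        g <- md[[fac]][ix]
        if (length(unique(g)) < 2L || any(table(g) < 2L)) next
        res$permdisp[[s]][[fac]] <- permdisp(
          dv, g, n_perm = n_perm,
          seed = subseed(seed, paste0("permdisp_", s, "_", fac)))
      }
    }
  }

  if (do_charts) {
    res$charts <- list()
    for (type in c("baseline", "sequential")) {
      spec <- chart_spec(type, m = baseline_m, B = B,
                         seed = subseed(seed, paste0("bootstrap_", type)))
      chart <- chart_build(d, md, spec)
      limits <- bootstrap_limits(d, md, spec)
      res$charts[[type]] <- list(chart = chart, limits = limits,
                                 table = flag_out_of_control(chart, limits))
    }
  }

  res <- structure(res, class = "community_workflow")
  if (!is.null(out_dir)) write_workflow(res, out_dir)
  res
}

#' @export
print.community_workflow <- function(x, ...) {
  cat("Community monitoring workflow\n")
  cat(" ", nrow(x$community$abundance), "samples,",
      ncol(x$community$abundance), "taxa\n")
  if (!is.null(x$clusters))
    cat("  SIMPROF clusters:", length(unique(x$clusters$cluster)), "\n")
  if (!is.null(x$permanova))
    for (s in names(x$permanova)) {
      tab <- x$permanova[[s]]$tab
      sig <- tab$term[!is.na(tab$P_perm) & tab$P_perm <= x$params$alpha]
      cat(sprintf("  %s PERMANOVA significant term(s): %s\n", s,
                  if (length(sig)) paste(sig, collapse = ", ") else "none"))
    }
  if (!is.null(x$charts)) {
    fl <- flagged_points(x)
    cat("  out-of-control points:", nrow(fl), "\n")
  }
  invisible(x)
}

flagged_points <- function(wf) {
  out <- list()
  for (type in names(wf$charts)) {
    tab <- wf$charts[[type]]$table
    hit <- tab[tab$flag & !tab$unstable, , drop = FALSE]
    if (nrow(hit)) {
      hit$chart_type <- type
      out[[type]] <- hit
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(site = character(0), plot = character(0),
               time = character(0), chart_type = character(0))
}

# Pairwise table in the two-block layout (upper block t, lower block
# P(perm)) used for survey reports.
pairwise_blocks <- function(pw) {
  levels <- order_time_labels(c(pw$level1, pw$level2))
  k <- length(levels)
  tmat <- pmat <- matrix(NA_real_, k, k, dimnames = list(levels, levels))
  for (i in seq_len(nrow(pw))) {
    a <- pw$level1[i]; b <- pw$level2[i]
    tmat[b, a] <- pw$t[i]
    pmat[b, a] <- pw$P_perm[i]
  }
  list(t = tmat, P = pmat)
}

#' Write workflow outputs and a run manifest
#'
#' Writes per-site PERMANOVA term tables, components of variation,
#' pairwise tables (t and P blocks), PERMDISP summaries, cluster
#' assignments, a Newick dendrogram, tidy chart CSVs
#' (site, plot, time, chart_type, deviation, cl50, cl95, flag,
#' unstable) and `manifest.json` recording every seed, parameter and an
#' MD5 hash of every file written.
#'
#' @param wf a `community_workflow`.
#' @param dir output directory.
#' @return Invisibly, the manifest list.
#' @export
write_workflow <- function(wf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(obj, name) {
    path <- file.path(dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    files <<- c(files, path)
  }
  if (!is.null(wf$permanova)) {
    for (s in names(wf$permanova)) {
      put(wf$permanova[[s]]$tab, paste0("permanova_", s, ".csv"))
      if (!is.null(wf$permanova[[s]]$components))
        put(wf$permanova[[s]]$components,
            paste0("components_", s, ".csv"))
      put(wf$pairwise[[s]], paste0("pairwise_", s, ".csv"))
    }
  }
  if (!is.null(wf$permdisp)) {
    rows <- list()
    for (s in names(wf$permdisp))
      for (fac in names(wf$permdisp[[s]])) {
        pd <- wf$permdisp[[s]][[fac]]
        rows[[paste(s, fac)]] <- data.frame(
          site = s, factor = fac, F = pd$F, P_perm = pd$P_perm,
          n_perm = pd$n_perm, stringsAsFactors = FALSE)
      }
    if (length(rows)) put(do.call(rbind, rows), "permdisp.csv")
  }
  if (!is.null(wf$clusters)) {
    put(data.frame(sample_id = names(wf$clusters$cluster),
                   cluster = unname(wf$clusters$cluster),
                   stringsAsFactors = FALSE), "clusters.csv")
    write_newick(wf$clusters$tree, file.path(dir, "dendrogram.nwk"))
    files <- c(files, file.path(dir, "dendrogram.nwk"))
  }
  if (!is.null(wf$charts)) {
    tabs <- lapply(names(wf$charts), function(type) {
      tab <- wf$charts[[type]]$table
      tab$chart_type <- type
      tab[c("site", "plot", "time", "chart_type", "deviation",
            "cl50", "cl95", "flag", "unstable")]
    })
    put(do.call(rbind, tabs), "control_charts.csv")
  }
  manifest <- list(
    params = wf$params,
    stages = setdiff(intersect(names(wf),
                               c("clusters", "permanova", "permdisp",
                                 "charts")),
                     character(0)),
    n_samples = nrow(wf$community$abundance),
    n_taxa = ncol(wf$community$abundance),
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarise a workflow run in plain text
#'
#' Human-readable digest: significant PERMANOVA terms, dispersion test
#' outcomes, cluster count, and every flagged (plot, time) — or a "no
#' out-of-control observations" line when the charts are clean.
#'
#' @param x a `community_workflow`, or a directory containing a
#'   `manifest.json` written by [write_workflow()].
#' @return Character vector of summary lines (also printed).
#' @export
summarize_workflow <- function(x) {
  if (is.character(x)) {
    manifest_path <- file.path(x, "manifest.json")
    if (!file.exists(manifest_path))
      stop("no manifest.json in ", x)
    man <- jsonlite::read_json(manifest_path)
    lines <- c(sprintf("workflow run: %s samples, %s taxa",
                       man$n_samples, man$n_taxa),
               sprintf("stages: %s",
                       paste(unlist(man$stages), collapse = ", ")))
    charts_path <- file.path(x, "control_charts.csv")
    if (file.exists(charts_path)) {
      tab <- utils::read.csv(charts_path)
      hit <- tab[tab$flag & !tab$unstable, , drop = FALSE]
      lines <- c(lines, if (nrow(hit) == 0L)
        "no out-of-control observations"
        else sprintf("out of control: %s %s plot %s time %s",
                     hit$chart_type, hit$site, hit$plot, hit$time))
    }
    cat(lines, sep = "\n")
    return(invisible(lines))
  }
  stopifnot(inherits(x, "community_workflow"))
  lines <- character(0)
  if (!is.null(x$permanova))
    for (s in names(x$permanova)) {
      tab <- x$permanova[[s]]$tab
      sig <- tab$term[!is.na(tab$P_perm) & tab$P_perm <= x$params$alpha]
      lines <- c(lines, sprintf("%s: significant PERMANOVA term(s): %s", s,
                                if (length(sig)) paste(sig, collapse = ", ")
                                else "none"))
    }
  if (!is.null(x$permdisp))
    for (s in names(x$permdisp))
      for (fac in names(x$permdisp[[s]])) {
        pd <- x$permdisp[[s]][[fac]]
        lines <- c(lines, sprintf(
          "%s: dispersion (%s) F = %.3g, P = %.3g%s", s, fac, pd$F,
          pd$P_perm,
          if (pd$P_perm <= x$params$alpha) " (heterogeneous)" else ""))
      }
  if (!is.null(x$clusters))
    lines <- c(lines, sprintf("SIMPROF clusters: %d",
                              length(unique(x$clusters$cluster))))
  if (!is.null(x$charts)) {
    fl <- flagged_points(x)
    lines <- c(lines, if (nrow(fl) == 0L) "no out-of-control observations"
               else sprintf("out of control: %s chart, %s plot %s, time %s",
                            fl$chart_type, fl$site, fl$plot, fl$time))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
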