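# Community abundance matrices: construction, I/O, filtering/pooling,
# transformation, and Bray-Curtis dissimilarity.

#' Construct a community matrix
#'
#' A `community_matrix` holds a samples x taxa table of non-negative
#' abundances (individuals per standard sample area) together with
#' per-sample metadata: site, plot, time and replicate labels.  It is the
#' entry point of every analysis in the package.
#'
#' @param abundance numeric matrix, samples as rows, taxa as columns;
#'   dimnames give sample and taxon labels.
#' @param metadata data frame with columns `sample_id`, `site`, `plot`,
#'   `time`, `replicate`, one row per sample of `abundance`.
#' @return An object of class `community_matrix` with components
#'   `abundance` (matrix) and `metadata` (data frame, rows aligned with
#'   the matrix).
#' @export
community_matrix <- function(abundance, metadata) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("sample", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("taxon", seq_len(ncol(abundance)))
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  need <- c("sample_id", "site", "plot", "time", "replicate")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  metadata <- metadata[, need]
  for (nm in need) metadata[[nm]] <- as.character(metadata[[nm]])
  m <- structure(list(abundance = abundance, metadata = metadata),
                 class = "community_matrix")
  validate_community(m)
}

validate_community <- function(m) {
  ab <- m$abundance
  md <- m$metadata
  if (anyNA(ab)) stop("abundance matrix contains missing cells")
  if (any(ab < 0)) {
    bad <- which(ab < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(ab)[bad[1L]], colnames(ab)[bad[2L]]))
  }
  if (anyDuplicated(rownames(ab)))
    stop("duplicate sample label: ", rownames(ab)[anyDuplicated(rownames(ab))])
  if (anyDuplicated(colnames(ab)))
    stop("duplicate taxon label: ", colnames(ab)[anyDuplicated(colnames(ab))])
  if (nrow(md) != nrow(ab))
    stop("metadata has ", nrow(md), " rows but abundance has ", nrow(ab), " samples")
  if (!identical(md$sample_id, rownames(ab))) {
    if (!setequal(md$sample_id, rownames(ab)))
      stop("metadata sample_id set does not match abundance sample labels")
    md <- md[match(rownames(ab), md$sample_id), , drop = FALSE]
    rownames(md) <- NULL
    m$metadata <- md
  }
  if (anyNA(md) || any(md == ""))
    stop("metadata contains missing values")
  key <- do.call(paste, c(md[c("site", "plot", "time", "replicate")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicated (site, plot, time, replicate) tuple: ",
         gsub("\r", "/", key[anyDuplicated(key)]))
  m
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix:", nrow(x$abundance), "samples x",
      ncol(x$abundance), "taxa\n")
  cat("  sites:", paste(unique(x$metadata$site), collapse = ", "), "\n")
  cat("  plots per site:",
      paste(tapply(x$metadata$plot, x$metadata$site,
                   function(p) length(unique(p))), collapse = ", "), "\n")
  cat("  times:", paste(order_time_labels(x$metadata$time), collapse = ", "), "\n")
  invisible(x)
}

#' Read a community abundance table from delimited text
#'
#' Reads a comma-delimited abundance table with a header row.  Metadata
#' (site, plot, time, replicate) may be embedded as reserved leading
#' columns, or supplied in a companion CSV keyed by `sample_id`.
#'
#' @param path path to the community CSV.  With samples as rows the first
#'   column holds sample ids; with `taxa_as_rows = TRUE` the table is
#'   transposed on read.
#' @param taxa_as_rows logical; set `TRUE` when taxa are rows.
#' @param metadata_path optional companion metadata CSV with columns
#'   `sample_id`, `site`, `plot`, `time`, `replicate`.
#' @return A [community_matrix].
#' @export
read_community_csv <- function(path, taxa_as_rows = FALSE, metadata_path = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2L) stop("community table needs an id column plus data columns")
  if (taxa_as_rows) {
    taxa <- raw[[1L]]
    vals <- t(as.matrix(raw[, -1L, drop = FALSE]))
    colnames(vals) <- taxa
    raw <- data.frame(sample_id = rownames(vals), vals, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  meta_cols <- intersect(c("site", "plot", "time", "replicate"), names(body))
  if (!is.null(metadata_path)) {
    md <- utils::read.csv(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
    if (!"sample_id" %in% names(md))
      stop("metadata file must have a sample_id column")
    hit <- match(ids, md$sample_id)
    if (anyNA(hit))
      stop("metadata missing for sample(s): ",
           paste(ids[is.na(hit)], collapse = ", "))
    md <- md[hit, , drop = FALSE]
  } else {
    if (length(meta_cols) < 4L)
      stop("embedded metadata columns missing: ",
           paste(setdiff(c("site", "plot", "time", "replicate"), meta_cols),
                 collapse = ", "))
    md <- data.frame(sample_id = ids, body[meta_cols],
                     stringsAsFactors = FALSE)
    body <- body[, setdiff(names(body), meta_cols), drop = FALSE]
  }
  if (any(!nzchar(as.matrix(body))) || anyNA(as.matrix(body)))
    stop("blank abundance cell in ", path)
  num <- suppressWarnings(
    matrix(as.numeric(as.matrix(body)), nrow = nrow(body),
           dimnames = list(ids, names(body))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric abundance at sample '%s', taxon '%s'",
                 ids[bad[1L]], names(body)[bad[2L]]))
  }
  community_matrix(num, md)
}

#' Write a community matrix as CSV with embedded metadata columns
#'
#' @param m a [community_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_community_csv <- function(m, path) {
  out <- data.frame(sample_id = m$metadata$sample_id,
                    m$metadata[c("site", "plot", "time", "replicate")],
                    m$abundance, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Drop and pool taxa
#'
#' Removes listed taxa and sums groups of taxa under new labels, e.g. to
#' exclude groups that cannot be used quantitatively or to repair
#' taxonomic inconsistencies between surveys.  Merge maps are explicit:
#' no taxonomy parsing is attempted.
#'
#' @param m a [community_matrix].
#' @param drop character vector of taxon labels to remove.
#' @param merge named character vector mapping old taxon label (name) to
#'   new pooled label (value); taxa sharing a new label are summed.
#' @return A [community_matrix] with the same samples.
#' @export
filter_and_aggregate <- function(m, drop = character(), merge = character()) {
  taxa <- colnames(m$abundance)
  drop <- as.character(drop)
  unknown <- setdiff(c(drop, names(merge)), taxa)
  if (length(unknown))
    stop("unknown taxon label(s): ", paste(unknown, collapse = ", "))
  both <- intersect(drop, names(merge))
  if (length(both))
    stop("taxon in both drop and merge: ", paste(both, collapse = ", "))
  ab <- m$abundance[, setdiff(taxa, drop), drop = FALSE]
  if (length(merge)) {
    grp <- colnames(ab)
    hit <- match(grp, names(merge))
    grp[!is.na(hit)] <- unname(merge[hit[!is.na(hit)]])
    pooled <- sapply(unique(grp), function(g)
      rowSums(ab[, grp == g, drop = FALSE]))
    ab <- matrix(pooled, nrow = nrow(ab),
                 dimnames = list(rownames(ab), unique(grp)))
  }
  community_matrix(ab, m$metadata)
}

#' Pool replicate samples
#'
#' Sums abundances over samples sharing the same metadata key tuple
#' (default site/plot/time), mirroring field pooling of replicate cores.
#' The replicate label of pooled samples is set to `"pooled"`.
#'
#' @param m a [community_matrix].
#' @param keys metadata fields to pool over, a subset of
#'   `c("site", "plot", "time")`.
#' @return A [community_matrix] with one sample per key tuple.
#' @export
pool_replicates <- function(m, keys = c("site", "plot", "time")) {
  if (nrow(m$abundance) == 0L) stop("cannot pool an empty community matrix")
  if (!all(keys %in% c("site", "plot", "time")))
    stop("keys must be a subset of site, plot, time")
  md <- m$metadata
  key <- do.call(paste, c(md[keys], sep = "_"))
  ukey <- unique(key)
  ab <- t(sapply(ukey, function(k)
    colSums(m$abundance[key == k, , drop = FALSE])))
  if (ncol(m$abundance) == 1L) {
    ab <- matrix(ab, ncol = 1L, dimnames = list(ukey, colnames(m$abundance)))
  } else rownames(ab) <- ukey
  first <- match(ukey, key)
  md2 <- data.frame(sample_id = ukey, md[first, c("site", "plot", "time")],
                    replicate = "pooled", stringsAsFactors = FALSE)
  for (f in setdiff(c("site", "plot", "time"), keys)) md2[[f]] <- "all"
  community_matrix(ab, md2)
}

#' Fourth-root transform abundances
#'
#' Applies the severe down-weighting transform `y^(1/4)` cell-wise so
#' that analyses respond to the whole community rather than to taxa with
#' extreme numerical dominance (abundances spanning up to three orders
#' of magnitude are common in lagoon infauna).
#'
#' @param m a [community_matrix] of non-negative abundances.
#' @return A [community_matrix] of transformed values; metadata unchanged.
#' @export
fourth_root_transform <- function(m) {
  if (any(m$abundance < 0)) stop("fourth-root transform requires non-negative input")
  m$abundance <- m$abundance^0.25
  m
}

#' Construct a dissimilarity matrix
#'
#' Square symmetric pairwise dissimilarities with sample labels; the
#' substrate of every test in the package.  Bray-Curtis values live on
#' \[0, 1\]; other measures need only be non-negative.
#'
#' @param values square numeric matrix of dissimilarities.
#' @param sample_ids optional sample labels (default taken from dimnames).
#' @param range permitted value range, default `c(0, 1)`.
#' @return An object of class `dissimilarity_matrix`.
#' @export
dissimilarity_matrix <- function(values, sample_ids = NULL, range = c(0, 1)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("dissimilarity matrix must be square")
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  dimnames(values) <- list(sample_ids, sample_ids)
  if (anyNA(values)) stop("dissimilarity matrix contains missing values")
  if (max(abs(values - t(values))) > 1e-12)
    stop("dissimilarity matrix is not symmetric")
  values <- (values + t(values)) / 2
  if (max(abs(diag(values))) > 1e-12) stop("dissimilarity diagonal must be zero")
  diag(values) <- 0
  if (any(values < range[1L] - 1e-12) || any(values > range[2L] + 1e-12))
    stop("dissimilarity values outside declared range [",
         range[1L], ", ", range[2L], "]")
  structure(list(values = values, sample_ids = sample_ids, range = range),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat("dissimilarity_matrix:", length(x$sample_ids), "samples, range [",
      x$range[1L], ",", x$range[2L], "]\n")
  invisible(x)
}

# Shared Bray-Curtis on a plain abundance matrix; pairs of all-zero
# samples are defined as identical (d = 0).
bc_dissim <- function(ab, warn = TRUE) {
  # vegdist warns about empty rows itself; the all-zero-pair condition
  # is detected and reported here instead
  d <- as.matrix(suppressWarnings(vegan::vegdist(ab, method = "bray")))
  if (anyNA(d)) {
    if (warn)
      warning("all-zero sample pair(s): Bray-Curtis undefined, set to 0",
              call. = FALSE)
    d[is.na(d)] <- 0
  }
  d
}

#' Bray-Curtis dissimilarity of a community matrix
#'
#' Computes `d_ij = sum_k |y_ik - y_jk| / sum_k (y_ik + y_jk)` between
#' all pairs of samples.  A pair of samples that are both all-zero has an
#' undefined ratio; it is defined here as `d = 0` (two empty samples are
#' treated as identical) and a warning is emitted.
#'
#' @param m a [community_matrix] (usually fourth-root transformed).
#' @return A [dissimilarity_matrix] on \[0, 1\].
#' @export
bray_curtis <- function(m) {
  if (nrow(m$abundance) < 2L) stop("Bray-Curtis needs at least 2 samples")
  dissimilarity_matrix(bc_dissim(m$abundance),
                       sample_ids = rownames(m$abundance))
}

#' Write / read a labelled square dissimilarity CSV
#'
#' First row and first column carry the sample ids.
#'
#' @param d a [dissimilarity_matrix].
#' @param path file path.
#' @return `write_dissimilarity_csv` returns `path` invisibly;
#'   `read_dissimilarity_csv` returns a [dissimilarity_matrix].
#' @export
write_dissimilarity_csv <- function(d, path) {
  out <- data.frame(sample_id = d$sample_ids, d$values, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity_csv
#' @export
read_dissimilarity_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  dissimilarity_matrix(vals, sample_ids = ids,
                       range = c(0, max(1, max(vals))))
}
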