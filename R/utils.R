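# Internal helpers: localized RNG, sub-seed streams, clip diagnostics.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

# Deterministic named sub-stream of a master seed, kept inside 32-bit
# integer range so toggling one analysis stage never shifts another's
# randomness.
subseed <- function(master, stream) {
  if (is.null(master)) return(NULL)
  ch <- utf8ToInt(stream)
  h <- sum((ch %% 64) * (seq_along(ch) %% 97)) * 131
  as.integer((abs(as.double(master)) * 48271 + h) %% 2147483629) + 1L
}

# Diagnostics stream for negative squared centroid distances (semimetric
# dissimilarities such as Bray-Curtis are not Euclidean-embeddable, so
# the D^2 identity can go slightly negative before clipping).
.clipdiag <- new.env(parent = emptyenv())
.clipdiag$count <- 0L
.clipdiag$most_negative <- 0

note_clip <- function(value) {
  .clipdiag$count <- .clipdiag$count + 1L
  if (value < .clipdiag$most_negative) .clipdiag$most_negative <- value
  invisible(NULL)
}

#' Clipping diagnostics for semimetric centroid geometry
#'
#' Squared centroid distances computed from a semimetric dissimilarity
#' (e.g. Bray-Curtis) can be negative; the package clips them to zero and
#' records each event.  `clip_diagnostics()` reports how often clipping
#' fired and the most negative raw value seen since the last reset.
#'
#' @return A list with elements `count` and `most_negative`.
#' @export
clip_diagnostics <- function() {
  list(count = .clipdiag$count, most_negative = .clipdiag$most_negative)
}

#' @rdname clip_diagnostics
#' @export
reset_clip_diagnostics <- function() {
  .clipdiag$count <- 0L
  .clipdiag$most_negative <- 0
  invisible(NULL)
}

# Numeric-aware ordering of time labels: numeric sort when every label
# parses as a number, lexicographic otherwise.
order_time_labels <- function(times) {
  u <- unique(as.character(times))
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else sort(u)
}
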