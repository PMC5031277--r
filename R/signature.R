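#' Apportion signature seats across sub-hierarchies
#'
#' Turns a target weight vector into integer per-sub-hierarchy seat counts
#' summing exactly to `n`, by largest-remainder (Hamilton) apportionment with
#' two side constraints: every sub-hierarchy gets at least one seat (so every
#' stratum is represented in the signature) and no sub-hierarchy gets more
#' seats than it has classes. Equivalently: the allocation minimises
#' `sum(|seats - n * weights|)` subject to those bounds, found by a greedy
#' fill that is optimal because the objective is separable and convex.
#'
#' @param weights named non-negative numeric vector summing to 1.
#' @param n total number of seats (`n >= length(weights)`).
#' @param capacity named integer vector of per-sub-hierarchy class counts
#'   (each >= 1, `sum(capacity) >= n`).
#' @return Named integer vector of seats, same names as `weights`,
#'   summing to `n`.
#' @examples
#' allocate_seats(c(A = 0.5, B = 0.3, C = 0.2), 10,
#'                c(A = 100, B = 100, C = 100))  # 5 3 2
#' @export
allocate_seats <- function(weights, n, capacity) {
  check(is.numeric(weights) && !is.null(names(weights)) && all(weights >= 0),
        "'weights' must be a named non-negative numeric vector")
  check(abs(sum(weights) - 1) < 1e-6, "'weights' must sum to 1 (got %g)",
        sum(weights))
  K <- length(weights)
  check(is_count(n, min = 1L) && n >= K,
        "'n' (%s) must be an integer >= number of sub-hierarchies (%d)",
        as.character(n), K)
  check(all(names(weights) %in% names(capacity)),
        "'capacity' must cover every sub-hierarchy in 'weights'")
  cap <- as.integer(capacity[names(weights)])
  check(all(cap >= 1L), "every capacity must be >= 1")
  check(sum(cap) >= n, "total capacity (%d) is smaller than n (%d)",
        sum(cap), n)

  quota <- n * as.numeric(weights)
  seats <- rep(1L, K)  # the minimum-one rule binds from below
  remaining <- as.integer(n) - K
  # marginal cost of seat s -> s+1 under sum|seats - quota| is
  # |s+1-q| - |s-q|: -1 below floor(q), 1-2*frac(q) at the floor, +1 above.
  # Greedy by minimal marginal cost (ties: larger quota, then name order)
  # is optimal for a separable convex objective with box constraints.
  while (remaining > 0L) {
    open <- which(seats < cap)
    dcost <- abs(seats[open] + 1L - quota[open]) - abs(seats[open] - quota[open])
    ord <- order(dcost, -quota[open], names(weights)[open])
    pick <- open[ord[1L]]
    seats[pick] <- seats[pick] + 1L
    remaining <- remaining - 1L
  }
  stats::setNames(as.integer(seats), names(weights))
}

#' Draw a stratified random signature
#'
#' Samples `n` classes from the ontology following a target sub-hierarchy
#' weight vector: seats are apportioned with [allocate_seats()] (at least one
#' class per sub-hierarchy, never more than a stratum holds), then classes
#' are drawn uniformly *without* replacement within each stratum. The draw is
#' deterministic for a fixed `rng_seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param graph an `ontology`.
#' @param weights named weight vector over the graph's sub-hierarchies
#'   (fractions summing to 1); defaults to the source ontology's own relative
#'   frequencies, the bootstrap choice of the rebalancing algorithm.
#' @param n signature size.
#' @param rng_seed integer seed.
#' @return A `signature`: list with `classes` (sorted character vector),
#'   `weights`, `allocation`, `size` and `rng_seed`.
#' @export
sample_signature <- function(graph, weights = NULL, n, rng_seed) {
  stopifnot(inherits(graph, "ontology"))
  prof <- shape_profile(graph)
  if (is.null(weights)) weights <- prof$freqs / 100
  shs <- names(prof$counts)
  check(setequal(names(weights), shs),
        "'weights' must be named by the graph's sub-hierarchies")
  weights <- weights[shs]
  alloc <- allocate_seats(weights, n, prof$counts)
  strata <- split(names(graph$subhierarchy), graph$subhierarchy)
  classes <- with_seed(rng_seed, {
    unlist(lapply(shs, function(k) {
      pool <- sort(strata[[k]])
      if (alloc[[k]] == length(pool)) pool else pool[sample.int(length(pool), alloc[[k]])]
    }), use.names = FALSE)
  })
  structure(list(classes = sort(classes), weights = weights,
                 allocation = alloc, size = as.integer(n),
                 rng_seed = as.integer(rng_seed)),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature> %d classes over %d sub-hierarchies (seed %d)\n",
              x$size, length(x$allocation), x$rng_seed))
  top <- sort(x$allocation, decreasing = TRUE)
  cat("  largest strata:",
      paste(sprintf("%s=%d", names(utils::head(top, 4L)), utils::head(top, 4L)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a signature as a seed-list file
#'
#' One class id per line, with a `#` header recording size and seed so the
#' file is self-describing; readable back with [read_seed_file()].
#'
#' @param signature a `signature`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_seed_file <- function(signature, path) {
  stopifnot(inherits(signature, "signature"))
  writeLines(c(sprintf("# signature: %d classes, rng_seed %d",
                       signature$size, signature$rng_seed),
               signature$classes), path)
  invisible(path)
}
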