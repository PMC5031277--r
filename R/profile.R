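#' Sub-hierarchy shape profile of a class set
#'
#' Counts classes per sub-hierarchy and converts the counts to relative
#' frequencies in percent. The "shape" of an ontology or module is this
#' frequency vector; two class sets have a similar shape when their
#' sub-hierarchy frequencies are close. The root is structural and is never
#' counted.
#'
#' @param graph an `ontology`.
#' @param subset optional character vector of class ids to profile; defaults
#'   to all classes. Sub-hierarchies of the graph absent from the subset
#'   appear with count 0.
#' @return A `shape_profile`: list with `counts` (named integer vector over
#'   all of the graph's sub-hierarchies), `total` and `freqs` (percent; empty
#'   when `total` is 0).
#' @examples
#' g <- ontology("R", parents = list(R = character(), A = "R", B = "R",
#'                                   A1 = "A", B1 = "B"))
#' shape_profile(g)$freqs  # A: 50, B: 50
#' @export
shape_profile <- function(graph, subset = NULL) {
  stopifnot(inherits(graph, "ontology"))
  shs <- subhierarchies(graph)
  if (is.null(subset)) {
    members <- setdiff(graph$ids, graph$root)
  } else {
    subset <- unique(as.character(subset))
    unknown <- setdiff(subset, graph$ids)
    check(length(unknown) == 0L, "unknown class id(s) in subset: %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
    members <- setdiff(subset, graph$root)
  }
  counts <- stats::setNames(integer(length(shs)), shs)
  if (length(members) > 0L) {
    tab <- table(graph$subhierarchy[members])
    counts[names(tab)] <- as.integer(tab)
  }
  total <- sum(counts)
  freqs <- if (total > 0L) 100 * counts / total else stats::setNames(numeric(0), character(0))
  structure(list(counts = counts, total = total, freqs = freqs),
            class = "shape_profile")
}

#' @export
print.shape_profile <- function(x, ...) {
  cat(sprintf("<shape_profile> %d classes over %d sub-hierarchies\n",
              x$total, length(x$counts)))
  if (x$total > 0L) {
    df <- as.data.frame(x)
    print(df[order(-df$count), ], row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.shape_profile <- function(x, ...) {
  data.frame(subhierarchy = names(x$counts),
             count = as.integer(x$counts),
             freq_pct = if (x$total > 0L) as.numeric(x$freqs) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Per-sub-hierarchy error between a module's shape and a reference shape
#'
#' The error for sub-hierarchy k is the module's relative frequency minus the
#' reference's, in percentage points; a positive error means the
#' sub-hierarchy is over-represented in the module. The residual sum of
#' squares is the mean of the squared errors over the reference's K
#' sub-hierarchies (see [rss()]); rebalancing declares convergence when it is
#' strictly below 1, i.e. when the root-mean-square error is under one
#' percentage point.
#'
#' @param module_profile `shape_profile` of the module (total > 0).
#' @param reference_profile `shape_profile` of the source ontology.
#' @return A `shape_error`: list with `errors` (named numeric, percentage
#'   points, over the reference sub-hierarchies), `rss` and `K`.
#' @export
shape_error <- function(module_profile, reference_profile) {
  stopifnot(inherits(module_profile, "shape_profile"),
            inherits(reference_profile, "shape_profile"))
  check(module_profile$total > 0L, "module profile is empty (total = 0)")
  check(reference_profile$total > 0L, "reference profile is empty (total = 0)")
  extra <- setdiff(names(module_profile$freqs), names(reference_profile$counts))
  check(length(extra) == 0L,
        "module has sub-hierarchies unknown to the reference: %s",
        paste(utils::head(extra, 5L), collapse = ", "))
  keys <- names(reference_profile$counts)
  mf <- stats::setNames(numeric(length(keys)), keys)
  mf[names(module_profile$freqs)] <- module_profile$freqs
  rf <- stats::setNames(numeric(length(keys)), keys)
  rf[names(reference_profile$freqs)] <- reference_profile$freqs
  errors <- mf - rf
  structure(list(errors = errors, rss = rss(errors, length(keys)),
                 K = length(keys)),
            class = "shape_error")
}

#' @export
print.shape_error <- function(x, ...) {
  cat(sprintf("<shape_error> K = %d, RSS = %.4f (%s)\n", x$K, x$rss,
              if (x$rss < 1) "converged: RSS < 1" else "not converged"))
  e <- sort(x$errors)
  worst <- c(utils::head(e, 3L), utils::tail(e, 3L))
  cat("  largest errors (pct points):\n")
  for (n in names(worst)) cat(sprintf("    %-30s %+ .2f\n", n, worst[[n]]))
  invisible(x)
}

#' Residual sum of squares of per-sub-hierarchy errors
#'
#' `rss(e, K) = (1/K) * sum(e^2)`: the mean squared per-sub-hierarchy error,
#' in squared percentage points. With K the number of sub-hierarchies of the
#' reference ontology (18 for SNOMED CT after removing the metadata
#' sub-hierarchy), values below 1 mean the module's shape deviates by less
#' than one percentage point RMS.
#'
#' @param errors numeric vector of errors in percentage points; entries for
#'   missing sub-hierarchies may be omitted (they contribute 0).
#' @param K number of sub-hierarchies of the reference (K >= 1 and K >=
#'   `length(errors)`).
#' @return Non-negative number.
#' @examples
#' rss(c(3, rep(0, 17)), 18)  # 0.5
#' @export
rss <- function(errors, K) {
  check(is_count(K, min = 1L), "'K' must be a positive integer")
  check(K >= length(errors), "'K' (%d) must be >= number of error entries (%d)",
        K, length(errors))
  sum(as.numeric(errors)^2) / K
}

#' Export a shape profile (optionally with errors) as CSV
#'
#' Columns: `subhierarchy`, `count`, `freq_pct` and, when `errors` is given,
#' `error_pct`.
#'
#' @param profile a `shape_profile`.
#' @param path output file path.
#' @param errors optional `shape_error` against the same reference.
#' @return Invisibly, `path`.
#' @export
export_profile <- function(profile, path, errors = NULL) {
  stopifnot(inherits(profile, "shape_profile"))
  df <- as.data.frame(profile)
  if (!is.null(errors)) {
    stopifnot(inherits(errors, "shape_error"))
    df$error_pct <- as.numeric(errors$errors[df$subhierarchy])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
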