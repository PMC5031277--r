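#' Multiplicative signature-weight update
#'
#' One rebalancing step: each sub-hierarchy's signature weight is scaled by
#' the ratio of its target (source-ontology) frequency to the frequency it
#' achieved in the extracted module,
#' `w'_k = w_k * target_k / module_k`,
#' so under-represented sub-hierarchies get more seeds next iteration and
#' over-represented ones fewer. Weights are renormalized to sum to 1
#' afterwards so seat apportionment stays well defined. When the module
#' reproduces the target exactly, the weights are a fixed point.
#'
#' @param sign_weights named weights of the current signature (fractions).
#' @param target_freqs named target frequencies (percent or fractions — only
#'   ratios matter), over the same sub-hierarchies.
#' @param module_freqs named achieved module frequencies (same units as
#'   `target_freqs`). Must be positive wherever the target is positive,
#'   which the at-least-one-seed sampling rule guarantees.
#' @return Named weight vector summing to 1.
#' @examples
#' update_weights(c(A = 0.2, B = 0.8), c(A = 30, B = 70), c(A = 15, B = 85))
#' @export
update_weights <- function(sign_weights, target_freqs, module_freqs) {
  keys <- names(sign_weights)
  check(!is.null(keys) && all(keys %in% names(target_freqs)) &&
          all(keys %in% names(module_freqs)),
        "all three vectors must be named over the same sub-hierarchies")
  tf <- as.numeric(target_freqs[keys])
  mf <- as.numeric(module_freqs[keys])
  w <- as.numeric(sign_weights)
  bad <- mf == 0 & tf > 0
  check(!any(bad),
        "module frequency is 0 where the target is positive (%s); ensure every stratum receives at least one seed",
        paste(utils::head(keys[bad], 5L), collapse = ", "))
  # tf > 0 guarantees mf > 0 here; a zero target zeroes the weight outright
  raw <- ifelse(tf == 0, 0, w * tf / ifelse(mf == 0, 1, mf))
  check(sum(raw) > 0, "all updated weights are zero")
  stats::setNames(raw / sum(raw), keys)
}

#' Fit a balanced module by iterative signature rebalancing
#'
#' The package's central algorithm. A *balanced module* of an ontology keeps
#' (a) every class's paths to the root, (b) every class's full definition,
#' and (c) a per-sub-hierarchy class distribution close to the source's.
#' Graph-traversal extraction guarantees (a) and (b) by construction but not
#' (c): following right-hand-side references drags in classes from coupled
#' sub-hierarchies (body-structure classes referenced by clinical findings
#' being the canonical case), skewing the shape. The only free lever is the
#' composition of the seed signature, so `balance()` iterates:
#'
#' 1. draw a stratified random signature of `n` classes under the current
#'    weights (initially the source ontology's own frequencies), at least
#'    one class per sub-hierarchy;
#' 2. extract the module and profile its sub-hierarchy distribution;
#' 3. stop if the residual sum of squares of the per-sub-hierarchy errors is
#'    below `rss_threshold` (strictly); otherwise scale each weight by
#'    target/achieved frequency ([update_weights()]) and repeat.
#'
#' Around the point where coupled sub-hierarchies can no longer be traded
#' off, the RSS oscillates rather than decreases; `max_iter` caps the loop
#' and the best-RSS iteration's module is returned either way, so the result
#' is never worse than the naive stratified module of iteration 1. Each
#' iteration draws a fresh signature with RNG seed `rng_seed + i`, making
#' the whole trajectory reproducible.
#'
#' @param graph an `ontology` with at least 2 sub-hierarchies.
#' @param n signature size (the reference experiment on SNOMED CT used
#'   2000); must be at least the number of sub-hierarchies.
#' @param rss_threshold convergence threshold on the RSS, in squared
#'   percentage points. The default 1 declares convergence when the RMS
#'   per-sub-hierarchy error is under one percentage point.
#' @param max_iter iteration cap (default 25).
#' @param rng_seed integer seed controlling all sampling.
#' @param closure_policy passed to [extract_module()].
#' @return An object of class `ontobalance`: list with `converged`,
#'   `best_iteration`, `module` (the best iteration's `module_result`),
#'   `trace` (list of per-iteration records: `index`, `signature`,
#'   `module_size`, `module_profile`, `error`), `reference` (the source
#'   profile) and `config`. Methods: `print`, `summary`, `coef` (best
#'   iteration's signature weights), `residuals` (best iteration's
#'   per-sub-hierarchy errors), `plot` (error and RSS trajectories),
#'   `as.data.frame` (the trace as a long table).
#' @examples
#' g <- generate_ontology(snomed_like_spec(0.004, rng_seed = 7))
#' fit <- balance(g, n = 80, rng_seed = 1)
#' summary(fit)
#' @export
balance <- function(graph, n = 2000, rss_threshold = 1.0, max_iter = 25,
                    rng_seed = 1, closure_policy = c("all", "seeds_and_references")) {
  stopifnot(inherits(graph, "ontology"))
  closure_policy <- match.arg(closure_policy)
  check(is_count(max_iter, min = 1L), "'max_iter' must be a positive integer")
  check(is.numeric(rss_threshold) && rss_threshold > 0,
        "'rss_threshold' must be positive")
  reference <- shape_profile(graph)
  K <- length(reference$counts)
  check(K >= 2L, "graph must have at least 2 sub-hierarchies (has %d)", K)
  check(is_count(n, min = 1L) && n >= K,
        "'n' must be an integer >= the number of sub-hierarchies (%d)", K)

  weights <- reference$freqs / 100
  trace <- vector("list", max_iter)
  best_i <- 0L
  best_rss <- Inf
  best_module <- NULL
  converged <- FALSE

  for (i in seq_len(max_iter)) {
    sig <- sample_signature(graph, weights, n, rng_seed + i)
    mod <- extract_module(graph, sig$classes, closure_policy)
    prof <- shape_profile(graph, mod$classes)
    err <- shape_error(prof, reference)
    trace[[i]] <- list(index = i, signature = sig,
                       module_size = length(mod$classes),
                       module_profile = prof, error = err)
    if (err$rss < best_rss) {
      best_rss <- err$rss
      best_i <- i
      best_module <- mod
    }
    if (err$rss < rss_threshold) { converged <- TRUE; break }
    if (i < max_iter) {
      weights <- update_weights(sig$weights, reference$freqs, prof$freqs)
    }
  }

  structure(list(converged = converged,
                 best_iteration = best_i,
                 module = best_module,
                 trace = trace[!vapply(trace, is.null, TRUE)],
                 reference = reference,
                 config = list(n = as.integer(n),
                               rss_threshold = rss_threshold,
                               max_iter = as.integer(max_iter),
                               rng_seed = as.integer(rng_seed),
                               closure_policy = closure_policy)),
            class = "ontobalance")
}

#' @export
print.ontobalance <- function(x, ...) {
  best <- x$trace[[x$best_iteration]]
  cat(sprintf("<ontobalance> %s after %d iteration(s)\n",
              if (x$converged) "converged" else "stopped (not converged)",
              length(x$trace)))
  cat(sprintf("  best iteration %d: module of %d classes (%.2f%% of source), RSS = %.4f\n",
              x$best_iteration, best$module_size,
              100 * best$module_size / x$reference$total, best$error$rss))
  invisible(x)
}

#' @export
summary.ontobalance <- function(object, ...) {
  best <- object$trace[[object$best_iteration]]
  err <- best$error$errors
  df <- data.frame(subhierarchy = names(object$reference$counts),
                   source_freq_pct = as.numeric(object$reference$freqs),
                   module_count = as.integer(best$module_profile$counts),
                   module_freq_pct = as.numeric(best$module_profile$freqs),
                   error_pct = as.numeric(err),
                   stringsAsFactors = FALSE)
  structure(list(converged = object$converged,
                 iterations = length(object$trace),
                 best_iteration = object$best_iteration,
                 module_size = best$module_size,
                 source_size = object$reference$total,
                 rss = best$error$rss,
                 max_abs_error = max(abs(err)),
                 table = df[order(-df$module_count), ],
                 rss_by_iteration = vapply(object$trace,
                                           function(r) r$error$rss, 0)),
            class = "summary.ontobalance")
}

#' @export
print.summary.ontobalance <- function(x, ...) {
  cat(sprintf("Balanced module extraction: %s\n",
              if (x$converged) sprintf("converged at iteration %d", x$best_iteration)
              else sprintf("not converged in %d iterations (best: %d)",
                           x$iterations, x$best_iteration)))
  cat(sprintf("  module: %d of %d classes (%.2f%%)\n", x$module_size,
              x$source_size, 100 * x$module_size / x$source_size))
  cat(sprintf("  RSS = %.4f; max |error| = %.2f pct points\n",
              x$rss, x$max_abs_error))
  cat(sprintf("  RSS by iteration: %s\n",
              paste(sprintf("%.2f", x$rss_by_iteration), collapse = " ")))
  print(utils::head(x$table, 8L), row.names = FALSE)
  if (nrow(x$table) > 8L) cat(sprintf("  ... and %d more sub-hierarchies\n",
                                      nrow(x$table) - 8L))
  invisible(x)
}

#' @export
coef.ontobalance <- function(object, ...) {
  object$trace[[object$best_iteration]]$signature$weights
}

#' @export
residuals.ontobalance <- function(object, ...) {
  object$trace[[object$best_iteration]]$error$errors
}

#' Plot rebalancing trajectories
#'
#' One line per sub-hierarchy whose error magnitude ever exceeds
#' `min_abs_error` (all of them with `min_abs_error = 0`), plus the RSS as a
#' dashed line — the diagnostic picture of how the algorithm traded
#' sub-hierarchies off against each other and where it converged or began to
#' oscillate.
#'
#' @param x an `ontobalance` fit.
#' @param min_abs_error hide sub-hierarchies whose |error| stays below this
#'   many percentage points in every iteration (default 1, display parity
#'   with small-error filtering; use 0 to show all).
#' @param ... ignored.
#' @return Invisibly, `x`.
#' @export
plot.ontobalance <- function(x, min_abs_error = 1, ...) {
  iters <- vapply(x$trace, `[[`, 0L, "index")
  errs <- vapply(x$trace, function(r) r$error$errors,
                 numeric(length(x$reference$counts)))
  if (is.null(dim(errs))) errs <- matrix(errs, nrow = length(x$reference$counts))
  keep <- apply(abs(errs), 1L, max) >= min_abs_error
  if (!any(keep)) keep[which.max(apply(abs(errs), 1L, max))] <- TRUE
  rssv <- vapply(x$trace, function(r) r$error$rss, 0)
  ylim <- range(errs[keep, , drop = FALSE], rssv, 0)
  graphics::matplot(iters, t(errs[keep, , drop = FALSE]), type = "b", pch = 16,
                    lty = 1, xlab = "iteration",
                    ylab = "error (percentage points)", ylim = ylim)
  graphics::lines(iters, rssv, lty = 2, lwd = 2)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright", bty = "n", cex = 0.7, lty = c(rep(1, sum(keep)), 2),
                   col = c(seq_len(sum(keep)), "black"),
                   legend = c(rownames(errs)[keep], "RSS"))
  invisible(x)
}

#' @export
as.data.frame.ontobalance <- function(x, ...) {
  do.call(rbind, lapply(x$trace, function(r) {
    shs <- names(x$reference$counts)
    data.frame(iteration = r$index,
               subhierarchy = shs,
               signature_weight = as.numeric(r$signature$weights[shs]),
               module_count = as.integer(r$module_profile$counts[shs]),
               module_freq_pct = as.numeric(r$module_profile$freqs[shs]),
               error_pct = as.numeric(r$error$errors[shs]),
               rss = r$error$rss,
               stringsAsFactors = FALSE)
  }))
}

#' Export a rebalancing trace as CSV
#'
#' Long-format table, one row per (iteration, sub-hierarchy): columns
#' `iteration`, `subhierarchy`, `signature_weight`, `module_count`,
#' `module_freq_pct`, `error_pct`, `rss` (the iteration's RSS, repeated on
#' each of its rows). Numbers are written in full precision so the trace
#' round-trips exactly.
#'
#' @param result an `ontobalance` fit with a non-empty trace.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
export_trace <- function(result, path) {
  stopifnot(inherits(result, "ontobalance"))
  check(length(result$trace) > 0L, "trace is empty; nothing to export")
  df <- as.data.frame(result)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(c) sprintf("%.17g", c))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
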