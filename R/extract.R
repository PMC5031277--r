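#' Ancestors of a class
#'
#' All classes reachable from `class_id` by following parent (is-a) edges,
#' excluding the class itself. For any non-root class the result contains the
#' root.
#'
#' @param graph an `ontology`.
#' @param class_id a class id.
#' @return Character vector of ancestor ids, sorted.
#' @export
class_ancestors <- function(graph, class_id) {
  stopifnot(inherits(graph, "ontology"))
  check(is_string(class_id) && class_id %in% graph$ids,
        "unknown class id '%s'", class_id)
  seen <- logical(length(graph$ids))
  queue <- graph$.pidx[[graph$.idx[[class_id]]]]
  seen[queue] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (p in graph$.pidx[[v]]) {
      if (!seen[p]) { seen[p] <- TRUE; queue <- c(queue, p) }
    }
  }
  sort(graph$ids[seen])
}

#' Extract a module from a seed signature
#'
#' Signature-driven graph-traversal extraction: starting from the seeds
#' (target nodes), the module iteratively adds (i) every included class's
#' ancestors, so each class stays hierarchically connected to the root
#' exactly as in the source ontology, and (ii) referenced classes — classes
#' appearing in the right-hand expressions of definitions — which then become
#' new target nodes themselves. The result is the least fixpoint of those
#' rules.
#'
#' Under `closure_policy = "all"` (default) the references of *every* module
#' class are followed, so every class's full definition is guaranteed to be
#' in the module. Under `"seeds_and_references"` references are followed only
#' from seeds and from classes that were themselves pulled in as references,
#' not from ancestor-only classes; such modules may not verify clean under
#' requirement (b) (see [verify_module()]).
#'
#' @param graph an `ontology`.
#' @param seeds non-empty character vector of class ids.
#' @param closure_policy `"all"` or `"seeds_and_references"`.
#' @return A `module_result`: list with `classes` (sorted character vector),
#'   `provenance` (named character: `"seed"`, `"reference"` or `"ancestor"` —
#'   the highest-priority rule under which each class is reachable),
#'   `seeds`, `policy` and `source` (the source ontology's root id).
#' @examples
#' g <- ontology("R", parents = list(R = character(), A = "R", B = "R",
#'                                   A1 = "A", B1 = "B", B2 = "B1"),
#'               references = list(A1 = "B2"))
#' m <- extract_module(g, "A1")
#' m$classes  # A1 plus ancestors A, R plus reference B2 and its ancestors
#' @export
extract_module <- function(graph, seeds,
                           closure_policy = c("all", "seeds_and_references")) {
  stopifnot(inherits(graph, "ontology"))
  closure_policy <- match.arg(closure_policy)
  seeds <- unique(as.character(seeds))
  check(length(seeds) > 0L, "'seeds' must be non-empty")
  unknown <- setdiff(seeds, graph$ids)
  check(length(unknown) == 0L, "unknown seed id(s): %s",
        paste(utils::head(unknown, 10L), collapse = ", "))

  n <- length(graph$ids)
  # status: 0 = out, 1 = ancestor, 2 = reference, 3 = seed.
  # References are traversable from status >= 2 (policy seeds_and_references)
  # or from any member (policy all). A member first reached as an ancestor
  # and later reachable as a reference target is upgraded (and, where that
  # unlocks its references, re-expanded), making provenance order-independent.
  status <- integer(n)
  sidx <- sort(unname(graph$.idx[seeds]))
  status[sidx] <- 3L
  follow_all <- closure_policy == "all"
  # worklist as a preallocated ring-free buffer: every node enters at most
  # twice (once on inclusion, once on an ancestor -> reference upgrade)
  buf <- integer(2L * n)
  tail <- length(sidx)
  buf[seq_len(tail)] <- sidx
  head <- 1L

  while (head <= tail) {
    v <- buf[head]; head <- head + 1L
    sv <- status[v]
    for (p in graph$.pidx[[v]]) {
      if (status[p] == 0L) {
        status[p] <- 1L
        tail <- tail + 1L; buf[tail] <- p
      }
    }
    if (follow_all || sv >= 2L) {
      for (r in graph$.ridx[[v]]) {
        if (status[r] == 0L) {
          status[r] <- 2L
          tail <- tail + 1L; buf[tail] <- r
        } else if (status[r] == 1L) {
          status[r] <- 2L  # upgrade: now a reference target
          if (!follow_all) { tail <- tail + 1L; buf[tail] <- r }  # refs unlock
        }
      }
    }
  }

  # under policy=all an ancestor-only member may still be a reference target
  # of some member: one vectorised upgrade pass settles provenance
  if (follow_all) {
    repeat {
      trav <- which(status >= 1L)
      tgt <- unique(unlist(graph$.ridx[trav], use.names = FALSE))
      up <- tgt[status[tgt] == 1L]
      if (length(up) == 0L) break
      status[up] <- 2L
    }
  } else {
    repeat {
      trav <- which(status >= 2L)
      tgt <- unique(unlist(graph$.ridx[trav], use.names = FALSE))
      up <- tgt[!is.na(tgt) & status[tgt] == 1L]
      if (length(up) == 0L) break
      status[up] <- 2L
    }
  }

  member <- which(status > 0L)
  prov <- c("ancestor", "reference", "seed")[status[member]]
  ids <- graph$ids[member]
  ord <- order(ids)
  structure(list(classes = ids[ord],
                 provenance = stats::setNames(prov[ord], ids[ord]),
                 seeds = sort(seeds),
                 policy = closure_policy,
                 source = graph$root),
            class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  tab <- table(factor(x$provenance, levels = c("seed", "reference", "ancestor")))
  cat(sprintf("<module_result> %d classes from %d seeds (policy %s)\n",
              length(x$classes), length(x$seeds), x$policy))
  cat(sprintf("  provenance: %d seed, %d reference, %d ancestor\n",
              tab[["seed"]], tab[["reference"]], tab[["ancestor"]]))
  invisible(x)
}

#' Verify module well-formedness
#'
#' Checks the two structural requirements of a balanced module: (a) every
#' module class keeps *all* its ancestors, so its paths to the root are
#' preserved verbatim, and (b) every module class keeps all its referenced
#' classes, so its definition copies over intact. Violations are reported,
#' never thrown.
#'
#' @param graph the source `ontology`.
#' @param module a `module_result`, or a character vector of class ids.
#' @return An `ontology_validation` report; empty `errors` iff (a) and (b)
#'   hold. Error codes are `missing_ancestor` and `missing_reference`, one
#'   entry per offending (class, missing id) pair.
#' @export
verify_module <- function(graph, module) {
  stopifnot(inherits(graph, "ontology"))
  classes <- if (inherits(module, "module_result")) module$classes else unique(as.character(module))
  unknown <- setdiff(classes, graph$ids)
  check(length(unknown) == 0L, "module contains unknown class id(s): %s",
        paste(utils::head(unknown, 10L), collapse = ", "))
  inmod <- logical(length(graph$ids))
  inmod[unname(graph$.idx[classes])] <- TRUE
  errors <- list()
  for (cid in classes) {
    v <- graph$.idx[[cid]]
    # direct-parent containment is equivalent to full ancestor containment
    # when it holds for every member; report the full missing ancestor set
    # for classes where it does not
    if (!all(inmod[graph$.pidx[[v]]])) {
      missing <- setdiff(class_ancestors(graph, cid), classes)
      for (m in missing) {
        errors[[length(errors) + 1L]] <-
          list("missing_ancestor", cid, sprintf("ancestor '%s' not in module", m))
      }
    }
    miss_ref <- graph$.ridx[[v]][!inmod[graph$.ridx[[v]]]]
    for (m in graph$ids[miss_ref]) {
      errors[[length(errors) + 1L]] <-
        list("missing_reference", cid, sprintf("reference '%s' not in module", m))
    }
  }
  new_report(errors, list())
}

#' Materialize a module as a standalone ontology
#'
#' Restricts the source graph to the module's classes and returns it as a
#' fully validated `ontology` with the same root, loadable and profilable
#' like any other. Refuses modules that do not verify clean, since those
#' would either be unrooted or lose definition content.
#'
#' @param graph the source `ontology`.
#' @param module a `module_result` (or character vector) passing
#'   [verify_module()].
#' @return An `ontology` over exactly the module's classes.
#' @export
materialize_module <- function(graph, module) {
  rep <- verify_module(graph, module)
  check(nrow(rep$errors) == 0L,
        "module does not verify clean (%d error(s)); cannot materialize",
        nrow(rep$errors))
  classes <- if (inherits(module, "module_result")) module$classes else unique(as.character(module))
  if (length(classes) == 0L) classes <- graph$root
  if (!graph$root %in% classes) classes <- c(graph$root, classes)
  ontology(graph$root, graph$parents[classes], graph$references[classes],
           graph$labels[classes])
}
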