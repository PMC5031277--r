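#' Ontology class graphs
#'
#' An `ontology` object is a rooted directed acyclic graph of classes. Each
#' class has a set of *parents* (direct is-a superclasses) and a set of
#' *references* (classes appearing in the right-hand expressions of its
#' definition, e.g. fillers of existential restrictions such as a finding
#' site). A *sub-hierarchy* is the region below one direct child of the root;
#' every non-root class is assigned to exactly one sub-hierarchy.
#'
#' @param root character id of the root class.
#' @param parents named list; one entry per class (including the root), each a
#'   character vector of direct parent ids. The root's entry must be empty.
#' @param references named list of character vectors of referenced class ids;
#'   classes may be omitted (no references).
#' @param labels named character vector of optional human-readable labels.
#'
#' @return An object of class `ontology` with components `root`, `ids`,
#'   `labels`, `parents`, `references` (canonically sorted), `subhierarchy`
#'   (named map non-root class id -> sub-hierarchy id) and `warnings`.
#'
#' @details Construction validates the graph (see [validate_ontology()]) and
#'   fails on any error. Classes whose top-level ancestors span several
#'   sub-hierarchies are assigned to the lexicographically smallest
#'   sub-hierarchy id and reported in `warnings`.
#' @export
ontology <- function(root, parents, references = NULL, labels = NULL) {
  g <- build_ontology(root, parents, references, labels)
  rep <- attr(g, "validation")
  if (nrow(rep$errors) > 0L) {
    stop("invalid ontology:\n", format_report_lines(rep$errors), call. = FALSE)
  }
  g
}

# Construct without stopping: returns the (possibly partial) object with a
# ValidationReport in attr(, "validation"). Derived fields (topology,
# sub-hierarchy map) are only present when there are no errors.
build_ontology <- function(root, parents, references = NULL, labels = NULL) {
  check(is_string(root), "'root' must be a single class id")
  check(is.list(parents) && !is.null(names(parents)) && all(nzchar(names(parents))),
        "'parents' must be a named list of character vectors")

  ids <- sort(names(parents))
  errors <- list()
  warns <- list()
  err <- function(code, id, msg) errors[[length(errors) + 1L]] <<- list(code, id, msg)
  wrn <- function(code, id, msg) warns[[length(warns) + 1L]] <<- list(code, id, msg)

  if (anyDuplicated(ids)) {
    for (d in unique(ids[duplicated(ids)])) err("duplicate_id", d, "class id declared more than once")
    ids <- unique(ids)
  }
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)

  par_chr <- lapply(ids, function(i) {
    p <- parents[[i]]
    if (is.null(p)) character() else sort(unique(as.character(p)))
  })
  names(par_chr) <- ids
  ref_chr <- lapply(ids, function(i) {
    r <- if (is.null(references)) NULL else references[[i]]
    if (is.null(r)) character() else sort(unique(as.character(r)))
  })
  names(ref_chr) <- ids

  lab <- rep(NA_character_, n)
  names(lab) <- ids
  if (!is.null(labels)) {
    keep <- intersect(names(labels), ids)
    lab[keep] <- as.character(labels[keep])
  }

  if (!root %in% ids) err("missing_root", root, "root class is not declared")

  for (i in ids) {
    if (i %in% par_chr[[i]]) err("self_parent", i, "class lists itself as a parent")
    if (i %in% ref_chr[[i]]) err("self_reference", i, "class lists itself as a reference")
    dangling_p <- setdiff(par_chr[[i]], ids)
    for (d in dangling_p) err("dangling_parent", i, sprintf("parent '%s' is not declared", d))
    dangling_r <- setdiff(ref_chr[[i]], ids)
    for (d in dangling_r) err("dangling_reference", i, sprintf("reference '%s' is not declared", d))
  }

  if (root %in% ids) {
    if (length(par_chr[[root]]) > 0L) err("root_has_parents", root, "root must have no parents")
    if (length(ref_chr[[root]]) > 0L) err("root_has_references", root, "root must have no references")
    parentless <- ids[vapply(par_chr, length, 1L) == 0L]
    for (p in setdiff(parentless, root)) {
      err("unrooted_class", p, "non-root class has no parents (cannot reach the root)")
    }
  }

  g <- structure(list(root = root, ids = ids, labels = lab,
                      parents = par_chr, references = ref_chr),
                 class = "ontology")

  if (length(errors) == 0L) {
    # integer adjacency + topological order (root first); Kahn on parent edges
    pidx <- lapply(par_chr, function(p) unname(idx[p]))
    ridx <- lapply(ref_chr, function(r) unname(idx[r]))
    ch <- vector("list", n)
    for (i in seq_len(n)) for (p in pidx[[i]]) ch[[p]] <- c(ch[[p]], i)
    indeg <- vapply(pidx, length, 1L)
    queue <- which(indeg == 0L)          # exactly the root when valid so far
    topo <- integer(0)
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      topo <- c(topo, v)
      for (c in ch[[v]]) {
        indeg[[c]] <- indeg[[c]] - 1L
        if (indeg[[c]] == 0L) queue <- c(queue, c)
      }
    }
    if (length(topo) < n) {
      cyc <- find_parent_cycle(pidx, setdiff(seq_len(n), topo))
      err("cycle", ids[cyc[1L]],
          sprintf("parent cycle: %s", paste(ids[cyc], collapse = " -> ")))
    } else {
      g$topo <- topo
      # sub-hierarchy assignment: propagate top-level ancestor sets downward
      ri <- idx[[root]]
      tops <- vector("list", n)
      for (v in topo) {
        if (v == ri) next
        ps <- pidx[[v]]
        if (length(ps) == 1L && ps == ri) {
          tops[[v]] <- ids[v]
        } else {
          acc <- character(0)
          for (p in ps) acc <- c(acc, if (p == ri) ids[v] else tops[[p]])
          tops[[v]] <- unique(acc)
        }
      }
      sub <- character(n)
      for (v in seq_len(n)) {
        if (v == ri) next
        tv <- sort(tops[[v]])
        sub[v] <- tv[1L]
        if (length(tv) > 1L) {
          wrn("multi_subhierarchy", ids[v],
              sprintf("class reachable from sub-hierarchies {%s}; assigned to '%s'",
                      paste(tv, collapse = ", "), tv[1L]))
        }
      }
      g$subhierarchy <- stats::setNames(sub[-ri], ids[-ri])
      g$.idx <- idx
      g$.pidx <- pidx
      g$.ridx <- ridx
      g$.children <- ch
    }
  }

  g$warnings <- report_frame(warns)
  attr(g, "validation") <- new_report(errors, warns)
  g
}

find_parent_cycle <- function(pidx, remaining) {
  inset <- logical(length(pidx)); inset[remaining] <- TRUE
  v <- remaining[[1L]]
  seen <- integer(0)
  repeat {
    if (v %in% seen) {
      start <- match(v, seen)
      return(c(seen[start:length(seen)], v))
    }
    seen <- c(seen, v)
    nxt <- pidx[[v]][inset[pidx[[v]]]]
    v <- nxt[[1L]]
  }
}

report_frame <- function(entries) {
  if (length(entries) == 0L) {
    return(data.frame(code = character(), class = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  data.frame(code = vapply(entries, `[[`, "", 1L),
             class = vapply(entries, `[[`, "", 2L),
             message = vapply(entries, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

new_report <- function(errors, warnings) {
  structure(list(errors = report_frame(if (is.data.frame(errors)) list() else errors),
                 warnings = report_frame(if (is.data.frame(warnings)) list() else warnings)),
            class = "ontology_validation")
}
# data.frame passthrough for pre-built frames
new_report2 <- function(errors, warnings) {
  structure(list(errors = errors, warnings = warnings), class = "ontology_validation")
}

format_report_lines <- function(df) {
  paste(sprintf("  [%s] %s: %s", df$code, df$class, df$message), collapse = "\n")
}

#' Validate an ontology graph
#'
#' Re-checks the structural invariants of an `ontology`: unique resolvable
#' identifiers, no self parent/reference, a unique parentless root, an acyclic
#' parent relation with every class reaching the root, and a well-defined
#' sub-hierarchy for every non-root class.
#'
#' @param graph an `ontology` object (or a candidate built with the same
#'   components).
#' @return A `ontology_validation` report with `errors` and `warnings` data
#'   frames (columns `code`, `class`, `message`). Empty `errors` if and only
#'   if all invariants hold.
#' @export
validate_ontology <- function(graph) {
  stopifnot(inherits(graph, "ontology"))
  attr(build_ontology(graph$root, graph$parents, graph$references,
                      graph$labels), "validation")
}

#' @export
print.ontology_validation <- function(x, ...) {
  cat(sprintf("ontology validation: %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) cat(format_report_lines(x$errors), "\n")
  if (nrow(x$warnings)) cat(format_report_lines(x$warnings), "\n")
  invisible(x)
}

#' @export
print.ontology <- function(x, ...) {
  K <- length(subhierarchies(x))
  cat(sprintf("<ontology> %d classes, root '%s', %d sub-hierarchies\n",
              length(x$ids), x$root, K))
  nref <- sum(vapply(x$references, length, 1L))
  cat(sprintf("  %d reference edges; %d multi-hierarchy warning(s)\n",
              nref, nrow(x$warnings)))
  invisible(x)
}

#' Number of classes in an ontology
#' @param graph an `ontology`.
#' @return Integer count of classes, root included.
#' @export
n_classes <- function(graph) length(graph$ids)

#' Sub-hierarchy identifiers of an ontology
#'
#' The sub-hierarchies are the direct children of the root, in sorted order.
#' @param graph an `ontology`.
#' @return Character vector of sub-hierarchy ids.
#' @export
subhierarchies <- function(graph) {
  stopifnot(inherits(graph, "ontology"))
  sort(graph$ids[graph$.children[[graph$.idx[[graph$root]]]]])
}

#' Sub-hierarchy assignment of every class
#'
#' Maps every non-root class to the direct child of the root under which it
#' sits. Classes reachable from several top-level children (possible in a
#' generic DAG, though SNOMED CT's top hierarchies are disjoint in practice)
#' are assigned to the lexicographically smallest sub-hierarchy id; these
#' ties are listed in `graph$warnings`.
#'
#' @param graph an `ontology`.
#' @return Named character vector: class id -> sub-hierarchy id. The root is
#'   absent from the map.
#' @export
assign_subhierarchies <- function(graph) {
  stopifnot(inherits(graph, "ontology"))
  graph$subhierarchy
}

#' Remove a sub-hierarchy and all its descendants
#'
#' Used e.g. to drop a metadata-only region (such as SNOMED CT's model
#' component concepts) before any profiling or extraction. References from
#' surviving classes into the removed region are dropped; their number is
#' available as `attr(result, "dropped_references")`.
#'
#' @param graph an `ontology`.
#' @param sh id of a direct child of the root.
#' @return A new validated `ontology` without `sh` and its descendants.
#' @export
strip_subhierarchy <- function(graph, sh) {
  stopifnot(inherits(graph, "ontology"))
  check(is_string(sh) && sh %in% subhierarchies(graph),
        "'sh' must be a direct child of the root (got '%s')", sh)
  # descendants of sh by downward BFS over child edges
  drop <- logical(length(graph$ids))
  queue <- graph$.idx[[sh]]
  drop[queue] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (c in graph$.children[[v]]) {
      if (!drop[c]) { drop[c] <- TRUE; queue <- c(queue, c) }
    }
  }
  keep <- graph$ids[!drop]
  gone <- graph$ids[drop]
  par <- graph$parents[keep]            # parents never dangle: a kept class
                                        # cannot have a removed ancestor-side
                                        # parent without being a descendant too
  refs <- graph$references[keep]
  ndrop <- 0L
  for (i in seq_along(refs)) {
    bad <- refs[[i]] %in% gone
    if (any(bad)) { ndrop <- ndrop + sum(bad); refs[[i]] <- refs[[i]][!bad] }
  }
  out <- ontology(graph$root, par, refs, graph$labels[keep])
  attr(out, "dropped_references") <- ndrop
  out
}

#' Load an ontology from a file
#'
#' @param path file path.
#' @param format `"native"` for the package's JSON graph-interchange format,
#'   `"owl-functional"` for the OWL functional-syntax EL-like subset (see
#'   [parse_owl_functional()]). Defaults from the file extension
#'   (`.owl`/`.ofn` -> owl-functional, otherwise native).
#' @return A validated `ontology`.
#' @seealso [write_ontology()] for the native format definition.
#' @export
load_ontology <- function(path, format = NULL) {
  check(is_string(path) && file.exists(path), "file '%s' does not exist", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("owl", "ofn")) "owl-functional" else "native"
  }
  format <- match.arg(format, c("native", "owl-functional"))
  if (format == "owl-functional") {
    return(parse_owl_functional(readLines(path, warn = FALSE, encoding = "UTF-8")))
  }
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop(sprintf("parse error in '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  check(is.list(doc) && identical(doc$format_version, 1L) ||
          (is.numeric(doc$format_version) && doc$format_version == 1),
        "'%s': missing or unsupported format_version (expected 1)", path)
  check(!is.null(doc$root) && !is.null(doc$classes),
        "'%s': native format requires 'root' and 'classes'", path)
  ids <- vapply(doc$classes, function(c) as.character(c$id), "")
  par <- lapply(doc$classes, function(c) unlist(c$parents, use.names = FALSE))
  refs <- lapply(doc$classes, function(c) unlist(c$references, use.names = FALSE))
  labs <- vapply(doc$classes, function(c) {
    if (is.null(c$label)) NA_character_ else as.character(c$label)
  }, "")
  names(par) <- ids; names(refs) <- ids; names(labs) <- ids
  g <- build_ontology(as.character(doc$root), par, refs, labs[!is.na(labs)])
  rep <- attr(g, "validation")
  if (nrow(rep$errors) > 0L) {
    stop(sprintf("'%s' failed validation:\n%s", path,
                 format_report_lines(rep$errors)), call. = FALSE)
  }
  g
}

#' Write an ontology in the native JSON format
#'
#' The native format is a UTF-8 JSON document
#' `{"format_version": 1, "root": id, "classes": [{"id", "label",
#' "parents", "references"}, ...]}` with unique ids and order-insensitive
#' semantics. Output is canonical (classes and edge lists sorted), so writing
#' the same graph always yields identical bytes and
#' `load_ontology(write_ontology(g))` is the identity.
#'
#' @param graph an `ontology`.
#' @param path output file path.
#' @param format only `"native"` is supported.
#' @return Invisibly, `path`.
#' @export
write_ontology <- function(graph, path, format = "native") {
  stopifnot(inherits(graph, "ontology"))
  format <- match.arg(format, "native")
  classes <- lapply(graph$ids, function(i) {
    lab <- graph$labels[[i]]
    list(id = jsonlite::unbox(i),
         label = if (is.na(lab)) NULL else jsonlite::unbox(lab),
         parents = as.list(graph$parents[[i]]),
         references = as.list(graph$references[[i]]))
  })
  doc <- list(format_version = jsonlite::unbox(1L),
              root = jsonlite::unbox(graph$root),
              classes = classes)
  json <- jsonlite::toJSON(doc, null = "null", pretty = 2L, digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

#' Read a seed-list file
#'
#' One class id per line; blank lines and `#` comments (full-line or trailing)
#' are ignored.
#' @param path file path.
#' @return Character vector of class ids.
#' @export
read_seed_file <- function(path) {
  check(is_string(path) && file.exists(path), "file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
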