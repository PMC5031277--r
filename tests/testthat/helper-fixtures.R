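# Shared fixtures and independent oracles.

# Two-sub-hierarchy toy: root R; A <- A1 <- A2; B <- B1 <- {B2, B3};
# A2's definition references B2.
toy1 <- function() {
  ontology("R",
           parents = list(R = character(), A = "R", A1 = "A", A2 = "A1",
                          B = "R", B1 = "B", B2 = "B1", B3 = "B1"),
           references = list(A2 = "B2"))
}

# Random small ontology via the generator with randomized shape parameters.
# Drawing the spec's parameters under a fixed seed keeps property tests
# reproducible.
random_ontology <- function(seed, max_classes = 500L, coupled = TRUE) {
  set.seed(seed)
  K <- sample(2:6, 1L)
  total <- sample(seq(4L * K, max_classes), 1L)
  sizes <- as.integer(1L + stats::rmultinom(1L, total - K, prob = runif(K)))
  names(sizes) <- paste0("SH", LETTERS[seq_len(K)])
  coupling <- numeric(0)
  if (coupled) {
    npair <- sample(0:3, 1L)
    if (npair > 0L) {
      pairs <- replicate(npair, paste(sample(names(sizes), 2L, replace = TRUE),
                                      collapse = "->"))
      coupling <- stats::setNames(runif(npair, 0.1, 1.5), pairs)
      coupling <- coupling[!duplicated(names(coupling))]
    }
  }
  spec <- generator_spec(sizes,
                         depth_mean = runif(1L, 1, 4),
                         branching = sample(c(1, 1, 2), 1L),
                         multiparent_prob = runif(1L, 0, 0.2),
                         coupling = coupling,
                         refs_per_class_max = 5L,
                         rng_seed = seed)
  generate_ontology(spec)
}

# Brute-force extraction oracle: repeat-until-stable set expansion over the
# public parents/references lists, independent of the package's traversal.
oracle_extract <- function(g, seeds, policy = "all") {
  mem <- unique(seeds)
  trav <- mem  # classes whose references may be followed
  repeat {
    new_par <- unique(unlist(g$parents[mem], use.names = FALSE))
    src <- if (policy == "all") mem else trav
    new_ref <- unique(unlist(g$references[src], use.names = FALSE))
    mem2 <- union(mem, union(new_par, new_ref))
    trav2 <- union(trav, new_ref)
    if (length(mem2) == length(mem) && length(trav2) == length(trav)) break
    mem <- mem2
    trav <- trav2
  }
  sort(mem)
}

# Ancestor oracle through igraph reachability (implementation-independent).
oracle_ancestors <- function(g, id) {
  edges <- do.call(rbind, lapply(g$ids, function(c) {
    if (length(g$parents[[c]]) == 0L) NULL else cbind(c, g$parents[[c]])
  }))
  ig <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (!id %in% igraph::V(ig)$name) return(character(0))
  reach <- igraph::subcomponent(ig, id, mode = "out")$name
  sort(setdiff(reach, id))
}

# Top-level-ancestor oracle: exhaustive upward BFS per class, lexicographic
# tie-break.
oracle_subhierarchy <- function(g) {
  tops <- sort(setdiff(names(Filter(function(p) g$root %in% p, g$parents)),
                       g$root))
  out <- character(0)
  for (c in setdiff(g$ids, g$root)) {
    anc <- c(c, oracle_ancestors(g, c))
    out[c] <- sort(intersect(anc, tops))[1L]
  }
  out
}

# All integer allocations with sum n, 1 <= seats_k <= caps_k (columns).
enumerate_allocations <- function(n, caps) {
  if (length(caps) == 1L) {
    if (n >= 1L && n <= caps) return(matrix(n)) else return(NULL)
  }
  rest <- caps[-1L]
  lo <- max(1L, n - sum(rest))
  hi <- min(caps[1L], n - length(rest))
  if (lo > hi) return(NULL)
  cols <- list()
  for (v in lo:hi) {
    sub <- enumerate_allocations(n - v, rest)
    if (!is.null(sub)) cols[[length(cols) + 1L]] <- rbind(v, sub)
  }
  if (length(cols) == 0L) NULL else do.call(cbind, cols)
}

# Minimum of sum|seats - n*w| over all feasible allocations.
oracle_allocation_objective <- function(weights, n, caps) {
  all_alloc <- enumerate_allocations(as.integer(n), as.integer(caps))
  quota <- n * weights
  min(colSums(abs(all_alloc - quota)))
}

expect_same_ontology <- function(a, b) {
  expect_identical(a$root, b$root)
  expect_identical(a$ids, b$ids)
  expect_identical(a$parents, b$parents)
  expect_identical(a$references, b$references)
  expect_identical(a$labels, b$labels)
}

# Two flat sub-hierarchies where every A-leaf references one B-leaf: the
# canonical coupled case. Any small-signature module over-represents B, so
# balance() can never converge at tiny n — handy for exit-code and
# compensation tests.
flat_coupled_fixture <- function() {
  parents <- list(R = character(), A = "R", B = "R")
  refs <- list()
  for (j in 1:30) {
    a <- sprintf("A%02d", j); b <- sprintf("B%02d", j)
    parents[[a]] <- "A"
    parents[[b]] <- "B"
    refs[[a]] <- b
  }
  ontology("R", parents, refs)
}
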