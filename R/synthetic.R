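# Published per-sub-hierarchy concept counts of the 18 main SNOMED CT
# sub-hierarchies (metadata sub-hierarchy removed); the size spectrum the
# synthetic generator reproduces. Frequencies are always recomputed from
# these counts.
SNOMED_SUBHIERARCHY_COUNTS <- c(
  CF = 100893L,  # Clinical Finding
  PR = 53914L,   # Procedure
  OR = 33273L,   # Organism
  BS = 30685L,   # Body Structure
  SU = 24021L,   # Substance
  PB = 16881L,   # Pharmaceutical / Biologic Product
  QV = 9055L,    # Qualifier Value
  OE = 8307L,    # Observable Entity
  SO = 4703L,    # Social Context
  PO = 4522L,    # Physical Object
  SI = 3695L,    # Situation with Explicit Context
  EV = 3673L,    # Event
  EG = 1814L,    # Environment / Geographical Location
  SN = 1447L,    # Specimen
  ST = 1309L,    # Staging and Scales
  SP = 649L,     # Special Concept
  RA = 227L,     # Record Artifact
  PF = 171L      # Physical Force
)

#' Generator specification for a synthetic SNOMED-like ontology
#'
#' Bundles the parameters of [generate_ontology()]: exact per-sub-hierarchy
#' sizes, within-sub-hierarchy tree shape, extra-parent rate, and the
#' cross-hierarchy definition-reference coupling that makes module shapes
#' drift (e.g. clinical-finding classes referencing their body-structure
#' finding sites).
#'
#' @param subhierarchy_sizes named integer vector (>= 1 each): exact class
#'   count per sub-hierarchy, top-level class included.
#' @param depth_mean mean within-sub-hierarchy depth below the top-level
#'   class; each class's depth is `1 + Poisson(depth_mean - 1)`. Use 1 for a
#'   flat sub-hierarchy (every class a direct child of its top).
#' @param branching parent-choice spread: candidate parents at the level
#'   above are drawn with weight `branching^(-children)`; 1 (default) is
#'   uniform, larger values even out family sizes, values below 1 favour
#'   already-busy parents (star-like levels).
#' @param multiparent_prob probability that a class gets one extra parent
#'   (an earlier-generated class of the same sub-hierarchy, keeping the
#'   graph acyclic by construction).
#' @param coupling named numeric vector of expected references per class;
#'   names are `"SRC->TGT"` sub-hierarchy pairs. Each source-class draws
#'   `Poisson(rate)` distinct reference targets uniformly from the target
#'   sub-hierarchy.
#' @param refs_per_class_max cap on total references per class.
#' @param rng_seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(subhierarchy_sizes, depth_mean = 5, branching = 1,
                           multiparent_prob = 0.02, coupling = numeric(0),
                           refs_per_class_max = 5L, rng_seed = 1L) {
  check(is.numeric(subhierarchy_sizes) && length(subhierarchy_sizes) >= 1L &&
          !is.null(names(subhierarchy_sizes)) &&
          all(subhierarchy_sizes >= 1) &&
          all(subhierarchy_sizes == floor(subhierarchy_sizes)),
        "'subhierarchy_sizes' must be named integers >= 1")
  check(is.numeric(depth_mean) && depth_mean >= 1, "'depth_mean' must be >= 1")
  check(is.numeric(branching) && branching > 0, "'branching' must be positive")
  check(is.numeric(multiparent_prob) && multiparent_prob >= 0 &&
          multiparent_prob <= 1, "'multiparent_prob' must be in [0, 1]")
  shs <- names(subhierarchy_sizes)
  if (length(coupling) > 0L) {
    check(!is.null(names(coupling)) && all(coupling >= 0),
          "'coupling' must be a named non-negative vector")
    pairs <- strsplit(names(coupling), "->", fixed = TRUE)
    ok <- vapply(pairs, function(p) length(p) == 2L && all(p %in% shs), TRUE)
    check(all(ok), "coupling names must be 'SRC->TGT' over declared sub-hierarchies")
  }
  check(is_count(refs_per_class_max, min = 0L),
        "'refs_per_class_max' must be a non-negative integer")
  structure(list(subhierarchy_sizes = stats::setNames(
                   as.integer(subhierarchy_sizes), shs),
                 depth_mean = depth_mean, branching = branching,
                 multiparent_prob = multiparent_prob,
                 coupling = coupling,
                 refs_per_class_max = as.integer(refs_per_class_max),
                 rng_seed = as.integer(rng_seed)),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("<generator_spec> %d sub-hierarchies, %d classes total (+root)\n",
              length(x$subhierarchy_sizes), sum(x$subhierarchy_sizes)))
  cat(sprintf("  depth_mean %g, branching %g, multiparent %g, %d coupling pair(s), seed %d\n",
              x$depth_mean, x$branching, x$multiparent_prob,
              length(x$coupling), x$rng_seed))
  invisible(x)
}

#' SNOMED-CT-shaped generator specification
#'
#' A `generator_spec` with 18 sub-hierarchies whose sizes are the published
#' SNOMED CT per-sub-hierarchy concept counts scaled by `scale` (each at
#' least 1, so the rank order and the extreme size ratio — clinical findings
#' vs physical forces — survive heavy down-scaling). The default coupling is
#' this package's own synthetic stand-in for SNOMED's cross-hierarchy
#' definition structure; it concentrates reference mass where SNOMED's
#' definitions do: findings on body structures (finding sites) and organisms
#' (causative agents), procedures on body structures, products on
#' substances.
#'
#' @param scale fraction in (0, 1]: 1 reproduces the published counts
#'   (299,239 classes), ~0.0334 gives a ten-thousand-class ontology.
#' @param coupling override the default coupling vector.
#' @param ... further arguments to [generator_spec()].
#' @return A `generator_spec`.
#' @examples
#' sum(snomed_like_spec(1)$subhierarchy_sizes)  # 299239
#' @export
snomed_like_spec <- function(scale = 0.0334,
                             coupling = c("CF->BS" = 0.10, "CF->OR" = 0.03,
                                          "PR->BS" = 0.06, "PB->SU" = 0.12),
                             ...) {
  check(is.numeric(scale) && length(scale) == 1L && scale > 0 && scale <= 1,
        "'scale' must be in (0, 1]")
  sizes <- stats::setNames(pmax(1L, as.integer(round(scale * SNOMED_SUBHIERARCHY_COUNTS))),
                           names(SNOMED_SUBHIERARCHY_COUNTS))
  generator_spec(sizes, coupling = coupling, ...)
}

#' Generate a synthetic ontology from a specification
#'
#' Builds a rooted DAG with one top-level class per sub-hierarchy and exactly
#' the requested number of classes in each (sizes are hard constraints, so
#' shape profiles of generated ontologies are deterministic; only edges are
#' stochastic). Within a sub-hierarchy, classes attach at a
#' Poisson-distributed depth below the top; extra parents and cross-hierarchy
#' references are drawn per the spec. Acyclicity holds by construction
#' (parents always precede children in generation order) and the result
#' always passes [validate_ontology()].
#'
#' @param spec a `generator_spec`.
#' @return A validated `ontology` with root `"ROOT"` and
#'   `sum(subhierarchy_sizes) + 1` classes.
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  sizes <- spec$subhierarchy_sizes
  shs <- names(sizes)
  check(!"ROOT" %in% shs, "'ROOT' is reserved for the root class")

  with_seed(spec$rng_seed, {
    parents <- list(ROOT = character(0))
    ids_by_sh <- vector("list", length(shs))
    names(ids_by_sh) <- shs

    for (sh in shs) {
      m <- sizes[[sh]]
      width <- max(4L, nchar(as.character(m)))
      ids <- c(sh, if (m > 1L) sprintf("%s_%0*d", sh, width, seq_len(m - 1L)))
      ids_by_sh[[sh]] <- ids
      depth <- integer(m)  # depth below the top-level class
      nchild <- integer(m)
      by_depth <- list(`0` = 1L)  # indices into ids, keyed by depth
      parents[[ids[1L]]] <- "ROOT"
      if (m > 1L) {
        want <- 1L + stats::rpois(m - 1L, spec$depth_mean - 1)
        extra <- stats::runif(m - 1L) < spec$multiparent_prob
        for (j in 2L:m) {
          d <- min(want[[j - 1L]], length(by_depth))  # clamp to reachable depth
          cand <- by_depth[[as.character(d - 1L)]]
          pick <- if (length(cand) == 1L) cand
                  else if (spec$branching == 1) cand[sample.int(length(cand), 1L)]
                  else cand[sample.int(length(cand), 1L,
                                       prob = spec$branching^(-nchild[cand]))]
          par <- ids[pick]
          if (extra[[j - 1L]] && j > 2L) {
            others <- setdiff(seq_len(j - 1L), pick)
            if (length(others) > 0L) {
              p2 <- others[sample.int(length(others), 1L)]
              par <- c(par, ids[p2])
              nchild[p2] <- nchild[p2] + 1L
            }
          }
          parents[[ids[j]]] <- par
          nchild[pick] <- nchild[pick] + 1L
          depth[j] <- d
          key <- as.character(d)
          by_depth[[key]] <- c(by_depth[[key]], j)
        }
      }
    }

    references <- list()
    if (length(spec$coupling) > 0L && spec$refs_per_class_max > 0L) {
      pairs <- strsplit(names(spec$coupling), "->", fixed = TRUE)
      nref <- lapply(sizes, integer)  # per-stratum running reference counts
      for (p in seq_along(pairs)) {
        src <- pairs[[p]][1L]; tgt <- pairs[[p]][2L]
        rate <- spec$coupling[[p]]
        if (rate == 0) next
        pool <- ids_by_sh[[tgt]]
        src_ids <- ids_by_sh[[src]]
        counts <- stats::rpois(length(src_ids), rate)
        for (i in seq_along(src_ids)) {
          k <- min(counts[[i]], spec$refs_per_class_max - nref[[src]][[i]])
          if (k <= 0L) next
          cid <- src_ids[[i]]
          avail <- if (src == tgt) setdiff(pool, cid) else pool
          k <- min(k, length(avail))
          draw <- avail[sample.int(length(avail), k)]
          references[[cid]] <- c(references[[cid]], draw)
          nref[[src]][[i]] <- nref[[src]][[i]] + k
        }
      }
    }

    ontology("ROOT", parents, references)
  })
}
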