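#' Parse an OWL functional-syntax EL-like subset
#'
#' Reads the restricted axiom shapes found in the OWL-EL rendering of SNOMED
#' CT: `SubClassOf` and `EquivalentClasses` over named classes,
#' `ObjectIntersectionOf` and `ObjectSomeValuesFrom` (arbitrarily nested,
#' which covers role groups). For each class, *parents* are the named
#' superclasses and the named conjuncts of top-level intersections; and
#' *references* are the named fillers of existential restrictions, collected
#' recursively through nested intersections and restrictions.
#'
#' `Declaration(Class(...))` registers a class; `Prefix`, `Ontology(` headers
#' and annotations are skipped. Any other axiom (object-property axioms,
#' annotation assertions, ...) is ignored and counted in
#' `attr(result, "ignored_axioms")`. The root is the unique class without
#' parents.
#'
#' @param lines character vector with the file's lines.
#' @return A validated `ontology`.
#' @export
parse_owl_functional <- function(lines) {
  text <- paste(lines, collapse = "\n")
  if (!nzchar(trimws(text))) stop("parse error: empty OWL document", call. = FALSE)
  toks <- owl_tokenize(text)
  if (length(toks$type) == 0L) stop("parse error: no OWL tokens found", call. = FALSE)

  parents <- list()
  refs <- list()
  declared <- character(0)
  ignored <- 0L

  ensure <- function(id) {
    if (is.null(parents[[id]])) {
      parents[[id]] <<- character(0)
      refs[[id]] <<- character(0)
    }
  }

  i <- 1L
  nt <- length(toks$type)
  # read one balanced parenthesised group starting at an opening '(' index;
  # returns index just past the matching ')'
  skip_group <- function(open) {
    depth <- 0L
    j <- open
    repeat {
      if (toks$type[j] == "(") depth <- depth + 1L
      if (toks$type[j] == ")") {
        depth <- depth - 1L
        if (depth == 0L) return(j + 1L)
      }
      j <- j + 1L
      if (j > nt) stop("parse error: unbalanced parentheses", call. = FALSE)
    }
  }

  while (i <= nt) {
    if (toks$type[i] != "name") { i <- i + 1L; next }
    kw <- toks$text[i]
    if (kw %in% c("Prefix", "Ontology")) {
      # Prefix(...) is skipped whole; Ontology( just opens a wrapper whose
      # closing paren is tolerated by the ')' fallthrough above
      if (kw == "Prefix" && i + 1L <= nt && toks$type[i + 1L] == "(") {
        i <- skip_group(i + 1L)
      } else {
        i <- i + 2L  # 'Ontology' '('
      }
      next
    }
    if (!(i + 1L <= nt && toks$type[i + 1L] == "(")) { i <- i + 1L; next }
    end <- skip_group(i + 1L)
    inner <- owl_slice(toks, i + 2L, end - 2L)  # tokens inside the axiom parens
    if (kw == "Declaration") {
      # Declaration(Class(:A))
      if (length(inner$type) >= 4L && inner$text[1L] == "Class") {
        nm <- inner$text[inner$type == "iri"]
        if (length(nm) == 1L) { ensure(nm); declared <- c(declared, nm) }
      } else ignored <- ignored + 1L
    } else if (kw == "SubClassOf") {
      ax <- owl_two_expressions(inner)
      if (is.null(ax)) {
        ignored <- ignored + 1L
      } else {
        lhs <- owl_expr_info(ax$first)
        rhs <- owl_expr_info(ax$second)
        if (is.null(lhs$name)) {
          ignored <- ignored + 1L  # complex left-hand sides are out of scope
        } else {
          ensure(lhs$name)
          for (p in rhs$parents) ensure(p)
          for (r in rhs$references) ensure(r)
          parents[[lhs$name]] <- c(parents[[lhs$name]], rhs$parents)
          refs[[lhs$name]] <- c(refs[[lhs$name]], rhs$references)
        }
      }
    } else if (kw == "EquivalentClasses") {
      ax <- owl_two_expressions(inner)
      if (is.null(ax)) {
        ignored <- ignored + 1L
      } else {
        lhs <- owl_expr_info(ax$first)
        rhs <- owl_expr_info(ax$second)
        if (is.null(lhs$name)) { tmp <- lhs; lhs <- rhs; rhs <- tmp }
        if (is.null(lhs$name)) {
          ignored <- ignored + 1L
        } else {
          ensure(lhs$name)
          for (p in rhs$parents) ensure(p)
          for (r in rhs$references) ensure(r)
          parents[[lhs$name]] <- c(parents[[lhs$name]], rhs$parents)
          refs[[lhs$name]] <- c(refs[[lhs$name]], rhs$references)
        }
      }
    } else {
      ignored <- ignored + 1L
    }
    i <- end
  }

  if (length(parents) == 0L) stop("parse error: no class axioms found", call. = FALSE)
  roots <- names(parents)[vapply(parents, length, 1L) == 0L]
  if (length(roots) != 1L) {
    stop(sprintf("expected exactly one parentless (root) class, found %d: %s",
                 length(roots), paste(utils::head(sort(roots), 5L), collapse = ", ")),
         call. = FALSE)
  }
  g <- ontology(roots, parents, refs)
  attr(g, "ignored_axioms") <- ignored
  g
}

# Tokenizer: parentheses, IRIs (<...>, :name, pref:name), caret literals and
# bare names. Comments and string literals are not part of the subset.
owl_tokenize <- function(text) {
  pat <- "<[^>]*>|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]+|:[A-Za-z0-9_.-]+|[A-Za-z][A-Za-z0-9_.-]*|[()]"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(list(type = character(0), text = character(0)))
  tok <- regmatches(text, list(m))[[1L]]
  type <- ifelse(tok == "(", "(",
          ifelse(tok == ")", ")",
          ifelse(grepl("^<|:", tok) | grepl(":", tok, fixed = TRUE), "iri", "name")))
  # keywords like SubClassOf are bare names; normalise IRI spellings
  iri <- type == "iri"
  tok[iri] <- owl_normalize_iri(tok[iri])
  list(type = type, text = tok)
}

owl_normalize_iri <- function(x) {
  # <http://...#Frag> or <...>/Frag -> Frag ; pref:Name / :Name -> Name
  x <- sub("^<(.*)>$", "\\1", x)
  x <- sub("^.*[#/]", "", x)
  sub("^.*:", "", x)
}

owl_slice <- function(toks, from, to) {
  if (to < from) return(list(type = character(0), text = character(0)))
  list(type = toks$type[from:to], text = toks$text[from:to])
}

# Split an axiom body into its two top-level class expressions.
owl_two_expressions <- function(toks) {
  exprs <- list()
  i <- 1L
  nt <- length(toks$type)
  while (i <= nt) {
    if (toks$type[i] == "iri") {
      exprs[[length(exprs) + 1L]] <- owl_slice(toks, i, i)
      i <- i + 1L
    } else if (toks$type[i] == "name") {
      if (i + 1L <= nt && toks$type[i + 1L] == "(") {
        depth <- 0L; j <- i + 1L
        repeat {
          if (toks$type[j] == "(") depth <- depth + 1L
          if (toks$type[j] == ")") { depth <- depth - 1L; if (depth == 0L) break }
          j <- j + 1L
          if (j > nt) return(NULL)
        }
        exprs[[length(exprs) + 1L]] <- owl_slice(toks, i, j)
        i <- j + 1L
      } else return(NULL)
    } else return(NULL)
  }
  if (length(exprs) != 2L) return(NULL)
  list(first = exprs[[1L]], second = exprs[[2L]])
}

# Interpret one class expression:
#   named class        -> name = id, parents = id
#   intersection       -> parents = named conjuncts; references from nested
#                         restrictions/intersections
#   some-values-from   -> references = named fillers (recursively)
owl_expr_info <- function(toks) {
  if (length(toks$type) == 1L && toks$type[1L] == "iri") {
    return(list(name = toks$text[1L], parents = toks$text[1L], references = character(0)))
  }
  head <- toks$text[1L]
  inner <- owl_slice(toks, 3L, length(toks$type) - 1L)
  if (head == "ObjectIntersectionOf") {
    parts <- owl_split_expressions(inner)
    parents <- character(0); references <- character(0)
    for (p in parts) {
      info <- owl_expr_info(p)
      if (length(info$parents) == 1L && !is.null(info$name)) {
        parents <- c(parents, info$name)
      } else {
        parents <- c(parents, setdiff(info$parents, NA))
      }
      references <- c(references, info$references)
    }
    return(list(name = NULL, parents = parents, references = references))
  }
  if (head == "ObjectSomeValuesFrom") {
    # first sub-expression is the property (iri), the rest is the filler
    parts <- owl_split_expressions(inner)
    references <- character(0)
    if (length(parts) >= 2L) {
      for (p in parts[-1L]) {
        info <- owl_expr_info(p)
        # named filler is a reference; nested expressions contribute both
        # their conjunct names and their own references as references
        references <- c(references, info$parents, info$references)
      }
    }
    return(list(name = NULL, parents = character(0), references = references))
  }
  # unknown constructor: contributes nothing
  list(name = NULL, parents = character(0), references = character(0))
}

owl_split_expressions <- function(toks) {
  parts <- list()
  i <- 1L
  nt <- length(toks$type)
  while (i <= nt) {
    if (toks$type[i] == "iri") {
      parts[[length(parts) + 1L]] <- owl_slice(toks, i, i)
      i <- i + 1L
    } else if (toks$type[i] == "name" && i + 1L <= nt && toks$type[i + 1L] == "(") {
      depth <- 0L; j <- i + 1L
      repeat {
        if (toks$type[j] == "(") depth <- depth + 1L
        if (toks$type[j] == ")") { depth <- depth - 1L; if (depth == 0L) break }
        j <- j + 1L
        if (j > nt) stop("parse error: unbalanced parentheses in expression",
                         call. = FALSE)
      }
      parts[[length(parts) + 1L]] <- owl_slice(toks, i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  parts
}
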