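test_that("construction validates structural invariants", {
  g <- toy1()
  expect_s3_class(g, "ontology")
  expect_equal(n_classes(g), 8L)
  expect_equal(subhierarchies(g), c("A", "B"))
  rep <- validate_ontology(g)
  expect_equal(nrow(rep$errors), 0L)

  # parent cycle is rejected and named
  expect_error(ontology("R", parents = list(R = character(), A = c("R", "B"),
                                            B = "A")),
               "cycle")
  # dangling identifiers
  expect_error(ontology("R", parents = list(R = character(), A = "R"),
                        references = list(A = "nope")),
               "dangling")
  # self edges
  expect_error(ontology("R", parents = list(R = character(), A = c("R", "A"))),
               "itself")
  # a second parentless class cannot reach the root
  expect_error(ontology("R", parents = list(R = character(), A = character())),
               "unrooted|no parents")
  # root with parents
  expect_error(ontology("R", parents = list(R = "A", A = "R")), "root")
})

test_that("sub-hierarchy assignment follows the documented tie-break", {
  # chain R -> A -> A1 -> A2
  g <- ontology("R", parents = list(R = character(), A = "R", A1 = "A",
                                    A2 = "A1"))
  expect_equal(assign_subhierarchies(g),
               c(A = "A", A1 = "A", A2 = "A"))
  # root absent from the map
  expect_false("R" %in% names(assign_subhierarchies(g)))

  # class with parents in both A and B: lexicographically smaller wins, warned
  g2 <- ontology("R", parents = list(R = character(), B = "R", A = "R",
                                     X = c("A", "B")))
  expect_equal(assign_subhierarchies(g2)[["X"]], "A")
  expect_true(any(g2$warnings$code == "multi_subhierarchy" &
                    g2$warnings$class == "X"))
})

test_that("sub-hierarchy assignment matches the exhaustive upward-BFS oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:12) {
    g <- random_ontology(seed, max_classes = 200L)
    expect_equal(assign_subhierarchies(g)[order(names(assign_subhierarchies(g)))],
                 oracle_subhierarchy(g)[order(names(oracle_subhierarchy(g)))],
                 info = paste("seed", seed))
  }
})

test_that("stripping a sub-hierarchy removes exactly its descendants", {
  g <- toy1()
  s <- strip_subhierarchy(g, "B")
  expect_equal(sort(s$ids), c("A", "A1", "A2", "R"))
  # A2's reference into the removed region was dropped and counted
  expect_equal(attr(s, "dropped_references"), 1L)
  expect_equal(s$references$A2, character(0))
  expect_equal(nrow(validate_ontology(s)$errors), 0L)

  # leaf-only sub-hierarchy of size 1
  g2 <- ontology("R", parents = list(R = character(), A = "R", B = "R",
                                     A1 = "A"))
  expect_equal(n_classes(strip_subhierarchy(g2, "B")), 3L)
  # the root is not a sub-hierarchy
  expect_error(strip_subhierarchy(g, "R"), "direct child")
})

test_that("stripping never leaves dangling parent edges", {
  for (seed in 1:8) {
    g <- random_ontology(seed + 100, max_classes = 150L)
    for (sh in subhierarchies(g)) {
      s <- strip_subhierarchy(g, sh)
      expect_equal(nrow(validate_ontology(s)$errors), 0L,
                   info = paste("seed", seed, "strip", sh))
    }
  }
})

test_that("native format round-trips the graph exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  for (seed in 1:8) {
    g <- random_ontology(seed + 200, max_classes = 120L)
    write_ontology(g, path)
    expect_same_ontology(load_ontology(path), g)
  }
  # unicode labels round-trip byte-exact
  g <- ontology("R", parents = list(R = character(), A = "R"),
                labels = c(A = "Körperstruktur — fémur"))
  write_ontology(g, path)
  expect_identical(load_ontology(path)$labels[["A"]],
                   "Körperstruktur — fémur")
})

test_that("loader rejects malformed input with useful errors", {
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("", empty)
  expect_error(load_ontology(empty), "parse error|format_version")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format_version": 1, "root": "R", "classes": [
    {"id": "R", "label": null, "parents": [], "references": []},
    {"id": "A", "label": null, "parents": ["R"], "references": ["ghost"]}]}',
    bad)
  expect_error(load_ontology(bad), "dangling")

  cyc <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format_version": 1, "root": "R", "classes": [
    {"id": "R", "label": null, "parents": [], "references": []},
    {"id": "A", "label": null, "parents": ["R", "B"], "references": []},
    {"id": "B", "label": null, "parents": ["A"], "references": []}]}',
    cyc)
  expect_error(load_ontology(cyc), "cycle")

  expect_error(load_ontology(tempfile("nope")), "does not exist")
})

test_that("unwritable paths raise I/O errors", {
  g <- toy1()
  suppressWarnings(
    expect_error(write_ontology(g, file.path(tempdir(), "no-such-dir", "x.json"))))
})

test_that("seed-list files support comments and blank lines", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "A2  ", "", "B1 # trailing", "#"), f)
  expect_equal(read_seed_file(f), c("A2", "B1"))
})
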