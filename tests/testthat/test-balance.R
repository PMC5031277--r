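test_that("weight updates follow the target/achieved frequency ratio", {
  # single scaled stratum: 0.2 * (0.3/0.15) = 0.4 before renormalization
  w <- update_weights(c(A = 0.2, B = 0.8), c(A = 30, B = 70), c(A = 15, B = 85))
  raw <- c(0.2 * 30 / 15, 0.8 * 70 / 85)
  expect_equal(unname(w), raw / sum(raw), tolerance = 1e-12)

  # perfect module: fixed point
  t <- c(A = 40, B = 60)
  expect_equal(update_weights(c(A = 0.4, B = 0.6), t, t), c(A = 0.4, B = 0.6))

  # pure renormalization of raw weights (0.4, 0.8)
  w2 <- update_weights(c(A = 0.4, B = 0.8), c(A = 1, B = 1), c(A = 1, B = 1))
  expect_equal(w2, c(A = 1 / 3, B = 2 / 3))

  # numerical guard: achieved 0 where the target is positive
  expect_error(update_weights(c(A = 0.5, B = 0.5), c(A = 50, B = 50),
                              c(A = 0, B = 100)),
               "at least one seed")
  # a zero target zeroes the weight
  w3 <- update_weights(c(A = 0.5, B = 0.5), c(A = 100, B = 0), c(A = 90, B = 10))
  expect_equal(unname(w3), c(1, 0))
})

test_that("updated weights stay on the probability simplex", {
  set.seed(123)
  for (i in 1:50) {
    K <- sample(2:18, 1L)
    w <- rexp(K); w <- stats::setNames(w / sum(w), paste0("S", 1:K))
    t <- rexp(K) + 0.01; t <- 100 * t / sum(t)
    m <- rexp(K) + 0.01; m <- 100 * m / sum(m)
    names(t) <- names(m) <- names(w)
    w2 <- update_weights(w, t, m)
    expect_true(all(w2 >= 0))
    expect_equal(sum(w2), 1, tolerance = 1e-12)
  }
})

test_that("coupled references over-represent the target sub-hierarchy, then
           the source sub-hierarchy's weight is raised in compensation", {
  g <- flat_coupled_fixture()
  fit <- balance(g, n = 10, max_iter = 2, rng_seed = 7)
  it1 <- fit$trace[[1]]
  # every A seed drags its B reference along: B over-represented at iteration 1
  expect_gt(it1$error$errors[["B"]], 0)
  expect_lt(it1$error$errors[["A"]], 0)
  if (length(fit$trace) > 1L) {
    # compensation: A's signature weight increases at iteration 2
    expect_gt(fit$trace[[2]]$signature$weights[["A"]],
              it1$signature$weights[["A"]])
  }
})

test_that("the iteration cap is honoured and the best iteration returned", {
  g <- flat_coupled_fixture()
  fit <- balance(g, n = 10, max_iter = 1, rng_seed = 7)
  expect_false(fit$converged)
  expect_equal(fit$best_iteration, 1L)
  expect_length(fit$trace, 1L)
  expect_error(balance(g, n = 10, max_iter = 0, rng_seed = 1), "positive")

  # the returned module is never worse than the naive first iteration
  fit25 <- balance(g, n = 10, max_iter = 25, rng_seed = 7)
  expect_lte(fit25$trace[[fit25$best_iteration]]$error$rss,
             fit25$trace[[1]]$error$rss)
})

test_that("balancing a flat uncoupled ontology converges immediately", {
  spec <- generator_spec(c(A = 40L, B = 30L, C = 20L, D = 10L),
                         depth_mean = 1, multiparent_prob = 0, rng_seed = 5)
  g <- generate_ontology(spec)
  fit <- balance(g, n = 80, rng_seed = 3)
  expect_true(fit$converged)
  expect_equal(fit$best_iteration, 1L)
  expect_lt(fit$trace[[1]]$error$rss, 1)
  # closed form: module = seeds + sub-hierarchy tops + root
  sig <- fit$trace[[1]]$signature
  expect_setequal(fit$module$classes,
                  unique(c(sig$classes, "A", "B", "C", "D", "ROOT")))
})

test_that("balance is bit-reproducible for a fixed seed", {
  g <- flat_coupled_fixture()
  f1 <- balance(g, n = 12, max_iter = 5, rng_seed = 11)
  f2 <- balance(g, n = 12, max_iter = 5, rng_seed = 11)
  expect_identical(f1, f2)
  f3 <- balance(g, n = 12, max_iter = 5, rng_seed = 12)
  expect_false(identical(f1$trace[[1]]$signature$classes,
                         f3$trace[[1]]$signature$classes))
})

test_that("fit accessors expose weights, residuals and summaries", {
  g <- flat_coupled_fixture()
  fit <- balance(g, n = 12, max_iter = 4, rng_seed = 2)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-12)
  expect_equal(names(residuals(fit)), c("A", "B"))
  s <- summary(fit)
  expect_s3_class(s, "summary.ontobalance")
  expect_equal(s$module_size, fit$trace[[fit$best_iteration]]$module_size)
  expect_output(print(fit), "ontobalance")
  expect_output(print(s), "module:")
  # plot renders without error
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, min_abs_error = 0))
})

test_that("traces export to CSV and round-trip numerically", {
  g <- flat_coupled_fixture()
  fit <- balance(g, n = 10, max_iter = 2, rng_seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  export_trace(fit, f)
  tab <- utils::read.csv(f)
  expect_equal(nrow(tab), length(fit$trace) * 2L)  # iterations x sub-hierarchies
  expect_equal(names(tab), c("iteration", "subhierarchy", "signature_weight",
                             "module_count", "module_freq_pct", "error_pct",
                             "rss"))
  long <- as.data.frame(fit)
  expect_equal(tab$error_pct, long$error_pct, tolerance = 1e-9)
  expect_equal(tab$rss, long$rss, tolerance = 1e-9)
  expect_equal(tab$signature_weight, long$signature_weight, tolerance = 1e-9)

  empty <- structure(list(trace = list()), class = "ontobalance")
  expect_error(export_trace(empty, f), "empty")
})
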