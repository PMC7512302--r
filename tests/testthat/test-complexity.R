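test_that("complete-model complexity follows the Dirichlet closed form", {
  expect_equal(complexity_complete(1)$value, log_pi)
  expect_equal(complexity_complete(2)$value, 2 * log_pi)
  expect_equal(complexity_complete(4)$value, 8 * log_pi - lgamma(8))
  # negative beyond n = 4: complete models are the simplest of all
  expect_lt(complexity_complete(5)$value, 0)
  expect_equal(complexity_complete(6)$value, 32 * log_pi - lgamma(32))
})

test_that("closed forms cover loopless, sub-complete and factorized models", {
  expect_equal(complexity_closed(spin_model(list(1, 2), 4))$value, 2 * log_pi)
  expect_equal(complexity_closed(spin_model(list(1, 2), 4))$method,
               "closed_loopless")
  ca <- complexity_closed(reference_class_model("a"))
  expect_equal(ca$value, 4 * log_pi - lgamma(4))
  expect_equal(ca$method, "closed_subcomplete")
  expect_equal(complexity_closed(complete_model(3))$method, "closed_complete")
  # two non-overlapping 3-loops: 2 log pi each, plus one free operator
  m2loops <- spin_model(list(1, 2, c(1, 2), 3, 4, c(3, 4), 5), n = 5)
  c2 <- complexity_closed(m2loops)
  expect_equal(c2$value, 4 * log_pi + log_pi)
  expect_equal(c2$method, "closed_nonoverlapping")
  # overlapping loops that are not sub-complete: no closed form
  expect_null(complexity_closed(pairwise_model(4, fields = TRUE)))
  expect_null(complexity_closed(single_loop_model(4)))
})

test_that("the theta substitution integrates loopless models exactly", {
  est <- complexity_mc(spin_model(list(1, 2), 2), n_samples = 1000,
                       n_reps = 5, seed = 1)
  expect_equal(est$value, 2 * log_pi, tolerance = 1e-12)
  expect_lt(est$std_error, 1e-12)
})

test_that("Monte Carlo agrees with closed forms within 3 standard errors", {
  est2 <- complexity_mc(complete_model(2), n_samples = 2e4, n_reps = 25,
                        seed = 2)
  expect_lt(abs(est2$value - 2 * log_pi), 3 * est2$std_error)
  esta <- complexity_mc(reference_class_model("a"), n_samples = 2e4,
                        n_reps = 25, seed = 3)
  expect_lt(abs(esta$value - (4 * log_pi - lgamma(4))), 3 * esta$std_error)
})

test_that("Monte Carlo estimates are gauge-invariant and reproducible", {
  est_a <- complexity_mc(reference_class_model("a"), n_samples = 2e4,
                         n_reps = 20, seed = 4)
  est_d <- complexity_mc(reference_class_model("d"), n_samples = 2e4,
                         n_reps = 20, seed = 5)
  comb <- sqrt(est_a$std_error^2 + est_d$std_error^2)
  expect_lt(abs(est_a$value - est_d$value), 3 * comb)
  again <- complexity_mc(reference_class_model("a"), n_samples = 2e4,
                         n_reps = 20, seed = 4)
  expect_identical(est_a$value, again$value)
  # extending n_reps keeps the earlier repetitions (counter seed scheme)
  longer <- complexity_mc(reference_class_model("a"), n_samples = 2e4,
                          n_reps = 21, seed = 4)
  expect_false(identical(est_a$value, longer$value))
})

test_that("every estimate respects the independent-operator upper bound", {
  for (seed in c(2, 9)) {
    model <- random_model(4, 5, seed)
    est <- model_complexity(model, n_samples = 1e4, n_reps = 15, seed = seed)
    expect_lt(est$value, n_operators(model) * log_pi + 3 * est$std_error +
                1e-9)
  }
})

test_that("single-loop models interpolate between complete and loopless", {
  expect_equal(complexity_single_loop(3, 3)$value, 2 * log_pi)
  expect_equal(complexity_single_loop(3, 5)$value, 4 * log_pi)
  expect_error(complexity_single_loop(2, 5), "at least 3")
  mod4 <- single_loop_model(4, 5)
  expect_equal(n_operators(mod4), 5L)
  expect_equal(loop_basis(mod4)$lam, 1L)
  est4 <- complexity_single_loop(4, 4, n_samples = 1e4, n_reps = 15, seed = 6)
  # longer loop: above the 3-loop value, below the loopless bound
  expect_gt(est4$value, complexity_single_loop(3, 4)$value - 3 * est4$std_error)
  expect_lt(est4$value, 4 * log_pi + 3 * est4$std_error)
})

test_that("the 3-loop marginal polytope is a strict subset of the cube", {
  expect_true(polytope_contains_3loop(c(0, 0, 0)))
  expect_true(polytope_contains_3loop(c(1, 1, 1)))    # boundary vertex
  expect_false(polytope_contains_3loop(c(1, 1, -1)))  # frustrated corner
  expect_error(polytope_contains_3loop(c(0, 0)), "length 3")
  expect_error(polytope_contains_3loop(c(0, 0, 2)), "\\[-1, 1\\]")
  # moments of an actual model distribution always lie inside
  model <- complete_model(2)
  for (gs in list(c(2, -1, 0.5), c(-3, 3, 1))) {
    expect_true(polytope_contains_3loop(operator_means(model, gs)))
  }
})

test_that("the complexity-spread bound grows with the parameter count", {
  dc <- complexity_gap_bound(2:63)
  expect_true(all(diff(dc) > 0))
})
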