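test_that("brute-force partition function matches closed forms and oracle", {
  m1 <- spin_model(list(1), n = 2)
  expect_equal(partition_brute(m1, 0), 4)
  expect_equal(partition_brute(m1, 1), 4 * cosh(1))
  model <- random_model(3, 4, seed = 2)
  g <- spinsc:::withr_seed(3, rnorm(4, sd = 0.8))
  expect_equal(partition_brute(model, g), oracle_Z(model, g),
               tolerance = 1e-12)
  # log-domain arithmetic keeps large couplings finite
  expect_true(is.finite(log_partition_brute(m1, 30)))
})

test_that("the loop expansion reproduces the brute-force partition function", {
  for (seed in 1:50) {
    n <- 2L + seed %% 3L
    m <- 1L + seed %% (2L^n - 1L)
    model <- random_model(n, m, seed)
    g <- spinsc:::withr_seed(seed + 1000L, runif(m, -2, 2))
    zb <- partition_brute(model, g)
    zl <- partition_loops(model, g)
    expect_lt(abs(zl - zb) / zb, 1e-10)
  }
  # loopless models: Z = 2^n prod cosh(g)
  model <- spin_model(list(1, 3, c(1, 2)), n = 3)
  g <- c(0.4, -1.1, 0.9)
  expect_equal(partition_loops(model, g), 2^3 * prod(cosh(g)),
               tolerance = 1e-12)
  expect_equal(partition_loops(model, c(0, 0, 0)), 8)
})

test_that("Fisher matrix is the exact operator covariance", {
  model <- random_model(3, 5, seed = 4)
  expect_equal(fisher_matrix(model, rep(0, 5)), diag(5), tolerance = 1e-12)
  g <- spinsc:::withr_seed(5, runif(5, -1, 1))
  expect_equal(fisher_matrix(model, g), oracle_fisher(model, g),
               tolerance = 1e-10)
  expect_gt(min(eigen(fisher_matrix(model, g), symmetric = TRUE,
                      only.values = TRUE)$values), -1e-12)
  # single operator: J = 1 - tanh^2(g)
  m1 <- spin_model(list(2), n = 3)
  expect_equal(fisher_matrix(m1, 0.7)[1, 1], 1 - tanh(0.7)^2,
               tolerance = 1e-12)
})

test_that("exact sampling is reproducible and matches model moments", {
  m1 <- spin_model(list(1), n = 2)
  d1 <- sample_states(m1, 2, N = 1e5, seed = 42)
  d2 <- sample_states(m1, 2, N = 1e5, seed = 42)
  expect_identical(d1$samples, d2$samples)
  # <s1> = tanh(2) within 3 standard errors
  se <- sqrt((1 - tanh(2)^2) / 1e5)
  expect_lt(abs(mean(d1$samples[, 1]) - tanh(2)), 3 * se + 3e-3)
  # uniform model: all operator means small
  model <- complete_model(2)
  d0 <- sample_states(model, rep(0, 3), N = 1e4, seed = 7)
  expect_lt(max(abs(empirical_means(model, d0))), 4 / sqrt(1e4))
})

test_that("log-likelihood identities hold", {
  model <- random_model(3, 4, seed = 6)
  data <- sample_states(model, rep(0.3, 4), N = 200, seed = 8)
  expect_equal(loglikelihood(model, rep(0, 4), data), -200 * 3 * log(2))
  # invariance under a joint gauge transformation of model and dataset
  C <- matrix(c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L), 3)
  g <- c(0.5, -0.2, 0.8, 0.1)
  sigma_data <- gauge_transform_dataset(data, C)
  expect_equal(loglikelihood(model, g, sigma_data),
               loglikelihood(apply_gauge(model, gauge_map(C)), g, data),
               tolerance = 1e-10)
})

test_that("maximum likelihood fits factorize for loopless models", {
  model <- spin_model(list(1, 2, c(2, 3)), n = 3)
  data <- sample_states(model, c(0.6, -0.4, 0.2), N = 5000, seed = 9)
  g_hat <- fit_ml(model, data)
  expect_equal(as.numeric(g_hat), atanh(empirical_means(model, data)),
               tolerance = 1e-7)
  # model expectations match empirical means at the optimum
  expect_lt(max(abs(operator_means(model, g_hat) -
                    empirical_means(model, data))), 1e-8)
})

test_that("fit_ml handles degenerate and boundary inputs", {
  model <- spin_model(list(1, 2), n = 2)
  balanced <- spin_dataset(rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1)))
  expect_equal(as.numeric(fit_ml(model, balanced)), c(0, 0))
  frozen <- spin_dataset(matrix(1L, nrow = 5, ncol = 2))
  expect_error(fit_ml(model, frozen), "boundary.*s1", perl = TRUE)
  g_empty <- fit_ml(spin_model(integer(0), 2), balanced)
  expect_length(g_empty, 0)
})

test_that("fit_ml recovers generating couplings on a looped model", {
  model <- complete_model(2)  # the smallest model with a loop
  g_true <- c(0.5, -0.3, 0.4)
  data <- sample_states(model, g_true, N = 1e5, seed = 10)
  g_hat <- fit_ml(model, data)
  J <- fisher_matrix(model, g_hat)
  post_sd <- sqrt(diag(solve(J)) / data$N)
  expect_true(all(abs(g_hat - g_true) < 3.5 * post_sd))
})

test_that("complete-model closed-form fit matches Newton ascent", {
  model <- complete_model(3)
  data <- sample_states(model, rep(0.2, 7), N = 4000, seed = 11)
  # compare on the same (unsmoothed) empirical distribution; at this N all
  # 8 states are observed
  g_closed <- fit_complete(data, pseudocount = 0)
  g_newton <- fit_ml(model, data)
  expect_equal(as.numeric(g_closed), as.numeric(g_newton), tolerance = 1e-6)
  # uniform empirical distribution gives g = 0 exactly
  uni <- spin_dataset(oracle_states(2))
  expect_equal(max(abs(fit_complete(uni, pseudocount = 0))), 0)
  # unobserved states are an explicit error without smoothing
  one_state <- spin_dataset(matrix(1L, 4, 3))
  expect_error(fit_complete(one_state, pseudocount = 0), "unobserved")
  expect_silent(fit_complete(one_state))  # Jeffreys pseudocount default
})

test_that("fit_complete recovers couplings from large samples", {
  model <- complete_model(3)
  g_true <- spinsc:::withr_seed(12, runif(7, -0.4, 0.4))
  data <- sample_states(model, g_true, N = 2e5, seed = 13)
  g_hat <- fit_complete(data, pseudocount = 0.5)
  expect_lt(max(abs(g_hat - g_true)), 0.05)
})
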