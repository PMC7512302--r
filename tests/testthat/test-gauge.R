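test_that("gauge-group counts match exhaustive enumeration", {
  expected <- c(1, 6, 168)
  for (n in 1:3) {
    maps <- enumerate_gauge_maps(n)
    expect_equal(count_gauge_maps(n), expected[n])
    expect_length(maps, expected[n])
    keys <- vapply(maps, function(mp) paste(mp$matrix, collapse = ""),
                   character(1))
    expect_false(anyDuplicated(keys) > 0)
  }
  expect_error(enumerate_gauge_maps(5), "capped")
})

test_that("the gauge group is closed under composition and inverse", {
  for (n in 2:3) {
    maps <- enumerate_gauge_maps(n)
    keys <- vapply(maps, function(mp) paste(mp$matrix, collapse = ""),
                   character(1))
    pairs <- spinsc:::withr_seed(5,
      matrix(sample.int(length(maps), 200, replace = TRUE), ncol = 2))
    for (r in seq_len(nrow(pairs))) {
      ab <- (maps[[pairs[r, 1]]]$matrix %*% maps[[pairs[r, 2]]]$matrix) %% 2L
      expect_true(paste(ab, collapse = "") %in% keys)
    }
    # every element has an inverse in the group: A B = I for some B
    id <- paste(diag(1L, n), collapse = "")
    a <- maps[[spinsc:::withr_seed(6, sample.int(length(maps), 1))]]$matrix
    has_inverse <- any(vapply(maps, function(mp)
      paste((a %*% mp$matrix) %% 2L, collapse = "") == id, logical(1)))
    expect_true(has_inverse)
  }
})

test_that("gauge maps act on operator masks by GF(2) matrix product", {
  m <- spin_model(list(1, 2), n = 2)
  id <- gauge_map(diag(1L, 2))
  expect_equal(apply_gauge(m, id)$masks, m$masks)
  swap <- gauge_map(matrix(c(0, 1, 1, 0), 2))
  expect_equal(apply_gauge(spin_model(list(1), 2), swap)$masks, 2L)
  # s1 -> s1, s2 -> s1 s2 (second column maps spin 2 to the pair operator)
  cmap <- gauge_map(matrix(c(1, 0, 1, 1), 2))
  expect_equal(sort(apply_gauge(m, cmap)$masks), c(1L, 3L))
  expect_error(gauge_map(matrix(c(1, 1, 1, 1), 2)), "invertible")
})

test_that("gauge action preserves the class invariants", {
  model <- random_model(4, 6, seed = 9)
  inv0 <- model_invariants(model)
  for (seed in 1:5) {
    cm <- spinsc:::withr_seed(seed, {
      repeat {
        cand <- matrix(sample(0:1, 16, replace = TRUE), 4)
        ok <- tryCatch({gauge_map(cand); TRUE}, error = function(e) FALSE)
        if (ok) break
      }
      cand
    })
    expect_equal(model_invariants(apply_gauge(model, gauge_map(cm))), inv0)
  }
})

test_that("the reference 4-spin class has 15 members sharing (7, 3, 4)", {
  cl <- orbit(reference_class_model("a"))
  expect_equal(cl$size, 15L)
  expect_equal(cl$n_ops, 7)
  expect_equal(cl$n_indep, 3)
  expect_equal(cl$lambda, 4)
  for (masks in cl$members) {
    inv <- model_invariants(spin_model(masks, 4L))
    expect_equal(unname(inv), c(7, 3, 4))
  }
  # all four captioned representatives lie in the orbit
  keys <- vapply(cl$members, paste, character(1), collapse = ",")
  for (w in c("a", "b", "c", "d")) {
    mw <- reference_class_model(w)
    expect_true(paste(sort(mw$masks), collapse = ",") %in% keys)
  }
})

test_that("degenerate orbits are singletons", {
  expect_equal(orbit(spin_model(list(1), n = 1))$size, 1L)
  expect_equal(orbit(complete_model(2))$size, 1L)
  expect_equal(orbit(spin_model(integer(0), n = 3))$size, 1L)
})

test_that("classification partitions the space of all models", {
  cls1 <- classify_models(1)
  expect_length(cls1, 2L)  # empty model and {s1}
  cls2 <- classify_models(2)
  expect_equal(sum(vapply(cls2, `[[`, numeric(1), "size")), 2^3)
  cls3 <- classify_models(3, keep_members = TRUE)
  expect_equal(sum(vapply(cls3, `[[`, numeric(1), "size")), 2^7)
  all_keys <- unlist(lapply(cls3, function(cl)
    vapply(cl$members, paste, character(1), collapse = ",")))
  expect_equal(length(all_keys), 2^7)
  expect_false(anyDuplicated(all_keys) > 0)
  # members listed in a class really are gauge-equivalent to its representative
  cl <- cls3[[spinsc:::withr_seed(4, sample.int(length(cls3), 1))]]
  member <- spin_model(cl$members[[length(cl$members)]], 3L)
  expect_equal(sort(canonical_representative(member)$masks),
               sort(cl$representative$masks))
})

test_that("duality complements the operator set and commutes with gauge", {
  expect_equal(n_operators(dual_model(complete_model(3))), 0L)
  expect_equal(sort(dual_model(spin_model(list(1), 2))$masks), c(2L, 3L))
  for (seed in 1:5) {
    model <- random_model(3, 4, seed)
    expect_equal(sort(dual_model(dual_model(model))$masks), sort(model$masks))
  }
  maps <- enumerate_gauge_maps(3)
  model <- random_model(3, 3, seed = 8)
  for (mp in maps[spinsc:::withr_seed(10, sample.int(length(maps), 10))]) {
    lhs <- sort(apply_gauge(dual_model(model), mp)$masks)
    rhs <- sort(dual_model(apply_gauge(model, mp))$masks)
    expect_equal(lhs, rhs)
  }
})
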