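test_that("category probabilities follow the graded-response form", {
  b <- tiny_bank()
  p <- category_probs(b, 0)
  expect_equal(as.numeric(p), oracle_probs(1, c(-1, 0, 1), 0))
  expect_equal(as.numeric(p), c(0.2689, 0.2311, 0.2311, 0.2689),
               tolerance = 1e-3)
  expect_equal(p[1, 1], p[1, 4])  # logistic symmetry about 0
  expect_equal(p[1, 2], p[1, 3])

  ## P*_k = 0.5 exactly at theta = b_k (checked on a published item)
  q6 <- bank_subset(cesd_bank(), "q6")
  p_at_b1 <- category_probs(q6, -2.81)
  expect_equal(sum(p_at_b1[1, 2:4]), 0.5)   # P(X >= 1) = P*_1

  ## saturation at the floor
  expect_equal(as.numeric(category_probs(b, -50)), c(1, 0, 0, 0))
})

test_that("probabilities sum to one across the theta range (property)", {
  for (bk in list(tiny_bank(), three_bank(), cesd_bank())) {
    pr <- category_probs(bk, seq(-8, 8, by = 0.5))
    expect_true(all(abs(rowSums(pr, dims = 2) - 1) < 1e-12))
  }
})

test_that("item information matches closed forms and numeric curvature", {
  ## dichotomous reduction: a = 1, b = 0 gives a^2/4 at theta = b
  dich <- item_bank("d", 1, matrix(0, 1))
  expect_equal(item_information(dich, 0), 0.25, ignore_attr = TRUE)

  ## non-negative on a dense grid
  expect_true(all(item_information(cesd_bank(), seq(-6, 6, by = 0.05)) >= 0))

  ## equals the numeric second derivative of the expected log-likelihood
  got <- item_information(item_bank("x", 2, matrix(c(-1, 0, 1), 1)), 0.5)
  expect_equal(as.numeric(got), oracle_info_numderiv(2, c(-1, 0, 1), 0.5),
               tolerance = 1e-5)
})

test_that("test information is additive and order invariant", {
  b <- three_bank()
  th <- c(-2, 0, 1.3)
  expect_equal(test_information(b, th),
               rowSums(cbind(item_information(b, th))))
  two <- item_bank(c("a", "b"), c(1.4, 1.4),
                   rbind(c(-1, 0, 1), c(-1, 0, 1)))
  expect_equal(test_information(two, 0.7),
               2 * item_information(bank_subset(two, "a"), 0.7),
               ignore_attr = TRUE)
  perm <- bank_subset(b, c(3, 1, 2))
  expect_equal(test_information(perm, th), test_information(b, th))
})

test_that("information at the tails is below the central maximum", {
  b <- cesd_bank()
  expect_lt(test_information(b, -4), test_information(b, 0))
  expect_lt(test_information(b, 4), test_information(b, 0))
})

test_that("ML scoring agrees with a grid-search oracle (property)", {
  b <- cesd_bank()
  set.seed(31)
  for (rep in 1:25) {
    k <- sample(2:8, 1)
    items <- sample(b$item_id, k)
    resp <- sample(0:3, k, replace = TRUE)
    if (all(resp == 0) || all(resp == 3)) resp[1] <- 1L
    est <- score_ml(b, resp, items = items)
    expect_lt(abs(est$theta - oracle_ml_grid(b, items, resp)), 1e-3)
    expect_identical(est$method, "ML")
  }
})

test_that("ML scoring clamps non-mixed patterns and ignores item order", {
  b <- cesd_bank()
  hi <- score_ml(b, rep(3L, 17), items = b$item_id)
  expect_equal(hi$theta, 4)
  expect_false(hi$converged)
  lo <- score_ml(b, rep(0L, 5), items = b$item_id[1:5])
  expect_equal(lo$theta, -4)

  items <- c("q3", "q9", "q17", "q5")
  resp <- c(2L, 1L, 0L, 3L)
  perm <- c(3, 1, 4, 2)
  expect_equal(score_ml(b, resp, items = items)$theta,
               score_ml(b, resp[perm], items = items[perm])$theta)
})

test_that("MAP scoring shrinks toward the prior and adds information", {
  b <- cesd_bank()
  none <- score_map(b, integer(0))
  expect_equal(none$theta, 0)
  expect_equal(none$se, 1)

  set.seed(99)
  for (rep in 1:10) {
    k <- sample(3:10, 1)
    items <- sample(b$item_id, k)
    resp <- sample(0:3, k, replace = TRUE)
    if (all(resp == 0) || all(resp == 3)) resp[1] <- 1L
    ml <- score_ml(b, resp, items = items)
    map <- score_map(b, resp, items = items)
    expect_lte(abs(map$theta), abs(ml$theta) + 1e-6)
    expect_lt(map$se, ml$se)
  }

  floor_est <- score_map(b, rep(0L, 17), items = cesd_bank()$item_id)
  expect_true(is.finite(floor_est$theta) && floor_est$theta > -4)
  expect_true(floor_est$converged)
})
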