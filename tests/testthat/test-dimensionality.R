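test_that("Cronbach's alpha matches direct formula evaluation", {
  ## perfectly correlated items
  x <- cbind(a = c(0L, 1L, 2L, 3L, 1L), b = c(0L, 1L, 2L, 3L, 1L))
  expect_equal(cronbach_alpha(x), 1)

  ## two items with zero covariance
  y <- cbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 1L, 1L, 0L))
  expect_equal(cronbach_alpha(y), 0)

  ## 4-person worked table evaluated by hand: alpha = k/(k-1) (1 - sum v / vt)
  w <- cbind(c(0, 1, 2, 3), c(1, 1, 2, 3))
  vt <- var(rowSums(w))
  expect_equal(cronbach_alpha(w),
               2 * (1 - (var(w[, 1]) + var(w[, 2])) / vt))

  expect_error(cronbach_alpha(cbind(c(1, 1), c(1, 1))), "variance")
})

test_that("one-factor CFA recovers clean one-factor structure", {
  d <- make_grm_data(cesd_bank(), 2000, seed = 41)
  fit <- fit_one_factor_cfa(d)
  expect_gte(fit$cfi, 0.99)
  expect_lte(fit$rmsea, 0.02)
  expect_equal(fit$df, 17 * 18 / 2 - 34)
  expect_true(all(fit$loadings > 0.3))
  ## loadings agree with the standard ML factor-analysis routine
  fa <- stats::factanal(covmat = cov(d$values), factors = 1, n.obs = 2000)
  expect_equal(unname(fit$loadings), unname(as.numeric(fa$loadings)),
               tolerance = 0.01)
})

test_that("CFA separates independent and two-factor data", {
  set.seed(55)
  ind <- matrix(sample(0:3, 9 * 2000, replace = TRUE), 2000, 9)
  fit <- fit_one_factor_cfa(ind)
  ## ML can park the factor on a single noise variable, but all the others
  ## must carry (near-)zero loadings and the model must fit like the null
  expect_lt(sort(abs(fit$loadings), decreasing = TRUE)[2], 0.1)
  expect_lt(fit$chi_square / fit$df, 1.5)
  expect_gte(fit$cfi, 0.99)

  ## two separated item blocks
  set.seed(56)
  f1 <- rnorm(2000); f2 <- rnorm(2000)
  blocks <- cbind(sapply(1:5, function(i) f1 + rnorm(2000, sd = 0.6)),
                  sapply(1:5, function(i) f2 + rnorm(2000, sd = 0.6)))
  x <- apply(blocks, 2, function(c_) findInterval(c_, c(-1, 0, 1)))
  fit2 <- fit_one_factor_cfa(x)
  expect_gt(fit2$rmsea, 0.05)
})

test_that("Loevinger coefficients match the comonotone-coupling oracle", {
  ## perfect Guttman data: every coefficient is 1
  g <- cbind(c(0, 0, 1, 1, 2, 3), c(0, 1, 1, 2, 3, 3), c(0, 0, 0, 1, 2, 3))
  mk <- mokken_scalability(g)
  expect_true(all(abs(mk$pair_H[upper.tri(mk$pair_H)] - 1) < 1e-12))
  expect_equal(unname(mk$item_H), rep(1, 3))
  expect_equal(mk$scale_H, 1)

  ## 3-item worked table against the independent Hoeffding oracle
  w <- cbind(q1 = c(0, 1, 1, 2, 3, 0), q2 = c(1, 0, 2, 2, 3, 1),
             q3 = c(0, 0, 1, 3, 2, 1))
  mk2 <- mokken_scalability(w)
  for (i in 1:2) for (j in (i + 1):3) {
    hij <- cov(w[, i], w[, j]) / oracle_cov_max(w[, i], w[, j])
    expect_equal(mk2$pair_H[i, j], hij)
  }

  ## independent items: scale H near zero
  set.seed(9)
  ind <- matrix(sample(0:3, 5 * 5000, replace = TRUE), 5000, 5)
  expect_lt(abs(mokken_scalability(ind)$scale_H), 0.03)
})

test_that("pairwise H values are unaffected by removing another item", {
  d <- make_grm_data(cesd_bank(), 400, seed = 61)
  full <- mokken_scalability(d)
  reduced <- mokken_scalability(d$values[, -17])
  expect_equal(reduced$pair_H[1:16, 1:16], full$pair_H[1:16, 1:16])
})

test_that("iterative removal strips only unscalable items", {
  d <- make_grm_data(cesd_bank(), 1500, seed = 71)
  res <- mokken_item_selection(d)
  expect_length(res$removed_items, 0)
  expect_gt(res$scale_H, 0.30)

  des <- simulation_design(cesd_bank(), n_persons = 2000,
                           off_dimension_items = c(q5 = 0.9, q7 = 0.9, q10 = 0.9),
                           seed = 83)
  sel <- mokken_item_selection(make_study_dataset(des))
  expect_setequal(sel$removed_items, c("q5", "q7", "q10"))
  expect_gt(sel$scale_H, 0.30)
  expect_true(all(sel$item_H >= 0.30))
})
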