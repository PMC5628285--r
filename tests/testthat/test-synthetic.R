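test_that("theta draws have the declared distribution and are reproducible", {
  th <- draw_thetas(1e5, seed = 3)
  expect_lt(abs(mean(th)), 0.02)
  expect_lt(abs(sd(th) - 1), 0.02)
  expect_identical(draw_thetas(50, seed = 11), draw_thetas(50, seed = 11))
  expect_error(draw_thetas(10, sd = 0))

  ## decile means of a standard-normal sample match the integral oracle
  th <- draw_thetas(1042, seed = 5)
  d <- ceiling(rank(th, ties.method = "first") / length(th) * 10)
  dm <- tapply(th, d, mean)
  expect_true(all(abs(dm - oracle_decile_means()) < 0.1))
})

test_that("simulated responses follow the model category distribution", {
  b <- tiny_bank()
  d <- simulate_grm_responses(b, rep(0, 1e5), seed = 4)
  freq <- tabulate(d$values + 1L, 4) / 1e5
  expect_equal(freq, c(0.2689, 0.2311, 0.2311, 0.2689), tolerance = 0.01)

  dd <- simulate_grm_responses(cesd_bank(), rep(-10, 50), seed = 1)
  expect_true(mean(dd$values == 0L) > 0.999)

  expect_identical(simulate_grm_responses(b, rep(0.3, 20), seed = 8)$values,
                   simulate_grm_responses(b, rep(0.3, 20), seed = 8)$values)
})

test_that("refitting simulated data recovers the generating slopes", {
  d <- make_grm_data(cesd_bank(), 2000, seed = 21)
  f <- suppressWarnings(fit_grm(d))
  expect_gt(cor(f$bank$a, cesd_bank()$a), 0.95)
})

test_that("a null design reproduces plain model draws from the same stream", {
  b <- cesd_bank()
  des <- simulation_design(b, n_persons = 100, seed = 77)
  d1 <- make_study_dataset(des)
  set.seed(77)
  th <- draw_thetas(100, seed = NULL)
  d2 <- simulate_grm_responses(b, th, seed = NULL)
  expect_identical(d1$values, d2$values)
  expect_identical(attr(d1, "thetas"), th)
})

test_that("designs validate their injection references", {
  b <- cesd_bank()
  expect_error(simulation_design(b, off_dimension_items = c(zz = 0.9)),
               "absent from bank")
  expect_error(simulation_design(b, dif_items = list(
    list(item = "q1", group = "nope", delta = 0.3))))
  expect_error(simulation_design(b, group_fractions = c(a = 0.5, b = 0.2)))
})

test_that("injected local dependence raises that pair's residual correlation", {
  b <- cesd_bank()
  des <- simulation_design(b, n_persons = 2000, dependent_pairs = list(
    list(items = c("q12", "q16"), rho = 0.5)), seed = 13)
  d <- make_study_dataset(des)
  q <- yen_q3(d, b)
  expect_gt(q$q3_matrix["q12", "q16"], 0.20)
  ## and it is the top flagged pair
  expect_setequal(unlist(q$flagged_pairs[1, 1:2]), c("q12", "q16"))
})

test_that("off-dimension items scale poorly with the rest", {
  b <- cesd_bank()
  des <- simulation_design(b, n_persons = 2000,
                           off_dimension_items = c(q5 = 0.9, q7 = 0.9, q10 = 0.9),
                           seed = 29)
  d <- make_study_dataset(des)
  mk <- mokken_scalability(d)
  expect_true(all(mk$item_H[c("q5", "q7", "q10")] < 0.30))
  expect_true(all(mk$item_H[setdiff(names(mk$item_H), c("q5", "q7", "q10"))] >
                    0.30))
})
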