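test_that("maximum-information selection matches the exhaustive oracle", {
  b <- cesd_bank()
  expect_equal(select_next_item(b, character(0), 0), "q6")  # steepest item

  set.seed(201)
  for (rep in 1:200) {
    th <- runif(1, -3.5, 3.5)
    admin <- sample(b$item_id, sample(0:15, 1))
    rem <- setdiff(b$item_id, admin)
    infos <- vapply(rem, function(id)
      item_information(bank_subset(b, id), th), numeric(1))
    expect_identical(select_next_item(b, admin, th), rem[which.max(infos)])
  }

  ## forced choice and deterministic tie-break
  expect_identical(select_next_item(b, b$item_id[-4], 1), b$item_id[4])
  twins <- item_bank(c("t1", "t2"), c(2, 2), rbind(c(-1, 0, 1), c(-1, 0, 1)))
  expect_identical(select_next_item(twins, character(0), 0.5), "t1")
  expect_error(select_next_item(b, b$item_id, 0), "exhausted")
})

test_that("interim estimation switches between MAP and ML on pattern mixing", {
  b <- cesd_bank()
  cfg <- cat_config()
  e1 <- update_estimate(b, "q6", 0L, cfg)
  expect_identical(e1$method, "MAP")
  e2 <- update_estimate(b, c("q6", "q3"), c(0L, 3L), cfg)
  expect_identical(e2$method, "ML")
  expect_lt(abs(e2$theta - oracle_ml_grid(b, c("q6", "q3"), c(0L, 3L))), 1e-3)
})

test_that("stopping rules terminate the test as configured", {
  b <- cesd_bank()
  set.seed(211)
  r1 <- run_cat(b, responder_grm(b, 0.4), cat_config(se_stop = Inf))
  expect_equal(r1$n_items, 1L)
  expect_identical(r1$stop_reason, "se_met")

  r2 <- run_cat(b, responder_grm(b, 0.4), cat_config(se_stop = 1e-9))
  expect_equal(r2$n_items, 17L)
  expect_identical(r2$stop_reason, "bank_exhausted")
  expect_identical(sort(r2$administered), sort(b$item_id))

  r3 <- run_cat(b, responder_grm(b, -0.2), cat_config())
  expect_false(anyDuplicated(r3$administered) > 0)
  expect_length(r3$trajectory, r3$n_items)
  expect_length(r3$responses, r3$n_items)
})

test_that("cumulative information grows so fixed-theta interim SE shrinks", {
  b <- cesd_bank()
  for (th in c(-2, 0, 1.5)) {
    admin <- character(0)
    info <- numeric(0)
    for (k in 1:10) {
      admin <- c(admin, select_next_item(b, admin, th))
      info <- c(info, sum(item_information(b, th, items = admin)))
    }
    expect_true(all(diff(info) > 0))
    expect_true(all(diff(1 / sqrt(info)) < 0))
  }
})

test_that("post-hoc runs pick a subset and track the full-vector score", {
  b <- cesd_bank()
  set.seed(221)
  th <- rnorm(60)
  d <- simulate_grm_responses(b, th)
  full <- cat_hat <- numeric(60)
  for (p in 1:60) {
    resp <- d$values[p, ]
    full[p] <- if (all(resp == 0) || all(resp == 3))
      score_map(b, resp)$theta else score_ml(b, resp)$theta
    r <- run_cat(b, responder_fixed(resp))
    expect_true(all(r$administered %in% b$item_id))
    expect_equal(r$responses,
                 unname(resp[r$administered]))
    cat_hat[p] <- r$final$theta
  }
  expect_gt(cor(cat_hat, full), 0.95)
})

test_that("invalid responder output is rejected", {
  b <- cesd_bank()
  expect_error(run_cat(b, function(id) 9L), "invalid category")
})
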