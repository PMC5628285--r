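test_that("exchangeable groups produce zero beta change and no flags", {
  b <- cesd_bank()
  d0 <- make_grm_data(b, 400, seed = 161)
  ## duplicate the data into two identical "groups"
  x <- rbind(d0$values, d0$values)
  d <- response_matrix(x, item_ids = d0$item_ids,
                       groups = data.frame(group = rep(c("a", "b"),
                                                       each = nrow(d0$values))))
  r <- detect_dif(d, "group", bank = b)
  expect_true(all(r$items$beta_change < 1e-5))
  expect_true(all(r$items$lr_chi2_total < 1e-5))
  expect_false(any(r$items$flagged))
})

test_that("likelihood-ratio statistics are coherent and label invariant", {
  b <- cesd_bank()
  des <- simulation_design(b, n_persons = 600, dif_items = list(
    list(item = "q9", group = "female", delta = 0.4)), seed = 171)
  d <- make_study_dataset(des)
  r1 <- detect_dif(d, "group", bank = b)
  expect_true(all(r1$items$lr_chi2_uniform >= 0, na.rm = TRUE))
  expect_true(all(r1$items$lr_chi2_total + 1e-8 >=
                    r1$items$lr_chi2_uniform, na.rm = TRUE))
  expect_true(all(r1$items$pseudo_r2_change > -1e-10, na.rm = TRUE))

  flipped <- ifelse(d$groups$group == "female", "male", "female")
  r2 <- detect_dif(d, flipped, bank = b)
  expect_lt(max(abs(r1$items$lr_chi2_total - r2$items$lr_chi2_total),
                na.rm = TRUE), 1e-4)
  expect_lt(max(abs(r1$items$beta_change - r2$items$beta_change),
                na.rm = TRUE), 1e-4)
})

test_that("injected uniform DIF is flagged on the right item", {
  b <- cesd_bank()
  des <- simulation_design(b, n_persons = 2000, dif_items = list(
    list(item = "q14", group = "female", delta = 0.5)), seed = 181)
  d <- make_study_dataset(des)
  r <- detect_dif(d, "group", bank = b)
  row <- r$items[r$items$item_id == "q14", ]
  expect_true(row$flagged)
  expect_lt(row$p_uniform, 0.001)
  ## the DIF item has by far the largest beta change
  expect_equal(r$items$item_id[which.max(r$items$beta_change)], "q14")
})

test_that("DIF-adjusted rescoring is the identity without flags and robust with them", {
  b <- cesd_bank()
  des <- simulation_design(b, n_persons = 800, dif_items = list(
    list(item = "q14", group = "female", delta = 0.3)), seed = 191)
  d <- make_study_dataset(des)

  none <- suppressWarnings(dif_adjusted_scores(d, "group", character(0)))
  expect_identical(none$original, none$adjusted)
  expect_equal(none$pearson_r, 1)
  expect_equal(none$t_statistic, 0)

  adj <- suppressWarnings(dif_adjusted_scores(d, "group", "q14"))
  expect_length(adj$adjusted, nrow(d$values))
  expect_true(all(is.finite(adj$adjusted)))
  ## one mildly biased item among 17 barely moves the scores
  expect_gt(adj$pearson_r, 0.98)
  expect_gt(adj$p_value, 0.01)
})
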