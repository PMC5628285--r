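## Decile-stratified simulation studies of the adaptive test: simulated
## respondents at known trait values (study I) and post-hoc runs over fixed
## full response vectors (study II).

.decile_of <- function(ref) ceiling(rank(ref, ties.method = "first") /
                                      length(ref) * 10)

.decile_table <- function(ref, est, len, se) {
  d <- .decile_of(ref)
  per <- lapply(1:10, function(k) {
    s <- d == k
    err <- est[s] - ref[s]
    data.frame(decile = k, mean_theta = mean(ref[s]),
               rmse = sqrt(mean(err^2)), mean_bias = mean(err),
               mean_test_length = mean(len[s]), mean_se = mean(se[s]),
               n_simulees = sum(s))
  })
  do.call(rbind, per)
}

#' Adaptive-test simulation over simulated respondents
#'
#' Draws `n` true trait values from the standard normal, simulates each
#' respondent's answers from the graded response model item by item, and runs
#' the adaptive test against them.  Respondents are sorted into deciles of
#' true theta; per decile the table reports mean true theta, RMSE and mean
#' bias of the final estimates, mean test length and mean (final) standard
#' error.
#'
#' @param bank an `item_bank`.
#' @param n number of simulees (default 1042).
#' @param config a [cat_config()].
#' @param seed integer seed.
#' @return an object of class `decile_summary`: list with `table` (10 rows),
#'   `overall` (mean/sd of test length, mean of decile RMSEs, mean of decile
#'   biases, overall mean bias and mean SE), and per-simulee vectors
#'   `theta_true`, `theta_hat`, `test_length`, `se`.
#' @export
simulation_one <- function(bank, n = 1042L, config = cat_config(), seed = 1L) {
  .bank_check(bank)
  stopifnot(n >= 10L)
  set.seed(seed)
  thetas <- stats::rnorm(n)
  ## per-person substreams so results do not depend on evaluation order
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  est <- len <- se <- numeric(n)
  for (p in seq_len(n)) {
    set.seed(seeds[p])
    r <- run_cat(bank, responder_grm(bank, thetas[p]), config)
    est[p] <- r$final$theta; len[p] <- r$n_items; se[p] <- r$final$se
  }
  tab <- .decile_table(thetas, est, len, se)
  overall <- list(mean_test_length = mean(len), sd_test_length = stats::sd(len),
                  mean_rmse = mean(tab$rmse), mean_bias_by_decile = mean(tab$mean_bias),
                  mean_bias = mean(est - thetas), mean_se = mean(se))
  structure(list(table = tab, overall = overall, theta_true = thetas,
                 theta_hat = est, test_length = len, se = se),
            class = "decile_summary")
}

#' Post-hoc adaptive-test simulation on fixed response data
#'
#' Uses each person's recorded full response vector: the full-bank trait
#' estimate (maximum likelihood, Bayesian modal fallback for non-mixed
#' patterns) is the reference score; the adaptive test is then replayed
#' against the fixed responses.  Deciles are assigned by reference score, and
#' RMSE/bias are of the adaptive estimate against the reference score.
#'
#' @param bank an `item_bank` covering all items in `data`.
#' @param data a `response_matrix` of complete responses to the whole bank.
#' @param config a [cat_config()].
#' @return a `decile_summary`; `overall$score_correlation` is the Pearson
#'   correlation between adaptive and reference scores.
#' @export
simulation_two <- function(bank, data, config = cat_config()) {
  .bank_check(bank)
  stopifnot(inherits(data, "response_matrix"))
  if (!all(bank$item_id %in% data$item_ids))
    stop("data must cover all bank items", call. = FALSE)
  x <- data$values[, bank$item_id, drop = FALSE]
  n <- nrow(x)
  m <- n_categories(bank)
  mixed <- .is_mixed(x, m)
  ref <- numeric(n)
  if (any(mixed)) {
    fitm <- .newton_theta(bank, x[mixed, , drop = FALSE],
                          bounds = config$theta_bounds)
    ref[mixed] <- fitm$theta
  }
  if (any(!mixed))
    ref[!mixed] <- .map_thetas(bank, x[!mixed, , drop = FALSE],
                               config$prior_mean, config$prior_sd,
                               config$theta_bounds)$theta
  est <- len <- se <- numeric(n)
  for (p in seq_len(n)) {
    r <- run_cat(bank, responder_fixed(x[p, ]), config)
    est[p] <- r$final$theta; len[p] <- r$n_items; se[p] <- r$final$se
  }
  tab <- .decile_table(ref, est, len, se)
  overall <- list(mean_test_length = mean(len), sd_test_length = stats::sd(len),
                  mean_rmse = mean(tab$rmse), mean_bias_by_decile = mean(tab$mean_bias),
                  mean_bias = mean(est - ref), mean_se = mean(se),
                  score_correlation = stats::cor(est, ref))
  structure(list(table = tab, overall = overall, theta_true = ref,
                 theta_hat = est, test_length = len, se = se),
            class = "decile_summary")
}

#' @export
print.decile_summary <- function(x, ...) {
  cat("Adaptive-test simulation, decile summary:\n")
  print(x$table, digits = 3, row.names = FALSE)
  ov <- x$overall
  cat(sprintf("overall: mean length %.2f (SD %.2f), mean decile RMSE %.3f, mean bias %.4f\n",
              ov$mean_test_length, ov$sd_test_length, ov$mean_rmse,
              ov$mean_bias))
  if (!is.null(ov$score_correlation))
    cat(sprintf("correlation with full-bank score: r = %.3f\n",
                ov$score_correlation))
  invisible(x)
}

#' Test length against trait level
#'
#' Scatter of administered test length against the (reference) trait value,
#' with decile means overlaid; the summary table is written alongside the
#' image.  The characteristic profile is U-shaped: respondents in the tails
#' need more items to reach the precision target.
#'
#' @param results a `decile_summary`, or a list of `cat_result` plus
#'   `reference_thetas`.
#' @param reference_thetas trait values matching `results` when `results` is a
#'   list of `cat_result`.
#' @param file image path (`.png`); `NULL` suppresses the image.
#' @param table_file table path; defaults to the image path with `.csv`.
#' @return the per-person data frame (`theta`, `test_length`), invisibly.
#' @export
length_by_theta_plot <- function(results, reference_thetas = NULL,
                                 file = NULL, table_file = NULL) {
  if (inherits(results, "decile_summary")) {
    df <- data.frame(theta = results$theta_true,
                     test_length = results$test_length)
  } else {
    stopifnot(length(results) >= 1L,
              length(reference_thetas) == length(results))
    df <- data.frame(theta = reference_thetas,
                     test_length = vapply(results, `[[`, numeric(1L),
                                          "n_items"))
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off())
    plot(df$theta, df$test_length, pch = 16,
         col = grDevices::adjustcolor("steelblue", 0.5),
         xlab = expression(theta), ylab = "items administered",
         main = "Test length by trait level")
    if (nrow(df) >= 10L) {
      d <- .decile_of(df$theta)
      mt <- tapply(df$theta, d, mean)
      ml <- tapply(df$test_length, d, mean)
      graphics::lines(mt, ml, lwd = 2, col = "firebrick")
      graphics::points(mt, ml, pch = 15, col = "firebrick")
    }
    if (is.null(table_file)) table_file <- sub("\\.[a-z]+$", ".csv", file)
  }
  if (!is.null(table_file))
    utils::write.table(df, table_file, sep = ",", row.names = FALSE,
                       quote = FALSE)
  invisible(df)
}
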