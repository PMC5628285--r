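## The adaptive test proper: maximum-Fisher-information item selection,
## interim Bayesian-modal scoring with a standard-error stopping rule, and a
## final maximum-likelihood estimate.

#' Adaptive-test configuration
#'
#' @param se_stop standard-error stopping threshold (default 0.32, which
#'   corresponds to reliability of about 0.90 via `1 - SE^2`).
#' @param max_items cap on administered items (default `NULL` = bank size).
#' @param prior_mean,prior_sd normal prior for Bayesian interim scoring.
#' @param theta_bounds estimation interval.
#' @param interim interim estimator driving selection and stopping:
#'   `"map"` (default) uses Bayesian modal estimates with their
#'   posterior-precision SE throughout, the convention under which the
#'   published decile test lengths are reproducible; `"ml_mixed"` switches to
#'   maximum likelihood (and its Fisher SE) as soon as the response pattern is
#'   mixed.  The final estimate is maximum likelihood either way.
#' @return an object of class `cat_config`.
#' @export
cat_config <- function(se_stop = 0.32, max_items = NULL, prior_mean = 0,
                       prior_sd = 1, theta_bounds = c(-4, 4),
                       interim = c("map", "ml_mixed")) {
  stopifnot(se_stop > 0, is.null(max_items) || max_items >= 1)
  structure(list(se_stop = se_stop, max_items = max_items,
                 prior_mean = prior_mean, prior_sd = prior_sd,
                 theta_bounds = theta_bounds,
                 interim = match.arg(interim)),
            class = "cat_config")
}

#' Select the next item by maximum Fisher information
#'
#' Returns the unadministered item whose Samejima information at the current
#' trait estimate is largest; ties break toward the lowest bank index.
#'
#' @param bank an `item_bank`.
#' @param administered item labels already used (may be empty).
#' @param theta current trait estimate.
#' @return the selected `item_id`.
#' @export
select_next_item <- function(bank, administered, theta) {
  .bank_check(bank)
  remaining <- setdiff(bank$item_id, administered)
  if (length(remaining) == 0L) stop("item bank exhausted", call. = FALSE)
  info <- item_information(bank, theta, items = remaining)
  remaining[which.max(info)]   # which.max takes the first maximum: low index
}

#' Interim trait estimate during an adaptive test
#'
#' Maximum likelihood when the response pattern is mixed (not all responses in
#' the floor category and not all in the ceiling category -- exactly the
#' condition under which the graded-model ML estimate is finite); Bayesian
#' modal with the configured prior otherwise.
#'
#' @param bank an `item_bank`.
#' @param administered item labels administered so far.
#' @param responses matching integer categories.
#' @param config a [cat_config()].
#' @return a `theta_estimate` (`method` is `"ML"` or `"MAP"`).
#' @export
update_estimate <- function(bank, administered, responses,
                            config = cat_config()) {
  stopifnot(length(administered) == length(responses),
            length(responses) >= 1L)
  if (.is_mixed(matrix(as.integer(responses), 1L), n_categories(bank)))
    score_ml(bank, responses, items = administered,
             bounds = config$theta_bounds)
  else
    score_map(bank, responses, items = administered,
              prior_mean = config$prior_mean, prior_sd = config$prior_sd,
              bounds = config$theta_bounds)
}

#' Responders for adaptive-test runs
#'
#' `responder_grm` answers by sampling the graded-response category
#' distribution at a fixed true theta; `responder_fixed` answers by looking
#' the item up in a complete response vector (post-hoc simulation on recorded
#' data).
#'
#' @param bank an `item_bank`.
#' @param theta true latent-trait value of the simulated respondent.
#' @return a function `f(item_id) -> category`.
#' @export
responder_grm <- function(bank, theta) {
  .bank_check(bank)
  force(theta)
  function(item_id) {
    pr <- category_probs(bank_subset(bank, item_id), theta)
    sample.int(length(pr), 1L, prob = pr) - 1L
  }
}

#' @rdname responder_grm
#' @param responses named complete response vector (names are item ids).
#' @export
responder_fixed <- function(responses) {
  stopifnot(!is.null(names(responses)))
  responses <- vapply(responses, as.integer, integer(1L))
  function(item_id) responses[[item_id]]
}

#' Run one adaptive test
#'
#' Starting from the prior mean, repeats select - administer - re-estimate
#' until the interim standard error reaches `config$se_stop` (checked after
#' each response) or the bank (or `max_items`) is exhausted.  The final
#' estimate is recomputed by maximum likelihood (Bayesian modal fallback for
#' all-floor/all-ceiling patterns).
#'
#' @param bank an `item_bank`.
#' @param responder a function `f(item_id) -> category`, e.g.
#'   [responder_grm()] or [responder_fixed()].
#' @param config a [cat_config()].
#' @return an object of class `cat_result`: list with `administered`,
#'   `responses`, `trajectory` (interim `theta_estimate`s), `final`
#'   (`theta_estimate`), `n_items`, `stop_reason` (`"se_met"` or
#'   `"bank_exhausted"`).
#' @examples
#' bank <- cesd_bank()
#' set.seed(7)
#' run_cat(bank, responder_grm(bank, theta = 1.2))
#' @export
run_cat <- function(bank, responder, config = cat_config()) {
  .bank_check(bank)
  m <- n_categories(bank)
  cap <- min(if (is.null(config$max_items)) nrow(bank) else config$max_items,
             nrow(bank))
  administered <- character(0)
  responses <- integer(0)
  trajectory <- list()
  theta <- config$prior_mean
  stop_reason <- "bank_exhausted"
  repeat {
    item <- select_next_item(bank, administered, theta)
    x <- responder(item)
    if (is.null(x) || is.na(x) || x < 0L || x >= m)
      stop(sprintf("responder returned invalid category for item %s", item),
           call. = FALSE)
    administered <- c(administered, item)
    responses <- c(responses, as.integer(x))
    est <- .interim_estimate(bank, administered, responses, config)
    trajectory[[length(trajectory) + 1L]] <- est
    theta <- est$theta
    if (est$se <= config$se_stop) { stop_reason <- "se_met"; break }
    if (length(administered) >= cap) break
  }
  final <- if (.is_mixed(matrix(responses, 1L), m))
    score_ml(bank, responses, items = administered,
             bounds = config$theta_bounds)
  else
    score_map(bank, responses, items = administered,
              prior_mean = config$prior_mean, prior_sd = config$prior_sd,
              bounds = config$theta_bounds)
  structure(list(administered = administered, responses = responses,
                 trajectory = trajectory, final = final,
                 n_items = length(administered), stop_reason = stop_reason),
            class = "cat_result")
}

.interim_estimate <- function(bank, administered, responses, config) {
  if (config$interim == "map")
    score_map(bank, responses, items = administered,
              prior_mean = config$prior_mean, prior_sd = config$prior_sd,
              bounds = config$theta_bounds)
  else
    update_estimate(bank, administered, responses, config)
}

#' @export
print.cat_result <- function(x, ...) {
  cat(sprintf("CAT: %d items (%s), final ", x$n_items, x$stop_reason))
  print(x$final)
  cat("  sequence:", paste(x$administered, collapse = " "), "\n")
  invisible(x)
}
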