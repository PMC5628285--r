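## Samejima graded response model: probabilities, information, scoring.
## Logistic metric throughout -- P*_k(theta) = 1 / (1 + exp(-a (theta - b_k))),
## no 1.702 scaling constant.  The 1.702 conversion appears only in the
## slope-to-loading transform.

## Cumulative boundary probabilities P*_k for one bank at a vector of thetas.
## Returns an array [n_theta, n_item, m+1] with P*_0 = 1 and P*_m = 0.
.pstar <- function(bank, theta) {
  a <- bank$a
  b <- .bank_b(bank)
  b[is.na(b)] <- Inf            # absent upper categories get probability 0
  nt <- length(theta); ni <- nrow(bank); mk <- ncol(b)
  out <- array(0, dim = c(nt, ni, mk + 2L))
  out[, , 1L] <- 1
  for (k in seq_len(mk)) {
    z <- outer(theta, a) * 1 - rep(a * b[, k], each = nt)
    ## z = a * (theta - b_k), computed as theta*a - a*b_k
    out[, , k + 1L] <- stats::plogis(z)
  }
  out
}

#' Category response probabilities under the graded response model
#'
#' Computes `P_k(theta) = P*_k(theta) - P*_{k+1}(theta)` where
#' `P*_k(theta) = 1 / (1 + exp(-a (theta - b_k)))`, with `P*_0 = 1` and
#' `P*_m = 0`.
#'
#' @param bank an `item_bank` (use [bank_subset()] for a single item).
#' @param theta latent-trait value(s).
#' @return an array `[length(theta), n_items, m]` of category probabilities;
#'   dropped to a matrix `[n_items, m]` when `theta` is scalar.
#' @examples
#' b <- item_bank("x", 1, matrix(c(-1, 0, 1), 1))
#' category_probs(b, 0)  # (0.2689, 0.2311, 0.2311, 0.2689)
#' @export
category_probs <- function(bank, theta) {
  .bank_check(bank)
  ps <- .pstar(bank, theta)
  m <- dim(ps)[3L] - 1L
  pr <- ps[, , 1:m, drop = FALSE] - ps[, , 2:(m + 1L), drop = FALSE]
  if (length(theta) == 1L) {
    pr <- array(pr, dim = dim(pr)[2:3])
    dimnames(pr) <- list(bank$item_id, paste0("p", 0:(m - 1L)))
  }
  pr
}

## Item information for every item at every theta: matrix [n_theta, n_item].
## Samejima: I_i(theta) = sum_k (P*'_k - P*'_{k+1})^2 / P_k,
## with P*'_k = a P*_k (1 - P*_k).
.item_info_matrix <- function(bank, theta) {
  ps <- .pstar(bank, theta)
  a <- bank$a
  nt <- length(theta); ni <- nrow(bank); m <- dim(ps)[3L] - 1L
  d <- ps * (1 - ps)
  d <- sweep(d, 2L, a, `*`)
  P <- ps[, , 1:m, drop = FALSE] - ps[, , 2:(m + 1L), drop = FALSE]
  dd <- d[, , 1:m, drop = FALSE] - d[, , 2:(m + 1L), drop = FALSE]
  matrix(rowSums(dd^2 / pmax(P, 1e-300), dims = 2L), nt, ni)
}

#' Fisher information of a single item
#'
#' @param bank an `item_bank`.
#' @param theta latent-trait value(s).
#' @param items optional item labels/indices; default all.
#' @return matrix `[length(theta), n_items]` of item informations (dropped to
#'   a vector when only one of the two dimensions is > 1).
#' @export
item_information <- function(bank, theta, items = NULL) {
  .bank_check(bank)
  if (!is.null(items)) bank <- bank_subset(bank, items)
  out <- .item_info_matrix(bank, theta)
  colnames(out) <- bank$item_id
  drop(out)
}

#' Test information and its standard-error curve
#'
#' Test information is the sum of item informations; the conditional standard
#' error of measurement is `SE(theta) = 1 / sqrt(I(theta))`.
#'
#' @param bank an `item_bank`.
#' @param theta latent-trait value(s).
#' @return numeric vector of test information values.
#' @examples
#' test_information(cesd_bank(), c(-2, 0, 2))
#' @export
test_information <- function(bank, theta) {
  .bank_check(bank)
  rowSums(.item_info_matrix(bank, theta))
}

#' @rdname test_information
#' @param grid theta grid for the curve (default `seq(-4, 4, 0.01)`).
#' @return for `info_curve`, a data frame with columns `theta`, `info`, `se`
#'   (`se` is `NA` where information is zero).
#' @export
info_curve <- function(bank, grid = seq(-4, 4, by = 0.01)) {
  info <- test_information(bank, grid)
  se <- ifelse(info > 0, 1 / sqrt(info), NA_real_)
  data.frame(theta = grid, info = info, se = se)
}

## ---- scoring ----------------------------------------------------------------

.theta_estimate <- function(theta, se, method, converged) {
  structure(list(theta = theta, se = se, method = method,
                 converged = converged), class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("theta = %.4f (SE %.4f), method %s%s\n", x$theta, x$se,
              x$method, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

## Gradient of the log-likelihood and Fisher information at theta, for one
## response vector on a (sub)bank.  Vectorized over a theta vector paired with
## a response matrix (one row per theta) when `resp` is a matrix.
.grm_score_info <- function(bank, resp, theta) {
  resp <- rbind(resp)
  nt <- length(theta)
  stopifnot(nrow(resp) == nt, ncol(resp) == nrow(bank))
  ps <- .pstar(bank, theta)
  a <- bank$a
  m <- dim(ps)[3L] - 1L
  d <- sweep(ps * (1 - ps), 2L, a, `*`)
  P <- ps[, , 1:m, drop = FALSE] - ps[, , 2:(m + 1L), drop = FALSE]
  dd <- d[, , 1:m, drop = FALSE] - d[, , 2:(m + 1L), drop = FALSE]
  info <- rowSums(matrix(rowSums(dd^2 / pmax(P, 1e-300), dims = 2L),
                         nt, nrow(bank)))
  ## pick the observed category per (person, item)
  ni <- nrow(bank)
  idx <- cbind(rep(seq_len(nt), ni), rep(seq_len(ni), each = nt),
               as.vector(resp) + 1L)
  g <- rowSums(matrix(dd[idx] / pmax(P[idx], 1e-300), nt, ni))
  list(grad = g, info = info)
}

## Safeguarded Newton ascent of loglik (+ optional normal log-prior), vectorized
## over persons.  resp: matrix persons x items on `bank`.
.newton_theta <- function(bank, resp, prior_prec = 0, prior_mean = 0,
                          bounds = c(-4, 4), tol = 1e-7, max_iter = 100L) {
  resp <- rbind(resp)
  n <- nrow(resp)
  th <- rep(prior_mean, n)
  for (i in seq_len(max_iter)) {
    si <- .grm_score_info(bank, resp, th)
    g <- si$grad - prior_prec * (th - prior_mean)
    H <- si$info + prior_prec
    step <- g / pmax(H, 1e-10)
    step <- pmin(pmax(step, -1), 1)      # damp long steps
    th_new <- pmin(pmax(th + step, bounds[1L]), bounds[2L])
    moved <- abs(th_new - th)
    th <- th_new
    if (max(moved) < tol) break
  }
  info <- .grm_score_info(bank, resp, th)$info
  list(theta = th, info = info)
}

.is_mixed <- function(resp, n_cat) {
  resp <- rbind(resp)
  !(apply(resp, 1L, function(r) all(r == 0L) || all(r == n_cat - 1L)))
}

#' Maximum-likelihood trait estimate
#'
#' Maximizes the graded-response log-likelihood of a (possibly partial)
#' response vector by safeguarded Newton iteration within `bounds`.
#' `SE = 1 / sqrt(I(theta_hat))` with `I` the Fisher information of the
#' administered items.  For a non-mixed pattern (all responses at the floor or
#' all at the ceiling) the likelihood is monotone, the estimate is clamped to
#' the corresponding bound and `converged` is `FALSE`.
#'
#' @param bank an `item_bank`.
#' @param responses integer categories `0..m-1`; either a named vector (names
#'   are item ids) or a vector aligned with `items`.
#' @param items item labels/indices the responses belong to; defaults to the
#'   names of `responses` or, unnamed, to the whole bank.
#' @param bounds estimation interval (default `c(-4, 4)`).
#' @return a `theta_estimate`.
#' @examples
#' b <- cesd_bank()
#' score_ml(b, c(q3 = 1, q6 = 2, q18 = 0))
#' @export
score_ml <- function(bank, responses, items = NULL, bounds = c(-4, 4)) {
  sb <- .score_prep(bank, responses, items)
  m <- n_categories(bank)
  if (!.is_mixed(sb$resp, m)) {
    th <- if (all(sb$resp == 0L)) bounds[1L] else bounds[2L]
    info <- .grm_score_info(sb$bank, sb$resp, th)$info
    return(.theta_estimate(th, 1 / sqrt(max(info, 1e-12)), "ML", FALSE))
  }
  fit <- .newton_theta(sb$bank, sb$resp, prior_prec = 0, bounds = bounds)
  .theta_estimate(fit$theta, 1 / sqrt(max(fit$info, 1e-12)), "ML",
                  fit$theta > bounds[1L] && fit$theta < bounds[2L])
}

#' Bayesian modal (MAP) trait estimate
#'
#' Maximizes log-likelihood plus a normal log-prior.  With no responses the
#' prior mode is returned.  `SE = 1 / sqrt(I(theta_hat) + 1 / prior_sd^2)`,
#' i.e. the posterior precision includes the prior.
#'
#' @inheritParams score_ml
#' @param prior_mean,prior_sd normal prior parameters (default standard
#'   normal, the latent density assumed in calibration).
#' @return a `theta_estimate`.
#' @export
score_map <- function(bank, responses, items = NULL, prior_mean = 0,
                      prior_sd = 1, bounds = c(-4, 4)) {
  if (length(responses) == 0L)
    return(.theta_estimate(prior_mean, prior_sd, "MAP", TRUE))
  sb <- .score_prep(bank, responses, items)
  prec <- 1 / prior_sd^2
  fit <- .newton_theta(sb$bank, sb$resp, prior_prec = prec,
                       prior_mean = prior_mean, bounds = bounds)
  .theta_estimate(fit$theta, 1 / sqrt(fit$info + prec), "MAP", TRUE)
}

.score_prep <- function(bank, responses, items) {
  .bank_check(bank)
  if (is.null(items)) {
    items <- if (!is.null(names(responses))) names(responses) else bank$item_id
  }
  if (length(responses) != length(items))
    stop("responses and items length mismatch", call. = FALSE)
  sb <- bank_subset(bank, items)
  resp <- matrix(as.integer(responses), nrow = 1L)
  m <- n_categories(bank)
  if (anyNA(resp) || any(resp < 0L) || any(resp >= m))
    stop("responses must be categories 0..m-1", call. = FALSE)
  list(bank = sb, resp = resp)
}

## Vectorized MAP scoring of a full response matrix (one theta per person);
## used by the Q3, item-fit and DIF stages.  Returns list(theta, se).
.map_thetas <- function(bank, values, prior_mean = 0, prior_sd = 1,
                        bounds = c(-4, 4)) {
  prec <- 1 / prior_sd^2
  fit <- .newton_theta(bank, values, prior_prec = prec,
                       prior_mean = prior_mean, bounds = bounds)
  list(theta = fit$theta, se = 1 / sqrt(fit$info + prec))
}
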