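## Model-adequacy diagnostics for a calibrated graded response model:
## Yen's Q3 residual correlations, testlet formation, stratified item fit.

#' Yen's Q3 local-dependence statistic
#'
#' Scores every person on the full response vector (Bayesian modal estimates,
#' so extreme responders stay finite), forms item residuals
#' `e_pi = x_pi - E[x_i | theta_p]` with
#' `E = sum_k k P_k(theta)`, and correlates residual columns.  Pairs with
#' `|Q3|` above the threshold indicate local dependence.
#'
#' @param data a `response_matrix`.
#' @param bank an `item_bank` covering all items in `data`.
#' @param threshold flagging threshold (default 0.20, the conventional cut).
#' @return an object of class `q3_result`: list with `q3_matrix`,
#'   `flagged_pairs` (data frame `item_i`, `item_j`, `q3`), `threshold`.
#' @export
yen_q3 <- function(data, bank, threshold = 0.20) {
  stopifnot(inherits(data, "response_matrix"))
  .bank_check(bank)
  if (!all(data$item_ids %in% bank$item_id))
    stop("bank does not cover all items in data", call. = FALSE)
  bank <- bank_subset(bank, data$item_ids)
  x <- data$values
  th <- .map_thetas(bank, x)$theta
  m <- n_categories(bank)
  pr <- category_probs(bank, th)                     # [n, items, m]
  Ex <- matrix(0, nrow(x), ncol(x))
  for (k in seq_len(m - 1L)) Ex <- Ex + k * pr[, , k + 1L]
  resid <- x - Ex
  v <- apply(resid, 2L, stats::var)
  if (any(v == 0)) stop("zero residual variance", call. = FALSE)
  q3 <- stats::cor(resid)
  diag(q3) <- NA_real_
  idx <- which(upper.tri(q3) & abs(q3) > threshold, arr.ind = TRUE)
  flagged <- data.frame(item_i = colnames(x)[idx[, 1L]],
                        item_j = colnames(x)[idx[, 2L]],
                        q3 = q3[idx])
  flagged <- flagged[order(-abs(flagged$q3)), , drop = FALSE]
  rownames(flagged) <- NULL
  structure(list(q3_matrix = q3, flagged_pairs = flagged,
                 threshold = threshold),
            class = "q3_result")
}

#' @export
print.q3_result <- function(x, ...) {
  cat(sprintf("Yen's Q3 (threshold %.2f): %d flagged pair(s)\n",
              x$threshold, nrow(x$flagged_pairs)))
  if (nrow(x$flagged_pairs)) print(x$flagged_pairs, digits = 3)
  invisible(x)
}

#' Collapse locally dependent items into a testlet
#'
#' Replaces the named items by a single summed polytomous super-item with
#' `sum(m_i - 1) + 1` categories, placed at the position of the first named
#' item.  A downstream refit treats the testlet as one graded item.
#'
#' @param data a `response_matrix`.
#' @param item_ids two or more distinct item labels to merge.
#' @param name label for the new super-item (default `tl_<first item>`).
#' @return a `response_matrix` with the merged column; note the testlet column
#'   has more categories than the others, so refit it with [fit_grm()] on the
#'   matrix values rather than mixing category counts.
#' @export
form_testlet <- function(data, item_ids, name = NULL) {
  stopifnot(inherits(data, "response_matrix"))
  item_ids <- as.character(item_ids)
  if (length(item_ids) < 2L || anyDuplicated(item_ids))
    stop("need at least 2 distinct items for a testlet", call. = FALSE)
  if (!all(item_ids %in% data$item_ids))
    stop("items not in matrix", call. = FALSE)
  if (is.null(name)) name <- paste0("tl_", item_ids[1L])
  pos <- match(item_ids, data$item_ids)
  keep <- setdiff(seq_along(data$item_ids), pos[-1L])
  x <- data$values
  x[, pos[1L]] <- as.integer(rowSums(x[, pos, drop = FALSE]))
  x <- x[, keep, drop = FALSE]
  ids <- data$item_ids[keep]
  ids[keep == pos[1L]] <- name
  colnames(x) <- ids
  n_cat <- (data$n_cat - 1L) * length(item_ids) + 1L
  out <- response_matrix(x, item_ids = ids, groups = data$groups,
                         coding_offset = data$coding_offset,
                         n_cat = max(n_cat, data$n_cat))
  attr(out, "testlet") <- stats::setNames(list(item_ids), name)
  out
}

#' Stratified chi-square item fit
#'
#' For each item, persons are stratified into `n_strata` groups by their
#' leave-one-out posterior mean trait (computed from the other items); within each stratum, observed category
#' counts are compared to model-expected counts by a Pearson chi-square.
#' Expected counts average the category probabilities over each person's
#' posterior trait distribution computed from the *other* items
#' (leave-one-out), so neither the noise in the point estimate nor the item's
#' own contribution distorts the reference distribution.
#' Cells with expected count below 5 are pooled into their lower-category
#' neighbour; strata with fewer than `min_per_stratum` persons are merged
#' (with a message).  Degrees of freedom are
#' `(used cells) - (strata) - (item parameter count)`, floored at 1.
#'
#' @param data a `response_matrix`.
#' @param fit a `grm_fit` (or an `item_bank`).
#' @param n_strata number of trait strata (default 10).
#' @param min_per_stratum minimum stratum size before merging (default 30).
#' @return data frame with one row per item: `item_id`, `statistic`, `df`,
#'   `p_value`.
#' @export
item_fit <- function(data, fit, n_strata = 10L, min_per_stratum = 30L) {
  stopifnot(inherits(data, "response_matrix"))
  bank <- if (inherits(fit, "grm_fit")) fit$bank else fit
  .bank_check(bank)
  bank <- bank_subset(bank, data$item_ids)
  x <- data$values
  n <- nrow(x)
  m <- n_categories(bank)

  ## posterior over quadrature nodes per person, under a standard-normal
  ## latent density (the calibration assumption)
  nodes <- seq(-5, 5, length.out = 41L)
  logw <- stats::dnorm(nodes, log = TRUE); logw <- logw - max(logw)
  prq <- category_probs(bank, nodes)                  # [q, items, m]
  lp <- matrix(logw, n, length(nodes), byrow = TRUE)
  contrib <- vector("list", nrow(bank))
  for (i in seq_len(nrow(bank))) {
    lPi <- log(pmax(prq[, i, ], 1e-300))              # [q, m]
    contrib[[i]] <- t(lPi)[x[, i] + 1L, , drop = FALSE]  # [n, q]
    lp <- lp + contrib[[i]]
  }
  npar <- 1L + (m - 1L)
  out <- data.frame(item_id = bank$item_id, statistic = NA_real_,
                    df = NA_integer_, p_value = NA_real_)
  for (i in seq_len(nrow(bank))) {
    lpi <- lp - contrib[[i]]                          # leave item i out
    W <- exp(lpi - apply(lpi, 1L, max)); W <- W / rowSums(W)
    Epk <- W %*% prq[, i, ]                           # [n, m] expected probs
    ## stratify by the leave-one-out posterior mean so stratum membership is
    ## a function of the other items only
    eap <- as.vector(W %*% nodes)
    br <- unique(stats::quantile(eap,
                                 probs = seq(0, 1, length.out = n_strata + 1L)))
    g <- cut(eap, breaks = br, include.lowest = TRUE, labels = FALSE)
    repeat {
      tab <- table(g)
      if (all(tab >= min_per_stratum) || length(tab) <= 2L) break
      small <- which.min(tab)
      target <- if (small == 1L) 2L else small - 1L
      lv <- as.integer(names(tab))
      g[g == lv[small]] <- lv[target]
      g <- match(g, sort(unique(g)))
      message("item_fit: merged a small stratum")
    }
    strata <- sort(unique(g))
    stat <- 0; cells <- 0L
    for (s in strata) {
      in_s <- g == s
      obs <- tabulate(x[in_s, i] + 1L, m)
      exp_ <- colSums(Epk[in_s, , drop = FALSE])
      ## pool low-expectation cells downward
      while (length(exp_) > 1L && any(exp_ < 5)) {
        j <- which(exp_ < 5)[1L]
        tgt <- if (j == 1L) 2L else j - 1L
        exp_[tgt] <- exp_[tgt] + exp_[j]; obs[tgt] <- obs[tgt] + obs[j]
        exp_ <- exp_[-j]; obs <- obs[-j]
      }
      stat <- stat + sum((obs - exp_)^2 / exp_)
      cells <- cells + length(exp_)
    }
    df <- max(cells - length(strata) - npar, 1L)
    out$statistic[i] <- stat
    out$df[i] <- df
    out$p_value[i] <- stats::pchisq(stat, df, lower.tail = FALSE)
  }
  out
}
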