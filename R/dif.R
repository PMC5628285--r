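## Differential item functioning by ordinal (proportional-odds) logistic
## regression, with beta-change and pseudo-R-squared criteria, and a
## DIF-adjusted rescoring that refits group-specific parameters for flagged
## items while anchoring the rest.

## proportional-odds fit with explicit starting values (empirical cumulative
## logits, slopes at zero): polr's internal start search can fail for very
## steep items with near-empty extreme categories
.polr_fit <- function(formula, data, n_coef) {
  ctl <- list(maxit = 500, reltol = 1e-12)
  pr <- cumsum(prop.table(table(data$y)))
  zeta <- stats::qlogis(pmin(pmax(pr[-length(pr)], 1e-4), 1 - 1e-4))
  zeta <- zeta + cumsum(c(0, diff(zeta) <= 0) * 1e-3)   # keep increasing
  tryCatch(
    MASS::polr(formula, data = data, Hess = FALSE, control = ctl),
    error = function(e)
      MASS::polr(formula, data = data, Hess = FALSE, control = ctl,
                 start = c(rep(0, n_coef), zeta)))
}

#' Detect differential item functioning by ordinal logistic regression
#'
#' For each item, three proportional-odds cumulative-logit models are fitted
#' to the item response with the pooled trait estimate as matching variable:
#' M1 `~ theta`, M2 `~ theta + group`, M3 `~ theta * group`.  Uniform DIF is
#' the likelihood-ratio test of M2 vs M1, non-uniform DIF M3 vs M2, total
#' M3 vs M1 (df 1, 1, 2).  `beta_change` is the relative change of the trait
#' coefficient between M1 and M2; `pseudo_r2_change` is the McFadden R-squared
#' difference between M3 and M1.  An item is flagged when
#' `beta_change > flag_beta_change` (the 1% operating rule); the R-squared
#' change is reported for severity grading against `flag_r2`.
#'
#' @param data a `response_matrix`.
#' @param group per-person binary labels (factor/character/vector), or the
#'   name of a column of `data$groups`.
#' @param bank optional calibrated `item_bank` for the matching trait
#'   estimate; when `NULL` the pooled sample is calibrated with [fit_grm()].
#' @param flag_beta_change relative beta-change flagging threshold
#'   (default 0.01).
#' @param flag_r2 McFadden R-squared severity threshold (default 0.13).
#' @return an object of class `dif_result`: data frame `items` with per-item
#'   statistics and flags, plus `theta` (matching scores), `group`,
#'   `thresholds`.
#' @export
detect_dif <- function(data, group, bank = NULL, flag_beta_change = 0.01,
                       flag_r2 = 0.13) {
  stopifnot(inherits(data, "response_matrix"))
  if (length(group) == 1L && is.character(group)) {
    if (is.null(data$groups) || !group %in% names(data$groups))
      stop("group column not found", call. = FALSE)
    group <- data$groups[[group]]
  }
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must be binary", call. = FALSE)
  if (any(table(group) < 2L)) stop("empty or near-empty group", call. = FALSE)
  if (is.null(bank)) bank <- fit_grm(data)$bank
  bank <- bank_subset(bank, data$item_ids)
  theta <- .map_thetas(bank, data$values)$theta
  g <- as.integer(group) - 1L

  ids <- data$item_ids
  out <- data.frame(item_id = ids, beta_change = NA_real_,
                    pseudo_r2_change = NA_real_,
                    lr_chi2_uniform = NA_real_, p_uniform = NA_real_,
                    lr_chi2_nonuniform = NA_real_, p_nonuniform = NA_real_,
                    lr_chi2_total = NA_real_, p_total = NA_real_,
                    flagged = FALSE, skipped = FALSE)
  for (i in seq_along(ids)) {
    y <- factor(data$values[, i], levels = sort(unique(data$values[, i])),
                ordered = TRUE)
    if (nlevels(y) < 2L) { out$skipped[i] <- TRUE; next }
    df_ <- data.frame(y = y, th = theta, g = g)
    fits <- tryCatch(suppressWarnings(list(
      m0 = .polr_fit(y ~ 1, df_, 0L),
      m1 = .polr_fit(y ~ th, df_, 1L),
      m2 = .polr_fit(y ~ th + g, df_, 2L),
      m3 = .polr_fit(y ~ th * g, df_, 3L)
    )), error = function(e) NULL)
    if (is.null(fits)) {
      out$skipped[i] <- TRUE
      warning(sprintf("item %s: ordinal models failed to converge, skipped",
                      ids[i]), call. = FALSE)
      next
    }
    ll <- vapply(fits, stats::logLik, numeric(1L))
    b1 <- stats::coef(fits$m1)[["th"]]
    b1_2 <- stats::coef(fits$m2)[["th"]]
    out$beta_change[i] <- abs(b1_2 - b1) / abs(b1)
    out$pseudo_r2_change[i] <- (1 - ll[["m3"]] / ll[["m0"]]) -
      (1 - ll[["m1"]] / ll[["m0"]])
    lr <- function(big, small, df_) {
      stat <- max(2 * (ll[[big]] - ll[[small]]), 0)
      c(stat, stats::pchisq(stat, df_, lower.tail = FALSE))
    }
    u <- lr("m2", "m1", 1L); nu <- lr("m3", "m2", 1L); tt <- lr("m3", "m1", 2L)
    out$lr_chi2_uniform[i] <- u[1L]; out$p_uniform[i] <- u[2L]
    out$lr_chi2_nonuniform[i] <- nu[1L]; out$p_nonuniform[i] <- nu[2L]
    out$lr_chi2_total[i] <- tt[1L]; out$p_total[i] <- tt[2L]
    out$flagged[i] <- out$beta_change[i] > flag_beta_change
  }
  structure(list(items = out, theta = theta, group = group,
                 flag_beta_change = flag_beta_change, flag_r2 = flag_r2),
            class = "dif_result")
}

#' @export
print.dif_result <- function(x, ...) {
  fl <- x$items$item_id[x$items$flagged]
  cat(sprintf("DIF screen (beta change > %g%%): %d item(s) flagged%s\n",
              100 * x$flag_beta_change, length(fl),
              if (length(fl)) paste0(": ", paste(fl, collapse = ", ")) else ""))
  print(x$items[, c("item_id", "beta_change", "pseudo_r2_change",
                    "p_uniform", "p_nonuniform", "flagged")], digits = 3)
  invisible(x)
}

#' DIF-adjusted person scores
#'
#' Refits the graded response model with group-specific parameters for the
#' flagged items (all other items anchored across groups by the pooled fit),
#' rescores each person with their own group's parameters, and compares the
#' adjusted scores to the original pooled scores by Pearson correlation and a
#' Welch two-sample t statistic.
#'
#' The group-specific refit represents each flagged item as two columns, one
#' per group, with the other group's responses missing; the marginal
#' likelihood handles the missingness directly.
#'
#' @param data a `response_matrix`.
#' @param group per-person binary labels or a `data$groups` column name.
#' @param flagged_items item labels to free across groups (e.g.
#'   `$items$item_id[$items$flagged]` from [detect_dif()]); may be empty, in
#'   which case original and adjusted scores coincide.
#' @return list with `original`, `adjusted` (per-person trait scores),
#'   `pearson_r`, `t_statistic`, `p_value`, `flagged_items`.
#' @export
dif_adjusted_scores <- function(data, group, flagged_items = character(0)) {
  stopifnot(inherits(data, "response_matrix"))
  if (length(group) == 1L && is.character(group)) group <- data$groups[[group]]
  group <- factor(group)
  stopifnot(nlevels(group) == 2L)
  if (!all(flagged_items %in% data$item_ids))
    stop("flagged item not in data", call. = FALSE)
  pooled <- fit_grm(data)
  orig <- .map_thetas(pooled$bank, data$values)$theta
  if (length(flagged_items) == 0L) {
    return(list(original = orig, adjusted = orig, pearson_r = 1,
                t_statistic = 0, p_value = 1, flagged_items = character(0)))
  }
  ## split each flagged item into two group-specific columns
  x <- data$values
  for (id in flagged_items) {
    j <- match(id, colnames(x))
    col_a <- col_b <- x[, j]
    col_a[group != levels(group)[1L]] <- NA
    col_b[group != levels(group)[2L]] <- NA
    x[, j] <- col_a
    x <- cbind(x, col_b)
    colnames(x)[c(j, ncol(x))] <- paste0(id, "@", levels(group))
  }
  refit <- suppressWarnings(fit_grm(x))
  ## a group may never have used some category of its own copy; apply the
  ## fit's collapse map so data and bank stay aligned
  for (id in names(refit$collapsed)) {
    j <- match(id, colnames(x))
    x[, j] <- refit$collapsed[[id]][x[, j] + 1L]
  }
  ## rescore each person against their own group's parameter set
  adj <- numeric(nrow(x))
  for (lv in levels(group)) {
    sel <- group == lv
    ids <- colnames(x)
    use <- !grepl("@", ids) | endsWith(ids, paste0("@", lv))
    bk <- bank_subset(refit$bank, which(use))
    adj[sel] <- .map_thetas(bk, x[sel, use, drop = FALSE])$theta
  }
  tt <- stats::t.test(adj, orig)
  list(original = orig, adjusted = adj,
       pearson_r = stats::cor(orig, adj),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       flagged_items = flagged_items)
}
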