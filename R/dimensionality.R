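## Scale-level evaluation: internal consistency, one-factor confirmatory
## factor analysis with fit indices, and Mokken scalability with iterative
## item removal.

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param data a `response_matrix` (or plain numeric matrix).
#' @return the alpha coefficient.
#' @export
cronbach_alpha <- function(data) {
  x <- .values(data)
  k <- ncol(x)
  stopifnot(k >= 2L, nrow(x) >= 2L)
  tv <- stats::var(rowSums(x))
  if (tv <= 0) stop("zero total-score variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(x, 2L, stats::var)) / tv)
}

.values <- function(data) {
  if (inherits(data, "response_matrix")) data$values else as.matrix(data)
}

## ---- one-factor CFA ---------------------------------------------------------

#' Fit a one-factor confirmatory model by maximum likelihood
#'
#' Treats the ordered scores as continuous (Pearson covariances) and minimizes
#' the normal-theory discrepancy
#' `F = log det(Sigma) + tr(S Sigma^-1) - log det(S) - p` over loadings and
#' uniquenesses, with the loading vector profiled out: given uniquenesses
#' `psi` the optimal loadings come from the leading eigenpair of
#' `psi^-1/2 S psi^-1/2` (Joreskog).  Chi-square is `(n-1) F` at the optimum;
#' CFI and TLI use the independence baseline; RMSEA and its 90% CI come from
#' the noncentral chi-square inversion.
#'
#' Heywood cases are handled by flooring each uniqueness at 0.5% of the item
#' variance (recorded in `$heywood`).
#'
#' @param data a `response_matrix` or numeric matrix.
#' @return an object of class `cfa_fit`: list with `loadings` (standardized),
#'   `uniquenesses`, `chi_square`, `df`, `chi_square_baseline`, `df_baseline`,
#'   `cfi`, `tli`, `rmsea`, `rmsea_ci` (90%), `n`, `converged`, `heywood`.
#' @export
fit_one_factor_cfa <- function(data) {
  x <- .values(data)
  n <- nrow(x); p <- ncol(x)
  stopifnot(p >= 3L, n > p)
  S <- stats::cov(x)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("sample covariance matrix is not positive definite", call. = FALSE)
  sd_ <- sqrt(diag(S))
  R <- stats::cov2cor(S)        # F_ML is scale invariant for this model
  floor_ <- 0.005
  ## discrepancy as a function of log-uniquenesses (correlation metric)
  obj <- function(lpsi) {
    psi <- exp(lpsi)
    isq <- 1 / sqrt(psi)
    M <- t(R * isq) * isq       # psi^-1/2 R psi^-1/2
    e <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
    f <- function(v) v - log(pmax(v, 1e-12)) - 1
    ## the leading eigenvalue is fitted exactly when > 1 (Joreskog 1967);
    ## otherwise the optimal loading is zero and its term stays in F
    sum(f(e[-1L])) + f(min(e[1L], 1))
  }
  start <- log(pmax(1 - (stats::cor(x, rowMeans(x))[, 1L])^2, 0.1))
  opt <- stats::nlminb(start, obj, lower = log(floor_), upper = log(1))
  psi <- exp(opt$par)
  heywood <- any(opt$par <= log(floor_) + 1e-6)
  isq <- 1 / sqrt(psi)
  M <- t(R * isq) * isq
  ee <- eigen(M, symmetric = TRUE)
  lambda <- sqrt(psi) * ee$vectors[, 1L] * sqrt(max(ee$values[1L] - 1, 0))
  if (sum(lambda) < 0) lambda <- -lambda
  Fmin <- obj(opt$par)
  df <- p * (p + 1) / 2 - 2 * p
  chisq <- (n - 1) * Fmin
  Fb <- -determinant(R, logarithm = TRUE)$modulus[1L]
  chisq_b <- (n - 1) * Fb
  df_b <- p * (p - 1) / 2
  cfi <- min(1, max(0, 1 - max(chisq - df, 0) / max(chisq_b - df_b,
                                                    chisq - df, 0 + 1e-12)))
  tli_raw <- ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)
  tli <- min(1, max(0, tli_raw))
  rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  ci <- .rmsea_ci(chisq, df, n)
  structure(list(loadings = stats::setNames(lambda, colnames(x)),
                 uniquenesses = stats::setNames(psi, colnames(x)),
                 chi_square = chisq, df = df,
                 chi_square_baseline = chisq_b, df_baseline = df_b,
                 cfi = cfi, tli = tli, rmsea = rmsea, rmsea_ci = ci, n = n,
                 converged = opt$convergence == 0, heywood = heywood),
            class = "cfa_fit")
}

## 90% RMSEA confidence interval by inverting the noncentral chi-square.
.rmsea_ci <- function(chisq, df, n, level = 0.90) {
  al <- (1 - level) / 2
  up <- function(ncp) stats::pchisq(chisq, df, ncp = ncp)
  lo_ncp <- if (up(0) < 1 - al) 0 else
    stats::uniroot(function(l) up(l) - (1 - al), c(0, max(chisq * 2, 1)),
                   extendInt = "downX")$root
  hi_ncp <- if (up(0) < al) 0 else
    stats::uniroot(function(l) up(l) - al, c(0, max(chisq * 3, 10)),
                   extendInt = "downX")$root
  c(lower = sqrt(lo_ncp / (df * (n - 1))), upper = sqrt(hi_ncp / (df * (n - 1))))
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf(paste0("One-factor CFA (n = %d): chi2(%d) = %.2f, CFI = %.3f, ",
                     "TLI = %.3f,\n  RMSEA = %.3f (90%% CI %.3f-%.3f)%s\n"),
              x$n, x$df, x$chi_square, x$cfi, x$tli, x$rmsea,
              x$rmsea_ci[1L], x$rmsea_ci[2L],
              if (x$heywood) " [Heywood floor applied]" else ""))
  invisible(x)
}

## ---- Mokken scalability -----------------------------------------------------

## Maximum attainable covariance of two discrete columns given their marginal
## category distributions: the comonotone coupling, i.e. the covariance after
## sorting both columns.
.cov_max <- function(xi, xj) stats::cov(sort(xi), sort(xj))

#' Loevinger scalability coefficients
#'
#' `H_ij = sigma_ij / sigma_ij^max` where `sigma_ij` is the observed item-pair
#' covariance and `sigma_ij^max` the largest covariance attainable under the
#' two items' marginal category distributions (comonotone coupling).  Item and
#' scale coefficients are the corresponding ratios of sums.  Item standard
#' errors use a first-order influence-function (delta-method) approximation
#' that treats the maximum covariances as fixed.
#'
#' @param data a `response_matrix` or integer matrix with >= 3 items.
#' @return an object of class `mokken_result`: list with `pair_H` (matrix),
#'   `item_H`, `item_se`, `scale_H`, `removed_items` (empty here).
#' @export
mokken_scalability <- function(data) {
  x <- .values(data)
  k <- ncol(x); n <- nrow(x)
  stopifnot(k >= 3L)
  if (any(apply(x, 2L, stats::var) == 0))
    stop("constant item (zero variance)", call. = FALSE)
  S <- stats::cov(x)
  Smax <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    Smax[i, j] <- Smax[j, i] <- .cov_max(x[, i], x[, j])
  H <- S / Smax; diag(H) <- NA_real_
  off <- upper.tri(S)
  item_H <- sapply(seq_len(k), function(i)
    sum(S[i, -i]) / sum(Smax[i, -i]))
  scale_H <- sum(S[off]) / sum(Smax[off])
  ## influence-function SE of item_H (denominator treated as fixed)
  xc <- scale(x, scale = FALSE)
  item_se <- sapply(seq_len(k), function(i) {
    infl <- xc[, i] * rowSums(xc[, -i, drop = FALSE])
    stats::sd(infl) / (sum(Smax[i, -i]) * sqrt(n))
  })
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("q", seq_len(k))
  dimnames(H) <- list(ids, ids)
  structure(list(pair_H = H,
                 item_H = stats::setNames(item_H, ids),
                 item_se = stats::setNames(item_se, ids),
                 scale_H = scale_H, removed_items = character(0)),
            class = "mokken_result")
}

#' @export
print.mokken_result <- function(x, ...) {
  cat(sprintf("Mokken scalability: scale H = %.3f (%d items)\n",
              x$scale_H, length(x$item_H)))
  print(round(data.frame(item_H = x$item_H, se = x$item_se), 3))
  if (length(x$removed_items))
    cat("removed:", paste(x$removed_items, collapse = ", "), "\n")
  invisible(x)
}

#' Iterative Mokken item removal
#'
#' Repeatedly removes the single item with the lowest item scalability while
#' that value falls below `h_min` (0.30 by convention), recomputing all
#' coefficients after each removal.  The removal trace preserves order.
#'
#' @param data a `response_matrix` or integer matrix.
#' @param h_min item scalability floor (default 0.30).
#' @return a `mokken_result` for the retained items, with `removed_items`
#'   giving the ordered removal trace.
#' @export
mokken_item_selection <- function(data, h_min = 0.30) {
  x <- .values(data)
  removed <- character(0)
  repeat {
    res <- mokken_scalability(x)
    worst <- which.min(res$item_H)
    if (res$item_H[worst] >= h_min) break
    removed <- c(removed, names(res$item_H)[worst])
    if (ncol(x) - 1L < 3L)
      stop("fewer than 3 items would remain", call. = FALSE)
    x <- x[, -worst, drop = FALSE]
  }
  res$removed_items <- removed
  res
}
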