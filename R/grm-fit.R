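## Marginal maximum likelihood calibration of the graded response model by EM
## with fixed normal quadrature, per-item Newton-type M-steps, and standard
## errors from the empirical cross-product of per-person score vectors.

## log category probabilities for one item at the quadrature nodes:
## matrix [n_quad, m]
.item_logP <- function(a, b, nodes) {
  ps <- cbind(1, stats::plogis(outer(nodes, b, function(t, bb) a * (t - bb))), 0)
  m <- length(b) + 1L
  log(pmax(ps[, 1:m, drop = FALSE] - ps[, 2:(m + 1L), drop = FALSE], 1e-300))
}

## complete-data expected negative loglik for one item given expected counts
## r [n_quad, m]; parameter vector zeta = (log a, b1, log diff2, log diff3...)
.zeta_to_ab <- function(zeta) {
  a <- exp(zeta[1L])
  b <- cumsum(c(zeta[2L], exp(zeta[-(1:2)])))
  list(a = a, b = b)
}
.ab_to_zeta <- function(a, b) c(log(a), b[1L], log(diff(b)))

.mstep_item <- function(r, nodes, zeta0) {
  negll <- function(zeta) {
    p <- .zeta_to_ab(zeta)
    -sum(r * .item_logP(p$a, p$b, nodes))
  }
  opt <- stats::nlminb(zeta0, negll,
                       lower = c(log(1e-3), -8, rep(log(1e-4), length(zeta0) - 2L)),
                       upper = c(log(50), 8, rep(log(16), length(zeta0) - 2L)))
  opt$par
}

#' Calibrate a graded response model by marginal maximum likelihood
#'
#' EM with fixed quadrature on `[-5, 5]` (nodes weighted by the standard
#' normal latent density), per-item quasi-Newton M-steps on the ordered
#' parameterization `(log a, b1, log diff)`, and standard errors from the
#' empirical cross-product approximation to the information matrix.
#' Standardized loadings use the `a/1.702` normal-ogive conversion.
#'
#' Items missing a category have the unseen categories collapsed into their
#' lower neighbour (with a warning); `NA` responses are allowed internally and
#' simply drop out of the likelihood (used by the DIF-adjusted refit).
#'
#' @param data a `response_matrix`, or an integer matrix (possibly with `NA`).
#' @param n_quadrature number of quadrature nodes (default 41).
#' @param tol EM stopping tolerance on the maximum absolute parameter change
#'   (default 1e-4).
#' @param max_iter maximum EM iterations (default 500).
#' @return an object of class `grm_fit`: list with `bank` (an `item_bank`
#'   with standard errors), `loadings`, `log_lik` (final marginal log
#'   likelihood), `log_lik_trace`, `converged`, `n_iter`, `n`,
#'   `collapsed` (per-item category merge map or `NULL`).
#' @export
fit_grm <- function(data, n_quadrature = 41L, tol = 1e-4, max_iter = 500L) {
  x <- .values(data)
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("q", seq_len(ncol(x)))
  n <- nrow(x); ni <- ncol(x)
  m <- if (inherits(data, "response_matrix")) data$n_cat else
    max(x, na.rm = TRUE) + 1L
  ## collapse unseen categories per item
  collapsed <- NULL
  for (i in seq_len(ni)) {
    seen <- sort(unique(x[!is.na(x[, i]), i]))
    if (length(seen) < m) {
      map <- cumsum(tabulate(x[, i] + 1L, m) > 0L) - 1L
      x[, i] <- map[x[, i] + 1L]
      collapsed <- c(collapsed, stats::setNames(list(map), ids[i]))
      warning(sprintf("item %s: unseen categories collapsed", ids[i]),
              call. = FALSE)
    }
  }
  mi <- apply(x, 2L, function(c_) max(c_, na.rm = TRUE)) + 1L  # cats per item
  if (any(mi < 2L)) stop("constant item", call. = FALSE)

  nodes <- seq(-5, 5, length.out = n_quadrature)
  logw <- stats::dnorm(nodes, log = TRUE)
  logw <- logw - log(sum(exp(logw)))

  ## starting values from category proportions and item-total correlation
  zeta <- vector("list", ni)
  for (i in seq_len(ni)) {
    pr <- tabulate(x[, i] + 1L, mi[i]) / sum(!is.na(x[, i]))
    cum <- pmin(pmax(rev(cumsum(rev(pr)))[-1L], 0.01), 0.99)
    b0 <- sort(-stats::qlogis(cum))
    b0 <- b0 + seq(0, 1e-3, length.out = length(b0))   # break exact ties
    zeta[[i]] <- .ab_to_zeta(1, cumsum(c(b0[1L], pmax(diff(b0), 1e-3))))
  }

  ## category indicator index per item (persons with NA excluded on the fly)
  ll_trace <- numeric(0)
  prev <- unlist(zeta)
  for (iter in seq_len(max_iter)) {
    ## E-step: log posterior over nodes per person
    lp <- matrix(logw, n, n_quadrature, byrow = TRUE)
    logP <- vector("list", ni)
    for (i in seq_len(ni)) {
      p <- .zeta_to_ab(zeta[[i]])
      logP[[i]] <- .item_logP(p$a, p$b, nodes)   # [q, m_i]
      obs <- !is.na(x[, i])
      lp[obs, ] <- lp[obs, ] + t(logP[[i]])[x[obs, i] + 1L, , drop = FALSE]
    }
    mx <- apply(lp, 1L, max)
    W <- exp(lp - mx)
    rs <- rowSums(W)
    ll <- sum(mx + log(rs))
    ll_trace <- c(ll_trace, ll)
    W <- W / rs
    ## M-step per item on expected counts r [q, m_i]
    for (i in seq_len(ni)) {
      obs <- which(!is.na(x[, i]))
      ind <- matrix(0, length(obs), mi[i])
      ind[cbind(seq_along(obs), x[obs, i] + 1L)] <- 1
      r <- crossprod(W[obs, , drop = FALSE], ind)    # [q, m_i]
      zeta[[i]] <- .mstep_item(r, nodes, zeta[[i]])
    }
    cur <- unlist(zeta)
    if (max(abs(cur - prev)) < tol) break
    prev <- cur
  }
  converged <- iter < max_iter || max(abs(cur - prev)) < tol

  ab <- lapply(zeta, .zeta_to_ab)
  a_hat <- vapply(ab, `[[`, numeric(1L), "a")
  ## items may differ in category count after collapsing; pad to common m
  bmax <- max(mi) - 1L
  ## trailing NAs mark absent upper categories (mixed category counts are
  ## legitimate, e.g. after testlet formation)
  b_hat <- t(vapply(ab, function(p) c(p$b, rep(NA_real_, bmax - length(p$b))),
                    numeric(bmax)))

  se <- .grm_se(x, a_hat, b_hat, nodes, logw)
  bank <- item_bank(ids, a_hat, b_hat, se_a = se$a, se_b = se$b)
  structure(list(bank = bank,
                 loadings = stats::setNames(slope_to_loading(a_hat), ids),
                 log_lik = ll_trace[length(ll_trace)],
                 log_lik_trace = ll_trace, converged = converged,
                 n_iter = iter, n = n, collapsed = collapsed),
            class = "grm_fit")
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("GRM fit: %d items, n = %d, logLik = %.2f, %d EM iterations%s\n",
              nrow(x$bank), x$n, x$log_lik, x$n_iter,
              if (x$converged) "" else " [not converged]"))
  print(x$bank)
  invisible(x)
}

## Empirical cross-product standard errors.  The score of the marginal
## likelihood equals the posterior-expected complete-data score; cross-products
## of per-person scores approximate the information matrix.
.grm_se <- function(x, a, b, nodes, logw) {
  n <- nrow(x); ni <- ncol(x); bmax <- ncol(b)
  nq <- length(nodes)
  ## posterior weights under the final parameters
  lp <- matrix(logw, n, nq, byrow = TRUE)
  for (i in seq_len(ni)) {
    bi <- b[i, !is.na(b[i, ])]
    lP <- .item_logP(a[i], bi, nodes)
    obs <- !is.na(x[, i])
    lp[obs, ] <- lp[obs, ] + t(lP)[x[obs, i] + 1L, , drop = FALSE]
  }
  W <- exp(lp - apply(lp, 1L, max)); W <- W / rowSums(W)
  cols <- vector("list", ni)        # parameter column indices per item
  Sc_list <- vector("list", ni)
  nxt <- 1L
  for (i in seq_len(ni)) {
    bi <- b[i, !is.na(b[i, ])]
    m <- length(bi) + 1L
    ps <- stats::plogis(outer(nodes, bi, function(t, bb) a[i] * (t - bb)))
    psE <- cbind(1, ps, 0)
    P <- pmax(psE[, 1:m, drop = FALSE] - psE[, 2:(m + 1L), drop = FALSE], 1e-300)
    pq <- ps * (1 - ps)                                      # [q, m-1]
    tb <- outer(nodes, bi, `-`)
    dPda <- cbind(0, tb * pq, 0)
    dloga <- (dPda[, 1:m, drop = FALSE] -
              dPda[, 2:(m + 1L), drop = FALSE]) / P          # [q, m]
    ## with 1-based category column k, P[, k] = P*_{k-1} - P*_k, and
    ## dP*_j/db_j = -a pq_j, so dP_k/db_{k-1} = -a pq_{k-1}, dP_k/db_k = +a pq_k
    dlogb <- array(0, dim = c(nq, m, m - 1L))
    for (k in seq_len(m)) {
      if (k >= 2L) dlogb[, k, k - 1L] <- -a[i] * pq[, k - 1L] / P[, k]
      if (k <= m - 1L) dlogb[, k, k] <- a[i] * pq[, k] / P[, k]
    }
    obs <- which(!is.na(x[, i]))
    xi <- x[obs, i] + 1L
    Wo <- W[obs, , drop = FALSE]
    Si <- matrix(0, n, m)             # score columns: a, b_1..b_{m-1}
    Si[obs, 1L] <- rowSums(Wo * t(dloga)[xi, , drop = FALSE])
    for (j in seq_len(m - 1L))
      Si[obs, 1L + j] <- rowSums(Wo * t(dlogb[, , j])[xi, , drop = FALSE])
    Sc_list[[i]] <- Si
    cols[[i]] <- seq(nxt, length.out = m)
    nxt <- nxt + m
  }
  Sc <- do.call(cbind, Sc_list)
  I <- crossprod(Sc)
  V <- tryCatch(solve(I), error = function(e) diag(1 / pmax(diag(I), 1e-12)))
  sev <- sqrt(pmax(diag(V), 0))
  se_b <- matrix(NA_real_, ni, bmax)
  for (i in seq_len(ni))
    se_b[i, seq_len(length(cols[[i]]) - 1L)] <- sev[cols[[i]][-1L]]
  list(a = vapply(cols, function(cc) sev[cc[1L]], numeric(1L)), b = se_b)
}
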