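## Shared fixtures and independent oracles used across test files.

tiny_bank <- function() item_bank("x1", a = 1, b = matrix(c(-1, 0, 1), 1))

three_bank <- function() {
  item_bank(c("i1", "i2", "i3"), a = c(1, 2, 0.8),
            b = rbind(c(-1, 0, 1), c(-0.5, 0.5, 1.5), c(-2, -1, 0.5)))
}

## GRM category probabilities computed independently (scalar arithmetic,
## no package internals)
oracle_probs <- function(a, b, theta) {
  pstar <- c(1, 1 / (1 + exp(-a * (theta - b))), 0)
  pstar[-length(pstar)] - pstar[-1]
}

## Fisher information as the negative second derivative of the expected
## log-likelihood, by central finite differences
oracle_info_numderiv <- function(a, b, theta, h = 1e-4) {
  p0 <- oracle_probs(a, b, theta)
  f <- function(t) sum(p0 * log(oracle_probs(a, b, t)))
  -(f(theta + h) - 2 * f(theta) + f(theta - h)) / h^2
}

## log-likelihood of a response vector on a bank, by direct probability lookup
oracle_loglik <- function(bank, items, resp, theta) {
  sum(vapply(seq_along(items), function(j) {
    r <- bank[bank$item_id == items[j], ]
    b <- as.numeric(r[grep("^b[0-9]+$", names(r))])
    log(oracle_probs(r$a, b[!is.na(b)], theta)[resp[j] + 1])
  }, numeric(1)))
}

## two-stage grid-search ML: coarse 0.01 grid, then 1e-4 refinement
oracle_ml_grid <- function(bank, items, resp) {
  ll <- function(g) vapply(g, function(t) oracle_loglik(bank, items, resp, t),
                           numeric(1))
  coarse <- seq(-4, 4, by = 0.01)
  t0 <- coarse[which.max(ll(coarse))]
  fine <- seq(max(-4, t0 - 0.02), min(4, t0 + 0.02), by = 1e-4)
  fine[which.max(ll(fine))]
}

## maximum attainable covariance of two integer columns given their margins:
## Hoeffding representation on the comonotone copula (independent of the
## sort-based implementation)
oracle_cov_max <- function(x, y) {
  n <- length(x)
  s <- sort(unique(x)); t <- sort(unique(y))
  tot <- 0
  for (u in s[-length(s)]) for (v in t[-length(t)]) {
    fx <- mean(x > u); fy <- mean(y > v)
    tot <- tot + (min(fx, fy) - fx * fy)
  }
  tot * n / (n - 1)   # match the n-1 denominator of sample covariances
}

## expected value of a standard normal within its k-th decile
oracle_decile_means <- function() {
  q <- qnorm(seq(0, 1, by = 0.1))
  10 * (dnorm(q[-11]) - dnorm(q[-1]))
}

make_grm_data <- function(bank, n, seed, theta_sd = 1) {
  set.seed(seed)
  th <- rnorm(n, 0, theta_sd)
  simulate_grm_responses(bank, th, seed = seed + 1)
}
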