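## Synthetic response generator.  Emulates the structure the analysis assumes:
## a unidimensional normal trait, graded responses from a calibrated bank, and
## optional controlled violations (off-dimension items, locally dependent
## pairs, DIF items) that exercise the screening stages.

#' Draw latent-trait values
#'
#' @param n number of persons.
#' @param mean,sd normal parameters (default standard normal, the latent
#'   density assumed in calibration).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return numeric vector of length `n`.
#' @export
draw_thetas <- function(n, mean = 0, sd = 1, seed = NULL) {
  stopifnot(n >= 1, sd > 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, mean, sd)
}

## Latent-propensity sampling.  For item i with slope a and thresholds b_k the
## graded response is x = #{k : a (theta - b_k) > -e} with e ~ logistic(0, 1),
## equivalently x = #{k : z_i > b_k} with propensity z_i = theta + e / a.
## Sampling through propensities (rather than inverse-CDF on category
## probabilities) lets injections perturb z before categorization.
.sample_grm <- function(bank, thetas, E = NULL) {
  n <- length(thetas)
  ni <- nrow(bank)
  if (is.null(E)) E <- matrix(stats::rlogis(n * ni), n, ni)
  z <- thetas + sweep(E, 2L, bank$a, `/`)
  b <- .bank_b(bank)
  x <- matrix(0L, n, ni)
  for (k in seq_len(ncol(b)))
    x <- x + (z > rep(b[, k], each = n))
  colnames(x) <- bank$item_id
  x
}

#' Simulate graded-response data at given trait values
#'
#' Each response is drawn from the model category distribution at that
#' person's theta (logistic metric).
#'
#' @param bank an `item_bank`.
#' @param thetas latent-trait value per person.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return a `response_matrix`.
#' @examples
#' simulate_grm_responses(cesd_bank(), draw_thetas(5, seed = 1), seed = 2)
#' @export
simulate_grm_responses <- function(bank, thetas, seed = NULL) {
  .bank_check(bank)
  stopifnot(all(is.finite(thetas)), length(thetas) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  response_matrix(.sample_grm(bank, thetas), item_ids = bank$item_id,
                  n_cat = n_categories(bank))
}

#' Describe a synthetic study design
#'
#' Defaults mirror the study the generator emulates: about a thousand persons
#' per group, a standard-normal trait, and a roughly 2:1 female/male split.
#'
#' @param bank generating `item_bank`.
#' @param n_persons sample size (default 1042, the validation-group size; use
#'   1018 for the evaluation group).
#' @param theta_mean,theta_sd latent trait distribution.
#' @param off_dimension_items named numeric vector: secondary loading
#'   `lambda2` per off-dimension item.  Those items load
#'   `sqrt(1 - lambda2^2)` on the primary trait and `lambda2` on one shared
#'   independent second trait.
#' @param dependent_pairs list of `list(items = c(id1, id2), rho = r)` --
#'   residual correlation injected through a shared normal shock added to the
#'   two items' latent propensities.
#' @param dif_items list of `list(item = id, group = label, delta = shift,
#'   kappa = slope_ratio)`: uniform DIF shifts all thresholds by `delta`,
#'   non-uniform DIF multiplies the slope by `kappa`, for the named group only.
#' @param group_fractions named proportions summing to 1.
#' @param seed integer seed fixing the whole dataset.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(bank, n_persons = 1042L, theta_mean = 0,
                              theta_sd = 1, off_dimension_items = NULL,
                              dependent_pairs = list(), dif_items = list(),
                              group_fractions = c(female = 0.66, male = 0.34),
                              seed = 1L) {
  .bank_check(bank)
  stopifnot(n_persons >= 2L, theta_sd > 0,
            abs(sum(group_fractions) - 1) < 1e-8)
  ids <- bank$item_id
  chk <- function(x) if (!all(x %in% ids))
    stop("referenced item_id absent from bank", call. = FALSE)
  if (!is.null(off_dimension_items)) {
    chk(names(off_dimension_items))
    stopifnot(all(off_dimension_items > 0 & off_dimension_items < 1))
  }
  for (p in dependent_pairs) {
    chk(p$items); stopifnot(length(p$items) == 2L, p$rho > -1, p$rho < 1)
  }
  for (d in dif_items) {
    chk(d$item)
    stopifnot(is.finite(d$delta), is.null(d$kappa) || d$kappa > 0,
              d$group %in% names(group_fractions))
  }
  structure(list(bank = bank, n_persons = as.integer(n_persons),
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 off_dimension_items = off_dimension_items,
                 dependent_pairs = dependent_pairs, dif_items = dif_items,
                 group_fractions = group_fractions, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Generate a full synthetic study dataset
#'
#' Base responses follow the graded response model at normally drawn trait
#' values; the design's injections then perturb the latent propensities before
#' categorization:
#' off-dimension items replace theta by
#' `sqrt(1 - lambda2^2) * theta + lambda2 * theta2` with a shared second trait
#' `theta2`; dependent pairs receive a shared standard-normal shock scaled so
#' the two items' residual correlation is approximately `rho`; DIF items use
#' thresholds `b + delta` and slope `a * kappa` for the named group only.
#' With no injections the dataset is identical to
#' [simulate_grm_responses()] drawn from the same RNG stream.
#'
#' @param design a [simulation_design()].
#' @return a `response_matrix` with a `group` covariate column and the true
#'   thetas in `attr(, "thetas")`.
#' @export
make_study_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  bank <- design$bank
  n <- design$n_persons
  ni <- nrow(bank)
  set.seed(design$seed)
  thetas <- stats::rnorm(n, design$theta_mean, design$theta_sd)
  E <- matrix(stats::rlogis(n * ni), n, ni)

  ## per-item effective theta and parameters (possibly person-specific)
  theta_eff <- matrix(thetas, n, ni)
  a_eff <- matrix(bank$a, n, ni, byrow = TRUE)
  b <- .bank_b(bank)
  shift <- matrix(0, n, ni)                 # added to propensity z

  if (!is.null(design$off_dimension_items)) {
    theta2 <- stats::rnorm(n)
    for (id in names(design$off_dimension_items)) {
      l2 <- design$off_dimension_items[[id]]
      j <- match(id, bank$item_id)
      theta_eff[, j] <- sqrt(1 - l2^2) * thetas + l2 * theta2
    }
  }
  for (p in design$dependent_pairs) {
    s <- stats::rnorm(n)
    cc <- sqrt(abs(p$rho) / (1 - abs(p$rho)))
    sgn <- c(1, sign(p$rho))                # negative rho: opposite loadings
    for (w in 1:2) {
      j <- match(p$items[w], bank$item_id)
      ## residual sd of e/a is (pi/sqrt(3))/a; scale the shock to it
      shift[, j] <- shift[, j] + sgn[w] * cc * (pi / sqrt(3)) / bank$a[j] * s
    }
  }

  counts <- diff(c(0L, round(cumsum(design$group_fractions) * n)))
  groups <- sample(rep(names(design$group_fractions), times = counts))
  for (d in design$dif_items) {
    j <- match(d$item, bank$item_id)
    in_g <- groups == d$group
    if (!is.null(d$kappa)) a_eff[in_g, j] <- a_eff[in_g, j] * d$kappa
    if (d$delta != 0) shift[in_g, j] <- shift[in_g, j] - d$delta
    ## b + delta for the group is equivalent to z - delta against the base b
  }

  z <- theta_eff + E / a_eff + shift
  x <- matrix(0L, n, ni)
  for (k in seq_len(ncol(b)))
    x <- x + (z > rep(b[, k], each = n))
  colnames(x) <- bank$item_id
  out <- response_matrix(x, item_ids = bank$item_id,
                         groups = data.frame(group = groups),
                         n_cat = n_categories(bank))
  attr(out, "thetas") <- thetas
  out
}
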