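#' Construct a graded-response item bank
#'
#' An item bank is the calibrated measurement model: one slope (discrimination)
#' and a strictly increasing vector of category thresholds per item, on the
#' logistic metric (no 1.702 scaling constant).  Thresholds are on the z-score
#' scale of the latent trait.
#'
#' @param item_id character vector of unique item labels.
#' @param a positive slopes, one per item.
#' @param b numeric matrix of thresholds (items x (categories - 1)), each row
#'   strictly increasing.
#' @param se_a,se_b optional standard errors with the same shapes as `a`, `b`.
#' @return An object of class `item_bank`: a data frame with columns
#'   `item_id`, `a`, `b1`..`b<m-1>` (and `se_*` columns when supplied).
#' @examples
#' item_bank("x1", a = 1.5, b = matrix(c(-1, 0, 1), 1))
#' @export
item_bank <- function(item_id, a, b, se_a = NULL, se_b = NULL) {
  item_id <- as.character(item_id)
  b <- rbind(b)
  stopifnot(length(item_id) == length(a), nrow(b) == length(a))
  if (anyDuplicated(item_id))
    stop("item_ids must be unique", call. = FALSE)
  if (any(!is.finite(a)) || any(a <= 0))
    stop("slopes must be positive and finite", call. = FALSE)
  ## trailing NAs mark absent upper categories (items may differ in category
  ## count, e.g. a summed testlet item); non-NA thresholds must be a strictly
  ## increasing prefix
  for (r in seq_len(nrow(b))) {
    bi <- b[r, ]
    ok <- !is.na(bi)
    if (any(ok != (cumsum(!ok) == 0L)))
      stop("NA thresholds must be trailing", call. = FALSE)
    bi <- bi[ok]
    if (length(bi) == 0L || any(!is.finite(bi)))
      stop("thresholds must be finite", call. = FALSE)
    if (length(bi) > 1 && any(diff(bi) <= 0))
      stop("thresholds must be strictly increasing within item", call. = FALSE)
  }
  out <- data.frame(item_id = item_id, a = as.numeric(a))
  colnames(b) <- paste0("b", seq_len(ncol(b)))
  out <- cbind(out, b)
  if (!is.null(se_a)) out$se_a <- as.numeric(se_a)
  if (!is.null(se_b)) {
    se_b <- rbind(se_b)
    colnames(se_b) <- paste0("se_b", seq_len(ncol(se_b)))
    out <- cbind(out, se_b)
  }
  rownames(out) <- NULL
  structure(out, class = c("item_bank", "data.frame"), n_cat = ncol(b) + 1L)
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Graded-response item bank: %d items, %d categories\n",
              nrow(x), n_categories(x)))
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Number of response categories of a bank
#' @param bank an `item_bank`.
#' @return integer category count `m` (responses are coded `0..m-1`).
#' @export
n_categories <- function(bank) attr(bank, "n_cat")

.bank_b <- function(bank) {
  as.matrix(bank[, grep("^b[0-9]+$", names(bank)), drop = FALSE])
}

.bank_check <- function(bank) {
  if (!inherits(bank, "item_bank")) stop("not an item_bank", call. = FALSE)
  if (nrow(bank) == 0L) stop("empty item bank", call. = FALSE)
  invisible(bank)
}

#' Subset an item bank
#' @param x an `item_bank`.
#' @param items item labels or indices to keep, in the requested order.
#' @return the reduced `item_bank`.
#' @export
bank_subset <- function(x, items) {
  idx <- if (is.character(items)) match(items, x$item_id) else as.integer(items)
  if (anyNA(idx)) stop("unknown item_id in subset", call. = FALSE)
  structure(x[idx, , drop = FALSE], class = class(x), n_cat = attr(x, "n_cat"))
}

#' Read an item bank from a delimited text file
#'
#' Expects columns `item_id`, `a`, `b1`..`b3` (or however many threshold
#' columns are present), and optionally `se_a`, `se_b1`.. .  Validation is the
#' same as [item_bank()]: positive slopes, strictly increasing thresholds.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return an `item_bank`.
#' @export
read_item_bank <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  if (!all(c("item_id", "a") %in% names(df)) || length(bcols) == 0L)
    stop("item bank file must have columns item_id, a, b1..", call. = FALSE)
  bcols <- bcols[order(as.integer(sub("b", "", bcols)))]
  sea <- if ("se_a" %in% names(df)) df$se_a else NULL
  sebcols <- grep("^se_b[0-9]+$", names(df), value = TRUE)
  seb <- if (length(sebcols)) as.matrix(df[, sebcols]) else NULL
  item_bank(df$item_id, df$a, as.matrix(df[, bcols]), se_a = sea, se_b = seb)
}

#' Write an item bank to a delimited text file
#' @param bank an `item_bank`.
#' @param path file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path, sep = ",") {
  .bank_check(bank)
  utils::write.table(as.data.frame(bank), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' The calibrated 17-item CES-D item bank
#'
#' Slopes, thresholds and their standard errors for the 17 CES-D items
#' retained after scalability screening (items 2, 11 and 15 removed),
#' calibrated under the graded response model on a general-population sample.
#' Thresholds are on the z-score scale; slopes on the logistic metric.
#'
#' @return an `item_bank` with 17 four-category items.
#' @examples
#' bank <- cesd_bank()
#' test_information(bank, 0)
#' @export
cesd_bank <- function() {
  read_item_bank(system.file("extdata", "cesd_item_bank.csv",
                             package = "cesdcat", mustWork = TRUE))
}

#' Standardized factor loading implied by a graded-response slope
#'
#' Converts logistic-metric slopes to standardized one-factor loadings via the
#' normal-ogive approximation: `a* = a / 1.702`, `lambda = a* / sqrt(a*^2 + 1)`.
#'
#' @param a logistic-metric slope(s).
#' @return loadings in (0, 1).
#' @export
slope_to_loading <- function(a) {
  astar <- a / 1.702
  astar / sqrt(astar^2 + 1)
}
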