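#' Construct a person-by-item response matrix
#'
#' Responses are integer categories coded `0..m-1` internally regardless of the
#' on-disk coding; `coding_offset` records the origin used on disk so files can
#' be round-tripped.
#'
#' @param values integer matrix (persons x items), categories `0..m-1`.
#' @param item_ids item labels; defaults to the matrix column names.
#' @param groups optional data frame of per-person covariates (e.g. gender,
#'   age group), one row per person.
#' @param coding_offset integer origin used on disk (0 or 1).
#' @param n_cat number of categories `m` (default 4, the CES-D coding).
#' @return an object of class `response_matrix`.
#' @export
response_matrix <- function(values, item_ids = colnames(values), groups = NULL,
                            coding_offset = 0L, n_cat = 4L) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(item_ids)) item_ids <- paste0("q", seq_len(ncol(values)))
  stopifnot(length(item_ids) == ncol(values))
  if (nrow(values) < 2L) stop("need at least 2 persons", call. = FALSE)
  if (anyNA(values) || any(values < 0L) || any(values >= n_cat))
    stop(sprintf("responses must be complete integers in 0..%d", n_cat - 1L),
         call. = FALSE)
  if (!is.null(groups)) {
    groups <- as.data.frame(groups)
    stopifnot(nrow(groups) == nrow(values))
  }
  colnames(values) <- item_ids
  structure(list(values = values, item_ids = as.character(item_ids),
                 groups = groups, coding_offset = as.integer(coding_offset),
                 n_cat = as.integer(n_cat)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d persons x %d items, categories 0..%d\n",
              nrow(x$values), ncol(x$values), x$n_cat - 1L))
  if (!is.null(x$groups))
    cat("  covariates:", paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Read a response matrix from a delimited text file
#'
#' The file must have a header row of item labels (`q1`, `q2`, ...).  Columns
#' that are not named like items (e.g. `gender`, `age`) are carried along as
#' per-person covariates.  Raw scores are shifted by `coding_offset` so that
#' internal coding is always `0..n_cat-1`; rows containing missing or
#' out-of-range entries are dropped with a warning (listwise deletion --
#' complete cases only, never imputed).
#'
#' @param path file path.
#' @param coding_offset on-disk origin, 0 or 1 (default 1: categories stored
#'   as 1..4).
#' @param n_cat number of response categories (default 4).
#' @param item_cols optional explicit item column names; by default every
#'   column matching `^q[0-9]+$`.
#' @param sep field separator.
#' @return a `response_matrix`.
#' @export
read_responses <- function(path, coding_offset = 1L, n_cat = 4L,
                           item_cols = NULL, sep = ",") {
  stopifnot(coding_offset %in% c(0L, 1L))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (is.null(item_cols)) item_cols <- grep("^q[0-9]+$", names(df), value = TRUE)
  if (length(item_cols) == 0L)
    stop("no item columns found (expected header names like q1, q2, ...)",
         call. = FALSE)
  raw <- df[, item_cols, drop = FALSE]
  num <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  num <- rbind(num)  # keep matrix shape for 1-row files
  if (any(abs(num - round(num)) > 0, na.rm = TRUE))
    stop("non-integer response cell", call. = FALSE)
  vals <- round(num) - coding_offset
  ok <- apply(vals, 1L, function(r) all(!is.na(r) & r >= 0 & r < n_cat))
  if (!any(ok)) stop("all rows dropped: no complete in-range responses",
                     call. = FALSE)
  if (any(!ok))
    warning(sprintf("dropped %d of %d rows with missing or out-of-range responses",
                    sum(!ok), length(ok)), call. = FALSE)
  extra <- setdiff(names(df), item_cols)
  groups <- if (length(extra)) df[ok, extra, drop = FALSE] else NULL
  if (!is.null(groups)) rownames(groups) <- NULL
  response_matrix(vals[ok, , drop = FALSE], item_ids = item_cols,
                  groups = groups, coding_offset = coding_offset, n_cat = n_cat)
}

#' Write a response matrix to a delimited text file
#'
#' Values are written back on the on-disk coding recorded in the object
#' (internal value + `coding_offset`), so write/read round-trips are exact.
#'
#' @param data a `response_matrix`.
#' @param path file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "response_matrix"))
  out <- as.data.frame(data$values + data$coding_offset)
  if (!is.null(data$groups)) out <- cbind(out, data$groups)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
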