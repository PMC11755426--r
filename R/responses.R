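#' Construct a response matrix
#'
#' Wide-format integer responses, persons in rows and items in columns,
#' categories coded 0..K.  Missing responses are rejected: the marginal
#' likelihood implemented here is defined for complete response patterns
#' only.
#'
#' @param data Matrix or data frame of integer responses; column names are
#'   item identifiers.
#' @param n_categories Number of categories K + 1; defaults to
#'   \code{max(data) + 1}.
#' @param item_map Optional item-to-trait assignment (integer vector named
#'   by item, or data frame with `item_id`/`trait_id`), carried as an
#'   attribute for convenience.
#' @return Integer matrix of class `mnrm_responses` with attributes
#'   `n_categories` and (optionally) `item_map`.
#' @export
mnrm_responses <- function(data, n_categories = NULL, item_map = NULL) {
  x <- as.matrix(data)
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("response matrix must have at least one person and one item",
         call. = FALSE)
  if (anyNA(x))
    stop("missing responses are not supported", call. = FALSE)
  if (!is.numeric(x) || any(x != round(x)))
    stop("responses must be integer category codes", call. = FALSE)
  storage.mode(x) <- "integer"
  if (any(x < 0L))
    stop("categories are coded 0..K; negative value found", call. = FALSE)
  if (is.null(n_categories)) n_categories <- max(x) + 1L
  n_categories <- check_count(n_categories, "n_categories")
  bad <- which(x > n_categories - 1L, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("category out of range 0..", n_categories - 1L, " at row ",
         bad[1L, 1L], ", item ", colnames(x)[bad[1L, 2L]], call. = FALSE)
  structure(x, n_categories = n_categories, item_map = item_map,
            class = c("mnrm_responses", class(x)))
}

#' @export
print.mnrm_responses <- function(x, ...) {
  cat("Response matrix:", nrow(x), "persons x", ncol(x), "items, categories 0..",
      attr(x, "n_categories") - 1L, "\n", sep = " ")
  invisible(x)
}

# internal: coerce to validated integer matrix + K1
as_responses <- function(responses, n_categories = NULL) {
  if (!inherits(responses, "mnrm_responses"))
    responses <- mnrm_responses(responses, n_categories = n_categories)
  responses
}
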