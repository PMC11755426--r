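#' Scoring-weight vector of a substantive trait dimension
#'
#' Ordinal items measuring a substantive trait receive equally spaced
#' scoring weights \code{0, 1, ..., K}, encoding the assumption that higher
#' trait levels trigger higher response categories.
#'
#' @param n_categories Number of response categories (K + 1), at least 2.
#' @return Numeric vector \code{0:(n_categories - 1)}.
#' @seealso [ers_weights()], [mrs_weights()], [scoring_weights()]
#' @export
#' @examples
#' trait_weights(7)
trait_weights <- function(n_categories) {
  n_categories <- check_count(n_categories, "n_categories")
  if (n_categories < 2L)
    stop("a rating scale needs at least 2 categories", call. = FALSE)
  as.numeric(seq_len(n_categories) - 1L)
}

#' Scoring-weight vector of the extreme response style (ERS) dimension
#'
#' ERS is the content-independent preference for the endpoint categories:
#' weight 1 on the first and last category, 0 elsewhere.
#'
#' @inheritParams trait_weights
#' @return Numeric vector of length \code{n_categories}.
#' @export
#' @examples
#' ers_weights(7)
ers_weights <- function(n_categories) {
  n_categories <- check_count(n_categories, "n_categories")
  if (n_categories < 3L)
    stop("ERS weights are degenerate with fewer than 3 categories: ",
         "a constant weight vector cancels from the model", call. = FALSE)
  w <- numeric(n_categories)
  w[c(1L, n_categories)] <- 1
  w
}

#' Scoring-weight vector of the midscale response style (MRS) dimension
#'
#' MRS is the preference for the scale midpoint: weight 1 on the middle
#' category, 0 elsewhere.  Requires an odd number of categories.
#'
#' @inheritParams trait_weights
#' @return Numeric vector of length \code{n_categories}.
#' @export
#' @examples
#' mrs_weights(7)
mrs_weights <- function(n_categories) {
  n_categories <- check_count(n_categories, "n_categories")
  if (n_categories < 3L || n_categories %% 2L == 0L)
    stop("MRS weights need an odd number of categories (>= 3): ",
         "an even scale has no single midpoint", call. = FALSE)
  w <- numeric(n_categories)
  w[(n_categories + 1L) / 2L] <- 1
  w
}

#' Rescale social-desirability ratings into faking scoring weights
#'
#' Mean desirability ratings collected on a pilot instrument are mapped
#' linearly onto \[0, 1\] so that the faking dimension shares the weight
#' metric of the response-style dimensions.  By default the instrument's
#' global scale bounds are used for every item, which preserves
#' between-item differences in desirability level; per-item min/max
#' scaling is available via \code{per_item = TRUE} but equalises items
#' whose trajectories differ only in level.
#'
#' @param ratings A `desirability_ratings` object from
#'   [read_desirability()] or [desirability_ratings()], or a numeric
#'   vector/matrix of mean ratings.
#' @param bounds Length-2 numeric \code{c(lo, hi)} giving the rating-scale
#'   bounds; taken from the object when available.
#' @param per_item If \code{TRUE}, rescale each item by its own min/max
#'   instead of the global bounds.
#' @return Numeric vector or items-by-categories matrix of weights in
#'   \[0, 1\].
#' @export
#' @examples
#' rescale_desirability(c(1, 4, 7), bounds = c(1, 7))
rescale_desirability <- function(ratings, bounds = NULL, per_item = FALSE) {
  if (inherits(ratings, "desirability_ratings")) {
    if (is.null(bounds)) bounds <- ratings$bounds
    ratings <- ratings$ratings
  }
  if (is.null(bounds))
    stop("rating-scale bounds are required", call. = FALSE)
  if (length(bounds) != 2L || !all(is.finite(bounds)))
    stop("bounds must be two finite numbers", call. = FALSE)
  lo <- bounds[1L]; hi <- bounds[2L]
  if (hi <= lo)
    stop("rating-scale bounds have zero or negative range", call. = FALSE)
  if (any(!is.finite(ratings)))
    stop("ratings contain non-finite values", call. = FALSE)
  if (any(ratings < lo | ratings > hi))
    stop("ratings fall outside the declared scale bounds", call. = FALSE)
  if (per_item && is.matrix(ratings)) {
    t(apply(ratings, 1L, function(r) {
      rng <- range(r)
      if (rng[2L] == rng[1L]) rep(0.5, length(r))
      else (r - rng[1L]) / (rng[2L] - rng[1L])
    }))
  } else {
    (ratings - lo) / (hi - lo)
  }
}

#' Container for per-item, per-category mean desirability ratings
#'
#' @param ratings Items-by-categories numeric matrix of mean ratings
#'   (categories 0..K in column order); rownames are item identifiers.
#' @param bounds Length-2 numeric \code{c(lo, hi)}: bounds of the pilot
#'   rating instrument.
#' @return An object of class `desirability_ratings`.
#' @export
desirability_ratings <- function(ratings, bounds) {
  ratings <- as.matrix(ratings)
  if (length(bounds) != 2L || bounds[2L] <= bounds[1L])
    stop("bounds must be c(lo, hi) with lo < hi", call. = FALSE)
  if (any(!is.finite(ratings)))
    stop("ratings contain missing or non-finite values", call. = FALSE)
  if (any(ratings < bounds[1L] | ratings > bounds[2L]))
    stop("ratings fall outside the declared scale bounds", call. = FALSE)
  if (is.null(rownames(ratings)))
    rownames(ratings) <- paste0("item", seq_len(nrow(ratings)))
  structure(list(ratings = ratings, bounds = as.numeric(bounds)),
            class = "desirability_ratings")
}

#' Assemble per-item scoring-weight matrices
#'
#' Builds the D x (K+1) scoring-weight matrix of every item: one row per
#' substantive trait (the item's own trait carries \code{0:K}, the others
#' are zero), optionally an ERS row, an MRS row, and a faking row holding
#' the item's rescaled desirability weights.  Row order is fixed as
#' traits, ERS, MRS, faking.
#'
#' @param item_map Item-to-trait assignment: an integer vector of trait
#'   indices (1..n_traits), optionally named with item identifiers, or a
#'   data frame with columns `item_id` and `trait_id`.
#' @param n_categories Number of response categories (K + 1).
#' @param n_traits Number of substantive trait dimensions; defaults to
#'   \code{max(trait index)}.
#' @param ers,mrs Include the response-style dimensions?
#' @param faking Items-by-categories matrix (or per-item list) of faking
#'   weights in \[0, 1\], e.g. from [rescale_desirability()]; `NULL` omits
#'   the faking dimension.
#' @return An object of class `scoring_weights`: list with elements
#'   `items`, `roles` (per-dimension tags `"trait<t>"`, `"ers"`, `"mrs"`,
#'   `"faking"`), `trait` (item-to-trait index), `n_categories`, and
#'   `weights` (named list of D x (K+1) matrices).
#' @export
#' @examples
#' sw <- scoring_weights(c(a = 1, b = 2), n_categories = 7, n_traits = 2)
#' sw$weights$a
scoring_weights <- function(item_map, n_categories, n_traits = NULL,
                            ers = TRUE, mrs = TRUE, faking = NULL) {
  if (is.data.frame(item_map)) {
    if (!all(c("item_id", "trait_id") %in% names(item_map)))
      stop("item_map data frame needs columns item_id and trait_id",
           call. = FALSE)
    ids <- as.character(item_map$item_id)
    trait <- as.integer(item_map$trait_id)
  } else {
    trait <- as.integer(item_map)
    ids <- names(item_map)
    if (is.null(ids)) ids <- paste0("item", seq_along(trait))
  }
  if (anyDuplicated(ids))
    stop("duplicate item identifiers in item_map", call. = FALSE)
  if (is.null(n_traits)) n_traits <- max(trait)
  n_traits <- check_count(n_traits, "n_traits")
  if (any(is.na(trait)) || any(trait < 1L) || any(trait > n_traits))
    stop("item_map assigns an item to an unknown trait", call. = FALSE)
  n_categories <- check_count(n_categories, "n_categories")
  K1 <- n_categories
  I <- length(trait)

  if (!is.null(faking)) {
    if (is.list(faking) && !is.data.frame(faking))
      faking <- do.call(rbind, faking)
    faking <- as.matrix(faking)
    if (nrow(faking) != I || ncol(faking) != K1)
      stop("faking weights must be an items x categories matrix matching ",
           "item_map and n_categories", call. = FALSE)
    if (any(!is.finite(faking)) || any(faking < 0 | faking > 1))
      stop("faking weights must lie in [0, 1]", call. = FALSE)
  }

  roles <- paste0("trait", seq_len(n_traits))
  if (ers) roles <- c(roles, "ers")
  if (mrs) roles <- c(roles, "mrs")
  if (!is.null(faking)) roles <- c(roles, "faking")
  D <- length(roles)

  tw <- trait_weights(K1)
  ew <- if (ers) ers_weights(K1) else NULL
  mw <- if (mrs) mrs_weights(K1) else NULL

  weights <- vector("list", I)
  names(weights) <- ids
  for (i in seq_len(I)) {
    S <- matrix(0, D, K1, dimnames = list(roles, NULL))
    S[trait[i], ] <- tw
    if (ers) S["ers", ] <- ew
    if (mrs) S["mrs", ] <- mw
    if (!is.null(faking)) S["faking", ] <- faking[i, ]
    weights[[i]] <- S
  }
  names(trait) <- ids
  structure(list(items = ids, roles = roles, trait = trait,
                 n_categories = K1, weights = weights),
            class = "scoring_weights")
}

#' Validate a scoring-weight set
#'
#' Checks the structural invariants: per-item D x (K+1) matrices, zero
#' rows for foreign traits, the \code{0:K} trait row, the endpoint/midpoint
#' response-style rows, and faking weights in \[0, 1\].
#'
#' @param x A `scoring_weights` object.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_scoring_weights <- function(x) {
  stopifnot(inherits(x, "scoring_weights"))
  K1 <- x$n_categories
  D <- length(x$roles)
  tr_idx <- grep("^trait", x$roles)
  for (id in x$items) {
    S <- x$weights[[id]]
    if (!is.matrix(S) || nrow(S) != D || ncol(S) != K1)
      stop("item ", id, ": weight matrix has wrong shape", call. = FALSE)
    own <- x$trait[[id]]
    for (t in seq_along(tr_idx)) {
      row <- S[tr_idx[t], ]
      if (t == own) {
        if (!isTRUE(all.equal(row, trait_weights(K1))))
          stop("item ", id, ": own-trait row is not 0:K", call. = FALSE)
      } else if (any(row != 0)) {
        stop("item ", id, ": foreign trait row not all zero", call. = FALSE)
      }
    }
    if ("ers" %in% x$roles &&
        !isTRUE(all.equal(S["ers", ], ers_weights(K1))))
      stop("item ", id, ": malformed ERS row", call. = FALSE)
    if ("mrs" %in% x$roles &&
        !isTRUE(all.equal(S["mrs", ], mrs_weights(K1))))
      stop("item ", id, ": malformed MRS row", call. = FALSE)
    if ("faking" %in% x$roles) {
      fw <- S["faking", ]
      if (any(fw < 0 | fw > 1))
        stop("item ", id, ": faking weights outside [0, 1]", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.scoring_weights <- function(x, ...) {
  cat("Scoring-weight set:", length(x$items), "items,",
      x$n_categories, "categories\n")
  cat("Dimensions (", length(x$roles), "): ",
      paste(x$roles, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# internal: positive integer scalar check
check_count <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < 1)
    stop(what, " must be a positive integer", call. = FALSE)
  as.integer(x)
}

# internal: dimension x (K+1) weight array (D x K1 x I cube) for the C++
# routines, in item order of the response matrix
weight_cube <- function(weights, items) {
  D <- length(weights$roles); K1 <- weights$n_categories
  arr <- array(0, dim = c(D, K1, length(items)))
  for (j in seq_along(items)) {
    S <- weights$weights[[items[j]]]
    if (is.null(S)) stop("no scoring weights for item ", items[j],
                         call. = FALSE)
    arr[, , j] <- S
  }
  arr
}
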