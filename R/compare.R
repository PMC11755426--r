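#' Count the free parameters of an MNRM configuration
#'
#' Free parameters are item slopes (one per active loading per item when
#' `constraints = "free"`, one per dimension when `"equal"`), K intercepts
#' per item (the first category's intercept is fixed at 0), and the
#' D(D-1)/2 latent correlations.
#'
#' @param weights Optional `scoring_weights` object or `mnrm` fit; when
#'   supplied, `n_items`, `n_categories`, `n_dims`, and the loading
#'   pattern are taken from it.
#' @param constraints `"free"` or `"equal"` slopes.
#' @param n_items,n_categories,n_dims Explicit configuration (used when
#'   `weights` is `NULL`).
#' @param loadings_per_item Number of dimensions each item loads on
#'   (scalar or per-item vector), e.g. 4 for own trait + ERS + MRS +
#'   faking.
#' @return Integer total with attribute `breakdown` =
#'   `c(slopes, intercepts, covariances)`.
#' @export
#' @examples
#' count_free_parameters(n_items = 48, n_categories = 7, n_dims = 8,
#'                       loadings_per_item = 4)  # 508
count_free_parameters <- function(weights = NULL,
                                  constraints = c("free", "equal"),
                                  n_items = NULL, n_categories = NULL,
                                  n_dims = NULL, loadings_per_item = NULL) {
  constraints <- match.arg(constraints)
  if (inherits(weights, "mnrm")) {
    constraints <- weights$constraints
    weights <- weights$weights
  }
  if (inherits(weights, "scoring_weights")) {
    n_items <- length(weights$items)
    n_categories <- weights$n_categories
    n_dims <- length(weights$roles)
    cube <- weight_cube(weights, weights$items)
    loadings_per_item <- vapply(seq_len(n_items), function(i)
      sum(apply(cube[, , i, drop = FALSE], 1L,
                function(r) diff(range(r)) > 0)), 0L)
  }
  n_items <- check_count(n_items, "n_items")
  n_categories <- check_count(n_categories, "n_categories")
  n_dims <- check_count(n_dims, "n_dims")
  slopes <- if (constraints == "free") sum(rep_len(loadings_per_item,
                                                   n_items))
            else n_dims
  intercepts <- n_items * (n_categories - 1L)
  covariances <- n_dims * (n_dims - 1L) / 2L
  structure(as.integer(slopes + intercepts + covariances),
            breakdown = c(slopes = as.integer(slopes),
                          intercepts = as.integer(intercepts),
                          covariances = as.integer(covariances)))
}

#' Likelihood-ratio test of two nested MH-RM fits
#'
#' Both fits must come from the same data and carry marginal
#' log-likelihoods computed with the same method (and seed, if
#' stochastic); the statistic is \eqn{2(\ell_{full} - \ell_{restricted})}
#' floored at 0 with degrees of freedom equal to the parameter-count
#' difference.
#'
#' @param restricted,full `mnrm` fits (or lists with `loglik`, `npar`,
#'   `N`, `loglik_method`).
#' @return List of class `mnrm_lrtest`: `statistic`, `df`, `p.value`.
#' @export
lr_test <- function(restricted, full) {
  df <- full$npar - restricted$npar
  if (df <= 0)
    stop("models are not nested: the full model must have more free ",
         "parameters", call. = FALSE)
  if (!is.null(restricted$N) && !is.null(full$N) &&
      restricted$N != full$N)
    stop("fits are based on different numbers of persons", call. = FALSE)
  if (!is.null(restricted$loglik_method) &&
      !identical(restricted$loglik_method, full$loglik_method))
    stop("marginal log-likelihoods use different methods; recompute with ",
         "a common method before testing", call. = FALSE)
  stat <- max(0, 2 * (full$loglik - restricted$loglik))
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "mnrm_lrtest")
}

#' @export
print.mnrm_lrtest <- function(x, ...) {
  cat("Likelihood-ratio test: X2(", x$df, ") = ",
      formatC(x$statistic, format = "f", digits = 2), ", p = ",
      format.pval(x$p.value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Information criteria of a fit
#'
#' AIC = -2 logLik + 2p and BIC = -2 logLik + p log N, with p the free
#' parameter count and N the number of persons.
#'
#' @param fit An `mnrm` fit (or list with `loglik`, `npar`, `N`).
#' @return Named numeric vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(fit) {
  c(AIC = -2 * fit$loglik + 2 * fit$npar,
    BIC = -2 * fit$loglik + fit$npar * log(fit$N))
}

#' Select among candidate fits
#'
#' `"aic"`/`"bic"` pick the criterion minimiser.  `"lr"` walks the
#' candidates in nesting order (ascending parameter count) and keeps
#' accepting the larger model while the adjacent likelihood-ratio test is
#' significant at `alpha`, stopping at the first non-significant step.
#'
#' @param fits List of `mnrm` fits of the same data.
#' @param criterion `"lr"`, `"aic"`, or `"bic"`.
#' @param alpha Significance level for the LR chain.
#' @return Index of the selected fit within `fits`.
#' @export
select_model <- function(fits, criterion = c("lr", "aic", "bic"),
                         alpha = 0.05) {
  criterion <- match.arg(criterion)
  if (length(fits) == 0L) stop("no candidate fits", call. = FALSE)
  if (length(fits) == 1L) return(1L)
  if (criterion == "lr") {
    ord <- order(vapply(fits, `[[`, 0, "npar"))
    cur <- 1L
    for (j in seq_along(ord)[-1L]) {
      lt <- lr_test(fits[[ord[cur]]], fits[[ord[j]]])
      if (lt$p.value < alpha) cur <- j else break
    }
    ord[cur]
  } else {
    ic <- vapply(fits, function(f)
      information_criteria(f)[[toupper(criterion)]], 0)
    which.min(ic)
  }
}
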