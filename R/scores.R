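#' Maximum a-posteriori (MAP) person scores
#'
#' Scores response patterns by maximising
#' \eqn{\log p(Y_n \mid \theta) + \log \phi(\theta; 0, \hat\Sigma)}
#' per person with a Newton ascent from \eqn{\theta = 0}, holding the item
#' parameters fixed.  Because the item parameters are treated as fixed, a
#' fit obtained in one sample (e.g. a high-stakes applicant pool) can score
#' a fresh sample (e.g. low-stakes incumbents) on the same scale: pass the
#' new responses as `responses`.
#'
#' @param object An `mnrm` fit, or a list with elements `weights`
#'   (`scoring_weights`), `alpha`, `gamma`, `Sigma`.
#' @param responses Response matrix to score; items must be covered by the
#'   parameters.
#' @param tol Newton convergence tolerance.
#' @param maxit Newton iteration cap; persons that fail to converge are
#'   flagged, not dropped.
#' @return N x D matrix of class `mnrm_scores` with dimension roles as
#'   column names and a logical attribute `converged` per person.
#' @export
map_scores <- function(object, responses, tol = 1e-8, maxit = 100L) {
  if (inherits(object, "mnrm")) {
    pars <- list(weights = object$weights,
                 alpha = object$coefficients$alpha,
                 gamma = object$coefficients$gamma, Sigma = object$Sigma)
    pars$weights$items <- rownames(pars$alpha)
  } else {
    pars <- object
    stopifnot(inherits(pars$weights, "scoring_weights"))
  }
  responses <- as_responses(responses, pars$weights$n_categories)
  items <- colnames(responses)
  fit_items <- if (!is.null(rownames(pars$alpha))) rownames(pars$alpha)
               else pars$weights$items
  idx <- match(items, fit_items)
  if (anyNA(idx))
    stop("no item parameters for: ",
         paste(items[is.na(idx)], collapse = ", "), call. = FALSE)
  cube <- weight_cube(pars$weights, items)
  alpha <- as.matrix(pars$alpha)[idx, , drop = FALSE]
  gamma <- as.matrix(pars$gamma)[idx, , drop = FALSE]
  check_corr(pars$Sigma)
  res <- cpp_map_scores(unclass(responses), cube, alpha, gamma,
                        as.matrix(pars$Sigma), tol, as.integer(maxit))
  th <- res$theta
  colnames(th) <- pars$weights$roles
  if (any(res$converged == 0L))
    warning(sum(res$converged == 0L), " person(s) flagged non-converged",
            call. = FALSE)
  structure(th, converged = res$converged == 1L, class = c("mnrm_scores",
                                                           class(th)))
}

#' @export
print.mnrm_scores <- function(x, ...) {
  cat("MAP person scores:", nrow(x), "persons x", ncol(x), "dimensions\n")
  print(utils::head(unclass(x)))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
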