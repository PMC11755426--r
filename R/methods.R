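#' @export
print.mnrm <- function(x, ...) {
  cat("Multidimensional nominal response model (MH-RM fit)\n")
  cat("  dimensions:", paste(x$roles, collapse = ", "), "\n")
  cat("  persons:", x$N, " items:", x$I, " categories:", x$n_categories, "\n")
  cat("  slopes:", x$constraints, " free parameters:", x$npar, "\n")
  cat("  marginal logLik (", x$loglik_method, "): ",
      formatC(x$loglik, format = "f", digits = 1), "\n", sep = "")
  cat("  cycles:", x$cycles,
      if (x$converged) "(converged)"
      else if (!is.na(x$drift))
        sprintf("(averaged estimates, residual drift %.3f)", x$drift)
      else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.mnrm <- function(object, ...) {
  a <- object$coefficients$alpha
  act <- object$amask == 1L
  slope_tab <- t(vapply(seq_along(object$roles), function(d) {
    v <- a[act[, d], d]
    c(n_items = sum(act[, d]), mean = mean(v), sd = stats::sd(v),
      min = min(v), max = max(v))
  }, numeric(5)))
  rownames(slope_tab) <- object$roles
  ic <- information_criteria(object)
  out <- list(call = object$call, slopes = slope_tab, Sigma = object$Sigma,
              loglik = object$loglik, loglik_method = object$loglik_method,
              npar = object$npar, N = object$N, AIC = ic[["AIC"]],
              BIC = ic[["BIC"]], converged = object$converged,
              cycles = object$cycles, constraints = object$constraints)
  class(out) <- "summary.mnrm"
  out
}

#' @export
print.summary.mnrm <- function(x, digits = 3, ...) {
  cat("Call: "); print(x$call)
  cat("\nSlope summary by dimension (", x$constraints, " slopes):\n", sep = "")
  print(round(x$slopes, digits))
  cat("\nLatent correlation matrix:\n")
  print(round(x$Sigma, digits))
  cat("\nMarginal logLik (", x$loglik_method, "): ",
      formatC(x$loglik, format = "f", digits = 1),
      " on ", x$npar, " parameters, N = ", x$N, "\n", sep = "")
  cat("AIC: ", formatC(x$AIC, format = "f", digits = 1),
      "  BIC: ", formatC(x$BIC, format = "f", digits = 1), "\n", sep = "")
  cat("Convergence:", if (x$converged) "yes" else "NO", "after",
      x$cycles, "cycles\n")
  invisible(x)
}

#' @export
coef.mnrm <- function(object, ...) object$coefficients

#' @export
logLik.mnrm <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$N,
            method = object$loglik_method, class = "logLik")
}

#' Convergence-trace plot of an MH-RM fit
#'
#' @param x An `mnrm` fit.
#' @param ... Passed to [graphics::plot.default()].
#' @export
plot.mnrm <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr[, "cycle"], pmax(tr[, "max_change"], 1e-12), log = "y",
                 type = "l", xlab = "MH-RM cycle",
                 ylab = "max |parameter change|", ...)
  graphics::abline(v = x$control$burnin, lty = 2)
  graphics::abline(h = x$control$tol, lty = 3)
  invisible(x)
}

#' Simulate response matrices from a fitted model
#'
#' Draws person parameters from N(0, Sigma-hat) and responses from the
#' fitted item parameters.
#'
#' @param object An `mnrm` fit.
#' @param nsim Number of response matrices.
#' @param seed Optional seed.
#' @param n Persons per simulated matrix (defaults to the fitted N).
#' @param ... Unused.
#' @return List of `mnrm_responses` matrices (a single matrix if
#'   `nsim = 1`).
#' @export
simulate.mnrm <- function(object, nsim = 1, seed = NULL, n = object$N, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(s) {
    Theta <- rmvnorm_chol(n, object$Sigma)
    sw <- object$weights
    sw$items <- rownames(object$coefficients$alpha)
    sample_responses(Theta, sw, object$coefficients$alpha,
                     object$coefficients$gamma)
  })
  if (nsim == 1) out[[1L]] else out
}

#' MAP person scores from a fitted model
#'
#' @param object An `mnrm` fit.
#' @param newdata Response matrix to score.
#' @param ... Passed to [map_scores()].
#' @return `mnrm_scores` matrix of MAP estimates.
#' @export
predict.mnrm <- function(object, newdata, ...) {
  map_scores(object, newdata, ...)
}

#' Likelihood-ratio chain over nested MH-RM fits
#'
#' Orders the supplied fits by free-parameter count and performs adjacent
#' likelihood-ratio tests, mirroring the usual model-building sequence
#' (traits, then ERS, then MRS, then faking).
#'
#' @param object An `mnrm` fit.
#' @param ... Further `mnrm` fits of nested models on the same data.
#' @return Data frame of class `anova`.
#' @export
anova.mnrm <- function(object, ...) {
  fits <- c(list(object), Filter(function(z) inherits(z, "mnrm"),
                                 list(...)))
  if (length(fits) < 2L)
    stop("anova.mnrm needs at least two fits to compare", call. = FALSE)
  fits <- fits[order(vapply(fits, `[[`, 0, "npar"))]
  k <- length(fits)
  stat <- df <- p <- rep(NA_real_, k)
  for (j in 2:k) {
    lt <- lr_test(fits[[j - 1L]], fits[[j]])
    stat[j] <- lt$statistic; df[j] <- lt$df; p[j] <- lt$p.value
  }
  out <- data.frame(
    npar = vapply(fits, `[[`, 0, "npar"),
    logLik = vapply(fits, `[[`, 0, "loglik"),
    AIC = vapply(fits, function(f) information_criteria(f)[["AIC"]], 0),
    BIC = vapply(fits, function(f) information_criteria(f)[["BIC"]], 0),
    Chisq = stat, Df = df, `Pr(>Chisq)` = p, check.names = FALSE)
  rownames(out) <- vapply(fits, function(f)
    paste(f$roles, collapse = "+"), "")
  structure(out, class = c("anova", "data.frame"),
            heading = "Likelihood-ratio tests of nested MNRM fits")
}

# internal: MVN(0, Sigma) draws via Cholesky
rmvnorm_chol <- function(n, Sigma, mean = NULL) {
  D <- ncol(Sigma)
  Z <- matrix(stats::rnorm(n * D), n, D)
  X <- Z %*% chol(Sigma)
  if (!is.null(mean)) X <- sweep(X, 2L, mean, "+")
  X
}
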