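#' Control parameters for the MH-RM estimator
#'
#' Tuning constants of the stochastic-approximation fit.  The defaults are
#' the package's standard schedule: a constant-gain burn-in stage during
#' which the per-dimension Metropolis proposal scales adapt towards an
#' acceptance rate in `accept_target`, followed by a Robbins-Monro stage
#' with gain \eqn{1/t^{\code{gain_power}}} and a sliding-window stopping
#' rule on the maximum absolute parameter change.
#'
#' @param burnin Constant-gain burn-in cycles.
#' @param max_cycles Hard cap on total cycles (burn-in included).
#' @param stage2_max Robbins-Monro cycles after burn-in; reaching this cap
#'   is a designed stop, with estimates taken as the Polyak-Ruppert
#'   average of the final \code{stage2_max / 2} cycles.
#' @param polyak Return suffix-averaged estimates (recommended: averaging
#'   the decreasing-gain iterates removes most of the stochastic
#'   approximation noise)?
#' @param tol Convergence threshold on the windowed max parameter change.
#' @param window Number of consecutive cycles that must fall below `tol`.
#' @param gain_power Robbins-Monro gain decay exponent.
#' @param burnin_gain Constant gain used during burn-in (below 1: full
#'   Newton steps on single-imputation data are unstable).
#' @param mh_sweeps Metropolis sweeps per cycle after burn-in.
#' @param mh_sweeps_burnin Metropolis sweeps per cycle during burn-in.
#' @param accept_target Length-2 acceptance-rate band for proposal
#'   adaptation (frozen after burn-in).
#' @param init_slope Starting value for active slopes.
#' @param ridge Ridge added to complete-data information before inversion.
#' @param max_step Elementwise cap on a single parameter update.
#' @param ll_method Marginal log-likelihood method stored with the fit
#'   (see [marginal_loglik()]).
#' @param ll_draws Importance-sampling draws if `ll_method = "importance"`.
#' @param ll_nodes Quadrature nodes per dimension if
#'   `ll_method = "quadrature"`.
#' @param verbose Print cycle diagnostics.
#' @return List of class `mnrm_control`.
#' @export
mnrm_control <- function(burnin = 100L, max_cycles = 2000L,
                         stage2_max = 300L, polyak = TRUE, tol = 1e-3,
                         window = 3L, gain_power = 0.75, burnin_gain = 0.25,
                         mh_sweeps = 3L, mh_sweeps_burnin = 5L,
                         accept_target = c(0.23, 0.45), init_slope = 0.5,
                         ridge = 1e-6, max_step = 0.25,
                         ll_method = c("laplace", "importance", "quadrature"),
                         ll_draws = 200L, ll_nodes = 21L, verbose = FALSE) {
  ctl <- list(burnin = check_count(burnin, "burnin"),
              max_cycles = check_count(max_cycles, "max_cycles"),
              stage2_max = check_count(stage2_max, "stage2_max"),
              polyak = isTRUE(polyak),
              tol = tol, window = check_count(window, "window"),
              gain_power = gain_power, burnin_gain = burnin_gain,
              mh_sweeps = check_count(mh_sweeps, "mh_sweeps"),
              mh_sweeps_burnin = check_count(mh_sweeps_burnin,
                                             "mh_sweeps_burnin"),
              accept_target = accept_target, init_slope = init_slope,
              ridge = ridge, max_step = max_step,
              ll_method = match.arg(ll_method),
              ll_draws = check_count(ll_draws, "ll_draws"),
              ll_nodes = check_count(ll_nodes, "ll_nodes"),
              verbose = isTRUE(verbose))
  if (ctl$max_cycles <= ctl$burnin)
    stop("max_cycles must exceed burnin", call. = FALSE)
  if (length(ctl$accept_target) != 2L ||
      ctl$accept_target[1L] >= ctl$accept_target[2L])
    stop("accept_target must be an increasing pair", call. = FALSE)
  class(ctl) <- "mnrm_control"
  ctl
}

#' Fit the multidimensional nominal response model
#'
#' Marginal maximum-likelihood estimation by the Metropolis-Hastings
#' Robbins-Monro (MH-RM) algorithm: each cycle imputes person parameters
#' by component-wise random-walk Metropolis given the current item
#' parameters, then takes a gain-damped Newton step on the complete-data
#' log-likelihood of the item parameters (using a Robbins-Monro average of
#' the complete-data information) and a stochastic-approximation update of
#' the latent correlation matrix.  Identification follows the usual
#' constraints: latent means 0, latent variances 1, and the first
#' category's intercept 0 for every item.
#'
#' With `constraints = "equal"` all items share one slope per dimension;
#' with `"free"` every item has its own slope on each dimension it loads
#' on (its own trait plus every included response-bias dimension).
#' Response categories never observed for an item have their intercept
#' pinned at -30 (probability effectively zero) and are excluded from
#' estimation, with a warning.
#'
#' @param responses `mnrm_responses` matrix (or coercible); columns must
#'   match items of `weights`.
#' @param weights A `scoring_weights` object defining the latent
#'   dimensions and per-item scoring weights.
#' @param constraints `"free"` or `"equal"` item slopes within dimensions.
#' @param control A [mnrm_control()] list.
#' @param seed Integer seed; fixes every random draw of the fit, so two
#'   runs with identical inputs and seed are identical.
#' @param init Optional warm start: list with any of `alpha`, `gamma`,
#'   `Sigma` used as starting values (inactive loadings and fixed
#'   intercepts are re-imposed).
#' @return Object of class `mnrm` with components `coefficients` (list
#'   `alpha`, `gamma`), `Sigma`, `loglik` (method-tagged), `npar`, `N`,
#'   `trace`, `converged`, `weights`, `constraints`, `seed`, `control`.
#' @seealso [map_scores()], [lr_test()], [information_criteria()],
#'   [anova.mnrm()]
#' @export
mnrm <- function(responses, weights, constraints = c("free", "equal"),
                 control = mnrm_control(), seed = 1L, init = NULL) {
  constraints <- match.arg(constraints)
  stopifnot(inherits(weights, "scoring_weights"),
            inherits(control, "mnrm_control"))
  responses <- as_responses(responses, weights$n_categories)
  items <- colnames(responses)
  if (!all(items %in% weights$items))
    stop("responses contain items without scoring weights: ",
         paste(setdiff(items, weights$items), collapse = ", "),
         call. = FALSE)
  cube <- weight_cube(weights, items)
  Y <- unclass(responses)
  N <- nrow(Y); I <- ncol(Y)
  K1 <- weights$n_categories
  D <- length(weights$roles)
  cl <- match.call()
  set.seed(seed)

  # active loadings: a dimension enters an item iff its weight row is
  # non-constant (a constant row cancels from the softmax)
  amask <- matrix(0L, I, D)
  for (i in seq_len(I))
    for (d in seq_len(D))
      if (diff(range(cube[d, , i])) > 0) amask[i, d] <- 1L
  if (any(colSums(amask) == 0L))
    stop("dimension ", paste(weights$roles[colSums(amask) == 0L],
                             collapse = ", "),
         " has constant weights on every item and is not identified",
         call. = FALSE)

  # free intercepts: category observed at least once; gamma_0 fixed to 0
  gmask <- matrix(0L, I, K1)
  pinned <- 0L
  counts <- matrix(0, I, K1)
  for (i in seq_len(I))
    counts[i, ] <- tabulate(Y[, i] + 1L, nbins = K1)
  gmask[, -1L] <- 1L * (counts[, -1L, drop = FALSE] > 0)
  pinned <- sum(counts[, -1L] == 0)
  if (pinned > 0L)
    warning(pinned, " item categor", if (pinned == 1L) "y was" else "ies were",
            " never observed; their intercepts are pinned at -30",
            call. = FALSE)

  # initial values
  alpha <- amask * control$init_slope
  aeq <- rep(control$init_slope, D)          # shared slopes (equal mode)
  gamma <- log((counts + 0.5) / (counts[, 1L] + 0.5))
  gamma[, 1L] <- 0
  gamma[gmask == 0L & col(gamma) > 1L] <- -30
  Theta <- matrix(0, N, D)
  Sigma <- diag(D)
  if (!is.null(init)) {                       # warm start
    if (!is.null(init$alpha)) alpha <- amask * as.matrix(init$alpha)
    if (!is.null(init$gamma)) {
      gamma <- as.matrix(init$gamma)
      gamma[, 1L] <- 0
      gamma[gmask == 0L & col(gamma) > 1L] <- -30
    }
    if (!is.null(init$Sigma)) Sigma <- as.matrix(init$Sigma)
  }
  SigmaInv <- solve(Sigma)
  M <- Sigma                                  # RM second-moment average
  steps <- rep(1, D)

  Hbar <- NULL                                # RM-averaged information
  recent <- rep(Inf, control$window)
  trace <- list()
  converged <- FALSE
  stopped <- "max_cycles"
  drift <- NA_real_
  cycle <- 0L
  # Polyak-Ruppert suffix average over the second half of stage 2
  avg_from <- control$burnin + ceiling(control$stage2_max / 2)
  avg <- list(n = 0L, alpha = 0 * alpha, gamma = 0 * gamma, Sigma = 0 * Sigma,
              h1 = NULL, h1n = 0L)

  repeat {
    cycle <- cycle + 1L
    stage1 <- cycle <= control$burnin
    nsw <- if (stage1) control$mh_sweeps_burnin else control$mh_sweeps
    mh <- cpp_mh_sweeps(Y, cube, alpha, gamma, Theta, SigmaInv, steps, nsw)
    Theta <- mh$theta
    # identification by construction: the latent means are fixed at 0 and
    # variances at 1, so the imputed person parameters are centred and
    # unit-scaled per dimension each cycle.  Without this the sample
    # location/scale of the imputations and the item parameters co-drift
    # along nearly flat likelihood directions.
    cm <- colMeans(Theta)
    Theta <- sweep(Theta, 2L, cm, "-")
    csd <- sqrt(colMeans(Theta^2))
    csd[csd < 1e-8] <- 1
    Theta <- sweep(Theta, 2L, csd, "/")
    if (stage1) {
      lo <- control$accept_target[1L]; hi <- control$accept_target[2L]
      steps <- pmin(3, pmax(0.05, steps *
        ifelse(mh$accept < lo, 0.85, ifelse(mh$accept > hi, 1.15, 1))))
    }
      gain <- if (stage1) control$burnin_gain
            else (control$burnin_gain^(-1 / control$gain_power) +
                    cycle - control$burnin)^(-control$gain_power)

    derivs <- cpp_item_derivs(Y, cube, alpha, gamma, Theta, amask, gmask)
    old <- c(alpha[amask == 1L], gamma[gmask == 1L], Sigma[lower.tri(Sigma)])

    if (constraints == "free") {
      if (is.null(Hbar)) Hbar <- lapply(derivs, `[[`, "hess")
      for (i in seq_len(I)) {
        di <- derivs[[i]]
        Hbar[[i]] <- Hbar[[i]] + gain * (di$hess - Hbar[[i]])
        np <- length(di$grad)
        step <- tryCatch(
          solve(Hbar[[i]] + control$ridge * diag(np), di$grad),
          error = function(e) di$grad / (diag(Hbar[[i]]) + 1))
        step <- pmin(control$max_step, pmax(-control$max_step, gain * step))
        na <- length(di$adims)
        if (na > 0L) alpha[i, di$adims] <- alpha[i, di$adims] + step[seq_len(na)]
        if (length(di$gcats) > 0L)
          gamma[i, di$gcats] <- gamma[i, di$gcats] + step[na + seq_along(di$gcats)]
      }
    } else {
      # blockwise Newton: shared slopes aggregated over items, intercepts
      # per item
      if (is.null(Hbar))
        Hbar <- list(a = diag(D), g = lapply(derivs, function(d)
          d$hess[length(d$adims) + seq_along(d$gcats),
                 length(d$adims) + seq_along(d$gcats), drop = FALSE]))
      ga <- numeric(D); Ha <- matrix(0, D, D)
      for (i in seq_len(I)) {
        di <- derivs[[i]]
        na <- length(di$adims)
        if (na > 0L) {
          ga[di$adims] <- ga[di$adims] + di$grad[seq_len(na)]
          Ha[di$adims, di$adims] <- Ha[di$adims, di$adims] +
            di$hess[seq_len(na), seq_len(na), drop = FALSE]
        }
        gi <- di$grad[na + seq_along(di$gcats)]
        Hg <- di$hess[na + seq_along(di$gcats), na + seq_along(di$gcats),
                      drop = FALSE]
        Hbar$g[[i]] <- Hbar$g[[i]] + gain * (Hg - Hbar$g[[i]])
        ng <- length(gi)
        if (ng > 0L) {
          step <- tryCatch(
            solve(Hbar$g[[i]] + control$ridge * diag(ng), gi),
            error = function(e) gi / (diag(Hbar$g[[i]]) + 1))
          step <- pmin(control$max_step, pmax(-control$max_step, gain * step))
          gamma[i, di$gcats] <- gamma[i, di$gcats] + step
        }
      }
      Hbar$a <- Hbar$a + gain * (Ha - Hbar$a)
      astep <- tryCatch(solve(Hbar$a + control$ridge * diag(D), ga),
                        error = function(e) ga / (diag(Hbar$a) + 1))
      astep <- pmin(control$max_step, pmax(-control$max_step, gain * astep))
      aeq <- aeq + astep
      alpha <- amask * rep(aeq, each = I)
    }

    # latent correlation: stochastic approximation of the second-moment
    # matrix of imputed person parameters, projected to unit variances
    S <- crossprod(Theta) / N
    M <- M + gain * (S - M)
    Sigma <- stats::cov2cor(M)
    ev <- eigen(Sigma, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
      lam <- pmax(ev$values, 1e-6)
      Sigma <- stats::cov2cor(ev$vectors %*% (lam * t(ev$vectors)))
    }
    SigmaInv <- solve(Sigma)

    new <- c(alpha[amask == 1L], gamma[gmask == 1L], Sigma[lower.tri(Sigma)])
    maxch <- max(abs(new - old))
    recent <- c(recent[-1L], maxch)
    trace[[cycle]] <- c(cycle = cycle, gain = gain, max_change = maxch,
                        accept = mean(mh$accept))
    if (control$verbose && cycle %% 50L == 0L)
      message("cycle ", cycle, " gain ", signif(gain, 3),
              " max|d| ", signif(maxch, 3))
    if (control$polyak && cycle > avg_from) {
      avg$n <- avg$n + 1L
      avg$alpha <- avg$alpha + alpha
      avg$gamma <- avg$gamma + gamma
      avg$Sigma <- avg$Sigma + Sigma
      if (avg$n == ceiling(control$stage2_max / 4)) {
        avg$h1 <- avg; avg$h1n <- avg$n      # first-half snapshot
      }
    }
    if (!stage1 && all(recent < control$tol)) {
      converged <- TRUE; stopped <- "tol"; break
    }
    if (cycle - control$burnin >= control$stage2_max) {
      stopped <- "stage2_max"; break
    }
    if (cycle >= control$max_cycles) break
  }

  if (control$polyak && avg$n >= 2L) {
    alpha <- avg$alpha / avg$n
    gamma <- avg$gamma / avg$n
    Sigma <- stats::cov2cor(avg$Sigma / avg$n)
    gamma[, 1L] <- 0
    gamma[gmask == 0L & col(gamma) > 1L] <- -30
    if (stopped == "stage2_max" && !is.null(avg$h1)) {
      # stability of the averaged iterates: first vs second suffix half
      h1 <- c(avg$h1$alpha[amask == 1L], avg$h1$gamma[gmask == 1L],
              avg$h1$Sigma[lower.tri(Sigma)]) / avg$h1n
      h2n <- avg$n - avg$h1n
      h2 <- (c(avg$alpha[amask == 1L], avg$gamma[gmask == 1L],
               avg$Sigma[lower.tri(Sigma)]) -
               c(avg$h1$alpha[amask == 1L], avg$h1$gamma[gmask == 1L],
                 avg$h1$Sigma[lower.tri(Sigma)])) / h2n
      nb <- c(sum(amask), sum(gmask))
      blk <- rep(c("alpha", "gamma", "Sigma"),
                 c(nb[1L], nb[2L], length(h1) - sum(nb)))
      drift_block <- vapply(split(abs(h2 - h1), blk), max, 0)
      drift <- max(abs(h2 - h1))
      converged <- drift < 20 * control$tol
    }
  }
  if (!isTRUE(converged) && (is.na(drift) || drift > 0.25))
    warning("MH-RM estimates may not have stabilised after ", cycle,
            " cycles (averaged-estimate drift ",
            signif(if (is.na(drift)) recent[length(recent)] else drift, 3),
            ")", call. = FALSE)

  npar <- as.integer(sum(if (constraints == "free") sum(amask) else D) +
                       sum(gmask) + D * (D - 1) / 2)
  ll <- marginal_loglik(responses, weights, alpha, gamma, Sigma,
                        method = control$ll_method,
                        draws = control$ll_draws, nodes = control$ll_nodes,
                        seed = seed + 1000003L)

  dimnames(alpha) <- list(items, weights$roles)
  dimnames(gamma) <- list(items, paste0("cat", seq_len(K1) - 1L))
  dimnames(Sigma) <- list(weights$roles, weights$roles)
  structure(list(call = cl,
                 coefficients = list(alpha = alpha, gamma = gamma),
                 Sigma = Sigma, loglik = as.numeric(ll),
                 loglik_method = attr(ll, "method"), npar = npar,
                 N = N, I = I, n_categories = K1, roles = weights$roles,
                 amask = amask, gmask = gmask, weights = weights,
                 constraints = constraints, seed = seed,
                 trace = do.call(rbind, trace), converged = converged,
                 stopped = stopped, drift = drift,
                 drift_block = if (exists("drift_block")) drift_block,
                 cycles = cycle, mh_steps = steps, control = control),
            class = "mnrm")
}
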