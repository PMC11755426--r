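#' Simulation design for recovery and model-selection studies
#'
#' Describes the data-generating process of the Monte Carlo study: a
#' battery of `n_traits` scales with `items_per_trait` items each on a
#' `n_categories`-point rating scale, contaminated with ERS and MRS and,
#' when `faking = TRUE`, with a faking dimension whose slopes are drawn
#' like all other slopes from \code{U(slope_range)}; when
#' `faking = FALSE` the faking slopes are 0 so the dimension cannot touch
#' the generated responses.  Item-category thresholds are drawn from a
#' normal distribution around `threshold_means` with variance
#' `threshold_var` and turned into intercepts by negative cumulative
#' summation (first intercept 0).  Person parameters are multivariate
#' normal with unit variances, trait intercorrelations `trait_cor`,
#' response styles orthogonal to everything, and faking-trait correlations
#' `faking_cor`.
#'
#' @param n_traits Number of substantive traits.
#' @param items_per_trait Items per trait scale.
#' @param n_categories Rating-scale points (K + 1, odd so MRS is defined).
#' @param n_persons Default sample size of a generated dataset.
#' @param faking Is faking part of the data-generating process?
#' @param include_faking_dim Keep the faking dimension (weights and latent
#'   dimension) in the generator even when `faking = FALSE`?  With
#'   `FALSE` the dimension is dropped entirely.
#' @param replications Default replication count for [run_study()].
#' @param threshold_means Length-K vector of threshold means.
#' @param threshold_var Common threshold variance (0 allowed, for exact
#'   closed-form intercepts).
#' @param slope_range Bounds of the uniform slope distribution.
#' @param faking_impact Scale of the generating faking effect.
#'   `"trait_metric"` (default) draws faking slopes from
#'   \code{K * U(slope_range)}: because scoring weights and slopes enter
#'   the logits only through their product, this is exactly equivalent to
#'   placing the \[0, 1\] faking weights on the 0..K metric of the trait
#'   weights, so that the faking dimension has on average the same impact
#'   on item responses as a substantive trait.  `"unit"` leaves faking
#'   slopes on \code{U(slope_range)}, giving faking roughly 1/K of a
#'   trait's impact.
#' @param trait_cor Trait-trait correlation matrix (defaults to a fixed
#'   positive-definite matrix with pairwise values in .10-.30).
#' @param faking_cor Faking-trait correlations (recycled to `n_traits`).
#' @param shape_census Proportions of monotone, nonmonotone-increasing and
#'   inverted-U desirability shapes within each trait block.
#' @param jitter Uniform jitter half-width applied to faking-weight
#'   templates (0 = deterministic templates).
#' @return List of class `sim_design`.
#' @export
sim_design <- function(n_traits = 5L, items_per_trait = 10L,
                       n_categories = 7L, n_persons = 250L, faking = TRUE,
                       include_faking_dim = TRUE, replications = 50L,
                       threshold_means = NULL, threshold_var = 0.7,
                       slope_range = c(0.25, 0.75),
                       faking_impact = c("trait_metric", "unit"),
                       trait_cor = NULL, faking_cor = NULL,
                       shape_census = c(monotone = 0.4,
                                        nonmonotone_increasing = 0.3,
                                        inverted_u = 0.3),
                       jitter = 0) {
  n_traits <- check_count(n_traits, "n_traits")
  items_per_trait <- check_count(items_per_trait, "items_per_trait")
  n_categories <- check_count(n_categories, "n_categories")
  if (n_categories %% 2L == 0L)
    stop("n_categories must be odd so that MRS has a midpoint",
         call. = FALSE)
  n_persons <- check_count(n_persons, "n_persons")
  K <- n_categories - 1L
  if (is.null(threshold_means))
    threshold_means <- if (n_categories == 7L)
      c(-1.5, -0.9, -0.3, 0.3, 0.9, 1.5)
    else seq(-1.5, 1.5, length.out = K)
  if (length(threshold_means) != K)
    stop("threshold_means must have length K = n_categories - 1",
         call. = FALSE)
  if (threshold_var < 0) stop("threshold_var must be >= 0", call. = FALSE)
  if (length(slope_range) != 2L || slope_range[1L] >= slope_range[2L] ||
      slope_range[1L] < 0)
    stop("slope_range must be an increasing non-negative pair",
         call. = FALSE)
  faking_impact <- match.arg(faking_impact)
  if (is.null(trait_cor)) trait_cor <- default_trait_cor(n_traits)
  trait_cor <- as.matrix(trait_cor)
  if (nrow(trait_cor) != n_traits) stop("trait_cor has wrong size",
                                        call. = FALSE)
  if (is.null(faking_cor))
    faking_cor <- rep_len(c(0, 0.10, -0.10, 0.30, -0.30), n_traits)
  faking_cor <- rep_len(faking_cor, n_traits)
  if (abs(sum(shape_census) - 1) > 1e-8 || any(shape_census < 0))
    stop("shape_census must be nonnegative proportions summing to 1",
         call. = FALSE)
  if (jitter < 0 || jitter > 0.5) stop("jitter must be in [0, 0.5]",
                                       call. = FALSE)
  design <- structure(
    list(n_traits = n_traits, items_per_trait = items_per_trait,
         n_categories = n_categories, n_persons = n_persons,
         faking = isTRUE(faking),
         include_faking_dim = isTRUE(include_faking_dim) || isTRUE(faking),
         replications = check_count(replications, "replications"),
         threshold_means = threshold_means, threshold_var = threshold_var,
         slope_range = slope_range, faking_impact = faking_impact,
         trait_cor = trait_cor,
         faking_cor = faking_cor, shape_census = shape_census,
         jitter = jitter),
    class = "sim_design")
  check_corr(build_generating_correlations(design))
  design
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Simulation design:", x$n_traits, "traits x", x$items_per_trait,
      "items,", x$n_categories, "categories, N =", x$n_persons, "\n")
  cat("  faking", if (x$faking) "present" else "absent",
      if (x$include_faking_dim) "(dimension included)\n" else
        "(dimension dropped)\n")
  invisible(x)
}

# fixed default trait intercorrelations: pairwise values in .10-.30,
# positive definite (checked at design construction)
default_trait_cor <- function(n_traits) {
  vals <- c(0.20, 0.15, 0.10, 0.25, 0.25, 0.20, 0.10, 0.20, 0.10, 0.15)
  R <- diag(n_traits)
  R[upper.tri(R)] <- rep_len(vals, n_traits * (n_traits - 1L) / 2L)
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
}

# dimension roles of a design
design_roles <- function(design) {
  roles <- paste0("trait", seq_len(design$n_traits))
  roles <- c(roles, "ers", "mrs")
  if (design$include_faking_dim) roles <- c(roles, "faking")
  roles
}

# item-to-trait map of a design
design_item_map <- function(design) {
  trait <- rep(seq_len(design$n_traits), each = design$items_per_trait)
  names(trait) <- sprintf("t%d_i%02d", trait,
                          rep(seq_len(design$items_per_trait),
                              design$n_traits))
  trait
}

#' Generating correlation matrix of a simulation design
#'
#' Assembles the latent correlation matrix: the trait block from
#' `trait_cor`, ERS and MRS orthogonal to each other and to everything
#' else, and (when the faking dimension is included) the faking-trait
#' block from `faking_cor` with faking orthogonal to the response styles.
#'
#' @param design A `sim_design`.
#' @return Positive-definite correlation matrix with role dimnames.
#' @export
build_generating_correlations <- function(design) {
  roles <- design_roles(design)
  D <- length(roles)
  R <- diag(D)
  nt <- design$n_traits
  R[seq_len(nt), seq_len(nt)] <- design$trait_cor
  if (design$include_faking_dim && design$faking) {
    # with faking absent the dimension is inert and truly uncorrelated
    fk <- which(roles == "faking")
    R[fk, seq_len(nt)] <- design$faking_cor
    R[seq_len(nt), fk] <- design$faking_cor
  }
  dimnames(R) <- list(roles, roles)
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop("assembled generating correlation matrix is not positive definite",
         call. = FALSE)
  R
}

#' Draw generating item slopes
#'
#' Active slopes (own trait, ERS, MRS, and faking when present) are drawn
#' from the design's uniform distribution; faking slopes are 0 when faking
#' is absent; foreign-trait slopes are 0.
#'
#' @param design A `sim_design`.
#' @param seeds Optional per-dimension seeds (internal use; when `NULL`
#'   the current RNG stream is used).
#' @return I x D slope matrix with role column names.
#' @export
draw_slopes <- function(design, seeds = NULL) {
  roles <- design_roles(design)
  trait <- design_item_map(design)
  I <- length(trait); D <- length(roles)
  lo <- design$slope_range[1L]; hi <- design$slope_range[2L]
  a <- matrix(0, I, D, dimnames = list(names(trait), roles))
  for (d in seq_len(D)) {
    if (!is.null(seeds)) set.seed(seeds[d])
    role <- roles[d]
    if (role == "faking") {
      fs <- if (identical(design$faking_impact, "unit")) 1
            else design$n_categories - 1L
      if (design$faking) a[, d] <- fs * stats::runif(I, lo, hi)
    } else if (startsWith(role, "trait")) {
      idx <- which(trait == as.integer(sub("trait", "", role)))
      a[idx, d] <- stats::runif(length(idx), lo, hi)
    } else {
      a[, d] <- stats::runif(I, lo, hi)
    }
  }
  a
}

#' Draw generating item-category intercepts
#'
#' Item- and category-specific thresholds are drawn from
#' \code{N(threshold_means, threshold_var)} and transformed to cumulative
#' intercepts \eqn{\gamma_{ik} = -\sum_{m \le k} \tau_{im}} with
#' \eqn{\gamma_{i0} = 0}.
#'
#' @param design A `sim_design`.
#' @param seed Optional seed (internal use).
#' @return List with `gamma` (I x (K+1)) and `tau` (I x K).
#' @export
draw_intercepts <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  I <- design$n_traits * design$items_per_trait
  K <- design$n_categories - 1L
  tau <- matrix(0, I, K)
  for (k in seq_len(K))
    tau[, k] <- stats::rnorm(I, design$threshold_means[k],
                             sqrt(design$threshold_var))
  gamma <- cbind(0, -t(apply(tau, 1L, cumsum)))
  colnames(gamma) <- paste0("cat", 0:K)
  list(gamma = gamma, tau = tau)
}

#' Faking-weight template of a desirability shape
#'
#' Deterministic templates in \[0, 1\] for the three desirability
#' trajectories used in data generation: `monotone` (linear, 0 to 1),
#' `nonmonotone_increasing` (increasing overall with a local dip), and
#' `inverted_u` (interior maximum, lower endpoints).  Optional uniform
#' jitter is applied to the template and values re-clipped to \[0, 1\]
#' (monotone templates are re-sorted so the shape survives the jitter).
#'
#' @param shape One of `"monotone"`, `"nonmonotone_increasing"`,
#'   `"inverted_u"`.
#' @param n_categories Number of categories.
#' @param jitter Uniform jitter half-width (0 = deterministic).
#' @return Weight vector of length `n_categories` in \[0, 1\].
#' @export
generate_faking_weights <- function(shape = c("monotone",
                                              "nonmonotone_increasing",
                                              "inverted_u"),
                                    n_categories = 7L, jitter = 0) {
  shape <- match.arg(shape)
  K1 <- check_count(n_categories, "n_categories")
  if (K1 < 3L) stop("faking-weight templates need >= 3 categories",
                    call. = FALSE)
  K <- K1 - 1L
  w <- switch(shape,
    monotone = seq(0, 1, length.out = K1),
    nonmonotone_increasing = {
      v <- seq(0, 1, length.out = K1)
      if (K1 == 3L) v[2L] <- 0           # plateau at the bottom
      else v[3L] <- v[2L] - 0.3 / K      # local dip below the neighbour
      pmin(1, pmax(0, v))
    },
    inverted_u = {
      k <- 0:K
      1 - ((k - K / 2) / (K / 2))^2
    })
  if (jitter > 0) {
    w <- w + stats::runif(K1, -jitter, jitter)
    w <- pmin(1, pmax(0, w))
    if (shape == "monotone") w <- sort(w)
  }
  w
}

# deterministic shape assignment within each trait block
assign_shapes <- function(design) {
  m <- design$items_per_trait
  cens <- design$shape_census
  n1 <- round(cens[[1L]] * m)
  n2 <- round(cens[[2L]] * m)
  n3 <- m - n1 - n2
  if (n3 < 0) { n2 <- n2 + n3; n3 <- 0 }
  shapes <- rep(c("monotone", "nonmonotone_increasing", "inverted_u"),
                c(n1, n2, n3))
  rep(shapes, design$n_traits)
}

#' Generate a synthetic dataset from a simulation design
#'
#' Runs the full generating pipeline: draw slopes, thresholds/intercepts
#' and faking weights, assemble the scoring-weight set, draw person
#' parameters from the generating multivariate normal, and sample
#' responses from the model.  Every building block consumes its own
#' RNG sub-stream derived from `seed`, so dropping an inert dimension
#' (e.g. the faking dimension when `faking = FALSE`) leaves the remaining
#' draws, and hence the responses, unchanged.
#'
#' @param design A `sim_design`.
#' @param seed Integer master seed for this dataset.
#' @param latent_means Optional length-D vector of latent means (default
#'   zero); useful for constructing shifted-population samples, e.g. a
#'   high-stakes sample with an elevated faking mean.
#' @return List of class `mnrm_sim`: `responses`, `weights`
#'   (`scoring_weights` including the faking row whenever the dimension is
#'   included), and `truth` (slopes, intercepts, thresholds, latent
#'   correlations, person parameters, faking weights, design, seed).
#' @export
generate_dataset <- function(design, seed = 1L, latent_means = NULL) {
  stopifnot(inherits(design, "sim_design"))
  seed <- as.integer(seed)
  roles <- design_roles(design)
  D <- length(roles)
  trait <- design_item_map(design)
  I <- length(trait)
  K1 <- design$n_categories
  sub <- function(k) as.integer((as.numeric(seed) + k * 131071) %%
                                  2147483629)
  # sub-stream indices are anchored on the full role set (traits, ERS,
  # MRS, faking) so that omitting the faking dimension leaves the other
  # streams untouched
  Dmax <- design$n_traits + 3L
  role_pos <- match(roles, c(paste0("trait", seq_len(design$n_traits)),
                             "ers", "mrs", "faking"))

  alpha <- draw_slopes(design, seeds = sub(role_pos))
  ints <- draw_intercepts(design, seed = sub(Dmax + 1L))
  shapes <- assign_shapes(design)
  if (design$jitter > 0) set.seed(sub(Dmax + 2L))
  fw <- if (design$include_faking_dim)
    t(vapply(shapes, generate_faking_weights, numeric(K1),
             n_categories = K1, jitter = design$jitter))
  else NULL
  if (!is.null(fw)) rownames(fw) <- names(trait)

  weights <- scoring_weights(trait, n_categories = K1,
                             n_traits = design$n_traits, ers = TRUE,
                             mrs = TRUE, faking = fw)
  Sigma <- build_generating_correlations(design)

  N <- design$n_persons
  Z <- matrix(0, N, D)
  for (d in seq_len(D)) {
    set.seed(sub(2L * Dmax + 2L + role_pos[d]))
    Z[, d] <- stats::rnorm(N)
  }
  Theta <- Z %*% chol(Sigma)
  if (!is.null(latent_means)) {
    stopifnot(length(latent_means) == D)
    Theta <- sweep(Theta, 2L, latent_means, "+")
  }
  colnames(Theta) <- roles

  set.seed(sub(3L * Dmax + 3L))
  responses <- sample_responses(Theta, weights, alpha, ints$gamma)

  structure(list(responses = responses, weights = weights,
                 truth = list(alpha = alpha, gamma = ints$gamma,
                              tau = ints$tau, Sigma = Sigma,
                              theta = Theta, faking_weights = fw,
                              shapes = shapes, design = design,
                              seed = seed)),
            class = "mnrm_sim")
}

#' @export
print.mnrm_sim <- function(x, ...) {
  d <- x$truth$design
  cat("Synthetic MNRM dataset:", nrow(x$responses), "persons x",
      ncol(x$responses), "items (faking",
      if (d$faking) "present)\n" else "absent)\n")
  invisible(x)
}

#' Bias and root mean square error of estimates against generating values
#'
#' @param est,true Aligned numeric vectors/matrices (estimates pooled
#'   across replications and the corresponding generating values).
#' @return List with `bias` = mean(est - true) and
#'   `rmse` = sqrt(mean((est - true)^2)).
#' @export
#' @examples
#' recovery_metrics(c(0.2, 0.4), c(0.25, 0.25))
recovery_metrics <- function(est, true) {
  est <- as.numeric(est); true <- as.numeric(true)
  if (length(est) != length(true))
    stop("est and true must be aligned", call. = FALSE)
  d <- est - true
  list(bias = mean(d), rmse = sqrt(mean(d^2)))
}

#' Mean correlation via Fisher's z-transformation
#'
#' Averages replication-wise correlations on the atanh scale and
#' back-transforms.  Undefined correlations (`NA`, from zero-variance
#' vectors) are excluded with a warning.
#'
#' @param r Vector of correlations.
#' @return Scalar mean correlation.
#' @export
#' @examples
#' fisher_mean_cor(c(0.8, 0.6))
fisher_mean_cor <- function(r) {
  bad <- !is.finite(r)
  if (any(bad)) {
    warning(sum(bad), " undefined correlation(s) excluded", call. = FALSE)
    r <- r[!bad]
  }
  if (length(r) == 0L) return(NA_real_)
  tanh(mean(atanh(pmin(1 - 1e-15, pmax(-1 + 1e-15, r)))))
}
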