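# Monte Carlo study driver: generate -> fit roster -> select -> recover.

# scoring-weight set of a roster model, from a generated dataset
roster_weights <- function(model, sim) {
  trait <- sim$weights$trait
  K1 <- sim$weights$n_categories
  nt <- sim$truth$design$n_traits
  fw <- sim$truth$faking_weights
  switch(model,
    traits = scoring_weights(trait, K1, nt, ers = FALSE, mrs = FALSE),
    ers    = scoring_weights(trait, K1, nt, ers = TRUE, mrs = FALSE),
    mrs    = scoring_weights(trait, K1, nt, ers = TRUE, mrs = TRUE),
    faking = {
      if (is.null(fw))
        stop("the generator did not include a faking dimension, so no ",
             "faking weights exist for the faking model", call. = FALSE)
      scoring_weights(trait, K1, nt, ers = TRUE, mrs = TRUE, faking = fw)
    },
    stop("unknown roster model: ", model, call. = FALSE))
}

#' Run a parameter-recovery and model-selection study
#'
#' For each sample size and replication: generate a dataset from `design`,
#' fit the roster of nested models (cumulative chain `traits` -> `+ERS` ->
#' `+MRS` -> `+faking`), apply the model-selection criteria, and collect
#' recovery metrics (bias/RMSE of trait-trait and faking-trait latent
#' correlations and of item slopes; Fisher-z mean correlation between MAP
#' and generating person parameters, aggregated across traits and reported
#' separately for faking).
#'
#' Selection criteria: `"aic"`/`"bic"` pick the criterion minimiser over
#' the roster; `"lr"` is the adjacent-pair likelihood-ratio test of the
#' two largest models at level `alpha` (the classical power/type-I
#' comparison); `"lr_chain"` walks the full nesting chain via
#' [select_model()].
#'
#' Replication-level fit failures are recorded in `failures` and the
#' replication is excluded from the aggregates, never silently dropped.
#' The whole study is reproducible from `seed`.
#'
#' @param design A `sim_design`.
#' @param sample_sizes Vector of sample sizes (paper design: 250, 500,
#'   1000, 3000).
#' @param replications Replications per condition.
#' @param models Roster subset of `c("traits", "ers", "mrs", "faking")`
#'   in nesting order.
#' @param criteria Subset of `c("lr", "aic", "bic", "lr_chain")`.
#' @param alpha LR significance level.
#' @param constraints Slope constraint mode passed to [mnrm()].
#' @param control [mnrm_control()] options for all fits.
#' @param score_persons Compute MAP-score recovery (adds one scoring pass
#'   per fit)?
#' @param seed Master seed; spawns one deterministic sub-stream per
#'   (condition, replication, model).
#' @param verbose Progress messages.
#' @return Object of class `mnrm_study` with data frames `selection`
#'   (proportion each model is selected, by condition and criterion, with
#'   Monte Carlo SEs), `recovery`, `person_recovery`, and `failures`.
#' @export
run_study <- function(design, sample_sizes = design$n_persons,
                      replications = design$replications,
                      models = c("traits", "ers", "mrs", "faking"),
                      criteria = c("lr", "aic", "bic"), alpha = 0.05,
                      constraints = c("free", "equal"),
                      control = mnrm_control(), score_persons = TRUE,
                      seed = 1L, verbose = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  constraints <- match.arg(constraints)
  models <- match.arg(models, c("traits", "ers", "mrs", "faking"),
                      several.ok = TRUE)
  criteria <- match.arg(criteria, c("lr", "aic", "bic", "lr_chain"),
                        several.ok = TRUE)
  if (length(models) < 2L)
    criteria <- character(0)              # nothing to select among
  nt <- design$n_traits
  pop_model <- if (design$faking) "faking" else "mrs"

  sel_rows <- list(); rec_rows <- list(); per_rows <- list()
  failures <- list()

  for (si in seq_along(sample_sizes)) {
    N <- sample_sizes[si]
    d2 <- design; d2$n_persons <- as.integer(N)
    sel_count <- matrix(0L, length(criteria), length(models),
                        dimnames = list(criteria, models))
    used <- 0L
    acc <- list()
    for (r in seq_len(replications)) {
      rseed <- as.integer((as.numeric(seed) + 7919 * r + 104729 * si) %%
                            2147483629)
      sim <- generate_dataset(d2, seed = rseed)
      fits <- vector("list", length(models)); names(fits) <- models
      failed <- FALSE
      for (mi in seq_along(models)) {
        m <- models[mi]
        w <- roster_weights(m, sim)
        fits[[m]] <- tryCatch(
          mnrm(sim$responses, w, constraints = constraints,
               control = control, seed = rseed + mi),
          error = function(e) e)
        if (inherits(fits[[m]], "error")) {
          failures[[length(failures) + 1L]] <-
            data.frame(n = N, replication = r, model = m,
                       message = conditionMessage(fits[[m]]))
          failed <- TRUE
        }
      }
      if (failed) next
      used <- used + 1L

      for (cr in criteria) {
        sel <- if (cr == "lr" && length(models) >= 2L) {
          k <- length(models)
          lt <- lr_test(fits[[k - 1L]], fits[[k]])
          if (lt$p.value < alpha) k else k - 1L
        } else if (cr == "lr_chain") {
          select_model(fits, "lr", alpha = alpha)
        } else {
          select_model(fits, cr)
        }
        sel_count[cr, models[sel]] <- sel_count[cr, models[sel]] + 1L
      }

      true_tt <- sim$truth$Sigma[seq_len(nt), seq_len(nt)]
      true_tt <- true_tt[lower.tri(true_tt)]
      true_ft <- if (design$faking) design$faking_cor else rep(0, nt)
      for (m in models) {
        f <- fits[[m]]
        est_tt <- f$Sigma[seq_len(nt), seq_len(nt)]
        est_tt <- est_tt[lower.tri(est_tt)]
        own <- cbind(seq_len(f$I), sim$weights$trait)
        d_sl <- f$coefficients$alpha[own] - sim$truth$alpha[own]
        rep_acc <- list(trait_cor = est_tt - true_tt,
                        trait_slopes = d_sl)
        if (m == "faking") {
          rep_acc$faking_cor <-
            f$Sigma["faking", seq_len(nt)] - true_ft
          rep_acc$faking_slopes <-
            f$coefficients$alpha[, "faking"] - sim$truth$alpha[, "faking"]
        }
        if (score_persons) {
          sc <- suppressWarnings(map_scores(f, sim$responses))
          rc <- vapply(seq_len(nt), function(d)
            stats::cor(sc[, d], sim$truth$theta[, d]), 0)
          rep_acc$person_traits <- rc
          if (m == "faking")
            rep_acc$person_faking <-
              stats::cor(sc[, "faking"], sim$truth$theta[, "faking"])
        }
        acc[[length(acc) + 1L]] <- list(model = m, rep = r, x = rep_acc)
      }
      if (verbose)
        message("N = ", N, " replication ", r, "/", replications, " done")
    }

    for (cr in criteria)
      for (m in models) {
        p <- sel_count[cr, m] / used
        sel_rows[[length(sel_rows) + 1L]] <-
          data.frame(n = N, criterion = cr, model = m, prop = p,
                     se = sqrt(p * (1 - p) / used), n_reps = used)
      }
    for (m in models) {
      sub <- Filter(function(a) a$model == m, acc)
      for (q in c("trait_cor", "faking_cor", "trait_slopes",
                  "faking_slopes")) {
        per_rep <- lapply(sub, function(a) a$x[[q]])
        per_rep <- per_rep[!vapply(per_rep, is.null, TRUE)]
        if (length(per_rep) == 0L) next
        d <- unlist(per_rep)
        means <- vapply(per_rep, mean, 0)
        rec_rows[[length(rec_rows) + 1L]] <-
          data.frame(n = N, model = m, quantity = q, bias = mean(d),
                     rmse = sqrt(mean(d^2)),
                     se_bias = stats::sd(means) / sqrt(length(means)),
                     n_reps = length(per_rep))
      }
      if (score_persons) {
        for (g in c("person_traits", "person_faking")) {
          rs <- unlist(lapply(sub, function(a) a$x[[g]]))
          if (is.null(rs)) next
          per_rows[[length(per_rows) + 1L]] <-
            data.frame(n = N, model = m,
                       group = sub("person_", "", g),
                       mean_cor = fisher_mean_cor(rs),
                       n_reps = length(sub))
        }
      }
    }
  }

  structure(list(selection = do.call(rbind, sel_rows),
                 recovery = do.call(rbind, rec_rows),
                 person_recovery = do.call(rbind, per_rows),
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 population_model = pop_model, models = models,
                 criteria = criteria, alpha = alpha,
                 sample_sizes = sample_sizes, replications = replications,
                 constraints = constraints, seed = seed, design = design),
            class = "mnrm_study")
}

#' @export
print.mnrm_study <- function(x, digits = 3, ...) {
  cat("MNRM Monte Carlo study:", x$replications, "replications, N in {",
      paste(x$sample_sizes, collapse = ", "), "}, faking",
      if (x$design$faking) "present\n" else "absent\n")
  cat("Population model:", x$population_model, "\n")
  if (!is.null(x$selection)) {
    cat("\nSelection proportions of the population model:\n")
    sel <- x$selection[x$selection$model == x$population_model, ,
                       drop = FALSE]
    sel$prop <- round(sel$prop, digits)
    sel$se <- round(sel$se, digits)
    print(sel, row.names = FALSE)
  }
  if (!is.null(x$failures))
    cat("\nFit failures:", nrow(x$failures), "\n")
  invisible(x)
}
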