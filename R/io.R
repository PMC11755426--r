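# CSV/JSON interfaces.  All files are UTF-8, comma-separated, with a
# header row; categories are 0-based everywhere.

#' Read a wide-format response CSV
#'
#' Header row = item identifiers, one row per person, integer cells 0..K.
#'
#' @param path CSV file.
#' @param n_categories Declared K + 1; defaults to `max + 1` in the file.
#' @return `mnrm_responses` matrix.
#' @export
read_responses <- function(path, n_categories = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicate item IDs in header of ", path, call. = FALSE)
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v) || anyNA(v) || any(v != round(v)))
      stop("non-integer or missing response in column '", names(df)[j],
           "' of ", path, call. = FALSE)
  }
  mnrm_responses(as.matrix(df), n_categories = n_categories)
}

#' Write a response matrix as CSV
#'
#' @param responses `mnrm_responses` matrix (or coercible).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  responses <- as_responses(responses)
  utils::write.csv(as.data.frame(unclass(responses)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an item-to-trait map CSV (columns `item_id`, `trait_id`)
#'
#' @param path CSV file.
#' @return Named integer vector of trait indices.
#' @export
read_item_map <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("item_id", "trait_id") %in% names(df)))
    stop("item map needs columns item_id and trait_id", call. = FALSE)
  if (anyDuplicated(df$item_id))
    stop("duplicate item IDs in ", path, call. = FALSE)
  stats::setNames(as.integer(df$trait_id), as.character(df$item_id))
}

#' Read per-item, per-category desirability ratings
#'
#' Long CSV with columns `item_id`, `category` (0..K, complete per item),
#' `mean_rating`.  The pilot instrument's scale bounds may be given as
#' comment lines `# scale_lo: <num>` / `# scale_hi: <num>` at the top of
#' the file, or passed via `bounds`.
#'
#' @param path CSV file.
#' @param bounds Optional `c(lo, hi)` overriding file metadata.
#' @return `desirability_ratings` object.
#' @export
read_desirability <- function(path, bounds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 10L)
  meta <- grep("^#", head_lines, value = TRUE)
  if (is.null(bounds)) {
    lo <- grep("scale_lo", meta, value = TRUE)
    hi <- grep("scale_hi", meta, value = TRUE)
    if (length(lo) == 1L && length(hi) == 1L)
      bounds <- c(as.numeric(sub(".*:", "", lo)),
                  as.numeric(sub(".*:", "", hi)))
    else stop("scale bounds not found in file metadata; pass `bounds`",
              call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("item_id", "category", "mean_rating") %in% names(df)))
    stop("desirability CSV needs item_id, category, mean_rating",
         call. = FALSE)
  items <- unique(as.character(df$item_id))
  K1 <- max(df$category) + 1L
  mat <- matrix(NA_real_, length(items), K1,
                dimnames = list(items, NULL))
  for (r in seq_len(nrow(df))) {
    k <- df$category[r]
    if (k != round(k) || k < 0 || k >= K1)
      stop("invalid category ", k, " at row ", r, " of ", path,
           call. = FALSE)
    mat[as.character(df$item_id[r]), k + 1L] <- df$mean_rating[r]
  }
  if (anyNA(mat))
    stop("incomplete category coverage: every item needs one rating per ",
         "category 0..", K1 - 1L, call. = FALSE)
  desirability_ratings(mat, bounds)
}

#' Write desirability ratings as CSV (with scale-bound metadata)
#'
#' @param ratings `desirability_ratings` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_desirability <- function(ratings, path) {
  stopifnot(inherits(ratings, "desirability_ratings"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# scale_lo: %.17g", ratings$bounds[1L]),
               sprintf("# scale_hi: %.17g", ratings$bounds[2L]),
               "item_id,category,mean_rating"), con)
  m <- ratings$ratings
  for (i in seq_len(nrow(m)))
    writeLines(sprintf("%s,%d,%.17g", rownames(m)[i],
                       seq_len(ncol(m)) - 1L, m[i, ]), con)
  invisible(path)
}

#' Write a scoring-weight set as long-format CSV
#'
#' Columns `item_id`, `dimension_role`, `category`, `weight`; values are
#' written at full double precision so the read/write round trip is
#' lossless.
#'
#' @param weights `scoring_weights` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "scoring_weights"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("item_id,dimension_role,category,weight", con)
  K1 <- weights$n_categories
  for (id in weights$items) {
    S <- weights$weights[[id]]
    for (d in seq_along(weights$roles))
      writeLines(sprintf("%s,%s,%d,%.17g", id, weights$roles[d],
                         0:(K1 - 1L), S[d, ]), con)
  }
  invisible(path)
}

#' Read a scoring-weight set from long-format CSV
#'
#' @param path CSV produced by [write_weights()].
#' @return `scoring_weights` object (validated).
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("item_id", "dimension_role", "category", "weight") %in%
           names(df)))
    stop("weight CSV needs item_id, dimension_role, category, weight",
         call. = FALSE)
  items <- unique(as.character(df$item_id))
  roles <- unique(as.character(df$dimension_role))
  K1 <- max(df$category) + 1L
  wl <- vector("list", length(items)); names(wl) <- items
  for (id in items) {
    sub <- df[df$item_id == id, ]
    S <- matrix(NA_real_, length(roles), K1, dimnames = list(roles, NULL))
    S[cbind(match(sub$dimension_role, roles), sub$category + 1L)] <-
      sub$weight
    if (anyNA(S)) stop("incomplete weights for item ", id, call. = FALSE)
    wl[[id]] <- S
  }
  tw <- trait_weights(K1)
  tr_roles <- grep("^trait", roles, value = TRUE)
  trait <- vapply(wl, function(S) {
    hit <- which(vapply(tr_roles, function(r)
      isTRUE(all.equal(S[r, ], tw)), TRUE))
    if (length(hit) != 1L) NA_integer_ else match(tr_roles[hit], tr_roles)
  }, 0L)
  if (anyNA(trait))
    stop("could not infer a unique trait assignment for every item",
         call. = FALSE)
  out <- structure(list(items = items, roles = roles, trait = trait,
                        n_categories = K1, weights = wl),
                   class = "scoring_weights")
  validate_scoring_weights(out)
  out
}

# content hash of a weight set: canonical long-format text, rounded to 12
# significant digits so serialization round trips (which may perturb the
# last ulp) keep the hash stable
weight_hash <- function(weights) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  con <- file(tf, "w")
  K1 <- weights$n_categories
  for (id in weights$items) {
    S <- weights$weights[[id]]
    for (d in seq_along(weights$roles))
      writeLines(sprintf("%s,%s,%d,%.12g", id, weights$roles[d],
                         0:(K1 - 1L), S[d, ]), con)
  }
  close(con)
  unname(tools::md5sum(tf))
}

#' Serialize a fitted model as JSON
#'
#' Stores estimates, the latent correlation matrix, the method-tagged
#' marginal log-likelihood, counts, convergence trace, seed, and the full
#' scoring-weight set together with its content hash (so scored samples
#' can be checked against the weights the fit used).
#'
#' @param fit An `mnrm` fit.
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mnrm"))
  w <- fit$weights
  payload <- list(
    package = "fakenrm", version = as.character(utils::packageVersion("fakenrm")),
    constraints = fit$constraints, seed = fit$seed,
    N = fit$N, I = fit$I, n_categories = fit$n_categories,
    roles = fit$roles, items = rownames(fit$coefficients$alpha),
    alpha = fit$coefficients$alpha, gamma = fit$coefficients$gamma,
    Sigma = fit$Sigma, loglik = fit$loglik,
    loglik_method = fit$loglik_method, npar = fit$npar,
    converged = fit$converged, cycles = fit$cycles, trace = fit$trace,
    weight_hash = weight_hash(w),
    weights = list(items = w$items, roles = w$roles,
                   trait = as.integer(w$trait),
                   n_categories = w$n_categories,
                   matrices = unname(w$weights)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a fitted model from JSON
#'
#' @param path File written by [write_fit()].
#' @return An `mnrm` object (verified against the stored weight hash).
#' @export
read_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  wl <- lapply(seq_along(p$weights$items), function(i)
    matrix(p$weights$matrices[i, , ], length(p$weights$roles),
           p$weights$n_categories))
  names(wl) <- p$weights$items
  for (i in seq_along(wl)) rownames(wl[[i]]) <- p$weights$roles
  w <- structure(list(items = p$weights$items, roles = p$weights$roles,
                      trait = stats::setNames(as.integer(p$weights$trait),
                                              p$weights$items),
                      n_categories = as.integer(p$weights$n_categories),
                      weights = wl),
                 class = "scoring_weights")
  if (!identical(unname(weight_hash(w)), p$weight_hash))
    stop("weight-set hash mismatch in ", path, call. = FALSE)
  alpha <- matrix(p$alpha, p$I, length(p$roles),
                  dimnames = list(p$items, p$roles))
  gamma <- matrix(p$gamma, p$I, p$n_categories,
                  dimnames = list(p$items,
                                  paste0("cat", seq_len(p$n_categories) - 1L)))
  Sigma <- matrix(p$Sigma, length(p$roles), length(p$roles),
                  dimnames = list(p$roles, p$roles))
  structure(list(call = NULL, coefficients = list(alpha = alpha,
                                                  gamma = gamma),
                 Sigma = Sigma, loglik = p$loglik,
                 loglik_method = p$loglik_method, npar = as.integer(p$npar),
                 N = as.integer(p$N), I = as.integer(p$I),
                 n_categories = as.integer(p$n_categories),
                 roles = p$roles, weights = w, constraints = p$constraints,
                 seed = p$seed, trace = p$trace,
                 converged = isTRUE(p$converged),
                 cycles = as.integer(p$cycles), control = NULL),
            class = "mnrm")
}

#' Write study outputs to a directory
#'
#' Deterministic layout: `selection_proportions.csv`,
#' `recovery_metrics.csv`, `person_recovery.csv`, `failures.csv` (only if
#' failures occurred), `study.json` (seed, conditions, package version),
#' and `manifest.json` listing every artifact with its MD5 content hash.
#'
#' @param study An `mnrm_study` result.
#' @param dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mnrm_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }
  wr(study$selection, "selection_proportions.csv")
  wr(study$recovery, "recovery_metrics.csv")
  wr(study$person_recovery, "person_recovery.csv")
  wr(study$failures, "failures.csv")
  meta <- file.path(dir, "study.json")
  jsonlite::write_json(
    list(package = "fakenrm",
         version = as.character(utils::packageVersion("fakenrm")),
         seed = study$seed, sample_sizes = study$sample_sizes,
         replications = study$replications, models = study$models,
         criteria = study$criteria, alpha = study$alpha,
         constraints = study$constraints,
         population_model = study$population_model,
         faking = study$design$faking),
    meta, auto_unbox = TRUE, digits = NA)
  files <- c(files, meta)
  manifest <- list(artifacts = data.frame(
    file = basename(files), md5 = unname(tools::md5sum(files))),
    seed = study$seed,
    version = as.character(utils::packageVersion("fakenrm")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
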