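test_that("MH-RM fits are reproducible and satisfy the identification constraints", {
  set.seed(21)
  I <- 8; N <- 150
  trait <- tiny_item_map(I, 1)
  sw <- scoring_weights(trait, 5, 1, ers = TRUE, mrs = FALSE)
  alpha <- cbind(runif(I, 0.8, 2), runif(I, 0.5, 1.5))
  gamma <- cbind(0, matrix(rnorm(I * 4, 0, 0.8), I, 4))
  th <- cbind(rnorm(N), rnorm(N))
  Y <- sample_responses(th, sw, alpha, gamma)

  f1 <- suppressWarnings(mnrm(Y, sw, seed = 77, control = light_control()))
  f2 <- suppressWarnings(mnrm(Y, sw, seed = 77, control = light_control()))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_equal(f1$Sigma, f2$Sigma, tolerance = 1e-12)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-12)

  # identification: unit diagonal, first-category intercepts exactly zero
  expect_equal(diag(f1$Sigma), rep(1, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(f1$coefficients$gamma[, 1] == 0))
  expect_true(all(is.finite(f1$trace)))
  expect_gt(nrow(f1$trace), 0)
})

test_that("slopes are recovered on two-dimensional data and nesting holds", {
  set.seed(22)
  I <- 10; N <- 1000
  trait <- tiny_item_map(I, 1)
  sw2 <- scoring_weights(trait, 7, 1, ers = TRUE, mrs = FALSE)
  sw1 <- scoring_weights(trait, 7, 1, ers = FALSE, mrs = FALSE)
  alpha <- cbind(runif(I, 0.8, 2), runif(I, 0.8, 2))
  tau <- sapply(c(-1.5, -0.9, -0.3, 0.3, 0.9, 1.5),
                function(m) rnorm(I, m, sqrt(0.7)))
  gamma <- cbind(0, -t(apply(tau, 1, cumsum)))
  th <- cbind(rnorm(N), rnorm(N))
  Y <- sample_responses(th, sw2, alpha, gamma)

  fit2 <- suppressWarnings(mnrm(Y, sw2, seed = 5,
                                control = study_control()))
  est <- fit2$coefficients$alpha
  expect_gt(cor(est[, 1], alpha[, 1]), 0.9)
  expect_gt(cor(est[, 2], alpha[, 2]), 0.9)

  fit1 <- suppressWarnings(mnrm(Y, sw1, seed = 6,
                                control = study_control()))
  # marginal LL of the full model dominates its nested restriction
  expect_gte(fit2$loglik, fit1$loglik - 1e-3)

  lt <- lr_test(fit1, fit2)
  expect_equal(lt$df, fit2$npar - fit1$npar)
  expect_lt(lt$p.value, 0.01)            # ERS is truly present
})

test_that("free-parameter counting reproduces the published configuration", {
  full <- count_free_parameters(n_items = 48, n_categories = 7, n_dims = 8,
                                loadings_per_item = 4)
  expect_identical(as.integer(full), 508L)
  expect_equal(attr(full, "breakdown"),
               c(slopes = 192L, intercepts = 288L, covariances = 28L))

  eq <- count_free_parameters(constraints = "equal", n_items = 48,
                              n_categories = 7, n_dims = 8,
                              loadings_per_item = 4)
  expect_identical(as.integer(eq), 324L)
  expect_equal(attr(eq, "breakdown"),
               c(slopes = 8L, intercepts = 288L, covariances = 28L))

  expect_identical(as.integer(count_free_parameters(
    n_items = 1, n_categories = 2, n_dims = 1, loadings_per_item = 1)), 2L)

  # counts derived from an assembled weight set agree with the formula
  trait <- setNames(rep(1:5, each = 2), paste0("j", 1:10))
  sw <- scoring_weights(trait, 7, 5,
                        faking = random_faking_weights(10, 7))
  cnt <- count_free_parameters(sw)
  expect_identical(as.integer(cnt), 10L * 4L + 10L * 6L + 28L)
})

test_that("LR test, information criteria and model selection behave as defined", {
  fA <- list(loglik = -100, npar = 10, N = 100, loglik_method = "laplace")
  fB <- list(loglik = -100, npar = 12, N = 100, loglik_method = "laplace")
  lt <- lr_test(fA, fB)
  expect_equal(lt$statistic, 0)
  expect_equal(lt$p.value, 1)
  expect_error(lr_test(fB, fA), "nested")

  # published degrees of freedom for adding faking with 48 free-slope items
  restr <- count_free_parameters(n_items = 48, n_categories = 7,
                                 n_dims = 7, loadings_per_item = 3)
  expect_identical(508L - as.integer(restr), 55L)

  ic <- information_criteria(fA)
  expect_equal(ic[["AIC"]], 220)
  expect_equal(ic[["BIC"]], 200 + 10 * log(100), tolerance = 1e-9)
  icB <- information_criteria(fB)
  expect_gt(icB[["AIC"]], ic[["AIC"]])    # same LL, more parameters
  expect_gt(icB[["BIC"]], ic[["BIC"]])
  fE <- list(loglik = -100, npar = 2, N = ceiling(exp(2)))
  icE <- information_criteria(fE)
  expect_equal(icE[["BIC"]] - icE[["AIC"]], 2 * (log(ceiling(exp(2))) - 2),
               tolerance = 1e-9)

  # dominance: equal parameter count, higher LL wins under AIC and BIC
  g1 <- list(loglik = -120, npar = 10, N = 100, loglik_method = "laplace")
  g2 <- list(loglik = -110, npar = 10, N = 100, loglik_method = "laplace")
  expect_identical(select_model(list(g1, g2), "aic"), 2L)
  expect_identical(select_model(list(g1, g2), "bic"), 2L)

  # LR chain stops at the first non-significant addition
  h1 <- list(loglik = -1000, npar = 10, N = 200, loglik_method = "laplace")
  h2 <- list(loglik = -950, npar = 15, N = 200, loglik_method = "laplace")
  h3 <- list(loglik = -949, npar = 25, N = 200, loglik_method = "laplace")
  expect_identical(select_model(list(h1, h2, h3), "lr"), 2L)
  expect_error(select_model(list(), "aic"), "no candidate")
})

test_that("MAP scores behave at the prior mode, rank midpoint responders, and recover truth", {
  # a dimension with all-zero slopes and an uncorrelated prior scores 0
  I <- 6
  trait <- tiny_item_map(I, 1)
  sw <- scoring_weights(trait, 7, 1, ers = TRUE, mrs = FALSE)
  alpha <- cbind(runif(I, 1, 2), 0)
  gamma <- cbind(0, matrix(rnorm(I * 6, 0, 0.5), I, 6))
  set.seed(31)
  Y <- sample_responses(cbind(rnorm(40), rnorm(40)), sw, alpha, gamma)
  sc <- map_scores(list(weights = sw, alpha = alpha, gamma = gamma,
                        Sigma = diag(2)), Y)
  expect_equal(unname(sc[, 2]), rep(0, 40), tolerance = 1e-10)
  expect_true(all(attr(sc, "converged")))

  # all-midpoint responder has the largest MRS score among 100 patterns
  sw3 <- scoring_weights(trait, 7, 1, ers = TRUE, mrs = TRUE)
  alpha3 <- cbind(runif(I, 0.5, 1), runif(I, 0.5, 1), runif(I, 0.5, 1))
  set.seed(32)
  pats <- matrix(sample(0:6, 99 * I, TRUE), 99, I)
  pats <- rbind(pats, rep(3L, I))
  colnames(pats) <- names(trait)
  sc3 <- map_scores(list(weights = sw3, alpha = alpha3, gamma = gamma,
                         Sigma = diag(3)),
                    mnrm_responses(pats, n_categories = 7))
  expect_identical(which.max(sc3[, "mrs"]), 100L)

  # recovery against generating person parameters (known item parameters)
  set.seed(33)
  I2 <- 50; N2 <- 500
  trait2 <- tiny_item_map(I2, 5)
  fw <- random_faking_weights(I2, 7)
  sw4 <- scoring_weights(trait2, 7, 5, faking = fw)
  D <- length(sw4$roles)
  alpha4 <- matrix(0, I2, D)
  alpha4[cbind(seq_len(I2), sw4$trait)] <- runif(I2, 0.25, 0.75)
  alpha4[, 6:7] <- matrix(runif(I2 * 2, 0.25, 0.75), I2, 2)
  alpha4[, 8] <- 6 * runif(I2, 0.25, 0.75)
  tau <- sapply(c(-1.5, -0.9, -0.3, 0.3, 0.9, 1.5),
                function(m) rnorm(I2, m, sqrt(0.7)))
  gamma4 <- cbind(0, -t(apply(tau, 1, cumsum)))
  th <- matrix(rnorm(N2 * D), N2, D)
  Y4 <- sample_responses(th, sw4, alpha4, gamma4)
  sc4 <- map_scores(list(weights = sw4, alpha = alpha4, gamma = gamma4,
                         Sigma = diag(D)), Y4)
  for (d in 1:5) expect_gt(cor(sc4[, d], th[, d]), 0.7)
})

test_that("equality-constrained slopes share one value per dimension", {
  set.seed(23)
  I <- 8; N <- 300
  trait <- tiny_item_map(I, 2)
  sw <- scoring_weights(trait, 5, 2, ers = TRUE, mrs = FALSE)
  a_eq <- c(1.2, 0.9, 0.7)
  alpha <- matrix(0, I, 3)
  alpha[cbind(seq_len(I), sw$trait)] <- a_eq[sw$trait]
  alpha[, 3] <- a_eq[3]
  gamma <- cbind(0, matrix(rnorm(I * 4, 0, 0.7), I, 4))
  Y <- sample_responses(matrix(rnorm(N * 3), N, 3), sw, alpha, gamma)
  fit <- suppressWarnings(mnrm(Y, sw, constraints = "equal", seed = 4,
                               control = light_control()))
  a <- fit$coefficients$alpha
  for (d in 1:3) {
    vals <- unique(round(a[a[, d] != 0, d], 12))
    expect_length(vals, 1L)
  }
  expect_identical(fit$npar,
                   as.integer(count_free_parameters(sw,
                                                    constraints = "equal")))
  # shared slopes land near their generating values
  est <- c(a[a[, 1] != 0, 1][1], a[a[, 2] != 0, 2][1], a[1, 3])
  expect_lt(max(abs(est - a_eq)), 0.3)
})

test_that("fixed-parameter scoring transfers across samples and recovers a faking mean shift", {
  d <- sim_design(n_traits = 2, items_per_trait = 5, n_persons = 400,
                  faking = TRUE, faking_cor = c(0.1, -0.1))
  high <- generate_dataset(d, seed = 91,
                           latent_means = c(0, 0, 0, 0, 0.8))
  low <- generate_dataset(d, seed = 92,
                          latent_means = c(0, 0, 0, 0, -0.8))
  fit <- suppressWarnings(mnrm(high$responses, high$weights, seed = 9,
                               control = study_control()))
  sc_high <- suppressWarnings(map_scores(fit, high$responses))
  sc_low <- suppressWarnings(map_scores(fit, low$responses))
  expect_gt(mean(sc_high[, "faking"]) - mean(sc_low[, "faking"]), 0)
})
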