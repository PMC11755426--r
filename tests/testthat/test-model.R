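test_that("category probabilities follow the multinomial-logistic form", {
  # equal logits
  expect_equal(category_probabilities(rep(0, 2), rep(0, 2),
                                      matrix(0, 2, 7), rep(0, 7)),
               rep(1 / 7, 7), tolerance = 1e-12)
  # hand softmax of logits (0, 1, 2)
  expect_equal(category_probabilities(1, 1, matrix(0:2, 1), c(0, 0, 0)),
               c(0.09003057, 0.24472847, 0.66524096), tolerance = 1e-7)
  expect_error(category_probabilities(c(1, 2), 1, matrix(0:2, 1), rep(0, 3)),
               "mismatch")
  expect_error(category_probabilities(NaN, 1, matrix(0:2, 1), rep(0, 3)),
               "finite")
})

test_that("probabilities match a brute-force softmax and obey the softmax invariances", {
  set.seed(101)
  for (rep in 1:2000) {
    D <- sample(1:4, 1); K1 <- sample(c(3, 5, 7), 1)
    th <- rnorm(D); a <- rnorm(D); W <- matrix(rnorm(D * K1), D, K1)
    g <- rnorm(K1)
    p <- category_probabilities(th, a, W, g)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    expect_equal(p, brute_force_probs(th, a, W, g), tolerance = 1e-12)
    # shift invariance: category-constant added to one weight row
    W2 <- W; W2[1, ] <- W2[1, ] + 5
    expect_equal(category_probabilities(th, a, W2, g), p, tolerance = 1e-12)
    # scale absorption between a weight row and its slope
    c0 <- runif(1, 0.2, 5)
    W3 <- W; W3[D, ] <- W3[D, ] * c0
    a3 <- a; a3[D] <- a3[D] / c0
    expect_equal(category_probabilities(th, a3, W3, g), p, tolerance = 1e-12)
  }
})

test_that("response sampling matches the model-implied distribution and is reproducible", {
  sw <- scoring_weights(setNames(1, "x"), 7, ers = FALSE, mrs = FALSE)
  # near-degenerate item: category 1 carries essentially all mass
  gdeg <- matrix(c(0, 50, rep(0, 5)), 1, 7)
  set.seed(1)
  Y <- sample_responses(matrix(rnorm(1000), 1000, 1), sw,
                        matrix(0, 1, 1), gdeg)
  expect_true(all(Y == 1L))

  # uniform item: frequencies within 3 binomial SEs of 1/7
  set.seed(2)
  Yu <- sample_responses(matrix(0, 10000, 1), sw, matrix(0, 1, 1),
                         matrix(0, 1, 7))
  freq <- tabulate(Yu + 1L, 7) / 10000
  se <- sqrt((1 / 7) * (6 / 7) / 10000)
  expect_true(all(abs(freq - 1 / 7) < 3 * se))

  # determinism under a fixed seed
  set.seed(33); A <- sample_responses(matrix(rnorm(50), 50, 1), sw,
                                      matrix(1, 1, 1), gdeg * 0)
  set.seed(33); B <- sample_responses(matrix(rnorm(50), 50, 1), sw,
                                      matrix(1, 1, 1), gdeg * 0)
  expect_identical(unclass(A), unclass(B))
})

test_that("complete-data log-likelihood equals the brute-force cellwise sum", {
  sw <- scoring_weights(setNames(1, "x"), 7, ers = FALSE, mrs = FALSE)
  y1 <- mnrm_responses(matrix(3L, 1, 1, dimnames = list(NULL, "x")),
                       n_categories = 7)
  ll1 <- complete_data_loglik(y1, matrix(0, 1, 1), sw, matrix(0, 1, 1),
                              matrix(0, 1, 7))
  expect_equal(ll1, log(1 / 7), tolerance = 1e-12)

  y2 <- mnrm_responses(matrix(c(3L, 5L), 2, 1,
                              dimnames = list(NULL, "x")), n_categories = 7)
  ll2 <- complete_data_loglik(y2, matrix(0, 2, 1), sw, matrix(0, 1, 1),
                              matrix(0, 1, 7))
  expect_equal(ll2, 2 * log(1 / 7), tolerance = 1e-12)

  set.seed(5)
  trait <- tiny_item_map(5, 2)
  fw <- random_faking_weights(5, 5)
  sw2 <- scoring_weights(trait, 5, 2, faking = fw)
  D <- length(sw2$roles)
  alpha <- matrix(runif(5 * D), 5, D)
  gamma <- cbind(0, matrix(rnorm(5 * 4), 5, 4))
  th <- matrix(rnorm(4 * D), 4, D)
  Y <- sample_responses(th, sw2, alpha, gamma)
  expect_equal(complete_data_loglik(Y, th, sw2, alpha, gamma),
               brute_force_loglik(unclass(Y), th, sw2, alpha, gamma),
               tolerance = 1e-10)
})

test_that("marginal log-likelihood approximations agree where closed forms exist", {
  # zero slopes: latent variables integrate out exactly
  sw <- scoring_weights(tiny_item_map(4, 1), 7, ers = FALSE, mrs = FALSE)
  set.seed(8)
  Y <- mnrm_responses(matrix(sample(0:6, 30 * 4, TRUE), 30, 4,
                             dimnames = list(NULL, names(sw$trait))),
                      n_categories = 7)
  alpha0 <- matrix(0, 4, 1); gamma0 <- matrix(0, 4, 7)
  ll <- marginal_loglik(Y, sw, alpha0, gamma0, diag(1))
  expect_equal(as.numeric(ll), 30 * 4 * log(1 / 7), tolerance = 1e-8)

  # D = 1: Laplace within 0.5% of adaptive quadrature
  set.seed(9)
  I <- 10; N <- 120
  sw1 <- scoring_weights(tiny_item_map(I, 1), 5, ers = FALSE, mrs = FALSE)
  alpha <- matrix(runif(I, 0.8, 2), I, 1)
  gamma <- cbind(0, matrix(rnorm(I * 4, 0, 0.8), I, 4))
  th <- matrix(rnorm(N), N, 1)
  Y1 <- sample_responses(th, sw1, alpha, gamma)
  lap <- marginal_loglik(Y1, sw1, alpha, gamma, diag(1), method = "laplace")
  quad <- marginal_loglik(Y1, sw1, alpha, gamma, diag(1),
                          method = "quadrature", nodes = 61)
  expect_lt(abs(lap - quad) / abs(quad), 0.005)

  # importance sampling agrees with quadrature closely at D = 1
  imp <- marginal_loglik(Y1, sw1, alpha, gamma, diag(1),
                         method = "importance", draws = 2000, seed = 4)
  expect_lt(abs(imp - quad) / abs(quad), 0.005)

  # appending an all-zero-slope dimension leaves the value unchanged
  sw2 <- scoring_weights(sw1$trait, 5, n_traits = 1, ers = TRUE,
                         mrs = FALSE)
  alpha2 <- cbind(alpha, 0)
  lap2 <- marginal_loglik(Y1, sw2, alpha2, gamma, diag(2),
                          method = "laplace")
  expect_lt(abs(lap2 - lap), 1e-8)

  # quadrature is capped at D = 3
  swq <- scoring_weights(tiny_item_map(4, 2), 5)
  expect_error(marginal_loglik(Y1[, 1:4], swq, matrix(0.5, 4, 4),
                               matrix(0, 4, 5), diag(4),
                               method = "quadrature"),
               "D <= 3")
})
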