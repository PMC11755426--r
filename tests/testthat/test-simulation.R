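test_that("generating slopes respect the uniform design", {
  d <- sim_design(n_traits = 5, items_per_trait = 10,
                  faking_impact = "unit")
  set.seed(41)
  draws <- replicate(40, draw_slopes(d), simplify = FALSE)
  act <- unlist(lapply(draws, function(a) a[a != 0]))
  expect_gte(min(act), 0.25)
  expect_lte(max(act), 0.75)
  se <- sqrt(0.5^2 / 12 / length(act))
  expect_lt(abs(mean(act) - 0.5), 3 * se)

  # faking absent: the faking column is identically zero
  d0 <- sim_design(faking = FALSE)
  set.seed(42)
  a0 <- draw_slopes(d0)
  expect_true(all(a0[, "faking"] == 0))

  # reproducibility under a fixed seed
  set.seed(43); s1 <- draw_slopes(d)
  set.seed(43); s2 <- draw_slopes(d)
  expect_identical(s1, s2)

  # trait-metric faking impact scales only the faking column, by K
  dk <- sim_design(n_traits = 2, items_per_trait = 5)
  set.seed(44); ak <- draw_slopes(dk)
  expect_gte(min(ak[, "faking"]), 6 * 0.25)
  expect_lte(max(ak[, "faking"]), 6 * 0.75)
})

test_that("intercepts are negative cumulative thresholds", {
  d0 <- sim_design(n_traits = 2, items_per_trait = 3, threshold_var = 0)
  g <- draw_intercepts(d0)$gamma
  target <- c(0, 1.5, 2.4, 2.7, 2.4, 1.5, 0)
  for (i in seq_len(nrow(g)))
    expect_equal(unname(g[i, ]), target, tolerance = 1e-12)

  d <- sim_design(n_traits = 1, items_per_trait = 100)
  set.seed(45)
  G <- do.call(rbind, replicate(25, draw_intercepts(d)$gamma,
                                simplify = FALSE))
  expect_true(all(G[, 1] == 0))
  # mean over draws matches the variance-0 closed form
  n <- nrow(G)
  for (k in 2:7) {
    se <- sqrt(0.7 * (k - 1) / n)     # sum of k-1 independent thresholds
    expect_lt(abs(mean(G[, k]) - target[k]), 4 * se)
  }
})

test_that("faking-weight templates have the three designed shapes", {
  m <- generate_faking_weights("monotone", 7)
  expect_equal(m, seq(0, 1, length.out = 7))

  nm <- generate_faking_weights("nonmonotone_increasing", 7)
  expect_equal(nm[c(1, 7)], c(0, 1))
  expect_gt(nm[7], nm[1])
  expect_true(any(diff(nm) <= 0))       # at least one local dip/plateau
  expect_true(all(nm >= 0 & nm <= 1))

  iu <- generate_faking_weights("inverted_u", 7)
  peak <- which.max(iu)
  expect_true(peak > 1 && peak < 7)
  expect_lt(iu[1], max(iu)); expect_lt(iu[7], max(iu))

  expect_error(generate_faking_weights("zigzag", 7))

  set.seed(46)
  jit <- replicate(1000, generate_faking_weights("monotone", 7,
                                                 jitter = 0.1))
  expect_true(all(jit >= 0 & jit <= 1))
  expect_true(all(apply(jit, 2, function(w) all(diff(w) >= 0))))
})

test_that("the generating correlation matrix matches the design", {
  d <- sim_design()
  R <- build_generating_correlations(d)
  expect_equal(R["faking", "trait4"], 0.30)
  expect_equal(R["faking", "trait1"], 0)
  expect_equal(R["ers", "mrs"], 0)
  expect_true(all(R[c("ers", "mrs"), paste0("trait", 1:5)] == 0))
  expect_true(min(eigen(R, symmetric = TRUE)$values) > 0)

  # fully independent configuration is accepted
  di <- sim_design(trait_cor = diag(5), faking_cor = rep(0, 5))
  expect_equal(build_generating_correlations(di), diag(8),
               ignore_attr = TRUE)

  # a non-positive-definite configuration is rejected
  expect_error(sim_design(trait_cor = diag(5), faking_cor = rep(0.99, 5)),
               "positive definite")
})

test_that("dataset generation is complete, inert-dimension invariant, and desirability-directional", {
  d <- sim_design()
  sim <- generate_dataset(d, seed = 51)
  expect_equal(ncol(sim$responses), 50)
  expect_equal(range(sim$responses), c(0, 6))
  expect_equal(length(sim$weights$roles), 8)
  expect_true(all(sim$truth$gamma[, 1] == 0))

  # dropping the inert faking dimension leaves the responses unchanged
  dA <- sim_design(faking = FALSE, include_faking_dim = TRUE)
  dB <- sim_design(faking = FALSE, include_faking_dim = FALSE)
  sA <- generate_dataset(dA, seed = 52)
  sB <- generate_dataset(dB, seed = 52)
  expect_identical(unclass(sA$responses), unclass(sB$responses))
  expect_equal(length(sB$weights$roles), 7)

  # forcing high faking levels shifts responses toward desirable categories
  d2 <- sim_design(n_traits = 2, items_per_trait = 5, n_persons = 800)
  hi <- generate_dataset(d2, seed = 53, latent_means = c(0, 0, 0, 0, 3))
  lo <- generate_dataset(d2, seed = 53, latent_means = c(0, 0, 0, 0, -3))
  des_of <- function(sim) {
    fw <- sim$truth$faking_weights
    mean(fw[cbind(rep(seq_len(ncol(sim$responses)),
                      each = nrow(sim$responses)),
                  as.vector(sim$responses) + 1L)])
  }
  expect_gt(des_of(hi), des_of(lo))
})

test_that("recovery metrics match hand computations and flag degenerate input", {
  rm0 <- recovery_metrics(c(0.3, -0.2), c(0.3, -0.2))
  expect_equal(rm0$bias, 0); expect_equal(rm0$rmse, 0)

  rm1 <- recovery_metrics(c(0.2, 0.4), c(0.25, 0.25))
  expect_equal(rm1$bias, 0.05, tolerance = 1e-12)
  expect_equal(rm1$rmse, sqrt((0.0025 + 0.0225) / 2), tolerance = 1e-12)

  expect_equal(fisher_mean_cor(c(0.8, 0.6)),
               tanh(mean(atanh(c(0.8, 0.6)))), tolerance = 1e-12)
  expect_equal(round(fisher_mean_cor(c(0.8, 0.6)), 3), 0.714)
  expect_warning(out <- fisher_mean_cor(c(0.5, NA)), "excluded")
  expect_equal(out, 0.5)
  expect_error(recovery_metrics(1:3, 1:2), "aligned")
})

test_that("the study runner aggregates selection and recovery and is seed-stable", {
  d <- sim_design(n_traits = 3, items_per_trait = 4, faking = TRUE,
                  faking_cor = c(0, 0.2, -0.2), replications = 3)
  st <- run_study(d, sample_sizes = c(150, 450), replications = 3,
                  models = c("mrs", "faking"),
                  criteria = c("lr", "aic", "bic"),
                  control = light_control(), seed = 61)
  sel <- st$selection
  # proportions over the roster partition the replications
  agg <- aggregate(prop ~ n + criterion, sel, sum)
  expect_true(all(abs(agg$prop - 1) < 1e-12))
  expect_true(all(sel$prop >= 0 & sel$prop <= 1))
  expect_true(is.null(st$failures))

  # person recovery is reported per dimension group, in (0, 1]
  pr <- st$person_recovery
  expect_true(all(pr$mean_cor > 0 & pr$mean_cor <= 1))

  # person recovery of traits is stable across sample sizes (scaled probe)
  tr <- pr[pr$model == "faking" & pr$group == "traits", ]
  expect_lt(abs(diff(tr$mean_cor)), 0.1)

  # reruns with the same seed are identical
  st2 <- run_study(d, sample_sizes = c(150, 450), replications = 3,
                   models = c("mrs", "faking"),
                   criteria = c("lr", "aic", "bic"),
                   control = light_control(), seed = 61)
  expect_identical(st$selection, st2$selection)
  expect_identical(st$recovery, st2$recovery)
})
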