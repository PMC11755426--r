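# Independent oracles: deliberately naive implementations that share no
# code with the package's computational path.

# plain softmax of one item's category logits, no stabilisation tricks
brute_force_probs <- function(theta, slopes, weights, intercepts) {
  K1 <- ncol(weights)
  logits <- numeric(K1)
  for (k in seq_len(K1)) {
    s <- 0
    for (d in seq_len(nrow(weights)))
      s <- s + slopes[d] * weights[d, k] * theta[d]
    logits[k] <- s + intercepts[k]
  }
  exp(logits) / sum(exp(logits))
}

# complete-data log-likelihood by direct cellwise evaluation
brute_force_loglik <- function(Y, theta, weights_obj, alpha, gamma) {
  ll <- 0
  for (n in seq_len(nrow(Y)))
    for (i in seq_len(ncol(Y))) {
      S <- weights_obj$weights[[colnames(Y)[i]]]
      p <- brute_force_probs(theta[n, ], alpha[i, ], S, gamma[i, ])
      ll <- ll + log(p[Y[n, i] + 1])
    }
  ll
}

# EM with fixed Gauss-Hermite quadrature for the unidimensional nominal
# model (trait weights 0..K, standard-normal latent trait).  M-step by
# direct numerical maximisation of the expected complete-data
# log-likelihood per item.
em_nrm_1d <- function(Y, K1, n_nodes = 101, max_iter = 2000, tol = 1e-8) {
  gh <- pracma::gaussHermite(n_nodes)
  nodes <- sqrt(2) * gh$x               # N(0,1) quadrature
  wq <- gh$w / sqrt(pi)
  N <- nrow(Y); I <- ncol(Y); Q <- n_nodes
  k_w <- 0:(K1 - 1)

  item_probs <- function(a, g, th) {    # K1 x Q
    lo <- outer(k_w * a, th) + g
    e <- exp(sweep(lo, 2, apply(lo, 2, max)))
    sweep(e, 2, colSums(e), "/")
  }

  a <- rep(1, I)
  g <- matrix(0, I, K1)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step: posterior weights over nodes
    logP <- matrix(0, N, Q)
    P_list <- vector("list", I)
    for (i in seq_len(I)) {
      P <- item_probs(a[i], g[i, ], nodes)
      P_list[[i]] <- P
      logP <- logP + log(P)[Y[, i] + 1, , drop = FALSE]
    }
    A <- sweep(logP, 2, log(wq), "+")
    m <- apply(A, 1, max)
    lik <- exp(A - m)
    ll <- sum(m + log(rowSums(lik)))
    r <- lik / rowSums(lik)             # N x Q posterior weights

    # expected counts per item, category, node
    for (i in seq_len(I)) {
      nk <- matrix(0, K1, Q)
      for (k in seq_len(K1)) {
        idx <- Y[, i] == (k - 1)
        if (any(idx)) nk[k, ] <- colSums(r[idx, , drop = FALSE])
      }
      obj <- function(par) {
        P <- item_probs(par[1], c(0, par[-1]), nodes)
        -sum(nk * log(pmax(P, 1e-300)))
      }
      o <- stats::optim(c(a[i], g[i, -1]), obj, method = "BFGS",
                        control = list(maxit = 200))
      a[i] <- o$par[1]
      g[i, ] <- c(0, o$par[-1])
    }
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(alpha = a, gamma = g, loglik = ll, iterations = it)
}
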