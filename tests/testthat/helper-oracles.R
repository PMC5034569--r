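# Independent reference implementations used to cross-check the package.
# These deliberately avoid the package's own code paths: densities use
# solve()/det() rather than Cholesky, sequence likelihoods are brute-force
# sums over all state paths, and integrals over missing dimensions use
# quadrature.

# Gaussian density of the observed sub-vector, via solve/det
oracle_obs_density <- function(mu, sigma, x) {
  o <- !is.na(x)
  if (!any(o)) return(1)
  S <- sigma[o, o, drop = FALSE]
  v <- x[o] - mu[o]
  as.numeric(exp(-0.5 * (sum(o) * log(2 * pi) + log(det(S)) +
                           v %*% solve(S, v))))
}

# observed-data likelihood by enumeration over all K^T paths
oracle_enum_loglik <- function(params, obs) {
  Tn <- nrow(obs); K <- params$K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    z <- paths[r, ]
    p <- params$pi[z[1]] *
      oracle_obs_density(params$mu[z[1], ], params$sigma[, , z[1]], obs[1, ])
    if (Tn > 1) for (t in 2:Tn)
      p <- p * params$A[z[t - 1], z[t]] *
        oracle_obs_density(params$mu[z[t], ], params$sigma[, , z[t]],
                           obs[t, ])
    tot <- tot + p
  }
  log(tot)
}

# smoothed posteriors by enumeration
oracle_enum_gamma <- function(params, obs) {
  Tn <- nrow(obs); K <- params$K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  wts <- apply(paths, 1, function(z) {
    p <- params$pi[z[1]] *
      oracle_obs_density(params$mu[z[1], ], params$sigma[, , z[1]], obs[1, ])
    if (Tn > 1) for (t in 2:Tn)
      p <- p * params$A[z[t - 1], z[t]] *
        oracle_obs_density(params$mu[z[t], ], params$sigma[, , z[t]],
                           obs[t, ])
    p
  })
  g <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) for (k in seq_len(K))
    g[t, k] <- sum(wts[paths[, t] == k])
  g / rowSums(g)
}

# most probable path by enumeration (first in expand.grid order on ties;
# random instances have no exact ties)
oracle_enum_viterbi <- function(params, obs) {
  Tn <- nrow(obs); K <- params$K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  wts <- apply(paths, 1, function(z) {
    p <- log(params$pi[z[1]]) +
      log(oracle_obs_density(params$mu[z[1], ], params$sigma[, , z[1]],
                             obs[1, ]))
    if (Tn > 1) for (t in 2:Tn)
      p <- p + log(params$A[z[t - 1], z[t]]) +
        log(oracle_obs_density(params$mu[z[t], ], params$sigma[, , z[t]],
                               obs[t, ]))
    p
  })
  as.integer(paths[which.max(wts), ])
}

# complete-data Gaussian-HMM EM (no missing-data machinery), mirroring the
# package's iteration bookkeeping so traces are comparable step for step
oracle_complete_em <- function(panel, init, n_iter, reg = 1e-6) {
  params <- init
  d <- init$d; K <- init$K
  trace <- numeric(0)
  dens_row <- function(k, x)
    oracle_obs_density(params$mu[k, ], params$sigma[, , k], x)
  for (iter in seq_len(n_iter)) {
    start_w <- numeric(K); trans_w <- matrix(0, K, K)
    w <- numeric(K); m1 <- matrix(0, K, d); m2 <- array(0, c(d, d, K))
    ll <- 0
    for (p in panel$patients) {
      Tn <- p$T
      B <- t(vapply(seq_len(Tn), function(t)
        vapply(seq_len(K), function(k) dens_row(k, p$obs[t, ]), numeric(1)),
        numeric(K)))
      dim(B) <- c(Tn, K)
      alpha <- matrix(0, Tn, K); cvec <- numeric(Tn)
      a <- params$pi * B[1, ]; cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
      if (Tn > 1) for (t in 2:Tn) {
        a <- as.vector(alpha[t - 1, ] %*% params$A) * B[t, ]
        cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
      }
      beta <- matrix(1, Tn, K)
      if (Tn > 1) for (t in (Tn - 1):1)
        beta[t, ] <- as.vector(params$A %*% (B[t + 1, ] * beta[t + 1, ])) /
          cvec[t + 1]
      g <- alpha * beta; g <- g / rowSums(g)
      ll <- ll + sum(log(cvec))
      start_w <- start_w + g[1, ]
      if (Tn > 1) for (t in seq_len(Tn - 1)) {
        M <- outer(alpha[t, ], B[t + 1, ] * beta[t + 1, ]) * params$A
        trans_w <- trans_w + M / sum(M)
      }
      for (t in seq_len(Tn)) for (k in seq_len(K)) {
        w[k] <- w[k] + g[t, k]
        m1[k, ] <- m1[k, ] + g[t, k] * p$obs[t, ]
        m2[, , k] <- m2[, , k] + g[t, k] * tcrossprod(p$obs[t, ])
      }
    }
    trace <- c(trace, ll)
    if (iter == n_iter) break
    pi_new <- start_w / sum(start_w)
    A_new <- trans_w / rowSums(trans_w)
    mu_new <- m1 / w
    sig_new <- array(0, c(d, d, K))
    for (k in seq_len(K)) {
      S <- m2[, , k] / w[k] - tcrossprod(mu_new[k, ])
      S <- (S + t(S)) / 2
      sig_new[, , k] <- S + diag(reg * mean(diag(S)), d)
    }
    params <- hmm_params(pi_new, A_new, mu_new, sig_new)
  }
  list(params = params, trace = trace)
}

# random valid HMM parameters for property tests
random_params <- function(K, d, seed) {
  set.seed(seed)
  rdir <- function(n) { g <- rgamma(n, 2); g / sum(g) }
  A <- t(vapply(seq_len(K), function(k) rdir(K), numeric(K)))
  if (K == 1) A <- matrix(1, 1, 1)
  sigma <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    M <- matrix(rnorm(d * d), d)
    sigma[, , k] <- crossprod(M) / d + diag(0.5, d)
  }
  hmm_params(pi = rdir(K), A = A,
             mu = matrix(rnorm(K * d, sd = 2), K, d), sigma = sigma)
}

# small random panel (optionally with missing entries) built from raw draws
random_panel <- function(n, d, seed, mar_rate = 0, max_T = 4) {
  set.seed(seed)
  patients <- lapply(seq_len(n), function(i) {
    Tn <- sample.int(max_T, 1)
    obs <- matrix(rnorm(Tn * d, sd = 1.5), Tn, d)
    if (mar_rate > 0) {
      drop <- matrix(runif(Tn * d) < mar_rate, Tn, d)
      drop[1, 1] <- FALSE   # keep every row anchored somewhere
      for (t in seq_len(Tn)) if (all(drop[t, ])) drop[t, 1] <- FALSE
      obs[drop] <- NA
    }
    list(patient_id = sprintf("R%03d", i), obs = obs)
  })
  coag_panel(patients, feature_names = paste0("V", seq_len(d)),
             grid_hours = GRID_HOURS_TEST[seq_len(max_T)])
}
GRID_HOURS_TEST <- c(0L, 24L, 48L, 72L, 96L, 120L)
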