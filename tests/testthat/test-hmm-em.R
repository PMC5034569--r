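test_that("marginal emission log-density handles the standard cases", {
  p <- hmm_params(pi = 1, A = matrix(1), mu = matrix(0, 1, 1),
                  sigma = array(1, c(1, 1, 1)))
  expect_equal(marginal_emission_loglik(p, 0), -0.5 * log(2 * pi))

  p2 <- random_params(3, 4, seed = 2)
  expect_equal(marginal_emission_loglik(p2, rep(NA_real_, 4)), rep(0, 3))
})

test_that("marginal emission density equals quadrature over missing dims", {
  p <- random_params(2, 2, seed = 5)
  x <- c(0.7, NA)
  ll <- marginal_emission_loglik(p, x)
  for (k in 1:2) {
    joint <- function(x2) vapply(x2, function(v)
      oracle_obs_density(p$mu[k, ], p$sigma[, , k], c(0.7, v)), numeric(1))
    q <- stats::integrate(joint, -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(ll[k], log(q), tolerance = 1e-6)
  }
  # d = 3, two dims missing: nested quadrature over both missing dims
  p3 <- random_params(1, 3, seed = 6)
  x3 <- c(NA, 0.4, NA)
  inner <- function(x1) stats::integrate(function(v) vapply(v, function(x3v)
    oracle_obs_density(p3$mu[1, ], p3$sigma[, , 1], c(x1, 0.4, x3v)),
    numeric(1)), -Inf, Inf, rel.tol = 1e-10)$value
  q2 <- stats::integrate(function(v) vapply(v, inner, numeric(1)),
                         -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(marginal_emission_loglik(p3, x3)[1], log(q2),
               tolerance = 1e-6)
})

test_that("conditional moments match the Schur-complement closed form", {
  # hand case: bivariate, rho = 0.5, x1 observed at 1
  cm <- conditional_moments(c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2),
                            c(1, NA))
  expect_equal(cm$mean, c(1, 0.5), tolerance = 1e-12)
  expect_equal(cm$cov, matrix(c(0, 0, 0, 0.75), 2), tolerance = 1e-12)

  # fully observed and fully missing rows
  p <- random_params(1, 3, seed = 7)
  x <- c(1, -2, 0.5)
  full <- conditional_moments(p$mu[1, ], p$sigma[, , 1], x)
  expect_equal(full$mean, x)
  expect_equal(full$cov, matrix(0, 3, 3))
  none <- conditional_moments(p$mu[1, ], p$sigma[, , 1], rep(NA_real_, 3))
  expect_equal(none$mean, p$mu[1, ])
  expect_equal(none$cov, p$sigma[, , 1])

  # general patterns against direct solve-based Schur complements
  for (seed in 1:5) {
    pp <- random_params(1, 4, seed = 100 + seed)
    mu <- pp$mu[1, ]; S <- pp$sigma[, , 1]
    x <- rnorm(4); x[c(2, 4)] <- NA
    o <- c(1, 3); m <- c(2, 4)
    cm <- conditional_moments(mu, S, x)
    W <- S[m, o] %*% solve(S[o, o])
    expect_equal(cm$mean[m],
                 mu[m] + as.vector(W %*% (x[o] - mu[o])),
                 tolerance = 1e-10)
    expect_equal(cm$cov[m, m], S[m, m] - W %*% S[o, m],
                 tolerance = 1e-10)
    expect_equal(cm$mean[o], x[o])
    expect_true(all(cm$cov[o, ] == 0) && all(cm$cov[, o] == 0))
  }
})

test_that("forward-backward matches path enumeration with missing data", {
  for (seed in 1:8) {
    K <- sample(2:3, 1)
    d <- sample(2:3, 1)
    p <- random_params(K, d, seed = 200 + seed)
    Tn <- sample(2:4, 1)
    set.seed(300 + seed)
    obs <- matrix(rnorm(Tn * d), Tn, d)
    obs[runif(Tn * d) < 0.3] <- NA
    if (all(is.na(obs[1, ]))) obs[1, 1] <- 0.1
    fb <- forward_backward(p, obs)
    expect_equal(fb$loglik, oracle_enum_loglik(p, obs), tolerance = 1e-8)
    expect_equal(fb$gamma, oracle_enum_gamma(p, obs), tolerance = 1e-8)
    # posterior consistency invariants
    expect_equal(rowSums(fb$gamma), rep(1, Tn), tolerance = 1e-8)
    if (Tn > 1) for (t in seq_len(Tn - 1))
      expect_equal(rowSums(fb$xi[t, , , drop = TRUE]), fb$gamma[t, ],
                   tolerance = 1e-8)
  }
})

test_that("forward-backward degenerates correctly at T = 1 and no data", {
  p <- random_params(3, 2, seed = 11)
  x <- matrix(c(0.3, -0.2), 1, 2)
  fb <- forward_backward(p, x)
  lk <- exp(marginal_emission_loglik(p, x[1, ]))
  expect_equal(fb$gamma[1, ], p$pi * lk / sum(p$pi * lk), tolerance = 1e-12)
  expect_equal(fb$loglik, log(sum(p$pi * lk)), tolerance = 1e-12)

  # all rows missing: pure prior propagation, zero log-likelihood
  blank <- matrix(NA_real_, 3, 2)
  fb2 <- forward_backward(p, blank)
  expect_equal(fb2$loglik, 0)
  expect_equal(fb2$gamma[1, ], p$pi, tolerance = 1e-12)
  expect_equal(fb2$gamma[2, ], as.vector(p$pi %*% p$A), tolerance = 1e-12)
  expect_equal(fb2$gamma[3, ], as.vector(p$pi %*% p$A %*% p$A),
               tolerance = 1e-12)
})

test_that("compiled and reference E-steps agree", {
  panel <- random_panel(12, 3, seed = 21, mar_rate = 0.3)
  p <- random_params(3, 3, seed = 22)
  a <- e_step(p, panel, engine = "cpp")
  b <- e_step(p, panel, engine = "r")
  expect_equal(a$loglik, b$loglik, tolerance = 1e-10)
  expect_equal(a$start_w, b$start_w, tolerance = 1e-10)
  expect_equal(a$trans_w, b$trans_w, tolerance = 1e-10)
  expect_equal(a$w, b$w, tolerance = 1e-10)
  expect_equal(a$m1, b$m1, tolerance = 1e-10)
  expect_equal(a$m2, b$m2, tolerance = 1e-10)
})

test_that("E-step pooled moments match enumeration + quadrature", {
  # d = 2, K = 2, one missing cell: gamma by path enumeration, conditional
  # moments by 1-D quadrature against the joint density
  p <- random_params(2, 2, seed = 31)
  obs <- matrix(c(0.5, -1.2, 0.9, NA), 2, 2, byrow = TRUE)
  panel <- coag_panel(list(list(patient_id = "A", obs = obs)),
                      feature_names = c("V1", "V2"),
                      grid_hours = c(0L, 24L))
  st <- e_step(p, panel, engine = "r")
  g <- oracle_enum_gamma(p, obs)
  m2_oracle <- array(0, c(2, 2, 2))
  m1_oracle <- matrix(0, 2, 2)
  for (k in 1:2) {
    m1_oracle[k, ] <- g[1, k] * obs[1, ]
    m2_oracle[, , k] <- g[1, k] * tcrossprod(obs[1, ])
    f <- function(v) vapply(v, function(x2)
      oracle_obs_density(p$mu[k, ], p$sigma[, , k], c(0.9, x2)), numeric(1))
    z0 <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-11)$value
    e1 <- stats::integrate(function(v) v * f(v), -Inf, Inf,
                           rel.tol = 1e-11)$value / z0
    e2 <- stats::integrate(function(v) v^2 * f(v), -Inf, Inf,
                           rel.tol = 1e-11)$value / z0
    xe <- c(0.9, e1)
    xx <- tcrossprod(xe)
    xx[2, 2] <- e2
    m1_oracle[k, ] <- m1_oracle[k, ] + g[2, k] * xe
    m2_oracle[, , k] <- m2_oracle[, , k] + g[2, k] * xx
  }
  expect_equal(st$m1, m1_oracle, tolerance = 1e-6)
  expect_equal(st$m2, m2_oracle, tolerance = 1e-6)
})

test_that("M-step reproduces Gaussian MLEs and maximizes the Q function", {
  # one state, fully observed: mean and 1/n covariance
  set.seed(51)
  X <- matrix(rnorm(40 * 3), 40, 3)
  panel <- coag_panel(list(list(patient_id = "A", obs = X[1:4, ])),
                      feature_names = paste0("V", 1:3),
                      grid_hours = GRID_HOURS_TEST[1:4])
  panel$patients <- lapply(seq_len(10), function(i)
    list(patient_id = paste0("P", i), obs = X[(4 * i - 3):(4 * i), ],
         T = 4L))
  p1 <- random_params(1, 3, seed = 52)
  upd <- m_step(e_step(p1, panel, engine = "r"), reg = 0)
  expect_equal(upd$mu[1, ], colMeans(X), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(upd$sigma[, , 1], cov(X) * 39 / 40, tolerance = 1e-10)

  # sequences surely starting in state 1 pin pi
  p2 <- random_params(2, 1, seed = 53)
  p2$mu <- matrix(c(0, 50), 2, 1)   # far-separated states
  p2$sigma <- array(1, c(1, 1, 2))
  pan2 <- coag_panel(list(list(patient_id = "a", obs = matrix(c(0.1, 50.2))),
                          list(patient_id = "b", obs = matrix(c(-0.1, 49)))),
                     feature_names = "V1", grid_hours = c(0L, 24L))
  upd2 <- m_step(e_step(p2, pan2, engine = "r"))
  expect_equal(upd2$pi, c(1, 0), tolerance = 1e-9)

  # K = 2, d = 1: closed form equals numerical maximization of Q
  p3 <- random_params(2, 1, seed = 54)
  pan3 <- random_panel(8, 1, seed = 55, mar_rate = 0.2)
  st <- e_step(p3, pan3, engine = "r")
  upd3 <- m_step(st, reg = 0)
  qfun <- function(theta) {
    pi1 <- plogis(theta[1])
    A <- rbind(c(plogis(theta[2]), 1 - plogis(theta[2])),
               c(plogis(theta[3]), 1 - plogis(theta[3])))
    mu <- theta[4:5]; s2 <- exp(theta[6:7])
    q <- sum(st$start_w * log(c(pi1, 1 - pi1))) +
      sum(st$trans_w * log(A))
    for (k in 1:2)
      q <- q - 0.5 * st$w[k] * log(2 * pi * s2[k]) -
        0.5 / s2[k] * (st$m2[1, 1, k] - 2 * mu[k] * st$m1[k, 1] +
                         st$w[k] * mu[k]^2)
    -q
  }
  opt <- optim(c(0, 0, 0, mean(st$m1 / st$w), mean(st$m1 / st$w), 0, 0),
               qfun, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(upd3$pi[1], plogis(opt$par[1]), tolerance = 1e-4)
  expect_equal(upd3$A[1, 1], plogis(opt$par[2]), tolerance = 1e-4)
  expect_equal(upd3$A[2, 1], plogis(opt$par[3]), tolerance = 1e-4)
  expect_equal(unname(upd3$mu[, 1]), opt$par[4:5], tolerance = 1e-4)
  expect_equal(unname(c(upd3$sigma[1, 1, ])), exp(opt$par[6:7]),
               tolerance = 1e-3)
})

test_that("M-step flags states with no posterior weight", {
  st <- list(start_w = c(1, 0), trans_w = matrix(0.5, 2, 2),
             w = c(5, 0), m1 = matrix(c(1, 0), 2, 1),
             m2 = array(c(2, 0), c(1, 1, 2)))
  expect_error(m_step(st), "degenerate state")
})

test_that("EM converges to the single-Gaussian MLE when K = 1", {
  panel <- random_panel(10, 2, seed = 61)
  fit <- fit_em(panel, K = 1, seed = 1)
  X <- do.call(rbind, lapply(panel$patients, function(p) p$obs))
  expect_lte(fit$n_iter, 3L)
  expect_equal(fit$params$mu[1, ], colMeans(X), tolerance = 1e-8,
               ignore_attr = TRUE)
  n <- nrow(X)
  expect_equal(fit$params$sigma[, , 1], unname(cov(X) * (n - 1) / n),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("fits are bit-reproducible from the seed", {
  panel <- random_panel(15, 2, seed = 71, mar_rate = 0.2)
  f1 <- fit_em(panel, K = 2, seed = 9, max_iter = 25)
  f2 <- fit_em(panel, K = 2, seed = 9, max_iter = 25)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  expect_identical(f1$params$mu, f2$params$mu)
  expect_identical(f1$params$A, f2$params$A)
})

test_that("EM log-likelihood traces are non-decreasing on random instances", {
  worst <- 0
  for (i in 1:50) {
    panel <- random_panel(6, 2, seed = 1000 + i,
                          mar_rate = ifelse(i %% 2 == 0, 0.3, 0))
    fit <- fit_em(panel, K = 2, seed = i, max_iter = 12)
    dl <- diff(fit$loglik_trace)
    worst <- min(worst, min(dl))
    expect_gte(min(dl), -1e-6)
  }
  # and on both engines for a handful of instances
  for (i in 1:5) {
    panel <- random_panel(6, 2, seed = 2000 + i, mar_rate = 0.25)
    fit <- fit_em(panel, K = 2, seed = i, max_iter = 12, engine = "r")
    expect_gte(min(diff(fit$loglik_trace)), -1e-6)
  }
})

test_that("missing-data EM reduces to complete-data EM when nothing is missing", {
  panel <- random_panel(12, 3, seed = 81, mar_rate = 0)
  init <- random_params(2, 3, seed = 82)
  fit <- fit_em(panel, K = 2, max_iter = 8, tol = 0, init = init)
  ora <- oracle_complete_em(panel, init, n_iter = 8)
  expect_equal(fit$loglik_trace, ora$trace, tolerance = 1e-9)
  expect_equal(fit$params$mu, ora$params$mu, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$params$A, ora$params$A, tolerance = 1e-8)
  expect_equal(fit$params$sigma, ora$params$sigma, tolerance = 1e-8)
})

test_that("viterbi matches brute-force path enumeration", {
  for (seed in 1:8) {
    K <- sample(2:3, 1); d <- 2
    p <- random_params(K, d, seed = 400 + seed)
    Tn <- sample(2:4, 1)
    set.seed(500 + seed)
    obs <- matrix(rnorm(Tn * d), Tn, d)
    obs[runif(Tn * d) < 0.25] <- NA
    expect_equal(viterbi(p, obs), oracle_enum_viterbi(p, obs))
  }
  # K = 1: constant path
  p1 <- random_params(1, 2, seed = 90)
  expect_equal(viterbi(p1, matrix(rnorm(6), 3, 2)), rep(1L, 3))
  # uninformative data with a concentrated prior and identity transitions
  p2 <- hmm_params(pi = c(1, 0), A = diag(2), mu = matrix(0, 2, 1),
                   sigma = array(1, c(1, 1, 2)))
  expect_equal(viterbi(p2, matrix(NA_real_, 4, 1)), rep(1L, 4))
})

test_that("a 2-state well-separated cohort is recovered by EM", {
  truth <- hmm_params(
    pi = c(0.7, 0.3),
    A = rbind(c(0.8, 0.2), c(0.3, 0.7)),
    mu = rbind(c(0, 0), c(4, 4)),
    sigma = array(diag(2), c(2, 2, 2)))
  cfg <- generator_config(params = truth, length_weights = rep(1, 6),
                          mar_rate = 0.2, outcome_probs = cbind(
                            death = c(0.5, 0.5), discharge = c(0.5, 0.5)),
                          seed = 123L)
  sim <- simulate_cohort(cfg, 500)
  masked <- apply_mar_mask(sim$panel, mar_rate = 0.2, seed = 124L)
  fit <- fit_em(masked$panel, K = 2, seed = 7)
  perm <- align_states(fit$params, truth)
  ap <- permute_states(fit$params, perm)
  expect_lt(max(abs(ap$A - truth$A)), 0.05)
  expect_lt(max(abs(ap$pi - truth$pi)), 0.05)
})

test_that("model JSON round trip is exact", {
  p <- random_params(3, 4, seed = 91)
  p$feature_names <- paste0("V", 1:4)
  colnames(p$mu) <- p$feature_names
  path <- tempfile(fileext = ".json")
  write_hmm_model(p, path)
  back <- read_hmm_model(path)
  expect_identical(back$pi, p$pi)
  expect_identical(unname(back$A), unname(p$A))
  expect_identical(unname(back$mu), unname(p$mu))
  expect_identical(back$sigma, p$sigma)
})
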