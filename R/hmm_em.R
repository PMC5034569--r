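#' State-wise emission log-density of a partially observed row
#'
#' For each state, evaluates the log density of the observed sub-vector under
#' the marginal Gaussian obtained by restricting that state's mean and
#' covariance to the observed dimensions. A row with nothing observed
#' contributes a unit factor to the likelihood, i.e. log-density 0 for every
#' state, so the latent state there is informed purely by its neighbours
#' through the transition structure.
#'
#' @param params an [hmm_params] object.
#' @param obs_row length-`d` numeric vector (entries at unobserved dims are
#'   ignored).
#' @param mask length-`d` logical, `TRUE` = observed. Defaults to
#'   `!is.na(obs_row)`.
#' @return length-`K` vector of log densities.
#' @export
marginal_emission_loglik <- function(params, obs_row, mask = !is.na(obs_row)) {
  K <- params$K
  o <- which(mask)
  if (length(o) == 0L) return(rep(0, K))
  x <- obs_row[o]
  vapply(seq_len(K), function(k) {
    S <- params$sigma[o, o, k, drop = FALSE]
    dim(S) <- c(length(o), length(o))
    R <- tryCatch(chol(S), error = function(e)
      stop("non-positive-definite observed-block covariance in state ", k))
    z <- backsolve(R, x - params$mu[k, o], transpose = TRUE)
    -0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
  }, numeric(1))
}

#' Conditional Gaussian moments of the missing entries of a row
#'
#' Given a Gaussian `N(mu, sigma)` and a row observed on a subset of
#' dimensions, returns the conditional mean and covariance of the full vector
#' given the observed part. Observed dimensions are clamped to their observed
#' values (zero conditional variance); missing dimensions get the regression
#' mean `mu_m + S_mo S_oo^{-1} (x_o - mu_o)` and the Schur-complement
#' covariance `S_mm - S_mo S_oo^{-1} S_om`.
#'
#' @param mu length-`d` mean vector.
#' @param sigma `d x d` covariance (symmetric positive definite).
#' @param obs_row length-`d` vector.
#' @param mask length-`d` logical, `TRUE` = observed.
#' @return list with `mean` (length `d`) and `cov` (`d x d`, zero on observed
#'   rows/columns).
#' @export
conditional_moments <- function(mu, sigma, obs_row, mask = !is.na(obs_row)) {
  d <- length(mu)
  o <- which(mask); m <- which(!mask)
  cmean <- numeric(d); ccov <- matrix(0, d, d)
  cmean[o] <- obs_row[o]
  if (length(m) == 0L) return(list(mean = cmean, cov = ccov))
  if (length(o) == 0L) return(list(mean = mu, cov = sigma))
  Soo <- sigma[o, o, drop = FALSE]
  Smo <- sigma[m, o, drop = FALSE]
  R <- tryCatch(chol(Soo),
                error = function(e) stop("singular observed block"))
  ## W = S_mo S_oo^{-1} via two triangular solves
  W <- t(backsolve(R, backsolve(R, t(Smo), transpose = TRUE)))
  cmean[m] <- mu[m] + as.vector(W %*% (obs_row[o] - mu[o]))
  ccov[m, m] <- sigma[m, m, drop = FALSE] - W %*% t(Smo)
  list(mean = cmean, cov = ccov)
}

#' Forward-backward smoothing for one patient series
#'
#' Runs the scaled forward-backward recursions over a patient's attended
#' window, marginalizing missing analytes out of each emission term. Returns
#' the smoothed state probabilities, pairwise transition posteriors and the
#' observed-data log-likelihood of the sequence.
#'
#' @param params an [hmm_params] object.
#' @param obs `T x d` observation matrix with `NA` marking missing entries
#'   (a patient entry's `obs`, or a full [coag_panel] patient).
#' @return list with `gamma` (`T x K`), `xi` (`(T-1) x K x K` array, or a
#'   `0 x K x K` array when `T = 1`), and `loglik`.
#' @export
forward_backward <- function(params, obs) {
  if (is.list(obs)) obs <- obs$obs
  obs <- as.matrix(obs)
  Tlen <- nrow(obs); K <- params$K
  logB <- t(vapply(seq_len(Tlen),
                   function(t) marginal_emission_loglik(params, obs[t, ]),
                   numeric(K)))
  dim(logB) <- c(Tlen, K)
  ## scale each row before exponentiating to avoid underflow
  shift <- apply(logB, 1, max)
  B <- exp(logB - shift)
  alpha <- matrix(0, Tlen, K); cvec <- numeric(Tlen)
  a <- params$pi * B[1, ]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  if (Tlen > 1L) for (t in 2:Tlen) {
    a <- as.vector(alpha[t - 1L, ] %*% params$A) * B[t, ]
    cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(1, Tlen, K)
  if (Tlen > 1L) for (t in (Tlen - 1L):1L) {
    beta[t, ] <- as.vector(params$A %*% (B[t + 1L, ] * beta[t + 1L, ])) /
      cvec[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- array(0, c(max(Tlen - 1L, 0L), K, K))
  if (Tlen > 1L) for (t in seq_len(Tlen - 1L)) {
    M <- outer(alpha[t, ], B[t + 1L, ] * beta[t + 1L, ]) * params$A
    xi[t, , ] <- M / sum(M)
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)) + sum(shift))
}

#' E-step: pooled expected sufficient statistics
#'
#' Accumulates, over all patients, the expected counts for the initial
#' distribution and transition matrix and the per-state expected first and
#' second moments of the completed observations, where missing entries are
#' replaced by their state-conditional Gaussian posterior moments
#' (see [conditional_moments()]).
#'
#' @param params an [hmm_params] object.
#' @param panel a [coag_panel].
#' @param engine `"cpp"` (compiled fast path) or `"r"` (reference
#'   implementation); both produce the same statistics.
#' @return list with `loglik` (total observed-data log-likelihood), `start_w`
#'   (length `K`), `trans_w` (`K x K`), `w` (length-`K` state weights), `m1`
#'   (`K x d` weighted first moments), `m2` (`d x d x K` weighted second
#'   moments), and `gamma` (list of per-patient smoothing matrices).
#' @export
e_step <- function(params, panel, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp") return(e_step_cpp(params, panel))
  K <- params$K; d <- params$d
  start_w <- numeric(K); trans_w <- matrix(0, K, K)
  w <- numeric(K); m1 <- matrix(0, K, d); m2 <- array(0, c(d, d, K))
  loglik <- 0; gammas <- vector("list", length(panel$patients))
  for (i in seq_along(panel$patients)) {
    p <- panel$patients[[i]]
    fb <- tryCatch(forward_backward(params, p$obs), error = function(e)
      stop("E-step failed for patient ", p$patient_id, ": ",
           conditionMessage(e)))
    loglik <- loglik + fb$loglik
    gammas[[i]] <- fb$gamma
    start_w <- start_w + fb$gamma[1, ]
    if (p$T > 1L) trans_w <- trans_w + apply(fb$xi, c(2, 3), sum)
    for (t in seq_len(p$T)) {
      for (k in seq_len(K)) {
        g <- fb$gamma[t, k]
        cm <- conditional_moments(params$mu[k, ], params$sigma[, , k],
                                  p$obs[t, ])
        w[k] <- w[k] + g
        m1[k, ] <- m1[k, ] + g * cm$mean
        m2[, , k] <- m2[, , k] + g * (tcrossprod(cm$mean) + cm$cov)
      }
    }
  }
  list(loglik = loglik, start_w = start_w, trans_w = trans_w,
       w = w, m1 = m1, m2 = m2, gamma = gammas)
}

e_step_cpp <- function(params, panel) {
  fl <- flatten_panel(panel)
  res <- hmm_estep_core(fl$obs, fl$mask, fl$lens, params$pi, params$A,
                        params$mu, params$sigma)
  offsets <- c(0L, cumsum(fl$lens))
  gammas <- lapply(seq_along(fl$lens), function(i)
    res$gamma[(offsets[i] + 1L):offsets[i + 1L], , drop = FALSE])
  list(loglik = res$loglik, start_w = as.vector(res$start_w),
       trans_w = res$trans_w, w = as.vector(res$w), m1 = res$m1,
       m2 = res$m2, gamma = gammas)
}

flatten_panel <- function(panel) {
  lens <- vapply(panel$patients, function(p) p$T, integer(1))
  obs <- do.call(rbind, lapply(panel$patients, function(p) p$obs))
  mask <- !is.na(obs)
  obs[!mask] <- 0
  list(obs = obs, mask = mask * 1L, lens = lens)
}

#' M-step: parameter updates from pooled statistics
#'
#' Closed-form maximizers of the expected complete-data log-likelihood:
#' `pi` proportional to the pooled first-slot smoothing weights, transition
#' rows proportional to pooled pairwise posteriors, means the weighted
#' expected first moments, covariances the weighted expected second moments
#' minus the mean outer product. A small ridge (`reg` times the mean diagonal)
#' is added to every covariance to keep it positive definite under heavy
#' missingness.
#'
#' @param stats pooled statistics from [e_step()].
#' @param reg relative covariance ridge (default `1e-6`).
#' @param feature_names optional names for the observation dimensions.
#' @return an [hmm_params] object.
#' @export
m_step <- function(stats, reg = 1e-6, feature_names = NULL) {
  K <- length(stats$w); d <- ncol(stats$m1)
  if (any(stats$w < 1e-8))
    stop("degenerate state: state ",
         paste(which(stats$w < 1e-8), collapse = ", "),
         " has (near-)zero posterior weight; restart advised")
  pi <- stats$start_w / sum(stats$start_w)
  rs <- rowSums(stats$trans_w)
  A <- stats$trans_w / ifelse(rs > 0, rs, 1)
  A[rs == 0, ] <- 1 / K   # state never followed by another slot
  mu <- stats$m1 / stats$w
  sigma <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    S <- stats$m2[, , k] / stats$w[k] - tcrossprod(mu[k, ])
    S <- (S + t(S)) / 2
    md <- mean(diag(S))
    if (!is.finite(md) || md <= 0)
      stop("degenerate state: state ", k,
           " collapsed to zero variance; restart advised")
    S <- S + diag(reg * md, d)
    ## a state supported by few effective observations can leave S on the
    ## PSD boundary; clip its spectrum just above zero
    ev <- eigen(S, symmetric = TRUE)
    if (ev$values[d] <= 0) {
      floor_ev <- max(reg, 1e-10) * md
      S <- ev$vectors %*% (pmax(ev$values, floor_ev) * t(ev$vectors))
    }
    sigma[, , k] <- (S + t(S)) / 2
  }
  hmm_params(pi = pi, A = A, mu = mu, sigma = sigma,
             feature_names = feature_names)
}

#' Fit the Gaussian HMM by EM
#'
#' Baum-Welch with the missing-data E-step: starting from a seeded
#' initialization (k-means centres on mean-imputed rows, pooled covariance,
#' near-uniform jittered `pi` and `A`), alternates [e_step()] and [m_step()]
#' until the relative log-likelihood improvement drops below `tol` or
#' `max_iter` iterations. The observed-data log-likelihood is non-decreasing
#' along the trace, a property the test suite checks.
#'
#' @param panel a [coag_panel].
#' @param K number of hidden states.
#' @param seed integer seed controlling the initialization (recorded in the
#'   result; the same seed reproduces the fit exactly).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @param reg covariance ridge passed to [m_step()].
#' @param engine `"cpp"` or `"r"` E-step (identical results).
#' @param init optional [hmm_params] to start from, overriding the seeded
#'   initialization.
#' @return object of class `hmm_fit`: list with `params`, `loglik_trace`,
#'   `loglik` (final), `n_iter`, `converged`, `seed`, `n_data`, `bic`.
#' @export
fit_em <- function(panel, K, seed = 1L, tol = 1e-6, max_iter = 500L,
                   reg = 1e-6, engine = c("cpp", "r"), init = NULL) {
  engine <- match.arg(engine)
  stopifnot(K >= 1L, length(panel$patients) > 0L)
  params <- if (is.null(init)) init_params(panel, K, seed) else init
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    stats <- e_step(params, panel, engine = engine)
    trace <- c(trace, stats$loglik)
    iter <- iter + 1L
    n <- length(trace)
    if (n > 1L &&
        abs(trace[n] - trace[n - 1L]) <=
          tol * (abs(trace[n - 1L]) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    params <- tryCatch(
      m_step(stats, reg = reg, feature_names = panel$feature_names),
      error = function(e) stop("EM iteration ", iter, ": ",
                               conditionMessage(e)))
  }
  nd <- n_pairs(panel)
  structure(list(params = params, loglik_trace = trace,
                 loglik = trace[length(trace)], n_iter = iter,
                 converged = converged, seed = seed, n_data = nd,
                 bic = hmm_bic(trace[length(trace)], K, params$d, nd)),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Gaussian-HMM fit: K =", x$params$K, " loglik =",
      format(x$loglik, digits = 8), " BIC =", format(x$bic, digits = 8),
      "\n  iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(iteration cap reached)",
      " seed:", x$seed, "\n")
  invisible(x)
}

## Seeded initialization: k-means on mean-imputed observation rows for the
## means, the pooled covariance for every state, and near-uniform pi and A
## with Dirichlet jitter to break ties.
init_params <- function(panel, K, seed) {
  fl <- flatten_panel(panel)
  X <- fl$obs
  X[fl$mask == 0L] <- NA
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- cm[j]
  set.seed(seed)
  centers <- if (K == 1L) {
    matrix(colMeans(X), 1L)
  } else {
    km <- suppressWarnings(
      stats::kmeans(X, centers = K, nstart = 1L, iter.max = 50L))
    km$centers
  }
  S <- stats::cov(X) * (nrow(X) - 1L) / nrow(X)
  S <- S + diag(1e-6 * mean(diag(S)) + 1e-12, ncol(X))
  sigma <- array(S, c(ncol(X), ncol(X), K))
  rdir <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }
  pi <- rdir(rep(50, K))
  A <- t(vapply(seq_len(K), function(k) rdir(rep(50, K)), numeric(K)))
  if (K == 1L) A <- matrix(1, 1, 1)
  hmm_params(pi = pi, A = A,
             mu = matrix(centers, K, ncol(X),
                         dimnames = list(NULL, panel$feature_names)),
             sigma = sigma, feature_names = panel$feature_names)
}

#' Most probable state path for one patient
#'
#' Log-space Viterbi decoding of the maximum-a-posteriori state sequence
#' given the observed entries of a patient's series. Ties are broken toward
#' the lowest state index.
#'
#' @param params an [hmm_params] object.
#' @param obs `T x d` observation matrix with `NA` for missing entries, or a
#'   panel patient entry.
#' @return integer vector of length `T` with states in `1..K`.
#' @export
viterbi <- function(params, obs) {
  if (is.list(obs)) obs <- obs$obs
  obs <- as.matrix(obs)
  Tlen <- nrow(obs); K <- params$K
  logA <- log(params$A)
  delta <- log(params$pi) + marginal_emission_loglik(params, obs[1, ])
  psi <- matrix(0L, Tlen, K)
  if (Tlen > 1L) for (t in 2:Tlen) {
    cand <- delta + logA           # cand[j, i] = delta[j] + log A[j, i]
    best <- apply(cand, 2, which.max)
    psi[t, ] <- best
    delta <- cand[cbind(best, seq_len(K))] +
      marginal_emission_loglik(params, obs[t, ])
  }
  path <- integer(Tlen)
  path[Tlen] <- which.max(delta)
  if (Tlen > 1L) for (t in (Tlen - 1L):1L)
    path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

#' Decode every patient in a panel
#'
#' @param params an [hmm_params] object.
#' @param panel a [coag_panel].
#' @return list of integer state paths named by patient id.
#' @export
decode_panel <- function(params, panel) {
  paths <- lapply(panel$patients, function(p) viterbi(params, p$obs))
  names(paths) <- vapply(panel$patients, function(p)
    as.character(p$patient_id), character(1))
  paths
}
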