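#' Construct and validate Gaussian-HMM parameters
#'
#' Bundles the parameters of a hidden Markov model with multivariate Gaussian
#' emissions: the initial state distribution `pi`, the `K x K` transition
#' matrix `A` (oriented `A[from, to]`), and per-state emission means and
#' covariances.
#'
#' @param pi numeric length-`K` initial state distribution; must sum to 1.
#' @param A `K x K` transition matrix; each row must sum to 1. `A[j, i]` is
#'   the probability of moving from state `j` to state `i` over one 24 h step.
#' @param mu `K x d` matrix of state-conditional emission means (one row per
#'   state).
#' @param sigma `d x d x K` array of state-conditional covariance matrices;
#'   each slice must be symmetric positive definite.
#' @param feature_names optional character vector of length `d` naming the
#'   observation dimensions.
#'
#' @return An object of class `hmm_params` with elements `K`, `d`, `pi`, `A`,
#'   `mu`, `sigma`, `feature_names`.
#' @examples
#' p <- hmm_params(pi = c(0.5, 0.5),
#'                 A = matrix(0.5, 2, 2),
#'                 mu = rbind(0, 3),
#'                 sigma = array(1, c(1, 1, 2)))
#' p$K
#' @export
hmm_params <- function(pi, A, mu, sigma, feature_names = NULL) {
  pi <- as.numeric(pi)
  K <- length(pi)
  A <- as.matrix(A)
  mu <- as.matrix(mu)
  d <- ncol(mu)
  if (is.matrix(sigma) && K == 1L) sigma <- array(sigma, c(d, d, 1L))
  if (is.null(feature_names)) feature_names <- colnames(mu)
  if (!is.null(feature_names)) colnames(mu) <- feature_names
  obj <- structure(
    list(K = K, d = d, pi = pi, A = A, mu = mu, sigma = sigma,
         feature_names = feature_names),
    class = "hmm_params")
  validate_hmm_params(obj)
  obj
}

#' @rdname hmm_params
#' @param params an `hmm_params` object.
#' @param tol tolerance for the sum-to-one checks.
#' @export
validate_hmm_params <- function(params, tol = 1e-10) {
  stopifnot(inherits(params, "hmm_params"))
  K <- params$K; d <- params$d
  if (nrow(params$A) != K || ncol(params$A) != K)
    stop("transition matrix must be ", K, " x ", K)
  if (nrow(params$mu) != K || ncol(params$mu) != d)
    stop("mu must be K x d")
  if (!all(dim(params$sigma) == c(d, d, K)))
    stop("sigma must be d x d x K")
  if (abs(sum(params$pi) - 1) > tol)
    stop("pi must sum to 1 (deviation ", format(abs(sum(params$pi) - 1)), ")")
  if (any(params$pi < 0)) stop("pi must be non-negative")
  rs <- rowSums(params$A)
  if (any(abs(rs - 1) > tol))
    stop("every row of A must sum to 1")
  if (any(params$A < 0)) stop("A must be non-negative")
  for (k in seq_len(K)) {
    S <- params$sigma[, , k]
    if (max(abs(S - t(S))) > 1e-8)
      stop("sigma[,,", k, "] is not symmetric")
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      stop("sigma[,,", k, "] is not positive definite (min eigenvalue ",
           format(ev), ")")
  }
  invisible(params)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Gaussian-emission HMM parameters\n")
  cat("  states K =", x$K, ", observation dim d =", x$d, "\n")
  cat("  pi:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  if (!is.null(x$feature_names))
    cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read and write HMM parameters as JSON
#'
#' The model file stores `K`, `d`, `feature_names`, `pi`, `A` (row-major,
#' from -> to), `mu` and the per-state covariances at full precision, so a
#' write/read round trip reproduces the object exactly.
#'
#' @param params an [hmm_params] object.
#' @param path file path of the JSON model file.
#' @return `write_hmm_model` returns `path` invisibly; `read_hmm_model`
#'   returns the reconstructed [hmm_params] object.
#' @export
write_hmm_model <- function(params, path) {
  validate_hmm_params(params)
  payload <- list(
    K = params$K, d = params$d,
    feature_names = params$feature_names,
    pi = params$pi,
    A = as.vector(t(params$A)),
    mu = as.vector(t(params$mu)),
    sigma = lapply(seq_len(params$K),
                   function(k) as.vector(t(params$sigma[, , k]))))
  ## I(17) = 17 significant digits, enough for doubles to round-trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_hmm_model
#' @export
read_hmm_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- payload$K; d <- payload$d
  ## per-state covariance vectors may arrive simplified into a K x d^2 matrix
  sig_rows <- if (is.matrix(payload$sigma))
    lapply(seq_len(K), function(k) payload$sigma[k, ]) else payload$sigma
  sigma <- array(0, c(d, d, K))
  for (k in seq_len(K))
    sigma[, , k] <- matrix(sig_rows[[k]], d, d, byrow = TRUE)
  fn <- payload$feature_names
  if (length(fn) == 0L) fn <- NULL
  hmm_params(pi = payload$pi,
             A = matrix(payload$A, K, K, byrow = TRUE),
             mu = matrix(payload$mu, K, d, byrow = TRUE,
                         dimnames = list(NULL, fn)),
             sigma = sigma,
             feature_names = fn)
}

#' Apply a state relabelling to HMM parameters
#'
#' Permutes all parameter blocks consistently: state `k` of the result is
#' state `perm[k]` of the input. Used to undo label switching after fitting
#' (see [align_states()]).
#'
#' @param params an [hmm_params] object.
#' @param perm integer permutation of `1:K`.
#' @return the relabelled [hmm_params].
#' @export
permute_states <- function(params, perm) {
  stopifnot(inherits(params, "hmm_params"),
            length(perm) == params$K,
            all(sort(perm) == seq_len(params$K)))
  hmm_params(pi = params$pi[perm],
             A = params$A[perm, perm, drop = FALSE],
             mu = params$mu[perm, , drop = FALSE],
             sigma = params$sigma[, , perm, drop = FALSE],
             feature_names = params$feature_names)
}
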