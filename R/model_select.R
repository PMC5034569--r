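#' Free-parameter count of a K-state Gaussian HMM
#'
#' `(K - 1)` initial probabilities, `K (K - 1)` transition probabilities,
#' `d K` emission means and `K d (d + 1) / 2` covariance entries.
#'
#' @param K number of states.
#' @param d observation dimension.
#' @return integer parameter count.
#' @examples
#' hmm_n_params(6, 10)  # 425
#' @export
hmm_n_params <- function(K, d) {
  stopifnot(K >= 1, d >= 1)
  (K - 1) + K * (K - 1) + d * K + K * d * (d + 1) / 2
}

#' Bayesian information criterion of a fitted HMM
#'
#' `BIC = -2 loglik + n_params(K, d) log(n_data)`, where `n_data` counts the
#' (patient, time) observation vectors entering the likelihood. Lower is
#' better.
#'
#' @param loglik observed-data log-likelihood.
#' @param K number of states.
#' @param d observation dimension.
#' @param n_data number of observation vectors.
#' @return the BIC value.
#' @export
hmm_bic <- function(loglik, K, d, n_data) {
  stopifnot(n_data >= 1)
  -2 * loglik + hmm_n_params(K, d) * log(n_data)
}

#' Select the number of hidden states by BIC over restarted fits
#'
#' For each candidate `K`, runs `n_restarts` EM fits from different seeded
#' initializations (seed `base_seed + 1000 K + i` for restart `i`), keeps the
#' best (highest-likelihood) fit per `K`, and returns the `K` minimizing BIC.
#' Restarts that collapse a state are logged and skipped; ties in BIC go to
#' the smaller `K`.
#'
#' @param panel a [coag_panel].
#' @param K_range candidate state counts (default `3:8`).
#' @param n_restarts restarts per `K` (default 10).
#' @param base_seed integer seed from which restart seeds are derived.
#' @param tol,max_iter,engine passed to [fit_em()].
#' @param verbose print per-K progress.
#' @return object of class `hmm_selection`: list with `best_K`, `best_fit`,
#'   `bic_curve` (data frame K/bic/loglik/n_failed/seed), and `fits` (the
#'   per-K best [fit_em()] results).
#' @export
select_model <- function(panel, K_range = 3:8, n_restarts = 10L,
                         base_seed = 1L, tol = 1e-6, max_iter = 500L,
                         engine = c("cpp", "r"), verbose = FALSE) {
  engine <- match.arg(engine)
  stopifnot(length(K_range) > 0L, length(panel$patients) > 0L)
  rows <- list(); fits <- list()
  for (K in sort(K_range)) {
    best <- NULL; n_failed <- 0L
    for (i in seq_len(n_restarts)) {
      seed_i <- as.integer(base_seed + 1000L * K + i)
      fit <- tryCatch(
        fit_em(panel, K, seed = seed_i, tol = tol, max_iter = max_iter,
               engine = engine),
        error = function(e) {
          message("select_model: K=", K, " restart ", i, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(fit)) { n_failed <- n_failed + 1L; next }
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best)) next
    fits[[as.character(K)]] <- best
    rows[[length(rows) + 1L]] <- data.frame(
      K = K, bic = best$bic, loglik = best$loglik,
      n_failed = n_failed, seed = best$seed)
    if (verbose)
      message("select_model: K=", K, " min BIC ", format(best$bic),
              " (", n_failed, " failed restarts)")
  }
  if (length(rows) == 0L)
    stop("model selection failed: every restart failed for every K")
  bic_curve <- do.call(rbind, rows)
  best_K <- bic_curve$K[which.min(bic_curve$bic)]  # ties -> smaller K
  structure(list(best_K = best_K,
                 best_fit = fits[[as.character(best_K)]],
                 bic_curve = bic_curve, fits = fits),
            class = "hmm_selection")
}

#' @export
print.hmm_selection <- function(x, ...) {
  cat("HMM state-count selection (min BIC)\n")
  print(x$bic_curve, row.names = FALSE)
  cat("best K:", x$best_K, "\n")
  invisible(x)
}

#' Write a selection result to JSON (+ CSV twin of the BIC curve)
#'
#' @param selection an `hmm_selection` object.
#' @param path JSON output path; the BIC curve is also written to
#'   `<path>.csv` for plotting.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  tmp <- tempfile(fileext = ".json")
  write_hmm_model(selection$best_fit$params, tmp)
  payload <- list(best_K = selection$best_K,
                  bic_curve = selection$bic_curve,
                  model = jsonlite::read_json(tmp, simplifyVector = TRUE))
  unlink(tmp)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(selection$bic_curve, paste0(path, ".csv"),
                   row.names = FALSE)
  invisible(path)
}
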