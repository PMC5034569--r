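#' Reference 6-state model parameters for the trauma coagulation panel
#'
#' The published fitted model for an urban trauma-center cohort: a 6-state initial
#' distribution, the 24 h transition matrix, and 10-dimensional emission
#' means over PT, PTT and the factor/anticoagulant activities. Fitted
#' covariances were never reported, so the generator uses a declared
#' stand-in: diagonal covariances whose per-analyte standard deviation is
#' `sigma_scale` times that analyte's between-state mean range (default 0.20,
#' keeping states identifiable but overlapping). Printed rounding is
#' absorbed by renormalizing each transition row into its largest entry.
#'
#' @param sigma_scale per-analyte emission s.d. as a fraction of the
#'   between-state mean range.
#' @return an [hmm_params] object with `K = 6`, `d = 10`.
#' @examples
#' p <- default_params()
#' p$pi[1]        # 0.666
#' p$A[1, 2]      # 0.768
#' @export
default_params <- function(sigma_scale = 0.20) {
  pi <- c(0.666, 0.151, 0.063, 0.054, 0.054, 0.012)
  A <- rbind(
    c(0.156, 0.768, 0.017, 0.013, 0.046, 0),
    c(0,     0.570, 0.050, 0.004, 0.017, 0.358),
    c(0,     0.121, 0.757, 0,     0.070, 0.052),
    c(0,     0.095, 0.037, 0.772, 0.047, 0.049),
    c(0,     0,     0,     0,     1,     0),
    c(0,     0,     0,     0,     0.056, 0.944))
  ## absorb printed rounding into the largest entry of each row
  for (j in seq_len(nrow(A))) {
    dev <- 1 - sum(A[j, ])
    A[j, which.max(A[j, ])] <- A[j, which.max(A[j, ])] + dev
  }
  mu <- cbind(
    PT    = c(13.883, 15.648, 17.67, 18.31, 14.287, 14.712),
    PTT   = c(27.195, 31.9, 33.376, 42.996, 31.609, 33.251),
    FII   = c(73.876, 61.495, 56.856, 65.047, 83.602, 73.627),
    FV    = c(53.025, 43.897, 53.199, 23.272, 68.063, 79.825),
    FVII  = c(85.94, 67.406, 59.516, 57.084, 109.144, 78.721),
    FVIII = c(189.304, 115.786, 314.08, 94.138, 243.429, 160.961),
    FIX   = c(121.607, 126.985, 121.193, 101.069, 189.968, 216.546),
    FX    = c(77.386, 60.911, 63.479, 58.019, 88.028, 73.885),
    ATIII = c(84.848, 73.927, 66.948, 55.363, 85.048, 87.858),
    PC    = c(90.467, 72.025, 61.216, 52.578, 96.591, 80.464))
  sds <- sigma_scale * (apply(mu, 2, max) - apply(mu, 2, min))
  sigma <- array(0, c(10, 10, 6))
  for (k in 1:6) sigma[, , k] <- diag(sds^2)
  hmm_params(pi = pi, A = A, mu = mu, sigma = sigma,
             feature_names = colnames(mu))
}

#' Per-state outcome probabilities of the reference model
#' @return `6 x 2` matrix with columns `death`, `discharge` (rows sum to 1).
#' @export
default_outcome_probs <- function() {
  p_death <- c(0.167, 0.316, 0.375, 0.6, 0.286, 0.333)
  cbind(death = p_death, discharge = 1 - p_death)
}

#' Generator configuration for synthetic cohorts
#'
#' Bundles everything the cohort simulator needs. The defaults are the study
#' conditions the analysis is validated against: the reference model
#' parameters, sequence-length weights proportional to the reported counts of
#' patients with consecutive data over 1..6 slots (588, 289, 42, 60, 2, 89),
#' 25.3 % entry-level missingness, and the reported per-state
#' death/discharge probabilities with outcome delays uniform on 0-120 h
#' after the last measurement.
#'
#' @param params an [hmm_params] (default [default_params()]).
#' @param length_weights probability weights over sequence lengths 1..6.
#' @param mar_rate entry-level missingness probability in `[0, 1)`.
#' @param outcome_probs per-state matrix with columns `death`, `discharge`.
#' @param outcome_lag_hours length-2 range of the uniform outcome delay.
#' @param seed integer seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(params = default_params(),
                             length_weights = c(588, 289, 42, 60, 2, 89),
                             mar_rate = 0.253,
                             outcome_probs = default_outcome_probs(),
                             outcome_lag_hours = c(0, 120),
                             seed = 1L) {
  length_weights <- length_weights / sum(length_weights)
  if (mar_rate < 0 || mar_rate >= 1)
    stop("mar_rate must be in [0, 1)")
  if (any(abs(rowSums(outcome_probs) - 1) > 1e-10))
    stop("outcome_probs rows must sum to 1")
  structure(list(params = params, length_weights = length_weights,
                 mar_rate = mar_rate, outcome_probs = outcome_probs,
                 outcome_lag_hours = outcome_lag_hours,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Simulate a complete (fully observed) cohort with its latent paths
#'
#' Draws, per patient, a sequence length from the length weights, a state
#' path from the initial distribution and transition matrix, and Gaussian
#' observations from the state-conditional emissions. The returned panel is
#' complete; apply [apply_mar_mask()] to emulate missing-at-random entries.
#'
#' @param config a [generator_config()].
#' @param n_patients number of patients.
#' @return list with `panel` (a [coag_panel]) and `paths` (named list of the
#'   true state sequences, for oracle testing).
#' @export
simulate_cohort <- function(config, n_patients) {
  p <- config$params
  set.seed(config$seed)
  chol_list <- lapply(seq_len(p$K), function(k) chol(p$sigma[, , k]))
  patients <- vector("list", n_patients)
  paths <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    Tlen <- sample.int(length(config$length_weights), 1L,
                       prob = config$length_weights)
    z <- integer(Tlen)
    z[1] <- sample.int(p$K, 1L, prob = p$pi)
    if (Tlen > 1L) for (t in 2:Tlen)
      z[t] <- sample.int(p$K, 1L, prob = p$A[z[t - 1L], ])
    obs <- matrix(0, Tlen, p$d, dimnames = list(NULL, p$feature_names))
    for (t in seq_len(Tlen))
      obs[t, ] <- p$mu[z[t], ] +
        as.vector(stats::rnorm(p$d) %*% chol_list[[z[t]]])
    id <- sprintf("P%05d", i)
    patients[[i]] <- list(patient_id = id, obs = obs)
    paths[[i]] <- z
  }
  names(paths) <- vapply(patients, `[[`, character(1), "patient_id")
  list(panel = coag_panel(patients, feature_names = p$feature_names),
       paths = paths)
}

#' Mask panel entries at random
#'
#' Masks each analyte entry independently with probability `mar_rate`
#' (missing completely at random, a special case of the missing-at-random
#' mechanism the model tolerates), then repairs any patient the cohort
#' inclusion rule would reject by unmasking one uniformly chosen entry in
#' their first-24 h slots. Rows left entirely missing at the end of a series
#' become censoring: the attended window `T` is recomputed. With
#' `mar_mode = "pt_dependent"` the masking probability of the other analytes
#' increases with the patient's (always observed at random) PT value,
#' exercising genuine missing-at-random dependence on observed data.
#'
#' @param panel a complete [coag_panel].
#' @param mar_rate entry-level masking probability in `[0, 1)`.
#' @param seed integer seed.
#' @param mar_mode `"mcar"` (default) or `"pt_dependent"`.
#' @return list with `panel` (masked [coag_panel]) and `realized_fraction`
#'   (the missingness fraction within attended windows).
#' @export
apply_mar_mask <- function(panel, mar_rate = 0.253, seed = 1L,
                           mar_mode = c("mcar", "pt_dependent")) {
  mar_mode <- match.arg(mar_mode)
  if (mar_rate < 0 || mar_rate >= 1) stop("mar_rate must be in [0, 1)")
  set.seed(seed)
  if (mar_rate == 0) {
    ms <- missingness_summary(panel)
    return(list(panel = panel, realized_fraction = ms$mar_fraction))
  }
  pt_col <- match("PT", panel$feature_names)
  all_pt <- unlist(lapply(panel$patients, function(p) p$obs[, pt_col]))
  pt_center <- mean(all_pt, na.rm = TRUE)
  pt_scale <- stats::sd(all_pt, na.rm = TRUE)
  kept <- vector("list", length(panel$patients))
  for (i in seq_along(panel$patients)) {
    p <- panel$patients[[i]]
    d <- ncol(p$obs)
    prob <- matrix(mar_rate, p$T, d)
    if (mar_mode == "pt_dependent") {
      z <- (p$obs[, pt_col] - pt_center) / pt_scale
      prob[, -pt_col] <- stats::plogis(
        stats::qlogis(mar_rate) + 0.5 * z)
    }
    drop <- matrix(stats::runif(p$T * d) < prob, p$T, d)
    ## repair: keep the patient admissible for the first-24 h inclusion rule
    early_rows <- seq_len(min(2L, p$T))
    early_cells <- which(
      row(p$obs) %in% early_rows & !is.na(p$obs), arr.ind = FALSE)
    if (all(drop[cbind(rep(early_rows, d),
                       rep(seq_len(d), each = length(early_rows)))])) {
      pick <- early_cells[sample.int(length(early_cells), 1L)]
      drop[pick] <- FALSE
    }
    obs <- p$obs
    obs[drop] <- NA_real_
    Tnew <- max(which(rowSums(!is.na(obs)) > 0L))
    p$obs <- obs[seq_len(Tnew), , drop = FALSE]
    kept[[i]] <- p
  }
  out <- coag_panel(kept, feature_names = panel$feature_names,
                    grid_hours = panel$grid_hours)
  ms <- missingness_summary(out)
  list(panel = out, realized_fraction = ms$mar_fraction)
}

#' Simulate death/discharge outcomes from true final states
#'
#' Draws each patient's outcome from the outcome-probability row of their
#' true final state and an outcome hour equal to the last attended slot hour
#' plus a uniform lag.
#'
#' @param paths named list of true state paths.
#' @param outcome_probs per-state matrix with columns `death`, `discharge`.
#' @param outcome_lag_hours length-2 uniform lag range (hours).
#' @param seed integer seed.
#' @param grid_hours slot hours (default the 24 h grid).
#' @return data frame with `patient_id`, `outcome`, `hour`.
#' @export
simulate_outcomes <- function(paths, outcome_probs = default_outcome_probs(),
                              outcome_lag_hours = c(0, 120), seed = 1L,
                              grid_hours = GRID_HOURS) {
  set.seed(seed)
  n <- length(paths)
  kind <- character(n); hour <- numeric(n)
  for (i in seq_len(n)) {
    z <- paths[[i]]
    k <- z[length(z)]
    kind[i] <- if (stats::runif(1) < outcome_probs[k, "death"])
      "death" else "discharge"
    hour[i] <- grid_hours[length(z)] +
      stats::runif(1, outcome_lag_hours[1], outcome_lag_hours[2])
  }
  data.frame(patient_id = names(paths), outcome = kind, hour = hour,
             stringsAsFactors = FALSE)
}

#' One-call synthetic study: masked panel, outcomes and ground truth
#'
#' Convenience wrapper running [simulate_cohort()], [apply_mar_mask()] and
#' [simulate_outcomes()] with seeds derived from `config$seed`, and attaching
#' the outcomes to the panel.
#'
#' @param config a [generator_config()].
#' @param n_patients number of patients.
#' @return list with `panel` (masked, outcomes attached), `outcomes`,
#'   `paths` (true states), `complete` (the unmasked panel), and
#'   `realized_mar` (achieved missingness fraction).
#' @export
simulate_study <- function(config, n_patients) {
  sim <- simulate_cohort(config, n_patients)
  masked <- apply_mar_mask(sim$panel, mar_rate = config$mar_rate,
                           seed = config$seed + 1L)
  outc <- simulate_outcomes(sim$paths, config$outcome_probs,
                            config$outcome_lag_hours,
                            seed = config$seed + 2L)
  panel <- masked$panel
  omap <- stats::setNames(seq_len(nrow(outc)), outc$patient_id)
  panel$patients <- lapply(panel$patients, function(p) {
    j <- omap[[as.character(p$patient_id)]]
    p$outcome <- list(kind = outc$outcome[j], hour = outc$hour[j])
    p
  })
  list(panel = panel, outcomes = outc, paths = sim$paths,
       complete = sim$panel, realized_mar = masked$realized_fraction)
}
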