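#' Expected state occupancy across the time grid
#'
#' Sums the smoothed posterior state probabilities over patients at each grid
#' slot: entry `(t, k)` is the expected number of patients in state `k` at
#' slot `t`, among patients whose attended window reaches slot `t`. Row `t`
#' therefore sums to the number of patients with `T >= t`.
#'
#' @param params fitted [hmm_params].
#' @param panel a [coag_panel].
#' @return `n_slots x K` matrix of expected patient counts.
#' @export
occupancy <- function(params, panel) {
  ns <- length(panel$grid_hours)
  occ <- matrix(0, ns, params$K,
                dimnames = list(paste0("h", panel$grid_hours), NULL))
  for (p in panel$patients) {
    g <- forward_backward(params, p$obs)$gamma
    occ[seq_len(p$T), ] <- occ[seq_len(p$T), , drop = FALSE] + g
  }
  occ
}

#' Attribute death/discharge outcomes to last decoded states
#'
#' A patient contributes when their series has at least `min_len` time points
#' (single-measurement series carry too much censoring bias), an outcome is
#' recorded, and the outcome occurred within `window_hours` of the last
#' measurement. The outcome is credited to the last state of the decoded
#' path. Per-state probabilities are the shares among contributors; states
#' with no contributors are reported as `NA`, not zero.
#'
#' @param paths named list of decoded state paths (see [decode_panel()]).
#' @param outcomes data frame with `patient_id`, `outcome`, `hour`.
#' @param panel the [coag_panel] the paths were decoded from (supplies last
#'   measurement hours).
#' @param K number of states.
#' @param window_hours attribution window after the last measurement
#'   (default 120 h, i.e. 5 days).
#' @param min_len minimum number of time points (default 2).
#' @return data frame with one row per state: `state` (0-based label),
#'   `n`, `p_death`, `p_discharge`.
#' @export
attribute_outcomes <- function(paths, outcomes, panel, K = NULL,
                               window_hours = 120, min_len = 2L) {
  if (is.null(K)) K <- max(unlist(paths))
  deaths <- integer(K); total <- integer(K)
  last_hour <- stats::setNames(
    vapply(panel$patients, function(p) panel$grid_hours[p$T], numeric(1)),
    vapply(panel$patients, function(p) as.character(p$patient_id),
           character(1)))
  n_inconsistent <- 0L
  for (i in seq_len(nrow(outcomes))) {
    id <- as.character(outcomes$patient_id[i])
    path <- paths[[id]]
    if (is.null(path) || length(path) < min_len) next
    lag <- outcomes$hour[i] - last_hour[[id]]
    if (lag < 0) { n_inconsistent <- n_inconsistent + 1L; next }
    if (lag > window_hours) next
    k <- path[length(path)]
    total[k] <- total[k] + 1L
    if (outcomes$outcome[i] == "death") deaths[k] <- deaths[k] + 1L
  }
  if (n_inconsistent > 0L)
    message("attribute_outcomes: excluded ", n_inconsistent,
            " patient(s) with outcome recorded before the last measurement")
  p_death <- ifelse(total > 0L, deaths / total, NA_real_)
  data.frame(state = seq_len(K) - 1L, n = total,
             p_death = p_death, p_discharge = 1 - p_death)
}

#' Rank distinct state trajectories
#'
#' Collapses each decoded path to its sequence of distinct consecutive states
#' (run-length collapse), appends the outcome label when one exists, and
#' counts the distinct patterns. Patterns are ranked by descending count with
#' lexicographic tie-breaking; patterns visiting a single distinct state are
#' kept but flagged.
#'
#' @param paths named list of decoded state paths.
#' @param outcomes optional outcomes data frame (`patient_id`, `outcome`,
#'   `hour`).
#' @return data frame with `pattern` (e.g. `"S0>S1>discharge"`), `count`,
#'   `single_state`.
#' @export
trajectory_frequencies <- function(paths, outcomes = NULL) {
  omap <- if (is.null(outcomes)) character(0) else
    stats::setNames(outcomes$outcome, as.character(outcomes$patient_id))
  pats <- vapply(names(paths), function(id) {
    states <- rle(paths[[id]])$values - 1L
    lab <- paste0("S", states, collapse = ">")
    if (id %in% names(omap)) lab <- paste0(lab, ">", omap[[id]])
    lab
  }, character(1))
  single <- vapply(names(paths), function(id)
    length(rle(paths[[id]])$values) == 1L, logical(1))
  tab <- table(pats)
  df <- data.frame(pattern = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$single_state <- df$pattern %in% unique(pats[single])
  df[order(-df$count, df$pattern), , drop = FALSE]
}

#' Partition states into early / intermediate / late stages
#'
#' Formalizes the stage structure read off the transition matrix. Transitions
#' `j -> i` with `A[j, i] >= threshold` (off-diagonal) form a directed graph,
#' whose strongly connected components are condensed to a DAG. Stages combine
#' this topology with the persistence (self-transition probability) of each
#' state: the late stage is the terminal set of components grown back from
#' the sinks whose states are all highly persistent
#' (`A[k, k] >= stable_self`); the early stage is the source components
#' (no incoming edges) whose states are all transient (`A[k, k] <
#' unstable_self`); everything else is intermediate. Patients thus start in
#' unstable entry states, pass through moderately persistent intermediate
#' states, and settle in near-absorbing late states.
#'
#' @param A `K x K` transition matrix, `A[from, to]`.
#' @param threshold minimum probability for a transition edge (default 0.04).
#' @param stable_self persistence bound defining late-stage states
#'   (default 0.9).
#' @param unstable_self persistence bound defining early-stage states
#'   (default 0.5).
#' @return list with `stages` (character vector `"early"` / `"intermediate"`
#'   / `"late"` per state), `components` (SCC membership), `edges` (data
#'   frame of retained transitions), `degenerate` (flag: thresholded graph
#'   had no edges).
#' @export
stage_partition <- function(A, threshold = 0.04, stable_self = 0.9,
                            unstable_self = 0.5) {
  K <- nrow(A)
  off <- A * (1 - diag(K))
  idx <- which(off >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = idx[, 1], to = idx[, 2],
                      prob = off[idx])
  degenerate <- nrow(edges) == 0L
  if (degenerate) {
    warning("stage_partition: no off-diagonal transition reaches the ",
            "threshold; partition is degenerate")
    stages <- ifelse(diag(A) >= stable_self, "late",
                     ifelse(diag(A) < unstable_self, "early",
                            "intermediate"))
    return(list(stages = stages, components = seq_len(K), edges = edges,
                degenerate = TRUE))
  }
  g <- igraph::graph_from_data_frame(
    edges[c("from", "to")], directed = TRUE,
    vertices = data.frame(name = seq_len(K)))
  comp <- igraph::components(g, mode = "strong")$membership
  ## condensation DAG over SCCs
  ce <- unique(data.frame(from = comp[edges$from], to = comp[edges$to]))
  ce <- ce[ce$from != ce$to, , drop = FALSE]
  n_comp <- max(comp)
  has_in  <- seq_len(n_comp) %in% ce$to
  has_out <- seq_len(n_comp) %in% ce$from
  self <- diag(A)
  comp_stable <- vapply(seq_len(n_comp), function(c)
    all(self[comp == c] >= stable_self), logical(1))
  comp_unstable <- vapply(seq_len(n_comp), function(c)
    all(self[comp == c] < unstable_self), logical(1))
  ## late: grow back from sinks through components whose successors are all
  ## already late, requiring high persistence throughout
  late <- !has_out & comp_stable
  repeat {
    succ_late <- vapply(seq_len(n_comp), function(c) {
      s <- ce$to[ce$from == c]
      length(s) > 0L && all(late[s])
    }, logical(1))
    add <- succ_late & comp_stable & !late
    if (!any(add)) break
    late <- late | add
  }
  early <- !has_in & comp_unstable & !late
  stage_of_comp <- ifelse(late, "late", ifelse(early, "early",
                                               "intermediate"))
  list(stages = stage_of_comp[comp],
       components = as.integer(comp),
       edges = edges[order(edges$from, edges$to), , drop = FALSE],
       degenerate = FALSE)
}

#' Export the thresholded transition diagram as DOT
#'
#' Writes a Graphviz DOT file of the stage-partitioned transition graph
#' (states grouped by stage, edge width scaled by probability) for rendering
#' state-diagram figures.
#'
#' @param partition result of [stage_partition()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stage_dot <- function(partition, path) {
  K <- length(partition$stages)
  lines <- c("digraph states {", "  rankdir=LR;")
  for (st in c("early", "intermediate", "late")) {
    members <- which(partition$stages == st) - 1L
    if (length(members) > 0L)
      lines <- c(lines, paste0(
        "  subgraph cluster_", st, " { label=\"", st, "\"; ",
        paste0("S", members, ";", collapse = " "), " }"))
  }
  if (nrow(partition$edges) > 0L)
    lines <- c(lines, sprintf(
      "  S%d -> S%d [penwidth=%.2f, label=\"%.3f\"];",
      partition$edges$from - 1L, partition$edges$to - 1L,
      1 + 6 * partition$edges$prob, partition$edges$prob))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Forecast future state probabilities for one patient
#'
#' Propagates the smoothed state distribution at the patient's last attended
#' slot through the transition matrix: row `h` is `gamma[T] %*% A^h`.
#'
#' @param params fitted [hmm_params].
#' @param obs a patient's `T x d` observation matrix (or panel entry).
#' @param horizon number of 24 h steps to forecast.
#' @return `(horizon + 1) x K` matrix of state probabilities, rows labelled
#'   `h0` (the filtered/smoothed present) through `h<horizon>`.
#' @export
forecast_states <- function(params, obs, horizon) {
  stopifnot(horizon >= 0L)
  g <- forward_backward(params, obs)$gamma
  cur <- g[nrow(g), ]
  out <- matrix(0, horizon + 1L, params$K,
                dimnames = list(paste0("h", 0:horizon), NULL))
  out[1, ] <- cur
  if (horizon > 0L) for (h in seq_len(horizon)) {
    cur <- as.vector(cur %*% params$A)
    out[h + 1L, ] <- cur
  }
  out
}

#' Resolve label switching against a reference parameter set
#'
#' Finds the relabelling of the estimated states minimizing the total
#' Euclidean distance between matched emission means (exact optimal
#' assignment by exhaustive search over permutations; `K <= 8` keeps this
#' cheap). `permute_states(est, perm)` then makes `est` label-consistent
#' with `ref`.
#'
#' @param est,ref [hmm_params] objects with equal `K` and `d`.
#' @return integer permutation `perm` such that estimated state `perm[k]`
#'   matches reference state `k`.
#' @export
align_states <- function(est, ref) {
  stopifnot(est$K == ref$K, est$d == ref$d)
  K <- est$K
  cost <- matrix(0, K, K)   # cost[i, j]: est state i vs ref state j
  for (i in seq_len(K)) for (j in seq_len(K))
    cost[i, j] <- sqrt(sum((est$mu[i, ] - ref$mu[j, ])^2))
  perms <- all_permutations(K)
  tot <- apply(perms, 1, function(p) sum(cost[cbind(p, seq_len(K))]))
  as.integer(unname(perms[which.min(tot), ]))
}

## all K! permutations of 1..K as rows (K <= 8 in this package)
all_permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(i) {
    rest <- setdiff(seq_len(K), i)
    cbind(i, matrix(rest[sub], nrow(sub), K - 1L))
  }))
}
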