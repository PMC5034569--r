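#' Assemble a cohort panel
#'
#' A `coag_panel` holds per-patient sequences of 10-dimensional blood-panel
#' observation vectors on the equally spaced 24 h grid (hours 0, 24, 48, 72,
#' 96, 120). Each patient contributes a `T x 10` matrix whose rows are the
#' first `T` grid slots, with `NA` marking analytes that were not measured at
#' an attended visit (missing at random). Slots beyond `T` do not exist: the
#' series is censored there (death, discharge or drop-out), which is a
#' different mechanism and is excluded from all missingness accounting.
#'
#' @param patients list of patient entries, each a list with elements
#'   `patient_id`, `obs` (`T x d` numeric matrix, `NA` = missing entry) and
#'   optionally `outcome` (list with `kind` in `"death"`/`"discharge"` and
#'   `hour`).
#' @param feature_names character vector naming the `d` analyte columns.
#' @param grid_hours slot hours of the aggregated grid.
#' @return object of class `coag_panel`.
#' @export
coag_panel <- function(patients, feature_names = COAG_FEATURES,
                       grid_hours = GRID_HOURS) {
  patients <- lapply(patients, function(p) {
    p$obs <- as.matrix(p$obs)
    colnames(p$obs) <- feature_names
    p$T <- nrow(p$obs)
    if (p$T < 1L) stop("patient ", p$patient_id, " has an empty series")
    if (p$T > length(grid_hours))
      stop("patient ", p$patient_id, " exceeds the grid length")
    p
  })
  structure(list(patients = patients,
                 feature_names = feature_names,
                 grid_hours = grid_hours),
            class = "coag_panel")
}

#' @export
print.coag_panel <- function(x, ...) {
  Ts <- vapply(x$patients, function(p) p$T, integer(1))
  cat("coag_panel:", length(x$patients), "patients,",
      sum(Ts), "(patient, time) pairs on a",
      length(x$grid_hours), "-slot 24 h grid\n")
  invisible(x)
}

#' Number of (patient, time) observation vectors in a panel
#' @param panel a [coag_panel].
#' @return integer count `sum(T)` over patients.
#' @export
n_pairs <- function(panel) {
  sum(vapply(panel$patients, function(p) p$T, integer(1)))
}

default_schema <- function() {
  nm <- c("patient_id", "hour", COAG_FEATURES)
  stats::setNames(as.list(nm), nm)
}

#' Load a long-format clinical cohort table
#'
#' Reads a comma-separated file with one row per attended (patient, hour)
#' visit and one column per analyte. Blank or unparseable numeric cells become
#' missing values. Rows whose hour is not one of the scheduled measurement
#' hours (0, 2, 3, 4, 6, 12, 24, 48, 72, 96, 120) are dropped with a message.
#'
#' @param path path to the CSV file (header row required, UTF-8).
#' @param schema named list mapping the canonical column names
#'   (`patient_id`, `hour`, and the 10 analytes `PT`, `PTT`, `FII`, `FV`,
#'   `FVII`, `FVIII`, `FIX`, `FX`, `ATIII`, `PC`) to the source file's column
#'   names; defaults to the identity map.
#' @return data frame of raw records with canonical column names, one row per
#'   retained visit.
#' @export
load_cohort <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("empty input: ", path, " has no data rows")
  full <- default_schema()
  full[names(schema)] <- schema
  missing_cols <- setdiff(unlist(full), names(raw))
  if (length(missing_cols) > 0L)
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  out <- data.frame(
    patient_id = raw[[full$patient_id]],
    hour = suppressWarnings(as.integer(raw[[full$hour]])),
    stringsAsFactors = FALSE)
  for (f in COAG_FEATURES)
    out[[f]] <- suppressWarnings(as.numeric(raw[[full[[f]]]]))
  off <- is.na(out$hour) | !(out$hour %in% RAW_HOURS)
  if (any(off))
    message("load_cohort: rejected ", sum(off),
            " row(s) with off-schedule hours")
  out[!off, , drop = FALSE]
}

#' Load an outcomes table
#'
#' @param path CSV with columns `patient_id`, `outcome`
#'   (`death`/`discharge`) and `hour` (hours since admission).
#' @return data frame with those three columns.
#' @export
load_outcomes <- function(path) {
  if (!file.exists(path)) stop("outcomes file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "outcome", "hour")
  if (!all(need %in% names(out)))
    stop("outcomes file must have columns: ", paste(need, collapse = ", "))
  bad <- !(out$outcome %in% c("death", "discharge"))
  if (any(bad)) stop("unknown outcome values: ",
                     paste(unique(out$outcome[bad]), collapse = ", "))
  out[need]
}

#' Aggregate raw visits onto the 24 h analysis grid
#'
#' Collapses the 11 scheduled measurement hours to 6 slots: the hour-0 slot is
#' the per-analyte mean of hours 0-6 and the hour-24 slot the mean of hours
#' 12 and 24 (the intermediate hours are individually too sparse to keep);
#' hours 48-120 map one-to-one. Means ignore missing cells; a slot analyte is
#' missing only when every contributing raw cell is missing. A patient's
#' sequence length `T` is the last slot with at least one observed analyte;
#' interior slots with no observed analyte are kept as all-missing rows so the
#' grid stays equally spaced. Patients with no observed data anywhere are
#' dropped.
#'
#' @param records data frame of raw records from [load_cohort()].
#' @param outcomes optional outcomes data frame carried through onto the
#'   matching patients.
#' @return a [coag_panel].
#' @export
aggregate_timepoints <- function(records, outcomes = NULL) {
  slot_of <- function(hour) {
    if (hour <= 6L) 1L
    else if (hour <= 24L) 2L
    else match(hour, GRID_HOURS)
  }
  ids <- unique(records$patient_id)
  patients <- list()
  for (id in ids) {
    rec <- records[records$patient_id == id, , drop = FALSE]
    full <- matrix(NA_real_, length(GRID_HOURS), length(COAG_FEATURES),
                   dimnames = list(NULL, COAG_FEATURES))
    for (s in unique(vapply(rec$hour, slot_of, integer(1)))) {
      sel <- vapply(rec$hour, slot_of, integer(1)) == s
      block <- as.matrix(rec[sel, COAG_FEATURES, drop = FALSE])
      m <- colMeans(block, na.rm = TRUE)
      m[is.nan(m)] <- NA_real_
      full[s, ] <- m
    }
    Tlen <- max(c(0L, which(rowSums(!is.na(full)) > 0L)))
    if (Tlen == 0L) next
    entry <- list(patient_id = id, obs = full[seq_len(Tlen), , drop = FALSE])
    if (!is.null(outcomes)) {
      hit <- which(outcomes$patient_id == id)
      if (length(hit) > 0L)
        entry$outcome <- list(kind = outcomes$outcome[hit[1L]],
                              hour = outcomes$hour[hit[1L]])
    }
    patients[[length(patients) + 1L]] <- entry
  }
  coag_panel(patients)
}

#' Retain patients with early data
#'
#' Applies the cohort inclusion rule: a patient is kept only with at least one
#' observed analyte in the first 24 hours (slots at hours 0 or 24). Patients
#' observed only later cannot anchor the initial state and are removed.
#'
#' @param panel a [coag_panel].
#' @return the filtered [coag_panel]; errors if no patient qualifies.
#' @export
filter_patients <- function(panel) {
  keep <- vapply(panel$patients, function(p) {
    early <- p$obs[seq_len(min(2L, p$T)), , drop = FALSE]
    any(!is.na(early))
  }, logical(1))
  if (!any(keep))
    stop("empty cohort: no patient has observed data in the first 24 hours")
  removed <- sum(!keep)
  if (removed > 0L)
    message("filter_patients: removed ", removed,
            " patient(s) with no data in the first 24 hours")
  panel$patients <- panel$patients[keep]
  panel
}

#' Summarize missing-at-random entries in a panel
#'
#' Counts the missing analyte entries within each patient's attended window
#' (rows 1..T). Slots beyond `T` are censored, not missing, and appear in
#' neither numerator nor denominator.
#'
#' @param panel a filtered [coag_panel].
#' @return list with `n_patients`, `n_pairs` and `mar_fraction`.
#' @export
missingness_summary <- function(panel) {
  miss <- sum(vapply(panel$patients, function(p) sum(is.na(p$obs)),
                     numeric(1)))
  np <- n_pairs(panel)
  list(n_patients = length(panel$patients),
       n_pairs = np,
       mar_fraction = miss / (length(panel$feature_names) * np))
}

#' Write and read the canonical panel file
#'
#' The panel file is a wide CSV with columns `patient_id`, `slot_hour` and the
#' 10 analytes (blank = missing), one row per (patient, slot) within each
#' patient's attended window, accompanied by a JSON sidecar recording
#' `n_patients`, `n_pairs` and `mar_fraction`. Outcomes, if present, are
#' written to `<path>.outcomes.csv`.
#'
#' @param panel a [coag_panel].
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns the
#'   reconstructed [coag_panel].
#' @export
write_panel <- function(panel, path) {
  rows <- do.call(rbind, lapply(panel$patients, function(p) {
    df <- as.data.frame(p$obs)
    df <- cbind(patient_id = p$patient_id,
                slot_hour = panel$grid_hours[seq_len(p$T)], df)
    df
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  ms <- missingness_summary(panel)
  jsonlite::write_json(ms, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  outc <- outcomes_table(panel)
  if (nrow(outc) > 0L)
    utils::write.csv(outc, paste0(path, ".outcomes.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  opath <- paste0(path, ".outcomes.csv")
  outcomes <- if (file.exists(opath)) load_outcomes(opath) else NULL
  patients <- lapply(unique(df$patient_id), function(id) {
    block <- df[df$patient_id == id, , drop = FALSE]
    block <- block[order(block$slot_hour), , drop = FALSE]
    m <- as.matrix(block[COAG_FEATURES])
    rownames(m) <- NULL
    entry <- list(patient_id = id, obs = m)
    if (!is.null(outcomes)) {
      hit <- which(outcomes$patient_id == id)
      if (length(hit) > 0L)
        entry$outcome <- list(kind = outcomes$outcome[hit[1L]],
                              hour = outcomes$hour[hit[1L]])
    }
    entry
  })
  coag_panel(patients)
}

#' Extract the outcomes table of a panel
#' @param panel a [coag_panel].
#' @return data frame with `patient_id`, `outcome`, `hour` (possibly empty).
#' @export
outcomes_table <- function(panel) {
  rows <- lapply(panel$patients, function(p) {
    if (is.null(p$outcome)) return(NULL)
    data.frame(patient_id = p$patient_id, outcome = p$outcome$kind,
               hour = p$outcome$hour, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(patient_id = character(), outcome = character(),
                      hour = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
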