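#' Log-transform cortisol trajectories
#'
#' Replaces raw salivary cortisol concentrations (nmol/L) by their natural
#' logarithm, the scale on which all slope statistics are computed. Missing
#' values pass through untouched.
#'
#' @param series Long tibble with columns `participant_id`, `timepoint`,
#'   `minutes`, `value`.
#' @return The same tibble with `value` log-transformed.
#' @export
log_cortisol <- function(series) {
  check_series(series)
  bad <- !is.na(series$value) & series$value <= 0
  if (any(bad)) {
    abort(paste0(
      "non-positive cortisol value(s) at: ",
      paste(paste0(series$participant_id[bad], "/", series$timepoint[bad]),
            collapse = ", ")
    ))
  }
  series$value <- log(series$value)
  series
}

#' Impute a missing day-1 baseline (T0) sample
#'
#' Fills a missing T0 value by linear extrapolation from the (T1, T2) pair
#' back to T0's sampling time — the only imputation the design admits; a
#' missing value at any other timepoint is an error. Imputed rows are
#' flagged in a logical `imputed` column.
#'
#' @inheritParams log_cortisol
#' @return The series with missing T0 values filled and an `imputed` flag.
#' @export
impute_baseline <- function(series) {
  check_series(series)
  series$imputed <- FALSE
  miss <- series[is.na(series$value), , drop = FALSE]
  other <- miss$timepoint != "T0"
  if (any(other)) {
    abort(paste0(
      "only a missing T0 is imputable; missing value(s) at: ",
      paste(paste0(miss$participant_id[other], "/", miss$timepoint[other]),
            collapse = ", ")
    ))
  }
  for (pid in unique(miss$participant_id)) {
    rows <- series$participant_id == pid
    v <- setNames(series$value[rows], series$timepoint[rows])
    t <- setNames(series$minutes[rows], series$timepoint[rows])
    if (anyNA(v[c("T1", "T2")])) {
      abort(paste0("cannot impute T0 for ", pid, ": T1/T2 not both present"))
    }
    slope <- (v[["T2"]] - v[["T1"]]) / (t[["T2"]] - t[["T1"]])
    fill <- v[["T1"]] + slope * (t[["T0"]] - t[["T1"]])
    idx <- rows & series$timepoint == "T0"
    series$value[idx] <- fill
    series$imputed[idx] <- TRUE
  }
  series
}

#' Stress reactivity slope
#'
#' The rise from the pre-stress baseline (T2, sampled immediately before
#' stress induction) to the post-stress peak (the larger of T3 and T4),
#' normalized by the elapsed minutes — so the statistic is a slope in
#' value-units per minute and robust to between-participant differences in
#' sampling times. A T3/T4 tie resolves to the earlier timepoint (T3).
#' Cortisol series are expected on the log scale; subjective stress ratings
#' use the identical formula on the raw Likert scale.
#'
#' @inheritParams log_cortisol
#' @return A tibble with columns `participant_id`, `reactivity`,
#'   `peak_label`.
#' @export
#' @examples
#' s <- tibble::tibble(participant_id = "p1",
#'                     timepoint = c("T2", "T3", "T4"),
#'                     minutes = c(0, 23, 40), value = c(2.0, 2.3, 2.6))
#' reactivity_slope(s)  # 0.6 / 40 = 0.015, peak T4
reactivity_slope <- function(series) {
  check_series(series)
  w <- wide_series(series, c("T2", "T3", "T4"))
  peak <- ifelse(w$value[, "T3"] >= w$value[, "T4"], "T3", "T4")
  idx <- cbind(seq_along(peak), match(peak, colnames(w$value)))
  dt <- w$minutes[idx] - w$minutes[, "T2"]
  if (any(dt <= 0)) {
    abort(paste0("malformed times for ",
                 paste(w$pid[dt <= 0], collapse = ", "),
                 ": peak not after T2"))
  }
  tibble(participant_id = w$pid,
         reactivity = unname((w$value[idx] - w$value[, "T2"]) / dt),
         peak_label = unname(peak))
}

#' Post-stress recovery slope
#'
#' The decline from the post-stress peak (T3 or T4, as identified by
#' [reactivity_slope()]) to the last post-stress sample (T5), normalized by
#' the elapsed minutes; typically negative for stressed participants.
#'
#' @inheritParams log_cortisol
#' @param peaks Tibble with columns `participant_id`, `peak_label` (e.g. the
#'   output of [reactivity_slope()]).
#' @return A tibble with columns `participant_id`, `recovery`.
#' @export
recovery_slope <- function(series, peaks) {
  check_series(series)
  w <- wide_series(series, c("T3", "T4", "T5"))
  peak <- peaks$peak_label[match(w$pid, peaks$participant_id)]
  if (anyNA(peak)) {
    abort(paste0("no peak label for participant(s): ",
                 paste(w$pid[is.na(peak)], collapse = ", ")))
  }
  idx <- cbind(seq_along(peak), match(peak, colnames(w$value)))
  dt <- w$minutes[, "T5"] - w$minutes[idx]
  if (any(dt <= 0)) {
    abort(paste0("malformed times for ",
                 paste(w$pid[dt <= 0], collapse = ", "),
                 ": T5 not after peak"))
  }
  tibble(participant_id = w$pid,
         recovery = unname((w$value[, "T5"] - w$value[idx]) / dt))
}

#' Area under a saliva trajectory
#'
#' Trapezoidal area under the curve over a window of timepoints, with
#' respect to ground (`"ground"`: the absolute level) or increase
#' (`"increase"`: ground minus the rectangle at the window's first value),
#' following the standard endocrine AUC decomposition. The default window
#' T2..T5 spans the reactivity and recovery timepoints.
#'
#' @inheritParams log_cortisol
#' @param mode `"ground"` or `"increase"`.
#' @param window Character vector of the first and last timepoint label.
#' @return A tibble with columns `participant_id`, `auc` (value-minutes).
#' @export
auc_measure <- function(series, mode = c("ground", "increase"),
                        window = c("T2", "T5")) {
  mode <- match.arg(mode)
  check_series(series)
  labels <- paste0("T", 0:6)
  span <- labels[seq(match(window[1], labels), match(window[2], labels))]
  sub <- series[series$timepoint %in% span, , drop = FALSE]
  bad <- is.na(sub$value)
  if (any(bad)) {
    abort(paste0("missing value(s) in the AUC window at: ",
                 paste(paste0(sub$participant_id[bad], "/", sub$timepoint[bad]),
                       collapse = ", ")))
  }
  pieces <- split(seq_len(nrow(sub)), sub$participant_id)
  aucs <- vapply(pieces, function(i) {
    t <- sub$minutes[i]; v <- sub$value[i]
    o <- order(t); t <- t[o]; v <- v[o]
    if (length(t) < 2) return(NA_real_)
    ground <- pracma::trapz(t, v)
    if (mode == "ground") ground else ground - v[1] * (t[length(t)] - t[1])
  }, numeric(1))
  if (anyNA(aucs)) {
    abort(paste0("participant(s) with < 2 points in the AUC window: ",
                 paste(names(aucs)[is.na(aucs)], collapse = ", ")))
  }
  tibble(participant_id = names(aucs), auc = as.numeric(aucs))
}

#' Derive all per-participant stress statistics
#'
#' Full stress-metrics chain for a cohort: log-transform cortisol, impute a
#' missing T0 if present, then compute reactivity and recovery slopes and
#' AUCg/AUCi on the log scale; subjective ratings (if supplied) go through
#' the same slope operations on the raw scale.
#'
#' @param saliva Long cortisol tibble (`participant_id`, `timepoint`,
#'   `minutes`, `value` in nmol/L).
#' @param ratings Optional long subjective-stress tibble (Likert scale).
#' @param auc_window Window for the AUC statistics.
#' @return A tibble with one row per participant: `reactivity`, `recovery`,
#'   `peak_label`, `auc_g`, `auc_i`, `baseline_log_cortisol`, and — when
#'   ratings are given — `subj_reactivity`, `subj_recovery`,
#'   `subj_peak_label`.
#' @export
stress_outcomes <- function(saliva, ratings = NULL, auc_window = c("T2", "T5")) {
  lg <- impute_baseline(log_cortisol(saliva))
  react <- reactivity_slope(lg)
  rec <- recovery_slope(lg, react)
  aucg <- auc_measure(lg, "ground", auc_window)
  auci <- auc_measure(lg, "increase", auc_window)
  base <- lg %>%
    filter(.data$timepoint == "T2") %>%
    select(participant_id = "participant_id", baseline_log_cortisol = "value")
  out <- react %>%
    inner_join(rec, by = "participant_id") %>%
    inner_join(rename(aucg, auc_g = "auc"), by = "participant_id") %>%
    inner_join(rename(auci, auc_i = "auc"), by = "participant_id") %>%
    inner_join(base, by = "participant_id")
  if (!is.null(ratings)) {
    sreact <- reactivity_slope(ratings)
    srec <- recovery_slope(ratings, sreact)
    out <- out %>%
      inner_join(rename(sreact, subj_reactivity = "reactivity",
                        subj_peak_label = "peak_label"),
                 by = "participant_id") %>%
      inner_join(rename(srec, subj_recovery = "recovery"),
                 by = "participant_id")
  }
  out
}

check_series <- function(series) {
  need <- c("participant_id", "timepoint", "minutes", "value")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0) {
    abort(paste0("series lacks column(s): ", paste(miss, collapse = ", ")))
  }
  dup <- duplicated(series[c("participant_id", "timepoint")])
  if (any(dup)) abort("duplicate (participant, timepoint) rows in series")
  invisible(series)
}

# participant-by-timepoint matrices of values and minutes for a required
# label set; absent or NA required cells abort with participant/timepoint
wide_series <- function(series, required) {
  pid <- unique(series$participant_id)
  v <- matrix(NA_real_, length(pid), length(required),
              dimnames = list(pid, required))
  t <- v
  keep <- series$timepoint %in% required
  ridx <- cbind(match(series$participant_id[keep], pid),
                match(series$timepoint[keep], required))
  v[ridx] <- series$value[keep]
  t[ridx] <- series$minutes[keep]
  if (anyNA(v)) {
    miss <- which(is.na(v), arr.ind = TRUE)
    abort(paste0("timepoint(s) missing: ",
                 paste(paste0(pid[miss[, 1]], "/", required[miss[, 2]]),
                       collapse = ", ")))
  }
  list(pid = pid, value = v, minutes = t)
}
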