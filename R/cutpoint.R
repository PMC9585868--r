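# Maximally selected rank statistics for the TSR survival cutpoint.
#
# The cutoff is the candidate split of the TSR distribution that maximizes
# the absolute standardized two-group log-rank statistic, scanned
# exhaustively over admissible candidates.

#' Admissible cutpoint candidates
#'
#' Candidates are midpoints between consecutive distinct TSR values such
#' that splitting there leaves at least a fraction `min_group_fraction` of
#' patients on each side. Midpoints make the "TSR <= cutoff" rule
#' unambiguous for floating-point TSR values.
#'
#' @param tsr Numeric vector of TSR percents.
#' @param min_group_fraction Minimum fraction of patients per group
#'   (default 0.10, the conventional maxstat constraint).
#' @return Sorted numeric vector of candidate cutpoints.
#' @export
candidate_cutpoints <- function(tsr, min_group_fraction = 0.10) {
  n <- length(tsr)
  k <- ceiling(min_group_fraction * n)
  if (n < 2 * k)
    stop_validation("too few patients for min_group_fraction = ",
                    min_group_fraction)
  u <- sort(unique(tsr))
  if (length(u) < 2)
    stop_validation("no admissible cutpoint candidate: all TSR values equal")
  mid <- (u[-1] + u[-length(u)]) / 2
  nlow <- vapply(mid, function(m) sum(tsr <= m), integer(1))
  keep <- nlow >= k & (n - nlow) >= k
  if (!any(keep))
    stop_validation("no admissible cutpoint candidate under the ",
                    "minimum-group constraint")
  mid[keep]
}

#' Standardized two-group log-rank statistic
#'
#' Computes `(O - E) / sqrt(V)` for group 1 from the standard log-rank
#' life table over distinct event times, with the hypergeometric variance
#' and the usual life-table treatment of tied event times.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (0/1).
#' @param group1 Logical (or 0/1) membership indicator of group 1.
#' @return Standardized statistic `z`; `z^2` is the usual log-rank
#'   chi-square on 1 df.
#' @export
logrank_z <- function(time, event, group1) {
  group1 <- as.logical(group1)
  if (!any(group1) || all(group1))
    stop_validation("both groups must be nonempty")
  if (sum(event) < 1)
    stop_validation("log-rank statistic undefined with zero events")
  ut <- sort(unique(time[event == 1]))
  st <- sort(time)
  st1 <- sort(time[group1])
  n_r <- length(time) - findInterval(ut, st, left.open = TRUE)
  n_r1 <- length(st1) - findInterval(ut, st1, left.open = TRUE)
  ev <- event == 1
  d <- tabulate(match(time[ev], ut), nbins = length(ut))
  d1 <- tabulate(match(time[ev & group1], ut), nbins = length(ut))
  O <- sum(d1)
  E <- sum(d * n_r1 / n_r)
  ok <- n_r > 1
  V <- sum((d * (n_r1 / n_r) * (1 - n_r1 / n_r) *
              (n_r - d) / (n_r - 1))[ok])
  if (V <= 0)
    stop_validation("log-rank variance is zero")
  (O - E) / sqrt(V)
}

#' Maximally selected rank statistic over TSR cutpoints
#'
#' Evaluates [logrank_z()] for the split (TSR <= c) vs (TSR > c) at every
#' admissible candidate c and selects the cutoff maximizing |z|. The scan
#' is exhaustive and deterministic; ties in |z| are broken toward the
#' smallest cutoff.
#'
#' @inheritParams candidate_cutpoints
#' @inheritParams logrank_z
#' @return An object of class `tsr_cutpoint`: `candidates`, `statistics`
#'   (z per candidate), `selected_cutoff`, `max_abs_statistic`,
#'   `naive_p` (the uncorrected two-sided normal p-value of the maximum —
#'   anti-conservative by construction, reported for reference only),
#'   `min_group_fraction`, `n`, `n_events`.
#' @export
max_selected_rank <- function(tsr, time, event, min_group_fraction = 0.10) {
  cand <- candidate_cutpoints(tsr, min_group_fraction)
  z <- vapply(cand, function(cc) {
    tryCatch(logrank_z(time, event, tsr <= cc),
             tsr_validation_error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(z)))
    stop_validation("log-rank statistic undefined at every candidate")
  best <- which.max(abs(z))  # first maximum = smallest cutoff on ties
  structure(list(candidates = cand, statistics = z,
                 selected_cutoff = cand[best],
                 max_abs_statistic = abs(z[best]),
                 naive_p = 2 * stats::pnorm(-abs(z[best])),
                 min_group_fraction = min_group_fraction,
                 n = length(tsr), n_events = sum(event)),
            class = "tsr_cutpoint")
}

#' @export
print.tsr_cutpoint <- function(x, ...) {
  cat(sprintf(
    "Maximally selected log-rank statistic\n  cutoff: %.3f%%  |z| = %.3f  (%d candidates, n = %d, events = %d)\n",
    x$selected_cutoff, x$max_abs_statistic, length(x$candidates), x$n,
    x$n_events))
  cat("  naive p (uncorrected for selection):",
      format_pvalue(x$naive_p), "\n")
  invisible(x)
}

#' Dichotomize TSR at a cutoff
#'
#' Patients with TSR at or below the cutoff are "stroma-high" (low TSR,
#' stroma-rich); above it "stroma-low". The boundary value goes to
#' stroma-high. The factor reference level is stroma-low, matching the
#' reporting convention of the Cox models.
#'
#' @param tsr Numeric TSR percents.
#' @param cutoff Cutoff in (0, 100).
#' @return Factor with levels `stroma-low`, `stroma-high`.
#' @export
dichotomize <- function(tsr, cutoff) {
  if (cutoff <= 0 || cutoff >= 100)
    stop_validation("cutoff must be in (0, 100)")
  factor(ifelse(tsr <= cutoff, "stroma-high", "stroma-low"),
         levels = c("stroma-low", "stroma-high"))
}

#' Permutation p-value for the selected cutpoint
#'
#' Optional correction for the selection effect: permutes the TSR values
#' across patients `B` times, re-runs the maximal selection, and reports
#' the proportion of permutation maxima at least as large as the observed
#' maximum (with the +1 correction).
#'
#' @inheritParams max_selected_rank
#' @param B Number of permutations.
#' @param seed Optional seed.
#' @return List with `p`, `observed` and the permutation maxima `null_max`.
#' @export
maxstat_permutation_p <- function(tsr, time, event,
                                  min_group_fraction = 0.10,
                                  B = 1000, seed = NULL) {
  obs <- max_selected_rank(tsr, time, event, min_group_fraction)
  with_seed(seed, {
    null_max <- vapply(seq_len(B), function(i) {
      max_selected_rank(sample(tsr), time, event,
                        min_group_fraction)$max_abs_statistic
    }, numeric(1))
    list(p = (1 + sum(null_max >= obs$max_abs_statistic)) / (B + 1),
         observed = obs$max_abs_statistic, null_max = null_max)
  })
}
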