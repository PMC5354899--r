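# Survival layer: does extreme circuit activity stratify outcome?
# For each activity feature the samples with the highest (or lowest) 10%
# activity are compared to the rest with the standard 1-df log-rank test on
# Kaplan-Meier strata, and the p-values are Benjamini-Hochberg corrected
# across all (feature, side) pairs.

check_survival <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("survival times must be finite and non-negative")
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Non-negative follow-up times.
#' @param event 1 = death observed, 0 = censored.
#' @return `data.frame` with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `survival` (the estimate just after that time).
#'   Censored times reduce the risk set without producing a step.
#' @export
km_estimate <- function(time, event) {
  check_survival(time, event)
  if (length(time) == 0L) stop("at least one record required")
  ut <- sort(unique(time[event == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event, survival = surv)
}

#' Survival probability of a K-M curve at a time point
#'
#' @param km Estimate from [km_estimate()].
#' @param t Time point.
#' @return S(t): 1 before the first event, otherwise the last step at or
#'   before `t`.
#' @export
km_survival_at <- function(km, t) {
  idx <- which(km$time <= t)
  if (length(idx) == 0L) 1 else km$survival[max(idx)]
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank: at every distinct pooled event time the observed
#' deaths in group A are compared with their hypergeometric expectation
#' given the risk sets, and the squared summed difference is referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param time_a,event_a Follow-up and status of group A.
#' @param time_b,event_b Follow-up and status of group B.
#' @return List with `statistic`, `p_value`, `observed` and `expected`
#'   deaths in group A.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  check_survival(time_a, event_a)
  check_survival(time_b, event_b)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  if (sum(event) == 0) stop("log-rank test needs at least one event")
  in_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  ut <- sort(unique(time[event == 1]))
  o_a <- e_a <- v <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & in_a)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & in_a)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) {
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
  }
  stat <- if (v > 0) (o_a - e_a)^2 / v else 0
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = o_a, expected = e_a)
}

#' Split samples into an extreme-activity stratum and the rest
#'
#' The extreme stratum holds `round(fraction * n)` samples (round-half-up,
#' at least 1) with the highest (`side = "high"`) or lowest (`side = "low"`)
#' activity for the feature. Ties at the cut are broken by stable sample
#' order, so the split is deterministic.
#'
#' @param acts Features x samples activity matrix.
#' @param feature Feature (row) id.
#' @param fraction Extreme fraction in (0, 0.5); default 0.1.
#' @param side `"high"` or `"low"`.
#' @return List with character vectors `extreme` and `rest` (disjoint,
#'   exhaustive).
#' @export
stratify_extreme <- function(acts, feature, fraction = 0.1,
                             side = c("high", "low")) {
  side <- match.arg(side)
  stopifnot(fraction > 0, fraction < 0.5)
  vals <- acts[feature, ]
  n <- length(vals)
  if (n < 10L) stop("need at least 10 samples to stratify")
  if (max(vals) - min(vals) == 0) {
    stop("feature '", feature, "' is constant: stratification meaningless")
  }
  k <- max(1L, round_half_up(fraction * n))
  ord <- order(vals, decreasing = (side == "high"))
  list(extreme = names(vals)[ord[seq_len(k)]],
       rest = names(vals)[ord[-seq_len(k)]])
}

#' Scan all activity features for survival associations
#'
#' For every feature and both sides (high and low extreme decile) the
#' extreme stratum is compared to the rest by log-rank test; p-values are
#' jointly Benjamini-Hochberg corrected over all (feature, side) pairs. The
#' prognosis call is `"bad"` when the extreme stratum's K-M curve lies below
#' the rest's at the median follow-up time (restricted mean survival breaks
#' exact ties), `"good"` otherwise. Features that cannot be stratified
#' (constant activity) or leave a stratum without events are skipped with a
#' warning.
#'
#' @param acts Features x samples activity matrix.
#' @param surv `data.frame` with columns `sample`, `time`, `event`.
#' @param fraction Extreme fraction; default 0.1.
#' @return `data.frame` with columns `feature`, `side`, `statistic`,
#'   `p_value`, `fdr`, `prognosis`.
#' @export
survival_scan <- function(acts, surv, fraction = 0.1) {
  stopifnot(is.matrix(acts), is.data.frame(surv),
            all(c("sample", "time", "event") %in% names(surv)))
  surv <- surv[!duplicated(surv$sample), ]
  common <- intersect(colnames(acts), surv$sample)
  if (length(common) < 10L) {
    stop("fewer than 10 samples shared between activities and survival data")
  }
  acts <- acts[, common, drop = FALSE]
  rownames(surv) <- surv$sample
  surv <- surv[common, ]
  check_survival(surv$time, surv$event)
  t_med <- median(surv$time)

  rows <- list()
  skipped <- character(0)
  for (f in rownames(acts)) {
    for (side in c("high", "low")) {
      strata <- tryCatch(stratify_extreme(acts, f, fraction, side),
                         error = function(e) NULL)
      if (is.null(strata)) {
        skipped <- c(skipped, paste0(f, "/", side))
        next
      }
      se <- surv[strata$extreme, ]
      sr <- surv[strata$rest, ]
      lr <- tryCatch(logrank_test(se$time, se$event, sr$time, sr$event),
                     error = function(e) NULL)
      if (is.null(lr)) {
        skipped <- c(skipped, paste0(f, "/", side))
        next
      }
      km_e <- km_estimate(se$time, se$event)
      km_r <- km_estimate(sr$time, sr$event)
      s_e <- km_survival_at(km_e, t_med)
      s_r <- km_survival_at(km_r, t_med)
      if (s_e == s_r) {
        # restricted mean survival over the shared follow-up window
        s_e <- km_rmst(km_e, max(surv$time))
        s_r <- km_rmst(km_r, max(surv$time))
      }
      rows[[paste0(f, "/", side)]] <- data.frame(
        feature = f, side = side, statistic = lr$statistic,
        p_value = lr$p_value,
        prognosis = if (s_e < s_r) "bad" else "good",
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    warning("skipped feature/side pair(s): ", paste(skipped, collapse = ", "))
  }
  if (!length(rows)) stop("no feature could be tested")
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out[, c("feature", "side", "statistic", "p_value", "fdr", "prognosis")]
}

# Restricted mean survival time: area under the K-M curve up to tau.
km_rmst <- function(km, tau) {
  times <- c(0, km$time[km$time <= tau], tau)
  surv <- c(1, km$survival[km$time <= tau])
  sum(diff(times) * surv)
}

#' Read a survival table
#'
#' TSV with columns `sample`, `time` (non-negative, e.g. days) and `event`
#' (1 = death observed, 0 = censored).
#'
#' @param path File path.
#' @return Validated `data.frame`.
#' @export
read_survival_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "time", "event") %in% names(df))) {
    stop("survival TSV '", path, "' needs columns sample, time, event")
  }
  check_survival(df$time, df$event)
  df
}
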