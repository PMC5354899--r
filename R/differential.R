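# Two-group differential activation testing. Activities are bounded, often
# skewed quantities, so the comparison is a two-sided Wilcoxon rank-sum per
# feature (exact when the combined sample size is small and no ties are
# present, normal approximation with tie and continuity correction
# otherwise), followed by Benjamini-Hochberg adjustment across all features
# of the matrix, i.e. per activity level.

#' Two-group design
#'
#' @param samples Character vector of sample ids.
#' @param groups Character vector of group labels parallel to `samples`;
#'   exactly two distinct labels, each with at least two samples.
#' @param reference Label of the reference (control) group; defaults to the
#'   first label in sorted order. Direction calls are relative to it: a
#'   feature is `UP` when the non-reference median exceeds the reference
#'   median.
#' @return Object of class `group_design`.
#' @export
group_design <- function(samples, groups, reference = NULL) {
  stopifnot(length(samples) == length(groups))
  samples <- as.character(samples)
  groups <- as.character(groups)
  if (anyDuplicated(samples)) stop("duplicated sample ids in design")
  lv <- sort(unique(groups))
  if (length(lv) != 2L) {
    stop("design must have exactly two group labels, got: ",
         paste(lv, collapse = ", "))
  }
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 samples")
  }
  reference <- reference %||% lv[1L]
  if (!(reference %in% lv)) stop("reference label '", reference,
                                 "' not among group labels")
  structure(list(samples = samples, groups = setNames(groups, samples),
                 reference = reference, case = setdiff(lv, reference)),
            class = "group_design")
}

wilcox_row <- function(x, y, exact_max_n = 20L) {
  pooled <- c(x, y)
  if (max(pooled) - min(pooled) == 0) {
    # constant feature carries no evidence either way
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  exact <- (length(pooled) <= exact_max_n) && !anyDuplicated(pooled)
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Differential activation between two sample groups
#'
#' @param acts Features x samples activity matrix.
#' @param design A [group_design()]; every design sample must be a column of
#'   `acts`.
#' @param exact_max_n Use the exact Wilcoxon null distribution when the
#'   combined group size is at most this and the data are tie-free.
#' @return `data.frame` with columns `feature`, `statistic` (Wilcoxon W of
#'   case vs reference), `p_value`, `fdr` (Benjamini-Hochberg across all
#'   features of `acts`), `direction` (`"UP"`/`"DOWN"`, `NA` when the group
#'   medians coincide), `median_case`, `median_control`.
#' @export
compare_groups <- function(acts, design, exact_max_n = 20L) {
  stopifnot(inherits(design, "group_design"), is.matrix(acts))
  missing <- setdiff(design$samples, colnames(acts))
  if (length(missing)) {
    stop("design sample(s) absent from activity matrix: ",
         paste(missing, collapse = ", "))
  }
  case_s <- design$samples[design$groups[design$samples] == design$case]
  ctrl_s <- design$samples[design$groups[design$samples] == design$reference]
  res <- lapply(rownames(acts), function(f) {
    x <- acts[f, case_s]
    y <- acts[f, ctrl_s]
    w <- wilcox_row(x, y, exact_max_n)
    mx <- median(x)
    my <- median(y)
    data.frame(feature = f, statistic = w$statistic, p_value = w$p,
               direction = if (mx > my) "UP" else if (mx < my) "DOWN"
                           else NA_character_,
               median_case = mx, median_control = my,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out[, c("feature", "statistic", "p_value", "fdr", "direction",
          "median_case", "median_control")]
}

#' Features significant after FDR control
#'
#' @param results `data.frame` from [compare_groups()] (or any table with
#'   `feature` and `fdr` columns).
#' @param threshold Strict upper bound on the adjusted p-value (default
#'   0.01).
#' @return Character vector of feature ids with `fdr < threshold`.
#' @export
significant_features <- function(results, threshold = 0.01) {
  stopifnot(is.data.frame(results), nrow(results) > 0,
            all(c("feature", "fdr") %in% names(results)))
  results$feature[results$fdr < threshold]
}
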