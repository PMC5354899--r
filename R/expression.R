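# Expression matrices are plain numeric matrices: genes in rows (rownames =
# gene ids), samples in columns (colnames = sample ids), as in limma-style
# workflows. Inputs are assumed library-normalized and batch-corrected
# upstream; this module only rescales to [0,1] and summarizes genes into
# pathway-node values.

check_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("duplicated gene or sample ids in expression matrix")
  }
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(m)
}

#' Rescale each gene to the unit interval
#'
#' Per gene the values are mapped by `(x - min) / (q - min)` and clamped to
#' \[0, 1\], where `q` is the per-gene `truncation_quantile` quantile.
#' Truncating at the 0.99 quantile (the default) keeps a single extreme
#' sample from compressing everyone else onto a tiny range; everything at or
#' above `q` saturates at 1. The scaled value is a proxy for protein
#' presence, the quantity the propagation rule consumes. Rank order is
#' preserved below the truncation point.
#'
#' Degenerate cases: a gene constant across samples carries no comparative
#' information and is set to 0.5 (signal-neutral) everywhere; with a single
#' sample scaling is undefined and the whole matrix becomes 0.5 with a
#' warning.
#'
#' @param m Numeric genes x samples matrix.
#' @param truncation_quantile Upper truncation quantile in (0.5, 1\];
#'   default 0.99.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
scale_to_unit <- function(m, truncation_quantile = 0.99) {
  check_expression_matrix(m)
  stopifnot(truncation_quantile > 0.5, truncation_quantile <= 1)
  if (ncol(m) == 1L) {
    warning("single-sample matrix: per-gene scaling undefined, ",
            "returning 0.5 throughout")
    m[] <- 0.5
    return(m)
  }
  mins <- apply(m, 1L, min)
  qs <- apply(m, 1L, quantile, probs = truncation_quantile,
              names = FALSE, type = 7)
  den <- qs - mins
  out <- clamp01((m - mins) / den)
  flat <- den == 0
  if (any(flat)) {
    maxs <- apply(m[flat, , drop = FALSE], 1L, max)
    constant <- flat
    constant[flat] <- maxs == mins[flat]
    # constant gene: no information, signal-neutral value
    out[constant, ] <- 0.5
    # non-constant gene whose truncation quantile equals its minimum:
    # everything above the quantile saturates, the rest is floor
    odd <- flat & !constant
    if (any(odd)) {
      out[odd, ] <- (m[odd, , drop = FALSE] > qs[odd]) + 0
    }
  }
  out
}

#' Summarize gene values into pathway-node values
#'
#' A plain node may contain several alternative proteins; its value is the
#' 90th percentile of the member genes' values (linear interpolation between
#' order statistics, i.e. `quantile(type = 7)`), so the node is "present"
#' when its best-supported members are. A complex node takes the minimum of
#' its members: the limiting component bounds the amount of assembled
#' complex.
#'
#' Genes absent from the matrix are ignored. A node none of whose genes were
#' measured gets `default_value` (0.5, signal-neutral) with a warning, or an
#' error when `missing_nodes = "error"`. A pathway with no measured genes at
#' all is always an error.
#'
#' @param p A `pathway`.
#' @param m Numeric genes x samples matrix already scaled to \[0, 1\].
#' @param default_value Value for unmeasured nodes under
#'   `missing_nodes = "default"`.
#' @param missing_nodes `"default"` or `"error"`.
#' @return Numeric nodes x samples matrix (rownames = node ids), values in
#'   \[0, 1\].
#' @export
summarize_nodes <- function(p, m, default_value = 0.5,
                            missing_nodes = c("default", "error")) {
  stopifnot(inherits(p, "pathway"))
  missing_nodes <- match.arg(missing_nodes)
  check_expression_matrix(m)
  if (any(m < 0 | m > 1)) {
    stop("summarize_nodes expects values already scaled to [0, 1]")
  }
  measured <- lapply(p$node_genes, intersect, rownames(m))
  if (all(lengths(measured) == 0L)) {
    stop("pathway '", p$pathway_id,
         "' shares no genes with the expression matrix")
  }
  unmeasured <- names(measured)[lengths(measured) == 0L]
  if (length(unmeasured)) {
    if (missing_nodes == "error") {
      stop("node(s) with no measured genes in pathway '", p$pathway_id,
           "': ", paste(unmeasured, collapse = ", "))
    }
    warning("pathway '", p$pathway_id, "': ", length(unmeasured),
            " node(s) with no measured genes set to ", default_value)
  }
  out <- matrix(default_value, nrow = length(p$node_ids), ncol = ncol(m),
                dimnames = list(p$node_ids, colnames(m)))
  for (nd in p$node_ids) {
    g <- measured[[nd]]
    if (length(g) == 0L) next
    vals <- m[g, , drop = FALSE]
    out[nd, ] <- if (p$node_type[[nd]] == "complex") {
      apply(vals, 2L, min)
    } else if (length(g) == 1L) {
      vals[1L, ]
    } else {
      apply(vals, 2L, quantile, probs = 0.9, names = FALSE, type = 7)
    }
  }
  out
}
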