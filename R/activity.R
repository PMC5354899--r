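# Activity matrices are features x samples numeric matrices in [0,1] with a
# "level" attribute ("circuit", "effector" or "function") and a "metadata"
# attribute describing each feature.

new_activity_matrix <- function(values, level, metadata = NULL) {
  stopifnot(level %in% c("circuit", "effector", "function"))
  attr(values, "level") <- level
  attr(values, "metadata") <- metadata
  class(values) <- c("activity_matrix", class(values))
  values
}

#' Level of an activity matrix
#' @param x An activity matrix.
#' @return `"circuit"`, `"effector"` or `"function"`.
#' @export
activity_level <- function(x) attr(x, "level")

#' Feature metadata of an activity matrix
#' @param x An activity matrix.
#' @return `data.frame` describing each feature (circuit -> pathway,
#'   receptors, effector, genes), or `NULL` for function level.
#' @export
activity_metadata <- function(x) attr(x, "metadata")

#' @export
print.activity_matrix <- function(x, ...) {
  cat("activity_matrix [", activity_level(x), "]: ", nrow(x),
      " features x ", ncol(x), " samples\n", sep = "")
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]))
  invisible(x)
}

circuit_metadata_row <- function(circ) {
  data.frame(
    feature = circ$circuit_id,
    pathway_id = circ$pathway_id,
    receptors = paste(circ$receptors, collapse = ";"),
    effector = circ$effector,
    n_nodes = length(circ$nodes),
    genes = paste(unique(unlist(circ$node_genes, use.names = FALSE)),
                  collapse = ";"),
    stringsAsFactors = FALSE)
}

pathway_node_values <- function(p, node_values) {
  if (is.list(node_values) && !is.matrix(node_values)) {
    nv <- node_values[[p$pathway_id]]
    if (is.null(nv)) {
      stop("no node-value matrix supplied for pathway '", p$pathway_id, "'")
    }
    nv
  } else {
    node_values
  }
}

#' Compute circuit- and effector-level activity profiles
#'
#' Decomposes each pathway, propagates the per-sample node values through
#' every canonical circuit and every effector circuit, and records the
#' signal arriving at the effector node. The result is deterministic given
#' the inputs and configuration.
#'
#' @param pathways A `pathway` or list of pathways.
#' @param node_values Nodes x samples matrix from [summarize_nodes()], or a
#'   named list of such matrices (one per pathway id) when node ids are not
#'   unique across pathways.
#' @param cfg A [propagation_config()].
#' @return List with activity matrices `circuit` and `effector`.
#' @export
compute_circuit_activities <- function(pathways, node_values,
                                       cfg = propagation_config()) {
  pathways <- as_pathway_list(pathways)
  rows_c <- list()
  rows_e <- list()
  meta_c <- list()
  meta_e <- list()
  for (p in pathways) {
    nv <- pathway_node_values(p, node_values)
    dec <- decompose_circuits(p)
    for (circ in dec$circuits) {
      st <- withCallingHandlers(
        propagate(circ, nv[circ$nodes, , drop = FALSE], cfg),
        error = function(e) {
          stop("circuit '", circ$circuit_id, "': ", conditionMessage(e))
        })
      rows_c[[circ$circuit_id]] <- effector_signal(st)
      meta_c[[circ$circuit_id]] <- circuit_metadata_row(circ)
    }
    for (circ in dec$effector_circuits) {
      st <- propagate(circ, nv[circ$nodes, , drop = FALSE], cfg)
      rows_e[[circ$circuit_id]] <- effector_signal(st)
      meta_e[[circ$circuit_id]] <- circuit_metadata_row(circ)
    }
  }
  list(
    circuit = new_activity_matrix(do.call(rbind, rows_c), "circuit",
                                  do.call(rbind, c(meta_c,
                                                   make.row.names = FALSE))),
    effector = new_activity_matrix(do.call(rbind, rows_e), "effector",
                                   do.call(rbind, c(meta_e,
                                                    make.row.names = FALSE))))
}

#' Aggregate effector activities into cell-function activities
#'
#' The signal arriving at the effectors that trigger a function is combined
#' with the same rule used for converging activations during propagation:
#' the function behaves as a virtual node of value 1 receiving only
#' activation inputs, so its activity is `1 - prod(1 - S_e)` over its
#' effectors. A function's activity is therefore never below the activity of
#' any of its effector circuits.
#'
#' @param effector_acts Effector-level activity matrix from
#'   [compute_circuit_activities()].
#' @param eff2fun Mapping function id -> effector circuit ids, from
#'   [map_effectors_to_functions()] / [merge_function_maps()].
#' @return Function-level activity matrix. Functions mapping to no computed
#'   effector are excluded with a warning.
#' @export
compute_function_activities <- function(effector_acts, eff2fun) {
  stopifnot(is.matrix(effector_acts), length(eff2fun) > 0)
  ids <- rownames(effector_acts)
  rows <- list()
  missing <- character(0)
  for (f in names(eff2fun)) {
    effs <- intersect(eff2fun[[f]], ids)
    if (!length(effs)) {
      missing <- c(missing, f)
      next
    }
    rows[[f]] <- 1 - colprods(1 - effector_acts[effs, , drop = FALSE])
  }
  if (length(missing)) {
    warning("function(s) with no computed effector circuit excluded: ",
            paste(missing, collapse = ", "))
  }
  if (!length(rows)) stop("no function maps to any computed effector circuit")
  out <- do.call(rbind, rows)
  colnames(out) <- colnames(effector_acts)
  new_activity_matrix(out, "function")
}

#' Full activity pipeline: expression to three activity levels
#'
#' Convenience wrapper chaining unit scaling, optional variant-integrity
#' multiplication, node summarization, circuit propagation and (when
#' annotations are given) function aggregation.
#'
#' @param pathways A `pathway` or list of pathways.
#' @param expression Genes x samples numeric matrix.
#' @param annotations Optional named list of function gene sets (GMT
#'   content).
#' @param integrity Optional binary integrity matrix from
#'   [compute_integrity()].
#' @param scale Rescale `expression` with [scale_to_unit()] first (set to
#'   `FALSE` when values are already in \[0, 1\]).
#' @param truncation_quantile Passed to [scale_to_unit()].
#' @param cfg A [propagation_config()].
#' @return List with `circuit`, `effector`, optionally `functions`, and
#'   `node_values` (named list per pathway).
#' @export
circuit_activity <- function(pathways, expression, annotations = NULL,
                             integrity = NULL, scale = TRUE,
                             truncation_quantile = 0.99,
                             cfg = propagation_config()) {
  pathways <- as_pathway_list(pathways)
  m <- if (scale) scale_to_unit(expression, truncation_quantile) else expression
  if (!is.null(integrity)) m <- apply_integrity(m, integrity)
  node_values <- lapply(pathways, summarize_nodes, m = m)
  acts <- compute_circuit_activities(pathways, node_values, cfg)
  out <- list(circuit = acts$circuit, effector = acts$effector,
              node_values = node_values)
  if (!is.null(annotations)) {
    eff2fun <- merge_function_maps(
      lapply(pathways, map_effectors_to_functions, annotations = annotations))
    out$functions <- compute_function_activities(acts$effector, eff2fun)
  }
  out
}
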