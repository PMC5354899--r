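#' Propagation configuration
#'
#' @param convergence_threshold Stop once no node changes by more than this
#'   between passes (default 1e-6).
#' @param max_passes Upper bound on worklist passes; pure negative-feedback
#'   cycles can oscillate and are cut off here.
#' @param non_convergence `"warn_return_last"` returns the final state with
#'   `converged = FALSE` and a warning; `"error"` aborts naming the circuit
#'   and the still-oscillating nodes.
#' @return Object of class `propagation_config`.
#' @export
propagation_config <- function(convergence_threshold = 1e-6,
                               max_passes = 100L,
                               non_convergence = c("warn_return_last",
                                                   "error")) {
  non_convergence <- match.arg(non_convergence)
  stopifnot(is.numeric(convergence_threshold), convergence_threshold > 0,
            max_passes >= 1)
  structure(list(convergence_threshold = convergence_threshold,
                 max_passes = as.integer(max_passes),
                 non_convergence = non_convergence),
            class = "propagation_config")
}

# Coerce node values (vector or matrix) to a nodes x samples matrix covering
# exactly the circuit's member nodes, and validate the [0,1] bound.
as_node_value_matrix <- function(node_values, nodes) {
  if (is.null(dim(node_values))) {
    node_values <- matrix(node_values, ncol = 1L,
                          dimnames = list(names(node_values), "value"))
  }
  missing <- setdiff(nodes, rownames(node_values))
  if (length(missing)) {
    stop("node value(s) missing for: ", paste(missing, collapse = ", "))
  }
  nv <- node_values[nodes, , drop = FALSE]
  if (any(!is.finite(nv)) || any(nv < 0 | nv > 1)) {
    stop("node values must lie in [0, 1]")
  }
  nv
}

# Incoming activation/inhibition parents and outgoing children per node.
circuit_adjacency <- function(circuit) {
  nodes <- circuit$nodes
  e <- circuit$edges
  lv <- factor(e$target, levels = nodes)
  list(
    act = split(e$source[e$sign == "activation"],
                lv[e$sign == "activation"]),
    inh = split(e$source[e$sign == "inhibition"],
                lv[e$sign == "inhibition"]),
    children = split(e$target, factor(e$source, levels = nodes)))
}

# Breadth-first node ordering from the receptors; unreached nodes (possible
# only inside cycles entered mid-way) are appended in pathway order.
bfs_order <- function(circuit, adj) {
  seen <- character(0)
  frontier <- circuit$receptors
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(adj$children[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  c(seen, setdiff(circuit$nodes, seen))
}

# Eq-style update for one node given the current signal matrix. An empty
# activation set contributes factor 1 (the node is not waiting for an
# activator): receptors thereby receive their virtual incoming signal of 1,
# and inhibition-only nodes still transmit v_n * prod(1 - s_i).
node_update <- function(nd, S, nv, adj) {
  ap <- adj$act[[nd]]
  ip <- adj$inh[[nd]]
  f_act <- if (length(ap)) 1 - colprods(1 - S[ap, , drop = FALSE]) else 1
  f_inh <- if (length(ip)) colprods(1 - S[ip, , drop = FALSE]) else 1
  nv[nd, ] * f_act * f_inh
}

#' Propagate signal through a circuit
#'
#' Starting from a virtual incoming signal of 1 at every receptor (so a
#' receptor's signal equals its node value), the signal intensity
#' \deqn{S_n = v_n \, (1 - \prod_{a}(1 - s_a)) \prod_{i}(1 - s_i)}
#' is iterated over the circuit with a worklist: whenever a node's signal
#' changes by more than the convergence threshold, its downstream neighbours
#' are marked for re-evaluation. Iteration makes the signal steady also in
#' the presence of loops; a pass limit guards against genuinely oscillating
#' feedback.
#'
#' Node values may be a named vector (one sample) or a nodes x samples
#' matrix, in which case all samples are propagated simultaneously.
#'
#' @param circuit A `circuit` from [decompose_circuits()].
#' @param node_values Named numeric vector or matrix with values in \[0, 1\]
#'   covering every member node.
#' @param cfg A [propagation_config()].
#' @param node_order Optional explicit processing order (used to check that
#'   results do not depend on worklist ordering); defaults to breadth-first
#'   order from the receptors.
#' @return Object of class `signal_state`: list with `signal` (nodes x
#'   samples matrix), `converged`, `passes`, `circuit_id`, `effector`.
#' @export
propagate <- function(circuit, node_values, cfg = propagation_config(),
                      node_order = NULL) {
  stopifnot(inherits(circuit, "circuit"))
  nv <- as_node_value_matrix(node_values, circuit$nodes)
  adj <- circuit_adjacency(circuit)
  order0 <- node_order %||% bfs_order(circuit, adj)
  stopifnot(setequal(order0, circuit$nodes))
  rank <- setNames(seq_along(order0), order0)
  thr <- cfg$convergence_threshold

  S <- matrix(0, nrow = length(circuit$nodes), ncol = ncol(nv),
              dimnames = dimnames(nv))
  dirty <- order0
  passes <- 0L
  while (length(dirty) && passes < cfg$max_passes) {
    passes <- passes + 1L
    touched <- character(0)
    for (nd in dirty) {
      s_new <- node_update(nd, S, nv, adj)
      if (max(abs(s_new - S[nd, ])) > thr) {
        S[nd, ] <- s_new
        touched <- c(touched, adj$children[[nd]])
      }
    }
    dirty <- unique(touched)
    dirty <- dirty[order(rank[dirty])]
  }
  converged <- length(dirty) == 0L
  if (!converged) {
    msg <- paste0("propagation did not converge in ", cfg$max_passes,
                  " passes on circuit '", circuit$circuit_id,
                  "'; oscillating node(s): ",
                  paste(dirty, collapse = ", "))
    if (cfg$non_convergence == "error") stop(msg) else warning(msg)
  }
  structure(list(signal = S, converged = converged, passes = passes,
                 circuit_id = circuit$circuit_id,
                 effector = circuit$effector),
            class = "signal_state")
}

#' Single-pass propagation oracle for acyclic circuits
#'
#' Applies the propagation rule once per node in topological order, which is
#' exact on a DAG. Kept as an independent reference implementation for
#' testing [propagate()]; errors on cyclic input.
#'
#' @inheritParams propagate
#' @return A `signal_state` (always `converged = TRUE`, `passes = 1`).
#' @export
propagate_dag_oracle <- function(circuit, node_values) {
  stopifnot(inherits(circuit, "circuit"))
  nv <- as_node_value_matrix(node_values, circuit$nodes)
  g <- igraph::graph_from_data_frame(
    circuit$edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = circuit$nodes))
  if (!igraph::is_dag(g)) {
    stop("circuit '", circuit$circuit_id,
         "' is cyclic; the single-pass oracle requires a DAG")
  }
  topo <- names(igraph::topo_sort(g, mode = "out"))
  adj <- circuit_adjacency(circuit)
  S <- matrix(0, nrow = length(circuit$nodes), ncol = ncol(nv),
              dimnames = dimnames(nv))
  for (nd in topo) {
    S[nd, ] <- node_update(nd, S, nv, adj)
  }
  structure(list(signal = S, converged = TRUE, passes = 1L,
                 circuit_id = circuit$circuit_id,
                 effector = circuit$effector),
            class = "signal_state")
}

#' Signal arriving at an effector (or any) node
#'
#' @param state A `signal_state` from [propagate()].
#' @param node Node id; defaults to the circuit's effector.
#' @return Named numeric vector of per-sample signal intensities.
#' @export
effector_signal <- function(state, node = NULL) {
  stopifnot(inherits(state, "signal_state"))
  node <- node %||% state$effector
  if (!(node %in% rownames(state$signal))) {
    stop("unknown node '", node, "' in circuit '", state$circuit_id, "'")
  }
  row <- state$signal[node, , drop = FALSE]
  setNames(as.vector(row), colnames(row))
}

#' @export
print.signal_state <- function(x, ...) {
  cat("signal_state for '", x$circuit_id, "': ", nrow(x$signal), " nodes x ",
      ncol(x$signal), " sample(s); ",
      if (x$converged) "converged" else "NOT converged",
      " after ", x$passes, " pass(es)\n", sep = "")
  invisible(x)
}
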