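#' Construct a pathway object
#'
#' A pathway is a directed graph whose nodes are one or more gene products
#' and whose edges are signed (activation or inhibition). Nodes are either
#' `plain` (alternative proteins, summarized by their 90th percentile) or
#' `complex` (a protein complex, limited by its least abundant component).
#'
#' @param pathway_id Identifier, unique across loaded pathways.
#' @param name Human-readable name; defaults to `pathway_id`.
#' @param nodes `data.frame` with columns `node_id` (character, unique),
#'   `node_type` (`"plain"` or `"complex"`) and a list column `genes`
#'   (non-empty character vectors).
#' @param edges `data.frame` with columns `source`, `target` (node ids) and
#'   `sign` (`"activation"` or `"inhibition"`).
#' @return An object of class `pathway`.
#' @export
new_pathway <- function(pathway_id, name = pathway_id, nodes, edges) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("node_id", "node_type", "genes") %in% names(nodes))) {
    stop("`nodes` needs columns node_id, node_type, genes")
  }
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicated node_id in pathway '", pathway_id, "': ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  }
  if (!all(nodes$node_type %in% c("plain", "complex"))) {
    stop("node_type must be 'plain' or 'complex'")
  }
  genes <- lapply(nodes$genes, as.character)
  if (any(lengths(genes) == 0L)) {
    stop("every node must contain at least one gene (pathway '",
         pathway_id, "')")
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  if (!all(c("source", "target", "sign") %in% names(edges))) {
    stop("`edges` needs columns source, target, sign")
  }
  if (!all(edges$sign %in% c("activation", "inhibition"))) {
    stop("edge sign must be 'activation' or 'inhibition'")
  }
  missing <- setdiff(c(edges$source, edges$target), nodes$node_id)
  if (length(missing)) {
    stop("edge references unknown node(s) in pathway '", pathway_id, "': ",
         paste(missing, collapse = ", "))
  }
  structure(
    list(pathway_id = pathway_id,
         name = name,
         node_ids = nodes$node_id,
         node_type = setNames(nodes$node_type, nodes$node_id),
         node_genes = setNames(genes, nodes$node_id),
         edges = edges[, c("source", "target", "sign")]),
    class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  term <- identify_terminals(x)
  cat("pathway '", x$pathway_id, "' (", x$name, ")\n",
      "  ", length(x$node_ids), " nodes (",
      sum(x$node_type == "complex"), " complexes), ",
      nrow(x$edges), " edges (",
      sum(x$edges$sign == "inhibition"), " inhibitions)\n",
      "  receptors: ", paste(term$receptors, collapse = ", "), "\n",
      "  effectors: ", paste(term$effectors, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' All genes appearing in a pathway (or list of pathways)
#' @param pathways A `pathway` or list of pathways.
#' @return Character vector of unique gene identifiers.
#' @export
pathway_genes <- function(pathways) {
  pathways <- as_pathway_list(pathways)
  unique(unlist(lapply(pathways, function(p) unlist(p$node_genes,
                                                    use.names = FALSE))))
}

as_pathway_list <- function(pathways) {
  if (inherits(pathways, "pathway")) pathways <- list(pathways)
  stopifnot(all(vapply(pathways, inherits, logical(1), "pathway")))
  setNames(pathways, vapply(pathways, `[[`, character(1), "pathway_id"))
}

pathway_igraph <- function(p) {
  igraph::graph_from_data_frame(
    p$edges[, c("source", "target", "sign")],
    directed = TRUE,
    vertices = data.frame(name = p$node_ids, stringsAsFactors = FALSE))
}

#' Load a pathway from a file
#'
#' Two dialects are supported. The native JSON dialect describes a pathway as
#' `{"pathway_id":..., "name":..., "nodes":[{"id":..., "genes":[...],
#' "type":"plain"|"complex"}], "edges":[{"source":..., "target":...,
#' "sign":"activation"|"inhibition"}]}`. The KGML dialect reads the KEGG XML
#' subset relevant here: `entry` elements of type `gene` (plain nodes, one or
#' more gene tokens in `@name`) and `group` (complex nodes whose genes are the
#' union of their components), and `relation` elements whose subtypes are
#' mapped to signs through `subtype_map`. Relation subtypes absent from the
#' map carry no sign information (e.g. "binding/association") and are dropped
#' with a warning, never silently signed.
#'
#' @param path File path.
#' @param dialect `"native_json"` or `"kgml"`.
#' @param subtype_map Named character vector mapping KGML relation subtype
#'   names to `"activation"`/`"inhibition"`.
#' @return A [new_pathway()] object.
#' @export
load_pathway <- function(path,
                         dialect = c("native_json", "kgml"),
                         subtype_map = c(activation = "activation",
                                         expression = "activation",
                                         inhibition = "inhibition",
                                         repression = "inhibition")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pathway file not found: ", path)
  switch(dialect,
         native_json = load_pathway_json(path),
         kgml = load_pathway_kgml(path, subtype_map))
}

load_pathway_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("cannot parse pathway JSON '", path, "': ",
                         conditionMessage(e))
                  })
  for (field in c("pathway_id", "nodes", "edges")) {
    if (is.null(doc[[field]])) {
      stop("pathway JSON '", path, "' lacks element '", field, "'")
    }
  }
  nodes <- data.frame(
    node_id = vapply(doc$nodes, function(n) as.character(n$id), character(1)),
    node_type = vapply(doc$nodes, function(n) n$type %||% "plain",
                       character(1)),
    stringsAsFactors = FALSE)
  nodes$genes <- lapply(doc$nodes, function(n) {
    g <- unlist(n$genes)
    if (is.null(g)) character(0) else as.character(g)
  })
  edges <- data.frame(
    source = vapply(doc$edges, function(e) as.character(e$source), character(1)),
    target = vapply(doc$edges, function(e) as.character(e$target), character(1)),
    sign = vapply(doc$edges, function(e) as.character(e$sign), character(1)),
    stringsAsFactors = FALSE)
  new_pathway(as.character(doc$pathway_id),
              as.character(doc$name %||% doc$pathway_id),
              nodes, edges)
}

load_pathway_kgml <- function(path, subtype_map) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("cannot parse KGML '", path, "': ",
                         conditionMessage(e))
                  })
  pid <- xml2::xml_attr(doc, "name")
  pname <- xml2::xml_attr(doc, "title")
  if (is.na(pid)) pid <- basename(path)
  if (is.na(pname)) pname <- pid

  entries <- xml2::xml_find_all(doc, ".//entry")
  etype <- xml2::xml_attr(entries, "type")
  eid <- xml2::xml_attr(entries, "id")

  gene_idx <- which(etype == "gene")
  gene_genes <- lapply(entries[gene_idx], function(e) {
    strsplit(trimws(xml2::xml_attr(e, "name")), "\\s+")[[1]]
  })
  names(gene_genes) <- eid[gene_idx]

  group_idx <- which(etype == "group")
  group_genes <- lapply(entries[group_idx], function(e) {
    comp <- xml2::xml_attr(xml2::xml_find_all(e, "./component"), "id")
    unique(unlist(gene_genes[comp], use.names = FALSE))
  })
  names(group_genes) <- eid[group_idx]
  keep_group <- lengths(group_genes) > 0L
  if (any(!keep_group)) {
    warning("KGML '", path, "': dropping ", sum(!keep_group),
            " group entr", if (sum(!keep_group) == 1L) "y" else "ies",
            " with no gene components")
    group_genes <- group_genes[keep_group]
  }

  node_ids <- c(names(gene_genes), names(group_genes))
  nodes <- data.frame(
    node_id = node_ids,
    node_type = c(rep("plain", length(gene_genes)),
                  rep("complex", length(group_genes))),
    stringsAsFactors = FALSE)
  nodes$genes <- c(gene_genes, group_genes)

  rels <- xml2::xml_find_all(doc, ".//relation")
  src <- tgt <- sgn <- character(0)
  dropped <- character(0)
  for (r in rels) {
    e1 <- xml2::xml_attr(r, "entry1")
    e2 <- xml2::xml_attr(r, "entry2")
    subtypes <- xml2::xml_attr(xml2::xml_find_all(r, "./subtype"), "name")
    sign <- unique(stats::na.omit(subtype_map[subtypes]))
    if (!(e1 %in% node_ids) || !(e2 %in% node_ids)) {
      dropped <- c(dropped, sprintf("%s->%s (non-gene endpoint)", e1, e2))
      next
    }
    if (length(sign) != 1L) {
      dropped <- c(dropped,
                   sprintf("%s->%s (subtype: %s)", e1, e2,
                           paste(subtypes, collapse = "/")))
      next
    }
    src <- c(src, e1)
    tgt <- c(tgt, e2)
    sgn <- c(sgn, sign)
  }
  if (length(dropped)) {
    warning("KGML '", path, "': dropped ", length(dropped),
            " unsigned or unresolvable relation(s): ",
            paste(dropped, collapse = "; "))
  }
  new_pathway(pid, pname, nodes,
              data.frame(source = src, target = tgt, sign = sgn,
                         stringsAsFactors = FALSE))
}

#' Identify receptor and effector nodes
#'
#' Receptors are nodes with no incoming edges (signal entry points); effectors
#' are nodes with no outgoing edges (the proteins that ultimately trigger cell
#' functions). The definition is purely topological; a self-loop counts as
#' both an in- and an out-edge.
#'
#' @param p A `pathway`.
#' @return List with character vectors `receptors` and `effectors` (either may
#'   be empty).
#' @export
identify_terminals <- function(p) {
  stopifnot(inherits(p, "pathway"))
  list(receptors = p$node_ids[!(p$node_ids %in% p$edges$target)],
       effectors = p$node_ids[!(p$node_ids %in% p$edges$source)])
}

new_circuit <- function(circuit_id, pathway_id, level, receptors, effector,
                        nodes, edges, node_genes, node_type) {
  structure(
    list(circuit_id = circuit_id, pathway_id = pathway_id, level = level,
         receptors = receptors, effector = effector, nodes = nodes,
         edges = edges, node_genes = node_genes, node_type = node_type),
    class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat("circuit '", x$circuit_id, "' [", x$level, "]: ",
      paste(x$receptors, collapse = ","), " -> ", x$effector, "; ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Build a circuit by hand from a pathway subgraph
#'
#' [propagate()] operates on `circuit` objects; this constructor makes one
#' directly from a pathway (or a subset of its nodes) with explicitly chosen
#' receptors and effector, without requiring in-degree-0/out-degree-0
#' terminals. Useful for hand-checkable fixtures, e.g. feedback loops closing
#' on the read-out node.
#'
#' @param p A `pathway`.
#' @param receptors Nodes seeded with the virtual incoming signal of 1.
#' @param effector Node whose signal is the circuit read-out.
#' @param nodes Member nodes; defaults to all pathway nodes. Edges are the
#'   pathway edges among them.
#' @param circuit_id Optional id; defaults to the canonical-circuit scheme.
#' @return A `circuit` object.
#' @export
manual_circuit <- function(p, receptors, effector, nodes = p$node_ids,
                           circuit_id = NULL) {
  stopifnot(inherits(p, "pathway"),
            all(c(receptors, effector, nodes) %in% p$node_ids))
  edges <- p$edges[p$edges$source %in% nodes & p$edges$target %in% nodes, ,
                   drop = FALSE]
  rownames(edges) <- NULL
  circuit_id <- circuit_id %||%
    sprintf("%s:%s->%s", p$pathway_id, paste(receptors, collapse = "+"),
            effector)
  new_circuit(circuit_id, p$pathway_id, "circuit", receptors, effector,
              nodes, edges, p$node_genes[nodes], p$node_type[nodes])
}

#' Decompose a pathway into canonical and effector circuits
#'
#' A canonical circuit collects, for one (receptor, effector) pair connected
#' by at least one directed path, every node that is simultaneously reachable
#' from the receptor and able to reach the effector, together with the edges
#' among those nodes. Convergent parallel branches therefore belong to one
#' circuit (they must be combined jointly by the propagation rule), and
#' cycles whose nodes lie between receptor and effector are retained rather
#' than clipped. An effector circuit is the union of all canonical circuits
#' of the pathway that end in the same effector node.
#'
#' Circuit ids are deterministic: `"<pathway>:<receptor>-><effector>"` for
#' canonical circuits and `"<pathway>:*-><effector>"` for effector circuits.
#'
#' @param p A `pathway` with at least one receptor and one effector.
#' @return List with elements `circuits` and `effector_circuits`, each a list
#'   of `circuit` objects.
#' @export
decompose_circuits <- function(p) {
  stopifnot(inherits(p, "pathway"))
  term <- identify_terminals(p)
  if (length(term$receptors) == 0L || length(term$effectors) == 0L) {
    stop("pathway '", p$pathway_id, "' cannot be decomposed: ",
         if (length(term$receptors) == 0L) "no receptor" else "no effector",
         " node (in-degree-0 / out-degree-0) found")
  }
  g <- pathway_igraph(p)
  reach_from <- lapply(term$receptors, function(r) {
    names(igraph::subcomponent(g, r, mode = "out"))
  })
  names(reach_from) <- term$receptors
  reach_to <- lapply(term$effectors, function(e) {
    names(igraph::subcomponent(g, e, mode = "in"))
  })
  names(reach_to) <- term$effectors

  circuits <- list()
  for (e in term$effectors) {
    for (r in term$receptors) {
      if (!(e %in% reach_from[[r]])) next
      member <- p$node_ids[p$node_ids %in%
                             intersect(reach_from[[r]], reach_to[[e]])]
      sub_edges <- p$edges[p$edges$source %in% member &
                             p$edges$target %in% member, , drop = FALSE]
      rownames(sub_edges) <- NULL
      cid <- sprintf("%s:%s->%s", p$pathway_id, r, e)
      circuits[[cid]] <- new_circuit(
        cid, p$pathway_id, "circuit", r, e, member, sub_edges,
        p$node_genes[member], p$node_type[member])
    }
  }
  if (length(circuits) == 0L) {
    stop("pathway '", p$pathway_id,
         "' has no directed path from any receptor to any effector")
  }

  effector_circuits <- list()
  by_eff <- split(circuits,
                  vapply(circuits, `[[`, character(1), "effector"))
  for (e in names(by_eff)) {
    members <- by_eff[[e]]
    nodes <- p$node_ids[p$node_ids %in%
                          unique(unlist(lapply(members, `[[`, "nodes")))]
    sub_edges <- unique(do.call(rbind, lapply(members, `[[`, "edges")))
    rownames(sub_edges) <- NULL
    eid <- sprintf("%s:*->%s", p$pathway_id, e)
    effector_circuits[[eid]] <- new_circuit(
      eid, p$pathway_id, "effector",
      sort(vapply(members, `[[`, character(1), "receptors")),
      e, nodes, sub_edges, p$node_genes[nodes], p$node_type[nodes])
  }
  # keep pathway node order in effector listing
  eff_order <- p$node_ids[p$node_ids %in%
                            vapply(effector_circuits, `[[`, character(1),
                                   "effector")]
  effector_circuits <- effector_circuits[
    sprintf("%s:*->%s", p$pathway_id, eff_order)]

  list(circuits = circuits, effector_circuits = effector_circuits)
}

#' Read gene-set annotations from a GMT file
#'
#' One set per line: set id, description, then member genes, tab-separated.
#' Lines with no member genes are skipped with a warning; duplicated set ids
#' are an error.
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors; set descriptions are kept in
#'   the `"labels"` attribute.
#' @export
load_function_annotations <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  labels <- character(0)
  skipped <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 3L) {
      skipped <- skipped + 1L
      next
    }
    id <- parts[[1]]
    if (id %in% names(sets)) {
      stop("duplicated function id in GMT '", path, "': ", id)
    }
    sets[[id]] <- unique(parts[-(1:2)])
    labels[[id]] <- parts[[2]]
  }
  if (skipped > 0L) {
    warning("GMT '", path, "': skipped ", skipped,
            " line(s) with no member genes")
  }
  attr(sets, "labels") <- labels
  sets
}

#' Map effector circuits to the cell functions they trigger
#'
#' An effector node triggers a function when the genes it contains intersect
#' the function's annotated gene set. The returned mapping uses
#' pathway-qualified effector-circuit ids (`"<pathway>:*-><node>"`), the same
#' ids used as rownames of effector-level activity matrices, so that node ids
#' shared between pathways never collide.
#'
#' @param p A `pathway`.
#' @param annotations Named list of gene sets, as from
#'   [load_function_annotations()].
#' @return Named list: function id -> character vector of effector circuit
#'   ids. Functions hitting no effector are omitted.
#' @export
map_effectors_to_functions <- function(p, annotations) {
  stopifnot(inherits(p, "pathway"), is.list(annotations))
  effectors <- identify_terminals(p)$effectors
  out <- lapply(annotations, function(gs) {
    hit <- effectors[vapply(effectors, function(e) {
      length(intersect(p$node_genes[[e]], gs)) > 0L
    }, logical(1))]
    if (length(hit)) sprintf("%s:*->%s", p$pathway_id, hit) else NULL
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Merge per-pathway function maps
#'
#' @param maps List of mappings as returned by [map_effectors_to_functions()].
#' @return Single mapping with effector-circuit ids concatenated per function.
#' @export
merge_function_maps <- function(maps) {
  ids <- unique(unlist(lapply(maps, names)))
  setNames(lapply(ids, function(f) {
    unique(unlist(lapply(maps, function(m) m[[f]])))
  }), ids)
}
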