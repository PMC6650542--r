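#' Orient a skeleton graph at the soma
#'
#' Directs every edge away from the soma by breadth-first traversal,
#' producing the rooted tree on which apical/basal and branch-order labels
#' are defined.
#'
#' @param graph a connected, acyclic [skeleton_graph()].
#' @param soma_node node id of the soma; defaults to the graph's
#'   `soma_node` attribute.
#' @return A `neuron_tree`: rooted edges (`from` = parent side), polylines
#'   oriented root-to-leaf, soma id.
#' @export
orient_tree <- function(graph, soma_node = attr(graph, "soma_node")) {
  if (is.null(soma_node) || !(soma_node %in% graph$nodes$id)) {
    stopf("lookup_error", "soma node `%s` not present in the graph",
          as.character(soma_node %||% "NULL"))
  }
  ne <- nrow(graph$edges)
  adj <- vector("list", nrow(graph$nodes))
  names(adj) <- graph$nodes$id
  for (e in seq_len(ne)) {
    f <- as.character(graph$edges$from[e])
    t <- as.character(graph$edges$to[e])
    adj[[f]] <- c(adj[[f]], e)
    adj[[t]] <- c(adj[[t]], e)
  }
  visited <- setNames(rep(FALSE, nrow(graph$nodes)), graph$nodes$id)
  used <- rep(FALSE, ne)
  visited[as.character(soma_node)] <- TRUE
  queue <- soma_node
  from <- integer(ne)
  to <- integer(ne)
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (e in adj[[as.character(v)]]) {
      if (used[e]) next
      other <- if (graph$edges$from[e] == v) graph$edges$to[e] else
        graph$edges$from[e]
      if (visited[as.character(other)]) {
        stopf("topology_error",
              "graph contains a cycle through edge %d (%d-%d)",
              graph$edges$id[e], graph$edges$from[e], graph$edges$to[e])
      }
      used[e] <- TRUE
      from[e] <- v
      to[e] <- other
      visited[as.character(other)] <- TRUE
      queue <- c(queue, other)
    }
  }
  if (!all(visited)) {
    stopf("topology_error", "graph is not connected (%d unreached nodes)",
          sum(!visited))
  }
  polylines <- graph$polylines
  for (e in seq_len(ne)) {
    if (graph$edges$from[e] != from[e]) {
      P <- polylines[[e]]
      polylines[[e]] <- P[rev(seq_len(nrow(P))), , drop = FALSE]
    }
  }
  edges <- data.frame(id = graph$edges$id, from = from, to = to,
                      length = graph$edges$length,
                      apical = NA, order = NA_integer_)
  structure(list(nodes = graph$nodes, edges = edges,
                 polylines = polylines, soma = soma_node),
            class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree> soma %d, %d edges, %.1f um\n", x$soma,
              nrow(x$edges), sum(x$edges$length)))
  invisible(x)
}

tree_child_edges <- function(tree) {
  out <- vector("list", max(tree$nodes$id))
  for (e in seq_len(nrow(tree$edges))) {
    f <- tree$edges$from[e]
    out[[f]] <- c(out[[f]], e)
  }
  out
}

# edge indices of the subtree rooted at edge index `eidx` (inclusive)
subtree_edges <- function(tree, eidx, child_edges = tree_child_edges(tree)) {
  out <- integer(0)
  stack <- eidx
  while (length(stack) > 0) {
    e <- stack[1]
    stack <- stack[-1]
    out <- c(out, e)
    stack <- c(stack, child_edges[[tree$edges$to[e]]])
  }
  out
}

#' Label the apical subtree of an oriented neuron tree
#'
#' The soma-emanating subtree containing the apical reference is flagged
#' apical; every other soma-emanating subtree is basal.
#'
#' @param tree a `neuron_tree` from [orient_tree()].
#' @param apical_edge edge id of the apical reference segment.
#' @param apical_xyz alternatively, a um position; the nearest edge is used.
#' @export
label_apical <- function(tree, apical_edge = NULL, apical_xyz = NULL) {
  if (is.null(apical_edge)) {
    if (is.null(apical_xyz)) {
      stopf("lookup_error", "supply `apical_edge` or `apical_xyz`")
    }
    apical_edge <- nearest_edge(tree, apical_xyz)
  }
  eidx <- which(tree$edges$id == apical_edge)
  if (length(eidx) != 1) {
    stopf("lookup_error", "apical reference edge `%s` not found",
          as.character(apical_edge))
  }
  # climb to the soma-emanating edge containing the reference
  cur <- eidx
  parent_edge <- function(e) {
    w <- which(tree$edges$to == tree$edges$from[e])
    if (length(w) == 0) NA_integer_ else w
  }
  while (tree$edges$from[cur] != tree$soma) {
    cur <- parent_edge(cur)
  }
  ce <- tree_child_edges(tree)
  apical_set <- subtree_edges(tree, cur, ce)
  tree$edges$apical <- FALSE
  tree$edges$apical[apical_set] <- TRUE
  tree
}

#' Assign branch orders by the recursive longest-path rule
#'
#' For every soma-emanating subtree the longest (in um) root-to-leaf path
#' is the primary (order-1) process; edges branching off an order-k path
#' root subtrees whose own longest paths are order k+1, recursively. Ties
#' between equally long paths are broken towards the smallest leaf node
#' id.
#'
#' @param tree an oriented `neuron_tree`.
#' @export
assign_orders <- function(tree) {
  ce <- tree_child_edges(tree)
  n_ids <- max(tree$nodes$id)
  L <- rep(0, n_ids)           # longest downstream path length from node
  bestleaf <- rep(NA_integer_, n_ids)
  bestedge <- rep(NA_integer_, n_ids)  # child edge continuing that path

  topo <- integer(0)  # nodes in BFS order from soma
  queue <- tree$soma
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    topo <- c(topo, v)
    for (e in ce[[v]]) queue <- c(queue, tree$edges$to[e])
  }
  for (v in rev(topo)) {
    kids <- ce[[v]]
    if (is.null(kids) || length(kids) == 0) {
      L[v] <- 0
      bestleaf[v] <- v
      next
    }
    best <- NA
    for (e in kids) {
      child <- tree$edges$to[e]
      cand_len <- tree$edges$length[e] + L[child]
      cand_leaf <- bestleaf[child]
      if (is.na(best) || cand_len > L[v] + 1e-12 ||
          (abs(cand_len - L[v]) <= 1e-12 && cand_leaf < bestleaf[v])) {
        L[v] <- cand_len
        bestleaf[v] <- cand_leaf
        bestedge[v] <- e
        best <- e
      }
    }
  }
  tree$edges$order <- NA_integer_
  assign_walk <- function(eidx, ord) {
    stack <- list(c(eidx, ord))
    while (length(stack) > 0) {
      it <- stack[[1]]
      stack <- stack[-1]
      e <- it[1]; k <- it[2]
      tree$edges$order[e] <<- k
      node <- tree$edges$to[e]
      for (ke in ce[[node]]) {
        stack[[length(stack) + 1L]] <-
          c(ke, if (ke == bestedge[node]) k else k + 1L)
      }
    }
  }
  for (e in ce[[tree$soma]]) assign_walk(e, 1L)
  tree
}

#' Per-neuron morphometry record
#'
#' Totals and per-order statistics of an oriented, apical-labeled,
#' order-labeled neuron tree: total/apical/basal length, number of
#' processes per order (maximal same-order paths), length per order and
#' bifurcations per order (branch nodes counted on the order of their
#' incoming edge; the soma is not a bifurcation). The aggregate category
#' `higher` collects orders >= 3.
#'
#' @param tree a `neuron_tree` after [orient_tree()], [label_apical()] and
#'   [assign_orders()].
#' @return A list of class `morphometry_record`.
#' @export
measure <- function(tree) {
  if (any(is.na(tree$edges$order)) || any(is.na(tree$edges$apical))) {
    stopf("precondition_error",
          "tree must be apical-labeled and order-labeled before measure()")
  }
  e <- tree$edges
  total <- sum(e$length)
  apical <- sum(e$length[e$apical])
  basal <- total - apical
  maxord <- max(e$order)
  ords <- seq_len(max(maxord, 3))
  parent_order <- function(eidx) {
    w <- which(e$to == e$from[eidx])
    if (length(w) == 0) 0L else e$order[w]
  }
  ce <- tree_child_edges(tree)
  n_proc <- integer(length(ords))
  len_ord <- numeric(length(ords))
  n_bif <- integer(length(ords))
  for (i in seq_len(nrow(e))) {
    k <- e$order[i]
    len_ord[k] <- len_ord[k] + e$length[i]
    if (parent_order(i) != k) n_proc[k] <- n_proc[k] + 1L
    kids <- ce[[e$to[i]]]
    if (!is.null(kids) && length(kids) >= 2) n_bif[k] <- n_bif[k] + 1L
  }
  structure(list(total_um = total, apical_um = apical, basal_um = basal,
                 orders = data.frame(order = ords, n_processes = n_proc,
                                     length_um = len_ord,
                                     n_bifurcations = n_bif),
                 n_primary = n_proc[1], n_secondary = n_proc[2],
                 n_higher = sum(n_proc[-(1:2)]),
                 length_primary = len_ord[1], length_secondary = len_ord[2],
                 length_higher = sum(len_ord[-(1:2)])),
            class = "morphometry_record")
}

#' @export
print.morphometry_record <- function(x, ...) {
  cat(sprintf(
    "<morphometry> total %.1f um (apical %.1f, basal %.1f); processes 1/2/3+: %d/%d/%d\n",
    x$total_um, x$apical_um, x$basal_um, x$n_primary, x$n_secondary,
    x$n_higher))
  invisible(x)
}

#' One-row data.frame view of a morphometry record
#' @param record a `morphometry_record`.
#' @export
morphometry_row <- function(record) {
  o <- record$orders
  bif <- function(k) if (k <= nrow(o)) o$n_bifurcations[k] else 0L
  data.frame(total_um = record$total_um, apical_um = record$apical_um,
             basal_um = record$basal_um,
             n_primary = record$n_primary,
             n_secondary = record$n_secondary,
             n_higher = record$n_higher,
             length_primary = record$length_primary,
             length_secondary = record$length_secondary,
             length_higher = record$length_higher,
             bif_primary = bif(1), bif_secondary = bif(2),
             bif_higher = sum(o$n_bifurcations[-(1:2)]))
}

#' Write per-neuron morphometry records to CSV
#' @param records list of `morphometry_record`.
#' @param path output CSV path.
#' @param ids optional neuron identifiers.
#' @export
write_morphometry <- function(records, path, ids = seq_along(records)) {
  df <- do.call(rbind, lapply(records, morphometry_row))
  df <- cbind(neuron = ids, df)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Morphometry of a ground-truth tree
#'
#' Runs the same orientation / apical labeling / order assignment /
#' measurement chain on the ground-truth graph of a `gt_tree`, providing
#' the reference values for recovery tests.
#'
#' @param tree a `gt_tree`.
#' @export
measure_tree <- function(tree) {
  g <- as_skeleton_graph(tree)
  nt <- orient_tree(g, attr(g, "soma_node"))
  nt <- label_apical(nt, apical_xyz = attr(g, "apical_ref_xyz"))
  nt <- assign_orders(nt)
  measure(nt)
}
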