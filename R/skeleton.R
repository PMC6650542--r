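#' Spatial skeleton graph
#'
#' Nodes are endpoints and junctions (degree != 2 in reduced form); each
#' edge carries an ordered polyline of 3D um points whose arc length is the
#' edge length. Built by [extract_initial_skeleton()] or
#' [as_skeleton_graph()].
#'
#' @param nodes data.frame with columns id, x, y, z (um).
#' @param from,to integer node ids per edge.
#' @param polylines list of m x 3 matrices; row 1 must coincide with the
#'   `from` node, the last row with the `to` node.
#' @param provenance `"raw"`, `"reduced"` or `"ground-truth"`.
#' @export
skeleton_graph <- function(nodes, from, to, polylines,
                           provenance = "raw") {
  stopifnot(length(from) == length(to),
            length(from) == length(polylines))
  lens <- vapply(polylines, poly_length, 0)
  edges <- data.frame(id = seq_along(from), from = as.integer(from),
                      to = as.integer(to), length = lens)
  structure(list(nodes = nodes, edges = edges, polylines = polylines,
                 provenance = provenance),
            class = "skeleton_graph")
}

poly_length <- function(P) {
  if (nrow(P) < 2) return(0)
  sum(sqrt(rowSums((P[-1, , drop = FALSE] -
                      P[-nrow(P), , drop = FALSE])^2)))
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph:%s> %d nodes, %d edges, %.1f um\n",
              x$provenance, nrow(x$nodes), nrow(x$edges),
              skeleton_total_length(x)))
  invisible(x)
}

#' Total length of a skeleton graph (um)
#' @param graph a [skeleton_graph()].
#' @export
skeleton_total_length <- function(graph) {
  if (is.null(graph$edges) || nrow(graph$edges) == 0) return(0)
  sum(graph$edges$length)
}

node_degrees <- function(graph) {
  deg <- setNames(rep(0L, nrow(graph$nodes)), graph$nodes$id)
  for (v in c(graph$edges$from, graph$edges$to)) {
    v <- as.character(v)
    deg[v] <- deg[v] + 1L
  }
  deg
}

node_xyz <- function(graph, id) {
  r <- graph$nodes[graph$nodes$id == id, ]
  c(r$x, r$y, r$z)
}

#' Extract the initial (raw) skeleton of a binary mask
#'
#' 3D topological thinning to a one-voxel-wide curve, conversion of the
#' voxel chain into a spatial graph: the 26-adjacency graph of skeleton
#' voxels is reduced to its minimum spanning tree (physical edge lengths;
#' this removes staircase triangles and any residual thinning loops), nodes
#' are placed at voxels of degree != 2, and chains become polylines in
#' physical um. Terminal polylines are optionally extended outward by the
#' local tube radius (distance-transform value at the tip), compensating
#' the retraction of thinning inside the end caps.
#'
#' @param mask a validated single-component [binary_mask()].
#' @param extend_tips logical; extend terminal branches outward by
#'   `tip_factor` times the local radius.
#' @param tip_factor fraction of the local distance-transform radius to
#'   extend each tip by. Vesselness filtering erodes tube end caps by
#'   roughly half a radius, which this compensates; 0 disables.
#' @return A `skeleton_graph` with provenance `"raw"`.
#' @export
extract_initial_skeleton <- function(mask, extend_tips = TRUE,
                                     tip_factor = 0.5) {
  d <- dim(mask$data)
  if (!any(mask$data)) stopf("precondition_error", "empty mask")
  lab <- cpp_label3(mask$data, d, 26L)
  if (max(lab) != 1) {
    stopf("precondition_error",
          "mask must contain exactly one 26-connected component (found %d)",
          max(lab))
  }
  sp <- mask$spacing
  thin <- cpp_thin3(mask$data, d)
  vox <- which(thin)
  if (length(vox) == 0) stopf("precondition_error", "thinning removed all voxels")
  coords <- voxel_centers(vox, d, sp)
  if (length(vox) == 1) {
    g <- skeleton_graph(data.frame(id = 1L, x = coords[1], y = coords[2],
                                   z = coords[3]),
                        integer(), integer(), list())
    attr(g, "spacing") <- sp
    return(g)
  }
  pairs <- cpp_adjacency_pairs(thin, d, 26L)
  vid <- match(pairs[, 1], vox)
  wid <- match(pairs[, 2], vox)
  wlen <- sqrt(rowSums((coords[vid, , drop = FALSE] -
                          coords[wid, , drop = FALSE])^2))
  ig <- igraph::graph_from_edgelist(cbind(vid, wid), directed = FALSE)
  igraph::E(ig)$weight <- wlen + 1e-9 * seq_along(wlen)  # deterministic MST
  mstg <- igraph::mst(ig)
  adj <- igraph::as_adj_list(mstg)
  deg <- vapply(adj, length, 1L)
  special <- which(deg != 2L)
  if (length(special) == 0) special <- 1L  # safeguard; MST of >1 voxel has leaves
  node_of <- integer(length(vox))
  node_of[special] <- seq_along(special)

  polys <- list()
  froms <- integer()
  tos <- integer()
  done <- new.env(parent = emptyenv())
  for (s in special) {
    for (nb in as.integer(adj[[s]])) {
      prev <- s
      cur <- nb
      chain <- c(s, cur)
      while (deg[cur] == 2L) {
        nxt <- setdiff(as.integer(adj[[cur]]), prev)
        prev <- cur
        cur <- nxt
        chain <- c(chain, cur)
      }
      ck <- paste(chain[1], chain[2], chain[length(chain)],
                  chain[length(chain) - 1])
      rk <- paste(chain[length(chain)], chain[length(chain) - 1],
                  chain[1], chain[2])
      if (exists(ck, envir = done) || exists(rk, envir = done)) next
      assign(ck, TRUE, envir = done)
      polys[[length(polys) + 1L]] <- coords[chain, , drop = FALSE]
      froms <- c(froms, node_of[chain[1]])
      tos <- c(tos, node_of[cur])
    }
  }
  nodes <- data.frame(id = seq_along(special),
                      x = coords[special, 1], y = coords[special, 2],
                      z = coords[special, 3])
  g <- skeleton_graph(nodes, froms, tos, polys, provenance = "raw")
  attr(g, "spacing") <- sp
  attr(g, "tip_voxel") <- vox[special]
  if (extend_tips && tip_factor > 0 && length(polys) > 0) {
    g <- extend_skeleton_tips(g, mask, tip_factor)
  }
  g
}

voxel_centers <- function(lin, d, sp) {
  lin0 <- lin - 1
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind((i + 0.5) * sp[1], (j + 0.5) * sp[2], (k + 0.5) * sp[3])
}

extend_skeleton_tips <- function(graph, mask, tip_factor = 0.5) {
  d <- dim(mask$data)
  edt_in <- cpp_edt3(!mask$data, d, mask$spacing)
  deg <- node_degrees(graph)
  for (nid in graph$nodes$id[deg[as.character(graph$nodes$id)] == 1L]) {
    eidx <- which(graph$edges$from == nid | graph$edges$to == nid)[1]
    P <- graph$polylines[[eidx]]
    at_start <- graph$edges$from[eidx] == nid
    if (at_start) P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
    m <- nrow(P)
    ref <- max(1, m - 3)
    dirv <- P[m, ] - P[ref, ]
    if (sum(dirv^2) == 0) next
    dirv <- vnorm(dirv)
    tipxyz <- P[m, ]
    vi <- pmin(pmax(ceiling(tipxyz / mask$spacing), 1), d)
    r <- edt_in[vi[1], vi[2], vi[3]] * tip_factor
    if (!is.finite(r) || r <= 0) next
    newtip <- tipxyz + dirv * r
    P <- rbind(P, newtip)
    if (at_start) P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
    graph$polylines[[eidx]] <- P
    graph$edges$length[eidx] <- poly_length(P)
    sel <- graph$nodes$id == nid
    graph$nodes$x[sel] <- newtip[1]
    graph$nodes$y[sel] <- newtip[2]
    graph$nodes$z[sel] <- newtip[3]
  }
  graph
}

#' Merge degree-2 chains of a skeleton graph into single edges
#' @param graph a [skeleton_graph()].
#' @param keep node ids never merged away (e.g. the soma).
#' @export
merge_degree2 <- function(graph, keep = integer()) {
  repeat {
    deg <- node_degrees(graph)
    cand <- graph$nodes$id[deg[as.character(graph$nodes$id)] == 2L &
                             !(graph$nodes$id %in% keep)]
    if (length(cand) == 0) break
    n <- cand[1]
    eidx <- which(graph$edges$from == n | graph$edges$to == n)
    if (length(eidx) != 2) break
    e1 <- eidx[1]; e2 <- eidx[2]
    p1 <- orient_poly_from(graph, e1,
                           setdiff(c(graph$edges$from[e1],
                                     graph$edges$to[e1]), n)[1])
    p2 <- orient_poly_from(graph, e2, n)
    a <- setdiff(c(graph$edges$from[e1], graph$edges$to[e1]), n)[1]
    b <- setdiff(c(graph$edges$from[e2], graph$edges$to[e2]), n)[1]
    if (is.na(a) || is.na(b)) break  # self-loop guard
    newpoly <- rbind(p1, p2[-1, , drop = FALSE])
    graph$polylines[[e1]] <- newpoly
    graph$edges$from[e1] <- a
    graph$edges$to[e1] <- b
    graph$edges$length[e1] <- poly_length(newpoly)
    graph$polylines[[e2]] <- NULL
    graph$edges <- graph$edges[-e2, ]
    graph$nodes <- graph$nodes[graph$nodes$id != n, ]
    graph$edges$id <- seq_len(nrow(graph$edges))
  }
  rownames(graph$edges) <- NULL
  graph
}

# polyline of edge eidx oriented to start at node `start`
orient_poly_from <- function(graph, eidx, start) {
  P <- graph$polylines[[eidx]]
  if (graph$edges$from[eidx] == start) return(P)
  P[rev(seq_len(nrow(P))), , drop = FALSE]
}

#' Remove short terminal spurs (thinning artifacts)
#'
#' Iteratively deletes leaf edges shorter than `min_length` um whose other
#' endpoint is a junction, then re-merges degree-2 chains.
#'
#' @param graph a [skeleton_graph()].
#' @param min_length um; spurs below this are removed.
#' @param keep node ids protected from merging.
#' @export
prune_spurs <- function(graph, min_length = 3, keep = integer()) {
  repeat {
    deg <- node_degrees(graph)
    isleaf <- function(id) deg[as.character(id)] == 1L
    isjunc <- function(id) deg[as.character(id)] >= 3L
    drop <- which(vapply(seq_len(nrow(graph$edges)), function(e) {
      f <- graph$edges$from[e]; t <- graph$edges$to[e]
      graph$edges$length[e] < min_length &&
        ((isleaf(f) && isjunc(t) && !(f %in% keep)) ||
           (isleaf(t) && isjunc(f) && !(t %in% keep)))
    }, TRUE))
    if (length(drop) == 0) break
    used <- unique(c(graph$edges$from[-drop], graph$edges$to[-drop]))
    graph$polylines[drop] <- NULL
    graph$edges <- graph$edges[-drop, ]
    graph$nodes <- graph$nodes[graph$nodes$id %in% used, ]
    graph$edges$id <- seq_len(nrow(graph$edges))
    graph <- merge_degree2(graph, keep = keep)
  }
  graph
}

#' Contract short junction-to-junction edges
#'
#' Thinning can split one anatomical branch point into two junctions a
#' voxel or two apart; edges shorter than `radius` joining two junctions
#' are contracted to a single node at their midpoint.
#'
#' @param graph a [skeleton_graph()].
#' @param radius um.
#' @export
merge_junction_clusters <- function(graph, radius = 2) {
  repeat {
    deg <- node_degrees(graph)
    isjunc <- function(id) deg[as.character(id)] >= 3L
    cand <- which(vapply(seq_len(nrow(graph$edges)), function(e) {
      graph$edges$length[e] < radius &&
        isjunc(graph$edges$from[e]) && isjunc(graph$edges$to[e])
    }, TRUE))
    if (length(cand) == 0) break
    e <- cand[1]
    a <- graph$edges$from[e]; b <- graph$edges$to[e]
    mid <- (node_xyz(graph, a) + node_xyz(graph, b)) / 2
    graph <- contract_nodes(graph, c(a, b), mid)
  }
  graph
}

#' Collapse all nodes near a soma position into a single soma node
#'
#' Nodes within `radius` um of `soma_xyz` are contracted to one node placed
#' exactly at `soma_xyz`; if none lie within the radius the nearest node is
#' designated the soma without moving it. The soma node id is stored in the
#' `soma_node` attribute.
#'
#' @param graph a [skeleton_graph()].
#' @param soma_xyz length-3 um position.
#' @param radius um.
#' @export
merge_soma_cluster <- function(graph, soma_xyz, radius = 3) {
  xyz <- as.matrix(graph$nodes[, c("x", "y", "z")])
  dist <- sqrt(colSums((t(xyz) - soma_xyz)^2))
  inside <- graph$nodes$id[dist <= radius]
  if (length(inside) == 0) {
    attr(graph, "soma_node") <- graph$nodes$id[which.min(dist)]
    return(graph)
  }
  graph <- contract_nodes(graph, inside, soma_xyz)
  soma <- graph$nodes$id[graph$nodes$x == soma_xyz[1] &
                           graph$nodes$y == soma_xyz[2] &
                           graph$nodes$z == soma_xyz[3]][1]
  attr(graph, "soma_node") <- soma
  graph <- merge_degree2(graph, keep = soma)
  graph
}

# contract the node set `ids` into one node at `xyz`; internal edges drop
contract_nodes <- function(graph, ids, xyz) {
  newid <- max(graph$nodes$id) + 1L
  internal <- graph$edges$from %in% ids & graph$edges$to %in% ids
  graph$polylines[which(internal)] <- NULL
  graph$edges <- graph$edges[!internal, ]
  for (e in seq_len(nrow(graph$edges))) {
    touched <- FALSE
    P <- graph$polylines[[e]]
    if (graph$edges$from[e] %in% ids) {
      graph$edges$from[e] <- newid
      P[1, ] <- xyz
      touched <- TRUE
    }
    if (graph$edges$to[e] %in% ids) {
      graph$edges$to[e] <- newid
      P[nrow(P), ] <- xyz
      touched <- TRUE
    }
    if (touched) {
      graph$polylines[[e]] <- P
      graph$edges$length[e] <- poly_length(P)
    }
  }
  graph$nodes <- graph$nodes[!(graph$nodes$id %in% ids), ]
  graph$nodes <- rbind(graph$nodes,
                       data.frame(id = newid, x = xyz[1], y = xyz[2],
                                  z = xyz[3]))
  # drop exact duplicate edges that contraction may create
  key <- paste(pmin(graph$edges$from, graph$edges$to),
               pmax(graph$edges$from, graph$edges$to))
  dup <- duplicated(key) & (graph$edges$from == newid |
                              graph$edges$to == newid)
  if (any(dup)) {
    graph$polylines[which(dup)] <- NULL
    graph$edges <- graph$edges[!dup, ]
  }
  graph$edges$id <- seq_len(nrow(graph$edges))
  rownames(graph$edges) <- NULL
  rownames(graph$nodes) <- NULL
  graph
}

#' Configuration of the two-term skeleton reduction
#'
#' The reduced skeleton minimizes `E = fidelity + lambda * n_segments`,
#' where fidelity is the mean distance (um) from foreground mask voxels to
#' the skeleton and `n_segments` counts polyline segments: a balance of
#' volume representation against parsimony.
#'
#' @param lambda parsimony weight, um per segment (>= 0).
#' @param max_fidelity hard cap (um) on the mean mask-to-skeleton distance;
#'   removals that would exceed it are rejected.
#' @export
reduction_config <- function(lambda = 0.5, max_fidelity = 1.5) {
  if (lambda < 0) stopf("parameter_error", "lambda must be >= 0")
  check_number(max_fidelity, "max_fidelity", lower = 0, strict_lower = TRUE)
  structure(list(lambda = lambda, max_fidelity = max_fidelity),
            class = "reduction_config")
}

#' Reduce a skeleton by greedy polyline-vertex decimation
#'
#' Douglas-Peucker-style candidate removals of interior polyline vertices,
#' lowest index first, accepting any removal that does not increase
#' `E = fidelity + lambda * n_segments`. Fidelity is the mean distance of
#' foreground mask voxels to the skeleton, with each voxel assigned once to
#' its initially nearest edge (the assignment is kept fixed during
#' decimation). Node positions, connectivity and cycles are untouched: only
#' interior vertices are removed, so the reduction can neither disconnect
#' the graph nor create cycles. The accepted-step values of E are recorded
#' in the `E_log` attribute (non-increasing by construction).
#'
#' @param graph a raw [skeleton_graph()].
#' @param mask the [binary_mask()] the skeleton was extracted from.
#' @param config a [reduction_config()].
#' @return The reduced `skeleton_graph` (provenance `"reduced"`), with
#'   attributes `E_log` and `fidelity`.
#' @export
reduce_skeleton <- function(graph, mask, config = reduction_config()) {
  if (!inherits(config, "reduction_config")) {
    stopf("parameter_error", "`config` must come from reduction_config()")
  }
  if (nrow(graph$edges) == 0) {
    graph$provenance <- "reduced"
    return(graph)
  }
  pts <- mask_points(mask)
  n <- nrow(pts)
  verts <- do.call(rbind, graph$polylines)
  sizes <- vapply(graph$polylines, nrow, 1L)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  asg <- cpp_assign_points_to_polylines(pts, verts, starts, ends)
  lambda <- config$lambda

  fid_sum <- sum(asg$dist)
  seg_count <- sum(sizes - 1L)
  E <- fid_sum / n + lambda * seg_count
  E_log <- E

  for (e in seq_along(graph$polylines)) {
    sel <- asg$edge == e
    pts_e <- pts[sel, , drop = FALSE]
    d_e <- if (any(sel)) {
      cpp_min_dist_to_polyline(pts_e, graph$polylines[[e]])
    } else numeric(0)
    P <- graph$polylines[[e]]
    repeat {
      improved <- FALSE
      v <- 2L
      while (v <= nrow(P) - 1L) {
        cand <- P[-v, , drop = FALSE]
        nd <- if (nrow(pts_e) > 0) {
          cpp_min_dist_to_polyline(pts_e, cand)
        } else numeric(0)
        delta_fid <- sum(nd) - sum(d_e)
        dE <- delta_fid / n - lambda
        new_fid <- (fid_sum + delta_fid) / n
        if (dE <= 1e-12 && new_fid <= config$max_fidelity) {
          P <- cand
          d_e <- nd
          fid_sum <- fid_sum + delta_fid
          seg_count <- seg_count - 1L
          E <- fid_sum / n + lambda * seg_count
          E_log <- c(E_log, E)
          improved <- TRUE
        } else {
          v <- v + 1L
        }
      }
      if (!improved) break
    }
    graph$polylines[[e]] <- P
    graph$edges$length[e] <- poly_length(P)
  }
  graph$provenance <- "reduced"
  attr(graph, "E_log") <- E_log
  attr(graph, "fidelity") <- fid_sum / n
  attr(graph, "lambda") <- lambda
  graph
}

#' Number of polyline segments in a skeleton graph
#' @param graph a [skeleton_graph()].
#' @export
skeleton_segment_count <- function(graph) {
  if (length(graph$polylines) == 0) return(0L)
  sum(vapply(graph$polylines, nrow, 1L) - 1L)
}

#' Nearest graph node / edge to a physical position
#' @param graph a [skeleton_graph()].
#' @param xyz length-3 um position.
#' @return `nearest_node`: a node id. `nearest_edge`: an edge id.
#' @export
nearest_node <- function(graph, xyz) {
  xyzm <- as.matrix(graph$nodes[, c("x", "y", "z")])
  graph$nodes$id[which.min(colSums((t(xyzm) - xyz)^2))]
}

#' @rdname nearest_node
#' @export
nearest_edge <- function(graph, xyz) {
  verts <- do.call(rbind, graph$polylines)
  sizes <- vapply(graph$polylines, nrow, 1L)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  asg <- cpp_assign_points_to_polylines(matrix(xyz, nrow = 1), verts,
                                        starts, ends)
  graph$edges$id[asg$edge[1]]
}
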