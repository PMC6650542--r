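#' Parameters for the ground-truth dendritic tree generator
#'
#' Trees are grown by a depth-limited Galton-Watson process: every process
#' ("branch") is a chain of `segments_per_branch` straight segments; at the
#' end of a branch of depth `d < max_depth` the tip bifurcates into two
#' daughter branches with probability `branch_probability`, otherwise the
#' branch terminates. One trunk system is apical (a trunk of exactly
#' `apical_trunk_length` um before its first possible bifurcation), the
#' remaining `n_basal_trunks` systems emanate from the soma in basal
#' directions.
#'
#' @param n_basal_trunks number of basal trunks (>= 1).
#' @param apical_trunk_length apical trunk length, um.
#' @param branch_probability per-branch-tip bifurcation probability in
#'   `[0, 1]`.
#' @param mean_segment_length,sd_segment_length segment length distribution
#'   (um, truncated at 20% of the mean).
#' @param segments_per_branch straight segments per branch (>= 1).
#' @param max_depth maximum branch depth (1 = unbranched trunks).
#' @param branch_angle_sd direction dispersion, degrees; also scales the
#'   jitter of the ~35 degree bifurcation half-angle.
#' @param radius tube radius, um (constant over the tree).
#' @param z_flatten factor in `(0, 1]` shrinking the z-component of growth
#'   directions, emulating the slab geometry of cortical slices.
#' @param min_separation if > 0, resample until all pairs of segments at
#'   tree distance >= 2 edges keep at least this centerline clearance (um).
#' @param bbox optional `c(xmin, xmax, ymin, ymax, zmin, zmax)` (um,
#'   relative to the soma at the origin) that all nodes must fit into.
#' @param max_tries resampling attempts for `min_separation`/`bbox`.
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `tree_gen_params`.
#' @export
tree_gen_params <- function(n_basal_trunks = 5,
                            apical_trunk_length = 18,
                            branch_probability = 0.9,
                            mean_segment_length = 6,
                            sd_segment_length = 1.2,
                            segments_per_branch = 2,
                            max_depth = 3,
                            branch_angle_sd = 20,
                            radius = 1.2,
                            z_flatten = 0.3,
                            min_separation = 0,
                            bbox = NULL,
                            max_tries = 50,
                            rng_seed = NULL) {
  check_number(n_basal_trunks, "n_basal_trunks", lower = 1)
  check_number(apical_trunk_length, "apical_trunk_length", lower = 0,
               strict_lower = TRUE)
  check_number(branch_probability, "branch_probability", 0, 1)
  check_number(mean_segment_length, "mean_segment_length", lower = 0,
               strict_lower = TRUE)
  check_number(sd_segment_length, "sd_segment_length", lower = 0)
  check_number(segments_per_branch, "segments_per_branch", lower = 1)
  check_number(max_depth, "max_depth", lower = 1)
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  check_number(z_flatten, "z_flatten", lower = 0, upper = 1,
               strict_lower = TRUE)
  structure(list(n_basal_trunks = as.integer(n_basal_trunks),
                 apical_trunk_length = apical_trunk_length,
                 branch_probability = branch_probability,
                 mean_segment_length = mean_segment_length,
                 sd_segment_length = sd_segment_length,
                 segments_per_branch = as.integer(segments_per_branch),
                 max_depth = as.integer(max_depth),
                 branch_angle_sd = branch_angle_sd,
                 radius = radius, z_flatten = z_flatten,
                 min_separation = min_separation, bbox = bbox,
                 max_tries = as.integer(max_tries), rng_seed = rng_seed),
            class = "tree_gen_params")
}

flatten_dir <- function(d, z_flatten) {
  vnorm(c(d[1], d[2], d[3] * z_flatten))
}

jitter_dir <- function(d, sd_deg) {
  if (sd_deg <= 0) return(d)
  ang <- stats::rnorm(1, 0, sd_deg) * pi / 180
  axis <- rotate_about(perp_vector(d), d, stats::runif(1, 0, 2 * pi))
  vnorm(rotate_about(d, axis, ang))
}

#' Sample a ground-truth dendritic tree
#'
#' @param params a [tree_gen_params()] object.
#' @return A `gt_tree`: `nodes` (id, x, y, z, radius um), `edges` (id,
#'   parent, child, length um, system, depth, branch), `soma_id`,
#'   `apical_root_edge_id`. The soma sits at the origin; the apical trunk
#'   grows along +y.
#' @export
sample_tree <- function(params) {
  if (!inherits(params, "tree_gen_params")) {
    stopf("parameter_error", "`params` must come from tree_gen_params()")
  }
  with_seed(params$rng_seed, {
    for (try in seq_len(max(1L, params$max_tries))) {
      tree <- grow_tree_once(params)
      if (tree_fits(tree, params)) return(tree)
    }
    stopf("parameter_error",
          paste("could not sample a tree satisfying min_separation/bbox",
                "after %d attempts"), params$max_tries)
  })
}

grow_tree_once <- function(p) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list(list(id = 1L, x = 0, y = 0, z = 0, radius = p$radius))
  env$edges <- list()
  env$next_node <- 2L
  env$next_edge <- 1L

  add_node <- function(xyz) {
    id <- env$next_node
    env$next_node <- id + 1L
    env$nodes[[length(env$nodes) + 1L]] <-
      list(id = id, x = xyz[1], y = xyz[2], z = xyz[3], radius = p$radius)
    id
  }
  add_edge <- function(parent, child, len, system, depth, branch) {
    id <- env$next_edge
    env$next_edge <- id + 1L
    env$edges[[length(env$edges) + 1L]] <-
      list(id = id, parent = parent, child = child, length = len,
           system = system, depth = depth, branch = branch)
    id
  }
  env$next_branch <- 1L
  seg_len <- function() {
    if (p$sd_segment_length <= 0) return(p$mean_segment_length)
    max(stats::rnorm(1, p$mean_segment_length, p$sd_segment_length),
        0.2 * p$mean_segment_length)
  }
  node_xyz <- function(id) {
    n <- env$nodes[[id]]
    c(n$x, n$y, n$z)
  }

  grow_branch <- function(start, dir, depth, system, seg_lengths = NULL) {
    branch <- env$next_branch
    env$next_branch <- branch + 1L
    cur <- start
    for (s in seq_len(p$segments_per_branch)) {
      dir <- jitter_dir(dir, p$branch_angle_sd)
      len <- if (is.null(seg_lengths)) seg_len() else seg_lengths[s]
      nxt <- add_node(node_xyz(cur) + dir * len)
      add_edge(cur, nxt, len, system, depth, branch)
      cur <- nxt
    }
    if (depth < p$max_depth &&
        stats::runif(1) < p$branch_probability) {
      half <- (35 + stats::rnorm(2, 0, p$branch_angle_sd / 2)) * pi / 180
      axis <- rotate_about(perp_vector(dir), dir, stats::runif(1, 0, 2 * pi))
      d1 <- flatten_dir(rotate_about(dir, axis, half[1]), p$z_flatten)
      d2 <- flatten_dir(rotate_about(dir, axis, -half[2]), p$z_flatten)
      grow_branch(cur, d1, depth + 1L, system)
      grow_branch(cur, d2, depth + 1L, system)
    }
    invisible(NULL)
  }

  # apical trunk: fixed total length, along +y
  apical_dir <- vnorm(c(0, 1, 0))
  trunk_seg <- rep(p$apical_trunk_length / p$segments_per_branch,
                   p$segments_per_branch)
  grow_branch(1L, apical_dir, 1L, "apical", seg_lengths = trunk_seg)
  apical_root_edge <- 1L

  # basal trunks: azimuths spread over the hemisphere away from the apical
  n <- p$n_basal_trunks
  for (i in seq_len(n)) {
    az <- (90 + 45 + (i - 0.5) * 270 / n + stats::rnorm(1, 0, 8)) * pi / 180
    tilt <- stats::rnorm(1, 0, 0.3) * p$z_flatten
    dir <- vnorm(c(cos(az), sin(az), tilt))
    grow_branch(1L, dir, 1L, "basal")
  }

  nodes <- do.call(rbind, lapply(env$nodes, as.data.frame))
  edges <- do.call(rbind, lapply(env$edges, as.data.frame))
  edges$system <- as.character(edges$system)
  structure(list(nodes = nodes, edges = edges, soma_id = 1L,
                 apical_root_edge_id = apical_root_edge, params = p),
            class = "gt_tree")
}

tree_fits <- function(tree, p) {
  if (!is.null(p$bbox)) {
    b <- p$bbox
    n <- tree$nodes
    if (any(n$x < b[1] | n$x > b[2] | n$y < b[3] | n$y > b[4] |
            n$z < b[5] | n$z > b[6])) {
      return(FALSE)
    }
  }
  if (p$min_separation > 0) {
    if (min_branch_separation(tree) < p$min_separation) return(FALSE)
  }
  TRUE
}

#' Minimum centerline clearance between non-adjacent segments of a tree
#'
#' Pairs of segments that share a node or whose endpoint nodes are directly
#' connected by another edge (tree distance < 2) are excluded: those pairs
#' meet at a junction by construction.
#'
#' @param tree a `gt_tree`.
#' @return minimum distance in um (Inf for trees with < 2 eligible pairs).
#' @export
min_branch_separation <- function(tree) {
  e <- tree$edges
  n <- tree$nodes
  xyz <- as.matrix(n[, c("x", "y", "z")])
  rownames(xyz) <- n$id
  S <- cbind(xyz[as.character(e$parent), , drop = FALSE],
             xyz[as.character(e$child), , drop = FALSE])
  D <- cpp_segseg_dist(S)
  ne <- nrow(e)
  pairkey <- paste(pmin(e$parent, e$child), pmax(e$parent, e$child))
  has_edge <- new.env(parent = emptyenv())
  for (k in pairkey) assign(k, TRUE, envir = has_edge)
  linked <- function(a, b) {
    na <- c(e$parent[a], e$child[a])
    nb <- c(e$parent[b], e$child[b])
    if (length(intersect(na, nb)) > 0) return(TRUE)
    for (u in na) for (v in nb) {
      if (exists(paste(min(u, v), max(u, v)), envir = has_edge)) return(TRUE)
    }
    FALSE
  }
  best <- Inf
  for (a in seq_len(ne - 1)) {
    for (b in (a + 1):ne) {
      if (D[a, b] < best && !linked(a, b)) best <- D[a, b]
    }
  }
  best
}

#' Total length of a ground-truth tree (um)
#' @param tree a `gt_tree`.
#' @export
total_tree_length <- function(tree) sum(tree$edges$length)

#' Length of one dendritic system of a ground-truth tree
#' @param tree a `gt_tree`.
#' @param system `"apical"` or `"basal"`.
#' @export
tree_system_length <- function(tree, system = c("apical", "basal")) {
  system <- match.arg(system)
  sum(tree$edges$length[tree$edges$system == system])
}

#' Number of bifurcation nodes of a ground-truth tree (soma excluded)
#' @param tree a `gt_tree`.
#' @export
count_bifurcations <- function(tree) {
  kids <- table(tree$edges$parent)
  sum(kids >= 2 & as.integer(names(kids)) != tree$soma_id)
}

#' @export
print.gt_tree <- function(x, ...) {
  cat(sprintf(
    "<gt_tree> %d nodes, %d edges, total %.1f um (apical %.1f, basal %.1f)\n",
    nrow(x$nodes), nrow(x$edges), total_tree_length(x),
    tree_system_length(x, "apical"), tree_system_length(x, "basal")))
  invisible(x)
}

# children lookup: list indexed by node id
tree_children <- function(tree) {
  kids <- vector("list", max(tree$nodes$id))
  for (r in seq_len(nrow(tree$edges))) {
    p <- tree$edges$parent[r]
    kids[[p]] <- c(kids[[p]], tree$edges$child[r])
  }
  kids
}

#' Convert a ground-truth tree into a skeleton graph
#'
#' Graph nodes are the soma, branch points and tips; chains of degree-2 tree
#' nodes become edge polylines. The result carries `soma_node` and
#' `apical_ref_xyz` attributes (a point on the apical trunk) so that the
#' morphometry layer can be applied to ground truth exactly as to an
#' image-derived skeleton.
#'
#' @param tree a `gt_tree`.
#' @return A `skeleton_graph`.
#' @export
as_skeleton_graph <- function(tree) {
  kids <- tree_children(tree)
  nkids <- vapply(seq_along(kids), function(i) length(kids[[i]]), 1L)
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  rownames(xyz) <- tree$nodes$id
  get_xyz <- function(id) xyz[as.character(id), ]
  special <- tree$nodes$id[nkids[tree$nodes$id] != 1L |
                             tree$nodes$id == tree$soma_id]
  node_map <- setNames(seq_along(special), special)
  polys <- list()
  froms <- integer()
  tos <- integer()
  for (s in special) {
    for (child in kids[[s]]) {
      pts <- list(get_xyz(s))
      cur <- child
      while (!(cur %in% special)) {
        pts[[length(pts) + 1L]] <- get_xyz(cur)
        cur <- kids[[cur]][1]
      }
      pts[[length(pts) + 1L]] <- get_xyz(cur)
      polys[[length(polys) + 1L]] <- do.call(rbind, pts)
      froms <- c(froms, node_map[[as.character(s)]])
      tos <- c(tos, node_map[[as.character(cur)]])
    }
  }
  nodes <- data.frame(id = seq_along(special),
                      x = xyz[as.character(special), 1],
                      y = xyz[as.character(special), 2],
                      z = xyz[as.character(special), 3])
  g <- skeleton_graph(nodes, froms, tos, polys, provenance = "ground-truth")
  attr(g, "soma_node") <- node_map[[as.character(tree$soma_id)]]
  apical_child <- tree$edges$child[tree$edges$id == tree$apical_root_edge_id]
  attr(g, "apical_ref_xyz") <- get_xyz(apical_child)
  g
}

#' Write / read a tree in SWC format
#'
#' Standard 7 columns (id, type, x, y, z, radius, parent); type 1 marks the
#' soma node, 4 apical dendrite, 3 basal dendrite.
#'
#' @param tree a `gt_tree`.
#' @param path file path.
#' @export
write_swc <- function(tree, path) {
  e <- tree$edges
  node_sys <- setNames(rep("soma", nrow(tree$nodes)), tree$nodes$id)
  for (r in seq_len(nrow(e))) node_sys[as.character(e$child[r])] <- e$system[r]
  parent_of <- setNames(rep(-1L, nrow(tree$nodes)), tree$nodes$id)
  for (r in seq_len(nrow(e))) {
    parent_of[as.character(e$child[r])] <- e$parent[r]
  }
  type <- c(soma = 1L, basal = 3L, apical = 4L)[node_sys]
  df <- data.frame(id = tree$nodes$id, type = type,
                   x = tree$nodes$x, y = tree$nodes$y, z = tree$nodes$z,
                   radius = tree$nodes$radius,
                   parent = parent_of[as.character(tree$nodes$id)])
  writeLines(c("# SWC written by neuroarbor",
               apply(df, 1, function(r) paste(format(r, trim = TRUE),
                                              collapse = " "))),
             path)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  df <- read.table(path, comment.char = "#",
                   col.names = c("id", "type", "x", "y", "z", "radius",
                                 "parent"))
  soma <- df$id[df$parent == -1][1]
  ed <- df[df$parent != -1, ]
  xyz <- as.matrix(df[, c("x", "y", "z")])
  rownames(xyz) <- df$id
  len <- sqrt(rowSums((xyz[as.character(ed$id), , drop = FALSE] -
                         xyz[as.character(ed$parent), , drop = FALSE])^2))
  system <- ifelse(ed$type == 4, "apical", "basal")
  edges <- data.frame(id = seq_len(nrow(ed)), parent = ed$parent,
                      child = ed$id, length = len, system = system,
                      depth = NA_integer_, branch = NA_integer_)
  apical_root <- edges$id[edges$system == "apical" &
                            edges$parent == soma][1]
  structure(list(nodes = df[, c("id", "x", "y", "z", "radius")],
                 edges = edges, soma_id = soma,
                 apical_root_edge_id = apical_root, params = NULL),
            class = "gt_tree")
}
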