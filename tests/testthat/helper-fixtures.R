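# Shared fixtures and independent oracles for the test suite.

# ---- geometric fixtures --------------------------------------------------

# rasterize tube segments directly (bypassing the tree machinery)
raster_mask <- function(segs, dim, spacing) {
  binary_mask(array(neuroarbor:::cpp_rasterize_tubes(segs, dim, spacing),
                    dim), spacing)
}

# sparse, well-separated tree parameters used for image-pipeline tests;
# inter-branch clearance >= 4 tube radii (4 x 1.2 = 4.8 um)
pipeline_tree_params <- function(seed) {
  tree_gen_params(n_basal_trunks = 3, apical_trunk_length = 18,
                  branch_probability = 0.6, mean_segment_length = 7,
                  sd_segment_length = 1.2, segments_per_branch = 2,
                  max_depth = 3, branch_angle_sd = 15, radius = 1.2,
                  z_flatten = 0.3, min_separation = 5,
                  bbox = c(-44, 44, -32, 54, -26, 26), rng_seed = seed)
}

pipeline_seg_config <- function() {
  segmentation_config(frangi_scales = c(0.8, 1.2), threshold = 0.1)
}

# ---- oracle: expected bifurcations of the branching process --------------
# Each branch tip at depth d < max_depth bifurcates with probability p.
# Independent recursion over the process, not used by the implementation.
oracle_expected_bifurcations <- function(p, max_depth, n_systems) {
  b <- function(d) if (d >= max_depth) 0 else p * (1 + 2 * b(d + 1))
  n_systems * b(1)
}

# ---- oracle: brute-force branch orders -----------------------------------
# Enumerates every root-to-leaf path explicitly and applies the recursive
# longest-path definition literally (no DP).
oracle_orders <- function(tree) {
  ce <- lapply(seq_len(max(tree$nodes$id)), function(v)
    which(tree$edges$from == v))
  all_paths <- function(eidx) {
    node <- tree$edges$to[eidx]
    kids <- ce[[node]]
    if (length(kids) == 0) {
      return(list(list(edges = eidx, len = tree$edges$length[eidx],
                       leaf = node)))
    }
    out <- list()
    for (k in kids) {
      for (p in all_paths(k)) {
        out[[length(out) + 1]] <- list(
          edges = c(eidx, p$edges),
          len = tree$edges$length[eidx] + p$len, leaf = p$leaf)
      }
    }
    out
  }
  ord <- rep(NA_integer_, nrow(tree$edges))
  label_subtree <- function(root_edge, k) {
    paths <- all_paths(root_edge)
    lens <- vapply(paths, function(p) p$len, 0)
    leaves <- vapply(paths, function(p) p$leaf, 0L)
    best <- which(lens > max(lens) - 1e-12)
    main <- paths[[best[which.min(leaves[best])]]]$edges
    ord[main] <<- k
    for (e in main) {
      node <- tree$edges$to[e]
      for (kid in ce[[node]]) {
        if (!(kid %in% main)) label_subtree(kid, k + 1L)
      }
    }
  }
  for (root in which(tree$edges$from == tree$soma)) {
    label_subtree(root, 1L)
  }
  ord
}

# random abstract neuron tree (graph only, random positive edge lengths)
random_abstract_tree <- function(n_edges, seed) {
  set.seed(seed)
  nodes <- data.frame(id = seq_len(n_edges + 1),
                      x = runif(n_edges + 1, 0, 100),
                      y = runif(n_edges + 1, 0, 100),
                      z = runif(n_edges + 1, 0, 30))
  from <- integer(n_edges)
  to <- integer(n_edges)
  for (e in seq_len(n_edges)) {
    from[e] <- sample(e, 1)       # parent among existing nodes
    to[e] <- e + 1L
  }
  polys <- lapply(seq_len(n_edges), function(e) {
    rbind(as.numeric(nodes[from[e], c("x", "y", "z")]),
          as.numeric(nodes[to[e], c("x", "y", "z")]))
  })
  g <- skeleton_graph(nodes, from, to, polys)
  attr(g, "soma_node") <- 1L
  g
}

# ---- oracle: Mann-Whitney exact p by literal enumeration -----------------
oracle_mw_exact_p <- function(a, b) {
  nA <- length(a)
  pool <- c(a, b)
  n <- length(pool)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  combos <- utils::combn(n, nA)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - nA * (nA + 1) / 2)
  mu <- nA * (n - nA) / 2
  # two-sided: labelings at least as extreme (|U - mu|) as observed
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# ---- oracle: closed-form Boltzmann integral ------------------------------
oracle_boltzmann_integral <- function(A1, A2, t50, k, lo, hi) {
  FF <- function(t) A2 * t + (A1 - A2) * (t - k * log(1 + exp((t - t50) / k)))
  FF(hi) - FF(lo)
}
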