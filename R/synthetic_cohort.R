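#' Simulate a control vs treated cohort of ground-truth trees
#'
#' Both groups draw trees from the same generator; every neuron receives a
#' lognormal whole-cell scale factor (between-neuron variability of arbor
#' size), and treated neurons additionally have their basal subtrees scaled
#' towards the soma by `1 - effect`, so the treated group's expected basal
#' length is `(1 - effect)` times the control expectation by construction.
#'
#' @param effect fractional basal-length reduction in `[0, 1)`.
#' @param n_per_group neurons per group (>= 3).
#' @param params generator parameters, see [tree_gen_params()].
#' @param lognormal_sd sd of `log` of the per-neuron scale factor.
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @return list with `control` and `treated` (lists of `gt_tree`) and the
#'   planted `effect`.
#' @export
simulate_cohort <- function(effect, n_per_group,
                            params = tree_gen_params(),
                            lognormal_sd = 0.2, rng_seed = NULL) {
  check_number(effect, "effect", 0, 1)
  if (effect >= 1) stopf("parameter_error", "`effect` must be < 1")
  check_number(n_per_group, "n_per_group", lower = 3)
  with_seed(rng_seed, {
    draw <- function(reduce_basal) {
      lapply(seq_len(n_per_group), function(i) {
        tree <- sample_tree(params)
        s <- exp(stats::rnorm(1, 0, lognormal_sd))
        tree <- scale_tree(tree, s)
        if (reduce_basal) tree <- scale_basal(tree, 1 - effect)
        tree
      })
    }
    list(control = draw(FALSE), treated = draw(TRUE), effect = effect)
  })
}

# scale the whole tree about the soma by factor f
scale_tree <- function(tree, f) {
  soma <- tree$nodes[tree$nodes$id == tree$soma_id, ]
  s <- c(soma$x, soma$y, soma$z)
  tree$nodes$x <- s[1] + (tree$nodes$x - s[1]) * f
  tree$nodes$y <- s[2] + (tree$nodes$y - s[2]) * f
  tree$nodes$z <- s[3] + (tree$nodes$z - s[3]) * f
  recompute_edge_lengths(tree)
}

# scale only basal-system nodes about the soma
scale_basal <- function(tree, f) {
  basal_nodes <- unique(tree$edges$child[tree$edges$system == "basal"])
  soma <- tree$nodes[tree$nodes$id == tree$soma_id, ]
  s <- c(soma$x, soma$y, soma$z)
  sel <- tree$nodes$id %in% basal_nodes
  tree$nodes$x[sel] <- s[1] + (tree$nodes$x[sel] - s[1]) * f
  tree$nodes$y[sel] <- s[2] + (tree$nodes$y[sel] - s[2]) * f
  tree$nodes$z[sel] <- s[3] + (tree$nodes$z[sel] - s[3]) * f
  recompute_edge_lengths(tree)
}

recompute_edge_lengths <- function(tree) {
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  rownames(xyz) <- tree$nodes$id
  d <- xyz[as.character(tree$edges$child), , drop = FALSE] -
    xyz[as.character(tree$edges$parent), , drop = FALSE]
  tree$edges$length <- sqrt(rowSums(d^2))
  tree
}
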