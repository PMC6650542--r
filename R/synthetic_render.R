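#' Parameters for rendering a tree into a voxel stack
#'
#' Emulates single-neuron confocal acquisition: tubes rasterized at the node
#' radii, optional Gaussian PSF blur, additive Gaussian noise, 8-bit
#' quantization. Rasterization works in physical um, so anisotropic spacing
#' (z coarser than xy) is handled exactly.
#'
#' @param spacing voxel spacing um (x, y, z).
#' @param shape stack shape in voxels (nx, ny, nz).
#' @param psf_sigma Gaussian PSF sigma per axis, um (0 disables blur).
#' @param background,foreground 8-bit intensity levels (DN), foreground >
#'   background.
#' @param noise_sd additive Gaussian noise sd (DN), 0 disables.
#' @param soma_frac fractional position of the soma inside the stack.
#' @param rng_seed integer seed for the noise; `NULL` uses the RNG stream.
#' @return A list of class `render_params`.
#' @export
render_params <- function(spacing = c(0.5, 0.5, 1.0),
                          shape = c(192, 192, 64),
                          psf_sigma = c(0.4, 0.4, 0.8),
                          background = 20, foreground = 200,
                          noise_sd = 10,
                          soma_frac = c(0.5, 0.35, 0.5),
                          rng_seed = NULL) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stopf("parameter_error", "`spacing` must be 3 positive numbers")
  }
  check_number(background, "background", 0, 255)
  check_number(foreground, "foreground", 0, 255)
  if (foreground <= background) {
    stopf("parameter_error", "foreground must exceed background")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(spacing = spacing, shape = as.integer(shape),
                 psf_sigma = as.numeric(psf_sigma),
                 background = background, foreground = foreground,
                 noise_sd = noise_sd, soma_frac = as.numeric(soma_frac),
                 rng_seed = rng_seed),
            class = "render_params")
}

#' Render a ground-truth tree into a noisy image stack
#'
#' The tree (soma at its origin) is translated so the soma lands at
#' `soma_frac` of the physical stack extent, rasterized as tubes of the node
#' radii, blurred by the PSF, corrupted by Gaussian noise and quantized to
#' 8 bits. The noise-free binary tube mask is returned alongside the stack.
#'
#' @param tree a `gt_tree` from [sample_tree()].
#' @param params a [render_params()] object.
#' @return A list: `stack` ([image_stack()], 8-bit), `mask` (ground-truth
#'   [binary_mask()]), `tree` (the tree in world um coordinates),
#'   `soma_xyz`, `apical_ref_xyz` (world um).
#' @export
render_stack <- function(tree, params) {
  if (!inherits(params, "render_params")) {
    stopf("parameter_error", "`params` must come from render_params()")
  }
  extent <- params$shape * params$spacing
  soma_xyz <- params$soma_frac * extent
  wtree <- translate_tree(tree, soma_xyz)
  margin <- wtree$nodes$radius + 1e-9
  bad <- wtree$nodes$x - margin < 0 | wtree$nodes$x + margin > extent[1] |
    wtree$nodes$y - margin < 0 | wtree$nodes$y + margin > extent[2] |
    wtree$nodes$z - margin < 0 | wtree$nodes$z + margin > extent[3]
  if (any(bad)) {
    stopf("geometry_error",
          "tree exceeds stack bounds at node(s) %s",
          paste(wtree$nodes$id[bad], collapse = ", "))
  }
  segs <- tree_segments(wtree)
  maskv <- cpp_rasterize_tubes(segs, params$shape, params$spacing)
  mask <- binary_mask(array(maskv, params$shape), params$spacing)

  img <- params$background +
    (params$foreground - params$background) * as.numeric(maskv)
  dim(img) <- params$shape
  if (any(params$psf_sigma > 0)) {
    img <- cpp_gaussian_blur3(img, params$shape,
                              params$psf_sigma / params$spacing)
  }
  with_seed(params$rng_seed, {
    if (params$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, params$noise_sd)
    }
  })
  img <- round(pmin(pmax(img, 0), 255))
  dim(img) <- params$shape
  apical_child <- wtree$edges$child[wtree$edges$id ==
                                      wtree$apical_root_edge_id]
  ar <- wtree$nodes[wtree$nodes$id == apical_child, ]
  list(stack = image_stack(img, params$spacing, "8bit"),
       mask = mask, tree = wtree, soma_xyz = soma_xyz,
       apical_ref_xyz = c(ar$x, ar$y, ar$z))
}

translate_tree <- function(tree, offset) {
  soma <- tree$nodes[tree$nodes$id == tree$soma_id, ]
  shift <- offset - c(soma$x, soma$y, soma$z)
  tree$nodes$x <- tree$nodes$x + shift[1]
  tree$nodes$y <- tree$nodes$y + shift[2]
  tree$nodes$z <- tree$nodes$z + shift[3]
  tree
}

# n x 7 matrix (x1,y1,z1,x2,y2,z2,r) of tube segments for rasterization
tree_segments <- function(tree) {
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  rownames(xyz) <- tree$nodes$id
  rad <- setNames(tree$nodes$radius, tree$nodes$id)
  e <- tree$edges
  cbind(xyz[as.character(e$parent), , drop = FALSE],
        xyz[as.character(e$child), , drop = FALSE],
        rad[as.character(e$child)])
}
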