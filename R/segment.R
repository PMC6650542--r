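#' Segmentation pipeline configuration
#'
#' Defaults follow the conventions of the FIJI filter family this pipeline
#' mirrors: Perona-Malik conductance threshold `kappa = 0.1` with time-step
#' factor `0.99` (the integration step is `0.99 / |neighborhood|`), and
#' Frangi vesselness with `alpha = beta = 0.5` and `c` set per scale to half
#' the maximum Hessian Frobenius norm.
#'
#' @param diffusion_kappa Perona-Malik conductance threshold (normalized
#'   intensity units).
#' @param diffusion_step time-step factor in `(0, 1]`; values above 1 are
#'   unstable for the explicit scheme and rejected.
#' @param diffusion_iters diffusion iterations (>= 1).
#' @param frangi_scales vesselness scales, um (Gaussian sigma; the response
#'   of a tube peaks at the scale nearest its radius).
#' @param frangi_alpha,frangi_beta plate/blob discrimination parameters.
#' @param frangi_c structureness parameter; `NULL` = half the maximum
#'   Hessian norm at each scale.
#' @param threshold binarization threshold in `(0, 1)` applied to the
#'   vesselness map; see [suggest_threshold()] for an Otsu suggestion.
#' @param min_component_size components below this voxel count are treated
#'   as speckle by [validate_object()].
#' @param slicewise apply the diffusion slice-by-slice (2D, 4-neighborhood)
#'   instead of volumetrically.
#' @export
segmentation_config <- function(diffusion_kappa = 0.1,
                                diffusion_step = 0.99,
                                diffusion_iters = 10,
                                frangi_scales = c(1, 2, 4),
                                frangi_alpha = 0.5, frangi_beta = 0.5,
                                frangi_c = NULL,
                                threshold = 0.1,
                                min_component_size = 100,
                                slicewise = FALSE) {
  check_number(diffusion_kappa, "diffusion_kappa", lower = 0,
               strict_lower = TRUE)
  check_number(diffusion_step, "diffusion_step", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(diffusion_iters, "diffusion_iters", lower = 1)
  if (any(frangi_scales <= 0)) {
    stopf("parameter_error", "frangi_scales must be > 0")
  }
  check_number(threshold, "threshold", 0, 1, strict_lower = TRUE)
  if (threshold >= 1) stopf("parameter_error", "threshold must be < 1")
  structure(list(diffusion_kappa = diffusion_kappa,
                 diffusion_step = diffusion_step,
                 diffusion_iters = as.integer(diffusion_iters),
                 frangi_scales = frangi_scales,
                 frangi_alpha = frangi_alpha, frangi_beta = frangi_beta,
                 frangi_c = frangi_c, threshold = threshold,
                 min_component_size = as.integer(min_component_size),
                 slicewise = slicewise),
            class = "segmentation_config")
}

#' Normalize a stack using its full histogram
#'
#' Linear map of the full-stack `[min, max]` onto `[0, 1]`, the
#' variability-reduction step applied before filtering.
#'
#' @param stack an [image_stack()].
#' @return A normalized [image_stack()]. Errors on constant stacks.
#' @export
normalize_stack <- function(stack) {
  rng <- range(stack$data)
  if (diff(rng) == 0) {
    stopf("degenerate_input", "constant stack cannot be normalized")
  }
  image_stack((stack$data - rng[1]) / diff(rng), stack$spacing, "normalized")
}

#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving smoothing: explicit diffusion with exponential
#' conductance `exp(-(grad/kappa)^2)` on the 6-neighborhood (4-neighborhood
#' per slice when `slicewise`), integration step
#' `diffusion_step / |neighborhood|`, zero-flux boundaries. Total intensity
#' is conserved and values stay within the input range.
#'
#' @param stack a normalized [image_stack()].
#' @param config a [segmentation_config()].
#' @return The diffused [image_stack()].
#' @export
anisotropic_diffusion <- function(stack, config = segmentation_config()) {
  if (stack$domain != "normalized") {
    stopf("parameter_error", "diffusion expects a normalized stack")
  }
  d <- dim(stack$data)
  if (config$slicewise) {
    lam <- config$diffusion_step / 4
    out <- stack$data
    for (k in seq_len(d[3])) {
      sl <- cpp_perona_malik3(out[, , k, drop = FALSE], c(d[1], d[2], 1L),
                              config$diffusion_kappa, lam,
                              config$diffusion_iters)
      out[, , k] <- sl
    }
  } else {
    lam <- config$diffusion_step / 6
    out <- cpp_perona_malik3(stack$data, d, config$diffusion_kappa, lam,
                             config$diffusion_iters)
  }
  dim(out) <- d
  image_stack(out, stack$spacing, "normalized")
}

#' Multiscale Frangi vesselness filter
#'
#' Hessian eigenvalue tubularity measure for bright tubes, maximum over the
#' configured scales. Derivatives are taken in physical um (Gaussian sigma
#' converted per axis by the voxel spacing), so anisotropic stacks are
#' handled correctly; second derivatives carry the scale-normalization
#' factor `sigma^2`.
#'
#' @param stack a (smoothed) normalized [image_stack()].
#' @param config a [segmentation_config()].
#' @return An [image_stack()] of vesselness values in `[0, 1]`.
#' @export
frangi_vesselness <- function(stack, config = segmentation_config()) {
  d <- dim(stack$data)
  if (any(d < 3)) {
    stopf("geometry_error", "need >= 3 voxels per axis for 3D filtering")
  }
  sp <- stack$spacing
  pairs <- list(c(0, 0), c(1, 1), c(2, 2), c(0, 1), c(0, 2), c(1, 2))
  hess <- vector("list", length(config$frangi_scales))
  maxnorm <- 0
  for (si in seq_along(config$frangi_scales)) {
    sg <- config$frangi_scales[si]
    sm <- cpp_gaussian_blur3(stack$data, d, sg / sp)
    h <- lapply(pairs, function(p) cpp_deriv2(sm, d, p[1], p[2], sp) * sg^2)
    frob2 <- h[[1]]^2 + h[[2]]^2 + h[[3]]^2 +
      2 * (h[[4]]^2 + h[[5]]^2 + h[[6]]^2)
    maxnorm <- max(maxnorm, max(frob2))
    hess[[si]] <- h
  }
  # c is shared across scales (half the maximum Hessian norm over the
  # whole scale space); a per-scale c would cancel the gamma = 2
  # normalization and spoil scale selection
  cval <- config$frangi_c %||% (0.5 * sqrt(maxnorm))
  if (cval == 0) cval <- 1  # uniform stack: response is zero anyway
  best <- numeric(prod(d))
  for (si in seq_along(hess)) {
    h <- hess[[si]]
    v <- cpp_vesselness(h[[1]], h[[2]], h[[3]], h[[4]], h[[5]], h[[6]],
                        config$frangi_alpha, config$frangi_beta, cval)
    best <- pmax(best, v)
  }
  dim(best) <- d
  image_stack(best, sp, "normalized")
}

#' Threshold a stack into a binary mask
#'
#' @param stack an [image_stack()] with values in `[0, 1]`.
#' @param threshold scalar threshold; voxels `>= threshold` become
#'   foreground.
#' @return A [binary_mask()]. Foreground voxel count is non-increasing in
#'   the threshold.
#' @export
binarize <- function(stack, threshold) {
  binary_mask(stack$data >= threshold, stack$spacing)
}

#' Otsu threshold suggestion for a vesselness map
#'
#' Computed on the 256-bin histogram of the nonzero voxels (the vesselness
#' background is exactly zero and would otherwise dominate).
#'
#' @param stack an [image_stack()] in `[0, 1]`.
#' @return Suggested scalar threshold.
#' @export
suggest_threshold <- function(stack) {
  v <- stack$data[stack$data > 0]
  if (length(v) == 0) return(0.5)
  h <- tabulate(pmin(pmax(ceiling(v * 256), 1), 256), nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 0.5) / 256)
  mu_t <- mu[256]
  between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- 0
  which.max(between) / 256
}

#' Validate that a mask contains a single well-separated 3D object
#'
#' Reports the 26-connected components, discards speckle below
#' `min_size`, checks that retained components keep at least a 1-voxel
#' background gap even under 1-voxel dilation, and (optionally) flags
#' single-voxel bridges inside a retained component (two neurons touching
#' at one voxel would be merged by 26-connectivity but remain joined only
#' through an articulation voxel).
#'
#' @param mask a [binary_mask()] (non-empty).
#' @param min_size minimum retained component size, voxels.
#' @param check_contact run the articulation-voxel contact check (can be
#'   slow on very large objects).
#' @return A list of class `validation_report`: `n_components`,
#'   `component_sizes`, `n_retained`, `separation_ok`,
#'   `potential_contact`, `passed`.
#' @export
validate_object <- function(mask, min_size = 100, check_contact = TRUE) {
  if (!any(mask$data)) {
    stopf("degenerate_input", "empty mask")
  }
  d <- dim(mask$data)
  lab <- cpp_label3(mask$data, d, 26L)
  sizes <- tabulate(lab[lab > 0])
  retained <- which(sizes >= min_size)
  separation_ok <- TRUE
  if (length(retained) >= 2) {
    # distance between retained components; adjacency under 1-voxel
    # dilation means a gap of only one background voxel
    for (a in seq_along(retained)) {
      for (b in seq_along(retained)) {
        if (b <= a) next
        fa <- array(lab == retained[a], d)
        dtb <- cpp_edt3(fa, d, c(1, 1, 1))
        gap <- min(dtb[lab == retained[b]])
        if (gap <= 2) separation_ok <- FALSE
      }
    }
  }
  potential_contact <- FALSE
  if (check_contact && length(retained) >= 1) {
    for (cc in retained) {
      if (component_has_bridge(lab, cc, d, part_min = 27L)) {
        potential_contact <- TRUE
        break
      }
    }
  }
  structure(list(n_components = length(sizes),
                 component_sizes = sort(sizes, decreasing = TRUE),
                 n_retained = length(retained),
                 separation_ok = separation_ok,
                 potential_contact = potential_contact,
                 passed = length(retained) == 1 && separation_ok),
            class = "validation_report")
}

# TRUE if the component contains an articulation voxel whose removal splits
# it into >= 2 parts of at least `part_min` voxels each
component_has_bridge <- function(lab, cc, d, part_min = 27L) {
  sub <- array(lab == cc, d)
  pairs <- cpp_adjacency_pairs(sub, d, 26L)
  if (nrow(pairs) == 0) return(FALSE)
  ids <- sort(unique(c(pairs[, 1], pairs[, 2])))
  g <- igraph::graph_from_edgelist(
    cbind(match(pairs[, 1], ids), match(pairs[, 2], ids)),
    directed = FALSE)
  arts <- igraph::articulation_points(g)
  if (length(arts) == 0) return(FALSE)
  for (a in head(as.integer(arts), 50)) {
    vox <- ids[a]
    sub2 <- sub
    sub2[vox] <- FALSE
    lab2 <- cpp_label3(sub2, d, 26L)
    parts <- tabulate(lab2[lab2 > 0])
    if (sum(parts >= part_min) >= 2) return(TRUE)
  }
  FALSE
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d component(s), %d retained; separation %s; %s\n",
    x$n_components, x$n_retained,
    if (x$separation_ok) "ok" else "VIOLATED",
    if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Drop connected components below a size threshold
#' @param mask a [binary_mask()].
#' @param min_size minimum component size (voxels); `keep_largest` retains
#'   only the single largest component.
#' @param keep_largest logical.
#' @return The cleaned [binary_mask()].
#' @export
clean_mask <- function(mask, min_size = 100, keep_largest = FALSE) {
  d <- dim(mask$data)
  lab <- cpp_label3(mask$data, d, 26L)
  sizes <- tabulate(lab[lab > 0])
  keep <- if (keep_largest) which.max(sizes) else which(sizes >= min_size)
  binary_mask(array(lab %in% keep, d), mask$spacing)
}

#' Full segmentation chain: normalize, diffuse, vesselness, threshold
#'
#' @param stack a raw 8-bit [image_stack()].
#' @param config a [segmentation_config()].
#' @param threshold optional override of `config$threshold`; `"otsu"`
#'   computes [suggest_threshold()] on the vesselness map.
#' @return A list: `mask` ([binary_mask()]), `vesselness`, `threshold`.
#' @export
segment_stack <- function(stack, config = segmentation_config(),
                          threshold = NULL) {
  nrm <- normalize_stack(stack)
  sm <- anisotropic_diffusion(nrm, config)
  ves <- frangi_vesselness(sm, config)
  thr <- threshold %||% config$threshold
  if (identical(thr, "otsu")) thr <- suggest_threshold(ves)
  list(mask = binarize(ves, thr), vesselness = ves, threshold = thr)
}
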