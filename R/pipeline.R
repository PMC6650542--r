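#' Reconstruct a neuron from an image stack and measure its morphometry
#'
#' The full analysis chain: normalization, anisotropic diffusion, Frangi
#' vesselness, thresholding, object validation (largest component),
#' topological thinning to a raw skeleton graph, junction consolidation,
#' spur pruning, soma-cluster merging, two-term reduction, orientation at
#' the soma, apical labeling and branch-order morphometry. The soma and
#' apical reference positions mirror the manual designations of the
#' original workflow and are taken as physical coordinates.
#'
#' @param stack a raw 8-bit [image_stack()].
#' @param soma_xyz soma position, um.
#' @param apical_xyz a point on the apical trunk, um.
#' @param seg_config a [segmentation_config()].
#' @param red_config a [reduction_config()].
#' @param soma_radius soma-cluster merge radius, um.
#' @param min_spur spur-pruning length, um.
#' @param junction_merge junction-consolidation radius, um.
#' @param check_contact forward to [validate_object()].
#' @return list: `morphometry` (a `morphometry_record`), `tree`
#'   (`neuron_tree`), `skeleton` (reduced), `mask`, `validation`,
#'   `threshold`.
#' @export
reconstruct_neuron <- function(stack, soma_xyz, apical_xyz,
                               seg_config = segmentation_config(),
                               red_config = reduction_config(),
                               soma_radius = 3, min_spur = 3,
                               junction_merge = 2, check_contact = FALSE) {
  seg <- segment_stack(stack, seg_config)
  report <- validate_object(seg$mask, seg_config$min_component_size,
                            check_contact = check_contact)
  mask <- clean_mask(seg$mask, seg_config$min_component_size,
                     keep_largest = TRUE)
  raw <- extract_initial_skeleton(mask)
  g <- merge_junction_clusters(raw, junction_merge)
  g <- prune_spurs(g, min_spur)
  g <- merge_soma_cluster(g, soma_xyz, soma_radius)
  red <- reduce_skeleton(g, mask, red_config)
  nt <- orient_tree(red, attr(g, "soma_node"))
  nt <- label_apical(nt, apical_xyz = apical_xyz)
  nt <- assign_orders(nt)
  list(morphometry = measure(nt), tree = nt, skeleton = red, mask = mask,
       validation = report, threshold = seg$threshold)
}
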