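test_that("unbranched single-segment tree has exactly one apical and one basal edge", {
  p <- tree_gen_params(n_basal_trunks = 1, apical_trunk_length = 25,
                       branch_probability = 0, mean_segment_length = 100,
                       sd_segment_length = 0, segments_per_branch = 1,
                       max_depth = 3, rng_seed = 1)
  tree <- sample_tree(p)
  expect_equal(nrow(tree$edges), 2)
  expect_setequal(tree$edges$system, c("apical", "basal"))
  expect_equal(total_tree_length(tree), 100 + 25, tolerance = 1e-9)
  expect_equal(tree_system_length(tree, "apical"), 25, tolerance = 1e-9)
})

test_that("tree generation is a pure function of its seed", {
  p <- tree_gen_params(rng_seed = 77)
  t1 <- sample_tree(p)
  t2 <- sample_tree(p)
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$edges, t2$edges)
  t3 <- sample_tree(tree_gen_params(rng_seed = 78))
  expect_false(identical(t1$nodes, t3$nodes))
})

test_that("tree invariants hold: connected, acyclic, positive lengths/radii", {
  for (s in 1:5) {
    tree <- sample_tree(tree_gen_params(rng_seed = s))
    expect_true(all(tree$edges$length > 0))
    expect_true(all(tree$nodes$radius > 0))
    # rooted tree: every non-soma node has exactly one parent
    expect_equal(nrow(tree$edges), nrow(tree$nodes) - 1)
    expect_equal(sort(tree$edges$child),
                 sort(setdiff(tree$nodes$id, tree$soma_id)))
    # exactly one soma-emanating apical root edge
    ar <- tree$edges[tree$edges$id == tree$apical_root_edge_id, ]
    expect_equal(ar$parent, tree$soma_id)
    expect_equal(ar$system, "apical")
  }
})

test_that("mean bifurcation count matches the branching-process expectation", {
  p <- tree_gen_params(n_basal_trunks = 2, branch_probability = 0.5,
                       max_depth = 4, segments_per_branch = 1,
                       mean_segment_length = 5, sd_segment_length = 1)
  set.seed(123)
  counts <- vapply(seq_len(1000), function(i) count_bifurcations(sample_tree(p)),
                   0)
  expected <- oracle_expected_bifurcations(0.5, 4, n_systems = 3)
  # binomial-ish spread: compare at ~4 standard errors
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se + 1e-9)
})

test_that("invalid generator parameters are rejected", {
  expect_error(tree_gen_params(branch_probability = 1.5), class = "parameter_error")
  expect_error(tree_gen_params(mean_segment_length = -1), class = "parameter_error")
  expect_error(tree_gen_params(max_depth = 0), class = "parameter_error")
  expect_error(sample_tree(list()), class = "parameter_error")
})

test_that("SWC round-trip preserves topology, lengths and systems", {
  tree <- sample_tree(tree_gen_params(rng_seed = 3))
  path <- tempfile(fileext = ".swc")
  write_swc(tree, path)
  back <- read_swc(path)
  expect_equal(total_tree_length(back), total_tree_length(tree),
               tolerance = 1e-4)
  expect_equal(tree_system_length(back, "apical"),
               tree_system_length(tree, "apical"), tolerance = 1e-4)
  expect_equal(nrow(back$edges), nrow(tree$edges))
  unlink(path)
})

test_that("noise-free unblurred render equals the analytic cylinder rasterization", {
  p <- tree_gen_params(n_basal_trunks = 1, apical_trunk_length = 15,
                       branch_probability = 0, mean_segment_length = 14,
                       sd_segment_length = 0, segments_per_branch = 1,
                       branch_angle_sd = 0, radius = 1.5,
                       bbox = c(-16, 16, -14, 22, -8, 8), rng_seed = 1)
  tree <- sample_tree(p)
  rp <- render_params(spacing = c(0.5, 0.5, 1), shape = c(96, 96, 32),
                      psf_sigma = c(0, 0, 0), noise_sd = 0)
  r <- render_stack(tree, rp)
  # independent oracle: point-to-segment distance over the whole grid
  segs <- neuroarbor:::tree_segments(r$tree)
  idx <- which(array(TRUE, rp$shape), arr.ind = TRUE)
  pts <- cbind((idx[, 1] - 0.5) * 0.5, (idx[, 2] - 0.5) * 0.5,
               (idx[, 3] - 0.5) * 1)
  inside <- rep(FALSE, nrow(pts))
  for (s in seq_len(nrow(segs))) {
    dd <- neuroarbor:::cpp_min_dist_to_polyline(
      pts, rbind(segs[s, 1:3], segs[s, 4:6]))
    inside <- inside | (dd <= segs[s, 7])
  }
  expect_identical(as.vector(r$mask$data), inside)
  # two-level histogram without blur and noise
  expect_setequal(unique(as.vector(r$stack$data)), c(20, 200))
})

test_that("render noise changes the stack but never the ground-truth mask", {
  tree <- sample_tree(pipeline_tree_params(5))
  r1 <- render_stack(tree, render_params(noise_sd = 10, rng_seed = 1))
  r2 <- render_stack(tree, render_params(noise_sd = 10, rng_seed = 2))
  expect_identical(r1$mask$data, r2$mask$data)
  expect_false(identical(r1$stack$data, r2$stack$data))
  # mask/stack consistency: pre-noise foreground >= background everywhere
  r0 <- render_stack(tree, render_params(noise_sd = 0))
  expect_true(all(r0$stack$data[r0$mask$data] >= 20))
})

test_that("trees exceeding the stack bounds raise a geometry error naming nodes", {
  p <- tree_gen_params(n_basal_trunks = 1, apical_trunk_length = 500,
                       branch_probability = 0, mean_segment_length = 10,
                       sd_segment_length = 0, segments_per_branch = 1,
                       rng_seed = 1)
  tree <- sample_tree(p)
  expect_error(render_stack(tree, render_params()), class = "geometry_error")
})

test_that("simulated fEPSP components follow the pharmacology", {
  # AMPA-only trace under CNQX is identically zero (noise-free)
  p <- fepsp_sim_params(
    amplitude_mV = c(AMPA = -0.5, GluN2B = 0, GluN2A = 0),
    condition = "CNQX", noise_sd_mV = 0)
  w <- simulate_fepsp(p)
  expect_true(all(w$voltage_mV == 0))
  # condition AUC ordering for all-negative amplitudes
  aucs <- vapply(c("aCSF", "CNQX", "CNQX+ifenprodil"), function(cc) {
    wc <- simulate_fepsp(fepsp_sim_params(condition = cc, noise_sd_mV = 0))
    auc_trapezoid(wc, 7, 37)
  }, 0)
  expect_true(aucs[1] >= aucs[2] && aucs[2] >= aucs[3])
})

test_that("single-component peak matches the closed-form extremum", {
  p <- fepsp_sim_params(noise_sd_mV = 0, sampling_khz = 100)
  w <- simulate_fepsp(p, components = "GluN2A")
  tstar <- fepsp_component_peak_time(3, 50)
  t_num <- w$time_ms[which.min(w$voltage_mV)] - 7  # onset = 5 + 2 ms
  expect_equal(t_num, tstar, tolerance = 1e-2)
  expect_equal(min(w$voltage_mV), -0.25, tolerance = 1e-6)
})

test_that("waveform equals the sum of its single-component simulations", {
  p <- fepsp_sim_params(noise_sd_mV = 0)
  w <- simulate_fepsp(p)
  parts <- lapply(c("AMPA", "GluN2B", "GluN2A"), function(nm)
    simulate_fepsp(p, components = nm)$voltage_mV)
  expect_equal(w$voltage_mV, parts[[1]] + parts[[2]] + parts[[3]],
               tolerance = 1e-12)
})

test_that("fepsp parameter validation enforces kinetics and duration", {
  expect_error(fepsp_sim_params(tau_rise_ms = c(AMPA = 10, GluN2B = 7, GluN2A = 3)),
               class = "parameter_error")  # decay !> rise for AMPA
  expect_error(fepsp_sim_params(duration_ms = 20), class = "parameter_error")
  expect_error(fepsp_sim_params(amplitude_mV = c(AMPA = 0.5, GluN2B = -0.1,
                                                 GluN2A = -0.1)),
               class = "parameter_error")
})

test_that("waveform CSV + JSON sidecar round-trips", {
  w <- simulate_fepsp(fepsp_sim_params(noise_sd_mV = 0.02, rng_seed = 4,
                                       slice_id = "s1", animal_id = "a1"))
  path <- tempfile(fileext = ".csv")
  write_waveform(w, path)
  back <- read_waveform(path)
  expect_equal(back$voltage_mV, w$voltage_mV, tolerance = 1e-9)
  expect_identical(attr(back, "condition"), attr(w, "condition"))
  expect_identical(attr(back, "slice_id"), "s1")
  unlink(c(path, paste0(path, ".json")))
})

test_that("cohort construction plants the requested basal reduction", {
  co <- simulate_cohort(0.35, 6, rng_seed = 9)
  expect_length(co$control, 6)
  expect_length(co$treated, 6)
  # effect = 0: both groups from the same distribution (same seeds differ,
  # but expected values match; check a large-sample ratio)
  co0 <- simulate_cohort(0, 40, lognormal_sd = 0, rng_seed = 10)
  b0c <- mean(vapply(co0$control, tree_system_length, 0, "basal"))
  b0t <- mean(vapply(co0$treated, tree_system_length, 0, "basal"))
  expect_equal(b0t / b0c, 1, tolerance = 0.15)
  # effect = 0.35 with variability switched off: exact ratio per neuron pair
  co35 <- simulate_cohort(0.35, 30, lognormal_sd = 0, rng_seed = 11)
  bc <- mean(vapply(co35$control, tree_system_length, 0, "basal"))
  bt <- mean(vapply(co35$treated, tree_system_length, 0, "basal"))
  expect_equal(bt / bc, 0.65, tolerance = 0.1)
  # apical untouched by the basal scaling
  ac <- vapply(co35$treated, tree_system_length, 0, "apical")
  expect_true(all(ac > 0))
  expect_error(simulate_cohort(1.2, 8), class = "parameter_error")
  expect_error(simulate_cohort(0.2, 2), class = "parameter_error")
})
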