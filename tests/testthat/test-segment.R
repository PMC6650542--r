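make_stack <- function(arr, spacing = c(1, 1, 1), domain = "8bit") {
  image_stack(arr, spacing, domain)
}

test_that("normalization maps the full histogram onto [0, 1]", {
  a <- array(10, c(3, 3, 3))
  a[1, 1, 1] <- 130
  a[2, 1, 1] <- 250
  n <- normalize_stack(make_stack(a))
  expect_equal(n$data[1, 1, 1], 0.5)
  expect_equal(n$data[2, 1, 1], 1)
  expect_equal(min(n$data), 0)
  # idempotent on an already normalized stack
  n2 <- normalize_stack(n)
  expect_equal(n2$data, n$data, tolerance = 1e-12)
  expect_error(normalize_stack(make_stack(array(7, c(3, 3, 3)))),
               class = "degenerate_input")
})

test_that("diffusion leaves uniform stacks unchanged and conserves intensity", {
  u <- image_stack(array(0.4, c(8, 8, 8)), c(1, 1, 1), "normalized")
  d <- anisotropic_diffusion(u)
  expect_equal(d$data, u$data, tolerance = 1e-12)
  set.seed(1)
  r <- image_stack(array(runif(8^3), c(8, 8, 8)), c(1, 1, 1), "normalized")
  dr <- anisotropic_diffusion(r, segmentation_config(diffusion_iters = 25))
  expect_equal(sum(dr$data), sum(r$data), tolerance = 1e-6)
  expect_true(all(dr$data >= min(r$data) - 1e-12 &
                    dr$data <= max(r$data) + 1e-12))
  expect_error(segmentation_config(diffusion_step = 1.5),
               class = "parameter_error")
})

test_that("diffusion matches an independent finite-difference oracle and preserves edges", {
  # step edge of height 0.8 >> kappa
  a <- array(0.1, c(16, 16, 5))
  a[9:16, , ] <- 0.9
  st <- image_stack(a, c(1, 1, 1), "normalized")
  cfg <- segmentation_config(diffusion_iters = 5)
  got <- anisotropic_diffusion(st, cfg)

  # oracle: plain R re-implementation of the explicit scheme
  lam <- 0.99 / 6
  x <- a
  # clamped shift duplicates the border plane, so the border gradient is
  # zero: the zero-flux boundary comes for free
  shift <- function(m, d, ax) {
    idx <- lapply(dim(m), seq_len)
    idx[[ax]] <- pmin(pmax(seq_len(dim(m)[ax]) + d, 1), dim(m)[ax])
    do.call(`[`, c(list(m), idx))
  }
  for (it in 1:5) {
    flux <- array(0, dim(x))
    for (ax in 1:3) {
      for (d in c(-1, 1)) {
        g <- shift(x, d, ax) - x
        flux <- flux + exp(-(g / 0.1)^2) * g
      }
    }
    x <- x + lam * flux
  }
  expect_equal(got$data, x, tolerance = 1e-10)

  # edge preservation: mid-edge gradient stays far above a Gaussian blur
  # matched to the same within-region variance (flat regions stay flat, so
  # compare the edge jump directly)
  jump_pm <- mean(got$data[9, , ]) - mean(got$data[8, , ])
  gs <- cpp_gaussian_blur3(a, dim(a), c(1, 1, 0))
  jump_gauss <- mean(gs[9 + 16 * (seq_len(16) - 1)]) -
    mean(gs[8 + 16 * (seq_len(16) - 1)])
  expect_gt(jump_pm, 0.5)
  expect_gt(jump_pm, jump_gauss)
})

test_that("vesselness is zero on uniform stacks and selects the matching scale", {
  u <- image_stack(array(0.5, c(8, 8, 8)), c(1, 1, 1), "normalized")
  expect_true(all(frangi_vesselness(u)$data == 0))

  sp <- c(0.5, 0.5, 0.5)
  d <- c(64, 64, 64)
  cyl <- raster_mask(matrix(c(4, 16, 16, 28, 16, 16, 2), nrow = 1), d, sp)
  img <- image_stack(cyl$data * 1.0, sp, "normalized")
  # fixed common c so per-scale responses are comparable
  resp <- vapply(c(1, 2, 4), function(sg)
    frangi_vesselness(img, segmentation_config(frangi_scales = sg,
                                               frangi_c = 1))$data[32, 32, 32],
    0)
  expect_equal(c(1, 2, 4)[which.max(resp)], 2)  # radius-2 tube
  expect_true(all(resp >= 0 & resp <= 1))
  expect_error(frangi_vesselness(image_stack(array(0.1, c(2, 5, 5)),
                                             c(1, 1, 1), "normalized")),
               class = "geometry_error")
})

test_that("vesselness at a tube axis exceeds an equal-radius sphere center", {
  sp <- c(0.5, 0.5, 0.5)
  d <- c(64, 64, 64)
  cyl <- raster_mask(matrix(c(4, 16, 16, 28, 16, 16, 2), nrow = 1), d, sp)
  sph <- raster_mask(matrix(c(16, 16, 16, 16, 16, 16, 2), nrow = 1), d, sp)
  cfg <- segmentation_config(frangi_scales = 2, frangi_c = 1)
  vc <- frangi_vesselness(image_stack(cyl$data * 1.0, sp, "normalized"), cfg)
  vs <- frangi_vesselness(image_stack(sph$data * 1.0, sp, "normalized"), cfg)
  expect_gt(vc$data[32, 32, 32], vs$data[32, 32, 32])

  # independent oracle at the axis voxel: smoothed Hessian eigenvalues via
  # base R numeric differentiation of a separately blurred volume
  sg <- 2
  sm <- cpp_gaussian_blur3(cyl$data * 1.0, d, rep(sg / 0.5, 3))
  dim(sm) <- d
  h <- matrix(0, 3, 3)
  ctr <- c(32, 32, 32)
  for (i in 1:3) for (j in 1:3) {
    ei <- ej <- c(0, 0, 0)
    ei[i] <- 1; ej[j] <- 1
    pp <- sm[t(ctr + ei + ej)]; pm <- sm[t(ctr + ei - ej)]
    mp <- sm[t(ctr - ei + ej)]; mm <- sm[t(ctr - ei - ej)]
    h[i, j] <- if (i == j) {
      (sm[t(ctr + ei)] - 2 * sm[t(ctr)] + sm[t(ctr - ei)]) / 0.25
    } else (pp - pm - mp + mm) / (4 * 0.25)
  }
  ev <- sort(eigen(h * sg^2, symmetric = TRUE)$values)
  ev <- ev[order(abs(ev))]
  expect_true(ev[2] < 0 && ev[3] < 0)  # bright tube signature
  Ra <- abs(ev[2]) / abs(ev[3])
  Rb <- abs(ev[1]) / sqrt(abs(ev[2] * ev[3]))
  S <- sqrt(sum(ev^2))
  vor <- (1 - exp(-Ra^2 / 0.5)) * exp(-Rb^2 / 0.5) * (1 - exp(-S^2 / 2))
  expect_equal(vc$data[32, 32, 32], vor, tolerance = 1e-6)
})

test_that("binarization is a simple threshold, monotone in the threshold", {
  a <- array(0.4, c(3, 3, 3))
  a[1, 1, 1] <- 0.6
  st <- image_stack(a, c(1, 1, 1), "normalized")
  m <- binarize(st, 0.5)
  expect_true(m$data[1, 1, 1])
  expect_equal(sum(m$data), 1)
  expect_equal(sum(binarize(st, 0)$data), 27)
  counts <- vapply(c(0, 0.3, 0.5, 0.7, 1), function(th)
    sum(binarize(st, th)$data), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("object validation counts components, checks separation, flags bridges", {
  d <- c(48, 48, 16)
  sp <- c(1, 1, 1)
  t1 <- c(4, 10, 8, 20, 10, 8, 1.4)
  t2 <- c(28, 10, 8, 44, 10, 8, 1.4)
  m2 <- raster_mask(rbind(t1, t2), d, sp)
  v <- validate_object(m2, min_size = 10)
  expect_equal(v$n_components, 2)
  expect_true(v$separation_ok)   # > 3 voxels apart
  expect_false(v$passed)         # two retained objects
  expect_false(v$potential_contact)

  # bridge the two tubes through a single-voxel-wide line: one 26-component
  # flagged as potential contact
  mb <- m2$data
  for (x in 21:27) mb[x, 10, 8] <- TRUE
  vb <- validate_object(binary_mask(mb, sp), min_size = 10)
  expect_equal(vb$n_components, 1)
  expect_true(vb$potential_contact)
  expect_true(vb$passed)

  # a clean single tube passes without contact flag
  v1 <- validate_object(raster_mask(matrix(t1, nrow = 1), d, sp),
                        min_size = 10)
  expect_true(v1$passed)
  expect_false(v1$potential_contact)
  expect_error(validate_object(binary_mask(array(FALSE, d), sp)),
               class = "degenerate_input")
})

test_that("rendered single-neuron mask validates as one component", {
  tree <- sample_tree(pipeline_tree_params(21))
  r <- render_stack(tree, render_params(noise_sd = 0))
  v <- validate_object(r$mask, min_size = 100)
  expect_true(v$passed)
  expect_equal(v$n_retained, 1)
})

test_that("segmentation chain is deterministic and shape/spacing preserving", {
  tree <- sample_tree(pipeline_tree_params(22))
  r <- render_stack(tree, render_params(noise_sd = 15, rng_seed = 1))
  s1 <- segment_stack(r$stack, pipeline_seg_config())
  s2 <- segment_stack(r$stack, pipeline_seg_config())
  expect_identical(s1$mask$data, s2$mask$data)
  expect_identical(dim(s1$mask$data), dim(r$stack$data))
  expect_identical(s1$mask$spacing, r$stack$spacing)
})
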