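test_that("straight unbranched processes give exactly the requested edges", {
  sp <- synthetic_spec(domain_size = c(60, 60, 60),
                       lacuna_centers = matrix(c(30, 30, 30), 1),
                       processes_per_lacuna = 3, branch_rate = 0,
                       segment_length_mean = 10, segment_length_sd = 0,
                       tortuosity = 0, min_separation = 0, seed = 7)
  gt <- generate_network(sp)
  net <- gt$network
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$edges$arc_length, rep(10, 3), tolerance = 1e-9)
  lac <- net$nodes[net$nodes$kind == "lacunar", ]
  expect_equal(nrow(lac), 1)
  expect_equal(lac$degree, 3L)
  expect_equal(gt$total_length, 30, tolerance = 1e-9)
})

test_that("density targeting reaches the requested density within 5%", {
  sp <- synthetic_spec(domain_size = c(50, 50, 50), target_density = 0.2,
                       seed = 3)
  gt <- suppressWarnings(generate_network(sp))
  expect_lt(abs(gt$total_length - 25000) / 25000, 0.05)
  # total_length is the sum of edge arc lengths
  expect_equal(gt$total_length, sum(gt$network$edges$arc_length))
})

test_that("generation is reproducible for a fixed seed", {
  sp <- synthetic_spec(domain_size = c(20, 20, 10), lacuna_count = 3,
                       target_density = 0.1, seed = 42)
  g1 <- suppressWarnings(generate_network(sp))
  g2 <- suppressWarnings(generate_network(sp))
  expect_identical(g1$network$nodes, g2$network$nodes)
  expect_identical(g1$network$edges, g2$network$edges)
  expect_identical(g1$network$geometry, g2$network$geometry)
})

test_that("generated geometry stays in the domain and arc >= chord", {
  gt <- small_truth()
  dom <- gt$spec$domain_size
  for (p in gt$network$geometry) {
    expect_true(all(p >= 0) && all(sweep(p, 2, dom, `<=`)))
  }
  chord <- vapply(gt$network$geometry,
                  function(p) sqrt(sum((p[1, ] - p[nrow(p), ])^2)), numeric(1))
  expect_true(all(gt$network$edges$arc_length >= chord - 1e-9))
  # every junction in the truth has exactly three incident edges
  jd <- gt$network$nodes$degree[gt$network$nodes$kind == "junction"]
  expect_true(all(jd == 3))
})

test_that("degenerate generator inputs are rejected", {
  expect_error(generate_network(
    synthetic_spec(lacuna_count = 0, processes_per_lacuna = 0)),
    "empty network")
  expect_error(synthetic_spec(target_density = -1), "target_density")
  expect_error(synthetic_spec(domain_size = c(10, 10)), "domain_size")
})

test_that("rendering an empty network gives a flat background", {
  gt <- tube_truth()
  gt$network <- lcnet:::empty_network(domain = gt$spec$domain_size)
  rend <- render_volume(gt, noise_free(voxel_size = c(0.25, 0.25, 0.25)))
  expect_equal(max(rend$volume$voxels), min(rend$volume$voxels))
  expect_false(any(rend$truth_foreground))
})

test_that("rendered tube mask matches the analytic capsule membership", {
  gt <- tube_truth(radius = 0.5)
  vs <- c(0.25, 0.25, 0.25)
  rend <- render_volume(gt, noise_free(voxel_size = vs))
  dims <- dim(rend$truth_foreground)
  ax <- attr(gt, "axis")
  xc <- (seq_len(dims[1]) - 0.5) * vs[1]
  yc <- (seq_len(dims[2]) - 0.5) * vs[2]
  zc <- (seq_len(dims[3]) - 0.5) * vs[3]
  grid <- expand.grid(x = xc, y = yc, z = zc)
  tx <- pmin(pmax(grid$x, ax[1, 1]), ax[2, 1])  # axis is along x
  d2 <- (grid$x - tx)^2 + (grid$y - ax[1, 2])^2 + (grid$z - ax[1, 3])^2
  analytic <- array(d2 <= 0.5^2, dims)
  expect_identical(rend$truth_foreground, analytic)
})

test_that("depth attenuation makes intensity strictly decreasing in z", {
  # vertical tube spanning the full depth
  pts <- cbind(5, 5, seq(0.6, 9.4, by = 0.2))
  net <- lcn_network(
    data.frame(id = 1:2, x = 5, y = 5, z = c(0.6, 9.4), kind = "endpoint",
               degree = 1L, stringsAsFactors = FALSE),
    data.frame(id = 1L, source = 1L, target = 2L, arc_length = 8.8),
    list(pts), domain = c(10, 10, 10))
  gt <- list(network = net, lacunae = NULL,
             spec = list(domain_size = c(10, 10, 10),
                         domain_origin = c(0, 0, 0),
                         canalicular_radius = 0.5))
  class(gt) <- "lcn_ground_truth"
  im_att <- imaging_spec(voxel_size = c(0.25, 0.25, 0.25),
                         psf_sigma = c(0, 0, 0),
                         noise = list(type = "none"),
                         attenuation_per_um = 0.05)
  rend <- render_volume(gt, im_att)
  sel <- apply(rend$truth_foreground, 3, any)   # slices containing the tube
  prof <- apply(rend$volume$voxels, 3, max)[sel]
  expect_true(all(diff(prof) < 0))
  im0 <- imaging_spec(voxel_size = c(0.25, 0.25, 0.25),
                      psf_sigma = c(0, 0, 0), noise = list(type = "none"))
  prof0 <- apply(render_volume(gt, im0)$volume$voxels, 3, max)[sel]
  expect_equal(diff(prof0), rep(0, sum(sel) - 1))
})

test_that("planar calcein labels partition the domain in the right ratio", {
  out <- generate_calcein_surfaces(c(50, 20, 10), list(10, 40),
                                   voxel_size = c(0.5, 0.5, 0.5))
  cnt <- tabulate(out$mask$labels, 3)
  # 10 : 30 : 10 um of a 50 um cortex
  expect_equal(cnt[3] / cnt[1], 1)                    # endosteal == periosteal
  expect_equal(cnt[2] / cnt[1], 3)                    # intercortex 3x
  expect_equal(sum(cnt), prod(dim(out$mask$labels)))  # partition
  # calcein channel is bright at the surfaces
  i10 <- round(10 / 0.5)
  expect_gt(mean(out$calcein$voxels[i10, , ]), 0.5)
})

test_that("labels on the domain faces leave everything intercortical", {
  out <- generate_calcein_surfaces(c(30, 10, 5), list(0, 30),
                                   voxel_size = c(0.5, 0.5, 0.5))
  expect_true(all(out$mask$labels == 2L))
})

test_that("sinusoidal calcein surfaces still partition every voxel", {
  out <- generate_calcein_surfaces(
    c(40, 30, 8),
    list(list(x0 = 10, amplitude = 2, period = 15),
         list(x0 = 30, amplitude = 2, period = 10, phase = 1)),
    voxel_size = c(0.4, 0.4, 0.4))
  cnt <- tabulate(out$mask$labels, 3)
  expect_equal(sum(cnt), prod(dim(out$mask$labels)))
  expect_true(all(cnt > 0))
})

test_that("intersecting calcein surfaces are rejected", {
  expect_error(generate_calcein_surfaces(c(30, 10, 5), list(20, 10),
                                         voxel_size = c(0.5, 0.5, 0.5)),
               "intersect")
})

test_that("oversized voxel grids are refused with a memory message", {
  gt <- tube_truth()
  im <- imaging_spec(voxel_size = c(0.01, 0.01, 0.01), max_voxels = 1e6)
  expect_error(render_volume(gt, im), "memory budget")
})
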