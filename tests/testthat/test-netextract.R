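test_that("a straight tube skeletonizes to one chain of the right length", {
  gt <- tube_truth(radius = 0.4)
  rend <- render_volume(gt, noise_free())
  skel <- skeletonize(rend$truth_foreground)
  gr <- build_chain_graph(skel, voxel_size = rend$volume$voxel_size,
                          foreground = rend$truth_foreground)
  expect_equal(length(gr$chains), 1)
  net <- fit_splines(gr)
  expect_equal(nrow(net$edges), 1)
  expect_lt(abs(net$edges$arc_length - 10) / 10, 0.05)
})

test_that("skeletonization preserves connected components", {
  for (seed in 1:6) {
    mask <- random_capsule_mask(seed)
    skel <- skeletonize(mask)
    expect_identical(cc_count(skel), cc_count(mask))
  }
})

test_that("a Y phantom produces one junction, three chains, three endpoints", {
  gt <- y_truth(radius = 0.4)
  rend <- render_volume(gt, noise_free())
  bin0 <- binary_volume(rend$truth_foreground,
                        array(as.integer(rend$truth_foreground),
                              dim(rend$truth_foreground)),
                        array(as.integer(rend$truth_foreground),
                              dim(rend$truth_foreground)),
                        rend$volume$voxel_size)
  net <- extract_network(bin0)
  expect_equal(sum(net$nodes$kind == "junction"), 1)
  expect_equal(sum(net$nodes$kind == "endpoint"), 3)
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$nodes$degree[net$nodes$kind == "junction"], 3L)
  expect_lt(abs(sum(net$edges$arc_length) - 21) / 21, 0.1)
})

test_that("a pure cycle becomes one node with a self-edge", {
  # closed ring tube in a plane
  th <- seq(0, 2 * pi, length.out = 200)
  pts <- cbind(6 + 4 * cos(th), 6 + 4 * sin(th), 1.5)
  net0 <- lcn_network(
    data.frame(id = 1L, x = 10, y = 6, z = 1.5, kind = "endpoint",
               degree = 2L, stringsAsFactors = FALSE),
    data.frame(id = 1L, source = 1L, target = 1L, arc_length = 8 * pi),
    list(pts), domain = c(12, 12, 3))
  gt <- list(network = net0, lacunae = NULL,
             spec = list(domain_size = c(12, 12, 3),
                         domain_origin = c(0, 0, 0),
                         canalicular_radius = 0.4))
  class(gt) <- "lcn_ground_truth"
  rend <- render_volume(gt, noise_free(voxel_size = c(0.3, 0.3, 0.3)))
  skel <- skeletonize(rend$truth_foreground)
  gr <- build_chain_graph(skel, voxel_size = c(0.3, 0.3, 0.3))
  net <- fit_splines(gr)
  self <- net$edges$source == net$edges$target
  expect_equal(sum(self), 1)
  expect_lt(abs(net$edges$arc_length[self] - 8 * pi) / (8 * pi), 0.05)
  # self-edges count twice in the degree
  expect_equal(net$nodes$degree[match(net$edges$source[self], net$nodes$id)],
               2L)
})

test_that("short free-ending fragments are pruned", {
  skel <- array(FALSE, c(20, 20, 10))
  skel[5:6, 5, 5] <- TRUE   # 2-voxel fragment, ~0.3 um
  gr <- build_chain_graph(skel, voxel_size = c(0.3, 0.3, 0.3),
                          prune_length = 1.0)
  expect_equal(length(gr$chains), 0)
  gr0 <- build_chain_graph(skel, voxel_size = c(0.3, 0.3, 0.3),
                           prune_length = 0)
  expect_equal(length(gr0$chains), 1)
})

test_that("spline arc length is exact for collinear chains", {
  net <- fit_splines(line_graph())
  expect_equal(net$edges$arc_length, 30 * 0.3, tolerance = 1e-6)
})

test_that("spline arc length recovers a quarter circle within 2%", {
  vs <- c(0.3, 0.3, 0.3)
  th <- seq(0, pi / 2, length.out = 400)
  pts <- cbind(3 + 10 * cos(th), 3 + 10 * sin(th), 2.1)
  net0 <- lcn_network(
    data.frame(id = 1:2, x = c(13, 3), y = c(3, 13), z = 2.1,
               kind = "endpoint", degree = 1L, stringsAsFactors = FALSE),
    data.frame(id = 1L, source = 1L, target = 2L, arc_length = 5 * pi),
    list(pts), domain = c(16, 16, 4.2))
  gt <- list(network = net0, lacunae = NULL,
             spec = list(domain_size = c(16, 16, 4.2),
                         domain_origin = c(0, 0, 0),
                         canalicular_radius = 0.5))
  class(gt) <- "lcn_ground_truth"
  rend <- render_volume(gt, noise_free(voxel_size = vs))
  skel <- skeletonize(rend$truth_foreground)
  gr <- build_chain_graph(skel, voxel_size = vs)
  net <- fit_splines(gr)
  expect_equal(nrow(net$edges), 1)
  expect_lt(abs(net$edges$arc_length - 5 * pi) / (5 * pi), 0.02)
})

test_that("chain voxels stay close to the fitted spline", {
  gt <- y_truth(radius = 0.4)
  rend <- render_volume(gt, noise_free())
  vs <- rend$volume$voxel_size
  skel <- skeletonize(rend$truth_foreground)
  gr <- build_chain_graph(skel, voxel_size = vs)
  net <- fit_splines(gr)
  half_diag <- 0.5 * sqrt(sum(vs^2))
  for (i in seq_along(gr$chains)) {
    pvox <- sweep(gr$chains[[i]]$vox - 0.5, 2, vs, `*`)
    pp <- net$geometry[[i]]
    d <- vapply(seq_len(nrow(pvox)), function(t)
      sqrt(min(colSums((t(pp) - pvox[t, ])^2))), numeric(1))
    expect_lt(max(d), 2 * half_diag)
  }
})

test_that("skeleton voxels map to exactly one network element", {
  bin <- small_binary()
  skel <- skeletonize(bin)
  gr <- build_chain_graph(skel, lacunar_mask = bin$class_labels == 2L,
                          voxel_size = bin$voxel_size, prune_length = 0)
  vox <- do.call(rbind, lapply(gr$chains, function(ch)
    ch$vox[ch$vox[, 1] == round(ch$vox[, 1]), , drop = FALSE]))
  keys <- paste(vox[, 1], vox[, 2], vox[, 3])
  expect_false(any(duplicated(keys)))
})

test_that("node degrees are consistent with edge incidences", {
  net <- small_network()
  inc <- c(net$edges$source, net$edges$target)
  expect_equal(sum(net$nodes$degree), length(inc))
  expect_true(all(net$nodes$degree[net$nodes$kind == "junction"] >= 3))
  expect_true(all(net$nodes$degree[net$nodes$kind == "endpoint"] == 1))
})

test_that("noise-free extraction recovers length and junction count", {
  rc <- recovery_case()
  ratio <- sum(rc$net$edges$arc_length) / rc$gt$total_length
  expect_lt(abs(ratio - 1), 0.10)
  jt <- sum(rc$gt$network$nodes$kind == "junction")
  je <- sum(rc$net$nodes$kind == "junction")
  expect_lt(abs(je - jt) / jt, 0.15)
})

test_that("lacunae become single nodes with canaliculi attached", {
  net <- small_network()
  gt <- small_truth()
  lac <- net$nodes[net$nodes$kind == "lacunar", ]
  expect_equal(nrow(lac), nrow(gt$lacunae$centers))
  expect_true(all(lac$degree >= 1))
  # lacunar node positions close to the true centres
  d <- vapply(seq_len(nrow(lac)), function(i)
    sqrt(min(colSums((t(gt$lacunae$centers) -
                        c(lac$x[i], lac$y[i], lac$z[i]))^2))), numeric(1))
  expect_lt(max(d), 1.5)
})
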