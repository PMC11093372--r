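# a minimal hand-built network with given straight edge lengths
straight_net <- function(lens, origin = c(0.3, 0.3, 0.3), gap = 1) {
  n <- length(lens)
  nodes <- list(); edges <- list(); geom <- list()
  id <- 0L
  for (i in seq_len(n)) {
    a <- origin + c(0, (i - 1) * gap, 0)
    b <- a + c(lens[i], 0, 0)
    nodes[[2 * i - 1]] <- c(id + 1, a)
    nodes[[2 * i]] <- c(id + 2, b)
    edges[[i]] <- c(i, id + 1, id + 2, lens[i])
    geom[[i]] <- rbind(a, b)
    id <- id + 2L
  }
  nd <- as.data.frame(do.call(rbind, nodes))
  names(nd) <- c("id", "x", "y", "z")
  nd$kind <- "endpoint"; nd$degree <- 1L
  ed <- as.data.frame(do.call(rbind, edges))
  names(ed) <- c("id", "source", "target", "arc_length")
  lcn_network(nd, ed, geom)
}

test_that("Can.Dn is total length over pore-excluded volume", {
  net <- straight_net(25)
  expect_equal(can_dn(net, 125), 0.2)
  expect_equal(can_dn(lcnet:::empty_network(), 125), 0)
  expect_error(can_dn(net, 0), "positive")
})

test_that("density unit conversion to km/cm^3 is exact", {
  expect_identical(density_to_km_per_cm3(0.202), 202)
  expect_identical(density_to_km_per_cm3(0), 0)
  expect_identical(density_to_km_per_cm3(1), 1000)
  expect_error(density_to_km_per_cm3(-0.1), "non-negative")
})

test_that("a 5 um edge inside one cell gives Can.Dn 0.04 there and 0 elsewhere", {
  a <- c(0.3, 0.3, 0.3)
  b <- a + c(3, 4, 0)   # length 5, inside cell (1,1,1) of a 5 um grid
  net <- lcn_network(
    data.frame(id = 1:2, x = c(a[1], b[1]), y = c(a[2], b[2]),
               z = c(a[3], b[3]), kind = "endpoint", degree = 1L,
               stringsAsFactors = FALSE),
    data.frame(id = 1L, source = 1L, target = 2L, arc_length = 5),
    list(rbind(a, b)), domain = c(10, 10, 5))
  g <- subvolume_map(net, L = 5, extent = c(10, 10, 5))
  expect_equal(g$dims, c(2L, 2L, 1L))
  cells <- g$cells
  hit <- cells$ix == 1 & cells$iy == 1 & cells$iz == 1
  expect_equal(cells$can_dn[hit], 5 / 125, tolerance = 1e-6)
  expect_equal(cells$length[!hit], rep(0, 3))
})

test_that("grid dimensions follow from the extents", {
  g <- subvolume_map(lcnet:::empty_network(domain = c(50, 50, 30)), L = 5,
                     extent = c(50, 50, 30))
  expect_equal(prod(g$dims), 600)
  expect_equal(g$L^3, 125)
})

test_that("cell lengths conserve the clipped network length at any L", {
  gt <- small_truth()
  total <- sum(gt$network$edges$arc_length)
  for (L in c(1, 3, 5, 8, 20)) {
    g <- subvolume_map(gt$network, L = L, extent = gt$spec$domain_size)
    expect_lt(abs(sum(g$cells$length) - total) / total, 1e-3)
  }
})

test_that("a single cell covering the ROI reproduces the global density", {
  gt <- small_truth()
  ext <- gt$spec$domain_size
  g <- subvolume_map(gt$network, L = max(ext), extent = ext)
  # take the cell covering the domain; partial cells use clipped volume
  expect_equal(sum(g$cells$length * (g$cells$v_roi > 0)),
               sum(gt$network$edges$arc_length), tolerance = 1e-3)
  one <- subvolume_map(gt$network, L = max(ext),
                       extent = c(max(ext), max(ext), max(ext)))
  expect_equal(nrow(one$cells), 1)
})

test_that("convergence scan is stable between 4 and 6 um cells", {
  gt <- fixture("convergence_truth", {
    sp <- synthetic_spec(domain_size = c(40, 40, 20), lacuna_count = 10,
                         target_density = 0.18, seed = 21)
    suppressWarnings(generate_network(sp))
  })
  sc <- convergence_scan(gt$network, L_values = 4:6,
                         extent = c(40, 40, 20))
  expect_equal(nrow(sc), 3)
  spread <- (max(sc$median) - min(sc$median)) / min(sc$median)
  expect_lt(spread, 0.10)
  # conservation at every L
  total <- sum(gt$network$edges$arc_length)
  expect_true(all(abs(sc$total_length - total) / total < 1e-3))
})

test_that("length histogram matches the worked example", {
  net <- straight_net(c(0.5, 1.5, 6.0))
  h <- length_histogram(net)
  expect_equal(h$percent[c(1, 2, 7)], rep(100 / 3, 3))
  expect_equal(sum(h$percent), 100)
  expect_equal(h$long_fraction_count, 1 / 3)
  expect_equal(h$long_fraction_length, 6 / 8)
  expect_false(h$empty)
})

test_that("whole edges are assigned to the cell of their centre of mass", {
  # 8 um edge crossing from cell 1 into cell 2, centre of mass in cell 1
  a <- c(0.5, 2, 2); b <- c(4.3, 2, 2); cpt <- c(4.3, 2 + 4.2, 2)
  geom <- rbind(a, b, cpt)
  net <- lcn_network(
    data.frame(id = 1:2, x = c(a[1], cpt[1]), y = c(a[2], cpt[2]),
               z = c(a[3], cpt[3]), kind = "endpoint", degree = 1L,
               stringsAsFactors = FALSE),
    data.frame(id = 1L, source = 1L, target = 2L, arc_length = 8),
    list(geom), domain = c(10, 10, 4))
  g <- subvolume_map(net, L = 5, extent = c(10, 10, 4))
  h11 <- length_histogram(net, scope = list(grid = g, cell = c(1, 1, 1)))
  h21 <- length_histogram(net, scope = list(grid = g, cell = c(2, 1, 1)))
  expect_equal(h11$n, 1)
  expect_true(h21$empty)
  # the full edge length lands in the centre-of-mass cell
  expect_equal(sum(h11$counts * 0), 0)
  expect_equal(h11$percent[9], 100)  # bin [8, 9)
})

test_that("DoC histogram covers junctions only and flags empty scopes", {
  net <- small_network()
  d <- doc_histogram(net)
  expect_false(d$empty)
  expect_true(all(d$degrees >= 3))
  expect_equal(sum(d$percent), 100, tolerance = 1e-6)
  expect_equal(d$tree_like_fraction,
               d$percent[match(3, d$degrees)] / 100)
  # a chain without branches has no junctions
  chain <- straight_net(4)
  expect_true(doc_histogram(chain)$empty)
})

test_that("single Y and X junctions give the textbook distributions", {
  y <- lcn_network(
    data.frame(id = 1:4, x = c(0, 1, -1, 0), y = c(0, 1, 1, -1), z = 0,
               kind = c("junction", rep("endpoint", 3)),
               degree = c(3L, 1L, 1L, 1L), stringsAsFactors = FALSE),
    data.frame(id = 1:3, source = 1L, target = 2:4, arc_length = 1.5),
    replicate(3, rbind(c(0, 0, 0), c(1, 1, 0)), simplify = FALSE))
  dy <- doc_histogram(y)
  expect_equal(dy$percent, 100)
  expect_equal(dy$degrees, 3L)
  expect_equal(dy$tree_like_fraction, 1)
  x <- lcn_network(
    data.frame(id = 1:5, x = c(0, 1, -1, 1, -1), y = c(0, 1, 1, -1, -1),
               z = 0, kind = c("junction", rep("endpoint", 4)),
               degree = c(4L, rep(1L, 4)), stringsAsFactors = FALSE),
    data.frame(id = 1:4, source = 1L, target = 2:5, arc_length = 1.5),
    replicate(4, rbind(c(0, 0, 0), c(1, 1, 0)), simplify = FALSE))
  dx <- doc_histogram(x)
  expect_equal(dx$degrees, 4L)
  expect_equal(dx$tree_like_fraction, 0)
})

test_that("Can.Dn scales as s^-2 when all coordinates scale by s", {
  gt <- small_truth()
  net <- gt$network
  v0 <- prod(gt$spec$domain_size)
  d0 <- can_dn(net, v0)
  s <- 2
  net2 <- net
  net2$nodes$x <- net$nodes$x * s
  net2$nodes$y <- net$nodes$y * s
  net2$nodes$z <- net$nodes$z * s
  net2$edges$arc_length <- net$edges$arc_length * s
  net2$geometry <- lapply(net$geometry, function(p) p * s)
  d2 <- can_dn(net2, v0 * s^3)
  expect_equal(d2, d0 / s^2, tolerance = 1e-12)
})

test_that("cortical profile is flat for homogeneous phantoms and spans [0,1]", {
  gt <- small_truth()
  vs <- c(0.303, 0.303, 0.27)
  cal <- generate_calcein_surfaces(gt$spec$domain_size, list(6, 19),
                                   voxel_size = vs)
  g <- subvolume_map(gt$network, mask = cal$mask, L = 5)
  prof <- cortical_profile(g, cal$mask)
  expect_equal(range(prof$profile$position), c(0, 1))
  expect_true(all(is.finite(prof$profile$mean)))
  # flat within sampling noise: no column deviates from the global mean by
  # more than 2 of the largest per-column SDs
  dev <- abs(prof$profile$mean - mean(prof$profile$mean))
  expect_lt(max(dev), 2 * max(prof$profile$sd))
  # calcein boundaries on the normalized axis
  expect_true(all(prof$boundaries > 0 & prof$boundaries < 1))
})

test_that("a density gradient produces a monotonic trend in the profile", {
  gt <- fixture("gradient_truth", {
    sp <- synthetic_spec(domain_size = c(40, 25, 12), lacuna_count = 10,
                         density_gradient = c(0.035, 0, 0),
                         processes_per_lacuna = 25, seed = 31)
    suppressWarnings(generate_network(sp))
  })
  vs <- c(0.303, 0.303, 0.27)
  cal <- generate_calcein_surfaces(c(40, 25, 12), list(5, 35),
                                   voxel_size = vs)
  g <- subvolume_map(gt$network, mask = cal$mask, L = 5)
  prof <- cortical_profile(g, cal$mask)
  fit <- lm(mean ~ position, data = prof$profile)
  expect_gt(coef(fit)[2], 0)
})

test_that("ordinary least squares matches collinear points exactly", {
  x <- c(0.05, 0.1, 0.2, 0.3)
  y <- -0.5 * x + 80
  f <- lcnet:::ols_fit(x, y)
  expect_equal(f$slope, -0.5, tolerance = 1e-9)
  expect_equal(f$intercept, 80, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_error(lcnet:::ols_fit(c(1, 2), c(1, 2)), "fewer than 3")
})

test_that("regressions report R^2 in [0, 1] and enough cells", {
  gt <- small_truth()
  g <- subvolume_map(gt$network, L = 5, extent = gt$spec$domain_size)
  r <- density_connectivity_regression(g, gt$network)
  for (f in list(r$long, r$tree)) {
    expect_gte(f$r_squared, 0)
    expect_lte(f$r_squared, 1)
    expect_gte(f$n, 3)
  }
})

test_that("denser regions built from shorter canaliculi give negative slopes", {
  two <- fixture("two_region", {
    spA <- synthetic_spec(domain_size = c(25, 25, 15), lacuna_count = 5,
                          target_density = 0.10, segment_length_mean = 6,
                          seed = 11)
    spB <- synthetic_spec(domain_size = c(25, 25, 15), lacuna_count = 7,
                          target_density = 0.26, segment_length_mean = 2.5,
                          domain_origin = c(25, 0, 0), seed = 12)
    combine_networks(suppressWarnings(generate_network(spA))$network,
                     suppressWarnings(generate_network(spB))$network)
  })
  g <- subvolume_map(two, L = 5, extent = c(50, 25, 15))
  r <- density_connectivity_regression(g, two)
  expect_lt(r$long$slope, 0)
})
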