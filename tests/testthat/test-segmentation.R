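test_that("a constant image yields empty foreground, not an error", {
  img <- image_volume(array(0.7, c(30, 30, 20)), c(0.3, 0.3, 0.3))
  bin <- dog_binarize(img)
  expect_false(any(bin$foreground))
})

test_that("invalid DoG parameters are rejected", {
  expect_error(dog_params(0, 1, 0.5), "positive")
  expect_error(dog_params(2, 1, 0.5), "smaller")
})

test_that("binarization is invariant to intensity offsets", {
  rend <- render_volume(tube_truth(), noise_free())
  b1 <- dog_binarize(rend$volume)
  shifted <- rend$volume
  shifted$voxels <- shifted$voxels + 3.7
  b2 <- dog_binarize(shifted)
  expect_identical(b1$foreground, b2$foreground)
  expect_identical(b1$provenance, b2$provenance)
})

test_that("foreground is the union of the thin and bulky passes", {
  rend <- render_volume(small_truth(), noise_free())
  both <- dog_binarize(rend$volume)
  off <- dog_params(0.15, 0.6, 1e12)   # effectively disabled pass
  thin_only <- dog_binarize(rend$volume, lacunar_params = off)
  bulky_only <- dog_binarize(rend$volume, canalicular_params = off)
  expect_identical(both$foreground,
                   thin_only$foreground | bulky_only$foreground)
})

test_that("noise-free tube phantoms are segmented with high overlap", {
  rend <- render_volume(small_truth(), noise_free())
  bin <- dog_binarize(rend$volume)
  inter <- sum(bin$foreground & rend$truth_foreground)
  dice <- 2 * inter / (sum(bin$foreground) + sum(rend$truth_foreground))
  expect_gte(dice, 0.8)
})

test_that("pore classification separates lacunae, canals and canaliculi", {
  vs <- c(0.5, 0.5, 0.5)
  dims <- c(80, 40, 30)
  xc <- (seq_len(dims[1]) - 0.5) * vs[1]
  yc <- (seq_len(dims[2]) - 0.5) * vs[2]
  zc <- (seq_len(dims[3]) - 0.5) * vs[3]
  g <- expand.grid(x = xc, y = yc, z = zc)
  # ellipsoid of ~147 um^3 at (10, 10, 7.5)
  ell <- array(((g$x - 10) / 4)^2 + ((g$y - 10) / 3.5)^2 +
                 ((g$z - 7.5) / 2.5)^2 <= 1, dims)
  # vascular canal: 36 um long cylinder along x, radius 2 um
  can <- array(((g$y - 15)^2 + (g$z - 12.5)^2 <= 4) &
                 g$x >= 2 & g$x <= 38, dims)
  # a thin tube: 9 voxels of ~1 um^3, away from both pores
  tube <- array(FALSE, dims)
  tube[14:22, 10, 8] <- TRUE
  prov <- array(0L, dims)
  prov[tube] <- 1L
  prov[ell | can] <- 2L
  fg <- prov > 0L
  cls <- array(0L, dims); cls[fg] <- 1L
  bin <- binary_volume(fg, cls, prov, vs)
  out <- classify_pores(bin)
  expect_true(all(out$class_labels[ell] == 2L))          # lacunar
  expect_true(all(out$class_labels[tube] == 1L))         # canalicular
  inner <- can & array(g$x >= 4 & g$x <= 36, dims)
  expect_true(mean(out$class_labels[inner] == 3L) > 0.95)  # vascular
  # idempotent
  out2 <- classify_pores(out)
  expect_identical(out$class_labels, out2$class_labels)
})

test_that("rendered lacunae are labelled lacunar, attached tubes canalicular", {
  rend <- render_volume(small_truth(), noise_free())
  bin <- small_binary()
  truth_lac <- rend$truth_mask == 2L
  truth_tube <- rend$truth_mask == 1L
  detected <- bin$foreground & rend$truth_mask > 0L
  agree <- sum((bin$class_labels == 2L & truth_lac)[detected] |
               (bin$class_labels == 1L & truth_tube)[detected]) / sum(detected)
  expect_gte(agree, 0.95)
})

test_that("region mask recovery finds planar calcein surfaces within a voxel", {
  vs <- c(0.303, 0.303, 0.27)
  out <- generate_calcein_surfaces(c(50, 15, 8), list(12, 38), voxel_size = vs)
  rec <- build_region_mask(out$calcein)
  expect_lt(abs(mean(rec$boundary_positions[[1]]) - 12), vs[1])
  expect_lt(abs(mean(rec$boundary_positions[[2]]) - 38), vs[1])
  # every voxel gets exactly one region label
  expect_true(all(rec$labels %in% 1:3))
  # agreement with the generating partition away from the surfaces
  expect_gt(mean(rec$labels == out$mask$labels), 0.98)
})

test_that("region mask recovery follows curved surfaces", {
  vs <- c(0.303, 0.303, 0.27)
  out <- generate_calcein_surfaces(
    c(50, 20, 8),
    list(list(x0 = 14, amplitude = 2, period = 12), 36), voxel_size = vs)
  rec <- build_region_mask(out$calcein)
  err <- abs(rec$boundary_positions[[1]] - out$mask$boundary_positions[[1]])
  expect_lt(mean(err), 2 * vs[1])
  expect_gt(mean(rec$labels == out$mask$labels), 0.97)
})

test_that("a single calcein band is reported as a missing surface", {
  vs <- c(0.4, 0.4, 0.4)
  out <- generate_calcein_surfaces(c(30, 10, 5), list(-5, 15), voxel_size = vs)
  expect_error(build_region_mask(out$calcein), "found 1")
})

test_that("roi_volume does pore-excluded bookkeeping", {
  vs <- c(0.5, 0.5, 0.5)
  labels <- array(2L, c(10, 10, 10))
  mask <- region_mask(labels, list(matrix(0, 1, 1), matrix(5, 1, 1)), vs)
  expect_equal(roi_volume(mask, NULL, "intercortex"), 1000 * 0.125)
  expect_equal(roi_volume(mask, NULL, "periosteal_new"), 0)
  # fully occupied by a lacuna -> zero
  fg <- array(TRUE, c(10, 10, 10))
  cls <- array(2L, c(10, 10, 10))
  bin <- binary_volume(fg, cls, array(2L, c(10, 10, 10)), vs)
  expect_equal(roi_volume(mask, bin, "intercortex"), 0)
  # additive over regions
  labels2 <- array(0L, c(10, 10, 10))
  labels2[1:3, , ] <- 3L; labels2[4:7, , ] <- 2L; labels2[8:10, , ] <- 1L
  mask2 <- region_mask(labels2, list(matrix(1.5), matrix(3.5)), vs)
  tot <- roi_volume(mask2, NULL, "endosteal_new") +
    roi_volume(mask2, NULL, "intercortex") +
    roi_volume(mask2, NULL, "periosteal_new")
  expect_equal(tot, roi_volume(mask2, NULL, "all"))
  # mismatched grids
  bin_small <- binary_volume(array(FALSE, c(5, 5, 5)), array(0L, c(5, 5, 5)),
                             array(0L, c(5, 5, 5)), vs)
  expect_error(roi_volume(mask, bin_small, "all"), "mismatched")
})

test_that("recovered lacunar volume is within a surface shell of the truth", {
  gt <- small_truth()
  bin <- small_binary()
  n_lac <- nrow(gt$lacunae$centers)
  semi <- gt$spec$lacuna_semiaxes
  true_vol <- 4 / 3 * pi * prod(semi) * n_lac
  # one voxel layer over each lacunar surface (Thomsen area approximation)
  p <- 1.6075
  surf <- 4 * pi * (((semi[1] * semi[2])^p + (semi[1] * semi[3])^p +
                       (semi[2] * semi[3])^p) / 3)^(1 / p)
  shell <- n_lac * surf * sqrt(sum(bin$voxel_size^2))
  est_vol <- sum(bin$class_labels == 2L) * prod(bin$voxel_size)
  expect_lt(abs(est_vol - true_vol), shell)
})
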