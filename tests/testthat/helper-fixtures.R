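# Shared fixtures, built once per test run and cached. All phantoms are
# generated in code under fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

noise_free <- function(voxel_size = c(0.303, 0.303, 0.27))
  imaging_spec(voxel_size = voxel_size, psf_sigma = c(0, 0, 0),
               noise = list(type = "none"))

# a single straight tube along x, known axis and radius
tube_truth <- function(radius = 0.4) {
  axis_a <- c(2, 5.05, 2.55)
  axis_b <- c(12, 5.05, 2.55)
  pts <- cbind(seq(axis_a[1], axis_b[1], by = 0.25),
               axis_a[2], axis_a[3])
  net <- lcn_network(
    data.frame(id = 1:2, x = c(axis_a[1], axis_b[1]), y = axis_a[2],
               z = axis_a[3], kind = "endpoint", degree = 1L,
               stringsAsFactors = FALSE),
    data.frame(id = 1L, source = 1L, target = 2L, arc_length = 10),
    list(pts), domain = c(14, 10, 5))
  gt <- list(network = net, lacunae = NULL,
             spec = list(domain_size = c(14, 10, 5),
                         domain_origin = c(0, 0, 0),
                         canalicular_radius = radius),
             total_length = 10)
  class(gt) <- "lcn_ground_truth"
  attr(gt, "axis") <- rbind(axis_a, axis_b)
  gt
}

# three tubes meeting at one point (a Y junction), arms 7 um
y_truth <- function(radius = 0.4) {
  ctr <- c(10, 10, 3.05)
  ang <- c(90, 210, 330) * pi / 180
  geom <- lapply(ang, function(a) {
    ends <- ctr + 7 * c(cos(a), sin(a), 0)
    t(sapply(seq(0, 1, by = 0.05), function(u) ctr + u * (ends - ctr)))
  })
  nodes <- data.frame(id = 1:4,
                      x = c(ctr[1], ctr[1] + 7 * cos(ang)),
                      y = c(ctr[2], ctr[2] + 7 * sin(ang)),
                      z = ctr[3],
                      kind = c("junction", rep("endpoint", 3)),
                      degree = c(3L, 1L, 1L, 1L), stringsAsFactors = FALSE)
  edges <- data.frame(id = 1:3, source = 1L, target = 2:4, arc_length = 7)
  gt <- list(network = lcn_network(nodes, edges, geom, domain = c(20, 20, 6.1)),
             lacunae = NULL,
             spec = list(domain_size = c(20, 20, 6.1),
                         domain_origin = c(0, 0, 0),
                         canalicular_radius = radius),
             total_length = 21)
  class(gt) <- "lcn_ground_truth"
  gt
}

# mid-size branched phantom shared across segmentation/extraction tests
small_truth <- function() fixture("small_truth", {
  sp <- synthetic_spec(domain_size = c(30, 30, 14), lacuna_count = 4,
                       target_density = 0.12, seed = 3)
  generate_network(sp)
})

small_binary <- function() fixture("small_binary", {
  rend <- render_volume(small_truth(), noise_free())
  classify_pores(dog_binarize(rend$volume))
})

small_network <- function() fixture("small_network", {
  extract_network(small_binary())
})

# sparse phantom used for the quantitative recovery contract
recovery_case <- function() fixture("recovery_case", {
  sp <- synthetic_spec(domain_size = c(40, 40, 20), lacuna_count = 10,
                       target_density = 0.08, seed = 9)
  gt <- suppressWarnings(generate_network(sp))
  rend <- render_volume(gt, noise_free())
  bin <- classify_pores(dog_binarize(rend$volume))
  list(gt = gt, bin = bin, net = extract_network(bin))
})

# full study-scale phantom (50 x 50 x 30 um at 0.2 um/um^3), computed once
study_case <- function() fixture("study_case", {
  sp <- synthetic_spec(target_density = 0.2, seed = 5)
  gt <- suppressWarnings(generate_network(sp))
  rend <- render_volume(gt, noise_free())
  bin <- classify_pores(dog_binarize(rend$volume))
  net <- extract_network(bin)
  vv <- prod(bin$voxel_size)
  v_roi <- prod(dim(bin$foreground)) * vv -
    sum(bin$class_labels >= 2L) * vv
  list(spec = sp, gt = gt, bin = bin, net = net, v_roi = v_roi)
})

# straight-line voxel chain wrapped as a skeleton graph
line_graph <- function(n = 31, vs = c(0.3, 0.3, 0.3)) {
  vox <- cbind(seq_len(n) + 4, 5, 5)
  structure(list(
    nodes = data.frame(id = 1:2,
                       x = (c(vox[1, 1], vox[n, 1]) - 0.5) * vs[1],
                       y = (5 - 0.5) * vs[2], z = (5 - 0.5) * vs[3],
                       kind = "endpoint", stringsAsFactors = FALSE),
    chains = list(list(vox = vox, a = 1L, b = 2L)),
    voxel_size = vs, dims = c(n + 10, 10, 10)),
    class = "skeleton_graph")
}

# random capsule phantoms for topology tests
random_capsule_mask <- function(seed, nseg = 6, dims = c(50, 50, 30),
                                vs = c(0.3, 0.3, 0.3)) {
  set.seed(seed)
  ext <- dims * vs
  segs <- t(replicate(nseg, c(runif(3, 0.1, 0.9) * ext,
                              runif(3, 0.1, 0.9) * ext)))
  lcnet:::cpp_rasterize_capsules(segs, runif(1, 0.35, 0.6), vs,
                                 c(0, 0, 0), as.integer(dims))
}

cc_count <- function(mask) max(lcnet:::cpp_label_components(mask, dim(mask), 26L))
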