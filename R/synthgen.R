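#' Parameters of the synthetic lacuno-canalicular phantom
#'
#' Defines a ground-truth network generator: ellipsoidal lacunae seeded in a
#' box, each sprouting canalicular processes that grow as biased random
#' walks with Poisson branching. Branch events create junction nodes of
#' degree 3, so the generated networks are tree-dominated, which is the
#' architecture the downstream connectomic statistics are designed to probe.
#'
#' @param domain_size box extent in um (length 3).
#' @param lacuna_count number of lacunae.
#' @param lacuna_semiaxes ellipsoid semi-axes in um; the default gives a
#'   lacunar volume of ~126 um^3, inside the 100-250 um^3 range typical of
#'   osteocyte lacunae.
#' @param processes_per_lacuna processes sprouted per lacuna when no
#'   `target_density` is set.
#' @param branch_rate expected branch events per um of grown canaliculus.
#' @param segment_length_mean,segment_length_sd edge (canaliculus) length
#'   distribution between consecutive nodes, um.
#' @param tortuosity amplitude of the random direction perturbation per
#'   0.5 um growth step (dimensionless; 0 = straight growth).
#' @param canalicular_radius tube radius used for rendering and collision
#'   spacing, um. Real canaliculi are below the optical resolution limit,
#'   so this is a free phantom parameter, not a measured value.
#' @param target_density if set, growth continues until the total true
#'   length reaches `target_density * prod(domain_size)` (um/um^3).
#' @param density_gradient optional length-3 vector g (1/um); local seeding
#'   intensity is modulated by `1 + g . (pos - centre)` to create a spatial
#'   density gradient.
#' @param min_separation minimum centre-to-centre spacing kept
#'   between canaliculi of different trees, um; 0 disables collision
#'   avoidance.
#' @param step growth sub-step in um (polyline resolution of the truth).
#' @param domain_origin lower corner of the box in um.
#' @param lacuna_centers optional n x 3 matrix of explicit lacuna centres
#'   (um); overrides random placement (and `lacuna_count`).
#' @param seed integer seed; the whole phantom is reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(domain_size = c(50, 50, 30),
                           lacuna_count = 24,
                           lacuna_semiaxes = c(3, 5, 2),
                           processes_per_lacuna = 60,
                           branch_rate = 0.11,
                           segment_length_mean = 4,
                           segment_length_sd = 1.5,
                           tortuosity = 0.12,
                           canalicular_radius = 0.3,
                           target_density = NULL,
                           density_gradient = NULL,
                           min_separation = 1.2,
                           step = 0.5,
                           domain_origin = c(0, 0, 0),
                           lacuna_centers = NULL,
                           seed = 1L) {
  stopifnot(length(domain_size) == 3, all(domain_size > 0),
            lacuna_count >= 0, all(lacuna_semiaxes > 0),
            processes_per_lacuna >= 0, branch_rate >= 0,
            segment_length_mean > 0, segment_length_sd >= 0,
            tortuosity >= 0, canalicular_radius > 0, step > 0,
            min_separation >= 0)
  if (!is.null(target_density) && target_density <= 0)
    stop("target_density, if set, must be > 0")
  structure(list(domain_size = as.numeric(domain_size),
                 lacuna_count = as.integer(lacuna_count),
                 lacuna_semiaxes = as.numeric(lacuna_semiaxes),
                 processes_per_lacuna = as.integer(processes_per_lacuna),
                 branch_rate = branch_rate,
                 segment_length_mean = segment_length_mean,
                 segment_length_sd = segment_length_sd,
                 tortuosity = tortuosity,
                 canalicular_radius = canalicular_radius,
                 target_density = target_density,
                 density_gradient = density_gradient,
                 min_separation = min_separation,
                 step = step,
                 domain_origin = as.numeric(domain_origin),
                 lacuna_centers = lacuna_centers,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Confocal imaging model for phantom rendering
#'
#' @param voxel_size voxel edge lengths in um. The defaults correspond to a
#'   303 nm in-plane pixel and a 30 um deep stack of ~110 slices.
#' @param psf_sigma Gaussian point-spread-function sigma per axis, um
#'   (0 = no blur).
#' @param noise list with `type` in `none`, `gaussian`, `poisson`,
#'   `poisson_gaussian`, plus `photons` (photons per intensity unit) and/or
#'   `read_sd` (additive read-noise SD).
#' @param attenuation_per_um fractional intensity loss per um of imaging
#'   depth, in `[0, 1)`; 0 models acquisition with depth-compensated laser
#'   power and detector gain.
#' @param background_level baseline intensity.
#' @param amplitude foreground intensity above background.
#' @param max_voxels refuse to render grids larger than this.
#' @return An object of class `imaging_spec`.
#' @export
imaging_spec <- function(voxel_size = c(0.303, 0.303, 0.27),
                         psf_sigma = c(0.2, 0.2, 0.45),
                         noise = list(type = "poisson_gaussian",
                                      photons = 100, read_sd = 0.02),
                         attenuation_per_um = 0,
                         background_level = 0.05,
                         amplitude = 1,
                         max_voxels = 2.5e8) {
  stopifnot(all(voxel_size > 0), all(psf_sigma >= 0),
            attenuation_per_um >= 0, attenuation_per_um < 1)
  noise$type <- match.arg(noise$type,
                          c("none", "gaussian", "poisson", "poisson_gaussian"))
  structure(list(voxel_size = as.numeric(voxel_size),
                 psf_sigma = as.numeric(psf_sigma),
                 noise = noise,
                 attenuation_per_um = attenuation_per_um,
                 background_level = background_level,
                 amplitude = amplitude,
                 max_voxels = max_voxels),
            class = "imaging_spec")
}

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- .GlobalEnv$.Random.seed
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

rand_unit3 <- function() unit3(rnorm(3))

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# local seeding modulation for density gradients
grad_weight <- function(pos, spec) {
  g <- spec$density_gradient
  if (is.null(g)) return(1)
  ctr <- spec$domain_origin + spec$domain_size / 2
  max(0.05, 1 + sum(g * (pos - ctr)))
}

#' Generate a ground-truth lacuno-canalicular network
#'
#' Grows canalicular trees from lacunar surfaces: each process advances in
#' 0.5 um sub-steps with a randomly perturbed direction, branches at a
#' Poisson rate per um (each branch creating a degree-3 junction), and
#' terminates at the domain boundary or at a collision with another
#' canaliculus. If `target_density` is set, trees are added (round-robin
#' over lacunae) until the accumulated true length reaches the target,
#' with the final tree growing only the remaining length budget, so the
#' achieved density is well within 5% of the target whenever the target
#' is feasible at the configured separation.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `lcn_ground_truth`: a list with `network`
#'   (the true [lcn_network()]), `total_length` (um), `lacunae` (centres and
#'   semi-axes), `per_cell_lengths` (true clipped length per default 5 um
#'   sub-volume) and the `spec` used.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$lacuna_count == 0)
    stop("empty network: no lacunae to seed processes from")
  if (is.null(spec$target_density) && spec$processes_per_lacuna == 0)
    stop("empty network: zero processes per lacuna and no target density")

  with_seed(spec$seed, {
    lo <- spec$domain_origin
    hi <- lo + spec$domain_size
    semi <- spec$lacuna_semiaxes
    h0 <- spec$step
    radius <- spec$canalicular_radius
    margin <- max(semi) + 0.5

    # --- place non-overlapping lacunae ------------------------------------
    if (!is.null(spec$lacuna_centers)) {
      centers <- matrix(as.numeric(spec$lacuna_centers), ncol = 3)
      spec$lacuna_count <- nrow(centers)
    }
    centers <- if (!is.null(spec$lacuna_centers)) centers
               else matrix(NA_real_, spec$lacuna_count, 3)
    placed <- if (!is.null(spec$lacuna_centers)) nrow(centers) else 0L
    tries <- 0L
    fmax <- if (is.null(spec$density_gradient)) 1 else
      max(grad_weight(lo, spec), grad_weight(hi, spec), 1)
    while (placed < spec$lacuna_count && tries < 4000L * spec$lacuna_count) {
      tries <- tries + 1L
      cand <- lo + margin + runif(3) * pmax(hi - lo - 2 * margin, 1e-6)
      if (!is.null(spec$density_gradient) &&
          runif(1) > grad_weight(cand, spec) / fmax) next
      if (placed > 0) {
        d2 <- colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2)
        if (min(d2) < (2 * max(semi))^2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    if (placed < spec$lacuna_count) {
      warning(sprintf("placed only %d of %d lacunae without overlap",
                      placed, spec$lacuna_count))
      centers <- centers[seq_len(placed), , drop = FALSE]
    }
    n_lac <- nrow(centers)

    # --- occupancy grid for inter-tree collision avoidance ----------------
    # cells of half the separation store one point (and its tree id) each;
    # candidate steps check exact distances to points in the surrounding
    # 5x5x5 cell block, which covers every stored point within min_separation
    use_occ <- spec$min_separation > 0
    if (use_occ) {
      cell <- max(0.4, spec$min_separation / 2)
      min_sep2 <- spec$min_separation^2
      od <- pmax(1L, as.integer(ceiling(spec$domain_size / cell)))
      occ <- array(0L, dim = od)
      opx <- array(0, dim = od); opy <- opx; opz <- opx
      oarc <- array(0, dim = od)   # arc position along the tree at laying
      self_window <- 1.6           # um of own lineage exempt from blocking
      # block (dilated) lacunar ellipsoids with surrogate points
      dl <- semi + radius + 0.2
      for (q in seq_len(n_lac)) {
        c0 <- centers[q, ]
        i0 <- pmax(1L, floor((c0 - dl - lo) / cell) + 1L)
        i1 <- pmin(od, ceiling((c0 + dl - lo) / cell))
        ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
        cx <- lo[1] + (ix - 0.5) * cell
        cy <- lo[2] + (iy - 0.5) * cell
        cz <- lo[3] + (iz - 0.5) * cell
        m <- outer(((cx - c0[1]) / dl[1])^2,
                   outer(((cy - c0[2]) / dl[2])^2,
                         ((cz - c0[3]) / dl[3])^2, "+"), "+") <= 1
        blk <- occ[ix, iy, iz, drop = FALSE]
        blk[m] <- -1L
        occ[ix, iy, iz] <- blk
        bx <- opx[ix, iy, iz, drop = FALSE]
        bx[m] <- rep(cx, times = length(iy) * length(iz))[m]
        opx[ix, iy, iz] <- bx
        by <- opy[ix, iy, iz, drop = FALSE]
        by[m] <- rep(rep(cy, each = length(ix)), times = length(iz))[m]
        opy[ix, iy, iz] <- by
        bz <- opz[ix, iy, iz, drop = FALSE]
        bz[m] <- rep(cz, each = length(ix) * length(iy))[m]
        opz[ix, iy, iz] <- bz
      }
    }

    # --- node / edge accumulators -----------------------------------------
    nx_ <- numeric(0); ny_ <- numeric(0); nz_ <- numeric(0); nk_ <- character(0)
    new_node <- function(pos, kind) {
      nx_[length(nx_) + 1L] <<- pos[1]
      ny_[length(ny_) + 1L] <<- pos[2]
      nz_[length(nz_) + 1L] <<- pos[3]
      nk_[length(nk_) + 1L] <<- kind
      length(nx_)
    }
    for (q in seq_len(n_lac)) new_node(centers[q, ], "lacunar")

    e_src <- integer(0); e_dst <- integer(0); e_len <- numeric(0)
    e_geom <- list()
    add_edge <- function(src, dst, len, geom) {
      e_src[length(e_src) + 1L] <<- src
      e_dst[length(e_dst) + 1L] <<- dst
      e_len[length(e_len) + 1L] <<- len
      e_geom[[length(e_geom) + 1L]] <<- geom
    }

    min_seg <- max(1.5, 0.3 * spec$segment_length_mean)
    root_free <- 1.5   # um grown before collision checks engage at a root
    max_edge <- 25 * spec$segment_length_mean   # runaway-edge safety cap
    # processes that collide almost immediately retract: edges shorter than
    # this (well below the rendered tube diameter) are not kept, so the
    # ground truth only contains structures the imaging could represent
    min_edge <- 4 * spec$canalicular_radius

    # grow one segment from a tip; returns list(pos, pts, acc, complete).
    # uid identifies the growing edge. Exemptions from the separation rule:
    # the tip's own recent trail (|arc difference| < self_window), and --
    # only while the tip is still within self_window of its spawn point --
    # the parent / sibling / grandparent edges near that same spawn point
    # (the branch splay zone).
    grow_segment <- function(pos, dir, uid, relatives, spawn_arc, arc_root) {
      seg_target <- max(min_seg,
                        rnorm(1, spec$segment_length_mean,
                              spec$segment_length_sd))
      nmax <- ceiling(seg_target / h0) + 2L
      pts <- matrix(NA_real_, nmax, 3)
      pts[1, ] <- pos
      npts <- 1L
      acc <- 0
      complete <- FALSE
      repeat {
        rem <- seg_target - acc
        if (rem <= 1e-9) { complete <- TRUE; break }
        h <- min(h0, rem)
        dir <- unit3(dir + spec$tortuosity * sqrt(h / h0) * rnorm(3))
        ok <- FALSE
        for (att in 1:5) {
          cand <- pos + h * dir
          inside <- all(cand > lo + radius) && all(cand < hi - radius)
          blocked <- FALSE
          cur_arc <- arc_root + acc
          if (inside && use_occ && cur_arc > root_free) {
            ci <- pmin(od, pmax(1L, floor((cand - lo) / cell) + 1L))
            i0 <- pmax(1L, ci - 2L); i1 <- pmin(od, ci + 2L)
            sx <- i0[1]:i1[1]; sy <- i0[2]:i1[2]; sz <- i0[3]:i1[3]
            vals <- occ[sx, sy, sz]
            arcs <- oarc[sx, sy, sz]
            exempt <- vals == uid & abs(arcs - cur_arc) < self_window
            if (cur_arc - spawn_arc < self_window)
              exempt <- exempt | ((vals %in% relatives) &
                                  abs(arcs - spawn_arc) < self_window)
            consider <- vals != 0L & !exempt
            if (any(consider)) {
              d2 <- (opx[sx, sy, sz][consider] - cand[1])^2 +
                    (opy[sx, sy, sz][consider] - cand[2])^2 +
                    (opz[sx, sy, sz][consider] - cand[3])^2
              blocked <- any(d2 < min_sep2)
            }
          }
          if (inside && !blocked) { ok <- TRUE; break }
          dir <- unit3(dir + 0.9 * rnorm(3))
        }
        if (!ok) break
        pos <- cand
        acc <- acc + h
        npts <- npts + 1L
        pts[npts, ] <- pos
        if (use_occ) {
          # store the point and the preceding midpoint, so the stored
          # samples track the tube axis to within ~0.13 um
          prev <- pts[npts - 1L, ]
          for (pw in list(list(p = (prev + pos) / 2, a = arc_root + acc - h / 2),
                          list(p = pos, a = arc_root + acc))) {
            ci <- pmin(od, pmax(1L, floor((pw$p - lo) / cell) + 1L))
            if (occ[ci[1], ci[2], ci[3]] == 0L) {
              occ[ci[1], ci[2], ci[3]] <<- uid
              opx[ci[1], ci[2], ci[3]] <<- pw$p[1]
              opy[ci[1], ci[2], ci[3]] <<- pw$p[2]
              opz[ci[1], ci[2], ci[3]] <<- pw$p[3]
              oarc[ci[1], ci[2], ci[3]] <<- pw$a
            }
          }
        }
      }
      list(pos = pos, dir = dir, pts = pts[seq_len(npts), , drop = FALSE],
           acc = acc, complete = complete)
    }

    # one tip grows an edge made of consecutive segments; the edge ends at a
    # branch event (junction, two child tips), or at a collision / the
    # domain boundary (endpoint). Unbranched segment ends just continue.
    uid_counter <- 0L
    next_uid <- function() { uid_counter <<- uid_counter + 1L; uid_counter }

    grow_tree <- function(lac_id, budget = Inf) {
      c0 <- centers[lac_id, ]
      u <- rand_unit3()
      p0 <- c0 + u / sqrt(sum((u / semi)^2))
      nrm <- unit3((p0 - c0) / semi^2)
      u0 <- next_uid()
      tips <- list(list(pos = p0, dir = unit3(nrm + 0.3 * rnorm(3)),
                        parent = lac_id, arc_root = 0, spawn_arc = 0,
                        uid = u0, relatives = c(0L, 0L, 0L)))
      tree_len <- 0
      while (length(tips) > 0 && tree_len < budget) {
        tip <- tips[[length(tips)]]
        tips[[length(tips)]] <- NULL
        pos <- tip$pos; dir <- tip$dir
        edge_pts <- matrix(pos, 1, 3)
        edge_len <- 0
        branch <- FALSE
        repeat {
          gs <- grow_segment(pos, dir, tip$uid, tip$relatives, tip$spawn_arc,
                             tip$arc_root + edge_len)
          if (nrow(gs$pts) >= 2) {
            edge_pts <- rbind(edge_pts, gs$pts[-1, , drop = FALSE])
            edge_len <- edge_len + gs$acc
            pos <- gs$pos; dir <- gs$dir
          }
          if (!gs$complete || edge_len >= max_edge) break
          if (spec$branch_rate == 0) break   # unbranched processes: one segment
          if (runif(1) < (1 - exp(-spec$branch_rate * gs$acc))) {
            branch <- TRUE
            break
          }
        }
        if (edge_len < min_edge && !branch) next
        if (edge_len <= 0) next
        tree_len <- tree_len + edge_len
        nd <- new_node(pos, if (branch) "junction" else "endpoint")
        add_edge(tip$parent, nd, edge_len, edge_pts)
        if (branch) {
          v <- unit3(cross3(dir, rnorm(3)))
          th <- (50 + runif(2) * 25) * pi / 180
          ua <- next_uid(); ub <- next_uid()
          arc1 <- tip$arc_root + edge_len
          tips[[length(tips) + 1L]] <-
            list(pos = pos, dir = unit3(cos(th[1]) * dir + sin(th[1]) * v),
                 parent = nd, arc_root = arc1, spawn_arc = arc1,
                 uid = ua, relatives = c(ub, tip$uid, tip$relatives[2]))
          tips[[length(tips) + 1L]] <-
            list(pos = pos, dir = unit3(cos(th[2]) * dir - sin(th[2]) * v),
                 parent = nd, arc_root = arc1, spawn_arc = arc1,
                 uid = ub, relatives = c(ua, tip$uid, tip$relatives[2]))
        }
      }
      tree_len
    }

    # --- tree scheduling ---------------------------------------------------
    # roots per lacuna are capped by the surface capacity at the working
    # separation, so processes do not crowd the lacunar surface into an
    # unresolvable halo
    total_len <- 0
    tree_id <- 0L
    wts <- vapply(seq_len(n_lac),
                  function(q) grad_weight(centers[q, ], spec), numeric(1))
    surf <- {  # Thomsen approximation of the ellipsoid surface area
      p <- 1.6075
      a <- semi[1]; b <- semi[2]; cc <- semi[3]
      4 * pi * (((a * b)^p + (a * cc)^p + (b * cc)^p) / 3)^(1 / p)
    }
    capacity <- if (use_occ)
      max(3L, floor(0.7 * surf / spec$min_separation^2)) else .Machine$integer.max
    if (is.null(spec$target_density)) {
      n_proc <- min(spec$processes_per_lacuna, capacity)
      alloc <- if (!is.null(spec$density_gradient))
        pmin(capacity, round(n_proc * wts / mean(wts)))
      else rep(n_proc, n_lac)
      for (q in seq_len(n_lac)) {
        for (p in seq_len(alloc[q])) {
          tree_id <- tree_id + 1L
          total_len <- total_len + grow_tree(q)
        }
      }
    } else {
      target_len <- spec$target_density * prod(spec$domain_size)
      roots_used <- integer(n_lac)
      pr <- wts / sum(wts)
      while (total_len < target_len && any(roots_used < capacity)) {
        open <- roots_used < capacity
        q <- if (sum(open) == 1) which(open)
             else sample(which(open), 1, prob = pr[open])
        roots_used[q] <- roots_used[q] + 1L
        tree_id <- tree_id + 1L
        total_len <- total_len + grow_tree(q, target_len - total_len)
      }
      if (total_len < 0.95 * target_len)
        warning(sprintf(
          "target density %.3f um/um^3 infeasible; achieved %.3f",
          spec$target_density, total_len / prod(spec$domain_size)))
    }

    nodes <- data.frame(id = seq_along(nx_), x = nx_, y = ny_, z = nz_,
                        kind = nk_, degree = 0L, stringsAsFactors = FALSE)
    edges <- data.frame(id = seq_along(e_src), source = e_src, target = e_dst,
                        arc_length = e_len, stringsAsFactors = FALSE)
    net <- lcn_network(nodes, edges, e_geom, domain = spec$domain_size)
    net <- cleanup_network(net)

    gt <- list(network = net,
               total_length = sum(net$edges$arc_length),
               lacunae = list(centers = centers,
                              semiaxes = matrix(semi, n_lac, 3, byrow = TRUE)),
               spec = spec)
    gt$per_cell_lengths <- cell_lengths(net, L = 5,
                                        origin = spec$domain_origin,
                                        extent = spec$domain_size)
    class(gt) <- "lcn_ground_truth"
    gt
  })
}

# dissolve degree-2 junctions (merge their incident edges), turn degree-1
# junctions into endpoints, drop isolated non-lacunar nodes, recompute degrees
cleanup_network <- function(net) {
  net <- recompute_degrees(net)
  repeat {
    bad <- which(net$nodes$kind == "junction" & net$nodes$degree == 2)
    if (length(bad) == 0) break
    j <- net$nodes$id[bad[1]]
    ei <- which(net$edges$source == j | net$edges$target == j)
    if (length(ei) != 2) {  # self-loop at j: leave as is
      net$nodes$kind[bad[1]] <- "endpoint"
      next
    }
    orient <- function(i, endpoint_last) {
      g <- net$geometry[[i]]
      e <- net$edges[i, ]
      if (endpoint_last) {
        if (e$target == j) list(g = g, far = e$source)
        else list(g = g[rev(seq_len(nrow(g))), , drop = FALSE], far = e$target)
      } else {
        if (e$source == j) list(g = g, far = e$target)
        else list(g = g[rev(seq_len(nrow(g))), , drop = FALSE], far = e$source)
      }
    }
    a <- orient(ei[1], endpoint_last = TRUE)   # ... -> j
    b <- orient(ei[2], endpoint_last = FALSE)  # j -> ...
    geom <- rbind(a$g, b$g[-1, , drop = FALSE])
    len <- net$edges$arc_length[ei[1]] + net$edges$arc_length[ei[2]]
    net$edges$source[ei[1]] <- a$far
    net$edges$target[ei[1]] <- b$far
    net$edges$arc_length[ei[1]] <- len
    net$geometry[[ei[1]]] <- geom
    net$edges <- net$edges[-ei[2], , drop = FALSE]
    net$geometry <- net$geometry[-ei[2]]
    keep <- net$nodes$id != j
    net$nodes <- net$nodes[keep, , drop = FALSE]
    net <- recompute_degrees(net)
  }
  net$nodes$kind[net$nodes$kind == "junction" & net$nodes$degree == 1] <-
    "endpoint"
  drop <- net$nodes$kind != "lacunar" & net$nodes$degree == 0
  net$nodes <- net$nodes[!drop, , drop = FALSE]
  net$edges$id <- seq_len(nrow(net$edges))
  rownames(net$nodes) <- rownames(net$edges) <- NULL
  net
}

#' @export
print.lcn_ground_truth <- function(x, ...) {
  cat(sprintf("<lcn_ground_truth> %d lacunae, total length %.1f um (density %.4f um/um^3)\n",
              nrow(x$lacunae$centers), x$total_length,
              x$total_length / prod(x$spec$domain_size)))
  print(x$network)
  invisible(x)
}

#' Render a ground-truth network into a confocal-like image stack
#'
#' Voxels whose centre lies within the canalicular radius of an edge curve,
#' or inside a lacunar ellipsoid, receive foreground intensity; the stack is
#' then blurred with the Gaussian PSF, attenuated with depth, and corrupted
#' with noise, in that order. The unblurred, noise-free foreground mask is
#' returned as ground truth.
#'
#' @param gt an `lcn_ground_truth` (or a list with `network`, `lacunae`,
#'   `spec`).
#' @param imaging an [imaging_spec()].
#' @return A list of class `lcn_rendering`: `volume` (rhodamine
#'   [image_volume()]), `truth_mask` (integer array, 0 background,
#'   1 canalicular, 2 lacunar) and `truth_foreground` (logical array).
#' @export
render_volume <- function(gt, imaging = imaging_spec()) {
  stopifnot(inherits(imaging, "imaging_spec"))
  net <- gt$network
  spec <- gt$spec
  vs <- imaging$voxel_size
  dims <- as.integer(ceiling(spec$domain_size / vs))
  if (prod(dims) > imaging$max_voxels)
    stop(sprintf("voxel grid %d x %d x %d exceeds the memory budget of %g voxels",
                 dims[1], dims[2], dims[3], imaging$max_voxels))
  origin <- spec$domain_origin

  # canalicular capsules from edge polylines
  if (nrow(net$edges) > 0) {
    segs <- do.call(rbind, lapply(net$geometry, function(p) {
      if (nrow(p) < 2) return(NULL)
      cbind(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])
    }))
    mask_can <- cpp_rasterize_capsules(segs, spec$canalicular_radius,
                                       vs, origin, dims)
  } else {
    mask_can <- array(FALSE, dims)
  }

  truth <- array(0L, dims)
  truth[mask_can] <- 1L
  lac <- gt$lacunae
  if (!is.null(lac) && nrow(lac$centers) > 0) {
    xc <- vox_centers(dims[1], vs[1], origin[1])
    yc <- vox_centers(dims[2], vs[2], origin[2])
    zc <- vox_centers(dims[3], vs[3], origin[3])
    for (q in seq_len(nrow(lac$centers))) {
      c0 <- lac$centers[q, ]; s0 <- lac$semiaxes[q, ]
      ix <- which(abs(xc - c0[1]) <= s0[1])
      iy <- which(abs(yc - c0[2]) <= s0[2])
      iz <- which(abs(zc - c0[3]) <= s0[3])
      if (!length(ix) || !length(iy) || !length(iz)) next
      m <- outer(((xc[ix] - c0[1]) / s0[1])^2,
                 outer(((yc[iy] - c0[2]) / s0[2])^2,
                       ((zc[iz] - c0[3]) / s0[3])^2, "+"), "+") <= 1
      blk <- truth[ix, iy, iz, drop = FALSE]
      blk[m] <- 2L
      truth[ix, iy, iz] <- blk
    }
  }

  vol <- imaging$background_level + imaging$amplitude * (truth > 0)
  if (any(imaging$psf_sigma > 0))
    vol <- cpp_gauss3d(vol, dims, imaging$psf_sigma / vs)
  if (imaging$attenuation_per_um > 0) {
    zc <- vox_centers(dims[3], vs[3], 0)
    att <- (1 - imaging$attenuation_per_um)^zc
    vol <- sweep(vol, 3, att, `*`)
  }
  vol <- apply_noise(vol, imaging$noise)
  dim(vol) <- dims

  structure(list(volume = image_volume(vol, vs, channel = "rhodamine",
                                       origin = origin),
                 truth_mask = truth,
                 truth_foreground = truth > 0L),
            class = "lcn_rendering")
}

apply_noise <- function(vol, noise) {
  switch(noise$type,
         none = vol,
         gaussian = vol + rnorm(length(vol), sd = noise$read_sd),
         poisson = rpois(length(vol), pmax(vol, 0) * noise$photons) /
           noise$photons,
         poisson_gaussian = rpois(length(vol), pmax(vol, 0) * noise$photons) /
           noise$photons + rnorm(length(vol), sd = noise$read_sd))
}

#' Generate calcein label surfaces and the true region partition
#'
#' Two bright label surfaces cross the cortex along the transcortical (x)
#' axis, marking past mineralization fronts. Everything below the first
#' surface is newly formed endosteal bone, everything above the second is
#' newly formed periosteal bone, and the volume between is pre-existing
#' intercortical bone.
#'
#' @param domain_size box extent in um.
#' @param surface_spec list of two surfaces ordered along x; each is either
#'   a single number (plane at that x), a list with `x0`, `amplitude`,
#'   `period`, `axis` (2 = y, 3 = z), `phase` (a sinusoid), or a
#'   `function(y, z)` returning x in um.
#' @param voxel_size voxel edge lengths in um.
#' @param band_sigma Gaussian thickness of the rendered bands, um.
#' @param background,amplitude calcein channel intensities.
#' @param origin lower corner of the box in um.
#' @return list with `calcein` (an [image_volume()]) and `mask` (the true
#'   [region_mask()]).
#' @export
generate_calcein_surfaces <- function(domain_size, surface_spec,
                                      voxel_size = c(0.303, 0.303, 0.27),
                                      band_sigma = 0.45,
                                      background = 0.02, amplitude = 1,
                                      origin = c(0, 0, 0)) {
  stopifnot(length(surface_spec) == 2)
  dims <- as.integer(ceiling(domain_size / voxel_size))
  xc <- vox_centers(dims[1], voxel_size[1], origin[1])
  yc <- vox_centers(dims[2], voxel_size[2], origin[2])
  zc <- vox_centers(dims[3], voxel_size[3], origin[3])

  eval_surface <- function(sp) {
    if (is.function(sp)) return(outer(yc, zc, sp))
    if (is.numeric(sp) && length(sp) == 1)
      return(matrix(sp, dims[2], dims[3]))
    ax <- sp$axis %||% 2L
    per <- sp$period %||% Inf
    amp <- sp$amplitude %||% 0
    ph <- sp$phase %||% 0
    u <- if (ax == 2L) matrix(yc, dims[2], dims[3])
         else matrix(zc, dims[2], dims[3], byrow = TRUE)
    sp$x0 + amp * sin(2 * pi * u / per + ph)
  }
  S1 <- eval_surface(surface_spec[[1]])
  S2 <- eval_surface(surface_spec[[2]])
  if (any(S1 >= S2))
    stop("calcein surfaces intersect; they must be strictly ordered along x")

  # labels: x < S1 endosteal_new (3), x > S2 periosteal_new (1), else 2
  A1 <- outer(xc, S1, `-`)   # x - S1
  A2 <- outer(xc, S2, `-`)
  labels <- array(2L, dims)
  labels[A1 < 0] <- 3L
  labels[A2 > 0] <- 1L

  calcein <- background +
    amplitude * (exp(-A1^2 / (2 * band_sigma^2)) +
                 exp(-A2^2 / (2 * band_sigma^2)))
  dim(calcein) <- dims

  list(calcein = image_volume(calcein, voxel_size, channel = "calcein",
                              origin = origin),
       mask = region_mask(labels, list(S1, S2), voxel_size))
}
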