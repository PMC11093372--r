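# --- length accumulation helpers --------------------------------------------

# midpoints and lengths of the polyline segments of a network, each
# original segment subdivided to at most `step` so assignment to cells is
# fine-grained; subdividing (rather than resampling) keeps the summed
# length exactly equal to the polyline length
segment_samples <- function(net, step = 0.1) {
  if (nrow(net$edges) == 0)
    return(list(mid = matrix(numeric(0), 0, 3), len = numeric(0),
                edge = integer(0)))
  parts <- lapply(seq_along(net$geometry), function(e) {
    p <- net$geometry[[e]]
    if (is.null(dim(p)) || nrow(p) < 2) return(NULL)
    a <- p[-nrow(p), , drop = FALSE]
    b <- p[-1, , drop = FALSE]
    seglen <- sqrt(rowSums((b - a)^2))
    keep <- seglen > 0
    if (!any(keep)) return(NULL)
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
    seglen <- seglen[keep]
    k <- pmax(1L, as.integer(ceiling(seglen / step)))
    idx <- rep.int(seq_along(seglen), k)
    frac <- (sequence(k) - 0.5) / k[idx]
    list(mid = a[idx, , drop = FALSE] +
           frac * (b[idx, , drop = FALSE] - a[idx, , drop = FALSE]),
         len = seglen[idx] / k[idx],
         edge = rep.int(e, length(idx)))
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  list(mid = do.call(rbind, lapply(parts, `[[`, "mid")),
       len = unlist(lapply(parts, `[[`, "len")),
       edge = unlist(lapply(parts, `[[`, "edge")))
}

# true canalicular length per cubic cell (half-open cells [lower, upper))
cell_lengths <- function(net, L, origin, extent, step = 0.1) {
  nc <- pmax(1L, as.integer(ceiling(extent / L)))
  out <- array(0, nc)
  ss <- segment_samples(net, step)
  if (length(ss$len) == 0) return(out)
  ci <- floor(sweep(ss$mid, 2, origin) / L) + 1L
  ok <- ci[, 1] >= 1 & ci[, 1] <= nc[1] & ci[, 2] >= 1 & ci[, 2] <= nc[2] &
        ci[, 3] >= 1 & ci[, 3] <= nc[3]
  lin <- ci[ok, 1] + (ci[ok, 2] - 1L) * nc[1] +
    (ci[ok, 3] - 1L) * nc[1] * nc[2]
  acc <- rowsum(ss$len[ok], lin)
  out[as.integer(rownames(acc))] <- acc
  out
}

# network length clipped to a box (sampled at `step`)
clipped_length <- function(net, origin, extent, step = 0.1) {
  ss <- segment_samples(net, step)
  if (length(ss$len) == 0) return(0)
  keep <- ss$mid[, 1] >= origin[1] & ss$mid[, 1] < origin[1] + extent[1] &
          ss$mid[, 2] >= origin[2] & ss$mid[, 2] < origin[2] + extent[2] &
          ss$mid[, 3] >= origin[3] & ss$mid[, 3] < origin[3] + extent[3]
  sum(ss$len[keep])
}

# --- headline scalar statistics ----------------------------------------------

#' Canalicular network density (Can.Dn)
#'
#' Total canalicular length per unit pore-excluded bone volume,
#' `Can.Dn = sum(Can.Seg_i) / V_ROI`, in um/um^3.
#'
#' @param network an [lcn_network()].
#' @param roi_volume pore-excluded volume of interest in um^3 (see
#'   [roi_volume()]).
#' @param clip optional `list(origin, extent)` box (um); only length inside
#'   the box is counted.
#' @return density in um/um^3.
#' @export
can_dn <- function(network, roi_volume, clip = NULL) {
  if (roi_volume <= 0) stop("roi_volume must be positive")
  len <- if (is.null(clip)) sum(network$edges$arc_length)
         else clipped_length(network, clip$origin, clip$extent)
  len / roi_volume
}

#' Convert a canalicular density to kilometres per cubic centimetre
#'
#' 1 um/um^3 equals 10^3 km/cm^3, so a typical murine cortical density of
#' 0.202 um/um^3 corresponds to 202 km of network per cm^3 of tissue.
#'
#' @param d density in um/um^3 (>= 0).
#' @return density in km/cm^3.
#' @export
density_to_km_per_cm3 <- function(d) {
  if (any(d < 0)) stop("density must be non-negative")
  d * 1000
}

# --- sub-volume grid ---------------------------------------------------------

#' Map canalicular density onto a cubic sub-volume grid
#'
#' Partitions the volume of interest into cubic cells of edge `L`
#' (default 5 um, i.e. 125 um^3), accumulates the spline-sampled
#' canalicular length into the half-open cell containing each length
#' increment, computes each cell's pore-excluded volume V_ROI, and derives
#' the per-cell density Can.Dn = length / V_ROI. Cells are annotated with
#' the majority anatomical region.
#'
#' @param network an [lcn_network()].
#' @param mask optional [region_mask()]; provides V_ROI voxel counting and
#'   region labels. Without it, V_ROI is the geometric cell-box volume
#'   clipped to the domain.
#' @param binary optional pore-classified [binary_volume()] for excluding
#'   lacunar/vascular voxels from V_ROI.
#' @param L cell edge length in um.
#' @param origin lower corner of the grid in um.
#' @param extent grid extent in um; defaults to the mask extent or the
#'   network domain.
#' @param step spline sampling step in um.
#' @return An object of class `subvolume_grid` with a `cells` data.frame
#'   (`ix, iy, iz, length, v_roi, can_dn, region`).
#' @export
subvolume_map <- function(network, mask = NULL, binary = NULL, L = 5,
                          origin = c(0, 0, 0), extent = NULL, step = 0.1) {
  stopifnot(L > 0)
  if (!is.null(mask) && !is.null(binary) &&
      !identical(dim(mask$labels), dim(binary$foreground)))
    stop("region mask and binary volume have mismatched grid shapes")
  if (is.null(extent)) {
    extent <- if (!is.null(mask)) dim(mask$labels) * mask$voxel_size
              else network$domain
    if (is.null(extent)) stop("no grid extent available")
  }
  nc <- pmax(1L, as.integer(ceiling(extent / L)))
  len <- cell_lengths(network, L, origin, extent, step)

  ncell <- prod(nc)
  idx <- seq_len(ncell)
  ai <- arrayInd(idx, nc)
  region <- integer(ncell)

  if (!is.null(mask)) {
    dims <- dim(mask$labels)
    vs <- mask$voxel_size
    vv <- prod(vs)
    cellx <- pmin(nc[1], pmax(1L, floor(vox_centers(dims[1], vs[1]) / L) + 1L))
    celly <- pmin(nc[2], pmax(1L, floor(vox_centers(dims[2], vs[2]) / L) + 1L))
    cellz <- pmin(nc[3], pmax(1L, floor(vox_centers(dims[3], vs[3]) / L) + 1L))
    vidx <- which(mask$labels > 0L)
    vii <- arrayInd(vidx, dims)
    cid <- cellx[vii[, 1]] + (celly[vii[, 2]] - 1L) * nc[1] +
      (cellz[vii[, 3]] - 1L) * nc[1] * nc[2]
    lab <- mask$labels[vidx]
    pore <- if (!is.null(binary)) binary$class_labels[vidx] >= 2L
            else rep(FALSE, length(vidx))
    v_roi <- tabulate(cid[!pore], ncell) * vv
    cnt <- sapply(1:3, function(r) tabulate(cid[lab == r], ncell))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = ncell)
    any_bone <- rowSums(cnt) > 0
    region[any_bone] <- max.col(cnt[any_bone, , drop = FALSE],
                                ties.method = "first")
  } else {
    ov <- function(a) {
      loc <- origin[a] + (ai[, a] - 1) * L
      pmax(0, pmin(loc + L, origin[a] + extent[a]) - loc)
    }
    v_roi <- ov(1) * ov(2) * ov(3)
  }

  cells <- data.frame(ix = ai[, 1], iy = ai[, 2], iz = ai[, 3],
                      length = as.numeric(len),
                      v_roi = v_roi,
                      can_dn = ifelse(v_roi > 0, as.numeric(len) / v_roi, NA),
                      region = region)
  structure(list(origin = origin, L = L, dims = nc, cells = cells,
                 mask = !is.null(mask)),
            class = "subvolume_grid")
}

#' @export
print.subvolume_grid <- function(x, ...) {
  ok <- x$cells$v_roi > 0
  cat(sprintf("<subvolume_grid> %d x %d x %d cells, edge %.1f um (%.0f um^3)\n",
              x$dims[1], x$dims[2], x$dims[3], x$L, x$L^3))
  cat(sprintf("  Can.Dn over %d cells: mean %.4f, median %.4f, sd %.4f um/um^3\n",
              sum(ok), mean(x$cells$can_dn[ok]), median(x$cells$can_dn[ok]),
              sd(x$cells$can_dn[ok])))
  invisible(x)
}

#' @export
plot.subvolume_grid <- function(x, z = NULL, ...) {
  cc <- x$cells
  if (is.null(z)) {
    # depth-averaged density map
    m <- with(cc, tapply(ifelse(is.na(can_dn), 0, can_dn),
                         list(ix, iy), mean))
  } else {
    sel <- cc$iz == z
    m <- with(cc[sel, ], tapply(ifelse(is.na(can_dn), 0, can_dn),
                                list(ix, iy), mean))
  }
  graphics::image(seq_len(nrow(m)) * x$L, seq_len(ncol(m)) * x$L, m,
                  xlab = "x (um)", ylab = "y (um)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Sub-volume size convergence scan
#'
#' Recomputes the sub-volume density map for a range of cell edge lengths
#' (1-20 um by default) and summarizes the per-cell Can.Dn distribution at
#' each size, to check that the working cell size sits on the stable
#' plateau.
#'
#' @param network an [lcn_network()].
#' @param mask,binary,origin,extent,step as in [subvolume_map()].
#' @param L_values cell edge lengths to test, um.
#' @return data.frame with one row per L: cell count, mean, SD, median,
#'   quartiles of Can.Dn, and the total accumulated length.
#' @export
convergence_scan <- function(network, mask = NULL, binary = NULL,
                             L_values = 1:20, origin = c(0, 0, 0),
                             extent = NULL, step = 0.1) {
  stopifnot(all(L_values > 0))
  rows <- lapply(L_values, function(L) {
    g <- subvolume_map(network, mask, binary, L = L, origin = origin,
                       extent = extent, step = step)
    ok <- g$cells$v_roi > 0
    d <- g$cells$can_dn[ok]
    data.frame(L = L, n_cells = sum(ok), mean = mean(d), sd = sd(d),
               median = median(d),
               q25 = quantile(d, 0.25, names = FALSE),
               q75 = quantile(d, 0.75, names = FALSE),
               total_length = sum(g$cells$length))
  })
  do.call(rbind, rows)
}

# --- per-edge / per-node scoped statistics -----------------------------------

# centre of mass of each edge (length-weighted over the sampled polyline)
edge_com <- function(net, step = 0.1) {
  t(vapply(net$geometry, function(p) {
    q <- resample_polyline(p, step)
    if (nrow(q) < 2) return(q[1, ])
    a <- q[-nrow(q), , drop = FALSE]; b <- q[-1, , drop = FALSE]
    w <- sqrt(rowSums((b - a)^2))
    colSums((a + b) / 2 * w) / sum(w)
  }, numeric(3)))
}

# resolve a scope argument to an edge (or node) selection
resolve_scope <- function(pos, scope) {
  if (is.null(scope)) return(rep(TRUE, nrow(pos)))
  if (is.logical(scope) || is.numeric(scope)) {
    sel <- rep(FALSE, nrow(pos))
    sel[scope] <- TRUE
    return(sel)
  }
  if (!is.null(scope$cell)) {
    g <- scope$grid
    ci <- floor(sweep(pos, 2, g$origin) / g$L) + 1L
    return(ci[, 1] == scope$cell[1] & ci[, 2] == scope$cell[2] &
           ci[, 3] == scope$cell[3])
  }
  if (!is.null(scope$region)) {
    mask <- scope$mask
    dims <- dim(mask$labels)
    vi <- pmin(matrix(rep(dims, each = nrow(pos)), ncol = 3),
               pmax(1L, floor(sweep(pos, 2, mask$voxel_size, `/`)) + 1L))
    lab <- mask$labels[cbind(vi[, 1], vi[, 2], vi[, 3])]
    return(lab == region_code(scope$region))
  }
  stop("unrecognized scope")
}

#' Canalicular length (Can.Ln) distribution
#'
#' Histogram of edge arc lengths in 1 um bins `[k, k+1)`, as percentages.
#' When scoped to a sub-volume cell, an edge belongs to the cell containing
#' its centre of mass and contributes its whole length there (this is
#' deliberately different from the density accumulation, which clips edge
#' length across cells). Canaliculi longer than `long_threshold` (5 um)
#' are "long"; both the count-weighted and the length-weighted long
#' fraction are reported.
#'
#' @param network an [lcn_network()].
#' @param scope `NULL` (all edges), an edge index vector, a
#'   `list(grid =, cell = c(ix, iy, iz))`, or a
#'   `list(mask =, region = )`; cell/region scoping uses edge centres of
#'   mass.
#' @param bin_width histogram bin width, um.
#' @param long_threshold long-canaliculus threshold, um.
#' @return An object of class `canln_histogram`.
#' @export
length_histogram <- function(network, scope = NULL, bin_width = 1,
                             long_threshold = 5) {
  lens <- network$edges$arc_length
  sel <- if (is.null(scope)) rep(TRUE, length(lens))
         else resolve_scope(edge_com(network), scope)
  lens <- lens[sel]
  if (length(lens) == 0) {
    return(structure(list(breaks = numeric(0), percent = numeric(0),
                          counts = integer(0), n = 0L,
                          long_fraction_count = NA_real_,
                          long_fraction_length = NA_real_,
                          bin_width = bin_width,
                          long_threshold = long_threshold, empty = TRUE),
                     class = "canln_histogram"))
  }
  nb <- floor(max(lens) / bin_width) + 1L
  bins <- floor(lens / bin_width) + 1L
  counts <- tabulate(bins, nb)
  structure(list(breaks = (seq_len(nb + 1L) - 1L) * bin_width,
                 percent = 100 * counts / sum(counts),
                 counts = counts, n = length(lens),
                 long_fraction_count = mean(lens > long_threshold),
                 long_fraction_length = sum(lens[lens > long_threshold]) /
                   sum(lens),
                 bin_width = bin_width, long_threshold = long_threshold,
                 empty = FALSE),
            class = "canln_histogram")
}

#' @export
print.canln_histogram <- function(x, ...) {
  if (x$empty) { cat("<canln_histogram> empty scope\n"); return(invisible(x)) }
  cat(sprintf("<canln_histogram> %d canaliculi, %.1f%% longer than %g um (length-weighted %.1f%%)\n",
              x$n, 100 * x$long_fraction_count, x$long_threshold,
              100 * x$long_fraction_length))
  invisible(x)
}

#' Degree-of-connectivity (DoC) distribution
#'
#' Percentage distribution of node degrees over junction nodes (a node
#' needs at least three intersecting canaliculi to count as a junction;
#' lacunar and endpoint nodes are excluded). The tree-like fraction is the
#' fraction of junctions with the minimum degree 3.
#'
#' @param network an [lcn_network()].
#' @param scope as in [length_histogram()], applied to node positions.
#' @return An object of class `doc_histogram`.
#' @export
doc_histogram <- function(network, scope = NULL) {
  jn <- network$nodes[network$nodes$kind == "junction" &
                      network$nodes$degree >= 3, , drop = FALSE]
  sel <- if (is.null(scope)) rep(TRUE, nrow(jn))
         else resolve_scope(as.matrix(jn[, c("x", "y", "z")]), scope)
  deg <- jn$degree[sel]
  if (length(deg) == 0) {
    return(structure(list(degrees = integer(0), percent = numeric(0),
                          counts = integer(0), n = 0L,
                          tree_like_fraction = NA_real_, empty = TRUE),
                     class = "doc_histogram"))
  }
  tab <- table(deg)
  structure(list(degrees = as.integer(names(tab)),
                 percent = 100 * as.numeric(tab) / length(deg),
                 counts = as.integer(tab), n = length(deg),
                 tree_like_fraction = mean(deg == 3), empty = FALSE),
            class = "doc_histogram")
}

#' @export
print.doc_histogram <- function(x, ...) {
  if (x$empty) { cat("<doc_histogram> no junction nodes in scope\n"); return(invisible(x)) }
  cat(sprintf("<doc_histogram> %d junctions, tree-like (DoC = 3) fraction %.3f\n",
              x$n, x$tree_like_fraction))
  invisible(x)
}

# --- cortical profile --------------------------------------------------------

#' Transcortical density profile
#'
#' Averages the sub-volume densities over the longitudinal and depth axes
#' for each transcortical column of cells, places columns on a normalized
#' axis running from 0 at the endosteal boundary of the bone to 1 at the
#' periosteal boundary, resamples to a fixed number of bins, and reports
#' the calcein surface positions on the same normalized axis.
#'
#' @param grid a [subvolume_map()] result.
#' @param mask the [region_mask()] used to build it (supplies the bone
#'   extent and the calcein boundary positions).
#' @param axis_spec list naming the `transcortical` axis (default 1 = x);
#'   the remaining axes are averaged over.
#' @param nbins number of bins of the resampled profile.
#' @return An object of class `cortical_profile` with a `profile`
#'   data.frame (`position, mean, sd`) and normalized calcein `boundaries`.
#' @export
cortical_profile <- function(grid, mask, axis_spec = list(transcortical = 1),
                             nbins = 50) {
  stopifnot(inherits(grid, "subvolume_grid"))
  if (!inherits(mask, "region_mask") ||
      length(mask$boundary_positions) < 2)
    stop("region mask with both calcein surfaces required")
  ta <- axis_spec$transcortical %||% 1
  cc <- grid$cells[grid$cells$v_roi > 0, ]
  col <- cc[[c("ix", "iy", "iz")[ta]]]
  mu <- tapply(cc$can_dn, col, mean)
  sdev <- tapply(cc$can_dn, col, function(v) if (length(v) > 1) sd(v) else 0)
  xs <- grid$origin[ta] + (as.numeric(names(mu)) - 0.5) * grid$L

  # bone extent along the transcortical axis, from the mask
  dims <- dim(mask$labels)
  bone <- which(mask$labels > 0L)
  bi <- arrayInd(bone, dims)[, ta]
  x0 <- (min(bi) - 1) * mask$voxel_size[ta]
  x1 <- max(bi) * mask$voxel_size[ta]
  pos <- (xs - x0) / (x1 - x0)

  grid_pos <- seq(0, 1, length.out = nbins)
  prof <- data.frame(position = grid_pos,
                     mean = approx(pos, mu, grid_pos, rule = 2)$y,
                     sd = approx(pos, sdev, grid_pos, rule = 2)$y)
  bnd <- vapply(mask$boundary_positions,
                function(s) (mean(s) - x0) / (x1 - x0), numeric(1))
  structure(list(profile = prof, boundaries = bnd,
                 bone_extent = c(x0, x1)),
            class = "cortical_profile")
}

#' @export
print.cortical_profile <- function(x, ...) {
  cat(sprintf("<cortical_profile> %d bins, Can.Dn %.4f-%.4f um/um^3, calcein surfaces at %.2f and %.2f\n",
              nrow(x$profile), min(x$profile$mean), max(x$profile$mean),
              x$boundaries[1], x$boundaries[2]))
  invisible(x)
}

#' @export
plot.cortical_profile <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$position, p$mean, type = "l", lwd = 2,
                 ylim = range(c(p$mean - p$sd, p$mean + p$sd)),
                 xlab = "normalized transcortical position (endosteal -> periosteal)",
                 ylab = "Can.Dn (um/um^3)", ...)
  graphics::polygon(c(p$position, rev(p$position)),
                    c(p$mean - p$sd, rev(p$mean + p$sd)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::abline(v = x$boundaries, col = "darkgreen", lty = 2)
  invisible(x)
}

# --- density vs connectivity regressions -------------------------------------

# per-cell edge statistics (centre-of-mass assignment)
cell_edge_stats <- function(network, grid, long_threshold = 5) {
  if (nrow(network$edges) == 0)
    return(data.frame(cell = integer(0)))
  com <- edge_com(network)
  ci <- floor(sweep(com, 2, grid$origin) / grid$L) + 1L
  nc <- grid$dims
  ok <- ci[, 1] >= 1 & ci[, 1] <= nc[1] & ci[, 2] >= 1 & ci[, 2] <= nc[2] &
        ci[, 3] >= 1 & ci[, 3] <= nc[3]
  lin <- ci[ok, 1] + (ci[ok, 2] - 1L) * nc[1] + (ci[ok, 3] - 1L) * nc[1] * nc[2]
  lens <- network$edges$arc_length[ok]
  long <- lens > long_threshold
  n <- tabulate(lin, prod(nc))
  nlong <- tabulate(lin[long], prod(nc))
  ltot <- as.numeric(rowsum_full(lens, lin, prod(nc)))
  llong <- as.numeric(rowsum_full(lens[long], lin[long], prod(nc)))
  data.frame(cell = seq_len(prod(nc)), n_edges = n,
             pct_long_count = ifelse(n > 0, 100 * nlong / n, NA),
             pct_long_length = ifelse(ltot > 0, 100 * llong / ltot, NA))
}

rowsum_full <- function(x, g, nbins) {
  out <- numeric(nbins)
  if (length(x)) {
    acc <- rowsum(x, g)
    out[as.integer(rownames(acc))] <- acc
  }
  out
}

# per-cell junction statistics
cell_junction_stats <- function(network, grid) {
  jn <- network$nodes[network$nodes$kind == "junction" &
                      network$nodes$degree >= 3, , drop = FALSE]
  nc <- grid$dims
  if (nrow(jn) == 0)
    return(data.frame(cell = seq_len(prod(nc)), n_junctions = 0,
                      pct_tree = NA))
  ci <- floor(sweep(as.matrix(jn[, c("x", "y", "z")]), 2, grid$origin) /
                grid$L) + 1L
  ok <- ci[, 1] >= 1 & ci[, 1] <= nc[1] & ci[, 2] >= 1 & ci[, 2] <= nc[2] &
        ci[, 3] >= 1 & ci[, 3] <= nc[3]
  lin <- ci[ok, 1] + (ci[ok, 2] - 1L) * nc[1] + (ci[ok, 3] - 1L) * nc[1] * nc[2]
  tree <- jn$degree[ok] == 3
  n <- tabulate(lin, prod(nc))
  ntree <- tabulate(lin[tree], prod(nc))
  data.frame(cell = seq_len(prod(nc)), n_junctions = n,
             pct_tree = ifelse(n > 0, 100 * ntree / n, NA))
}

ols_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3)
    stop("fewer than 3 eligible sub-volumes for the regression")
  fit <- lm(y[ok] ~ x[ok])
  r2 <- suppressWarnings(summary(fit)$r.squared)   # exact fits are fine
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = sum(ok))
}

#' Density vs connectivity regressions over sub-volumes
#'
#' Ordinary least-squares fits of the percentage of long canaliculi and of
#' tree-like (DoC = 3) junctions against the sub-volume density Can.Dn.
#' Cells need at least one assigned edge (respectively one junction) to
#' enter the fit. Negative slopes indicate that dense network regions are
#' built from shorter, slightly more branched canaliculi.
#'
#' @param grid a [subvolume_map()] result.
#' @param network the [lcn_network()] the grid was computed from.
#' @param long_threshold long-canaliculus threshold, um.
#' @param long_weighting `"length"` (default) or `"count"` weighting of
#'   the long-canaliculi percentage.
#' @return list with `long` and `tree` fits (`slope`, `intercept`,
#'   `r_squared`, `n`) of class `lcn_regressions`.
#' @export
density_connectivity_regression <- function(grid, network,
                                            long_threshold = 5,
                                            long_weighting = c("length",
                                                               "count")) {
  long_weighting <- match.arg(long_weighting)
  es <- cell_edge_stats(network, grid, long_threshold)
  js <- cell_junction_stats(network, grid)
  dn <- grid$cells$can_dn
  ycol <- if (long_weighting == "length") es$pct_long_length
          else es$pct_long_count
  long_ok <- es$n_edges >= 1 & grid$cells$v_roi > 0
  tree_ok <- js$n_junctions >= 1 & grid$cells$v_roi > 0
  structure(list(
    long = ols_fit(dn[long_ok], ycol[long_ok]),
    tree = ols_fit(dn[tree_ok], js$pct_tree[tree_ok]),
    long_weighting = long_weighting),
    class = "lcn_regressions")
}

#' @export
print.lcn_regressions <- function(x, ...) {
  cat(sprintf("%%long (%s-weighted) vs Can.Dn: slope %.3f, intercept %.2f, R^2 %.3f (n = %d)\n",
              x$long_weighting, x$long$slope, x$long$intercept,
              x$long$r_squared, x$long$n))
  cat(sprintf("%%tree-like vs Can.Dn:          slope %.3f, intercept %.2f, R^2 %.3f (n = %d)\n",
              x$tree$slope, x$tree$intercept, x$tree$r_squared, x$tree$n))
  invisible(x)
}
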