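#' Topology-preserving 3D skeletonization
#'
#' Reduces the canalicular foreground to a one-voxel-wide, 26-connected
#' medial curve representation by iteratively deleting simple border
#' voxels (surface peeling). Deleting only simple points guarantees that
#' connected components and loops are preserved; curve end points are
#' protected so canaliculi keep their full extent.
#'
#' @param binary a [binary_volume()] (the canalicular class is used) or a
#'   3D logical array.
#' @return 3D logical array of skeleton voxels.
#' @export
skeletonize <- function(binary) {
  mask <- if (inherits(binary, "binary_volume")) {
    binary$class_labels == 1L
  } else {
    stopifnot(is.array(binary), is.logical(binary))
    binary
  }
  if (!any(mask)) return(array(FALSE, dim(mask)))
  cpp_thin3d(mask, dim(mask))
}

NB26 <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
NB26 <- NB26[rowSums(abs(NB26)) > 0, ]

# logical dilation by one voxel (26-connectivity)
dilate26 <- function(mask) mask | (cpp_count_neighbors(mask, dim(mask)) > 0L)

#' Build the chain graph of a skeleton
#'
#' Classifies skeleton voxels by their 26-neighbour count (1 = end,
#' 2 = chain, >= 3 = branch), collapses branch-voxel clusters within the
#' merge radius into single junction nodes, maps skeleton voxels adjacent
#' to a lacunar component onto that lacuna's node, and traces the simple
#' voxel chains between terminals. Free-ending chains shorter than the
#' pruning threshold are removed as skeletonization spurs.
#'
#' @param skeleton 3D logical array from [skeletonize()].
#' @param lacunar_mask optional 3D logical array of lacunar voxels; each
#'   connected lacunar component becomes one lacunar node at its centroid.
#' @param voxel_size voxel edge lengths in um.
#' @param merge_radius branch voxels within this many voxels collapse to
#'   one junction node.
#' @param prune_length free-ending chains shorter than this (um) are
#'   discarded.
#' @param foreground optional 3D logical array of the canalicular
#'   foreground. When given, free chain ends are extended along their
#'   outgoing direction while they remain inside the foreground, which
#'   compensates the tip retraction (about one tube radius per free end)
#'   that curve thinning inevitably produces at rounded tube caps.
#' @param tip_extension maximum tip extension in um.
#' @return An object of class `skeleton_graph`: nodes (id, position, kind)
#'   and chains (ordered voxel index matrices with terminal node ids).
#' @export
build_chain_graph <- function(skeleton, lacunar_mask = NULL,
                              voxel_size = c(1, 1, 1),
                              merge_radius = 1, prune_length = 1.0,
                              foreground = NULL, tip_extension = 2.0) {
  dims <- dim(skeleton)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  idx <- which(skeleton)
  n <- length(idx)
  empty <- structure(list(nodes = data.frame(id = integer(), x = numeric(),
                                             y = numeric(), z = numeric(),
                                             kind = character(),
                                             stringsAsFactors = FALSE),
                          chains = list(), voxel_size = voxel_size,
                          dims = dims),
                     class = "skeleton_graph")
  if (n == 0) return(empty)
  ii <- arrayInd(idx, dims)

  # adjacency among skeleton voxels
  vlist <- integer(0); wlist <- integer(0)
  for (o in seq_len(nrow(NB26))) {
    di <- NB26[o, 1]; dj <- NB26[o, 2]; dk <- NB26[o, 3]
    ok <- ii[, 1] + di >= 1 & ii[, 1] + di <= nx &
          ii[, 2] + dj >= 1 & ii[, 2] + dj <= ny &
          ii[, 3] + dk >= 1 & ii[, 3] + dk <= nz
    nb <- idx[ok] + di + dj * nx + dk * nx * ny
    m <- match(nb, idx)
    hit <- !is.na(m)
    vlist <- c(vlist, which(ok)[hit])
    wlist <- c(wlist, m[hit])
  }
  adj <- split(wlist, factor(vlist, levels = seq_len(n)))
  deg <- lengths(adj)

  # lacunar contact voxels and lacuna nodes
  contact_lac <- integer(n)     # 0 = not a contact voxel, else lacuna comp
  lac_nodes <- NULL
  if (!is.null(lacunar_mask) && any(lacunar_mask)) {
    lablac <- cpp_label_components(lacunar_mask, dims, 26L)
    ncomp <- max(lablac)
    lidx <- which(lacunar_mask)
    lii <- arrayInd(lidx, dims)
    lcomp <- lablac[lidx]
    cx <- tapply((lii[, 1] - 0.5) * voxel_size[1], lcomp, mean)
    cy <- tapply((lii[, 2] - 0.5) * voxel_size[2], lcomp, mean)
    cz <- tapply((lii[, 3] - 0.5) * voxel_size[3], lcomp, mean)
    lac_nodes <- data.frame(comp = as.integer(names(cx)),
                            x = as.numeric(cx), y = as.numeric(cy),
                            z = as.numeric(cz))
    near <- dilate26(lacunar_mask)
    touching <- which(near[idx])
    for (v in touching) {
      p <- ii[v, ]
      for (o in seq_len(nrow(NB26))) {
        q <- p + NB26[o, ]
        if (any(q < 1) || q[1] > nx || q[2] > ny || q[3] > nz) next
        lc <- lablac[q[1], q[2], q[3]]
        if (lc > 0L) { contact_lac[v] <- lc; break }
      }
    }
  }

  # branch clusters (merge radius realized by dilation before labelling)
  is_branch <- deg >= 3 & contact_lac == 0L
  cluster_of <- integer(n)
  clus_nodes <- NULL
  if (any(is_branch)) {
    bmask <- array(FALSE, dims)
    bmask[idx[is_branch]] <- TRUE
    dm <- bmask
    for (r in seq_len(max(0, merge_radius - 1))) dm <- dilate26(dm)
    labb <- cpp_label_components(dm, dims, 26L)
    cluster_of[is_branch] <- labb[idx[is_branch]]
    bsel <- which(is_branch)
    bcl <- cluster_of[bsel]
    cx <- tapply((ii[bsel, 1] - 0.5) * voxel_size[1], bcl, mean)
    cy <- tapply((ii[bsel, 2] - 0.5) * voxel_size[2], bcl, mean)
    cz <- tapply((ii[bsel, 3] - 0.5) * voxel_size[3], bcl, mean)
    clus_nodes <- data.frame(comp = as.integer(names(cx)),
                             x = as.numeric(cx), y = as.numeric(cy),
                             z = as.numeric(cz))
  }

  # node table ---------------------------------------------------------------
  nid <- 0L
  nx_ <- numeric(0); ny_ <- numeric(0); nz_ <- numeric(0); nk_ <- character(0)
  add_node <- function(pos, kind) {
    nid <<- nid + 1L
    nx_[nid] <<- pos[1]; ny_[nid] <<- pos[2]; nz_[nid] <<- pos[3]
    nk_[nid] <<- kind
    nid
  }
  lac_id <- integer(0)
  if (!is.null(lac_nodes))
    lac_id <- vapply(seq_len(nrow(lac_nodes)), function(q)
      add_node(c(lac_nodes$x[q], lac_nodes$y[q], lac_nodes$z[q]), "lacunar"),
      integer(1))
  clus_id <- integer(0)
  if (!is.null(clus_nodes))
    clus_id <- vapply(seq_len(nrow(clus_nodes)), function(q)
      add_node(c(clus_nodes$x[q], clus_nodes$y[q], clus_nodes$z[q]),
               "junction"), integer(1))
  node_of_cluster <- function(cl) clus_id[match(cl, clus_nodes$comp)]
  node_of_lacuna <- function(lc) lac_id[match(lc, lac_nodes$comp)]
  vox_pos <- function(v) (ii[v, ] - 0.5) * voxel_size

  # clusters adjacent to each traceable voxel
  traceable <- cluster_of == 0L
  adj_clusters <- function(v) unique(cluster_of[adj[[v]]][cluster_of[adj[[v]]] > 0L])

  visited <- !traceable   # cluster voxels never traced
  chains <- list()
  add_chain <- function(vox, a, b) chains[[length(chains) + 1L]] <<-
    list(vox = ii[vox, , drop = FALSE], a = a, b = b)

  trace_from <- function(s, start_node, start_cluster) {
    path <- integer(512); np <- 0L
    cur <- s
    repeat {
      np <- np + 1L
      if (np > length(path)) path <- c(path, integer(length(path)))
      path[np] <- cur
      visited[cur] <<- TRUE
      # stop at a lacunar contact (edge ends at the lacuna surface)
      if (contact_lac[cur] > 0L && np > 1L)
        return(list(path = path[seq_len(np)],
                    end = node_of_lacuna(contact_lac[cur])))
      cl <- adj_clusters(cur)
      if (np == 1L && !is.na(start_cluster))
        cl <- setdiff(cl, start_cluster)
      if (length(cl) > 0L)
        return(list(path = path[seq_len(np)], end = node_of_cluster(cl[1]),
                    end_cluster = cl[1]))
      nxt <- adj[[cur]]
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0L)
        return(list(path = path[seq_len(np)], end = NA_integer_))
      cur <- nxt[1]
    }
  }

  finish_chain <- function(tr, start_node) {
    endn <- tr$end
    if (is.na(endn)) {
      v <- tr$path[length(tr$path)]
      if (contact_lac[v] > 0L) endn <- node_of_lacuna(contact_lac[v])
      else endn <- add_node(vox_pos(v), "endpoint")
    }
    add_chain(tr$path, start_node, endn)
  }

  # 1) chains leaving branch clusters
  if (any(is_branch)) {
    for (b in which(is_branch)) {
      for (w in adj[[b]]) {
        if (!traceable[w] || visited[w]) next
        cl0 <- cluster_of[b]
        tr <- trace_from(w, node_of_cluster(cl0), cl0)
        finish_chain(tr, node_of_cluster(cl0))
      }
    }
  }
  # 2) chains starting at free ends / contact voxels
  order_start <- which(traceable & !visited &
                       (deg <= 1L | contact_lac > 0L))
  for (s in order_start) {
    if (visited[s]) next
    start_node <- if (contact_lac[s] > 0L) node_of_lacuna(contact_lac[s])
                  else add_node(vox_pos(s), "endpoint")
    tr <- trace_from(s, start_node, NA)
    finish_chain(tr, start_node)
  }
  # 3) leftover pure cycles: insert a node at the smallest remaining voxel
  repeat {
    left <- which(traceable & !visited)
    if (length(left) == 0L) break
    s <- left[1]
    start_node <- add_node(vox_pos(s), "junction")
    tr <- trace_from(s, start_node, NA)
    endn <- tr$end
    if (is.na(endn)) endn <- start_node   # closed loop -> self edge
    add_chain(tr$path, start_node, endn)
  }

  nodes <- data.frame(id = seq_len(nid), x = nx_, y = ny_, z = nz_,
                      kind = nk_, stringsAsFactors = FALSE)

  # prune free-ending spurs
  if (prune_length > 0 && length(chains) > 0) {
    keep <- vapply(chains, function(ch) {
      free_a <- nodes$kind[ch$a] == "endpoint"
      free_b <- nodes$kind[ch$b] == "endpoint"
      if (!free_a && !free_b) return(TRUE)
      p <- sweep(ch$vox - 0.5, 2, voxel_size, `*`)
      polyline_length(p) >= prune_length
    }, logical(1))
    chains <- chains[keep]
  }

  # extend free tips through the remaining foreground cap. The foreground
  # run beyond a retracted tip is roughly (retraction + cap radius), and
  # the true curve end sits one cap radius short of the foreground
  # boundary, so the tip is advanced by (run - tip_margin).
  if (!is.null(foreground) && tip_extension > 0 && length(chains) > 0) {
    tip_margin <- 0.4
    extend <- function(vox, at_end) {
      npv <- nrow(vox)
      if (npv < 2) return(vox)
      tipi <- if (at_end) npv else 1L
      refi <- if (at_end) max(1L, npv - 3L) else min(npv, 4L)
      tip <- (vox[tipi, ] - 0.5) * voxel_size
      ref <- (vox[refi, ] - 0.5) * voxel_size
      d <- tip - ref
      nrm <- sqrt(sum(d * d))
      if (nrm < 1e-9) return(vox)
      d <- d / nrm
      run <- 0
      for (t in seq(0.1, tip_extension, by = 0.1)) {
        p <- tip + t * d
        vv <- floor(p / voxel_size) + 1L
        if (any(vv < 1) || any(vv > dims)) break
        if (!foreground[vv[1], vv[2], vv[3]]) break
        run <- t
      }
      ext <- run - tip_margin
      if (ext < 0.1) return(vox)
      best <- (tip + ext * d) / voxel_size + 0.5   # fractional voxel coords
      if (at_end) rbind(vox, best) else rbind(best, vox)
    }
    for (i in seq_along(chains)) {
      ch <- chains[[i]]
      if (nodes$kind[ch$b] == "endpoint") ch$vox <- extend(ch$vox, TRUE)
      if (nodes$kind[ch$a] == "endpoint") ch$vox <- extend(ch$vox, FALSE)
      chains[[i]] <- ch
    }
  }

  structure(list(nodes = nodes, chains = chains, voxel_size = voxel_size,
                 dims = dims),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d chains\n",
              nrow(x$nodes), length(x$chains)))
  invisible(x)
}

# moving-average smoothing of chain coordinates; end points preserved,
# window shrinking towards the ends
smooth_chain <- function(p, k) {
  np <- nrow(p)
  if (k < 3 || np < 5) return(p)
  half <- k %/% 2
  out <- p
  for (t in 2:(np - 1)) {
    h <- min(half, t - 1, np - t)
    out[t, ] <- colMeans(p[(t - h):(t + h), , drop = FALSE])
  }
  out
}

#' Fit cubic splines to skeleton chains
#'
#' Each voxel chain is lightly smoothed (moving average, window
#' `smoothing` um, end points fixed), then interpolated per coordinate by a
#' natural cubic spline over the cumulative chordal parameter. Arc length
#' (Can.Ln) is measured on a dense resampling of the spline. Chain
#' terminals attach to their node positions; edges ending on a lacuna stop
#' at the lacunar surface contact, so lacunar volume does not inflate
#' canalicular length. Degree-2 junctions left over from pruning are
#' dissolved and degrees recomputed on the final graph.
#'
#' @param graph a [build_chain_graph()] result.
#' @param smoothing moving-average window in um (0 disables smoothing).
#' @param sample_step spline sampling step in um for arc length and the
#'   stored polyline.
#' @return An [lcn_network()].
#' @export
fit_splines <- function(graph, smoothing = 1.0, sample_step = 0.1) {
  stopifnot(inherits(graph, "skeleton_graph"))
  vs <- graph$voxel_size
  nodes <- graph$nodes
  k <- if (smoothing > 0) max(3L, 2L * floor(smoothing / (2 * mean(vs))) + 1L)
       else 0L

  e_src <- integer(0); e_dst <- integer(0); e_len <- numeric(0)
  geom <- list()
  for (ch in graph$chains) {
    p <- sweep(ch$vox - 0.5, 2, vs, `*`)
    # attach junction terminals at the node centroid
    if (nodes$kind[ch$a] == "junction")
      p <- rbind(c(nodes$x[ch$a], nodes$y[ch$a], nodes$z[ch$a]), p)
    if (nodes$kind[ch$b] == "junction")
      p <- rbind(p, c(nodes$x[ch$b], nodes$y[ch$b], nodes$z[ch$b]))
    if (nrow(p) < 2) next
    p <- p[c(TRUE, rowSums(abs(diff(p))) > 1e-12), , drop = FALSE]
    if (nrow(p) < 2) next
    if (k >= 3) p <- smooth_chain(p, k)
    t0 <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    L0 <- t0[length(t0)]
    if (L0 <= 0) next
    if (nrow(p) >= 3) {
      m <- max(3L, as.integer(ceiling(L0 / sample_step)) + 1L)
      tt <- seq(0, L0, length.out = m)
      pp <- cbind(stats::splinefun(t0, p[, 1], method = "natural")(tt),
                  stats::splinefun(t0, p[, 2], method = "natural")(tt),
                  stats::splinefun(t0, p[, 3], method = "natural")(tt))
    } else {
      pp <- p
    }
    e_src[length(e_src) + 1L] <- ch$a
    e_dst[length(e_dst) + 1L] <- ch$b
    e_len[length(e_len) + 1L] <- polyline_length(pp)
    geom[[length(geom) + 1L]] <- pp
    # keep endpoint node positions on the (possibly tip-extended) curve
    if (nodes$kind[ch$a] == "endpoint")
      nodes[ch$a, c("x", "y", "z")] <- pp[1, ]
    if (nodes$kind[ch$b] == "endpoint")
      nodes[ch$b, c("x", "y", "z")] <- pp[nrow(pp), ]
  }

  nodes$degree <- 0L
  edges <- data.frame(id = seq_along(e_src), source = e_src, target = e_dst,
                      arc_length = e_len, stringsAsFactors = FALSE)
  net <- lcn_network(nodes, edges, geom, domain = graph$dims * vs)
  cleanup_network(net)
}

#' Extract the spatial network from a segmented volume
#'
#' Convenience wrapper chaining [skeletonize()], [build_chain_graph()] and
#' [fit_splines()].
#'
#' @param binary a pore-classified [binary_volume()].
#' @param merge_radius,prune_length,smoothing,sample_step passed through.
#' @return An [lcn_network()].
#' @export
extract_network <- function(binary, merge_radius = 1, prune_length = 1.0,
                            smoothing = 1.0, sample_step = 0.1) {
  stopifnot(inherits(binary, "binary_volume"))
  skel <- skeletonize(binary)
  lac <- binary$class_labels == 2L
  graph <- build_chain_graph(skel, lacunar_mask = if (any(lac)) lac else NULL,
                             voxel_size = binary$voxel_size,
                             merge_radius = merge_radius,
                             prune_length = prune_length,
                             foreground = binary$class_labels == 1L)
  fit_splines(graph, smoothing = smoothing, sample_step = sample_step)
}
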