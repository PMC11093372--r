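# --- image stacks ------------------------------------------------------------

#' Write an image volume as a multi-page TIFF
#'
#' One page per z-slice, 32-bit float. Voxel sizes and channel are stored
#' in a JSON sidecar (`<path>.meta.json`), the metadata carrier used by
#' [read_image_stack()].
#'
#' @param volume an [image_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$voxels
  # TIFF stores values in [0, 1]; rescale and keep the mapping in the sidecar
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  v <- (v - lo) / scale
  # TIFF pages are row x col = y x x; keep a lossless, explicit mapping
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(voxel_size = volume$voxel_size, channel = volume$channel,
               origin = volume$origin, dim = dim(v),
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into an image volume
#'
#' @param path TIFF path.
#' @param voxel_size override or fallback voxel size in um; required if no
#'   metadata sidecar is present.
#' @param channel override or fallback channel name.
#' @return An [image_volume()].
#' @export
read_image_stack <- function(path, voxel_size = NULL, channel = NULL) {
  if (!file.exists(path)) stop("cannot read image stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("inconsistent page shapes in ", path)
  v <- array(0, c(shp[2], shp[1], length(pages)))
  for (k in seq_along(pages)) v[, , k] <- t(pages[[k]])

  mpath <- paste0(path, ".meta.json")
  meta <- if (file.exists(mpath)) jsonlite::read_json(mpath,
                                                      simplifyVector = TRUE)
          else NULL
  if (is.null(voxel_size)) {
    if (is.null(meta$voxel_size))
      stop("voxel_size metadata missing for ", path,
           " and no override given")
    voxel_size <- meta$voxel_size
  } else if (!is.null(meta$voxel_size) &&
             !isTRUE(all.equal(as.numeric(meta$voxel_size),
                               as.numeric(voxel_size)))) {
    warning("voxel_size override differs from stored metadata")
  }
  if (is.null(channel)) channel <- meta$channel %||% "rhodamine"
  origin <- meta$origin %||% c(0, 0, 0)
  if (!is.null(meta$intensity_scale))
    v <- v * meta$intensity_scale + (meta$intensity_offset %||% 0)
  image_volume(v, voxel_size, channel = channel, origin = origin)
}

# --- networks ----------------------------------------------------------------

#' Write a network as GraphML plus CSV tables
#'
#' Writes `<prefix>.graphml` (topology and attributes via igraph),
#' `<prefix>_nodes.csv`, `<prefix>_edges.csv` and, when geometry is
#' included, `<prefix>_polylines.csv` (edge_id, s, x, y, z).
#'
#' @param network an [lcn_network()].
#' @param prefix output path prefix.
#' @param include_geometry write the sampled edge polylines.
#' @return `prefix`, invisibly.
#' @export
write_network <- function(network, prefix, include_geometry = TRUE) {
  stopifnot(inherits(network, "lcn_network"))
  nd <- network$nodes
  ed <- network$edges
  g <- igraph::graph_from_data_frame(
    d = if (nrow(ed)) data.frame(from = as.character(ed$source),
                                 to = as.character(ed$target),
                                 edge_id = ed$id,
                                 arc_length = ed$arc_length)
        else data.frame(from = character(), to = character(),
                        edge_id = integer(), arc_length = numeric()),
    directed = FALSE,
    vertices = data.frame(name = as.character(nd$id), x = nd$x, y = nd$y,
                          z = nd$z, kind = nd$kind, degree = nd$degree))
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")

  fmt <- function(df) {
    for (cn in names(df)) if (is.numeric(df[[cn]]) && !is.integer(df[[cn]]))
      df[[cn]] <- formatC(df[[cn]], format = "g", digits = 17)
    df
  }
  write.csv(fmt(nd), paste0(prefix, "_nodes.csv"), row.names = FALSE)
  write.csv(fmt(ed), paste0(prefix, "_edges.csv"), row.names = FALSE)
  if (include_geometry && length(network$geometry)) {
    pl <- do.call(rbind, lapply(seq_along(network$geometry), function(e) {
      p <- network$geometry[[e]]
      data.frame(edge_id = ed$id[e], s = seq_len(nrow(p)),
                 x = p[, 1], y = p[, 2], z = p[, 3])
    }))
    write.csv(pl, paste0(prefix, "_polylines.csv"), row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a network written by [write_network()]
#'
#' @param prefix path prefix used at write time.
#' @return An [lcn_network()].
#' @export
read_network <- function(prefix) {
  nd <- read.csv(paste0(prefix, "_nodes.csv"), stringsAsFactors = FALSE)
  ed <- read.csv(paste0(prefix, "_edges.csv"), stringsAsFactors = FALSE)
  if (nrow(ed) && (!all(ed$source %in% nd$id) || !all(ed$target %in% nd$id)))
    stop("dangling edge references in ", prefix)
  ppath <- paste0(prefix, "_polylines.csv")
  geom <- vector("list", nrow(ed))
  if (file.exists(ppath) && nrow(ed)) {
    pl <- read.csv(ppath)
    sp <- split(pl[, c("x", "y", "z")], pl$edge_id)
    for (e in seq_len(nrow(ed))) {
      m <- sp[[as.character(ed$id[e])]]
      geom[[e]] <- if (is.null(m)) straight_geom(nd, ed[e, ])
                   else unname(as.matrix(m))
    }
  } else {
    for (e in seq_len(nrow(ed))) geom[[e]] <- straight_geom(nd, ed[e, ])
  }
  lcn_network(nd, ed, geom)
}

straight_geom <- function(nd, erow) {
  a <- match(erow$source, nd$id); b <- match(erow$target, nd$id)
  rbind(c(nd$x[a], nd$y[a], nd$z[a]), c(nd$x[b], nd$y[b], nd$z[b]))
}

# --- configuration -----------------------------------------------------------

#' Default pipeline configuration
#'
#' All stage parameters with their working defaults: 5 um sub-volumes
#' (125 um^3 cells), 1 um Can.Ln bins, 5 um long-canaliculus threshold,
#' order-3 splines, junction degree minimum 3.
#'
#' @param seed root seed for all stochastic stages.
#' @return nested configuration list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    synthetic = list(enabled = TRUE,
                     spec = synthetic_spec(seed = seed),
                     imaging = imaging_spec(),
                     calcein_surfaces = list(10, 40)),
    input = list(rhodamine = NULL, calcein = NULL, voxel_size = NULL),
    segmentation = list(canalicular = list(sigma_small = 0.15,
                                           sigma_large = 0.6,
                                           threshold = 0.6),
                        lacunar = list(sigma_small = 1.5, sigma_large = 6,
                                       threshold = 1.2),
                        scale_window = 8,
                        lacuna_min = 100, lacuna_max = 300,
                        vascular_span = 20),
    netextract = list(merge_radius = 1, prune_length = 1.0,
                      smoothing = 1.0, sample_step = 0.1),
    connectomics = list(subvolume_edge = 5, bin_width = 1,
                        long_threshold = 5,
                        long_weighting = "length",
                        transcortical_axis = 1, profile_bins = 50),
    output = list(dir = NULL, write_network = TRUE, write_grid = TRUE),
    verbosity = 1L), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [default_config()]; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_config(seed = usr$seed %||% 1L)
  merge_in <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(upd[[k]]) && is.list(base[[k]]))
        merge_in(base[[k]], upd[[k]]) else upd[[k]]
    }
    base
  }
  cfg2 <- merge_in(unclass(cfg), usr)
  if (!is.null(usr$synthetic$spec))
    cfg2$synthetic$spec <- do.call(synthetic_spec, usr$synthetic$spec)
  if (!is.null(usr$synthetic$imaging))
    cfg2$synthetic$imaging <- do.call(imaging_spec, usr$synthetic$imaging)
  structure(cfg2, class = "pipeline_config")
}

# --- end-to-end pipeline -----------------------------------------------------

pipe_msg <- function(verbosity, fmt, ...) {
  if (verbosity > 0) message(sprintf(fmt, ...))
}

#' Run the full image-to-connectome pipeline
#'
#' Executes phantom generation (when configured) or stack loading, then
#' segmentation, network extraction and the connectomic analyses, and
#' optionally writes all artefacts (network files, sub-volume grid CSV,
#' histogram and profile CSVs, summary JSON, the configuration used) to an
#' output directory.
#'
#' @param config a `pipeline_config` from [default_config()] or
#'   [read_pipeline_config()].
#' @return An object of class `connectome_summary`.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  vb <- config$verbosity
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL; rho <- NULL; calcein <- NULL
  if (isTRUE(config$synthetic$enabled)) {
    stage("synthgen", {
      spec <- config$synthetic$spec
      spec$seed <- config$seed
      pipe_msg(vb, "synthgen: growing ground-truth network (seed %d)",
               config$seed)
      truth <- generate_network(spec)
      rend <- with_seed(config$seed + 1L,
                        render_volume(truth, config$synthetic$imaging))
      rho <- rend$volume
      cal <- generate_calcein_surfaces(spec$domain_size,
                                       config$synthetic$calcein_surfaces,
                                       voxel_size = config$synthetic$imaging$voxel_size,
                                       origin = spec$domain_origin)
      calcein <- cal$calcein
    })
  } else {
    stage("io", {
      rho <- read_image_stack(config$input$rhodamine,
                              voxel_size = config$input$voxel_size)
      calcein <- if (!is.null(config$input$calcein))
        read_image_stack(config$input$calcein,
                         voxel_size = config$input$voxel_size) else NULL
    })
  }

  seg <- stage("segmentation", {
    sc <- config$segmentation
    pipe_msg(vb, "segmentation: dual-pass DoG binarization")
    bin <- dog_binarize(rho,
                        canalicular_params = do.call(dog_params, sc$canalicular),
                        lacunar_params = do.call(dog_params, sc$lacunar),
                        scale_window = sc$scale_window)
    classify_pores(bin, sc$lacuna_min, sc$lacuna_max, sc$vascular_span)
  })
  mask <- stage("segmentation", {
    if (!is.null(calcein)) build_region_mask(calcein) else NULL
  })

  net <- stage("netextract", {
    pipe_msg(vb, "netextract: skeletonization, chain graph, spline fitting")
    ne <- config$netextract
    extract_network(seg, merge_radius = ne$merge_radius,
                    prune_length = ne$prune_length,
                    smoothing = ne$smoothing, sample_step = ne$sample_step)
  })

  summary <- stage("connectomics", {
    pipe_msg(vb, "connectomics: densities, distributions, profiles")
    cn <- config$connectomics
    grid <- subvolume_map(net, mask = mask, binary = seg,
                          L = cn$subvolume_edge, step = ne_step(config))
    vroi_all <- if (!is.null(mask)) roi_volume(mask, seg, "all")
                else prod(dim(rho$voxels) * rho$voxel_size)
    global_dn <- can_dn(net, vroi_all)
    per_region <- if (!is.null(mask)) {
      lapply(names(REGION_LEVELS), function(r) {
        sel <- grid$cells$region == REGION_LEVELS[[r]] & grid$cells$v_roi > 0
        d <- grid$cells$can_dn[sel]
        list(region = r, n_cells = sum(sel),
             mean = if (length(d)) mean(d) else NA_real_,
             sd = if (length(d) > 1) sd(d) else NA_real_)
      })
    } else NULL
    lh <- length_histogram(net, bin_width = cn$bin_width,
                           long_threshold = cn$long_threshold)
    dh <- doc_histogram(net)
    prof <- if (!is.null(mask))
      cortical_profile(grid, mask,
                       axis_spec = list(transcortical = cn$transcortical_axis),
                       nbins = cn$profile_bins) else NULL
    reg <- tryCatch(
      density_connectivity_regression(grid, net,
                                      long_threshold = cn$long_threshold,
                                      long_weighting = cn$long_weighting),
      error = function(e) NULL)
    structure(list(global_can_dn = global_dn,
                   per_region = per_region,
                   length_histogram = lh,
                   doc_histogram = dh,
                   cortical_profile = prof,
                   regressions = reg,
                   grid = grid, network = net,
                   truth = truth,
                   seed = config$seed,
                   elapsed = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))),
              class = "connectome_summary")
  })

  if (!is.null(config$output$dir))
    stage("io", write_summary_artifacts(summary, seg, mask, config))
  summary
}

ne_step <- function(config) config$netextract$sample_step %||% 0.1

write_summary_artifacts <- function(summary, seg, mask, config) {
  dir.create(config$output$dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output$dir, f)
  if (isTRUE(config$output$write_network))
    write_network(summary$network, out("network"))
  if (isTRUE(config$output$write_grid)) {
    g <- summary$grid
    cc <- g$cells
    cc$cx <- g$origin[1] + (cc$ix - 0.5) * g$L
    cc$cy <- g$origin[2] + (cc$iy - 0.5) * g$L
    cc$cz <- g$origin[3] + (cc$iz - 0.5) * g$L
    write.csv(cc, out("subvolume_grid.csv"), row.names = FALSE)
  }
  lh <- summary$length_histogram
  if (!lh$empty)
    write.csv(data.frame(bin_lower = head(lh$breaks, -1),
                         bin_upper = tail(lh$breaks, -1),
                         count = lh$counts, percent = lh$percent),
              out("canln_histogram.csv"), row.names = FALSE)
  dh <- summary$doc_histogram
  if (!dh$empty)
    write.csv(data.frame(degree = dh$degrees, count = dh$counts,
                         percent = dh$percent),
              out("doc_histogram.csv"), row.names = FALSE)
  if (!is.null(summary$cortical_profile))
    write.csv(summary$cortical_profile$profile, out("cortical_profile.csv"),
              row.names = FALSE)
  js <- list(seed = summary$seed,
             global_can_dn = summary$global_can_dn,
             km_per_cm3 = density_to_km_per_cm3(summary$global_can_dn),
             tree_like_fraction = summary$doc_histogram$tree_like_fraction,
             long_fraction_count = lh$long_fraction_count,
             long_fraction_length = lh$long_fraction_length,
             per_region = summary$per_region,
             regressions = if (!is.null(summary$regressions))
               unclass(summary$regressions) else NULL,
             elapsed_seconds = summary$elapsed)
  jsonlite::write_json(js, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  cfg <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(cfg, out("config_used.yaml"))
  invisible(config$output$dir)
}

#' @export
print.connectome_summary <- function(x, ...) {
  cat("== LCN connectome summary ==\n")
  cat(sprintf("global Can.Dn: %.4f um/um^3 (%.0f km/cm^3)\n",
              x$global_can_dn, density_to_km_per_cm3(x$global_can_dn)))
  if (!is.null(x$per_region))
    for (r in x$per_region)
      if (r$n_cells > 0)
        cat(sprintf("  %-15s mean %.4f +/- %.4f um/um^3 over %d sub-volumes\n",
                    r$region, r$mean, r$sd, r$n_cells))
  print(x$length_histogram)
  print(x$doc_histogram)
  if (!is.null(x$regressions)) print(x$regressions)
  cat(sprintf("elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}
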