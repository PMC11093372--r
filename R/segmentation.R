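#' Parameters for one Difference-of-Gaussians detection pass
#'
#' @param sigma_small,sigma_large Gaussian scales in um,
#'   `sigma_small < sigma_large`. The band-pass response peaks for
#'   structures whose radius matches roughly `sigma_small`.
#' @param threshold detection threshold on the DoG response, relative to
#'   the local signal-amplitude scale (see [dog_binarize()]).
#' @return list of class `dog_params`.
#' @export
dog_params <- function(sigma_small, sigma_large, threshold) {
  if (sigma_small <= 0 || sigma_large <= 0)
    stop("DoG sigmas must be positive")
  if (sigma_small >= sigma_large)
    stop("sigma_small must be smaller than sigma_large")
  structure(list(sigma_small = sigma_small, sigma_large = sigma_large,
                 threshold = threshold), class = "dog_params")
}

# band-pass response in physical units (sigmas in um -> voxels per axis)
dog_response <- function(vol, voxel_size, sigma_small, sigma_large) {
  dims <- dim(vol)
  cpp_gauss3d(vol, dims, rep(sigma_small, 3) / voxel_size) -
    cpp_gauss3d(vol, dims, rep(sigma_large, 3) / voxel_size)
}

# local signal-amplitude scale: wide Gaussian of |I - wide Gaussian(I)|.
# Shift-invariant by construction, and tracks depth-dependent contrast.
local_scale <- function(vol, voxel_size, window_um) {
  dims <- dim(vol)
  sw <- rep(window_um, 3) / voxel_size
  bg <- cpp_gauss3d(vol, dims, sw)
  cpp_gauss3d(abs(vol - bg), dims, sw)
}

#' Dual-pass adaptive Difference-of-Gaussians binarization
#'
#' Binarizes a rhodamine stack with two band-pass detections: a thin pass
#' scale-matched to sub-micrometre canaliculi and a bulky pass matched to
#' micrometre-scale lacunae. Each pass thresholds its DoG response
#' adaptively, relative to a local signal-amplitude scale (a wide Gaussian
#' of the local mean absolute deviation), which makes the detection
#' invariant to intensity offsets and robust to residual depth-dependent
#' intensity trends. The foreground is the union of the two passes;
#' per-voxel provenance records which pass fired.
#'
#' @param image rhodamine [image_volume()].
#' @param canalicular_params thin-pass [dog_params()] (defaults 0.15/0.6 um).
#' @param lacunar_params bulky-pass [dog_params()] (defaults 1.5/6 um).
#' @param scale_window window (um) of the local amplitude estimate.
#' @return A [binary_volume()]; all foreground is initially labelled
#'   canalicular (see [classify_pores()]).
#' @export
dog_binarize <- function(image,
                         canalicular_params = dog_params(0.15, 0.6, 0.6),
                         lacunar_params = dog_params(1.5, 6, 1.2),
                         scale_window = 8) {
  stopifnot(inherits(image, "image_volume"))
  vol <- image$voxels
  vs <- image$voxel_size
  if (diff(range(vol)) == 0) {   # constant image: nothing to detect
    z <- array(0L, dim(vol))
    return(binary_volume(array(FALSE, dim(vol)), z, z, vs))
  }
  sc <- local_scale(vol, vs, scale_window)

  pass <- function(p) {
    r <- dog_response(vol, vs, p$sigma_small, p$sigma_large)
    r > p$threshold * sc   # strict: a constant image yields empty foreground
  }
  thin <- pass(canalicular_params)
  bulky <- pass(lacunar_params)

  prov <- array(0L, dim(vol))
  prov[thin] <- 1L
  prov[bulky] <- prov[bulky] + 2L
  fg <- prov > 0L
  cls <- array(0L, dim(vol))
  cls[fg] <- 1L
  binary_volume(fg, cls, prov, vs)
}

#' Separate lacunae and vascular canals from canaliculi
#'
#' Connected components of the bulky-pass detections are classified by
#' volume and extent: compact blobs of at least `lacuna_min` um^3 become
#' lacunar; components larger than `lacuna_max` um^3 that also span more
#' than `vascular_span` um along some axis are vascular canals. Everything
#' else stays canalicular. Operating on the bulky-pass provenance keeps the
#' thin canaliculi attached to a lacuna from being absorbed into it.
#'
#' @param binary a [binary_volume()] from [dog_binarize()].
#' @param lacuna_min,lacuna_max volume thresholds in um^3; osteocyte
#'   lacunae are typically 100-250 um^3, canalicular junctions 1-30 um^3.
#' @param vascular_span minimum axis span in um for a vascular canal.
#' @param core_neighbors bulky voxels need at least this many bulky
#'   26-neighbours to seed a pore core; this strips the thin false-positive
#'   bridges the bulky pass picks up over dense canalicular tangles, so
#'   that separate lacunae are not fused into one elongated component.
#' @return The [binary_volume()] with `class_labels` updated.
#' @export
classify_pores <- function(binary, lacuna_min = 100, lacuna_max = 300,
                           vascular_span = 20, core_neighbors = 13L) {
  stopifnot(inherits(binary, "binary_volume"))
  vs <- binary$voxel_size
  vv <- prod(vs)
  dims <- dim(binary$foreground)
  cls <- array(0L, dims)
  cls[binary$foreground] <- 1L

  bulky <- binary$provenance >= 2L
  if (any(bulky)) {
    # compact cores of the bulky mask (erosion by neighbour count)
    core <- bulky & (cpp_count_neighbors(bulky, dims) >= core_neighbors)
    if (any(core)) {
      lab <- cpp_label_components(core, dims, 26L)
      # grow labels back over the detected foreground (1 voxel shell)
      lab <- cpp_dilate_labels(lab, binary$foreground, dims, 1L)
      idx <- which(lab > 0L)
      comp <- lab[idx]
      n_per <- tabulate(comp)
      ii <- arrayInd(idx, dims)
      span <- sapply(1:3, function(a) {
        mx <- tapply(ii[, a], comp, max)
        mn <- tapply(ii[, a], comp, min)
        (mx - mn + 1) * vs[a]
      })
      if (is.null(dim(span))) span <- matrix(span, nrow = 1)
      vol_um <- n_per * vv
      max_span <- apply(span, 1, max)
      kind <- rep(1L, length(n_per))                      # canalicular
      kind[vol_um >= lacuna_min] <- 2L                    # lacunar
      kind[vol_um > lacuna_max & max_span > vascular_span] <- 3L  # vascular
      cls[idx] <- kind[comp]
    }
  }
  binary$class_labels <- cls
  binary
}

#' Recover the calcein region partition from a label image
#'
#' Detects the two bright calcein bands crossing the cortex, fits a smooth
#' surface to each, and partitions the bone volume into endosteal new bone,
#' intercortex, and periosteal new bone.
#'
#' @param calcein calcein-channel [image_volume()].
#' @param bone_mask optional logical array restricting the labelled volume.
#' @param threshold band detection threshold as a fraction of the intensity
#'   range above the median.
#' @param min_coverage minimum fraction of the (y, z) cross-section a
#'   component must cover to count as a label surface.
#' @param smooth_sigma smoothing (in voxels) of the fitted surfaces.
#' @return A [region_mask()].
#' @export
build_region_mask <- function(calcein, bone_mask = NULL, threshold = 0.5,
                              min_coverage = 0.5, smooth_sigma = 1.5) {
  stopifnot(inherits(calcein, "image_volume"))
  vol <- calcein$voxels
  vs <- calcein$voxel_size
  dims <- dim(vol)
  med <- median(vol)
  fg <- vol > med + threshold * (max(vol) - med)
  lab <- cpp_label_components(fg, dims, 26L)
  idx <- which(lab > 0L)
  if (!length(idx))
    stop("no calcein bands detected: expected two label surfaces, found 0")
  ii <- arrayInd(idx, dims)
  comp <- lab[idx]
  jk <- ii[, 2] + (ii[, 3] - 1L) * dims[2]
  cover <- vapply(split(jk, comp), function(v) length(unique(v)),
                  numeric(1)) / (dims[2] * dims[3])
  cand <- as.integer(names(cover))[cover >= min_coverage]
  if (length(cand) < 2)
    stop(sprintf(
      "calcein band missing: expected two label surfaces crossing the cortex, found %d",
      length(cand)))
  mean_x <- vapply(cand, function(cc) mean(ii[comp == cc, 1]), numeric(1))
  if (length(cand) > 2)
    cand <- cand[order(-cover[as.character(cand)])][1:2]
  cand <- cand[order(vapply(cand, function(cc) mean(ii[comp == cc, 1]),
                            numeric(1)))]

  fit_surface <- function(cc) {
    sel <- comp == cc
    w <- vol[idx[sel]]
    xw <- ii[sel, 1] * w
    sx <- rowsum(xw, jk[sel])
    sw <- rowsum(w, jk[sel])
    smap <- rep(NA_real_, dims[2] * dims[3])
    smap[as.integer(rownames(sx))] <- sx / sw
    smap <- matrix(smap, dims[2], dims[3])
    # fill gaps along y then z, then smooth
    fill1 <- function(v) {
      if (all(is.na(v))) return(v)
      if (sum(!is.na(v)) == 1) { v[] <- v[!is.na(v)]; return(v) }
      approx(which(!is.na(v)), v[!is.na(v)], seq_along(v), rule = 2)$y
    }
    smap <- apply(smap, 2, fill1)
    smap <- t(apply(smap, 1, fill1))
    if (any(is.na(smap))) smap[is.na(smap)] <- mean(smap, na.rm = TRUE)
    dim(smap) <- c(dims[2], dims[3])
    sm <- cpp_gauss3d(array(smap, c(dims[2], dims[3], 1L)),
                      c(dims[2], dims[3], 1L), c(smooth_sigma, smooth_sigma, 0))
    # convert from voxel index to physical x (um)
    (sm[, , 1] - 0.5) * vs[1] + calcein$origin[1]
  }
  S1 <- fit_surface(cand[1])
  S2 <- fit_surface(cand[2])

  xc <- vox_centers(dims[1], vs[1], calcein$origin[1])
  A1 <- outer(xc, S1, `-`)
  A2 <- outer(xc, S2, `-`)
  labels <- array(2L, dims)
  labels[A1 < 0] <- 3L
  labels[A2 > 0] <- 1L
  if (!is.null(bone_mask)) labels[!bone_mask] <- 0L
  region_mask(labels, list(S1, S2), vs)
}

#' Pore-excluded region volume (V_ROI)
#'
#' Volume of an anatomical region available to the canalicular network:
#' region voxels minus lacunar and vascular voxels, times the voxel volume.
#' This is the denominator of the canalicular density Can.Dn.
#'
#' @param mask a [region_mask()].
#' @param binary a (pore-classified) [binary_volume()], or `NULL` for no
#'   pore exclusion.
#' @param region `"periosteal_new"`, `"intercortex"`, `"endosteal_new"` or
#'   `"all"`.
#' @return volume in um^3.
#' @export
roi_volume <- function(mask, binary = NULL, region = "all") {
  stopifnot(inherits(mask, "region_mask"))
  if (!is.null(binary) &&
      !identical(dim(mask$labels), dim(binary$foreground)))
    stop("region mask and binary volume have mismatched grid shapes")
  sel <- if (identical(region, "all")) mask$labels > 0L
         else mask$labels == region_code(region)
  if (!is.null(binary)) sel <- sel & binary$class_labels < 2L
  sum(sel) * prod(mask$voxel_size)
}
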