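#' 3D image volume with physical voxel sizes
#'
#' A thin container around a 3D numeric array carrying one fluorescence
#' channel. Array axes are `[x, y, z]`; voxel `(i, j, k)` (1-based) has its
#' centre at `origin + (c(i, j, k) - 0.5) * voxel_size`, all in micrometres.
#'
#' @param voxels 3D numeric array of intensities.
#' @param voxel_size numeric length-3, voxel edge lengths in um (> 0).
#' @param channel channel name, `"rhodamine"` or `"calcein"`.
#' @param origin numeric length-3 offset of the grid in um.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, voxel_size, channel = "rhodamine",
                         origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths in um")
  if (any(!is.finite(voxels))) stop("image intensities must be finite")
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 channel = channel, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %s channel, %d x %d x %d voxels @ %.3f x %.3f x %.3f um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  physical extent %.1f x %.1f x %.1f um, intensity range [%.3g, %.3g]\n",
              d[1] * x$voxel_size[1], d[2] * x$voxel_size[2],
              d[3] * x$voxel_size[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

# voxel-centre coordinates along one axis, in um
vox_centers <- function(n, vs, origin = 0) origin + (seq_len(n) - 0.5) * vs

#' Binary segmentation volume
#'
#' Foreground voxels with per-voxel pore class and provenance (which
#' DoG pass detected the voxel).
#'
#' @param foreground 3D logical array.
#' @param class_labels 3D integer array; 0 = background, 1 = canalicular,
#'   2 = lacunar, 3 = vascular. Defined only on foreground.
#' @param provenance 3D integer array; 0 none, 1 thin pass, 2 bulky pass,
#'   3 both.
#' @param voxel_size voxel edge lengths in um.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(foreground, class_labels, provenance, voxel_size) {
  stopifnot(identical(dim(foreground), dim(class_labels)),
            identical(dim(foreground), dim(provenance)))
  if (any(class_labels[!foreground] != 0L))
    stop("class labels must be zero on background")
  structure(list(foreground = foreground, class_labels = class_labels,
                 provenance = provenance,
                 voxel_size = as.numeric(voxel_size)),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  n <- sum(x$foreground)
  vv <- prod(x$voxel_size)
  cat(sprintf("<binary_volume> %d foreground voxels (%.1f um^3)\n", n, n * vv))
  cl <- tabulate(x$class_labels[x$foreground], 3)
  cat(sprintf("  canalicular %d, lacunar %d, vascular %d\n", cl[1], cl[2], cl[3]))
  invisible(x)
}

# region label codes used throughout
REGION_LEVELS <- c(periosteal_new = 1L, intercortex = 2L, endosteal_new = 3L)

#' Anatomical region mask from calcein label surfaces
#'
#' Per-voxel labels partitioning the bone volume into newly formed bone at
#' the endosteal surface, pre-existing intercortical bone, and newly formed
#' bone at the periosteal surface. The transcortical axis runs from the
#' endosteal (low coordinate) to the periosteal (high coordinate) side.
#'
#' @param labels 3D integer array; 0 = background, 1 = periosteal_new,
#'   2 = intercortex, 3 = endosteal_new.
#' @param boundary_positions list of two matrices (endosteal-side surface
#'   first) giving the transcortical coordinate (um) of each calcein surface
#'   over the two remaining axes.
#' @param voxel_size voxel edge lengths in um.
#' @param axis transcortical axis (1 = x).
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(labels, boundary_positions, voxel_size, axis = 1L) {
  stopifnot(length(dim(labels)) == 3, length(boundary_positions) == 2)
  structure(list(labels = labels, boundary_positions = boundary_positions,
                 voxel_size = as.numeric(voxel_size), axis = as.integer(axis)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cnt <- tabulate(x$labels[x$labels > 0], 3)
  cat("<region_mask> voxels per region:\n")
  cat(sprintf("  periosteal_new %d, intercortex %d, endosteal_new %d\n",
              cnt[1], cnt[2], cnt[3]))
  cat(sprintf("  calcein surfaces at mean x = %.2f and %.2f um\n",
              mean(x$boundary_positions[[1]]), mean(x$boundary_positions[[2]])))
  invisible(x)
}

region_code <- function(region) {
  if (is.numeric(region)) return(as.integer(region))
  code <- REGION_LEVELS[match.arg(region, names(REGION_LEVELS))]
  unname(code)
}
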