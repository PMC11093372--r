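#' Spatial network of lacunae and canaliculi
#'
#' The connectome extracted from (or generated for) an image volume: nodes
#' are lacunae, canalicular junctions or free endpoints; edges are canaliculi
#' with a sampled spline polyline and an arc length (Can.Ln) in um.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (um), `kind`
#'   (`"lacunar"`, `"junction"`, `"endpoint"`), `degree`.
#' @param edges data.frame with columns `id`, `source`, `target`
#'   (node ids), `arc_length` (um).
#' @param geometry list (one entry per edge, in `edges` row order) of
#'   n x 3 matrices sampling the edge curve in um.
#' @param domain physical extent of the imaged/generated domain in um.
#' @return An object of class `lcn_network`.
#' @export
lcn_network <- function(nodes, edges, geometry, domain = NULL) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges),
            is.list(geometry), length(geometry) == nrow(edges))
  if (nrow(edges) > 0 &&
      (!all(edges$source %in% nodes$id) || !all(edges$target %in% nodes$id)))
    stop("edge endpoints reference unknown node ids")
  structure(list(nodes = nodes, edges = edges, geometry = geometry,
                 domain = domain),
            class = "lcn_network")
}

empty_network <- function(domain = NULL) {
  lcn_network(
    nodes = data.frame(id = integer(), x = numeric(), y = numeric(),
                       z = numeric(), kind = character(), degree = integer(),
                       stringsAsFactors = FALSE),
    edges = data.frame(id = integer(), source = integer(), target = integer(),
                       arc_length = numeric(), stringsAsFactors = FALSE),
    geometry = list(), domain = domain)
}

#' @export
print.lcn_network <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind,
                        levels = c("lacunar", "junction", "endpoint")))
  cat(sprintf("<lcn_network> %d nodes (%d lacunar, %d junction, %d endpoint), %d edges\n",
              nrow(x$nodes), kinds[1], kinds[2], kinds[3], nrow(x$edges)))
  if (nrow(x$edges) > 0)
    cat(sprintf("  total canalicular length %.1f um, mean Can.Ln %.2f um\n",
                sum(x$edges$arc_length), mean(x$edges$arc_length)))
  invisible(x)
}

#' @export
summary.lcn_network <- function(object, ...) {
  jn <- object$nodes$degree[object$nodes$kind == "junction"]
  out <- list(
    n_nodes = nrow(object$nodes),
    n_edges = nrow(object$edges),
    total_length = sum(object$edges$arc_length),
    mean_edge_length = if (nrow(object$edges)) mean(object$edges$arc_length) else NA_real_,
    junction_degrees = if (length(jn)) table(jn) else table(integer()),
    tree_like_fraction = if (length(jn)) mean(jn == 3) else NA_real_)
  class(out) <- "summary.lcn_network"
  out
}

#' @export
print.summary.lcn_network <- function(x, ...) {
  cat(sprintf("nodes %d | edges %d | total length %.1f um | mean Can.Ln %.2f um\n",
              x$n_nodes, x$n_edges, x$total_length, x$mean_edge_length))
  if (!is.na(x$tree_like_fraction))
    cat(sprintf("tree-like junction fraction (DoC = 3): %.3f\n",
                x$tree_like_fraction))
  invisible(x)
}

#' @export
plot.lcn_network <- function(x, axes = c(1, 2), cex = 0.4, ...) {
  labs <- c("x (um)", "y (um)", "z (um)")
  graphics::plot(NA, xlim = range(vapply(x$geometry, function(p) range(p[, axes[1]]),
                                         numeric(2))),
                 ylim = range(vapply(x$geometry, function(p) range(p[, axes[2]]),
                                     numeric(2))),
                 xlab = labs[axes[1]], ylab = labs[axes[2]], asp = 1, ...)
  for (p in x$geometry) graphics::lines(p[, axes[1]], p[, axes[2]], col = "grey40")
  nd <- x$nodes
  graphics::points(nd[nd$kind == "lacunar", c("x", "y", "z")[axes]],
                   col = "firebrick", pch = 19, cex = 3 * cex)
  graphics::points(nd[nd$kind == "junction", c("x", "y", "z")[axes]],
                   col = "dodgerblue3", pch = 19, cex = cex)
  invisible(x)
}

# total polyline length of an n x 3 matrix of points
polyline_length <- function(p) {
  if (is.null(dim(p)) || nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# resample a polyline at (approximately) uniform arc-length spacing `step`
resample_polyline <- function(p, step) {
  if (nrow(p) < 2) return(p)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) return(p[1, , drop = FALSE])
  m <- max(2L, ceiling(L / step) + 1L)
  si <- seq(0, L, length.out = m)
  cbind(approx(s, p[, 1], si, ties = "ordered")$y,
        approx(s, p[, 2], si, ties = "ordered")$y,
        approx(s, p[, 3], si, ties = "ordered")$y)
}

# recompute node degrees from edge incidences (self-edges count twice)
recompute_degrees <- function(net) {
  deg <- integer(nrow(net$nodes))
  if (nrow(net$edges) > 0) {
    inc <- c(match(net$edges$source, net$nodes$id),
             match(net$edges$target, net$nodes$id))
    tt <- tabulate(inc, nbins = nrow(net$nodes))
    deg <- tt
  }
  net$nodes$degree <- deg
  net
}

#' Merge two spatial networks into one
#'
#' Node and edge ids of the second network are shifted so they do not
#' collide; useful for composing multi-region phantoms.
#'
#' @param a,b `lcn_network` objects.
#' @return A single `lcn_network`.
#' @export
combine_networks <- function(a, b) {
  off_n <- if (nrow(a$nodes)) max(a$nodes$id) else 0L
  off_e <- if (nrow(a$edges)) max(a$edges$id) else 0L
  nb <- b$nodes; nb$id <- nb$id + off_n
  eb <- b$edges
  if (nrow(eb)) {
    eb$id <- eb$id + off_e
    eb$source <- eb$source + off_n
    eb$target <- eb$target + off_n
  }
  dom <- if (!is.null(a$domain) && !is.null(b$domain))
    pmax(a$domain, b$domain) else a$domain %||% b$domain
  lcn_network(rbind(a$nodes, nb), rbind(a$edges, eb),
              c(a$geometry, b$geometry), domain = dom)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
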