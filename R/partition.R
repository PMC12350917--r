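#' Spatial co-expression field of two marker genes
#'
#' Evaluates the pointwise product of the two genes' Gaussian kernel
#' density estimates on a regular grid. The product is large only where
#' both genes have transcripts nearby, so its ridge traces the spatial
#' co-expression of the two markers (e.g. the Shh+ oral epithelium and
#' the adjacent Ptch1+ mesenchyme).
#'
#' @param table a transcript table (data.frame with `feature_name`,
#'   `x_location`, `y_location`). A gene is *known* if it appears among
#'   the factor levels of `feature_name` (or its values); a known gene
#'   with zero transcripts yields an identically-zero field, while an
#'   unknown gene is an error.
#' @param gene_a,gene_b marker gene symbols.
#' @param bandwidth Gaussian kernel standard deviation in um.
#' @param step grid spacing in um.
#' @param lims optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   transcript bounding box padded by three bandwidths.
#' @return Object of class `coexpression_field`: list with grid vectors
#'   `x`, `y` and matrix `z` (`z[i, j]` at `(x[i], y[j])`).
#' @export
coexpression_field <- function(table, gene_a, gene_b, bandwidth = 20,
                               step = 5, lims = NULL) {
  stopifnot(bandwidth > 0, step > 0)
  genes <- if (is.factor(table$feature_name)) {
    levels(table$feature_name)
  } else {
    unique(as.character(table$feature_name))
  }
  for (g in c(gene_a, gene_b)) {
    if (!g %in% genes) stop("gene not present in table: ", g, call. = FALSE)
  }
  if (is.null(lims)) {
    lims <- c(range(table$x_location) + c(-3, 3) * bandwidth,
              range(table$y_location) + c(-3, 3) * bandwidth)
  }
  nx <- max(2L, round((lims[2L] - lims[1L]) / step) + 1L)
  ny <- max(2L, round((lims[4L] - lims[3L]) / step) + 1L)
  gx <- seq(lims[1L], lims[2L], length.out = nx)
  gy <- seq(lims[3L], lims[4L], length.out = ny)

  one_kde <- function(gene) {
    rows <- table$feature_name == gene
    if (!any(rows)) return(matrix(0, nx, ny))
    ## MASS::kde2d divides h by 4 internally; pass 4*bandwidth so the
    ## kernel sd equals `bandwidth` um.
    MASS::kde2d(table$x_location[rows], table$y_location[rows],
                h = 4 * bandwidth, n = c(nx, ny), lims = lims)$z
  }

  z <- one_kde(gene_a) * one_kde(gene_b)
  structure(list(x = gx, y = gy, z = z, bandwidth = bandwidth, step = step,
                 genes = c(gene_a, gene_b)),
            class = "coexpression_field")
}

#' Fit an oronasal axis from a marker co-expression field
#'
#' The axis is anchored at the co-expression-weighted centroid of the
#' field restricted to the shelf polygon and directed along the first
#' principal axis of the top-decile field support (the grid points whose
#' field value reaches the 90th percentile of positive values inside the
#' shelf). Fully deterministic.
#'
#' @param field a [coexpression_field()].
#' @param shelf_polygon n x 2 vertex matrix of the shelf outline (um).
#' @param shelf shelf label (`"PL"` or `"PR"`) carried into the result.
#' @return Object of class `axis_line`: list with `anchor` (um),
#'   `direction` (unit vector) and `shelf`.
#' @export
fit_oronasal_axis <- function(field, shelf_polygon, shelf = NA_character_) {
  g <- expand.grid(x = field$x, y = field$y)
  w <- as.vector(field$z)    # z[i, j] varies fastest in x, as does expand.grid
  inside <- points_in_polygon(g$x, g$y, shelf_polygon)
  w_in <- w[inside]
  if (sum(w_in) <= 0) {
    stop("markers absent from shelf", if (!is.na(shelf)) paste0(" ", shelf),
         ": co-expression field has no mass inside the polygon",
         call. = FALSE)
  }
  anchor <- c(sum(g$x[inside] * w_in), sum(g$y[inside] * w_in)) / sum(w_in)

  thr <- stats::quantile(w_in[w_in > 0], 0.9, names = FALSE)
  support <- inside & w >= thr
  pts <- cbind(g$x[support], g$y[support])
  dir <- if (nrow(pts) < 2L) {
    c(1, 0)
  } else {
    v <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 1L]
    v / sqrt(sum(v^2))
  }
  ## Canonical sign: positive x component (ties: positive y).
  if (dir[1L] < 0 || (dir[1L] == 0 && dir[2L] < 0)) dir <- -dir
  structure(list(anchor = anchor, direction = dir, shelf = shelf),
            class = "axis_line")
}

#' @export
print.axis_line <- function(x, ...) {
  ang <- atan2(x$direction[2L], x$direction[1L]) * 180 / pi
  cat(sprintf("Oronasal axis [%s]: anchor (%.1f, %.1f) um, direction %.1f deg\n",
              x$shelf %||% "?", x$anchor[1L], x$anchor[2L], ang))
  invisible(x)
}

#' Assign points to oral (OP) or nasal (NP) domains
#'
#' Labels each point by the side of the oronasal axis it falls on. The
#' half-plane containing `oral_side_reference` (typically the epithelial
#' strip centroid, or [marker_oral_reference()] when only transcripts
#' are available) is `OP`; points exactly on the axis are `OP` by
#' convention.
#'
#' @param points numeric vector `c(x, y)` or an n x 2 matrix.
#' @param axis an [fit_oronasal_axis()] result.
#' @param oral_side_reference point `c(x, y)` on the oral side.
#' @return Character vector of `"OP"` / `"NP"`.
#' @export
assign_domain <- function(points, axis, oral_side_reference) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  nv <- c(-axis$direction[2L], axis$direction[1L])
  s_ref <- sum((oral_side_reference - axis$anchor) * nv)
  if (s_ref == 0) {
    stop("oral_side_reference lies exactly on the axis; ",
         "pick a reference point off the line", call. = FALSE)
  }
  s <- (points[, 1L] - axis$anchor[1L]) * nv[1L] +
    (points[, 2L] - axis$anchor[2L]) * nv[2L]
  ifelse(s * sign(s_ref) >= 0, "OP", "NP")
}

#' Mode of a single gene's spatial density
#'
#' Location of the maximum of a gene's Gaussian KDE on a grid; used as
#' the default oral-side reference (Shh marks the oral epithelium).
#'
#' @inheritParams coexpression_field
#' @param gene gene symbol.
#' @param polygon optional n x 2 vertex matrix; when given, the mode is
#'   taken over grid points inside the polygon only.
#' @return `c(x, y)` in um.
#' @export
gene_density_mode <- function(table, gene, bandwidth = 20, step = 5,
                              lims = NULL, polygon = NULL) {
  f <- coexpression_field(table, gene, gene, bandwidth = bandwidth,
                          step = step, lims = lims)
  z <- f$z
  if (!is.null(polygon)) {
    g <- expand.grid(x = f$x, y = f$y)
    z[!points_in_polygon(g$x, g$y, polygon)] <- -Inf
  }
  idx <- arrayInd(which.max(z), dim(z))
  c(f$x[idx[1L]], f$y[idx[2L]])
}
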