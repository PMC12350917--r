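#' ROI generation configuration
#'
#' @param target_area ROI surface area in um^2 (default 6400).
#' @param area_tolerance allowed deviation from `target_area` (um^2).
#' @param n_per_domain_side ROIs per (shelf, domain) pair.
#' @param shape `"square"` (side `sqrt(target_area)`) or `"circle"`
#'   (regular 64-gon scaled to the target area).
#' @param min_qv transcript quality threshold; transcripts with
#'   `qv < min_qv` are ignored both for placement and counting.
#' @param seed integer seed for the placement grid jitter.
#' @param candidate_step spacing (um) of the candidate-center lattice.
#' @return A list of class `roi_config`.
#' @export
roi_config <- function(target_area = 6400, area_tolerance = 100,
                       n_per_domain_side = 3, shape = c("square", "circle"),
                       min_qv = 20, seed = 1L, candidate_step = 20) {
  shape <- match.arg(shape)
  stopifnot(target_area > 0, area_tolerance >= 0, n_per_domain_side >= 1,
            candidate_step > 0)
  structure(list(target_area = target_area, area_tolerance = area_tolerance,
                 n_per_domain_side = as.integer(n_per_domain_side),
                 shape = shape, min_qv = min_qv, seed = seed,
                 candidate_step = candidate_step),
            class = "roi_config")
}

## ROI outline centered at the origin with polygon area exactly `area`.
roi_template <- function(shape, area) {
  if (shape == "square") {
    s <- sqrt(area) / 2
    cbind(c(-s, s, s, -s), c(-s, -s, s, s))
  } else {
    t <- seq(0, 2 * pi, length.out = 65L)[-65L]
    poly <- cbind(cos(t), sin(t))
    poly * sqrt(area / polygon_area(poly))
  }
}

make_roi <- function(template, center, shelf, domain, idx) {
  poly <- sweep(template, 2L, center, "+")
  structure(list(roi_id = sprintf("%s_%s_%d", shelf, domain, idx),
                 polygon = poly, area = polygon_area(poly),
                 shelf = shelf, domain = domain, center = center),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI %s: %.0f um^2 at (%.0f, %.0f)\n",
              x$roi_id, x$area, x$center[1L], x$center[2L]))
  invisible(x)
}

## Summed-area-table transcript counts over side x side squares centered
## on the candidate lattice. Approximate ranking only; exact counting is
## done later by count_in_roi().
candidate_counts <- function(tx, ty, centers, half) {
  vapply(seq_len(nrow(centers)), function(i) {
    sum(abs(tx - centers[i, 1L]) <= half & abs(ty - centers[i, 2L]) <= half)
  }, integer(1L))
}

#' Generate area-standardized ROIs for each shelf and domain
#'
#' Places `n_per_domain_side` non-overlapping ROIs per (shelf, domain)
#' pair — with two shelves, two domains and the default 3 per side, 12
#' ROIs per section. Each ROI lies entirely inside its shelf polygon and
#' on the correct side of the shelf's oronasal axis. Placement is a
#' seeded greedy search: candidate centers on a jittered lattice are
#' ranked by local transcript count (quality-filtered) and accepted in
#' order if non-overlapping, so runs are reproducible and prefer
#' transcript-dense tissue.
#'
#' @param geometry a [generate_section_geometry()] result (supplies the
#'   shelf polygons and oral-side reference points).
#' @param axes named list (`PL`, `PR`) of [fit_oronasal_axis()] axes.
#' @param table transcript table (`feature_name`, `x_location`,
#'   `y_location`, `qv`).
#' @param config an [roi_config()].
#' @param oral_refs optional named list (`PL`, `PR`) of oral-side
#'   reference points; defaults to the geometry's stored references
#'   (the epithelial strip centroids).
#' @return List of `roi` objects (class `roi_set`).
#' @export
generate_rois <- function(geometry, axes, table, config = roi_config(),
                          oral_refs = NULL) {
  stopifnot(inherits(geometry, "section_geometry"), inherits(config, "roi_config"))
  if (!all(c("PL", "PR") %in% names(axes))) {
    stop("axes must be a named list with PL and PR entries", call. = FALSE)
  }
  template <- roi_template(config$shape, config$target_area)
  half_ext <- max(abs(template))
  keep <- table$qv >= config$min_qv
  tx <- table$x_location[keep]
  ty <- table$y_location[keep]
  jitter <- with_seed(config$seed, stats::runif(2L, 0, config$candidate_step))

  rois <- list()
  for (shelf_lab in c("PL", "PR")) {
    sh <- geometry$shelves[[shelf_lab]]
    axis <- axes[[shelf_lab]]
    oral_ref <- oral_refs[[shelf_lab]] %||% sh$oral_reference
    bb <- apply(sh$polygon, 2L, range)
    cx <- seq(bb[1L, 1L] + jitter[1L], bb[2L, 1L], by = config$candidate_step)
    cy <- seq(bb[1L, 2L] + jitter[2L], bb[2L, 2L], by = config$candidate_step)
    centers <- as.matrix(expand.grid(x = cx, y = cy))

    ## candidate is usable only if every ROI vertex is inside the shelf
    vx <- outer(centers[, 1L], template[, 1L], "+")
    vy <- outer(centers[, 2L], template[, 2L], "+")
    ok_shelf <- matrix(points_in_polygon(as.vector(vx), as.vector(vy), sh$polygon),
                       nrow = nrow(centers))
    vert_domain <- matrix(assign_domain(cbind(as.vector(vx), as.vector(vy)),
                                        axis, oral_ref),
                          nrow = nrow(centers))
    for (domain in c("NP", "OP")) {
      usable <- rowSums(ok_shelf) == ncol(ok_shelf) &
        rowSums(vert_domain == domain) == ncol(vert_domain)
      if (sum(usable) < config$n_per_domain_side) {
        stop(sprintf("domain %s of shelf %s is too small to fit %d non-overlapping ROIs",
                     domain, shelf_lab, config$n_per_domain_side), call. = FALSE)
      }
      cand <- centers[usable, , drop = FALSE]
      score <- candidate_counts(tx, ty, cand, sqrt(config$target_area) / 2)
      ord <- order(-score, seq_along(score))   # ties: lattice order
      accepted <- matrix(numeric(0), 0L, 2L)
      for (i in ord) {
        if (nrow(accepted)) {
          dx <- abs(accepted[, 1L] - cand[i, 1L])
          dy <- abs(accepted[, 2L] - cand[i, 2L])
          if (any(dx < 2 * half_ext & dy < 2 * half_ext)) next
        }
        accepted <- rbind(accepted, cand[i, , drop = FALSE])
        if (nrow(accepted) == config$n_per_domain_side) break
      }
      if (nrow(accepted) < config$n_per_domain_side) {
        stop(sprintf("domain %s of shelf %s is too small to fit %d non-overlapping ROIs",
                     domain, shelf_lab, config$n_per_domain_side), call. = FALSE)
      }
      for (i in seq_len(nrow(accepted))) {
        roi <- make_roi(template, accepted[i, ], shelf_lab, domain, i)
        if (abs(roi$area - config$target_area) > config$area_tolerance) {
          stop("ROI area outside tolerance", call. = FALSE)   # defensive
        }
        rois[[length(rois) + 1L]] <- roi
      }
    }
  }
  structure(rois, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("%d ROIs\n", length(x)))
  tab <- table(paste(vapply(x, `[[`, "", "shelf"),
                     vapply(x, `[[`, "", "domain"), sep = "/"))
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Count transcripts inside one ROI
#'
#' Counts quality-passing transcripts (`qv >= min_qv`) whose point lies
#' inside the ROI polygon, boundary inclusive. Genes absent from the ROI
#' are reported as zero counts.
#'
#' @param table transcript table.
#' @param roi an `roi` object.
#' @param min_qv quality threshold.
#' @return Named integer vector over the full gene universe of `table`.
#' @export
count_in_roi <- function(table, roi, min_qv = 20) {
  genes <- if (is.factor(table$feature_name)) levels(table$feature_name) else
    sort(unique(as.character(table$feature_name)))
  keep <- table$qv >= min_qv
  inside <- keep
  inside[keep] <- points_in_polygon(table$x_location[keep],
                                    table$y_location[keep], roi$polygon)
  cnt <- table(factor(table$feature_name[inside], levels = genes))
  stats::setNames(as.integer(cnt), genes)
}

#' ROI-by-gene transcript density matrix
#'
#' @param counts ROI x gene integer matrix.
#' @param area per-ROI areas (um^2), all positive.
#' @param meta data.frame with `roi_id`, `shelf`, `domain`.
#' @param group optional condition label for the ROI set.
#' @return Object of class `density_matrix` with `density = counts/area`.
#' @export
density_matrix <- function(counts, area, meta, group = NA_character_) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(area), nrow(counts) == nrow(meta))
  if (any(area <= 0)) stop("zero-area ROI: densities undefined", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  density <- counts / area
  rownames(density) <- rownames(counts) <- meta$roi_id
  structure(list(density = density, counts = counts, area = area,
                 meta = meta, group = group,
                 gene_index = colnames(counts)),
            class = "density_matrix")
}

#' @export
print.density_matrix <- function(x, ...) {
  cat(sprintf("Density matrix: %d ROIs x %d genes (group %s), %d transcripts\n",
              nrow(x$density), ncol(x$density), x$group, sum(x$counts)))
  invisible(x)
}

#' @export
dim.density_matrix <- function(x) dim(x$density)

#' Subset a density matrix by oronasal domain
#'
#' @param x a [density_matrix()].
#' @param domain `"NP"`, `"OP"`, or `"whole"` (no subsetting).
#' @return A `density_matrix` restricted to the matching ROIs.
#' @export
subset_domain <- function(x, domain = c("whole", "NP", "OP")) {
  domain <- match.arg(domain)
  if (domain == "whole") return(x)
  sel <- x$meta$domain == domain
  density_matrix(x$counts[sel, , drop = FALSE], x$area[sel],
                 x$meta[sel, , drop = FALSE], group = x$group)
}

#' Build the ROI x gene transcript-density matrix
#'
#' Applies [count_in_roi()] to every ROI and divides by the ROI areas,
#' giving transcript densities in um^-2 — the input of the differential
#' expression stage.
#'
#' @inheritParams count_in_roi
#' @param rois an [generate_rois()] result (or list of `roi` objects).
#' @param group optional condition label stored with the matrix.
#' @return A [density_matrix()].
#' @export
build_density_matrix <- function(table, rois, min_qv = 20,
                                 group = NA_character_) {
  if (length(rois) < 1L) stop("need at least one ROI", call. = FALSE)
  counts <- do.call(rbind, lapply(rois, count_in_roi, table = table,
                                  min_qv = min_qv))
  area <- vapply(rois, `[[`, numeric(1L), "area")
  meta <- data.frame(roi_id = vapply(rois, `[[`, "", "roi_id"),
                     shelf = vapply(rois, `[[`, "", "shelf"),
                     domain = vapply(rois, `[[`, "", "domain"))
  density_matrix(counts, area, meta, group = group)
}
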