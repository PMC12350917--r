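#' Configuration for synthetic coronal-section geometry
#'
#' Parameters controlling the simulated section: a rectangular frame (in
#' micrometres, image convention: x rightward, y downward, origin at the
#' top-left) containing two palatal shelves (`PL` left, `PR` right). Each
#' shelf is a superellipse with its oral surface facing +y; a thin
#' epithelial strip runs along the oral half of the shelf boundary
#' (the Shh-expressing epithelium) with a subepithelial mesenchyme band
#' just inside it (the Ptch1-expressing mesenchyme).
#'
#' The ground-truth oronasal axis of each shelf is *defined* as the axis
#' fitted to the noise-free expected Shh x Ptch1 co-expression field (a
#' deterministic grid of pseudo-points through [coexpression_field()] and
#' [fit_oronasal_axis()]), so the estimator recovers it up to sampling
#' noise.
#'
#' @param frame_width,frame_height frame size in um.
#' @param shelf_halfwidth,shelf_halfheight ranges (um) from which each
#'   shelf's superellipse semi-axes are drawn.
#' @param superellipse_exponent shape exponent (2 = ellipse, larger =
#'   boxier).
#' @param center_x_frac horizontal shelf center positions as fractions of
#'   the frame width.
#' @param center_jitter uniform jitter (um) applied to shelf centers.
#' @param rotation_range_deg range of per-shelf rotation angles (degrees).
#' @param strip_q,band_q superellipse level sets bounding the epithelial
#'   strip (`strip_q < q <= 1`) and subepithelial band
#'   (`band_q < q <= strip_q`).
#' @param oral_cut_frac the strip/band cover the boundary arc with local
#'   depth `y' > oral_cut_frac * b`; the negative default extends the
#'   oral epithelium a little past the shelf equator, as it wraps the
#'   medial and lateral faces in a coronal section, which also places
#'   the marker co-expression centroid (the fitted axis anchor) near
#'   mid-shelf.
#' @param axis_bandwidth,axis_grid_step KDE bandwidth and grid step (um)
#'   used when deriving the truth axis from the expected marker field.
#' @param pseudo_spacing spacing (um) of the deterministic pseudo-point
#'   grid representing the noise-free marker intensities.
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(frame_width = 1600, frame_height = 900,
                            shelf_halfwidth = c(300, 340),
                            shelf_halfheight = c(250, 290),
                            superellipse_exponent = 2.5,
                            center_x_frac = c(0.25, 0.75),
                            center_jitter = 10,
                            rotation_range_deg = c(-8, 8),
                            strip_q = 0.85,
                            band_q = 0.60,
                            oral_cut_frac = -0.35,
                            axis_bandwidth = 20,
                            axis_grid_step = 5,
                            pseudo_spacing = 7) {
  cfg <- list(frame_width = frame_width, frame_height = frame_height,
              shelf_halfwidth = shelf_halfwidth,
              shelf_halfheight = shelf_halfheight,
              superellipse_exponent = superellipse_exponent,
              center_x_frac = center_x_frac,
              center_jitter = center_jitter,
              rotation_range_deg = rotation_range_deg,
              strip_q = strip_q, band_q = band_q,
              oral_cut_frac = oral_cut_frac,
              axis_bandwidth = axis_bandwidth,
              axis_grid_step = axis_grid_step,
              pseudo_spacing = pseudo_spacing)
  class(cfg) <- "geometry_config"
  cfg
}

## Local shelf coordinates: x' along the (rotated) mediolateral axis,
## y' positive toward the oral surface.
shelf_local <- function(shelf, x, y) {
  ct <- cos(shelf$theta)
  st <- sin(shelf$theta)
  dx <- x - shelf$center[1L]
  dy <- y - shelf$center[2L]
  xp <- ct * dx + st * dy
  yp <- -st * dx + ct * dy
  n <- shelf$exponent
  q <- abs(xp / shelf$a)^n + abs(yp / shelf$b)^n
  list(xp = xp, yp = yp, q = q)
}

shelf_contains <- function(shelf, x, y) shelf_local(shelf, x, y)$q <= 1

in_strip <- function(shelf, x, y) {
  l <- shelf_local(shelf, x, y)
  l$q <= 1 & l$q > shelf$strip_q & l$yp > shelf$oral_cut
}

in_band <- function(shelf, x, y) {
  l <- shelf_local(shelf, x, y)
  l$q <= shelf$strip_q & l$q > shelf$band_q & l$yp > shelf$oral_cut
}

superellipse_polygon <- function(shelf, scale = 1, n_vertices = 96L) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  e <- 2 / shelf$exponent
  xp <- scale * shelf$a * sign(cos(t)) * abs(cos(t))^e
  yp <- scale * shelf$b * sign(sin(t)) * abs(sin(t))^e
  ct <- cos(shelf$theta)
  st <- sin(shelf$theta)
  cbind(shelf$center[1L] + ct * xp - st * yp,
        shelf$center[2L] + st * xp + ct * yp)
}

## Polygon tracing the epithelial strip: outer arc (q = 1) oral of the
## depth cut, then the inner arc (q = strip_q) in reverse.
strip_polygon <- function(shelf, n_vertices = 64L) {
  arc <- function(scale) {
    e <- 2 / shelf$exponent
    bb <- scale * shelf$b
    u <- min(1, (abs(shelf$oral_cut) / bb)^(1 / e))  # |sin t| at the cut
    t0 <- if (shelf$oral_cut >= 0) asin(u) else -asin(u)
    t <- seq(t0, pi - t0, length.out = n_vertices)
    xp <- scale * shelf$a * sign(cos(t)) * abs(cos(t))^e
    yp <- bb * sign(sin(t)) * abs(sin(t))^e
    ct <- cos(shelf$theta)
    st <- sin(shelf$theta)
    cbind(shelf$center[1L] + ct * xp - st * yp,
          shelf$center[2L] + st * xp + ct * yp)
  }
  outer_arc <- arc(1 - 1e-9)   # nudge inside so vertices satisfy q <= 1
  inner_arc <- arc(shelf$strip_q^(1 / shelf$exponent))
  rbind(outer_arc, inner_arc[rev(seq_len(nrow(inner_arc))), , drop = FALSE])
}

## Deterministic pseudo-transcripts representing the noise-free marker
## layout: grid points inside the strip labelled Shh, inside the band
## labelled Ptch1.
marker_pseudo_table <- function(shelves, frame, spacing) {
  xs <- seq(spacing / 2, frame[1L], by = spacing)
  ys <- seq(spacing / 2, frame[2L], by = spacing)
  g <- expand.grid(x = xs, y = ys)
  keep_a <- rep(FALSE, nrow(g))
  keep_b <- rep(FALSE, nrow(g))
  for (sh in shelves) {
    keep_a <- keep_a | in_strip(sh, g$x, g$y)
    keep_b <- keep_b | in_band(sh, g$x, g$y)
  }
  data.frame(
    transcript_id = seq_len(sum(keep_a) + sum(keep_b)),
    feature_name = factor(rep(c("Shh", "Ptch1"), c(sum(keep_a), sum(keep_b))),
                          levels = c("Shh", "Ptch1")),
    x_location = c(g$x[keep_a], g$x[keep_b]),
    y_location = c(g$y[keep_a], g$y[keep_b]),
    qv = 40
  )
}

region_grid_areas <- function(shelf, axis, oral_ref, step = 2) {
  r <- max(shelf$a, shelf$b)
  xs <- seq(shelf$center[1L] - r, shelf$center[1L] + r, by = step)
  ys <- seq(shelf$center[2L] - r, shelf$center[2L] + r, by = step)
  g <- expand.grid(x = xs, y = ys)
  l <- shelf_local(shelf, g$x, g$y)
  inside <- l$q <= 1
  strip <- inside & l$q > shelf$strip_q & l$yp > shelf$oral_cut
  band <- inside & !strip & l$q > shelf$band_q & l$yp > shelf$oral_cut
  side <- axis_side(cbind(g$x, g$y), axis, oral_ref)
  oral <- inside & !strip & !band & side
  nasal <- inside & !strip & !band & !side
  a <- step^2
  list(epithelium = sum(strip) * a, subepithelial = sum(band) * a,
       oral = sum(oral) * a, nasal = sum(nasal) * a,
       tissue = sum(inside) * a)
}

## TRUE where a point falls on the oral side of the axis (side of the
## reference point); points exactly on the line count as oral.
axis_side <- function(xy, axis, oral_ref) {
  nv <- c(-axis$direction[2L], axis$direction[1L])
  s_ref <- sum((oral_ref - axis$anchor) * nv)
  s <- (xy[, 1L] - axis$anchor[1L]) * nv[1L] +
    (xy[, 2L] - axis$anchor[2L]) * nv[2L]
  s * sign(s_ref) >= 0
}

#' Generate a synthetic two-shelf section geometry
#'
#' Builds a seeded coronal-section geometry: two non-overlapping palatal
#' shelf polygons (`PL`, `PR`), each with an epithelial strip and a
#' subepithelial mesenchyme band along its oral surface, a ground-truth
#' oronasal axis, and per-region areas. Deterministic for a fixed
#' `(seed, params)` pair.
#'
#' @param seed integer seed.
#' @param params a [geometry_config()].
#' @return An object of class `section_geometry`: a list with `frame`
#'   (width/height in um), `shelves` (named list `PL`/`PR`, each holding
#'   `polygon`, `strip_polygon`, `axis_truth`, `oral_reference`, `areas`
#'   and the analytic shape parameters), `config` and `seed`.
#' @export
generate_section_geometry <- function(seed, params = geometry_config()) {
  stopifnot(inherits(params, "geometry_config"))
  if (params$frame_width <= 0 || params$frame_height <= 0) {
    stop("degenerate frame: width and height must be positive", call. = FALSE)
  }
  frame <- c(width = params$frame_width, height = params$frame_height)

  shelves <- with_seed(seed, {
    lapply(seq_len(2L), function(i) {
      a <- stats::runif(1, params$shelf_halfwidth[1L], params$shelf_halfwidth[2L])
      b <- stats::runif(1, params$shelf_halfheight[1L], params$shelf_halfheight[2L])
      cx <- params$center_x_frac[i] * params$frame_width +
        stats::runif(1, -params$center_jitter, params$center_jitter)
      cy <- params$frame_height / 2 +
        stats::runif(1, -params$center_jitter, params$center_jitter)
      theta <- stats::runif(1, params$rotation_range_deg[1L],
                            params$rotation_range_deg[2L]) * pi / 180
      list(label = c("PL", "PR")[i], center = c(cx, cy), a = a, b = b,
           exponent = params$superellipse_exponent, theta = theta,
           strip_q = params$strip_q, band_q = params$band_q,
           oral_cut = params$oral_cut_frac * b)
    })
  })
  names(shelves) <- c("PL", "PR")

  polys <- lapply(shelves, superellipse_polygon)
  if (max(polys$PL[, 1L]) >= min(polys$PR[, 1L])) {
    stop("shelf polygons overlap; enlarge the frame or shrink the shelves",
         call. = FALSE)
  }

  pseudo <- marker_pseudo_table(shelves, frame, params$pseudo_spacing)
  field <- coexpression_field(pseudo, "Shh", "Ptch1",
                              bandwidth = params$axis_bandwidth,
                              step = params$axis_grid_step,
                              lims = c(0, frame[[1L]], 0, frame[[2L]]))

  out <- lapply(names(shelves), function(lab) {
    sh <- shelves[[lab]]
    poly <- polys[[lab]]
    ## oral pole of the shelf: unambiguous oral-side reference
    oral_ref <- c(sh$center[1L] - sin(sh$theta) * 0.98 * sh$b,
                  sh$center[2L] + cos(sh$theta) * 0.98 * sh$b)
    axis <- fit_oronasal_axis(field, poly, shelf = lab)
    sh$polygon <- poly
    sh$strip_polygon <- strip_polygon(sh)
    sh$axis_truth <- axis
    sh$oral_reference <- oral_ref
    sh$areas <- region_grid_areas(sh, axis, oral_ref)
    sh
  })
  names(out) <- names(shelves)

  geom <- list(frame = frame, shelves = out, config = params, seed = seed)
  class(geom) <- "section_geometry"
  geom
}

#' @export
print.section_geometry <- function(x, ...) {
  cat("Synthetic coronal section (", x$frame[["width"]], " x ",
      x$frame[["height"]], " um, seed ", x$seed, ")\n", sep = "")
  for (sh in x$shelves) {
    cat(sprintf(
      "  %s: center (%.0f, %.0f), semi-axes %.0f x %.0f um, tissue %.0f um^2\n",
      sh$label, sh$center[1L], sh$center[2L], sh$a, sh$b, sh$areas$tissue))
  }
  invisible(x)
}

#' Classify points into tissue regions of a synthetic section
#'
#' @param geometry a `section_geometry`.
#' @param x,y point coordinates in um.
#' @return A data.frame with columns `shelf` (`PL`, `PR` or `NA`) and
#'   `region` (`epithelium`, `subepithelial`, `oral`, `nasal`,
#'   `background`).
#' @export
section_region <- function(geometry, x, y) {
  shelf <- rep(NA_character_, length(x))
  region <- rep("background", length(x))
  for (sh in geometry$shelves) {
    l <- shelf_local(sh, x, y)
    inside <- l$q <= 1
    strip <- inside & l$q > sh$strip_q & l$yp > sh$oral_cut
    band <- inside & !strip & l$q > sh$band_q & l$yp > sh$oral_cut
    side <- axis_side(cbind(x, y), sh$axis_truth, sh$oral_reference)
    shelf[inside] <- sh$label
    region[strip] <- "epithelium"
    region[band] <- "subepithelial"
    region[inside & !strip & !band & side] <- "oral"
    region[inside & !strip & !band & !side] <- "nasal"
  }
  data.frame(shelf = shelf, region = region)
}

#' Ground-truth oronasal domain of points in a synthetic section
#'
#' Labels each point `OP` (oral) or `NP` (nasal) by the side of its
#' shelf's ground-truth axis; points outside both shelves get `NA`.
#'
#' @inheritParams section_region
#' @return Character vector of `OP` / `NP` / `NA`.
#' @export
truth_domain <- function(geometry, x, y) {
  lab <- rep(NA_character_, length(x))
  for (sh in geometry$shelves) {
    inside <- shelf_contains(sh, x, y)
    side <- axis_side(cbind(x, y), sh$axis_truth, sh$oral_reference)
    lab[inside] <- ifelse(side[inside], "OP", "NP")
  }
  lab
}
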