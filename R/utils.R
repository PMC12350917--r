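#' @keywords internal
"_PACKAGE"

## Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards so library calls never clobber user seeds.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Shoelace area of a polygon given as an n x 2 matrix (vertices in order,
## not closed). Positive regardless of orientation.
polygon_area <- function(poly) {
  x <- poly[, 1L]
  y <- poly[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1L]
  y <- poly[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

## Boundary-inclusive point-in-polygon, vectorized over points.
points_in_polygon <- function(x, y, poly) {
  if (length(x) == 0L) return(logical(0))
  pracma::inpolygon(x, y, poly[, 1L], poly[, 2L], boundary = TRUE)
}

rotate2 <- function(xy, theta, center = c(0, 0)) {
  ct <- cos(theta)
  st <- sin(theta)
  dx <- xy[, 1L] - center[1L]
  dy <- xy[, 2L] - center[2L]
  cbind(center[1L] + ct * dx - st * dy,
        center[2L] + st * dx + ct * dy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
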