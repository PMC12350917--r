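#' Nuclei placement parameters for the high-resolution bin simulator
#'
#' @param n number of nuclei.
#' @param radius range (um) of nucleus radii (nuclei are disks).
#' @param min_sep minimum center-to-center separation (um); the default
#'   exceeds twice the maximum radius, so disks never overlap.
#' @param extra_nuclear_fraction fraction of all transcripts placed in
#'   bins outside every nucleus (ambient/extra-nuclear signal).
#' @param pixel_size label-mask pixel size (um per pixel).
#' @param max_tries placement attempts before giving up.
#' @return A list of class `nuclei_config`.
#' @export
nuclei_config <- function(n = 120, radius = c(3.5, 7), min_sep = 16,
                          extra_nuclear_fraction = 0.3, pixel_size = 1,
                          max_tries = 50000L) {
  stopifnot(n >= 1, radius[1L] > 0, diff(radius) >= 0, min_sep > 0,
            extra_nuclear_fraction >= 0, extra_nuclear_fraction < 1,
            pixel_size > 0)
  structure(list(n = n, radius = radius, min_sep = min_sep,
                 extra_nuclear_fraction = extra_nuclear_fraction,
                 pixel_size = pixel_size, max_tries = as.integer(max_tries)),
            class = "nuclei_config")
}

#' Sparse 2x2 um bin count grid
#'
#' Constructor for the high-resolution spatial count container. Bin
#' `(row, col)` (0-based) covers the half-open square
#' `[x0 + col*pitch, x0 + (col+1)*pitch) x [y0 + row*pitch, y0 + (row+1)*pitch)`.
#'
#' @param counts bins x genes count matrix (base or `Matrix` sparse);
#'   one row per occupied bin.
#' @param row,col integer 0-based bin indices, parallel to `counts` rows.
#' @param gene_index ordered gene symbols (columns of `counts`).
#' @param pitch bin edge length in um.
#' @param origin `c(x0, y0)` in um.
#' @return Object of class `bin_count_grid`.
#' @export
bin_count_grid <- function(counts, row, col, gene_index, pitch = 2,
                           origin = c(0, 0)) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  stopifnot(nrow(counts) == length(row), length(row) == length(col),
            ncol(counts) == length(gene_index), pitch > 0)
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("bin counts must be non-negative integers", call. = FALSE)
  }
  colnames(counts) <- gene_index
  structure(list(counts = counts, row = as.integer(row), col = as.integer(col),
                 pitch = pitch, origin = origin, gene_index = gene_index),
            class = "bin_count_grid")
}

#' @export
print.bin_count_grid <- function(x, ...) {
  cat(sprintf("Bin count grid: %d occupied %g-um bins, %d genes, %d UMIs\n",
              nrow(x$counts), x$pitch, length(x$gene_index), sum(x$counts)))
  invisible(x)
}

#' Integer nuclei label mask
#'
#' @param labels integer matrix raster (0 = background, k > 0 = nucleus
#'   k); rows index y (downward), columns x.
#' @param pixel_size um per pixel.
#' @param origin `c(x0, y0)` of the mask's top-left corner in um.
#' @return Object of class `nuclei_mask`.
#' @export
nuclei_mask <- function(labels, pixel_size = 1, origin = c(0, 0)) {
  stopifnot(is.matrix(labels), pixel_size > 0)
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size = pixel_size, origin = origin),
            class = "nuclei_mask")
}

#' @export
print.nuclei_mask <- function(x, ...) {
  cat(sprintf("Nuclei label mask: %d x %d px (%g um/px), %d nuclei\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size, max(x$labels)))
  invisible(x)
}

## Mask pixel indices (row, col) of coordinates in um.
mask_pixel_index <- function(mask, x, y) {
  ps <- mask$pixel_size
  j <- pmin(ncol(mask$labels), floor((x - mask$origin[1L]) / ps) + 1L)
  i <- pmin(nrow(mask$labels), floor((y - mask$origin[2L]) / ps) + 1L)
  cbind(as.integer(i), as.integer(j))
}

#' Simulate a high-resolution spatial capture with segmented nuclei
#'
#' Emulates a 2x2-um binned spatial gene-expression assay: nuclei are
#' placed as non-overlapping disks inside the tissue, rasterized into an
#' integer label mask, and per-nucleus expression is drawn from the gene
#' model (expected count = intensity at the nucleus center times the
#' rasterized nucleus area). Each nuclear transcript is placed in one of
#' the nucleus's *interior bins* (bins whose center pixel carries the
#' nucleus label) so that center-containment binning recovers the
#' per-nucleus ground truth exactly; extra-nuclear transcripts go to
#' tissue bins whose center pixel is background.
#'
#' @param geometry a [generate_section_geometry()] result.
#' @param model a [gene_model()].
#' @param nuclei_params a [nuclei_config()].
#' @param condition `"A"` or `"B"`.
#' @param seed integer seed.
#' @return A list with `grid` ([bin_count_grid()]), `mask`
#'   ([nuclei_mask()]) and `truth` (per-nucleus `counts` matrix,
#'   `centers`, `radii`, `area_um2`), plus `condition` and `seed`.
#' @export
simulate_visium_hd <- function(geometry, model,
                               nuclei_params = nuclei_config(),
                               condition = c("A", "B"), seed = 1L) {
  stopifnot(inherits(geometry, "section_geometry"), inherits(model, "gene_model"),
            inherits(nuclei_params, "nuclei_config"))
  condition <- match.arg(condition)
  np <- nuclei_params
  eff <- if (condition == "B") 2^model$effect_lfc else rep(1, length(model$genes))
  w <- geometry$frame[["width"]]
  h <- geometry$frame[["height"]]
  pitch <- 2
  ncol_bins <- ceiling(w / pitch)
  nrow_bins <- ceiling(h / pitch)

  with_seed(seed, {
    ## --- place nuclei -------------------------------------------------
    centers <- matrix(NA_real_, np$n, 2L)
    radii <- numeric(np$n)
    placed <- 0L
    tries <- 0L
    while (placed < np$n) {
      tries <- tries + 1L
      if (tries > np$max_tries) {
        stop(sprintf(
          "nuclei cannot be placed without overlap: %d of %d after %d tries",
          placed, np$n, np$max_tries), call. = FALSE)
      }
      x <- stats::runif(1, 0, w)
      y <- stats::runif(1, 0, h)
      in_tissue <- FALSE
      for (sh in geometry$shelves) {
        if (shelf_local(sh, x, y)$q <= 0.9) { in_tissue <- TRUE; break }
      }
      if (!in_tissue) next
      if (placed > 0L) {
        d2 <- (centers[seq_len(placed), 1L] - x)^2 +
          (centers[seq_len(placed), 2L] - y)^2
        if (min(d2) < np$min_sep^2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- c(x, y)
      radii[placed] <- stats::runif(1, np$radius[1L], np$radius[2L])
    }

    ## --- rasterize mask ----------------------------------------------
    ps <- np$pixel_size
    labels <- matrix(0L, ceiling(h / ps), ceiling(w / ps))
    px_x <- (seq_len(ncol(labels)) - 0.5) * ps
    px_y <- (seq_len(nrow(labels)) - 0.5) * ps
    for (k in seq_len(np$n)) {
      jr <- which(abs(px_x - centers[k, 1L]) <= radii[k])
      ir <- which(abs(px_y - centers[k, 2L]) <= radii[k])
      if (!length(jr) || !length(ir)) next
      dd <- outer((px_y[ir] - centers[k, 2L])^2, (px_x[jr] - centers[k, 1L])^2, "+")
      hit <- dd <= radii[k]^2
      labels[ir, jr][hit] <- k
    }
    mask <- nuclei_mask(labels, pixel_size = ps)
    area_um2 <- tabulate(labels[labels > 0L], nbins = np$n) * ps^2

    ## --- interior bins per nucleus (bin center's pixel carries label) --
    bin_cx <- (seq_len(ncol_bins) - 0.5) * pitch
    bin_cy <- (seq_len(nrow_bins) - 0.5) * pitch
    center_px <- mask_pixel_index(mask,
                                  rep(bin_cx, each = length(bin_cy)),
                                  rep(bin_cy, times = length(bin_cx)))
    center_label <- labels[center_px]            # column-major over (row, col)
    bin_lin <- function(row0, col0) col0 * nrow_bins + row0 + 1L
    all_row0 <- rep(seq_len(nrow_bins) - 1L, times = ncol_bins)
    all_col0 <- rep(seq_len(ncol_bins) - 1L, each = nrow_bins)
    interior <- split(which(center_label > 0L), center_label[center_label > 0L])

    ## tissue bins with background center pixel (for ambient signal)
    bg_tissue <- rep(FALSE, length(center_label))
    bx <- (all_col0 + 0.5) * pitch
    by <- (all_row0 + 0.5) * pitch
    for (sh in geometry$shelves) {
      bg_tissue <- bg_tissue | shelf_contains(sh, bx, by)
    }
    bg_tissue <- which(bg_tissue & center_label == 0L)

    ## --- draw expression ---------------------------------------------
    n_genes <- length(model$genes)
    truth_counts <- matrix(0L, np$n, n_genes,
                           dimnames = list(NULL, model$genes))
    reg <- section_region(geometry, centers[, 1L], centers[, 2L])$region
    trip_bin <- integer(0); trip_gene <- integer(0)
    for (k in seq_len(np$n)) {
      bins_k <- interior[[as.character(k)]]
      if (is.null(bins_k) || !length(bins_k)) next
      mult <- model$multipliers[, reg[k]]
      lambda <- model$base_intensity * mult * eff * area_um2[k]
      cnt <- stats::rpois(n_genes, lambda)
      truth_counts[k, ] <- cnt
      tot <- sum(cnt)
      if (tot == 0L) next
      picked <- if (length(bins_k) == 1L) rep(bins_k, tot) else
        sample(bins_k, tot, replace = TRUE)
      trip_bin <- c(trip_bin, picked)
      trip_gene <- c(trip_gene, rep(seq_len(n_genes), cnt))
    }

    f <- np$extra_nuclear_fraction
    if (f > 0 && length(bg_tissue)) {
      n_extra <- stats::rpois(1, sum(truth_counts) * f / (1 - f))
      if (n_extra > 0L) {
        gp <- model$base_intensity * eff
        trip_bin <- c(trip_bin, sample(bg_tissue, n_extra, replace = TRUE))
        trip_gene <- c(trip_gene, sample.int(n_genes, n_extra, replace = TRUE,
                                             prob = gp / sum(gp)))
      }
    }

    ## --- assemble sparse grid ----------------------------------------
    occ <- sort(unique(trip_bin))
    counts <- Matrix::sparseMatrix(
      i = match(trip_bin, occ), j = trip_gene, x = 1,
      dims = c(length(occ), n_genes))
    grid <- bin_count_grid(counts, row = all_row0[occ], col = all_col0[occ],
                           gene_index = model$genes, pitch = pitch)
    list(grid = grid, mask = mask,
         truth = list(counts = truth_counts, centers = centers, radii = radii,
                      area_um2 = area_um2, nucleus_id = seq_len(np$n)),
         condition = condition, seed = seed)
  })
}
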