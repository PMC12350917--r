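#' Nuclei quality-filter configuration
#'
#' Thresholds used to drop improperly segmented nuclei by size and UMI
#' count, plus the mitochondrial gene-symbol prefix.
#'
#' @param min_area,max_area retained nucleus area bounds (um^2).
#' @param min_umi minimum per-nucleus UMI total.
#' @param mt_prefix case-insensitive gene-symbol prefix identifying
#'   mitochondrial genes.
#' @return A list of class `nuclei_filter_config`.
#' @export
nuclei_filter_config <- function(min_area = 16, max_area = 800,
                                 min_umi = 10, mt_prefix = "mt-") {
  stopifnot(min_area > 0, min_area < max_area, min_umi >= 0)
  structure(list(min_area = min_area, max_area = max_area,
                 min_umi = as.integer(min_umi), mt_prefix = mt_prefix),
            class = "nuclei_filter_config")
}

grid_bin_centers <- function(grid) {
  cbind(grid$origin[1L] + (grid$col + 0.5) * grid$pitch,
        grid$origin[2L] + (grid$row + 0.5) * grid$pitch)
}

#' Assign spatial bins to segmented nuclei
#'
#' A bin is assigned to the nucleus whose mask label contains the bin's
#' center point (nearest-pixel lookup after converting both to um);
#' bins whose center falls on background are unassigned. Assignment is
#' integer-preserving: every bin goes to exactly one nucleus or to the
#' unassigned pool.
#'
#' @param grid a [bin_count_grid()].
#' @param mask a [nuclei_mask()] sharing the grid's coordinate frame.
#' @return Object of class `bin_assignment`: list with `label` (integer
#'   per grid bin, 0 = unassigned) and `nuclei` (data.frame
#'   `nucleus_id, area_um2, x, y` for every label in the mask).
#' @export
assign_bins_to_nuclei <- function(grid, mask) {
  stopifnot(inherits(grid, "bin_count_grid"), inherits(mask, "nuclei_mask"))
  ctr <- grid_bin_centers(grid)
  ps <- mask$pixel_size
  mask_ext <- c(mask$origin[1L], mask$origin[1L] + ncol(mask$labels) * ps,
                mask$origin[2L], mask$origin[2L] + nrow(mask$labels) * ps)
  grid_ext <- c(range(ctr[, 1L]), range(ctr[, 2L]))
  if (grid_ext[1L] < mask_ext[1L] || grid_ext[2L] > mask_ext[2L] ||
      grid_ext[3L] < mask_ext[3L] || grid_ext[4L] > mask_ext[4L]) {
    stop(sprintf(
      paste0("mismatched frames: grid bin centers span x [%.1f, %.1f], ",
             "y [%.1f, %.1f] um but mask covers x [%.1f, %.1f], ",
             "y [%.1f, %.1f] um"),
      grid_ext[1L], grid_ext[2L], grid_ext[3L], grid_ext[4L],
      mask_ext[1L], mask_ext[2L], mask_ext[3L], mask_ext[4L]), call. = FALSE)
  }
  label <- mask$labels[mask_pixel_index(mask, ctr[, 1L], ctr[, 2L])]

  lab_px <- mask$labels[mask$labels > 0L]
  ids <- sort(unique(lab_px))
  area <- tabulate(lab_px, nbins = max(ids)) [ids] * ps^2
  ii <- row(mask$labels)[mask$labels > 0L]
  jj <- col(mask$labels)[mask$labels > 0L]
  cx <- tapply(mask$origin[1L] + (jj - 0.5) * ps, mask$labels[mask$labels > 0L], mean)
  cy <- tapply(mask$origin[2L] + (ii - 0.5) * ps, mask$labels[mask$labels > 0L], mean)
  nuclei <- data.frame(nucleus_id = ids, area_um2 = area,
                       x = as.numeric(cx[as.character(ids)]),
                       y = as.numeric(cy[as.character(ids)]))
  structure(list(label = as.integer(label), nuclei = nuclei),
            class = "bin_assignment")
}

#' Nucleus-by-gene count matrix
#'
#' Constructor for the cell-level count container produced by
#' [aggregate_to_cells()].
#'
#' @param counts nuclei x genes integer matrix.
#' @param nucleus_id integer nucleus labels (rows).
#' @param area_um2 per-nucleus area (um^2).
#' @param centroid n x 2 matrix of nucleus centroids (um).
#' @param gene_index ordered gene symbols.
#' @return Object of class `cell_by_gene`.
#' @export
cell_by_gene <- function(counts, nucleus_id, area_um2, centroid, gene_index) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(nucleus_id),
            length(area_um2) == length(nucleus_id),
            ncol(counts) == length(gene_index))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(area_um2) && any(area_um2 <= 0)) {
    stop("nucleus areas must be positive", call. = FALSE)
  }
  dimnames(counts) <- list(nucleus_id, gene_index)
  structure(list(counts = counts, nucleus_id = nucleus_id,
                 area_um2 = area_um2, centroid = centroid,
                 gene_index = gene_index),
            class = "cell_by_gene")
}

#' @export
print.cell_by_gene <- function(x, ...) {
  cat(sprintf("Cell-by-gene matrix: %d nuclei x %d genes, %d UMIs\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  rem <- attr(x, "removed")
  if (!is.null(rem) && nrow(rem)) {
    cat(sprintf("  (%d nuclei removed by filtering)\n", nrow(rem)))
  }
  invisible(x)
}

#' @export
dim.cell_by_gene <- function(x) dim(x$counts)

#' Aggregate bin counts to nuclei
#'
#' Sums gene counts over the bins assigned to each nucleus. Unassigned
#' bins are excluded, so per-gene totals over nuclei never exceed the
#' grid totals, with equality when no bin is unassigned. Nuclei with no
#' assigned bins do not appear.
#'
#' @param grid the [bin_count_grid()] the assignment was produced from.
#' @param assignment an [assign_bins_to_nuclei()] result.
#' @return A [cell_by_gene()] matrix with mask-derived nucleus areas and
#'   centroids.
#' @export
aggregate_to_cells <- function(grid, assignment) {
  stopifnot(inherits(grid, "bin_count_grid"), inherits(assignment, "bin_assignment"))
  if (length(assignment$label) != nrow(grid$counts)) {
    stop("assignment was not produced from this grid", call. = FALSE)
  }
  sel <- assignment$label > 0L
  if (!any(sel)) {
    return(cell_by_gene(matrix(0L, 0L, length(grid$gene_index)),
                        integer(0), numeric(0),
                        matrix(numeric(0), 0L, 2L), grid$gene_index))
  }
  ids <- sort(unique(assignment$label[sel]))
  grp <- factor(assignment$label[sel], levels = ids)
  agg <- rowsum(as.matrix(grid$counts[sel, , drop = FALSE]), group = grp)
  meta <- assignment$nuclei[match(ids, assignment$nuclei$nucleus_id), ]
  cell_by_gene(agg, nucleus_id = ids, area_um2 = meta$area_um2,
               centroid = cbind(meta$x, meta$y), gene_index = grid$gene_index)
}

#' Filter improperly segmented nuclei by size and UMI count
#'
#' Retains nuclei with `min_area <= area <= max_area` and UMI total
#' `>= min_umi`, preserving order. The removed nuclei and the reasons
#' (`small_area`, `large_area`, `low_umi`, comma-joined when several
#' apply) are attached as the `"removed"` attribute and available via
#' [filter_report()].
#'
#' @param matrix a [cell_by_gene()] matrix.
#' @param config a [nuclei_filter_config()].
#' @return The filtered `cell_by_gene` matrix.
#' @export
filter_nuclei <- function(matrix, config = nuclei_filter_config()) {
  stopifnot(inherits(matrix, "cell_by_gene"),
            inherits(config, "nuclei_filter_config"))
  umi <- rowSums(matrix$counts)
  small <- matrix$area_um2 < config$min_area
  large <- matrix$area_um2 > config$max_area
  low <- umi < config$min_umi
  drop <- small | large | low
  reason <- vapply(which(drop), function(i) {
    paste(c("small_area"[small[i]], "large_area"[large[i]], "low_umi"[low[i]]),
          collapse = ",")
  }, character(1L))
  removed <- data.frame(nucleus_id = matrix$nucleus_id[drop],
                        area_um2 = matrix$area_um2[drop],
                        total_umi = umi[drop],
                        reason = reason)
  keep <- !drop
  out <- cell_by_gene(matrix$counts[keep, , drop = FALSE],
                      matrix$nucleus_id[keep], matrix$area_um2[keep],
                      matrix$centroid[keep, , drop = FALSE],
                      matrix$gene_index)
  attr(out, "removed") <- removed
  out
}

#' @rdname filter_nuclei
#' @param x a filtered `cell_by_gene` matrix.
#' @export
filter_report <- function(x) {
  attr(x, "removed") %||%
    data.frame(nucleus_id = integer(0), area_um2 = numeric(0),
               total_umi = numeric(0), reason = character(0))
}

#' Remove mitochondrial genes by symbol prefix
#'
#' Drops every gene whose symbol starts with `mt_prefix`
#' (case-insensitive) from a count container; all other columns are
#' untouched.
#'
#' @param x a [cell_by_gene()] or [bin_count_grid()].
#' @param mt_prefix non-empty gene-symbol prefix.
#' @return The same type of object without the mitochondrial genes.
#' @export
remove_mt_genes <- function(x, mt_prefix = "mt-") {
  if (!is.character(mt_prefix) || length(mt_prefix) != 1L ||
      is.na(mt_prefix) || nchar(mt_prefix) == 0L) {
    stop("mt_prefix must be a non-empty string ",
         "(an empty prefix would drop every gene)", call. = FALSE)
  }
  UseMethod("remove_mt_genes")
}

#' @export
remove_mt_genes.cell_by_gene <- function(x, mt_prefix = "mt-") {
  keep <- !startsWith(tolower(x$gene_index), tolower(mt_prefix))
  out <- cell_by_gene(x$counts[, keep, drop = FALSE], x$nucleus_id,
                      x$area_um2, x$centroid, x$gene_index[keep])
  attr(out, "removed") <- attr(x, "removed")
  out
}

#' @export
remove_mt_genes.bin_count_grid <- function(x, mt_prefix = "mt-") {
  keep <- !startsWith(tolower(x$gene_index), tolower(mt_prefix))
  bin_count_grid(x$counts[, keep, drop = FALSE], x$row, x$col,
                 x$gene_index[keep], pitch = x$pitch, origin = x$origin)
}

#' One-call nuclei-anchored binning pipeline
#'
#' Convenience wrapper chaining [assign_bins_to_nuclei()],
#' [aggregate_to_cells()], mitochondrial-gene removal and
#' [filter_nuclei()].
#'
#' @inheritParams assign_bins_to_nuclei
#' @param filter a [nuclei_filter_config()].
#' @return List with `cells` (filtered [cell_by_gene()]), `report`
#'   (removed nuclei), `assignment`, and `unassigned_umi` (total counts
#'   in background bins).
#' @export
run_nuclei_binning <- function(grid, mask, filter = nuclei_filter_config()) {
  assignment <- assign_bins_to_nuclei(grid, mask)
  cells <- aggregate_to_cells(grid, assignment)
  cells <- remove_mt_genes(cells, filter$mt_prefix)
  cells <- filter_nuclei(cells, filter)
  unassigned <- sum(grid$counts[assignment$label == 0L, , drop = FALSE])
  list(cells = cells, report = filter_report(cells),
       assignment = assignment, unassigned_umi = unassigned)
}
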