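## File formats -------------------------------------------------------
##
## transcripts.csv : transcript_id,feature_name,x_location,y_location,qv
## bin grid dir    : matrix.mtx (bins x genes), bin_positions.csv
##                   (bin_id,row,col,x_um,y_um), features.csv (gene)
## nuclei mask     : 16-bit single-channel TIFF + <path>.json sidecar
##                   (pixel_size, origin)
## cells dir       : matrix.mtx, cells.csv
##                   (cell_id,area_um2,x,y,total_umi), features.csv
## ROI csv         : roi_id,shelf,domain,area_um2,gene,count,
##                   density_per_um2 (long), "# key: value" comments
## gene sets       : one set per line, "set_name<TAB>gene1,gene2,..."

#' Read and write transcript tables
#'
#' CSV dialect with header
#' `transcript_id,feature_name,x_location,y_location,qv`.
#'
#' @param table transcript data.frame.
#' @param path file path.
#' @return `read_transcripts_csv()` returns the data.frame with
#'   `feature_name` as a factor.
#' @export
write_transcripts_csv <- function(table, path) {
  cols <- c("transcript_id", "feature_name", "x_location", "y_location", "qv")
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transcripts_csv
#' @export
read_transcripts_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "feature_name", "x_location", "y_location", "qv")
  if (!all(need %in% names(tab))) {
    stop("malformed transcript CSV: expected columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  tab$feature_name <- factor(tab$feature_name)
  tab
}

#' Read and write sparse bin count grids
#'
#' MatrixMarket counts plus `bin_positions.csv`
#' (`bin_id,row,col,x_um,y_um`) and `features.csv`.
#'
#' @param grid a [bin_count_grid()].
#' @param dir output directory (created if missing).
#' @return `read_bin_grid()` returns a `bin_count_grid`.
#' @export
write_bin_grid <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(grid$counts, file.path(dir, "matrix.mtx"))
  ctr <- grid_bin_centers(grid)
  utils::write.csv(
    data.frame(bin_id = seq_len(nrow(grid$counts)), row = grid$row,
               col = grid$col, x_um = ctr[, 1L], y_um = ctr[, 2L]),
    file.path(dir, "bin_positions.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(gene = grid$gene_index),
                   file.path(dir, "features.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(jsonlite::toJSON(list(pitch = grid$pitch, origin = grid$origin),
                              auto_unbox = TRUE),
             file.path(dir, "grid_meta.json"))
  invisible(dir)
}

#' @rdname write_bin_grid
#' @export
read_bin_grid <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  pos <- utils::read.csv(file.path(dir, "bin_positions.csv"))
  feats <- utils::read.csv(file.path(dir, "features.csv"))
  meta <- jsonlite::fromJSON(file.path(dir, "grid_meta.json"))
  bin_count_grid(counts, pos$row, pos$col, feats$gene,
                 pitch = meta$pitch, origin = meta$origin)
}

#' Read and write nuclei label masks
#'
#' 16-bit single-channel TIFF (labels up to 65535) with a JSON sidecar
#' `<path>.json` recording `pixel_size` and `origin`.
#'
#' @param mask a [nuclei_mask()].
#' @param path `.tif` path.
#' @return `read_nuclei_mask()` returns a `nuclei_mask`.
#' @export
write_nuclei_mask <- function(mask, path) {
  if (max(mask$labels) > 65535L) {
    stop("more than 65535 nuclei cannot be stored in a 16-bit mask",
         call. = FALSE)
  }
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  writeLines(jsonlite::toJSON(list(pixel_size = mask$pixel_size,
                                   origin = mask$origin), auto_unbox = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_nuclei_mask
#' @export
read_nuclei_mask <- function(path) {
  labels <- tiff::readTIFF(path, as.is = TRUE)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    nuclei_mask(labels, pixel_size = meta$pixel_size, origin = meta$origin)
  } else {
    nuclei_mask(labels)
  }
}

#' Write a filtered cell-by-gene matrix
#'
#' MatrixMarket counts plus `cells.csv`
#' (`cell_id,area_um2,x,y,total_umi`) and `features.csv`; the nuclei
#' filter report, when present, goes to `filter_report.csv`.
#'
#' @param cells a [cell_by_gene()] matrix.
#' @param dir output directory.
#' @export
write_cells <- function(cells, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(cells$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.csv(
    data.frame(cell_id = cells$nucleus_id, area_um2 = cells$area_um2,
               x = cells$centroid[, 1L], y = cells$centroid[, 2L],
               total_umi = rowSums(cells$counts)),
    file.path(dir, "cells.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(gene = cells$gene_index),
                   file.path(dir, "features.csv"), row.names = FALSE,
                   quote = FALSE)
  rep <- attr(cells, "removed")
  if (!is.null(rep)) {
    utils::write.csv(rep, file.path(dir, "filter_report.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

roi_csv_header <- c("roi_id", "shelf", "domain", "area_um2", "gene",
                    "count", "density_per_um2")

#' Write a density matrix as ROI CSV
#'
#' Long-format schema
#' `roi_id,shelf,domain,area_um2,gene,count,density_per_um2`, with the
#' group label stored as a `# group: <label>` comment line. The
#' write/read pair round-trips counts, areas and metadata losslessly.
#'
#' @param matrix a [density_matrix()].
#' @param path file path.
#' @export
write_roi_csv <- function(matrix, path) {
  m <- matrix
  long <- data.frame(
    roi_id = rep(m$meta$roi_id, times = ncol(m$counts)),
    shelf = rep(m$meta$shelf, times = ncol(m$counts)),
    domain = rep(m$meta$domain, times = ncol(m$counts)),
    area_um2 = rep(m$area, times = ncol(m$counts)),
    gene = rep(m$gene_index, each = nrow(m$counts)),
    count = as.vector(m$counts),
    density_per_um2 = as.vector(m$density))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# group: ", m$group), con)
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ROI CSV back into a density matrix
#'
#' Validates the header and rejects negative counts, reporting the
#' offending file line.
#'
#' @param path file written by [write_roi_csv()].
#' @return A [density_matrix()].
#' @export
read_roi_csv <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  group <- NA_character_
  gl <- grep("^# group: ", lines, value = TRUE)
  if (length(gl)) group <- sub("^# group: ", "", gl[1L])
  body_idx <- which(!is_comment)
  header <- strsplit(lines[body_idx[1L]], ",")[[1L]]
  if (!identical(header, roi_csv_header)) {
    stop("malformed ROI CSV header at line ", body_idx[1L], ": expected ",
         paste(roi_csv_header, collapse = ","), call. = FALSE)
  }
  long <- utils::read.csv(text = lines[body_idx], stringsAsFactors = FALSE)
  bad <- which(long$count < 0)
  if (length(bad)) {
    stop("negative count at line ", body_idx[bad[1L] + 1L], " of ", path,
         call. = FALSE)
  }
  roi_ids <- unique(long$roi_id)
  genes <- unique(long$gene)
  counts <- matrix(0L, length(roi_ids), length(genes),
                   dimnames = list(roi_ids, genes))
  counts[cbind(match(long$roi_id, roi_ids), match(long$gene, genes))] <-
    long$count
  first <- long[!duplicated(long$roi_id), ]
  first <- first[match(roi_ids, first$roi_id), ]
  density_matrix(counts, first$area_um2,
                 data.frame(roi_id = roi_ids, shelf = first$shelf,
                            domain = first$domain),
                 group = group)
}

#' Assemble a density matrix from legacy per-ROI count files
#'
#' Each file holds one ROI: `# roi_id: ...`, `# shelf: ...`,
#' `# domain: ...`, `# area_um2: ...` comment lines followed by a
#' two-column `gene,count` table.
#'
#' @param paths character vector of per-ROI CSV paths.
#' @param group optional condition label.
#' @return A [density_matrix()].
#' @export
read_roi_legacy <- function(paths, group = NA_character_) {
  parts <- lapply(paths, function(p) {
    lines <- readLines(p)
    meta <- function(key) {
      v <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
      if (!length(v)) stop("missing '# ", key, ":' header in ", p,
                           call. = FALSE)
      sub(paste0("^# ", key, ": "), "", v[1L])
    }
    tab <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
    if (any(tab$count < 0)) stop("negative count in ", p, call. = FALSE)
    list(roi_id = meta("roi_id"), shelf = meta("shelf"),
         domain = meta("domain"), area = as.numeric(meta("area_um2")),
         counts = stats::setNames(tab$count, tab$gene))
  })
  genes <- unique(unlist(lapply(parts, function(x) names(x$counts))))
  counts <- t(vapply(parts, function(x) {
    v <- stats::setNames(rep(0L, length(genes)), genes)
    v[names(x$counts)] <- x$counts
    v
  }, integer(length(genes))))
  density_matrix(counts, vapply(parts, `[[`, numeric(1L), "area"),
                 data.frame(roi_id = vapply(parts, `[[`, "", "roi_id"),
                            shelf = vapply(parts, `[[`, "", "shelf"),
                            domain = vapply(parts, `[[`, "", "domain")),
                 group = group)
}

#' Write DGE results and the volcano table
#'
#' `write_dge_csv()` emits the per-gene table
#' (`gene,mean_a,mean_b,lfc,variance_p,branch,t,p_raw,p_adj,class`);
#' `write_volcano_csv()` emits `gene,lfc,neg_log10_p,class` on the
#' classification p-value scale.
#'
#' @param fit a [run_dge()] result.
#' @param path file path.
#' @export
write_dge_csv <- function(fit, path) {
  r <- fit$results
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# groups: %s vs %s; classified on %s p",
                     fit$groups[["a"]], fit$groups[["b"]], fit$p_used), con)
  utils::write.csv(r[, c("gene", "mean_a", "mean_b", "lfc", "variance_p",
                         "branch", "t", "p_raw", "p_adj", "class")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dge_csv
#' @export
write_volcano_csv <- function(fit, path) {
  r <- fit$results
  p <- if (fit$p_used == "adjusted") r$p_adj else r$p_raw
  utils::write.csv(
    data.frame(gene = r$gene, lfc = r$lfc,
               neg_log10_p = -log10(pmax(p, 1e-300)), class = r$class),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an oronasal axis as JSON
#'
#' @param axis an [fit_oronasal_axis()] result.
#' @param path file path.
#' @export
write_axis_json <- function(axis, path) {
  writeLines(jsonlite::toJSON(list(anchor = axis$anchor,
                                   direction = axis$direction,
                                   shelf = axis$shelf),
                              auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read user-supplied gene sets
#'
#' One set per line: `set_name<TAB>gene1,gene2,...`.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed gene-set line ", bad[1L],
         ": expected 'set_name<TAB>gene1,gene2,...'", call. = FALSE)
  }
  sets <- lapply(parts, function(p) trimws(strsplit(p[2L], ",")[[1L]]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}
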