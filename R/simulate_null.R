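#' Simulate ROI-level null transcript counts
#'
#' Draws an ROI-by-gene count matrix directly at the ROI level under a
#' homogeneous Poisson null — every gene and every ROI shares the same
#' expected count — and wraps it as a [density_matrix()]. This is the
#' ROI-scale shortcut of the full spatial simulator, used for
#' calibration studies (e.g. type-I error of the variance-gated test)
#' where simulating thousands of genes as point patterns would be
#' needlessly slow: conditional on ROI placement, per-ROI counts of a
#' spatially homogeneous gene are exactly Poisson.
#'
#' @param n_genes number of genes.
#' @param n_rois number of ROIs.
#' @param mean_count expected transcripts per ROI.
#' @param area ROI area in um^2.
#' @param seed integer seed.
#' @param group condition label.
#' @param gene_names optional gene symbols (default `g1 ... gN`).
#' @return A [density_matrix()] with densities `counts / area`.
#' @export
simulate_null_density_matrix <- function(n_genes, n_rois, mean_count = 50,
                                         area = 6400, seed = 1L,
                                         group = "A", gene_names = NULL) {
  stopifnot(n_genes >= 1, n_rois >= 1, mean_count >= 0, area > 0)
  genes <- gene_names %||% paste0("g", seq_len(n_genes))
  counts <- with_seed(seed, {
    matrix(stats::rpois(n_genes * n_rois, mean_count), n_rois, n_genes)
  })
  colnames(counts) <- genes
  meta <- data.frame(roi_id = sprintf("%s_roi_%d", group, seq_len(n_rois)),
                     shelf = "PL", domain = "NP")
  density_matrix(counts, rep(area, n_rois), meta, group = group)
}
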