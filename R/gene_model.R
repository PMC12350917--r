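#' Gene expression model for the synthetic-section simulator
#'
#' Describes per-gene transcript intensities over the tissue regions of a
#' synthetic section. The expected transcript count of gene g in a region
#' R under condition `cond` is
#' `base_intensity[g] * multiplier[g, region(R)] * 2^(effect_lfc[g] * [cond == "B"]) * area(R)`.
#'
#' Regions are `epithelium` (the Shh+ strip), `subepithelial` (the
#' Ptch1+ mesenchyme band adjacent to the strip), `oral` and `nasal`
#' (the remaining tissue on either side of the oronasal axis).
#'
#' @param genes character vector of gene symbols.
#' @param base_intensity per-gene transcripts per um^2 (recycled).
#' @param multipliers numeric matrix `length(genes) x 4` with columns
#'   `epithelium`, `subepithelial`, `oral`, `nasal`; or `NULL` for
#'   uniform 1s.
#' @param effect_lfc per-gene log2 fold change applied under condition
#'   `"B"` (named vector entries matched by gene; unnamed genes get 0).
#' @param mt_flags logical per-gene mitochondrial indicator; defaults to
#'   a case-insensitive `"mt-"` symbol prefix.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(genes, base_intensity,
                       multipliers = NULL,
                       effect_lfc = 0,
                       mt_flags = NULL) {
  stopifnot(length(genes) >= 1L, !anyDuplicated(genes))
  base_intensity <- rep_len(base_intensity, length(genes))
  if (any(base_intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (is.null(multipliers)) {
    multipliers <- matrix(1, length(genes), 4L)
  }
  colnames(multipliers) <- c("epithelium", "subepithelial", "oral", "nasal")
  rownames(multipliers) <- genes
  if (any(multipliers < 0)) stop("multipliers must be >= 0", call. = FALSE)
  lfc <- rep(0, length(genes))
  names(lfc) <- genes
  if (!is.null(names(effect_lfc))) {
    bad <- setdiff(names(effect_lfc), genes)
    if (length(bad)) stop("effect_lfc names not in genes: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    lfc[names(effect_lfc)] <- effect_lfc
  } else {
    lfc[] <- rep_len(effect_lfc, length(genes))
  }
  if (any(!is.finite(lfc))) stop("effect_lfc must be finite", call. = FALSE)
  if (is.null(mt_flags)) {
    mt_flags <- startsWith(tolower(genes), "mt-")
  }
  structure(list(genes = genes, base_intensity = stats::setNames(base_intensity, genes),
                 multipliers = multipliers, effect_lfc = lfc,
                 mt_flags = stats::setNames(mt_flags, genes)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model:", length(x$genes), "genes,",
      sum(x$effect_lfc != 0), "with condition effects,",
      sum(x$mt_flags), "mitochondrial\n")
  invisible(x)
}

## Palate-relevant background symbols used by the default panel.
palate_background_genes <- c(
  "Col1a1", "Eln", "Bgn", "Prrx1", "Alx1", "Dlx1", "Msx1", "Gsc",
  "Dkk1", "Rspo1", "Lgr5", "Wif1", "Sparc", "Prickle1", "Jag1",
  "Wnt5a", "Wnt16", "Lum", "Ogn", "Dcn", "Postn", "Adamts17",
  "Palld", "Fgf7", "Foxc1", "Gdf10", "Igf1", "Pdpn", "Creb3l1",
  "Ndrg2")

#' Default gene panel for synthetic sections
#'
#' Markers `Shh` (epithelial strip only) and `Ptch1` (subepithelial
#' mesenchyme band only), a set of uniformly expressed background genes
#' drawn from a murine palate panel, two mitochondrial genes, and
#' optional condition-effect genes.
#'
#' @param n_background number of uniform background genes (<= 30).
#' @param background_intensity their intensity (transcripts per um^2);
#'   the default 0.012 gives roughly 75 expected transcripts per
#'   6400-um^2 ROI.
#' @param effect_lfc named numeric vector of log2 fold changes applied
#'   under condition `"B"`; names may be new genes (added at
#'   `background_intensity`) or existing panel genes.
#' @param shh_intensity,ptch1_intensity marker intensities within their
#'   restricted regions.
#' @param mito include the `mt-Co1` / `mt-Nd1` pair (flagged
#'   mitochondrial)?
#' @return A [gene_model()].
#' @export
default_gene_model <- function(n_background = 20,
                               background_intensity = 0.012,
                               effect_lfc = c(Tnn = 3, Fmod = 2.5),
                               shh_intensity = 0.10,
                               ptch1_intensity = 0.06,
                               mito = TRUE) {
  bg <- palate_background_genes[seq_len(min(n_background, length(palate_background_genes)))]
  extra <- setdiff(names(effect_lfc), c(bg, "Shh", "Ptch1"))
  genes <- c("Shh", "Ptch1", bg, extra)
  if (mito) genes <- c(genes, "mt-Co1", "mt-Nd1")
  n <- length(genes)
  intensity <- rep(background_intensity, n)
  names(intensity) <- genes
  intensity["Shh"] <- shh_intensity
  intensity["Ptch1"] <- ptch1_intensity
  if (mito) intensity[c("mt-Co1", "mt-Nd1")] <- 0.02
  mult <- matrix(1, n, 4L, dimnames = list(genes, NULL))
  mult["Shh", ] <- c(1, 0, 0, 0)
  mult["Ptch1", ] <- c(0, 1, 0, 0)
  gene_model(genes, intensity, mult, effect_lfc = effect_lfc)
}
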