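#' Differential-expression configuration
#'
#' Thresholds of the transcript-density DGE procedure: the significance
#' level of the F-test variance gate that chooses between the Student
#' and Welch t-test branches, the volcano-plot significance thresholds,
#' and the pseudocount used when forming log2 fold changes of raw
#' densities.
#'
#' @param f_alpha variance-gate significance level (two-tailed F test).
#' @param p_threshold p-value threshold for calling a gene up/down.
#' @param lfc_threshold absolute log2-fold-change threshold.
#' @param pseudocount density pseudocount (um^-2) added to both means;
#'   the default `1/6400` is one transcript per default-sized ROI.
#' @param use_adjusted_p_for_class classify on BH-adjusted p-values
#'   (`TRUE`, default) or raw p-values.
#' @return A list of class `dge_config`.
#' @export
dge_config <- function(f_alpha = 0.05, p_threshold = 0.05,
                       lfc_threshold = 1, pseudocount = 1 / 6400,
                       use_adjusted_p_for_class = TRUE) {
  stopifnot(f_alpha > 0, f_alpha < 1, p_threshold > 0, lfc_threshold > 0,
            pseudocount >= 0)
  structure(list(f_alpha = f_alpha, p_threshold = p_threshold,
                 lfc_threshold = lfc_threshold, pseudocount = pseudocount,
                 use_adjusted_p_for_class = use_adjusted_p_for_class),
            class = "dge_config")
}

#' Log2 fold change of raw mean densities
#'
#' `log2((a + eps) / (b + eps))` with `eps` the pseudocount, applied
#' symmetrically to numerator and denominator. With `eps = 0` a zero
#' denominator is an error instructing the caller to set a pseudocount.
#'
#' @param a,b non-negative mean densities (`a` is the numerator);
#'   vectorized.
#' @param pseudocount `eps >= 0`.
#' @return `log2((a + eps)/(b + eps))`.
#' @export
log2_fold_change <- function(a, b, pseudocount = 1 / 6400) {
  if (any(a < 0) || any(b < 0)) stop("means must be >= 0", call. = FALSE)
  if (pseudocount == 0 && any(b == 0)) {
    stop("zero denominator with pseudocount 0; ",
         "set a positive pseudocount to define the fold change",
         call. = FALSE)
  }
  log2((a + pseudocount) / (b + pseudocount))
}

#' Variance-reducing log2(x + 1) transform
#'
#' @param values non-negative densities.
#' @return `log2(values + 1)` elementwise.
#' @export
log2p1_transform <- function(values) {
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  log2(values + 1)
}

#' F-test-gated two-sample t-test
#'
#' Performs a two-tailed F test of the variance ratio (larger sample
#' variance in the numerator, the spreadsheet `F.TEST` convention). If
#' the F-test p-value falls below `f_alpha`, a Welch t-test
#' (Welch–Satterthwaite degrees of freedom) is used; otherwise a
#' pooled-variance Student t-test. Samples whose total variance is zero
#' are degenerate: they get `p = 1`, `t = 0` and a `degenerate` flag.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param f_alpha variance-gate significance level.
#' @return List with `variance_p`, `branch` (`"student"`/`"welch"`),
#'   `t_stat`, `df`, `p_raw`, `degenerate`.
#' @export
variance_gated_t_test <- function(a, b, f_alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va + vb == 0) {
    return(list(variance_p = 1, branch = "student", t_stat = 0,
                df = length(a) + length(b) - 2L, p_raw = 1,
                degenerate = TRUE))
  }
  ## Two-tailed F test, larger variance in the numerator.
  if (va >= vb) {
    fp <- 2 * stats::pf(va / vb, length(a) - 1L, length(b) - 1L,
                        lower.tail = FALSE)
  } else {
    fp <- 2 * stats::pf(vb / va, length(b) - 1L, length(a) - 1L,
                        lower.tail = FALSE)
  }
  fp <- min(1, fp)
  branch <- if (fp < f_alpha) "welch" else "student"
  tt <- stats::t.test(a, b, var.equal = branch == "student")
  list(variance_p = fp, branch = branch,
       t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = tt$p.value, degenerate = FALSE)
}

#' Benjamini–Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment returned in input order:
#' `p_adj(i) = min over j >= i of (m/j) * p(j)` on the sorted p-values,
#' capped at 1. Idempotent and monotone in the sorted order.
#'
#' @param p_values p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Volcano significance classification
#'
#' `"up"` if `p < p_threshold` and `lfc > lfc_threshold`, `"down"` if
#' `p < p_threshold` and `lfc < -lfc_threshold`, otherwise `"ns"`.
#'
#' @param lfc log2 fold change(s).
#' @param p p-value(s) on the scale chosen by the caller (raw or
#'   adjusted).
#' @param config a [dge_config()].
#' @return Character vector of `"up"` / `"down"` / `"ns"`.
#' @export
classify_deg <- function(lfc, p, config = dge_config()) {
  stopifnot(all(is.finite(lfc)), all(is.finite(p)))
  out <- rep("ns", length(lfc))
  out[p < config$p_threshold & lfc > config$lfc_threshold] <- "up"
  out[p < config$p_threshold & lfc < -config$lfc_threshold] <- "down"
  out
}

#' Transcript-density differential gene expression
#'
#' The package's core procedure. For each gene: the log2 fold change is
#' computed on the *raw* mean densities (group B over group A, with a
#' symmetric pseudocount); the p-value comes from the F-test-gated
#' Student/Welch t-test applied to `log2(x + 1)`-transformed densities;
#' p-values are Benjamini–Hochberg adjusted across all genes; genes are
#' classified `up` / `down` / `ns` against the volcano thresholds
#' (adjusted p by default). Degenerate genes (zero variance in both
#' groups) are flagged and never classified up or down.
#'
#' @param matrix_a [density_matrix()] of the reference group (A).
#' @param matrix_b [density_matrix()] of the comparison group (B);
#'   positive `lfc` means enriched in B.
#' @param config a [dge_config()].
#' @return Object of class `spatial_dge`; see [as.data.frame.spatial_dge()]
#'   for the per-gene table (`gene`, `mean_a`, `mean_b`, `lfc`,
#'   `variance_p`, `branch`, `t`, `p_raw`, `p_adj`, `class`,
#'   `degenerate`).
#' @export
run_dge <- function(matrix_a, matrix_b, config = dge_config()) {
  stopifnot(inherits(matrix_a, "density_matrix"),
            inherits(matrix_b, "density_matrix"),
            inherits(config, "dge_config"))
  ga <- matrix_a$gene_index
  gb <- matrix_b$gene_index
  if (!identical(ga, gb)) {
    dif <- c(setdiff(ga, gb), setdiff(gb, ga))
    stop("gene indices differ between groups; symmetric difference: ",
         paste(dif, collapse = ", "), call. = FALSE)
  }
  if (nrow(matrix_a$density) < 2L || nrow(matrix_b$density) < 2L) {
    stop("each group needs at least 2 ROIs", call. = FALSE)
  }
  da <- matrix_a$density
  db <- matrix_b$density
  ta <- log2p1_transform(da)
  tb <- log2p1_transform(db)
  mean_a <- colMeans(da)
  mean_b <- colMeans(db)
  lfc <- log2_fold_change(mean_b, mean_a, config$pseudocount)

  tests <- lapply(seq_along(ga), function(j) {
    variance_gated_t_test(ta[, j], tb[, j], config$f_alpha)
  })
  p_raw <- vapply(tests, `[[`, numeric(1L), "p_raw")
  p_adj <- benjamini_hochberg(p_raw)
  degenerate <- vapply(tests, `[[`, logical(1L), "degenerate")
  p_class <- if (config$use_adjusted_p_for_class) p_adj else p_raw
  cls <- classify_deg(lfc, p_class, config)
  cls[degenerate] <- "ns"

  results <- data.frame(
    gene = ga,
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    lfc = unname(lfc),
    variance_p = vapply(tests, `[[`, numeric(1L), "variance_p"),
    branch = vapply(tests, `[[`, character(1L), "branch"),
    t = vapply(tests, `[[`, numeric(1L), "t_stat"),
    p_raw = p_raw, p_adj = p_adj,
    class = cls, degenerate = degenerate)
  structure(list(results = results, config = config,
                 n_a = nrow(da), n_b = nrow(db),
                 groups = c(a = matrix_a$group, b = matrix_b$group),
                 p_used = if (config$use_adjusted_p_for_class) "adjusted" else "raw"),
            class = "spatial_dge")
}

#' @export
print.spatial_dge <- function(x, ...) {
  tab <- table(factor(x$results$class, levels = c("up", "down", "ns")))
  cat(sprintf("Transcript-density DGE: %d genes, %d vs %d ROIs (%s vs %s)\n",
              nrow(x$results), x$n_a, x$n_b,
              x$groups[["a"]], x$groups[["b"]]))
  cat(sprintf("  up %d, down %d, ns %d (classified on %s p < %g, |lfc| > %g)\n",
              tab[["up"]], tab[["down"]], tab[["ns"]],
              x$p_used, x$config$p_threshold, x$config$lfc_threshold))
  invisible(x)
}

#' @export
summary.spatial_dge <- function(object, n = 10L, ...) {
  print(object)
  sig <- object$results[object$results$class != "ns", ]
  sig <- sig[order(sig$p_adj), ]
  if (nrow(sig)) {
    cat("Top differential genes:\n")
    print(utils::head(sig[, c("gene", "lfc", "p_raw", "p_adj", "class")], n),
          row.names = FALSE, digits = 4)
  }
  invisible(object$results)
}

#' @export
coef.spatial_dge <- function(object, ...) {
  stats::setNames(object$results$lfc, object$results$gene)
}

#' Per-gene results of a DGE fit
#'
#' @param x a `spatial_dge` object.
#' @param row.names,optional,... unused, present for generic
#'   compatibility.
#' @return The per-gene results data.frame.
#' @export
as.data.frame.spatial_dge <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  x$results
}

#' Volcano plot of a DGE fit
#'
#' Log2 fold change against `-log10` of the classification p-value,
#' upregulated genes in red, downregulated in blue, non-significant in
#' grey; dashed lines mark the thresholds.
#'
#' @param x a `spatial_dge` object.
#' @param label_sig annotate significant genes with their symbols?
#' @param ... passed to [graphics::plot()].
#' @export
plot.spatial_dge <- function(x, label_sig = TRUE, ...) {
  r <- x$results
  p <- if (x$p_used == "adjusted") r$p_adj else r$p_raw
  nlp <- -log10(pmax(p, 1e-300))
  col <- c(up = "red3", down = "blue3", ns = "grey60")[r$class]
  graphics::plot(r$lfc, nlp, pch = 19, cex = 0.6, col = col,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = bquote(-log[10] ~ .(x$p_used) ~ italic(p)), ...)
  graphics::abline(v = c(-1, 1) * x$config$lfc_threshold, lty = 2,
                   col = "grey40")
  graphics::abline(h = -log10(x$config$p_threshold), lty = 2, col = "grey40")
  if (label_sig && any(r$class != "ns")) {
    sig <- r$class != "ns"
    graphics::text(r$lfc[sig], nlp[sig], r$gene[sig], pos = 3, cex = 0.6)
  }
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided (upper-tail) hypergeometric test of a hit list against
#' named gene sets within a universe. A set is significant when its
#' p-value is below `p_threshold` *and* more than one hit gene overlaps
#' it (the gene-count rule).
#'
#' @param hits character vector of hit genes (must lie in `universe`).
#' @param gene_sets named list of character vectors; genes outside the
#'   universe are ignored.
#' @param universe character vector of all testable genes.
#' @param p_threshold significance level.
#' @return data.frame with `set`, `set_size`, `overlap`, `p`,
#'   `significant`.
#' @export
over_representation <- function(hits, gene_sets, universe,
                                p_threshold = 0.05) {
  hits <- unique(hits)
  bad <- setdiff(hits, universe)
  if (length(bad)) {
    stop("hit genes outside the universe: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  N <- length(unique(universe))
  n <- length(hits)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(hits, set))
    p <- stats::phyper(k - 1, length(set), N - length(set), n,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               significant = p < p_threshold & k > 1)
  })
  do.call(rbind, rows)
}
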