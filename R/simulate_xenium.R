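## Rejection-sample `n` uniform points from one tissue region of a shelf.
sample_region_points <- function(shelf, oral_ref, region, n) {
  if (n == 0L) return(cbind(numeric(0), numeric(0)))
  r <- max(shelf$a, shelf$b)
  out_x <- numeric(0)
  out_y <- numeric(0)
  batch <- max(200L, 4L * n)
  guard <- 0L
  while (length(out_x) < n) {
    guard <- guard + 1L
    if (guard > 1000L) stop("region sampling failed to converge", call. = FALSE)
    x <- stats::runif(batch, shelf$center[1L] - r, shelf$center[1L] + r)
    y <- stats::runif(batch, shelf$center[2L] - r, shelf$center[2L] + r)
    l <- shelf_local(shelf, x, y)
    inside <- l$q <= 1
    strip <- inside & l$q > shelf$strip_q & l$yp > shelf$oral_cut
    band <- inside & !strip & l$q > shelf$band_q & l$yp > shelf$oral_cut
    keep <- switch(region,
      epithelium = strip,
      subepithelial = band,
      oral = inside & !strip & !band &
        axis_side(cbind(x, y), shelf$axis_truth, oral_ref),
      nasal = inside & !strip & !band &
        !axis_side(cbind(x, y), shelf$axis_truth, oral_ref),
      stop("unknown region: ", region))
    out_x <- c(out_x, x[keep])
    out_y <- c(out_y, y[keep])
    ## adapt batch size to the observed acceptance rate
    acc <- max(mean(keep), 1e-3)
    batch <- as.integer(min(2e5, max(200, ceiling((n - length(out_x)) / acc * 1.3))))
  }
  cbind(out_x[seq_len(n)], out_y[seq_len(n)])
}

#' Simulate imaging-based in situ transcripts over a synthetic section
#'
#' Draws decoded transcripts as an inhomogeneous Poisson point process:
#' the expected count of gene g in tissue region R is
#' `base_intensity[g] * multiplier[g, region(R)] * 2^(effect_lfc[g] * [condition == "B"]) * area(R)`,
#' with positions uniform within each region. Quality scores are uniform
#' in `[20, 40]`, with a configurable fraction of low-quality
#' transcripts (`qv` in `[5, 20)`) injected to exercise filtering.
#' Deterministic for a fixed seed.
#'
#' @param geometry a [generate_section_geometry()] result.
#' @param model a [gene_model()].
#' @param condition `"A"` (reference) or `"B"` (effect condition).
#' @param seed integer seed.
#' @param low_qv_fraction fraction of transcripts given `qv < 20`.
#' @return A list with `transcripts` (data.frame
#'   `transcript_id, feature_name, x_location, y_location, qv`; the
#'   `feature_name` factor levels carry the full panel) and `truth`
#'   (list: per-transcript `domain` (`OP`/`NP`), `shelf`, `region`, and
#'   per-gene `true_lfc`), plus `condition` and `seed`.
#' @export
simulate_xenium_transcripts <- function(geometry, model,
                                        condition = c("A", "B"),
                                        seed = 1L,
                                        low_qv_fraction = 0.05) {
  stopifnot(inherits(geometry, "section_geometry"), inherits(model, "gene_model"))
  condition <- match.arg(condition)
  if (length(model$genes) == 0L) stop("gene model is empty", call. = FALSE)
  eff <- if (condition == "B") 2^model$effect_lfc else rep(1, length(model$genes))
  regions <- c("epithelium", "subepithelial", "oral", "nasal")

  sim <- with_seed(seed, {
    parts <- list()
    for (shelf_lab in c("PL", "PR")) {
      sh <- geometry$shelves[[shelf_lab]]
      for (reg in regions) {
        rate <- model$base_intensity * model$multipliers[, reg] * eff
        lambda <- rate * sh$areas[[reg]]
        counts <- stats::rpois(length(lambda), lambda)
        total <- sum(counts)
        if (total == 0L) next
        xy <- sample_region_points(sh, sh$oral_reference, reg, total)
        parts[[length(parts) + 1L]] <- data.frame(
          feature_name = rep(model$genes, counts),
          x_location = xy[, 1L], y_location = xy[, 2L],
          shelf = shelf_lab, region = reg)
      }
    }
    tab <- if (length(parts)) do.call(rbind, parts) else
      data.frame(feature_name = character(0), x_location = numeric(0),
                 y_location = numeric(0), shelf = character(0),
                 region = character(0))
    n <- nrow(tab)
    qv <- stats::runif(n, 20, 40)
    low <- stats::runif(n) < low_qv_fraction
    qv[low] <- stats::runif(sum(low), 5, 20)
    tab$qv <- qv
    tab
  })

  domain <- truth_domain(geometry, sim$x_location, sim$y_location)
  transcripts <- data.frame(
    transcript_id = seq_len(nrow(sim)),
    feature_name = factor(sim$feature_name, levels = model$genes),
    x_location = sim$x_location,
    y_location = sim$y_location,
    qv = sim$qv)
  list(transcripts = transcripts,
       truth = list(domain = domain, shelf = sim$shelf, region = sim$region,
                    true_lfc = model$effect_lfc),
       condition = condition, seed = seed)
}
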