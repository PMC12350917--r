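#' Two-group comparison configuration
#'
#' Declarative description of a synthetic two-group comparison run:
#' how many sections to simulate per group, the gene panel, and the
#' geometry / ROI / DGE parameters. Group A is simulated under
#' condition `"A"` (reference) and group B under condition `"B"`
#' (condition effects from the gene model applied), so positive fold
#' changes mean enrichment in group B.
#'
#' @param n_sections sections simulated per group.
#' @param model a [gene_model()].
#' @param geometry a [geometry_config()].
#' @param roi an [roi_config()].
#' @param dge a [dge_config()].
#' @param group_labels labels of the two comparison groups.
#' @param low_qv_fraction fraction of low-quality transcripts injected
#'   by the simulator.
#' @param bandwidth,step KDE bandwidth and grid step (um) for the
#'   marker-partition stage.
#' @return A list of class `comparison_config`.
#' @export
comparison_config <- function(n_sections = 2, model = default_gene_model(),
                              geometry = geometry_config(),
                              roi = roi_config(), dge = dge_config(),
                              group_labels = c("WT", "KO"),
                              low_qv_fraction = 0.05,
                              bandwidth = 20, step = 5) {
  stopifnot(n_sections >= 1, length(group_labels) == 2L)
  structure(list(n_sections = as.integer(n_sections), model = model,
                 geometry = geometry, roi = roi, dge = dge,
                 group_labels = group_labels,
                 low_qv_fraction = low_qv_fraction,
                 bandwidth = bandwidth, step = step),
            class = "comparison_config")
}

#' Load a comparison configuration from a YAML or JSON file
#'
#' Flat key paths mirror the configuration fields (e.g. `roi:
#' target_area: 6400`, `dge: f_alpha: 0.05`); unspecified fields keep
#' their defaults. The gene model is controlled by the
#' [default_gene_model()] arguments under a `model:` block.
#'
#' @param path YAML or JSON file.
#' @return A [comparison_config()].
#' @export
load_comparison_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_into <- function(ctor, values) {
    if (is.null(values)) return(ctor())
    if (!is.null(values$effect_lfc)) {
      values$effect_lfc <- unlist(values$effect_lfc)
    }
    do.call(ctor, values)
  }
  comparison_config(
    n_sections = raw$n_sections %||% 2,
    model = merge_into(default_gene_model, raw$model),
    geometry = merge_into(geometry_config, raw$geometry),
    roi = merge_into(roi_config, raw$roi),
    dge = merge_into(dge_config, raw$dge),
    group_labels = raw$group_labels %||% c("WT", "KO"),
    low_qv_fraction = raw$low_qv_fraction %||% 0.05,
    bandwidth = raw$bandwidth %||% 20,
    step = raw$step %||% 5)
}

#' Oral-side reference from the epithelial marker distribution
#'
#' The oral side of a fitted oronasal axis is identified from the
#' epithelial marker itself: Shh is restricted to the oral epithelium,
#' so the side of the axis carrying the majority of the shelf's Shh
#' transcripts is oral. Returns the centroid of the majority-side
#' transcripts, which lies strictly on that side. (A single density
#' mode is not reliable here: when the epithelium wraps around the
#' shelf margin, the mode can sit on an arm of the strip that crosses
#' to the nasal side.)
#'
#' @param table transcript table.
#' @param polygon shelf polygon (n x 2 matrix, um).
#' @param axis the shelf's fitted [fit_oronasal_axis()] axis.
#' @param gene epithelial marker symbol.
#' @return Reference point `c(x, y)` on the oral side.
#' @export
marker_oral_reference <- function(table, polygon, axis, gene = "Shh") {
  sel <- table$feature_name == gene
  ins <- points_in_polygon(table$x_location[sel], table$y_location[sel],
                           polygon)
  x <- table$x_location[sel][ins]
  y <- table$y_location[sel][ins]
  if (!length(x)) {
    stop("no ", gene, " transcripts inside the shelf polygon", call. = FALSE)
  }
  nv <- c(-axis$direction[2L], axis$direction[1L])
  s <- (x - axis$anchor[1L]) * nv[1L] + (y - axis$anchor[2L]) * nv[2L]
  pick <- if (sum(s >= 0) >= sum(s < 0)) s >= 0 else s < 0
  c(mean(x[pick]), mean(y[pick]))
}

## Partition one simulated section: marker field, per-shelf fitted axes
## and marker-derived oral references.
partition_section <- function(geometry, table, bandwidth = 20, step = 5) {
  lims <- c(0, geometry$frame[["width"]], 0, geometry$frame[["height"]])
  field <- coexpression_field(table, "Shh", "Ptch1", bandwidth = bandwidth,
                              step = step, lims = lims)
  axes <- list()
  refs <- list()
  for (lab in c("PL", "PR")) {
    poly <- geometry$shelves[[lab]]$polygon
    axes[[lab]] <- fit_oronasal_axis(field, poly, shelf = lab)
    refs[[lab]] <- marker_oral_reference(table, poly, axes[[lab]])
  }
  list(field = field, axes = axes, oral_refs = refs)
}

rbind_density <- function(mats) {
  density_matrix(do.call(rbind, lapply(mats, `[[`, "counts")),
                 unlist(lapply(mats, `[[`, "area")),
                 do.call(rbind, lapply(mats, `[[`, "meta")),
                 group = mats[[1L]]$group)
}

#' Run a full two-group sub-regional comparison
#'
#' Orchestrates simulate -> partition -> ROI -> density -> DGE for a
#' two-group design and runs the differential analysis at three scopes:
#' whole shelves (all ROIs), nasal domains only (NP), and oral domains
#' only (OP). Every source of randomness derives from `seed`; running
#' the same configuration and seed twice produces byte-identical CSV
#' outputs. A JSON manifest records the configuration, seed, package
#' version and per-stage record counts; a plain-text log gets one INFO
#' line per stage. Any stage failure aborts with the failing stage
#' named and the manifest marked incomplete.
#'
#' @param config a [comparison_config()] or path to a YAML/JSON file
#'   for [load_comparison_config()].
#' @param seed integer master seed.
#' @param out_dir output directory (created).
#' @return Invisibly, a list with `fits` (named `spatial_dge` objects
#'   for scopes `whole`, `NP`, `OP`), `density` (per-group pooled
#'   [density_matrix()]s), `manifest` and `out_dir`.
#' @export
run_comparison <- function(config = comparison_config(), seed = 1L,
                           out_dir = tempfile("spatroi_run_")) {
  if (is.character(config)) config <- load_comparison_config(config)
  stopifnot(inherits(config, "comparison_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("%s INFO %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  manifest <- list(seed = seed, package_version = as.character(
    utils::packageVersion("spatroi")),
    groups = config$group_labels, n_sections = config$n_sections,
    thresholds = list(f_alpha = config$dge$f_alpha,
                      p_threshold = config$dge$p_threshold,
                      lfc_threshold = config$dge$lfc_threshold,
                      pseudocount = config$dge$pseudocount,
                      p_used = if (config$dge$use_adjusted_p_for_class)
                        "adjusted" else "raw",
                      target_area = config$roi$target_area,
                      area_tolerance = config$roi$area_tolerance,
                      min_qv = config$roi$min_qv),
    stages = list(), status = "incomplete")
  write_manifest <- function() {
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(out_dir, "manifest.json"))
  }
  write_manifest()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      manifest$status <<- paste0("failed at stage ", name)
      write_manifest()
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    log_line("stage %s done in %.2f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  groups <- list(list(label = config$group_labels[1L], condition = "A"),
                 list(label = config$group_labels[2L], condition = "B"))
  pooled <- list()
  section_counts <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    mats <- list()
    for (s in seq_len(config$n_sections)) {
      sec_seed <- seed + 7919L * ((gi - 1L) * config$n_sections + s)
      tag <- sprintf("%s_s%d", grp$label, s)
      geom <- stage(paste0("geometry:", tag),
                    generate_section_geometry(sec_seed, config$geometry))
      sim <- stage(paste0("simulate:", tag),
                   simulate_xenium_transcripts(
                     geom, config$model, condition = grp$condition,
                     seed = sec_seed + 1L,
                     low_qv_fraction = config$low_qv_fraction))
      part <- stage(paste0("partition:", tag),
                    partition_section(geom, sim$transcripts,
                                      config$bandwidth, config$step))
      roi_cfg <- config$roi
      roi_cfg$seed <- sec_seed + 2L
      rois <- stage(paste0("roi:", tag),
                    generate_rois(geom, part$axes, sim$transcripts, roi_cfg,
                                  oral_refs = part$oral_refs))
      dm <- stage(paste0("density:", tag),
                  build_density_matrix(sim$transcripts, rois,
                                       min_qv = config$roi$min_qv,
                                       group = grp$label))
      dm$meta$roi_id <- paste0(tag, "_", dm$meta$roi_id)
      rownames(dm$counts) <- rownames(dm$density) <- dm$meta$roi_id
      write_roi_csv(dm, file.path(out_dir, paste0("roi_", tag, ".csv")))
      for (lab in c("PL", "PR")) {
        write_axis_json(part$axes[[lab]],
                        file.path(out_dir, sprintf("axis_%s_%s.json", tag, lab)))
      }
      section_counts[[tag]] <- list(transcripts = nrow(sim$transcripts),
                                    rois = length(rois))
      mats[[s]] <- dm
    }
    pooled[[grp$label]] <- rbind_density(mats)
  }

  fits <- list()
  for (scope in c("whole", "NP", "OP")) {
    fit <- stage(paste0("dge:", scope), {
      a <- subset_domain(pooled[[1L]], if (scope == "whole") "whole" else scope)
      b <- subset_domain(pooled[[2L]], if (scope == "whole") "whole" else scope)
      run_dge(a, b, config$dge)
    })
    write_dge_csv(fit, file.path(out_dir, paste0("dge_", scope, ".csv")))
    write_volcano_csv(fit, file.path(out_dir, paste0("volcano_", scope, ".csv")))
    fits[[scope]] <- fit
  }

  manifest$stages <- c(section_counts,
                       list(genes = length(config$model$genes),
                            rois_per_group = vapply(pooled, function(m)
                              nrow(m$density), integer(1L))))
  manifest$status <- "complete"
  write_manifest()
  log_line("run complete: %d x 3 scopes written to %s",
           length(groups), out_dir)
  invisible(list(fits = fits, density = pooled,
                 manifest = file.path(out_dir, "manifest.json"),
                 out_dir = out_dir))
}
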