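## Expensive fixtures (section geometries, simulations) are built once
## per test run and shared across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

default_section <- function() {
  fixture("geom1", function() generate_section_geometry(1))
}

default_sim <- function() {
  fixture("sim1", function() {
    simulate_xenium_transcripts(default_section(), default_gene_model(),
                                condition = "A", seed = 101)
  })
}

## Fitted partition (field, axes, Shh-mode references) of the default sim.
default_partition <- function() {
  fixture("part1", function() {
    spatroi:::partition_section(default_section(), default_sim()$transcripts)
  })
}

truth_axes <- function(geometry) {
  list(PL = geometry$shelves$PL$axis_truth, PR = geometry$shelves$PR$axis_truth)
}

## Minimal hand-built square ROI for counting tests.
square_roi <- function(x0, y0, side, id = "T_OP_1") {
  poly <- cbind(c(x0, x0 + side, x0 + side, x0),
                c(y0, y0, y0 + side, y0 + side))
  structure(list(roi_id = id, polygon = poly, area = side^2,
                 shelf = "T", domain = "OP", center = c(x0 + side / 2, y0 + side / 2)),
            class = "roi")
}
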