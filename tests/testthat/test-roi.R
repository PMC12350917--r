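test_that("default configuration yields 12 standardized ROIs", {
  g <- default_section()
  sim <- default_sim()
  rois <- generate_rois(g, truth_axes(g), sim$transcripts, roi_config(seed = 2))
  expect_length(rois, 12)
  tab <- table(vapply(rois, `[[`, "", "shelf"), vapply(rois, `[[`, "", "domain"))
  expect_true(all(tab == 3))
  areas <- vapply(rois, `[[`, numeric(1), "area")
  expect_true(all(abs(areas - 6400) <= 100))
  ## each ROI inside its shelf and on its side of the axis
  for (r in rois) {
    sh <- g$shelves[[r$shelf]]
    expect_true(all(spatroi:::points_in_polygon(r$polygon[, 1], r$polygon[, 2],
                                                sh$polygon)))
    lab <- assign_domain(r$polygon, sh$axis_truth, sh$oral_reference)
    expect_true(all(lab == r$domain))
  }
  ## pairwise disjoint (squares: separation test on centers)
  ctrs <- t(vapply(rois, `[[`, numeric(2), "center"))
  d <- as.matrix(dist(ctrs))
  side <- sqrt(6400)
  for (i in 1:11) for (j in (i + 1):12) {
    expect_true(abs(ctrs[i, 1] - ctrs[j, 1]) >= side ||
                  abs(ctrs[i, 2] - ctrs[j, 2]) >= side)
  }
})

test_that("ROI count scales with n_per_domain_side and placement is seeded", {
  g <- default_section()
  sim <- default_sim()
  r1 <- generate_rois(g, truth_axes(g), sim$transcripts,
                      roi_config(n_per_domain_side = 1, seed = 4))
  expect_length(r1, 4)
  a <- generate_rois(g, truth_axes(g), sim$transcripts, roi_config(seed = 9))
  b <- generate_rois(g, truth_axes(g), sim$transcripts, roi_config(seed = 9))
  expect_identical(a, b)
  expect_error(generate_rois(g, truth_axes(g), sim$transcripts,
                             roi_config(n_per_domain_side = 50)),
               "too small to fit")
})

test_that("circular ROIs hit the target area exactly", {
  g <- default_section()
  sim <- default_sim()
  rois <- generate_rois(g, truth_axes(g), sim$transcripts,
                        roi_config(shape = "circle", seed = 3))
  expect_length(rois, 12)
  areas <- vapply(rois, `[[`, numeric(1), "area")
  expect_equal(areas, rep(6400, 12), tolerance = 1e-9)
})

test_that("transcript counting matches a brute-force containment loop", {
  set.seed(5)
  tab <- data.frame(
    transcript_id = 1:500,
    feature_name = factor(sample(c("g1", "g2", "g3"), 500, replace = TRUE)),
    x_location = runif(500, 0, 200), y_location = runif(500, 0, 200),
    qv = runif(500, 10, 40))
  roi <- square_roi(40, 60, 80)
  cnt <- count_in_roi(tab, roi, min_qv = 20)
  inside <- tab$qv >= 20 &
    tab$x_location >= 40 & tab$x_location <= 120 &
    tab$y_location >= 60 & tab$y_location <= 140
  for (gn in c("g1", "g2", "g3")) {
    expect_equal(cnt[[gn]], sum(inside & tab$feature_name == gn))
  }
  ## boundary inclusive; quality filter respected
  edge <- data.frame(transcript_id = 1:2, feature_name = factor(c("g1", "g1")),
                     x_location = c(40, 40), y_location = c(60, 61),
                     qv = c(30, 10))
  expect_equal(count_in_roi(edge, roi, min_qv = 20)[["g1"]], 1L)
  ## empty region -> all zeros
  expect_true(all(count_in_roi(tab, square_roi(1000, 1000, 80), 20) == 0))
})

test_that("densities are counts over area with exact linearity", {
  tab <- data.frame(transcript_id = 1:64, feature_name = factor(rep("g1", 64)),
                    x_location = runif(64, 41, 119),
                    y_location = runif(64, 61, 139), qv = 30)
  roi <- square_roi(40, 60, 80)
  dm <- build_density_matrix(tab, list(roi), min_qv = 20)
  expect_equal(dm$density[1, "g1"], 64 / 6400)
  expect_equal(dm$density, dm$counts / dm$area)
  dbl <- density_matrix(dm$counts * 2L, dm$area, dm$meta)
  expect_equal(dbl$density, 2 * dm$density)
  expect_error(density_matrix(dm$counts, 0, dm$meta), "zero-area")
})

test_that("ROI counts never exceed the section total and respect rigid motion", {
  g <- default_section()
  sim <- default_sim()
  rois <- generate_rois(g, truth_axes(g), sim$transcripts, roi_config(seed = 2))
  dm <- build_density_matrix(sim$transcripts, rois, min_qv = 20)
  expect_lte(sum(dm$counts), sum(sim$transcripts$qv >= 20))
  ## translate transcripts and ROIs together: identical counts
  shift <- c(-31.7, 12.3)
  tab2 <- sim$transcripts
  tab2$x_location <- tab2$x_location + shift[1]
  tab2$y_location <- tab2$y_location + shift[2]
  rois2 <- lapply(rois, function(r) {
    r$polygon <- sweep(r$polygon, 2, shift, "+")
    r
  })
  dm2 <- build_density_matrix(tab2, rois2, min_qv = 20)
  expect_identical(dm$counts, dm2$counts)
})

test_that("ROI CSV write/read round-trips the density matrix", {
  g <- default_section()
  sim <- default_sim()
  rois <- generate_rois(g, truth_axes(g), sim$transcripts, roi_config(seed = 2))
  dm <- build_density_matrix(sim$transcripts, rois, group = "WT")
  path <- withr::local_tempfile(fileext = ".csv")
  write_roi_csv(dm, path)
  back <- read_roi_csv(path)
  expect_equal(unname(back$counts), unname(dm$counts))
  expect_equal(back$density, dm$density, ignore_attr = TRUE)
  expect_equal(back$area, dm$area)
  expect_equal(back$meta, dm$meta)
  expect_equal(back$group, "WT")
})

test_that("malformed ROI CSVs are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# group: A",
               "roi_id,shelf,domain,area_um2,gene,count,density_per_um2",
               "r1,PL,NP,6400,g1,5,0.00078125",
               "r1,PL,NP,6400,g2,-3,-0.000469"), path)
  expect_error(read_roi_csv(path), "line 4")
  writeLines(c("roi,wrong,header", "1,2,3"), path)
  expect_error(read_roi_csv(path), "header")
})

test_that("legacy per-ROI files assemble to the direct construction", {
  g <- default_section()
  sim <- default_sim()
  rois <- generate_rois(g, truth_axes(g), sim$transcripts, roi_config(seed = 2))
  dm <- build_density_matrix(sim$transcripts, rois, group = "WT")
  dir <- withr::local_tempdir()
  paths <- vapply(seq_along(rois), function(i) {
    p <- file.path(dir, paste0(dm$meta$roi_id[i], ".csv"))
    writeLines(c(sprintf("# roi_id: %s", dm$meta$roi_id[i]),
                 sprintf("# shelf: %s", dm$meta$shelf[i]),
                 sprintf("# domain: %s", dm$meta$domain[i]),
                 sprintf("# area_um2: %.10g", dm$area[i]),
                 "gene,count",
                 sprintf("%s,%d", colnames(dm$counts), dm$counts[i, ])), p)
    p
  }, character(1))
  back <- read_roi_legacy(paths, group = "WT")
  expect_equal(unname(back$counts), unname(dm$counts))
  expect_equal(back$area, dm$area)
  expect_equal(back$meta, dm$meta)
})
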