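## Hand-built 3-nucleus fixture: 1-um mask with small disks, full bin
## grid with one count per bin for one gene.
tiny_mask_grid <- function() {
  labels <- matrix(0L, 40, 40)
  px <- col(labels) - 0.5
  py <- row(labels) - 0.5
  labels[(px - 10)^2 + (py - 10)^2 <= 25] <- 5L     # nucleus "5", r = 5
  labels[(px - 30)^2 + (py - 28)^2 <= 16] <- 2L     # nucleus "2", r = 4
  mask <- nuclei_mask(labels, pixel_size = 1)
  nb <- 20L
  row0 <- rep(0:(nb - 1L), times = nb)
  col0 <- rep(0:(nb - 1L), each = nb)
  grid <- bin_count_grid(matrix(1L, nb * nb, 1L), row0, col0, "g1", pitch = 2)
  list(mask = mask, grid = grid)
}

test_that("bins are assigned by center containment", {
  f <- tiny_mask_grid()
  asn <- assign_bins_to_nuclei(f$grid, f$mask)
  ctr <- spatroi:::grid_bin_centers(f$grid)
  ## bin centered at (9, 9) lies inside nucleus 5; corner bin is background
  expect_equal(asn$label[ctr[, 1] == 9 & ctr[, 2] == 9], 5L)
  expect_equal(asn$label[ctr[, 1] == 1 & ctr[, 2] == 1], 0L)
  expect_equal(length(asn$label), nrow(f$grid$counts))
  ## every bin is assigned or unassigned, nothing lost
  expect_equal(sum(asn$label > 0) + sum(asn$label == 0), nrow(f$grid$counts))
})

test_that("assigned-bin count of a disk nucleus matches the bin-center oracle", {
  ## 100x100 um mask, one disk of radius 10 um; full 2-um bin grid
  labels <- matrix(0L, 100, 100)
  px <- col(labels) - 0.5
  py <- row(labels) - 0.5
  labels[(px - 50)^2 + (py - 50)^2 <= 100] <- 1L
  mask <- nuclei_mask(labels)
  nb <- 50L
  row0 <- rep(0:(nb - 1L), times = nb)
  col0 <- rep(0:(nb - 1L), each = nb)
  grid <- bin_count_grid(matrix(1L, nb * nb, 1L), row0, col0, "g1", pitch = 2)
  asn <- assign_bins_to_nuclei(grid, mask)
  n_assigned <- sum(asn$label == 1L)
  ## oracle: count of 2-um bin centers falling in the disk (the
  ##  nearest-pixel lookup may differ by a boundary bin or two)
  ctr <- spatroi:::grid_bin_centers(grid)
  oracle <- sum((ctr[, 1] - 50)^2 + (ctr[, 2] - 50)^2 <= 100)
  expect_lte(abs(n_assigned - oracle), 2)
  ## and the analytic disk area in bin units: pi * 10^2 / 4 ~ 78.5
  expect_lt(abs(n_assigned - pi * 100 / 4), 0.1 * pi * 100 / 4)
})

test_that("aggregation equals a naive per-bin accumulation", {
  g <- default_section()
  m <- gene_model(c("g1", "g2", "g3"), c(0.05, 0.02, 0.01))
  v <- simulate_visium_hd(g, m, nuclei_config(n = 20), seed = 5)
  asn <- assign_bins_to_nuclei(v$grid, v$mask)
  cells <- aggregate_to_cells(v$grid, asn)
  dense <- as.matrix(v$grid$counts)
  for (k in cells$nucleus_id) {
    ref <- colSums(dense[asn$label == k, , drop = FALSE])
    expect_equal(unname(cells$counts[match(k, cells$nucleus_id), ]),
                 unname(ref))
  }
  ## conservation: cells + unassigned = grid total, exactly
  expect_identical(sum(cells$counts) + sum(dense[asn$label == 0L, ]),
                   sum(dense))
})

test_that("binning is invariant under a common origin shift", {
  f <- tiny_mask_grid()
  asn0 <- assign_bins_to_nuclei(f$grid, f$mask)
  shift <- c(13.5, -7.25)
  grid2 <- bin_count_grid(f$grid$counts, f$grid$row, f$grid$col,
                          f$grid$gene_index, pitch = f$grid$pitch,
                          origin = f$grid$origin + shift)
  mask2 <- nuclei_mask(f$mask$labels, pixel_size = f$mask$pixel_size,
                       origin = f$mask$origin + shift)
  asn2 <- assign_bins_to_nuclei(grid2, mask2)
  expect_identical(asn0$label, asn2$label)
  expect_identical(aggregate_to_cells(f$grid, asn0)$counts,
                   aggregate_to_cells(grid2, asn2)$counts)
})

test_that("mismatched grid/mask frames are rejected with both extents", {
  f <- tiny_mask_grid()
  grid_off <- bin_count_grid(f$grid$counts, f$grid$row, f$grid$col,
                             f$grid$gene_index, pitch = 2, origin = c(200, 0))
  expect_error(assign_bins_to_nuclei(grid_off, f$mask), "mismatched frames")
  expect_error(assign_bins_to_nuclei(grid_off, f$mask), "mask covers")
})

test_that("nuclei filtering applies the size/UMI predicate exactly", {
  areas <- c(5, 10, 16, 30, 80, 150, 250, 399, 401, 500)
  umi <- c(50, 50, 3, 50, 9, 11, 50, 50, 50, 2)
  counts <- matrix(umi, ncol = 1)
  cells <- cell_by_gene(counts, seq_len(10), areas,
                        cbind(seq_len(10), seq_len(10)), "g1")
  cfg <- nuclei_filter_config(min_area = 16, max_area = 400, min_umi = 10)
  out <- filter_nuclei(cells, cfg)
  keep_oracle <- areas >= 16 & areas <= 400 & umi >= 10
  expect_equal(out$nucleus_id, which(keep_oracle))
  rep <- filter_report(out)
  expect_equal(sort(rep$nucleus_id), which(!keep_oracle))
  expect_equal(rep$reason[rep$nucleus_id == 3], "low_umi")
  expect_equal(rep$reason[rep$nucleus_id == 1], "small_area")
  expect_equal(rep$reason[rep$nucleus_id == 9], "large_area")
  expect_equal(rep$reason[rep$nucleus_id == 10], "large_area,low_umi")
  ## all-pass is the identity
  ok <- filter_nuclei(out, cfg)
  expect_equal(ok$counts, out$counts)
  expect_equal(nrow(filter_report(ok)), 0)
})

test_that("mitochondrial gene removal uses case-insensitive prefixes", {
  genes <- c("mt-Co1", "Mt-Nd1", "Mtor", "Shh")
  cells <- cell_by_gene(matrix(1L, 2, 4), 1:2, c(50, 60),
                        cbind(1:2, 1:2), genes)
  out <- remove_mt_genes(cells, "mt-")
  expect_equal(out$gene_index, c("Mtor", "Shh"))
  expect_equal(out$counts, cells$counts[, 3:4])
  ## no mt genes -> identity
  clean <- cell_by_gene(matrix(1L, 2, 2), 1:2, c(50, 60),
                        cbind(1:2, 1:2), c("Mtor", "Shh"))
  expect_equal(remove_mt_genes(clean, "mt-")$gene_index, c("Mtor", "Shh"))
  expect_error(remove_mt_genes(cells, ""), "non-empty")
})

test_that("center-binning recovers simulator ground truth exactly at zero ambient", {
  g <- default_section()
  m <- default_gene_model()
  v <- simulate_visium_hd(g, m, nuclei_config(n = 40, extra_nuclear_fraction = 0),
                          seed = 8)
  asn <- assign_bins_to_nuclei(v$grid, v$mask)
  cells <- aggregate_to_cells(v$grid, asn)
  expect_equal(unname(cells$counts),
               unname(v$truth$counts[cells$nucleus_id, , drop = FALSE]))
  missing <- setdiff(v$truth$nucleus_id, cells$nucleus_id)
  expect_true(all(v$truth$counts[missing, ] == 0))
  ## with zero ambient fraction, every occupied bin center is nuclear
  expect_true(all(asn$label[Matrix::rowSums(v$grid$counts) > 0] > 0))
})

test_that("nuclei placement fails loudly when the tissue is too crowded", {
  g <- default_section()
  m <- gene_model("g1", 0.001)
  expect_error(
    simulate_visium_hd(g, m, nuclei_config(n = 400, min_sep = 150,
                                           max_tries = 3000), seed = 1),
    "cannot be placed")
})
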