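test_that("log2 fold change handles pseudocounts and zeros as specified", {
  expect_equal(log2_fold_change(0.02, 0.01, 0), 1)
  expect_equal(log2_fold_change(0.5, 0.5, 0), 0)
  ## zero numerator against 0.01 with one-transcript-per-ROI pseudocount
  expect_equal(log2_fold_change(0, 0.01, 1 / 6400),
               log2(0.00015625 / 0.01015625))
  expect_lt(abs(log2_fold_change(0, 0.01, 1 / 6400) - (-6.0224)), 1e-3)
  expect_error(log2_fold_change(0.1, 0, 0), "pseudocount")
  expect_error(log2_fold_change(-1, 1), ">= 0")
})

test_that("the log2(x+1) transform is exact on anchor points", {
  expect_equal(log2p1_transform(c(0, 1, 7)), c(0, 1, 3))
  expect_true(all(diff(log2p1_transform(seq(0, 5, 0.1))) > 0))
  expect_error(log2p1_transform(-0.1), ">= 0")
})

test_that("variance-gated t-test handles identical and degenerate samples", {
  r <- variance_gated_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_raw, 1)
  expect_equal(r$branch, "student")
  expect_false(r$degenerate)
  d <- variance_gated_t_test(c(0, 0, 0), c(0, 0, 0))
  expect_true(d$degenerate)
  expect_equal(d$p_raw, 1)
  ## constant but different samples are still degenerate by convention
  d2 <- variance_gated_t_test(c(2, 2, 2), c(5, 5, 5))
  expect_true(d2$degenerate)
  expect_error(variance_gated_t_test(1, c(1, 2)), "n >= 2")
})

test_that("both test branches match the closed-form oracles", {
  set.seed(31)
  ## forced Welch branch: variances 100 vs 1
  a <- rnorm(6, 0, 10)
  b <- rnorm(6, 0, 1)
  r <- variance_gated_t_test(a, b)
  expect_equal(r$branch, "welch")
  expect_equal(r$variance_p, oracle_f_p(a, b), tolerance = 1e-12)
  o <- oracle_welch_t(a, b)
  expect_equal(r$t_stat, o$t, tolerance = 1e-10)
  expect_equal(r$df, o$df, tolerance = 1e-10)
  expect_equal(r$p_raw, o$p, tolerance = 1e-10)
  ## random cases across both branches
  for (i in 1:200) {
    na <- sample(3:8, 1)
    nb <- sample(3:8, 1)
    a <- rnorm(na, 0, sample(c(1, 5), 1))
    b <- rnorm(nb, 1, 1)
    r <- variance_gated_t_test(a, b)
    expect_equal(r$variance_p, oracle_f_p(a, b), tolerance = 1e-10)
    o <- if (r$branch == "welch") oracle_welch_t(a, b) else oracle_student_t(a, b)
    expect_equal(r$t_stat, o$t, tolerance = 1e-10)
    expect_equal(r$p_raw, o$p, tolerance = 1e-10)
  }
})

test_that("Student and Welch agree when variances and sizes are equal", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)          # same sample variance, same n
  s <- stats::t.test(a, b, var.equal = TRUE)
  w <- stats::t.test(a, b, var.equal = FALSE)
  expect_equal(unname(s$statistic), unname(w$statistic), tolerance = 1e-12)
  expect_equal(s$p.value, w$p.value, tolerance = 1e-12)
  r <- variance_gated_t_test(a, b)
  expect_equal(r$p_raw, s$p.value, tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.3), 0.3)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    ## bounded below by the raw p and monotone along the sorted order
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("volcano classification applies the published thresholds", {
  cfg <- dge_config()
  ## printed worked examples: strong oral-shelf markers classify up
  expect_equal(classify_deg(8.369539, 0.008112, cfg), "up")
  expect_equal(classify_deg(7.12479, 0.00019, cfg), "up")
  expect_equal(classify_deg(0.5, 0.001, cfg), "ns")
  expect_equal(classify_deg(-2, 0.01, cfg), "down")
  expect_equal(classify_deg(2, 0.2, cfg), "ns")
  expect_equal(classify_deg(1, 0.001, cfg), "ns")   # threshold is strict
})

test_that("run_dge composes the scalar operations per gene", {
  dmA <- simulate_null_density_matrix(15, 6, mean_count = 40, seed = 1, group = "A")
  dmB <- simulate_null_density_matrix(15, 6, mean_count = 40, seed = 2, group = "B")
  fit <- run_dge(dmA, dmB, dge_config())
  r <- as.data.frame(fit)
  for (j in c(1, 7, 15)) {
    a <- dmA$density[, j]
    b <- dmB$density[, j]
    expect_equal(r$lfc[j], log2_fold_change(mean(b), mean(a), 1 / 6400))
    tt <- variance_gated_t_test(log2p1_transform(a), log2p1_transform(b))
    expect_equal(r$p_raw[j], tt$p_raw)
    expect_equal(r$branch[j], tt$branch)
  }
  expect_equal(r$p_adj, benjamini_hochberg(r$p_raw))
  expect_true(all(r$p_adj >= r$p_raw))
})

test_that("identical groups give null results and swaps are antisymmetric", {
  dmA <- simulate_null_density_matrix(10, 6, mean_count = 60, seed = 5, group = "A")
  same <- run_dge(dmA, dmA)
  expect_true(all(as.data.frame(same)$lfc == 0))
  expect_true(all(as.data.frame(same)$class == "ns"))
  dmB <- simulate_null_density_matrix(10, 6, mean_count = 60, seed = 6, group = "B")
  fwd <- as.data.frame(run_dge(dmA, dmB))
  rev <- as.data.frame(run_dge(dmB, dmA))
  expect_equal(fwd$lfc, -rev$lfc)
  expect_equal(fwd$p_raw, rev$p_raw)
  map <- c(up = "down", down = "up", ns = "ns")
  expect_equal(unname(map[fwd$class]), rev$class)
})

test_that("mismatched gene universes are reported by symmetric difference", {
  dmA <- simulate_null_density_matrix(4, 3, seed = 1, gene_names = c("a", "b", "c", "d"))
  dmB <- simulate_null_density_matrix(4, 3, seed = 2, gene_names = c("a", "b", "x", "y"))
  expect_error(run_dge(dmA, dmB), "c, d, x, y")
})

test_that("degenerate genes are flagged and never called significant", {
  counts <- matrix(0L, 4, 2, dimnames = list(NULL, c("zero", "live")))
  counts[, 2] <- c(10L, 12L, 9L, 11L)
  meta <- data.frame(roi_id = paste0("r", 1:4), shelf = "PL", domain = "NP")
  dmA <- density_matrix(counts, rep(6400, 4), meta, group = "A")
  counts2 <- counts
  counts2[, 2] <- c(55L, 60L, 52L, 58L)
  dmB <- density_matrix(counts2, rep(6400, 4), meta, group = "B")
  r <- as.data.frame(run_dge(dmA, dmB))
  expect_true(r$degenerate[r$gene == "zero"])
  expect_equal(r$class[r$gene == "zero"], "ns")
  expect_false(r$degenerate[r$gene == "live"])
})

test_that("hypergeometric enrichment matches enumeration and the count rule", {
  universe <- paste0("g", 1:20)
  sets <- list(S = universe[1:5])
  ## overlap 4 of a 5-gene set with 5 hits: exhaustive oracle
  hits <- c(universe[1:4], "g20")
  res <- over_representation(hits, sets, universe)
  expect_equal(res$overlap, 4)
  expect_lt(abs(res$p - oracle_hyper_enum(4, 5, 20, 5)), 1e-12)
  expect_lt(abs(res$p - oracle_hyper_upper(4, 5, 20, 5)), 1e-12)
  ## overlap 0 -> p = 1
  res0 <- over_representation(universe[6:8], sets, universe)
  expect_equal(res0$p, 1)
  expect_false(res0$significant)
  ## the gene-count rule: a single overlapping gene is never significant
  tiny_universe <- paste0("u", 1:1000)
  tiny_sets <- list(T = tiny_universe[1])
  r1 <- over_representation(tiny_universe[1], tiny_sets, tiny_universe)
  expect_lt(r1$p, 0.05)
  expect_false(r1$significant)
  expect_error(over_representation("nope", sets, universe), "outside the universe")
})
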