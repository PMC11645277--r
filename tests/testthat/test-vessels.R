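## build a bin_matrix from tile indices (pitch 50)
bm_from_tiles <- function(tiles, gene_counts = NULL, roi = "r") {
  genes <- if (is.null(gene_counts)) c(VWF = 1, GJA5 = 1) else gene_counts
  counts <- matrix(rep(genes, each = nrow(tiles)), nrow(tiles),
                   dimnames = list(NULL, names(genes)))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, x = (tiles[, 1] + 0.5) * 50,
                 y = (tiles[, 2] + 0.5) * 50, roi = rep(roi, nrow(tiles)),
                 pitch = 50L), class = "bin_matrix")
}

test_that("vessel clustering keeps contiguous runs of >= 5 bins", {
  six <- bm_from_tiles(cbind(0:5, 0))
  v6 <- cluster_vessels(six)
  expect_equal(nrow(v6), 1L)
  expect_equal(v6$n_bins, 6L)
  ## four contiguous bins: removed
  four <- bm_from_tiles(cbind(0:3, 0))
  expect_equal(nrow(cluster_vessels(four)), 0L)
  ## empty input
  empty <- bin_transcripts(data.frame(x = numeric(0), y = numeric(0),
                                      gene = character(0)))
  expect_equal(nrow(cluster_vessels(empty)), 0L)
})

test_that("two separated blobs match the connected-components oracle", {
  tiles <- rbind(cbind(0:5, 0), cbind(10:15, 0))   # 3+ pitches apart
  bm <- bm_from_tiles(tiles)
  cl <- cluster_vessels(bm)
  expect_equal(nrow(cl), 2L)
  ## oracle: 8-neighborhood connected components at the same threshold
  n <- nrow(tiles)
  adj <- as.matrix(stats::dist(cbind(bm$x, bm$y))) <= 1.5 * 50
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  comp <- match(apply(reach, 1, paste, collapse = ""),
                unique(apply(reach, 1, paste, collapse = "")))
  expect_equal(length(unique(comp)), 2L)
  memb <- attr(cl, "membership")
  pkg_split <- lapply(split(memb$bin, memb$vessel_id), sort)
  orc_split <- lapply(split(seq_len(n), comp), sort)
  expect_setequal(pkg_split, unname(orc_split))
})

test_that("caliber classification follows the 30-bin threshold", {
  expect_equal(classify_caliber(31), "larger")
  expect_equal(classify_caliber(30), "smaller")
  expect_equal(classify_caliber(5), "smaller")
})

test_that("per-vessel gene statistics follow the expressing-bins convention", {
  tiles <- cbind(0:2, 0)
  bm <- bm_from_tiles(tiles, c(VWF = 1L, GJA5 = 1L))
  bm$counts <- cbind(bm$counts, SULF1 = c(0L, 2L, 4L))
  ## treat the 3 bins as one cluster despite being < 5 (direct call)
  cl <- cluster_vessels(bm, vessel_params(min_cluster_bins = 1))
  st <- vessel_gene_stats(cl, bm, "SULF1")
  expect_equal(st$pct_expressing, 100 * 2 / 3)
  expect_equal(st$mean_expressing, 3)
  ## all zeros: pct 0, mean undefined
  bm$counts[, "SULF1"] <- 0L
  st0 <- vessel_gene_stats(cl, bm, "SULF1")
  expect_equal(st0$pct_expressing, 0)
  expect_true(is.na(st0$mean_expressing))
  ## constant c: pct 100, mean c
  bm$counts[, "SULF1"] <- 3L
  stc <- vessel_gene_stats(cl, bm, "SULF1")
  expect_equal(stc$pct_expressing, 100)
  expect_equal(stc$mean_expressing, 3)
  expect_error(vessel_gene_stats(cl, bm, "ABSENT"), "unknown")
})

test_that("rank-sum test is exact for small tie-free samples", {
  expect_equal(compare_groups(c(5, 1, 3), c(5, 1, 3) + 0)$p_value, 1)
  cg <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cg$p_value, 0.1)
  expect_true(cg$exact)
  ## random small samples vs full enumeration
  set.seed(23)
  for (i in 1:20) {
    a <- sample(100, sample(2:6, 1))
    b <- sample(200 + seq_len(100), sample(2:6, 1))
    expect_equal(compare_groups(a, b)$p_value, oracle_ranksum_exact(a, b))
  }
  expect_error(compare_groups(numeric(0), 1), "non-empty")
})

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(29)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})

test_that("null caliber comparison controls the BH discovery rate", {
  set.seed(101)
  n_genes <- 200
  disc <- 0
  p <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    a <- rpois(12, 2) + runif(12) / 1e3   # both groups: one distribution
    b <- rpois(12, 2) + runif(12) / 1e3
    p[g] <- compare_groups(a, b)$p_value
  }
  frac <- mean(bh_adjust(p) < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n_genes))
})

test_that("planted caliber effect is recovered with adjusted significance", {
  vs <- data.frame(
    cx = rep(seq(400, 4400, 800), 2),
    cy = rep(c(400, 1200), each = 6),
    outer_radius = rep(c(280, 110), each = 6),
    wall = rep(c(90, 55), each = 6),
    vessel_type = "artery")
  sc <- make_vessel_scene(vs, field_px = c(4800, 1600), n_planes = 4,
                          seed = 9)
  res <- analyze_transcripts(sc$transcripts)
  expect_equal(nrow(res$vessels), 12L)
  expect_equal(sum(res$vessels$caliber == "larger"), 6L)
  pct <- res$comparisons[res$comparisons$metric == "pct_expressing", ]
  expect_lt(pct$p_adj, 0.05)
})
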