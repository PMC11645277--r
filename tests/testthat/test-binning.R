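test_that("binning follows the fixed-tile convention", {
  one <- bin_transcripts(data.frame(x = 10, y = 10, gene = "A"), pitch = 50)
  expect_equal(nrow(one$counts), 1L)
  expect_equal(c(one$x, one$y), c(25, 25))
  expect_equal(sum(one$counts), 1L)

  two <- bin_transcripts(data.frame(x = c(10, 60), y = c(10, 10),
                                    gene = c("A", "A")), pitch = 50)
  expect_equal(nrow(two$counts), 2L)
  expect_setequal(two$x, c(25, 75))
})

test_that("binning conserves counts for arbitrary input", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    tr <- data.frame(x = runif(n, 0, 700), y = runif(n, 0, 500),
                     gene = sample(LETTERS[1:6], n, TRUE))
    bm <- bin_transcripts(tr, pitch = 50)
    expect_equal(sum(bm$counts), n)
    ## per-gene totals match
    expect_equal(as.list(colSums(bm$counts)[sort(unique(tr$gene))]),
                 as.list(table(tr$gene)[sort(unique(tr$gene))]))
    ## centroids lie on the (i + 0.5) * pitch lattice
    expect_true(all((bm$x / 50 - 0.5) %% 1 == 0))
  }
  empty <- bin_transcripts(data.frame(x = numeric(0), y = numeric(0),
                                      gene = character(0)))
  expect_equal(nrow(empty$counts), 0L)
})

test_that("bin filter retains exactly >1 gene and >1 count, and is idempotent", {
  ## exhaustive toy grid: every composition of counts over two genes, 0..3
  comp <- expand.grid(a = 0:3, b = 0:3)
  comp <- comp[comp$a + comp$b > 0, ]
  tr <- do.call(rbind, lapply(seq_len(nrow(comp)), function(i) {
    x <- (i - 1) * 50 + 25
    rbind(
      if (comp$a[i] > 0) data.frame(x = rep(x, comp$a[i]), y = 25, gene = "A"),
      if (comp$b[i] > 0) data.frame(x = rep(x, comp$b[i]), y = 25, gene = "B"))
  }))
  bm <- bin_transcripts(tr, pitch = 50)
  fb <- filter_bins(bm)
  ## oracle: >= 2 distinct genes AND >= 2 total counts
  expected <- sum(comp$a > 0 & comp$b > 0 & comp$a + comp$b >= 2)
  expect_equal(nrow(fb$counts), expected)
  expect_true(all(rowSums(fb$counts > 0) >= 2 & rowSums(fb$counts) >= 2))
  ## single gene at count 5 is removed; two genes at one count each retained
  expect_false(any(fb$counts[, "A"] == 5 & fb$counts[, "B"] == 0))
  expect_true(any(fb$counts[, "A"] == 1 & fb$counts[, "B"] == 1))
  ## idempotent
  expect_equal(filter_bins(fb)$counts, fb$counts)
  ## empty passes through
  expect_equal(nrow(filter_bins(bin_transcripts(tr[0, ]))$counts), 0L)
})

test_that("marker subsetting implements the any/all/exclude rules", {
  tr <- rbind(
    data.frame(x = 25, y = 25, gene = c("VWF", "GJA5")),        # both
    data.frame(x = 75, y = 25, gene = c("VWF", "TTN")),          # excluded
    data.frame(x = 125, y = 25, gene = "VWF"),                   # pan only
    data.frame(x = 175, y = 25, gene = c("MYH11", "SULF1")))     # mural
  bm <- bin_transcripts(tr, pitch = 50)
  ## vasculature rule: any of VWF/MYH11 positive, TTN absent
  vasc <- subset_by_markers(bm, require_any = c("VWF", "MYH11"),
                            exclude = "TTN")
  expect_equal(nrow(vasc$counts), 3L)
  expect_true(all(vasc$counts[, "TTN"] == 0))
  ## arterial rule: VWF and GJA5 co-expressed
  art <- subset_by_markers(bm, require_all = c("VWF", "GJA5"))
  expect_equal(nrow(art$counts), 1L)
  expect_equal(art$x, 25)
  ## unknown gene errors
  expect_error(subset_by_markers(bm, exclude = "ABSENT"), "unknown")
  ## subset of input; composition with filter_bins commutes
  f_then_s <- subset_by_markers(filter_bins(bm), require_any = "VWF")
  s_then_f <- filter_bins(subset_by_markers(bm, require_any = "VWF"))
  expect_equal(f_then_s$counts, s_then_f$counts)
})

test_that("gene correlation matches the direct Pearson formula", {
  counts <- matrix(c(1, 3, 5, 2, 4,
                     2, 6, 10, 4, 8,
                     5, 1, 0, 3, 2), 5, 3,
                   dimnames = list(NULL, c("A", "B", "C")))
  bm <- structure(list(counts = counts, x = seq(25, 225, 50), y = rep(25, 5),
                       roi = rep("r", 5), pitch = 50L), class = "bin_matrix")
  m <- gene_correlation(bm)
  ## hand formula for one pair
  a <- counts[, "A"]; c_ <- counts[, "C"]
  r_ac <- sum((a - mean(a)) * (c_ - mean(c_))) /
    sqrt(sum((a - mean(a))^2) * sum((c_ - mean(c_))^2))
  expect_equal(m["A", "C"], r_ac)
  expect_equal(m["A", "B"], 1)          # B is 2 * A
  expect_equal(unname(diag(m)), rep(1, 3))
  ## zero-variance gene dropped
  counts2 <- cbind(counts, D = 2)
  bm$counts <- counts2
  m2 <- gene_correlation(bm)
  expect_false("D" %in% colnames(m2))
  expect_equal(attr(m2, "dropped"), "D")
  ## < 2 bins errors
  bm1 <- structure(list(counts = counts[1, , drop = FALSE], x = 25, y = 25,
                        roi = "r", pitch = 50L), class = "bin_matrix")
  expect_error(gene_correlation(bm1), "2 bins")
})

test_that("bin matrices merge across ROIs with aligned gene columns", {
  b1 <- bin_transcripts(data.frame(x = 10, y = 10, gene = "A"), roi = "r1")
  b2 <- bin_transcripts(data.frame(x = c(10, 20), y = c(10, 10),
                                   gene = c("B", "B")), roi = "r2")
  m <- merge_bin_matrices(list(b1, b2))
  expect_equal(nrow(m$counts), 2L)
  expect_equal(colnames(m$counts), c("A", "B"))
  expect_equal(sum(m$counts), 3L)
  expect_equal(m$roi, c("r1", "r2"))
})
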