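test_that("maxima target follows the floored area rule", {
  expect_equal(maxima_target(1000, 0.5), 500L)
  expect_equal(maxima_target(0, 0.5), 0L)
  expect_equal(maxima_target(333.3, 0.5), 166L)
  expect_error(maxima_target(-1, 0.5), "non-negative")
  set.seed(1)
  areas <- runif(100, 0, 5000)
  expect_equal(vapply(areas, maxima_target, integer(1), factor = 0.5),
               as.integer(floor(areas * 0.5)))
})

test_that("plane maxima are strict local maxima, capped at target", {
  p <- detection_params()
  expect_equal(nrow(detect_plane_maxima(matrix(3, 20, 20), 100, p)), 0L)

  img <- matrix(0, 20, 20); img[8, 12] <- 9
  d <- detect_plane_maxima(img, 100, p)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$x, d$y, d$Babs, d$Bback), c(11, 7, 9, 0))

  ## planted gaussian spots match an exhaustive scan oracle
  set.seed(3)
  img <- matrix(0, 60, 60)
  centers <- cbind(x = c(10, 30, 50, 20), y = c(15, 40, 10, 50))
  for (i in seq_len(nrow(centers))) {
    for (dy in -4:4) for (dx in -4:4) {
      img[centers[i, "y"] + 1 + dy, centers[i, "x"] + 1 + dx] <-
        img[centers[i, "y"] + 1 + dy, centers[i, "x"] + 1 + dx] +
        100 * exp(-(dx^2 + dy^2) / (2 * 1.2^2))
    }
  }
  d <- detect_plane_maxima(img, 10, p)
  expect_equal(nrow(d), 4L)
  orc <- oracle_local_maxima(img, p$local_max_radius_px)
  expect_setequal(paste(d$x, d$y), paste(orc[, 1], orc[, 2]))
  ## within 1 px of planted centers
  for (i in seq_len(nrow(centers))) {
    expect_lte(min(abs(d$x - centers[i, "x"]) + abs(d$y - centers[i, "y"])), 1)
  }

  ## cap: never more than target, ordered by brightness
  dn <- detect_plane_maxima(img, 2, p)
  expect_lte(nrow(dn), 2L)
  expect_true(all(diff(dn$Babs) <= 0))
})

test_that("noisy plane maxima equal the brute-force scan and respect the cap", {
  set.seed(9)
  img <- matrix(runif(900), 30, 30)
  p <- detection_params()
  d <- detect_plane_maxima(img, 1000, p)
  orc <- oracle_local_maxima(img, p$local_max_radius_px)
  expect_equal(nrow(d), nrow(orc))
  expect_setequal(paste(d$x, d$y), paste(orc[, 1], orc[, 2]))
  ## every reported point re-checks as a strict local maximum
  r <- p$local_max_radius_px
  for (i in seq_len(nrow(d))) {
    y <- d$y[i] + 1; x <- d$x[i] + 1
    nb <- img[max(1, y - r):min(30, y + r), max(1, x - r):min(30, x + r)]
    expect_equal(sum(nb >= img[y, x]), 1L)
  }
})

test_that("z-linking keeps only maxima with adjacent-plane neighbors", {
  base <- data.frame(x = 10, y = 10, z = 3, Babs = 5, Bback = 0, Bperi = 1)
  expect_equal(nrow(link_z_groups(base)), 0L)

  two <- rbind(base, transform(base, z = 4))
  g <- link_z_groups(two)
  expect_equal(nrow(g), 2L)
  expect_equal(length(unique(g$zgroup_id)), 1L)

  ## same plane twice: not adjacent, both dropped
  same <- rbind(base, base)
  expect_equal(nrow(link_z_groups(same)), 0L)
})

test_that("z-group assignment equals brute-force transitive closure", {
  set.seed(5)
  n <- 60
  cand <- data.frame(x = runif(n, 0, 40), y = runif(n, 0, 40),
                     z = sample(0:5, n, TRUE),
                     Babs = runif(n, 5, 10), Bback = 0, Bperi = 1)
  g <- link_z_groups(cand, link_radius_px = 2)
  ## oracle: adjacency matrix + transitive closure by repeated multiplication
  adj <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i != j && abs(cand$z[i] - cand$z[j]) == 1 &&
        (cand$x[i] - cand$x[j])^2 + (cand$y[i] - cand$y[j])^2 <= 4) {
      adj[i, j] <- TRUE
    }
  }
  reach <- adj | diag(n) > 0
  for (k in 1:n) reach <- reach | (reach %*% reach) > 0
  comp <- match(apply(reach, 1, paste, collapse = ""),
                unique(apply(reach, 1, paste, collapse = "")))
  keep <- tabulate(comp)[comp] >= 2
  expect_equal(nrow(g), sum(keep))
  ## same partition on the survivors
  key_pkg <- split(paste(g$x, g$y, g$z), g$zgroup_id)
  key_orc <- split(paste(cand$x, cand$y, cand$z)[keep], comp[keep])
  expect_setequal(unname(lapply(key_pkg, sort)), unname(lapply(key_orc, sort)))
})

test_that("iterative filter reaches the target and picks brightest margins", {
  cand <- data.frame(
    x = rep(c(10, 30, 50), each = 2), y = 10,
    z = rep(c(1, 2), 3),
    Babs = c(10, 10, 20, 20, 30, 30), Bback = 0,
    Bperi = c(10, 10, 20, 20, 30, 30))
  cand <- link_z_groups(cand)
  ## target at or above the group count: everything survives
  all_kept <- iterative_feature_filter(cand, 10)
  expect_equal(nrow(all_kept), 3L)
  expect_true(attr(all_kept, "converged"))
  expect_true(all(all_kept$group_size == 2L))

  ## target 1: the group with the largest minimum margin survives (oracle:
  ## sort groups by min(Babs - Bback))
  one <- iterative_feature_filter(cand, 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$Babs, 30)

  empty <- iterative_feature_filter(cand[0, ], 5)
  expect_equal(nrow(empty), 0L)
})

test_that("surviving feature count is monotone in the threshold", {
  set.seed(11)
  n <- 80
  cand <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100),
                     z = sample(0:4, n, TRUE),
                     Babs = runif(n, 1, 50), Bback = runif(n, 0, 1))
  cand$Bperi <- cand$Babs * 0.4
  cand <- link_z_groups(cand, link_radius_px = 15)
  counts <- vapply(0:12, function(tgt) {
    nrow(iterative_feature_filter(cand, tgt))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_true(all(counts <= 0:12))
})

test_that("round detection finds every planted transcript in on-bit rounds", {
  cb <- make_codebook(codebook_spec(n_genes = 10, seed = 6))
  tr <- make_isolated_transcripts(12, cb$genes, c(96, 96), 5, min_sep = 10,
                                  seed = 2)
  sc <- make_point_scene(tr, field_px = c(96, 96), n_planes = 5)
  rd <- render_rounds(sc, cb)
  gene_idx <- match(tr$gene, cb$genes)
  for (r in 1:8) {
    fc <- detect_round_features(rd$stacks[(r - 1) * 2 + 1:2],
                                pixel_size_um = 0.138)
    on <- which(rowSums(cb$codes[gene_idx, (r - 1) * 2 + 1:2,
                                 drop = FALSE]) > 0)
    for (i in on) {
      d <- sqrt((fc$x - tr$x[i])^2 + (fc$y - tr$y[i])^2)
      expect_lte(min(d), 1)
    }
  }
})
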