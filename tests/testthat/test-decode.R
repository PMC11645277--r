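test_that("profiles stack one value per slot with the default 16-slot layout", {
  stacks <- replicate(16, array(0, c(4, 4, 2)), simplify = FALSE)
  names(stacks) <- paste0("s", 1:16)
  pr <- build_profiles(stacks)
  expect_equal(ncol(pr$values), 16L)
  expect_equal(nrow(pr$values), 32L)
  expect_true(all(pr$values == 0))
  stacks[[2]] <- array(1, c(4, 4, 3))
  expect_error(build_profiles(stacks), "mismatch")
})

test_that("concentration score matches its closed form", {
  uniform <- rep(3, 16)
  onehot <- c(10, rep(0, 15))
  four <- c(rep(5, 4), rep(0, 12))
  sc <- profile_score(rbind(uniform, onehot, four))
  expect_equal(unname(sc), c(1, 16, 4))
  expect_true(is.na(profile_score(matrix(0, 1, 16))))
  ## filtering removes uniform and zero profiles at min_score 2
  keep <- score_and_filter_profiles(rbind(uniform, onehot, four, rep(0, 16)),
                                    min_score = 2)
  expect_equal(unname(keep), c(2L, 3L))
})

test_that("code assignment uses cosine similarity with a unique-argmax rule", {
  cb <- make_codebook(codebook_spec(n_genes = 20, n_unused = 5, seed = 4))
  ## profile equal to a code matches at similarity 1
  pr <- matrix(as.numeric(cb$codes[7, ]), 1)
  a <- assign_codes(pr, cb, min_match = 0.7)
  expect_equal(a$code, cb$genes[7])
  expect_equal(a$match, 1)
  expect_true(a$used)
  ## profile exactly between two codes is unassigned
  tie <- matrix(as.numeric(cb$codes[1, ] + cb$codes[2, ]), 1)
  expect_equal(nrow(assign_codes(tie, cb, min_match = 1e-9)), 0L)
  ## scaling invariance
  a2 <- assign_codes(pr * 37.5, cb, min_match = 0.7)
  expect_equal(a2$match, 1)
})

test_that("assignments equal the brute-force argmax oracle on random profiles", {
  cb <- make_codebook(codebook_spec(n_genes = 30, n_unused = 10, seed = 8))
  set.seed(21)
  profs <- matrix(rexp(1000 * 16), 1000, 16)
  a <- assign_codes(profs, cb, min_match = 0.5)
  codes <- rbind(cb$codes, cb$unused_codes)
  for (i in seq_len(nrow(profs))) {
    sims <- apply(codes, 1, function(cd) {
      sum(profs[i, ] * cd) / sqrt(sum(profs[i, ]^2) * sum(cd^2))
    })
    best <- max(sims)
    row <- a[a$voxel == i, ]
    if (best >= 0.5 && sum(sims == best) == 1L) {
      expect_equal(row$code, names(which.max(sims)))
      expect_equal(row$match, best)
    } else {
      expect_equal(nrow(row), 0L)
    }
  }
})

test_that("pixel grouping applies size, adjacency and span rules", {
  dm <- c(6L, 6L, 3L)
  vox <- function(y, x, z) y + (x - 1L) * 6L + (z - 1L) * 36L
  mk <- function(voxels) data.frame(voxel = voxels, code = "g", match = 1,
                                    used = TRUE)
  ## isolated pixel: removed
  expect_equal(nrow(group_and_filter_pixels(mk(vox(2, 2, 1)), dm)), 0L)
  ## 2x2x1 block: retained (size 4, all face-adjacent, spans 2 axes)
  block <- mk(c(vox(2, 2, 1), vox(3, 2, 1), vox(2, 3, 1), vox(3, 3, 1)))
  g <- group_and_filter_pixels(block, dm)
  expect_equal(nrow(g), 4L)
  expect_equal(length(unique(g$group_id)), 1L)
  ## diagonal-only contact: two singletons, both removed
  diag2 <- mk(c(vox(2, 2, 1), vox(3, 3, 1)))
  expect_equal(nrow(group_and_filter_pixels(diag2, dm)), 0L)
  ## 1D line of 3: only one axis spans >= 2, removed by the span rule
  line <- mk(c(vox(2, 2, 1), vox(3, 2, 1), vox(4, 2, 1)))
  expect_equal(nrow(group_and_filter_pixels(line, dm)), 0L)
})

test_that("localization recovers clean spots and drops unsupported groups", {
  cb <- make_codebook(codebook_spec(n_genes = 10, n_unused = 3, seed = 5))
  tr <- data.frame(x = 20, y = 24, z = 2, gene = cb$genes[3])
  sc <- make_point_scene(tr, field_px = c(48, 48), n_planes = 5)
  rd <- render_rounds(sc, cb)
  profiles <- build_profiles(rd$stacks)
  keep <- score_and_filter_profiles(profiles, 2)
  asg <- assign_codes(profiles, cb, 0.7, voxels = keep)
  grp <- group_and_filter_pixels(asg, profiles$dim)
  tab <- localize_and_validate(grp, profiles, rd$stacks, cb)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$gene, cb$genes[3])
  expect_lte(sqrt((tab$x - 20)^2 + (tab$y - 24)^2 + (tab$z - 2)^2), 1)
  expect_gt(tab$code_score, 0.99)

  ## a fabricated group over empty stacks fails raw-maxima validation
  zero_stacks <- lapply(rd$stacks, function(s) array(0, dim(s)))
  tab0 <- localize_and_validate(grp, profiles, zero_stacks, cb)
  expect_equal(nrow(tab0), 0L)
  ## empty group set
  expect_equal(nrow(localize_and_validate(grp[0, ], profiles, rd$stacks, cb)),
               0L)
})

test_that("specificity ratio is 0 for clean scenes and ~1 for random codes", {
  cb <- make_codebook(codebook_spec(n_genes = 24, n_unused = 8, seed = 6))
  clean <- estimate_specificity(list(used_hits = 500L, unused_hits = 0L), cb)
  expect_equal(clean$ratio, 0)
  ## sampling oracle: hits drawn uniformly over all 32 codes
  set.seed(31)
  draws <- sample(c(rep(TRUE, 24), rep(FALSE, 8)), 1e4, replace = TRUE)
  est <- estimate_specificity(list(used_hits = sum(draws),
                                   unused_hits = sum(!draws)), cb)
  expect_lt(abs(est$ratio - 1), 0.1)
  ## degenerate cases
  cb0 <- make_codebook(codebook_spec(n_genes = 5, n_unused = 0, seed = 1))
  expect_error(estimate_specificity(list(used_hits = 1, unused_hits = 0), cb0),
               "unused")
  flagged <- estimate_specificity(list(used_hits = 0L, unused_hits = 2L), cb)
  expect_true(flagged$undefined)
})

test_that("decoding conserves per-gene counts and survives planted offsets", {
  cb <- make_codebook(codebook_spec(n_genes = 30, n_unused = 6, seed = 10))
  tr <- make_isolated_transcripts(120, cb$genes, c(200, 200), 5,
                                  min_sep = 7, seed = 13)
  ## offset-free reference
  sc0 <- make_point_scene(tr, field_px = c(200, 200), n_planes = 5)
  dec0 <- decode_stacks(render_rounds(sc0, cb)$stacks, cb)
  expect_equal(nrow(dec0$transcripts), nrow(tr))
  expect_equal(as.list(table(dec0$transcripts$gene)), as.list(table(tr$gene)))
  r0 <- recovery_stats(tr, dec0$transcripts)
  expect_equal(r0$recovered, 1)
  expect_equal(nrow(dec0$unused_transcripts), 0L)

  ## planted rigid offsets <= 5 px / 3 deg: registration restores recovery
  offsets <- lapply(1:8, function(r) {
    if (r == 1) NULL else list(angle_deg = ((r %% 3) - 1) * 1.5,
                               translation = c((r %% 5) - 2, (r %% 4) - 1.5, 0))
  })
  sc1 <- make_point_scene(tr, field_px = c(200, 200), n_planes = 5,
                          offsets = offsets)
  rd1 <- render_rounds(sc1, cb)
  stacks <- rd1$stacks
  clouds <- lapply(1:8, function(r) {
    detect_round_features(stacks[(r - 1) * 2 + 1:2], pixel_size_um = 0.138)
  })
  for (r in 2:8) {
    fit <- icp_register(clouds[[r]], clouds[[1]])
    plan <- vascmap:::resample_plan(dim(stacks[[1]]), fit$transform)
    for (ch in 1:2) {
      s <- (r - 1) * 2 + ch
      stacks[[s]] <- vascmap:::resample_with_plan(stacks[[s]], plan)
    }
  }
  dec1 <- decode_stacks(stacks, cb)
  r1 <- recovery_stats(tr, dec1$transcripts, tol = 1.5)
  expect_equal(r1$recovered, r0$recovered)
})

test_that("assignment is invariant to uniform intensity scaling of stacks", {
  cb <- make_codebook(codebook_spec(n_genes = 10, n_unused = 2, seed = 2))
  tr <- make_isolated_transcripts(8, cb$genes, c(80, 80), 4, seed = 5)
  sc <- make_point_scene(tr, field_px = c(80, 80), n_planes = 4)
  rd <- render_rounds(sc, cb)
  dec_a <- decode_stacks(rd$stacks, cb)
  dec_b <- decode_stacks(lapply(rd$stacks, function(s) s * 12.3), cb)
  expect_equal(dec_a$transcripts[, c("x", "y", "z", "gene")],
               dec_b$transcripts[, c("x", "y", "z", "gene")])
})
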