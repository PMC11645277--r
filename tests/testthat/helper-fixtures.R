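## Shared fixtures and independent oracles. Oracles are deliberately naive
## (brute force, enumeration) and never reuse package internals.

## transcripts at random positions, rejection-sampled to a minimum pairwise
## xy separation (resolvable spots)
make_isolated_transcripts <- function(n, genes, field_px, n_planes,
                                      min_sep = 6, seed = 1) {
  set.seed(seed)
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    x <- runif(1, 6, field_px[1] - 7)
    y <- runif(1, 6, field_px[2] - 7)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_sep^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x = xs, y = ys, z = sample.int(n_planes, n, replace = TRUE) - 1L,
             gene = sample(genes, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

## fraction of truth transcripts recovered within `tol` px by a decoded
## table with matching gene
recovery_stats <- function(truth, decoded, tol = 1) {
  err <- vapply(seq_len(nrow(truth)), function(i) {
    d <- decoded[decoded$gene == truth$gene[i], , drop = FALSE]
    if (!nrow(d)) return(Inf)
    min(sqrt((d$x - truth$x[i])^2 + (d$y - truth$y[i])^2 +
               (d$z - truth$z[i])^2))
  }, numeric(1))
  list(recovered = mean(err <= tol), max_err = max(err[is.finite(err)]),
       err = err)
}

## brute-force strict local maxima scan (square radius)
oracle_local_maxima <- function(plane, r) {
  out <- NULL
  for (y in seq_len(nrow(plane))) for (x in seq_len(ncol(plane))) {
    ys <- max(1, y - r):min(nrow(plane), y + r)
    xs <- max(1, x - r):min(ncol(plane), x + r)
    nb <- plane[ys, xs]
    if (sum(nb >= plane[y, x]) == 1L) out <- rbind(out, c(x - 1L, y - 1L))
  }
  out
}

## exact two-sided rank-sum p by full enumeration of rank assignments
oracle_ranksum_exact <- function(a, b) {
  n <- length(a); m <- length(b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) sum(seq_len(n + m)[idx]) - n * (n + 1) / 2)
  ## two-sided: double the smaller tail (matching the exact Wilcoxon
  ## distribution convention), capped at 1
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

## closed-form BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, m * p[o[i]] / i)
    adj[o[i]] <- min(1, run)
  }
  adj
}

## naive separable gaussian blur with renormalized truncated kernel
oracle_gaussian_blur <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  k <- function(d) exp(-d^2 / (2 * sigma^2))
  one_dim <- function(v) {
    n <- length(v); out <- numeric(n)
    for (i in seq_len(n)) {
      js <- max(1, i - r):min(n, i + r)
      w <- k(js - i)
      out[i] <- sum(w * v[js]) / sum(w)
    }
    out
  }
  tmp <- apply(img, 2, one_dim)
  t(apply(tmp, 1, one_dim))
}

## naive grayscale opening with a flat disc (erosion then dilation)
oracle_opening_disc <- function(img, radius) {
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  morph <- function(m, f) {
    out <- matrix(NA_real_, nrow(m), ncol(m))
    for (y in seq_len(nrow(m))) for (x in seq_len(ncol(m))) {
      ys <- y + offs$dy; xs <- x + offs$dx
      ok <- ys >= 1 & ys <= nrow(m) & xs >= 1 & xs <= ncol(m)
      out[y, x] <- f(m[cbind(ys[ok], xs[ok])])
    }
    out
  }
  morph(morph(img, min), max)
}
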