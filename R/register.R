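#' Rigid 3D transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric (px).
#' @return object of class `rigid_transform3d`.
#' @export
rigid_transform3d <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform3d")
}

#' @export
print.rigid_transform3d <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("rigid_transform3d: rotation %.4f deg, translation (%.3f, %.3f, %.3f) px\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param points n x 3 matrix or data.frame with columns `x`, `y`, `z`.
#' @param transform a `rigid_transform3d`.
#' @return object of the same shape with transformed coordinates.
#' @export
transform_points <- function(points, transform) {
  stopifnot(inherits(transform, "rigid_transform3d"))
  df <- is.data.frame(points)
  m <- if (df) as.matrix(points[, c("x", "y", "z")]) else as.matrix(points)
  stopifnot(ncol(m) == 3L)
  out <- m %*% t(transform$rotation) +
    matrix(transform$translation, nrow(m), 3L, byrow = TRUE)
  if (df) {
    points$x <- out[, 1]; points$y <- out[, 2]; points$z <- out[, 3]
    points
  } else {
    out
  }
}

#' Invert a rigid transform
#'
#' @param transform a `rigid_transform3d`.
#' @return the inverse `rigid_transform3d`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform3d"))
  Rt <- t(transform$rotation)
  rigid_transform3d(Rt, -as.vector(Rt %*% transform$translation))
}

## index of nearest neighbor in `ref` for each row of `pts` (brute force;
## clouds here are a few hundred points)
.nn_index <- function(pts, ref) {
  d2 <- outer(rowSums(pts^2), rowSums(ref^2), "+") - 2 * pts %*% t(ref)
  max.col(-d2, ties.method = "first")
}

## closed-form orthogonal Procrustes (Kabsch) for paired points
.kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform3d(R, qc - as.vector(R %*% pc))
}

#' Register a feature cloud to a reference by rigid ICP
#'
#' Iterative closest point with mutual-nearest-neighbor correspondences, a
#' trimming step, and a closed-form orthogonal Procrustes update per
#' iteration. Because each imaging round images a different subset of
#' transcripts (those whose code has an on-bit in that round), the two clouds
#' overlap only partially; each update therefore uses the best `trim`
#' fraction of the mutual pairs by current distance, which rejects
#' correspondences between non-shared spots. Iteration stops when the
#' root-mean-square residual over the trimmed correspondences changes by
#' less than `tol`, or after `max_iter` iterations.
#'
#' @param moving,reference feature clouds: data.frames with `x`, `y`, `z`, or
#'   n x 3 matrices. Both need at least 3 non-collinear points.
#' @param tol rms convergence tolerance in px (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @param trim fraction of mutual-nearest-neighbor pairs (best by distance)
#'   used for each update (default 0.4; at least 3 pairs are always kept).
#' @return list with `transform` (`rigid_transform3d` mapping moving onto the
#'   reference), `rms` (final root-mean-square distance over the trimmed
#'   correspondences) and `trace` (rms after each iteration).
#' @export
icp_register <- function(moving, reference, tol = 1e-6, max_iter = 100L,
                         trim = 0.4) {
  P <- if (is.data.frame(moving)) as.matrix(moving[, c("x", "y", "z")]) else as.matrix(moving)
  Q <- if (is.data.frame(reference)) as.matrix(reference[, c("x", "y", "z")]) else as.matrix(reference)
  if (nrow(P) < 3L || nrow(Q) < 3L) {
    stop("ICP requires at least 3 points in each cloud", call. = FALSE)
  }
  for (M in list(P, Q)) {
    sv <- svd(sweep(M, 2, colMeans(M)))$d
    if (sv[2] < 1e-9 * max(sv[1], 1)) {
      stop("degenerate (collinear) point cloud", call. = FALSE)
    }
  }
  transform <- rigid_transform3d()
  cur <- P
  trace <- numeric(0)
  prev_rms <- Inf
  for (it in seq_len(max_iter)) {
    nn_pq <- .nn_index(cur, Q)
    nn_qp <- .nn_index(Q, cur)
    mutual <- which(nn_qp[nn_pq] == seq_len(nrow(cur)))
    if (length(mutual) < 3L) {
      pairs_p <- seq_len(nrow(cur)); pairs_q <- nn_pq
    } else {
      pairs_p <- mutual; pairs_q <- nn_pq[mutual]
    }
    ## trim: keep the closest fraction of the pairs, then gate at 3x the
    ## median kept distance (drops residual spurious matches while keeping
    ## every genuine pair under a smooth planted offset)
    pd <- sqrt(rowSums((cur[pairs_p, , drop = FALSE] -
                          Q[pairs_q, , drop = FALSE])^2))
    ord_pd <- order(pd)
    keep_n <- max(3L, floor(trim * length(pairs_p)))
    best <- ord_pd[seq_len(min(keep_n, length(ord_pd)))]
    gate <- 3 * stats::median(pd[best]) + 1e-9
    gated <- best[pd[best] <= gate]
    if (length(gated) >= 3L) best <- gated
    pairs_p <- pairs_p[best]; pairs_q <- pairs_q[best]
    step <- .kabsch(cur[pairs_p, , drop = FALSE], Q[pairs_q, , drop = FALSE])
    ## compose: new total = step o transform
    transform <- rigid_transform3d(
      step$rotation %*% transform$rotation,
      as.vector(step$rotation %*% transform$translation) + step$translation)
    cur <- transform_points(P, transform)
    rms <- sqrt(mean(rowSums((cur[pairs_p, , drop = FALSE] -
                                Q[pairs_q, , drop = FALSE])^2)))
    trace <- c(trace, rms)
    if (abs(prev_rms - rms) < tol) break
    prev_rms <- rms
  }
  list(transform = transform, rms = trace[length(trace)], trace = trace)
}

#' Resample a 3D stack under a rigid transform
#'
#' Output voxel value = tri-linear interpolation of the input stack at
#' `T^-1(voxel)`; coordinates falling outside the input field read as
#' `fill`. Use the transform that maps the moving round onto the reference
#' (as returned by [icp_register()]); the resampled stack then lives in the
#' reference frame.
#'
#' @param stack 3D array `[y, x, z]` (0-based coordinate convention:
#'   voxel `[i, j, k]` sits at x = j - 1, y = i - 1, z = k - 1).
#' @param transform a `rigid_transform3d`.
#' @param fill out-of-bounds value (default 0).
#' @return array of the same dimension.
#' @export
resample_stack <- function(stack, transform, fill = 0) {
  stopifnot(length(dim(stack)) == 3L, inherits(transform, "rigid_transform3d"))
  resample_with_plan(stack, resample_plan(dim(stack), transform), fill)
}

## Precompute the tri-linear gather (corner indices + weights) for one
## transform; reusable across all stacks sharing the geometry.
resample_plan <- function(dm, transform) {
  inv <- invert_transform(transform)
  n <- prod(dm)
  y <- rep.int(seq_len(dm[1]) - 1, dm[2] * dm[3])
  x <- rep.int(rep(seq_len(dm[2]) - 1, each = dm[1]), dm[3])
  z <- rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2])
  R <- inv$rotation; tr <- inv$translation
  sx <- R[1, 1] * x + R[1, 2] * y + R[1, 3] * z + tr[1]
  sy <- R[2, 1] * x + R[2, 2] * y + R[2, 3] * z + tr[2]
  sz <- R[3, 1] * x + R[3, 2] * y + R[3, 3] * z + tr[3]
  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
  idx <- matrix(0L, n, 8L); wgt <- matrix(0, n, 8L)
  k <- 0L
  for (dz in 0:1) for (dx in 0:1) for (dy in 0:1) {
    k <- k + 1L
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    ok <- xi >= 0 & xi <= dm[2] - 1 & yi >= 0 & yi <= dm[1] - 1 &
      zi >= 0 & zi <= dm[3] - 1
    idx[ok, k] <- as.integer(yi[ok] + 1 + xi[ok] * dm[1] +
                               zi[ok] * dm[1] * dm[2])
    wgt[, k] <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
  }
  list(dm = dm, idx = idx, wgt = wgt,
       inside = sx >= -1 & sx <= dm[2] & sy >= -1 & sy <= dm[1] &
         sz >= -1 & sz <= dm[3])
}

resample_with_plan <- function(stack, plan, fill = 0) {
  stopifnot(identical(dim(stack), plan$dm))
  v <- c(0, as.vector(stack))   # index 0 (outside) reads as 0
  acc <- numeric(nrow(plan$idx))
  for (k in 1:8) acc <- acc + v[plan$idx[, k] + 1L] * plan$wgt[, k]
  out <- rep(fill, length(acc))
  out[plan$inside] <- acc[plan$inside]
  array(out, dim = plan$dm)
}
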