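#' Spot detection parameters
#'
#' @param maxima_area_factor allowed maxima per plane = floor(slice area in
#'   um^2 x this factor); default 0.5.
#' @param feature_volume_factor feature target per round = floor(image volume
#'   in um^3 x this factor); default 0.5.
#' @param local_max_radius_px square radius defining the strict local-maximum
#'   neighborhood (default 2).
#' @param link_radius_px max xy distance linking maxima on adjacent planes
#'   into a z-group (default 2).
#' @param peri_factor scale relating the periphery margin (Bperi - Bback) to
#'   the brightness margin (Babs - Bback) on the shared threshold scale
#'   (default 0.25).
#' @param max_iterations bisection iterations for the feature filter
#'   (default 30).
#' @return object of class `detection_params`.
#' @export
detection_params <- function(maxima_area_factor = 0.5,
                             feature_volume_factor = 0.5,
                             local_max_radius_px = 2L,
                             link_radius_px = 2L,
                             peri_factor = 0.25,
                             max_iterations = 30L) {
  p <- list(
    maxima_area_factor = assert_number(maxima_area_factor, "maxima_area_factor", min = 0),
    feature_volume_factor = assert_number(feature_volume_factor, "feature_volume_factor", min = 0),
    local_max_radius_px = assert_count(local_max_radius_px, "local_max_radius_px", min = 1L),
    link_radius_px = assert_number(link_radius_px, "link_radius_px", min = 0),
    peri_factor = assert_number(peri_factor, "peri_factor", min = 1e-9),
    max_iterations = assert_count(max_iterations, "max_iterations", min = 1L))
  class(p) <- "detection_params"
  p
}

#' Allowed number of maxima for a plane
#'
#' The per-plane candidate budget is the slice area in square microns
#' multiplied by a factor (default 0.5), floored.
#'
#' @param area_um2 slice area in um^2.
#' @param factor dimensionless multiplier (default 0.5).
#' @return integer count.
#' @export
#' @examples
#' maxima_target(1000, 0.5)   # 500
maxima_target <- function(area_um2, factor = 0.5) {
  if (!is.numeric(area_um2) || length(area_um2) != 1L || !is.finite(area_um2) ||
      area_um2 < 0) {
    stop("`area_um2` must be a single non-negative number", call. = FALSE)
  }
  assert_number(factor, "factor", min = 0)
  as.integer(floor(area_um2 * factor))
}

#' Feature target for a 3D image
#'
#' @param volume_um3 image volume in um^3.
#' @param factor dimensionless multiplier.
#' @return integer count.
#' @export
feature_target <- function(volume_um3, factor = 0.5) {
  if (!is.numeric(volume_um3) || length(volume_um3) != 1L ||
      !is.finite(volume_um3) || volume_um3 < 0) {
    stop("`volume_um3` must be a single non-negative number", call. = FALSE)
  }
  as.integer(floor(volume_um3 * factor))
}

## offsets of the annulus used for the local background estimate
## (Euclidean distance in [inner, outer])
annulus_offsets <- function(inner = 3, outer = 5) {
  g <- expand.grid(dy = -outer:outer, dx = -outer:outer)
  d <- sqrt(g$dy^2 + g$dx^2)
  g[d >= inner & d <= outer, , drop = FALSE]
}

.annulus <- annulus_offsets(3, 5)
.ring8 <- expand.grid(dy = -1:1, dx = -1:1)[-5, ]  # 8-neighbor ring

## per-candidate brightness attributes on one plane
candidate_brightness <- function(plane, ys, xs) {
  nr <- nrow(plane); nc <- ncol(plane)
  n <- length(ys)
  Bback <- numeric(n); Bperi <- numeric(n)
  for (i in seq_len(n)) {
    ay <- ys[i] + .annulus$dy; ax <- xs[i] + .annulus$dx
    ok <- ay >= 1L & ay <= nr & ax >= 1L & ax <= nc
    Bback[i] <- stats::median(plane[cbind(ay[ok], ax[ok])])
    ry <- ys[i] + .ring8$dy; rx <- xs[i] + .ring8$dx
    ok <- ry >= 1L & ry <= nr & rx >= 1L & rx <= nc
    Bperi[i] <- mean(plane[cbind(ry[ok], rx[ok])])
  }
  list(Bback = Bback, Bperi = Bperi)
}

#' Detect the brightest strict local maxima on one plane
#'
#' A candidate is a pixel strictly greater than every pixel within a square
#' radius (`local_max_radius_px`). At most `target` candidates are returned,
#' ordered by absolute brightness descending (ties broken by (y, x) for
#' determinism). Each carries the brightness attributes used downstream:
#' `Babs` (pixel value), `Bback` (median of a 3-5 px annulus) and `Bperi`
#' (mean of the 8-neighbor ring).
#'
#' @param plane 2D numeric matrix indexed `[y + 1, x + 1]`.
#' @param target maximum number of candidates.
#' @param params [detection_params()].
#' @return data.frame with `x`, `y` (0-based px), `x_sub`, `y_sub`
#'   (sub-pixel positions from a background-subtracted 3x3 intensity
#'   centroid), `Babs`, `Bback`, `Bperi`.
#' @export
detect_plane_maxima <- function(plane, target, params = detection_params()) {
  stopifnot(is.matrix(plane))
  target <- assert_count(target, "target", min = 0L)
  empty <- data.frame(x = integer(0), y = integer(0), x_sub = numeric(0),
                      y_sub = numeric(0), Babs = numeric(0),
                      Bback = numeric(0), Bperi = numeric(0))
  if (target == 0L || length(plane) == 0L) return(empty)
  r <- params$local_max_radius_px
  neighmax <- matrix(-Inf, nrow(plane), ncol(plane))
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0L && dx == 0L) next
    neighmax <- pmax(neighmax, shift_matrix(plane, dy, dx))
  }
  idx <- which(plane > neighmax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  vals <- plane[idx]
  ord <- order(-vals, idx[, 1], idx[, 2])
  ord <- ord[seq_len(min(target, length(ord)))]
  ys <- idx[ord, 1]; xs <- idx[ord, 2]
  b <- candidate_brightness(plane, ys, xs)
  ## sub-pixel refinement: background-subtracted intensity centroid (3x3)
  nr <- nrow(plane); nc <- ncol(plane)
  x_sub <- xs - 1; y_sub <- ys - 1
  for (i in seq_along(ys)) {
    yy <- max(1L, ys[i] - 1L):min(nr, ys[i] + 1L)
    xx <- max(1L, xs[i] - 1L):min(nc, xs[i] + 1L)
    w <- pmax(plane[yy, xx, drop = FALSE] - b$Bback[i], 0)
    sw <- sum(w)
    if (sw > 0) {
      x_sub[i] <- sum(rep(xx - 1, each = length(yy)) * w) / sw
      y_sub[i] <- sum(rep(yy - 1, length(xx)) * w) / sw
    }
  }
  data.frame(x = xs - 1L, y = ys - 1L, x_sub = x_sub, y_sub = y_sub,
             Babs = vals[ord], Bback = b$Bback, Bperi = b$Bperi)
}

#' Link per-plane maxima across z into groups
#'
#' Candidates on adjacent planes within `link_radius_px` in xy belong to the
#' same z-group (transitively). Maxima with no neighbor on an adjacent plane
#' (singleton groups) are excluded.
#'
#' @param candidates data.frame with `x`, `y`, `z` (plane index) and the
#'   brightness columns.
#' @param link_radius_px xy linking radius (default 2).
#' @return the surviving candidates with a `zgroup_id` column.
#' @export
link_z_groups <- function(candidates, link_radius_px = 2) {
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$zgroup_id <- integer(0)
    return(out)
  }
  n <- nrow(candidates)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  ## adjacency only between consecutive planes keeps this near-linear
  by_z <- split(seq_len(n), candidates$z)
  zs <- as.integer(names(by_z))
  for (k in seq_along(zs)) {
    j <- match(zs[k] + 1L, zs)
    if (is.na(j)) next
    a <- by_z[[k]]; b <- by_z[[j]]
    for (i in a) {
      d2 <- (candidates$x[b] - candidates$x[i])^2 +
        (candidates$y[b] - candidates$y[i])^2
      for (m in b[d2 <= link_radius_px^2]) union_(i, m)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  size <- table(root)
  keep <- size[as.character(root)] >= 2L
  out <- candidates[keep, , drop = FALSE]
  out$zgroup_id <- as.integer(factor(root[keep]))
  rownames(out) <- NULL
  out
}

## number of z-groups (with >= 2 members) surviving a margin threshold t
.groups_at_threshold <- function(cand, margin, t) {
  keep <- margin >= t
  if (!any(keep)) return(list(n = 0L, keep = keep))
  tab <- table(cand$zgroup_id[keep])
  good <- names(tab)[tab >= 2L]
  keep <- keep & cand$zgroup_id %in% as.integer(good)
  list(n = length(good), keep = keep)
}

#' Iteratively filter z-groups to a volume-based feature target
#'
#' Raises a single threshold scalar applied to both brightness margins,
#' `Babs - Bback` and `(Bperi - Bback) / peri_factor`, by bisection until the
#' number of surviving z-groups (those keeping at least two members) is at or
#' below `target`. The representative of each surviving group — its member
#' with the highest absolute brightness — becomes one feature of the round's
#' point cloud.
#'
#' @param candidates output of [link_z_groups()].
#' @param target feature target count (see [feature_target()]).
#' @param params [detection_params()].
#' @return data.frame feature cloud (`x`, `y`, `z`, `Babs`, `Bback`, `Bperi`,
#'   `zgroup_id`, `group_size`) with attribute `converged` (FALSE when the
#'   iteration budget ran out before reaching the target).
#' @export
iterative_feature_filter <- function(candidates, target,
                                     params = detection_params()) {
  target <- assert_count(target, "target", min = 0L)
  empty <- data.frame(x = integer(0), y = integer(0), z = integer(0),
                      Babs = numeric(0), Bback = numeric(0),
                      Bperi = numeric(0), zgroup_id = integer(0),
                      group_size = integer(0))
  if (nrow(candidates) == 0L) return(structure(empty, converged = TRUE))
  margin <- pmin(candidates$Babs - candidates$Bback,
                 (candidates$Bperi - candidates$Bback) / params$peri_factor)
  lo <- 0; hi <- max(margin) + 1e-9
  res <- .groups_at_threshold(candidates, margin, lo)
  converged <- TRUE
  if (res$n > target) {
    ## bisect for the smallest threshold reaching the target
    best <- NULL
    for (it in seq_len(params$max_iterations)) {
      mid <- (lo + hi) / 2
      r <- .groups_at_threshold(candidates, margin, mid)
      if (r$n <= target) { best <- r; hi <- mid } else { lo <- mid }
    }
    if (is.null(best)) {
      converged <- FALSE
      res <- .groups_at_threshold(candidates, margin, hi)
    } else {
      res <- best
    }
  }
  surv <- candidates[res$keep, , drop = FALSE]
  if (nrow(surv) == 0L) return(structure(empty, converged = converged))
  ## representative per group: brightest member, ties by (z, y, x)
  ord <- order(surv$zgroup_id, -surv$Babs, surv$z, surv$y, surv$x)
  surv <- surv[ord, , drop = FALSE]
  sizes <- table(surv$zgroup_id)
  rep_rows <- surv[!duplicated(surv$zgroup_id), , drop = FALSE]
  rep_rows$group_size <- as.integer(sizes[as.character(rep_rows$zgroup_id)])
  rownames(rep_rows) <- NULL
  cols <- c("x", "y", "z", "Babs", "Bback", "Bperi", "zgroup_id",
            "group_size")
  cols <- c(cols, intersect(c("x_sub", "y_sub"), names(rep_rows)))
  structure(rep_rows[, cols], converged = converged)
}

#' Detect a feature point cloud for one imaging round
#'
#' Runs the full per-round detection chain on a 3D stack (or on the pixelwise
#' max across a round's channel stacks): per-plane strict local maxima capped
#' at the area-based target, z-linking, and the iterative volume-based group
#' filter.
#'
#' @param stack 3D array `[y, x, z]`, or a list of such arrays (channels of
#'   one round) combined by pixelwise max.
#' @param pixel_size_um microns per pixel.
#' @param plane_um micron depth ascribed to one plane for the volume target
#'   (default 1).
#' @param params [detection_params()].
#' @return feature cloud data.frame as from [iterative_feature_filter()],
#'   with `x`, `y` at sub-pixel (centroid-refined) positions.
#' @export
detect_round_features <- function(stack, pixel_size_um,
                                  plane_um = 1,
                                  params = detection_params()) {
  if (is.list(stack)) {
    stack <- Reduce(function(a, b) pmax(a, b), stack)
  }
  stopifnot(length(dim(stack)) == 3L)
  area <- prod(dim(stack)[1:2]) * pixel_size_um^2
  tgt_plane <- maxima_target(area, params$maxima_area_factor)
  cand <- do.call(rbind, lapply(seq_len(dim(stack)[3]), function(z) {
    d <- detect_plane_maxima(stack[, , z], tgt_plane, params)
    if (nrow(d)) d$z <- z - 1L else d$z <- integer(0)
    d
  }))
  cand <- link_z_groups(cand, params$link_radius_px)
  tgt_vol <- feature_target(area * dim(stack)[3] * plane_um,
                            params$feature_volume_factor)
  fc <- iterative_feature_filter(cand, tgt_vol, params)
  ## registration benefits from sub-pixel feature positions
  if (all(c("x_sub", "y_sub") %in% names(fc))) {
    fc$x <- fc$x_sub; fc$y <- fc$y_sub
    fc$x_sub <- NULL; fc$y_sub <- NULL
  }
  fc
}
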