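#' Build per-voxel intensity profiles from registered stacks
#'
#' Stacks one intensity value per (round, channel) slot for every voxel. With
#' the default geometry (eight rounds, two channels) each profile has 16
#' values, in round-major, channel-minor slot order.
#'
#' @param stacks named list of equally shaped 3D arrays, one per
#'   (round, channel) slot in slot order (as produced by [render_rounds()] or
#'   [read_round_stacks()]).
#' @return list with `values` (n_voxel x n_slot matrix), `dim` (stack
#'   dimension) — a `pixel_profiles` object. Voxel i corresponds to
#'   `arrayInd(i, dim)` in `[y, x, z]`.
#' @export
build_profiles <- function(stacks) {
  stopifnot(is.list(stacks), length(stacks) >= 1L)
  dm <- dim(stacks[[1]])
  if (length(dm) != 3L) stop("stacks must be 3D arrays", call. = FALSE)
  for (s in stacks) {
    if (!identical(dim(s), dm)) stop("stack shape mismatch", call. = FALSE)
  }
  values <- vapply(stacks, as.vector, numeric(prod(dm)))
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  structure(list(values = values, dim = dm), class = "pixel_profiles")
}

#' Concentration score of intensity profiles
#'
#' A scale-invariant measure of how concentrated a profile is on few slots:
#' `s = n * sum(v^2) / sum(v)^2` with `n` the profile length. A uniform
#' nonzero profile scores 1; a one-hot profile scores `n`; a profile with
#' exactly `w` equal on-bits scores `n / w`. This operationalizes filtering
#' by "variance from zero normalized by total brightness": profiles spread
#' evenly over all slots (pure background) score low, profiles concentrated
#' on a code's worth of slots score high.
#'
#' @param profiles a `pixel_profiles` object or a numeric matrix (rows =
#'   profiles).
#' @return numeric vector of scores; `NA` for all-zero profiles.
#' @export
profile_score <- function(profiles) {
  v <- if (inherits(profiles, "pixel_profiles")) profiles$values else as.matrix(profiles)
  tot <- rowSums(v)
  s <- ncol(v) * rowSums(v^2) / tot^2
  s[tot == 0] <- NA_real_
  s
}

#' Filter profiles by concentration score
#'
#' Removes profiles with zero total brightness or score below `min_score`.
#'
#' @inheritParams profile_score
#' @param min_score minimum concentration score (>= 1; default 2).
#' @return integer vector of retained voxel indices.
#' @export
score_and_filter_profiles <- function(profiles, min_score = 2) {
  assert_number(min_score, "min_score", min = 1)
  s <- profile_score(profiles)
  which(!is.na(s) & s >= min_score)
}

#' Match profiles against a codebook
#'
#' Computes the cosine similarity between each profile and every binary code
#' (used and unused). A voxel is assigned the argmax code when the similarity
#' reaches `min_match` and the maximum is unique; otherwise it stays
#' unassigned. Cosine matching is invariant to uniform intensity scaling.
#'
#' @param profiles `pixel_profiles` or numeric matrix.
#' @param codebook a `codebook`.
#' @param min_match minimum cosine similarity in (0, 1] (default 0.7).
#' @param voxels optional integer vector restricting matching to these voxel
#'   rows (e.g. from [score_and_filter_profiles()]).
#' @return data.frame with `voxel` (row index), `code` (name: gene or
#'   unusedNNN), `match` (cosine similarity), `used` (logical). Unassigned
#'   voxels are omitted.
#' @export
assign_codes <- function(profiles, codebook, min_match = 0.7, voxels = NULL) {
  stopifnot(inherits(codebook, "codebook"))
  assert_number(min_match, "min_match", min = 1e-12, max = 1)
  v <- if (inherits(profiles, "pixel_profiles")) profiles$values else as.matrix(profiles)
  codes <- rbind(codebook$codes, codebook$unused_codes)
  if (nrow(codes) == 0L) stop("empty codebook", call. = FALSE)
  if (ncol(v) != ncol(codes)) {
    stop("profile length does not match code length", call. = FALSE)
  }
  if (is.null(voxels)) voxels <- seq_len(nrow(v))
  v <- v[voxels, , drop = FALSE]
  norm_p <- sqrt(rowSums(v^2))
  norm_c <- sqrt(rowSums(codes^2))
  sim <- (v %*% t(codes)) / outer(norm_p, norm_c)
  sim[norm_p == 0, ] <- -Inf
  best <- max.col(sim, ties.method = "first")
  best_val <- sim[cbind(seq_len(nrow(sim)), best)]
  ## unique argmax: second-best strictly lower
  sim2 <- sim
  sim2[cbind(seq_len(nrow(sim)), best)] <- -Inf
  second <- apply(sim2, 1, max)
  ok <- is.finite(best_val) & best_val >= min_match & best_val > second
  data.frame(
    voxel = voxels[ok],
    code = rownames(codes)[best[ok]],
    match = best_val[ok],
    used = best[ok] <= nrow(codebook$codes),
    stringsAsFactors = FALSE)
}

## 6-connected components over sparse voxel coordinates (one gene at a time)
.components6 <- function(coords) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  key <- paste(coords[, 1], coords[, 2], coords[, 3], sep = ",")
  lut <- seq_len(n); names(lut) <- key
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (o in seq_len(3)) {
    nb <- sweep(coords, 2, offs[o, ], "+")
    j <- lut[paste(nb[, 1], nb[, 2], nb[, 3], sep = ",")]
    hit <- which(!is.na(j))
    for (i in hit) {
      ri <- find(i); rj <- find(j[[i]])
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(root))
}

#' Group assigned voxels and filter groups
#'
#' Voxels assigned the same code are grouped by 6-connectivity. A group is
#' retained iff (a) it has at least two voxels, (b) every member touches at
#' least one other member face-on, and (c) its bounding box spans at least
#' two voxels along at least two of the three axes. Under 6-connectivity
#' rule (b) is implied by (a); it is still checked explicitly since the
#' connectivity is configurable in principle.
#'
#' @param assignment output of [assign_codes()].
#' @param dim stack dimension `[ny, nx, nz]` (e.g. `profiles$dim`).
#' @param min_size minimum group size (default 2).
#' @param min_span_axes number of axes that must span >= 2 voxels
#'   (default 2).
#' @return data.frame of voxel memberships: `voxel`, `code`, `match`, `used`,
#'   `group_id`; groups failing the filters are dropped.
#' @export
group_and_filter_pixels <- function(assignment, dim, min_size = 2L,
                                    min_span_axes = 2L) {
  if (nrow(assignment) == 0L) {
    assignment$group_id <- integer(0)
    return(assignment)
  }
  out <- vector("list", 0L)
  next_id <- 0L
  for (code in unique(assignment$code)) {
    sub <- assignment[assignment$code == code, , drop = FALSE]
    coords <- arrayInd(sub$voxel, dim)   # [y, x, z]
    comp <- .components6(coords)
    for (g in unique(comp)) {
      sel <- comp == g
      if (sum(sel) < min_size) next
      cg <- coords[sel, , drop = FALSE]
      spans <- apply(cg, 2, function(a) diff(range(a)) + 1L)
      if (sum(spans >= 2L) < min_span_axes) next
      ## direct-adjacency check per member
      ok <- vapply(seq_len(nrow(cg)), function(i) {
        any(rowSums(abs(sweep(cg[-i, , drop = FALSE], 2, cg[i, ]))) == 1L)
      }, logical(1))
      if (!all(ok)) next
      next_id <- next_id + 1L
      grp <- sub[sel, , drop = FALSE]
      grp$group_id <- next_id
      out[[length(out) + 1L]] <- grp
    }
  }
  if (!length(out)) {
    res <- assignment[0, , drop = FALSE]
    res$group_id <- integer(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## is stack[pos] a 3D local maximum within Chebyshev radius `r`?
.is_local_max3 <- function(stack, yxz, r = 1L) {
  dm <- dim(stack)
  ys <- max(1L, yxz[1] - r):min(dm[1], yxz[1] + r)
  xs <- max(1L, yxz[2] - r):min(dm[2], yxz[2] + r)
  zs <- max(1L, yxz[3] - r):min(dm[3], yxz[3] + r)
  stack[yxz[1], yxz[2], yxz[3]] >= max(stack[ys, xs, zs])
}

#' Localize transcripts from pixel groups and validate against raw maxima
#'
#' For each retained group, candidate transcript positions are the local 3D
#' maxima of the summed on-bit intensity among the group's member voxels
#' (26-neighborhood; plateaus deduplicated deterministically), so one group
#' can yield several transcripts when two same-gene molecules sit a few
#' pixels apart. A candidate is kept only when an intensity local maximum
#' exists within `search_px` of its position in at least `k_required` of the
#' code's on-bit images. The recorded `code_score` is the cosine fit of the
#' position's profile to the assigned code.
#'
#' @param groups output of [group_and_filter_pixels()].
#' @param profiles the `pixel_profiles` the groups were decoded from.
#' @param stacks the registered stacks (named list, slot order).
#' @param codebook the `codebook`.
#' @param k_required on-bit images that must show a nearby local maximum;
#'   default `code_weight - 1`.
#' @param search_px search radius for raw maxima (default 2).
#' @return a transcript table: data.frame `x`, `y`, `z` (0-based px/planes),
#'   `gene`, `code_score`, `group_size`; unused-code groups are reported with
#'   the unused code name in `gene` and flagged by `used = FALSE`.
#' @export
localize_and_validate <- function(groups, profiles, stacks, codebook,
                                  k_required = NULL, search_px = 2L) {
  stopifnot(inherits(codebook, "codebook"))
  if (is.null(k_required)) k_required <- codebook$code_weight - 1L
  empty <- data.frame(x = integer(0), y = integer(0), z = integer(0),
                      gene = character(0), code_score = numeric(0),
                      group_size = integer(0), used = logical(0))
  if (nrow(groups) == 0L) return(empty)
  all_codes <- rbind(codebook$codes, codebook$unused_codes)
  dm <- profiles$dim
  ## summed on-bit stacks, cached per code
  sum_cache <- new.env(parent = emptyenv())
  summed_stack <- function(code_name) {
    if (!is.null(sum_cache[[code_name]])) return(sum_cache[[code_name]])
    on_bits <- which(all_codes[code_name, ] == 1L)
    s <- Reduce(`+`, stacks[on_bits])
    sum_cache[[code_name]] <- s
    s
  }
  rows <- vector("list", 0L)
  for (gid in unique(groups$group_id)) {
    sub <- groups[groups$group_id == gid, , drop = FALSE]
    code_name <- sub$code[1]
    code <- all_codes[code_name, ]
    on_bits <- which(code == 1L)
    ss <- summed_stack(code_name)
    coords <- arrayInd(sub$voxel, dm)   # [y, x, z]
    ## local 3D maxima of the summed on-bit intensity among members:
    ## >= all 26-neighbors, plateaus deduplicated by smallest linear index
    peaks <- integer(0)
    for (m in seq_len(nrow(sub))) {
      pos <- coords[m, ]
      v <- ss[pos[1], pos[2], pos[3]]
      ys <- max(1L, pos[1] - 1L):min(dm[1], pos[1] + 1L)
      xs <- max(1L, pos[2] - 1L):min(dm[2], pos[2] + 1L)
      zs <- max(1L, pos[3] - 1L):min(dm[3], pos[3] + 1L)
      nb <- ss[ys, xs, zs]
      if (v < max(nb)) next
      ## plateau tie-break: skip if an equal-valued neighbor member has a
      ## smaller linear index
      eq_members <- sub$voxel[abs(coords[, 1] - pos[1]) <= 1L &
                                abs(coords[, 2] - pos[2]) <= 1L &
                                abs(coords[, 3] - pos[3]) <= 1L]
      eq_members <- eq_members[ss[eq_members] == v]
      if (min(eq_members) < sub$voxel[m]) next
      peaks <- c(peaks, m)
    }
    if (!length(peaks)) peaks <- which.max(ss[sub$voxel])
    for (m in peaks) {
      pos <- coords[m, ]
      ## validation in the on-bit images
      hits <- 0L
      for (b in on_bits) {
        st <- stacks[[b]]
        found <- FALSE
        ys <- max(1L, pos[1] - search_px):min(dm[1], pos[1] + search_px)
        xs <- max(1L, pos[2] - search_px):min(dm[2], pos[2] + search_px)
        zs <- max(1L, pos[3] - search_px):min(dm[3], pos[3] + search_px)
        for (zz in zs) { for (yy in ys) { for (xx in xs) {
          if (st[yy, xx, zz] > 0 && .is_local_max3(st, c(yy, xx, zz), 1L)) {
            found <- TRUE; break
          }
        }; if (found) break }; if (found) break }
        if (found) hits <- hits + 1L
      }
      if (hits < k_required) next
      prof <- profiles$values[sub$voxel[m], ]
      cs <- sum(prof * code) / (sqrt(sum(prof^2)) * sqrt(sum(code^2)))
      rows[[length(rows) + 1L]] <- data.frame(
        x = pos[2] - 1L, y = pos[1] - 1L, z = pos[3] - 1L,
        gene = code_name, code_score = cs,
        group_size = nrow(sub), used = sub$used[1],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Estimate decoding specificity from unused-code hits
#'
#' The rate of signals matching reserved unused codes, normalized per code,
#' relative to the per-code rate of signals matching used codes:
#' `(unused_hits / n_unused) / (used_hits / n_used)`. Near 0 means decoded
#' signal is specific; near 1 means assignments are random.
#'
#' @param transcripts a transcript table with a `used` logical column (from
#'   [localize_and_validate()]), or a list/vector with counts `used_hits`
#'   and `unused_hits`.
#' @param codebook the `codebook` (needs >= 1 unused code).
#' @return list with `used_hits`, `unused_hits`, `ratio` (NA with
#'   `undefined = TRUE` when no used hits exist).
#' @export
estimate_specificity <- function(transcripts, codebook) {
  stopifnot(inherits(codebook, "codebook"))
  n_unused <- nrow(codebook$unused_codes)
  if (n_unused == 0L) {
    stop("codebook has no unused codes; specificity is not estimable",
         call. = FALSE)
  }
  n_used <- nrow(codebook$codes)
  if (is.data.frame(transcripts)) {
    used_hits <- sum(transcripts$used)
    unused_hits <- sum(!transcripts$used)
  } else {
    used_hits <- transcripts[["used_hits"]]
    unused_hits <- transcripts[["unused_hits"]]
  }
  if (used_hits == 0L) {
    return(list(used_hits = used_hits, unused_hits = unused_hits,
                ratio = NA_real_, undefined = TRUE))
  }
  list(used_hits = used_hits, unused_hits = unused_hits,
       ratio = (unused_hits / n_unused) / (used_hits / n_used),
       undefined = FALSE)
}

#' Decode registered stacks into a transcript table
#'
#' Convenience wrapper chaining [build_profiles()],
#' [score_and_filter_profiles()], [assign_codes()],
#' [group_and_filter_pixels()] and [localize_and_validate()].
#'
#' @param stacks named list of registered 3D stacks in slot order.
#' @param codebook the `codebook`.
#' @param min_score concentration score cutoff (default 2).
#' @param min_match cosine match cutoff (default 0.7).
#' @param k_required raw-maxima validation count (default weight - 1).
#' @return list with `transcripts` (used-code transcript table without the
#'   `used` column), `unused_transcripts`, and `specificity`.
#' @export
decode_stacks <- function(stacks, codebook, min_score = 2, min_match = 0.7,
                          k_required = NULL) {
  profiles <- build_profiles(stacks)
  keep <- score_and_filter_profiles(profiles, min_score)
  assignment <- assign_codes(profiles, codebook, min_match, voxels = keep)
  groups <- group_and_filter_pixels(assignment, profiles$dim)
  tab <- localize_and_validate(groups, profiles, stacks, codebook, k_required)
  spec <- if (nrow(codebook$unused_codes) > 0L) {
    estimate_specificity(tab, codebook)
  } else {
    NULL
  }
  list(transcripts = tab[tab$used, setdiff(names(tab), "used"), drop = FALSE],
       unused_transcripts = tab[!tab$used, , drop = FALSE],
       specificity = spec)
}
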