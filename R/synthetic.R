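#' Generate a synthetic vessel scene
#'
#' Builds a ground-truth scene emulating a vascular tissue section: vessel
#' cross-sections appear as annular rings of marker transcripts on a square
#' tile grid. Every ring tile emits a pan-endothelial marker and the vessel
#' type marker (arterial or venous); a designated caliber-dependent gene is
#' emitted per ring tile with Bernoulli probability `rate_larger` in vessels
#' whose ring spans more than `caliber_threshold_bins` tiles and
#' `rate_smaller` otherwise. Optional uniform background transcripts of
#' random genes model non-vascular signal.
#'
#' @param vessels data.frame with columns `cx`, `cy` (center, px),
#'   `outer_radius` (px), `wall` (wall thickness, px), `vessel_type`
#'   ("artery" or "vein"). May have zero rows.
#' @param field_px integer length-2, field size in x and y (default
#'   `c(512, 512)`).
#' @param n_planes z planes (default 6).
#' @param pixel_size_um microns per pixel (default 0.138, so a 50 px tile is
#'   about 7 um).
#' @param pitch tile pitch in px used to lay transcripts on ring tiles
#'   (default 50).
#' @param markers named list with entries `pan` (pan-EC, default "VWF"),
#'   `artery` (default "GJA5"), `vein` (default "ACKR1"), `caliber`
#'   (caliber-dependent gene, default "SULF1").
#' @param rate_larger,rate_smaller per-tile emission probability of the
#'   caliber gene in larger / smaller vessels (defaults 0.6 and 0.2).
#' @param caliber_threshold_bins ring-tile count above which a vessel counts
#'   as larger (default 30).
#' @param background_rate expected number of uniform background transcripts
#'   (default 0).
#' @param background_genes genes drawn for background transcripts (defaults
#'   to the markers).
#' @param offsets optional list of per-round rigid offsets, each
#'   `list(angle_deg =, translation = c(dx, dy, dz))`; element r applies to
#'   round r (round 1 should be identity). Defaults to no offsets.
#' @param background_level,noise_sd additive constant background and Gaussian
#'   noise sd used later at rendering (stored on the scene; defaults 0 and 0).
#' @param seed integer seed.
#' @return object of class `vessel_scene`: transcripts data.frame
#'   (`x`, `y`, `z` 0-based px/planes, `gene`, `vessel_id`; `vessel_id` 0 for
#'   background), the vessel table with `n_ring_bins` and `caliber` columns,
#'   and the field geometry.
#' @export
make_vessel_scene <- function(vessels,
                              field_px = c(512L, 512L),
                              n_planes = 6L,
                              pixel_size_um = 0.138,
                              pitch = 50L,
                              markers = list(pan = "VWF", artery = "GJA5",
                                             vein = "ACKR1", caliber = "SULF1"),
                              rate_larger = 0.6,
                              rate_smaller = 0.2,
                              caliber_threshold_bins = 30L,
                              background_rate = 0,
                              background_genes = NULL,
                              offsets = NULL,
                              background_level = 0,
                              noise_sd = 0,
                              seed = 1L) {
  if (is.null(vessels)) {
    vessels <- data.frame(cx = numeric(0), cy = numeric(0),
                          outer_radius = numeric(0), wall = numeric(0),
                          vessel_type = character(0))
  }
  stopifnot(is.data.frame(vessels),
            all(c("cx", "cy", "outer_radius", "wall", "vessel_type") %in%
                  names(vessels)))
  if (nrow(vessels) > 0) {
    if (any(vessels$outer_radius <= 0) || any(vessels$wall <= 0)) {
      stop("vessel radii and wall thickness must be positive", call. = FALSE)
    }
    if (!all(vessels$vessel_type %in% c("artery", "vein"))) {
      stop("vessel_type must be 'artery' or 'vein'", call. = FALSE)
    }
  }
  field_px <- as.integer(field_px)
  n_planes <- assert_count(n_planes, "n_planes", min = 1L)
  pitch <- assert_count(pitch, "pitch", min = 1L)

  ## tile centers on the pitch lattice covering the field
  tx <- (seq_len(ceiling(field_px[1] / pitch)) - 0.5) * pitch
  ty <- (seq_len(ceiling(field_px[2] / pitch)) - 0.5) * pitch
  grid <- expand.grid(x = tx, y = ty)

  res <- with_seed(seed, {
    tr <- list()
    vtab <- vessels
    vtab$n_ring_bins <- integer(nrow(vessels))
    vtab$caliber <- character(nrow(vessels))
    for (v in seq_len(nrow(vessels))) {
      d <- sqrt((grid$x - vessels$cx[v])^2 + (grid$y - vessels$cy[v])^2)
      ring <- which(d <= vessels$outer_radius[v] &
                      d >= vessels$outer_radius[v] - vessels$wall[v])
      vtab$n_ring_bins[v] <- length(ring)
      larger <- length(ring) > caliber_threshold_bins
      vtab$caliber[v] <- if (larger) "larger" else "smaller"
      rate <- if (larger) rate_larger else rate_smaller
      type_marker <- if (vessels$vessel_type[v] == "artery") markers$artery else markers$vein
      for (b in ring) {
        ## one pan-EC + one type-marker transcript per ring tile, plus the
        ## caliber gene with the planted per-tile probability
        genes <- c(markers$pan, type_marker)
        if (stats::runif(1) < rate) genes <- c(genes, markers$caliber)
        n <- length(genes)
        tr[[length(tr) + 1L]] <- data.frame(
          x = pmin(pmax(grid$x[b] + stats::runif(n, -pitch / 2 + 2, pitch / 2 - 2), 0),
                   field_px[1] - 1),
          y = pmin(pmax(grid$y[b] + stats::runif(n, -pitch / 2 + 2, pitch / 2 - 2), 0),
                   field_px[2] - 1),
          z = sample.int(n_planes, n, replace = TRUE) - 1L,
          gene = genes, vessel_id = v, stringsAsFactors = FALSE)
      }
    }
    n_bg <- if (background_rate > 0) stats::rpois(1L, background_rate) else 0L
    if (n_bg > 0L) {
      pool <- if (is.null(background_genes)) unlist(markers, use.names = FALSE) else background_genes
      tr[[length(tr) + 1L]] <- data.frame(
        x = stats::runif(n_bg, 0, field_px[1] - 1),
        y = stats::runif(n_bg, 0, field_px[2] - 1),
        z = sample.int(n_planes, n_bg, replace = TRUE) - 1L,
        gene = sample(pool, n_bg, replace = TRUE),
        vessel_id = 0L, stringsAsFactors = FALSE)
    }
    list(transcripts = if (length(tr)) do.call(rbind, tr) else
      data.frame(x = numeric(0), y = numeric(0), z = integer(0),
                 gene = character(0), vessel_id = integer(0)),
      vessels = vtab)
  })

  structure(
    list(transcripts = res$transcripts, vessels = res$vessels,
         field_px = field_px, n_planes = n_planes,
         pixel_size_um = pixel_size_um, pitch = pitch, markers = markers,
         offsets = offsets, background_level = background_level,
         noise_sd = noise_sd, seed = seed),
    class = "vessel_scene")
}

#' Place arbitrary transcripts into a scene
#'
#' Low-level constructor used when a test or simulation needs exact
#' transcript placement rather than vessel rings.
#'
#' @param transcripts data.frame with `x`, `y`, `z` (0-based px/planes) and
#'   `gene`.
#' @inheritParams make_vessel_scene
#' @return a `vessel_scene` with no vessels.
#' @export
make_point_scene <- function(transcripts, field_px = c(128L, 128L),
                             n_planes = 6L, pixel_size_um = 0.138,
                             offsets = NULL, background_level = 0,
                             noise_sd = 0, seed = 1L) {
  stopifnot(is.data.frame(transcripts),
            all(c("x", "y", "z", "gene") %in% names(transcripts)))
  if (nrow(transcripts) > 0 &&
      (any(transcripts$x < 0 | transcripts$x > field_px[1] - 1) ||
       any(transcripts$y < 0 | transcripts$y > field_px[2] - 1) ||
       any(transcripts$z < 0 | transcripts$z > n_planes - 1))) {
    stop("transcript coordinates outside the field", call. = FALSE)
  }
  transcripts$vessel_id <- if (nrow(transcripts)) 0L else integer(0)
  structure(
    list(transcripts = transcripts,
         vessels = data.frame(cx = numeric(0), cy = numeric(0),
                              outer_radius = numeric(0), wall = numeric(0),
                              vessel_type = character(0)),
         field_px = as.integer(field_px), n_planes = as.integer(n_planes),
         pixel_size_um = pixel_size_um, pitch = 50L,
         markers = NULL, offsets = offsets,
         background_level = background_level, noise_sd = noise_sd,
         seed = seed),
    class = "vessel_scene")
}

#' @export
print.vessel_scene <- function(x, ...) {
  cat(sprintf(
    "vessel_scene: %d x %d px, %d planes; %d transcripts, %d vessels\n",
    x$field_px[1], x$field_px[2], x$n_planes, nrow(x$transcripts),
    nrow(x$vessels)))
  invisible(x)
}

## rigid transform of scene coordinates for round r (rotation about z through
## the field center, then translation)
apply_round_offset <- function(xyz, offset, center) {
  if (is.null(offset)) return(xyz)
  a <- offset$angle_deg * pi / 180
  tr <- offset$translation
  if (is.null(tr)) tr <- c(0, 0, 0)
  xc <- xyz[, 1] - center[1]; yc <- xyz[, 2] - center[2]
  cbind(cos(a) * xc - sin(a) * yc + center[1] + tr[1],
        sin(a) * xc + cos(a) * yc + center[2] + tr[2],
        xyz[, 3] + tr[3])
}

#' Render a scene into per-(round, channel) image stacks
#'
#' Forward model of the acquisition: every transcript contributes an
#' isotropic-in-xy Gaussian spot to exactly the images where its gene's code
#' has an on-bit. Rounds two and onward are rendered with the scene's planted
#' rigid offsets (stage drift that registration must undo), then a constant
#' background and additive Gaussian noise are applied.
#'
#' @param scene a `vessel_scene`.
#' @param codebook a `codebook` covering every gene in the scene.
#' @param amplitude peak spot intensity (default 100).
#' @param sigma_xy,sigma_z Gaussian spot sd in px laterally (default 1.2) and
#'   in planes axially (default 0.8).
#' @param seed seed for the rendering noise (default `scene$seed + 1`).
#' @return list with `stacks` (named list `R{r}_C{c}` of 3D arrays indexed
#'   `[y + 1, x + 1, z + 1]`), `truth` (the scene transcript table,
#'   unmodified), `codebook`, and the scene.
#' @export
render_rounds <- function(scene, codebook, amplitude = 100,
                          sigma_xy = 1.2, sigma_z = 0.8, seed = NULL) {
  stopifnot(inherits(scene, "vessel_scene"), inherits(codebook, "codebook"))
  tr <- scene$transcripts
  if (nrow(tr) > 0 && !all(tr$gene %in% codebook$genes)) {
    missing <- setdiff(unique(tr$gene), codebook$genes)
    stop(sprintf("scene gene(s) absent from codebook: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(seed)) seed <- scene$seed + 1L
  nx <- scene$field_px[1]; ny <- scene$field_px[2]; nz <- scene$n_planes
  nr <- codebook$n_rounds; nc <- codebook$n_channels
  center <- c((nx - 1) / 2, (ny - 1) / 2)
  stacks <- replicate(nr * nc, array(0, dim = c(ny, nx, nz)), simplify = FALSE)
  names(stacks) <- as.vector(t(outer(seq_len(nr), seq_len(nc),
                                     function(r, c) sprintf("R%d_C%d", r, c))))

  gene_idx <- match(tr$gene, codebook$genes)
  win <- ceiling(4 * sigma_xy)
  winz <- ceiling(4 * sigma_z)
  for (r in seq_len(nr)) {
    off <- if (!is.null(scene$offsets) && r >= 2 && r <= length(scene$offsets))
      scene$offsets[[r]] else NULL
    if (nrow(tr) > 0) {
      pos <- apply_round_offset(as.matrix(tr[, c("x", "y", "z")]), off, center)
      for (i in seq_len(nrow(tr))) {
        code <- codebook$codes[gene_idx[i], ]
        on_ch <- which(code[slot_index(r, seq_len(nc), nc)] == 1L)
        if (!length(on_ch)) next
        x0 <- pos[i, 1]; y0 <- pos[i, 2]; z0 <- pos[i, 3]
        xs <- max(1L, floor(x0 + 1 - win)):min(nx, ceiling(x0 + 1 + win))
        ys <- max(1L, floor(y0 + 1 - win)):min(ny, ceiling(y0 + 1 + win))
        zs <- max(1L, floor(z0 + 1 - winz)):min(nz, ceiling(z0 + 1 + winz))
        if (!length(xs) || !length(ys) || !length(zs)) next
        gx <- exp(-((xs - 1) - x0)^2 / (2 * sigma_xy^2))
        gy <- exp(-((ys - 1) - y0)^2 / (2 * sigma_xy^2))
        gz <- exp(-((zs - 1) - z0)^2 / (2 * sigma_z^2))
        spot <- amplitude * (gy %o% gx %o% gz)
        for (ch in on_ch) {
          s <- slot_index(r, ch, nc)
          stacks[[s]][ys, xs, zs] <- stacks[[s]][ys, xs, zs] + spot
        }
      }
    }
  }
  if (scene$background_level > 0 || scene$noise_sd > 0) {
    stacks <- with_seed(seed, {
      lapply(stacks, function(s) {
        s <- s + scene$background_level
        if (scene$noise_sd > 0) {
          s <- s + array(stats::rnorm(length(s), 0, scene$noise_sd), dim = dim(s))
          s[s < 0] <- 0
        }
        s
      })
    })
  }
  list(stacks = stacks, truth = scene$transcripts, codebook = codebook,
       scene = scene)
}

#' Generate an RNAscope-style multi-channel 2D fixture
#'
#' Renders Gaussian blobs of known channel membership and intensity onto a
#' constant background, clips to the 8-bit range and rounds to integers.
#'
#' @param channels character vector of channel names (e.g.
#'   `c("ACTA2", "CDH5", "TINAGL1")`).
#' @param blobs data.frame with `x`, `y` (0-based px), `channel`,
#'   `intensity`, and optionally `radius` (Gaussian sd in px, default 3). May
#'   have zero rows.
#' @param size_px image side length (default 400).
#' @param background constant background level (default 0).
#' @param noise_sd Gaussian noise sd added before 8-bit clipping (default 0).
#' @param seed integer seed.
#' @return list with `images` (named list of `size_px` x `size_px` integer
#'   matrices in `[0, 255]`, indexed `[y + 1, x + 1]`) and `blobs` (truth
#'   table).
#' @export
make_rnascope_fixture <- function(channels, blobs = NULL, size_px = 400L,
                                  background = 0, noise_sd = 0, seed = 1L) {
  stopifnot(is.character(channels), length(channels) >= 1L)
  if (is.null(blobs)) {
    blobs <- data.frame(x = numeric(0), y = numeric(0),
                        channel = character(0), intensity = numeric(0))
  }
  stopifnot(all(c("x", "y", "channel", "intensity") %in% names(blobs)))
  if (nrow(blobs) > 0 && !all(blobs$channel %in% channels)) {
    stop("blob channel not in channel list", call. = FALSE)
  }
  if (is.null(blobs$radius)) blobs$radius <- rep(3, nrow(blobs))
  size_px <- assert_count(size_px, "size_px", min = 8L)
  imgs <- with_seed(seed, {
    lapply(channels, function(ch) {
      img <- matrix(background, size_px, size_px)
      sel <- which(blobs$channel == ch)
      for (i in sel) {
        r <- blobs$radius[i]
        win <- ceiling(4 * r)
        xs <- max(1L, floor(blobs$x[i] + 1 - win)):min(size_px, ceiling(blobs$x[i] + 1 + win))
        ys <- max(1L, floor(blobs$y[i] + 1 - win)):min(size_px, ceiling(blobs$y[i] + 1 + win))
        gx <- exp(-((xs - 1) - blobs$x[i])^2 / (2 * r^2))
        gy <- exp(-((ys - 1) - blobs$y[i])^2 / (2 * r^2))
        img[ys, xs] <- img[ys, xs] + blobs$intensity[i] * (gy %o% gx)
      }
      if (noise_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                            size_px, size_px)
      }
      matrix(as.integer(round(pmin(pmax(img, 0), 255))), size_px, size_px)
    })
  })
  names(imgs) <- channels
  list(images = imgs, blobs = blobs)
}
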