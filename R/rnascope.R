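#' RNAscope quantification parameters
#'
#' @param gaussian_sigma sd (px) of the Gaussian blur subtracted from the raw
#'   image (default 50).
#' @param rolling_ball_radius radius (px) of the rolling-ball background
#'   structuring element (default 50).
#' @param intensity_floor 8-bit intensity below which pixels are zeroed
#'   (default 40).
#' @param bin_px bin side length for ROI quantification (default 50).
#' @return object of class `rnascope_params`.
#' @export
rnascope_params <- function(gaussian_sigma = 50, rolling_ball_radius = 50L,
                            intensity_floor = 40, bin_px = 50L) {
  p <- list(
    gaussian_sigma = assert_number(gaussian_sigma, "gaussian_sigma", min = 1e-9),
    rolling_ball_radius = assert_count(rolling_ball_radius,
                                       "rolling_ball_radius", min = 1L),
    intensity_floor = assert_number(intensity_floor, "intensity_floor",
                                    min = 0, max = 255),
    bin_px = assert_count(bin_px, "bin_px", min = 1L))
  class(p) <- "rnascope_params"
  p
}

#' Gaussian blur of a 2D image
#'
#' Separable Gaussian convolution with the kernel truncated at
#' `ceiling(3 * sigma)` and renormalized at the image borders (so constant
#' images blur to themselves at any image size, including images smaller
#' than the kernel).
#'
#' @param img numeric matrix.
#' @param sigma Gaussian sd in px.
#' @return blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img))
  assert_number(sigma, "sigma", min = 1e-9)
  conv1 <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    r <- ceiling(3 * sigma)
    k <- exp(-d^2 / (2 * sigma^2))
    k[abs(d) > r] <- 0
    k / rowSums(k)
  }
  conv1(nrow(img)) %*% img %*% t(conv1(ncol(img)))
}

#' Rolling-ball background of a 2D image
#'
#' Grayscale morphological opening with a flat disc structuring element of
#' the given radius; the opening is everywhere <= the image and estimates the
#' smooth background under features smaller than the disc. Borders use
#' in-bounds (clamped) semantics: the min/max at each pixel runs over the
#' part of the disc inside the image, implemented by edge-replication
#' padding around the EBImage opening.
#'
#' @param img numeric matrix.
#' @param radius disc radius in px.
#' @return background matrix of the same size.
#' @export
rolling_ball_background <- function(img, radius) {
  stopifnot(is.matrix(img))
  radius <- assert_count(radius, "radius", min = 1L)
  ## explicit disc mask: offsets with dx^2 + dy^2 <= radius^2
  d <- seq(-radius, radius)
  brush <- 1 * (outer(d^2, d^2, `+`) <= radius^2)
  r <- radius
  pad <- function(m) m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)),
                       c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))]
  crop <- function(m) m[r + seq_len(nrow(m) - 2L * r),
                        r + seq_len(ncol(m) - 2L * r)]
  ## EBImage grayscale morphology clamps to [0, 1]; flat-SE morphology
  ## commutes with positive affine scaling, so normalize and restore.
  ## Erosion and dilation each get their own replicate pad + crop, which
  ## yields in-bounds (clamped) border semantics for either step.
  lo <- min(img); hi <- max(img)
  if (hi - lo < .Machine$double.eps) return(img)
  z <- (img - lo) / (hi - lo)
  eroded <- crop(as.matrix(EBImage::erode(pad(z), brush)))
  opened <- crop(as.matrix(EBImage::dilate(pad(eroded), brush)))
  opened * (hi - lo) + lo
}

#' Background-removal chain for one RNAscope channel
#'
#' Three steps, in order: (1) subtract a sigma-50 Gaussian blur of the raw
#' image from the raw image (negatives clipped to 0); (2) subtract the
#' rolling-ball (radius 50) background; (3) zero every pixel below the
#' 8-bit intensity floor (40). The output contains no value in
#' `(0, intensity_floor)` and stays within `[0, 255]` for 8-bit input.
#'
#' @param img single-channel 2D numeric matrix (8-bit range).
#' @param params a [rnascope_params()].
#' @return processed matrix of the same size.
#' @export
preprocess_channel <- function(img, params = rnascope_params()) {
  if (!is.matrix(img)) stop("input must be a 2D matrix", call. = FALSE)
  s1 <- pmax(img - gaussian_blur(img, params$gaussian_sigma), 0)
  s2 <- s1 - rolling_ball_background(s1, params$rolling_ball_radius)
  s2[s2 < params$intensity_floor] <- 0
  pmin(s2, 255)
}

#' Per-bin channel maxima over an ROI
#'
#' Tiles the ROI into `bin_px` squares (anchored at the ROI origin; a bin
#' larger than the ROI yields a single bin) and records the maximum
#' intensity of every channel in each bin.
#'
#' @param channels named list of equally shaped 2D matrices.
#' @param bin_px bin side length in px.
#' @param roi optional `c(x0, y0, width, height)` in 0-based px; default the
#'   whole image.
#' @return data.frame with `bin_x`, `bin_y` (tile indices) and one max
#'   column per channel.
#' @export
bin_roi_max <- function(channels, bin_px = 50L, roi = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  bin_px <- assert_count(bin_px, "bin_px", min = 1L)
  dm <- dim(channels[[1]])
  for (ch in channels) if (!identical(dim(ch), dm)) {
    stop("channel shape mismatch", call. = FALSE)
  }
  if (is.null(roi)) roi <- c(0L, 0L, dm[2], dm[1])
  if (roi[1] < 0 || roi[2] < 0 || roi[1] + roi[3] > dm[2] ||
      roi[2] + roi[4] > dm[1]) {
    stop("roi outside the image", call. = FALSE)
  }
  nbx <- max(1L, ceiling(roi[3] / bin_px))
  nby <- max(1L, ceiling(roi[4] / bin_px))
  g <- expand.grid(bin_x = seq_len(nbx) - 1L, bin_y = seq_len(nby) - 1L)
  for (nm in names(channels)) g[[paste0("max_", nm)]] <- NA_real_
  for (i in seq_len(nrow(g))) {
    xs <- (roi[1] + g$bin_x[i] * bin_px + 1):min(roi[1] + (g$bin_x[i] + 1) * bin_px, roi[1] + roi[3])
    ys <- (roi[2] + g$bin_y[i] * bin_px + 1):min(roi[2] + (g$bin_y[i] + 1) * bin_px, roi[2] + roi[4])
    for (nm in names(channels)) {
      g[[paste0("max_", nm)]][i] <- max(channels[[nm]][ys, xs])
    }
  }
  g
}

#' Marker co-expression fractions after double-positive exclusion
#'
#' Binarizes each marker per bin (max > 0 after preprocessing), removes bins
#' positive for both `a` and `b`, and reports the fraction of remaining
#' a-positive bins that are target-positive, and likewise for b.
#'
#' @param bin_table output of [bin_roi_max()] on preprocessed channels.
#' @param a,b,target channel names (e.g. "ACTA2", "CDH5", "TINAGL1").
#' @return list with `frac_a` and `frac_b` (each a list of `fraction`,
#'   `n_positive`, `n_bins`, `undefined`); `fraction` is `NA` with
#'   `undefined = TRUE` for an empty denominator.
#' @export
coexpression_fractions <- function(bin_table, a, b, target) {
  cols <- paste0("max_", c(a, b, target))
  if (!all(cols %in% names(bin_table))) {
    stop(sprintf("missing marker column(s): %s",
                 paste(setdiff(cols, names(bin_table)), collapse = ", ")),
         call. = FALSE)
  }
  pos <- lapply(cols, function(cl) bin_table[[cl]] > 0)
  names(pos) <- c("a", "b", "target")
  keep <- !(pos$a & pos$b)   # drop double positives
  one <- function(which_pos) {
    denom <- which(keep & pos[[which_pos]])
    if (!length(denom)) {
      return(list(fraction = NA_real_, n_positive = 0L, n_bins = 0L,
                  undefined = TRUE))
    }
    hits <- sum(pos$target[denom])
    list(fraction = hits / length(denom), n_positive = as.integer(hits),
         n_bins = length(denom), undefined = FALSE)
  }
  list(frac_a = one("a"), frac_b = one("b"))
}
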