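#' Bin transcripts onto a square tile grid
#'
#' Transcript x/y coordinates are assigned to fixed 50-px (~7 um) tiles:
#' a transcript at (x, y) falls in tile `(floor(x / pitch), floor(y / pitch))`
#' whose centroid is `((i + 0.5) * pitch, (j + 0.5) * pitch)`. For interior
#' points this is the nearest tile centroid; the fixed-tile convention makes
#' boundary points deterministic. z is ignored. Total counts are conserved.
#'
#' @param transcripts data.frame with `x`, `y`, `gene` (finite coordinates,
#'   0-based px).
#' @param pitch tile pitch in px (default 50).
#' @param roi label attached to every bin (default "roi1").
#' @return object of class `bin_matrix`: integer `counts` (bins x genes),
#'   `x`, `y` (tile centroids, px), `roi`, `pitch`.
#' @export
bin_transcripts <- function(transcripts, pitch = 50L, roi = "roi1") {
  pitch <- assert_count(pitch, "pitch", min = 1L)
  stopifnot(is.data.frame(transcripts),
            all(c("x", "y", "gene") %in% names(transcripts)))
  if (nrow(transcripts) > 0 &&
      (!all(is.finite(transcripts$x)) || !all(is.finite(transcripts$y)))) {
    stop("transcript coordinates must be finite", call. = FALSE)
  }
  if (nrow(transcripts) == 0L) {
    return(structure(list(counts = matrix(0L, 0L, 0L), x = numeric(0),
                          y = numeric(0), roi = character(0), pitch = pitch),
                     class = "bin_matrix"))
  }
  ix <- floor(transcripts$x / pitch)
  iy <- floor(transcripts$y / pitch)
  key <- paste(ix, iy, sep = ",")
  tab <- table(key, transcripts$gene)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  kk <- do.call(rbind, strsplit(rownames(counts), ","))
  structure(
    list(counts = counts,
         x = (as.numeric(kk[, 1]) + 0.5) * pitch,
         y = (as.numeric(kk[, 2]) + 0.5) * pitch,
         roi = rep(roi, nrow(counts)), pitch = pitch),
    class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("bin_matrix: %d bins x %d genes, pitch %d px, %d total counts\n",
              nrow(x$counts), ncol(x$counts), x$pitch, sum(x$counts)))
  invisible(x)
}

## subset a bin_matrix to a logical/integer bin index
subset_bins <- function(bm, keep) {
  bm$counts <- bm$counts[keep, , drop = FALSE]
  bm$x <- bm$x[keep]; bm$y <- bm$y[keep]; bm$roi <- bm$roi[keep]
  bm
}

#' Filter bins for informative content
#'
#' Retains bins with more than one distinct gene and more than one total
#' count (i.e. >= 2 nonzero genes and total count >= 2). Idempotent.
#'
#' @param bm a `bin_matrix`.
#' @return the filtered `bin_matrix`.
#' @export
filter_bins <- function(bm) {
  stopifnot(inherits(bm, "bin_matrix"))
  if (nrow(bm$counts) == 0L) return(bm)
  keep <- rowSums(bm$counts > 0L) >= 2L & rowSums(bm$counts) >= 2L
  subset_bins(bm, keep)
}

#' Subset bins by marker expression rules
#'
#' A bin is retained iff it has a positive count for at least one
#' `require_any` gene, a count >= 1 for every `require_all` gene, and zero
#' counts for every `exclude` gene. This expresses e.g. the vasculature rule
#' (any of VWF/MYH11/KCNJ8 > 0 and TTN = 0) and the arterial-EC rule
#' (VWF and GJA5 both >= 1).
#'
#' @param bm a `bin_matrix`.
#' @param require_any,require_all,exclude character vectors of gene names
#'   (any may be empty). Unknown genes raise an error.
#' @return the subset `bin_matrix`.
#' @export
subset_by_markers <- function(bm, require_any = character(0),
                              require_all = character(0),
                              exclude = character(0)) {
  stopifnot(inherits(bm, "bin_matrix"))
  genes <- colnames(bm$counts)
  unknown <- setdiff(c(require_any, require_all, exclude), genes)
  if (length(unknown)) {
    stop(sprintf("unknown gene(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(bm$counts) == 0L) return(bm)
  keep <- rep(TRUE, nrow(bm$counts))
  if (length(require_any)) {
    keep <- keep & rowSums(bm$counts[, require_any, drop = FALSE] > 0L) >= 1L
  }
  if (length(require_all)) {
    keep <- keep & rowSums(bm$counts[, require_all, drop = FALSE] >= 1L) ==
      length(require_all)
  }
  if (length(exclude)) {
    keep <- keep & rowSums(bm$counts[, exclude, drop = FALSE]) == 0L
  }
  subset_bins(bm, keep)
}

#' Gene-gene Pearson correlation across bins
#'
#' @param bm a `bin_matrix` with >= 2 bins.
#' @return symmetric correlation matrix over the genes with nonzero variance;
#'   dropped genes are recorded in attribute `dropped`.
#' @export
gene_correlation <- function(bm) {
  stopifnot(inherits(bm, "bin_matrix"))
  if (nrow(bm$counts) < 2L) {
    stop("gene correlation requires at least 2 bins", call. = FALSE)
  }
  v <- apply(bm$counts, 2, stats::var)
  keep <- v > 0
  m <- stats::cor(bm$counts[, keep, drop = FALSE])
  attr(m, "dropped") <- colnames(bm$counts)[!keep]
  m
}

#' Concatenate bin matrices from several ROIs
#'
#' Aligns gene columns (union, missing filled with 0) and stacks bins; bins
#' keep their per-ROI `roi` labels and coordinates.
#'
#' @param bms list of `bin_matrix` objects with a common pitch.
#' @return a single `bin_matrix`.
#' @export
merge_bin_matrices <- function(bms) {
  stopifnot(length(bms) >= 1L, all(vapply(bms, inherits, logical(1), "bin_matrix")))
  pitch <- unique(vapply(bms, function(b) b$pitch, numeric(1)))
  if (length(pitch) != 1L) stop("bin matrices have different pitches", call. = FALSE)
  genes <- sort(unique(unlist(lapply(bms, function(b) colnames(b$counts)))))
  counts <- do.call(rbind, lapply(bms, function(b) {
    m <- matrix(0L, nrow(b$counts), length(genes),
                dimnames = list(NULL, genes))
    if (ncol(b$counts)) m[, colnames(b$counts)] <- b$counts
    m
  }))
  structure(
    list(counts = counts,
         x = unlist(lapply(bms, function(b) b$x)),
         y = unlist(lapply(bms, function(b) b$y)),
         roi = unlist(lapply(bms, function(b) b$roi)),
         pitch = as.integer(pitch)),
    class = "bin_matrix")
}
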