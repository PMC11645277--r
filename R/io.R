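## File formats: TIFF stacks (one file per (round, channel)), CSV tables,
## MTX + TSV bin matrices, JSON transforms and reports. All coordinates in
## files are 0-based pixels; z is a plane index.

#' Write / read per-(round, channel) image stacks as TIFF
#'
#' One multi-page 16-bit TIFF per slot, filename `R{round}_C{channel}.tif`.
#' Intensities are rounded to integers; values above 65535 raise an error.
#'
#' @param stacks named list of 3D arrays in slot order (names
#'   `R{r}_C{c}`).
#' @param dir output directory (created if missing).
#' @return `write_round_stacks` returns the file paths invisibly.
#' @export
write_round_stacks <- function(stacks, dir) {
  stopifnot(is.list(stacks), !is.null(names(stacks)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(stacks)) {
    s <- round(stacks[[nm]])
    if (any(s < 0) || any(s > 65535)) {
      stop("stack intensities must lie in [0, 65535] for 16-bit TIFF",
           call. = FALSE)
    }
    pages <- lapply(seq_len(dim(s)[3]), function(k) s[, , k] / 65535)
    path <- file.path(dir, paste0(nm, ".tif"))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_round_stacks
#' @param n_rounds,n_channels stack geometry to read back.
#' @return `read_round_stacks` returns the named list of 3D arrays.
#' @export
read_round_stacks <- function(dir, n_rounds = 8L, n_channels = 2L) {
  stacks <- list()
  for (r in seq_len(n_rounds)) for (ch in seq_len(n_channels)) {
    nm <- sprintf("R%d_C%d", r, ch)
    path <- file.path(dir, paste0(nm, ".tif"))
    if (!file.exists(path)) {
      stop(sprintf("missing stack file: %s", path), call. = FALSE)
    }
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    stacks[[nm]] <- array(unlist(pages),
                          dim = c(dim(pages[[1]]), length(pages)))
  }
  stacks
}

#' Write / read a transcript table as CSV
#'
#' Columns `x`, `y`, `z` (0-based px / plane index), `gene`, and any further
#' columns present (`code_score`, `group_size`).
#'
#' @param transcripts data.frame.
#' @param path CSV path.
#' @export
write_transcripts <- function(transcripts, path) {
  utils::write.csv(transcripts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transcripts
#' @export
read_transcripts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "gene")
  if (!all(need %in% names(df))) {
    stop("transcript table needs x, y, gene columns", call. = FALSE)
  }
  df
}

#' Write / read a bin matrix (MTX + TSV)
#'
#' `matrix.mtx` holds the sparse bins x genes counts, `bins.tsv` the bin
#' centroids and ROI labels, `genes.tsv` the gene names — the common
#' single-cell exchange layout.
#'
#' @param bm a `bin_matrix`.
#' @param dir output directory.
#' @export
write_bin_matrix <- function(bm, dir) {
  stopifnot(inherits(bm, "bin_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(bm$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(x = bm$x, y = bm$y, roi = bm$roi, pitch = bm$pitch),
    file.path(dir, "bins.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(colnames(bm$counts), file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' @rdname write_bin_matrix
#' @export
read_bin_matrix <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  bins <- utils::read.delim(file.path(dir, "bins.tsv"),
                            stringsAsFactors = FALSE)
  colnames(m) <- readLines(file.path(dir, "genes.tsv"))
  structure(list(counts = m, x = bins$x, y = bins$y, roi = as.character(bins$roi),
                 pitch = as.integer(bins$pitch[1])),
            class = "bin_matrix")
}

#' Write / read a rigid transform as JSON
#'
#' @param transform a `rigid_transform3d`.
#' @param path JSON path.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform3d"))
  jsonlite::write_json(
    list(rotation = transform$rotation,
         translation = transform$translation),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform3d(x$rotation, x$translation)
}
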