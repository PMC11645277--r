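#' Specify a combinatorial codebook
#'
#' A codebook maps each gene to a fixed-weight binary code over
#' `n_rounds * n_channels` (round, channel) slots; the default geometry is
#' eight imaging rounds in two color channels, i.e. 16-slot codes. A number of
#' valid codes can be reserved as *unused*: they are matched during decoding
#' but assigned to no gene, which makes them an internal false-positive
#' control.
#'
#' @param n_genes number of genes to encode.
#' @param n_rounds imaging rounds (default 8).
#' @param n_channels color channels per round (default 2).
#' @param code_weight number of on-bits per code (default 4).
#' @param min_hamming minimum pairwise Hamming distance between any two codes,
#'   used or unused (default 4).
#' @param n_unused number of reserved unused codes (default 0).
#' @param seed integer seed controlling the randomized code selection.
#' @return an object of class `codebook_spec`.
#' @seealso [make_codebook()]
#' @export
codebook_spec <- function(n_genes, n_rounds = 8L, n_channels = 2L,
                          code_weight = 4L, min_hamming = 4L,
                          n_unused = 0L, seed = 1L) {
  spec <- list(
    n_genes = assert_count(n_genes, "n_genes", min = 1L),
    n_rounds = assert_count(n_rounds, "n_rounds", min = 1L),
    n_channels = assert_count(n_channels, "n_channels", min = 1L),
    code_weight = assert_count(code_weight, "code_weight", min = 1L),
    min_hamming = assert_count(min_hamming, "min_hamming", min = 0L),
    n_unused = assert_count(n_unused, "n_unused", min = 0L),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (spec$code_weight > spec$n_rounds * spec$n_channels) {
    stop("code_weight exceeds the number of (round, channel) slots",
         call. = FALSE)
  }
  class(spec) <- "codebook_spec"
  spec
}

#' Generate a codebook from a specification
#'
#' Selects `n_genes + n_unused` distinct fixed-weight binary codes whose
#' pairwise Hamming distance is at least `min_hamming`, in a seeded random
#' order, and fails with an explicit error when the constraints cannot be
#' satisfied. Generation is deterministic per seed.
#'
#' Because equal-weight codes always differ in an even number of bits, a
#' requirement of `min_hamming` in 3..4 is met exactly by codes at pairwise
#' distance >= 4. When the code length is a power of two these are drawn
#' from the parity pool of weight-`w` codes whose on-bit position vectors
#' (as elements of GF(2)^m) XOR to zero: two distinct such codes can never
#' differ in only one on-bit, so their distance is at least 4. This pool
#' reaches the maximal constant-weight code size (140 codes for weight 4 of
#' 16). For other geometries, or `min_hamming > 4`, a randomized greedy
#' selection with seeded restarts is used.
#'
#' Slot order is round-major, channel-minor: slot `(r, c)` maps to column
#' `(r - 1) * n_channels + c`.
#'
#' @param spec a [codebook_spec()].
#' @return an object of class `codebook`: list with `genes` (character),
#'   `codes` (n_genes x n_slots binary matrix, rownames = genes),
#'   `unused_codes` (n_unused x n_slots binary matrix), and the spec fields.
#' @export
#' @examples
#' cb <- make_codebook(codebook_spec(n_genes = 10, n_unused = 5, seed = 7))
#' rowSums(cb$codes)        # all equal code_weight
make_codebook <- function(spec) {
  stopifnot(inherits(spec, "codebook_spec"))
  n_slots <- spec$n_rounds * spec$n_channels
  w <- spec$code_weight
  need <- spec$n_genes + spec$n_unused
  n_all <- choose(n_slots, w)
  if (need > n_all) {
    stop(sprintf(
      "infeasible codebook: %d codes requested but only %d weight-%d codes of length %d exist",
      need, n_all, w, n_slots), call. = FALSE)
  }
  ## all weight-w codes, one per column of combn
  combos <- utils::combn(n_slots, w)
  all_codes <- matrix(0L, ncol(combos), n_slots)
  all_codes[cbind(rep(seq_len(ncol(combos)), each = w), as.vector(combos))] <- 1L

  ## greedy pass over a random order, keeping codes at pairwise distance
  ## >= min_hamming (distance via dot products: d = 2 * (w - <x_i, x_j>))
  greedy_pick <- function(ord) {
    sel <- integer(0)
    for (i in ord) {
      if (length(sel)) {
        dots <- as.vector(all_codes[sel, , drop = FALSE] %*% all_codes[i, ])
        if (!all(2L * (w - dots) >= spec$min_hamming)) next
      }
      sel <- c(sel, i)
      if (length(sel) == need) break
    }
    sel
  }

  pow2 <- n_slots >= 4 && bitwAnd(n_slots, n_slots - 1L) == 0L
  selected <- with_seed(spec$seed, {
    if (spec$min_hamming <= 2L) {
      sample.int(nrow(all_codes))[seq_len(need)]
    } else if (spec$min_hamming <= 4L && pow2) {
      ## parity pool: on-bit positions (0-based, as GF(2)^m vectors) XOR to 0
      xors <- apply(combos - 1L, 2L, function(p) Reduce(bitwXor, p))
      pool <- which(xors == 0L)
      if (length(pool) >= need) {
        sample(pool)[seq_len(need)]
      } else {
        greedy_pick(sample.int(nrow(all_codes)))
      }
    } else {
      best <- integer(0)
      for (restart in seq_len(50L)) {
        sel <- greedy_pick(sample.int(nrow(all_codes)))
        if (length(sel) > length(best)) best <- sel
        if (length(best) == need) break
      }
      best
    }
  })
  if (length(selected) < need) {
    stop(sprintf(
      "infeasible codebook: only %d codes with pairwise Hamming >= %d found (%d requested)",
      length(selected), spec$min_hamming, need), call. = FALSE)
  }
  ## hard invariant check on the final selection
  dots <- tcrossprod(all_codes[selected, , drop = FALSE])
  dmin <- 2L * (w - dots[upper.tri(dots)])
  if (need > 1L && min(dmin) < spec$min_hamming) {
    stop("internal error: selected codes violate the Hamming constraint",
         call. = FALSE)
  }
  genes <- sprintf("gene%03d", seq_len(spec$n_genes))
  codes <- all_codes[selected[seq_len(spec$n_genes)], , drop = FALSE]
  rownames(codes) <- genes
  unused <- all_codes[selected[spec$n_genes + seq_len(spec$n_unused)], ,
                      drop = FALSE]
  if (spec$n_unused > 0L) {
    rownames(unused) <- sprintf("unused%03d", seq_len(spec$n_unused))
  }
  structure(
    list(genes = genes, codes = codes, unused_codes = unused,
         n_rounds = spec$n_rounds, n_channels = spec$n_channels,
         code_weight = w, min_hamming = spec$min_hamming),
    class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf(
    "codebook: %d genes + %d unused codes, %d rounds x %d channels (length %d), weight %d, min Hamming %d\n",
    length(x$genes), nrow(x$unused_codes), x$n_rounds, x$n_channels,
    x$n_rounds * x$n_channels, x$code_weight, x$min_hamming))
  invisible(x)
}

#' Rename the genes of a codebook
#'
#' Convenience for synthetic scenes that need marker gene names (e.g. VWF,
#' GJA5) to occupy codebook slots.
#'
#' @param cb a `codebook`.
#' @param names character vector, one name per gene (or a named character
#'   vector `c(gene001 = "VWF", ...)` renaming a subset).
#' @return the codebook with genes renamed.
#' @export
rename_genes <- function(cb, names) {
  stopifnot(inherits(cb, "codebook"))
  if (!is.null(base::names(names))) {
    idx <- match(base::names(names), cb$genes)
    if (anyNA(idx)) stop("unknown gene in rename", call. = FALSE)
    cb$genes[idx] <- unname(names)
  } else {
    if (length(names) != length(cb$genes)) {
      stop("need one name per gene", call. = FALSE)
    }
    cb$genes <- as.character(names)
  }
  if (anyDuplicated(cb$genes)) stop("duplicate gene names", call. = FALSE)
  rownames(cb$codes) <- cb$genes
  cb
}

## slot index for (round, channel), round-major channel-minor
slot_index <- function(round, channel, n_channels) {
  (round - 1L) * n_channels + channel
}

#' Write / read a codebook as CSV
#'
#' Columns: `gene`, `code` (0/1 string of length `n_rounds * n_channels`),
#' `used` (1 for genes, 0 for reserved unused codes). A `# slots:` comment
#' records the round-major, channel-minor slot order.
#'
#' @param cb a `codebook`.
#' @param path file path.
#' @return `write_codebook` returns `path` invisibly; `read_codebook` returns
#'   a `codebook`.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  all_codes <- rbind(cb$codes, cb$unused_codes)
  df <- data.frame(
    gene = rownames(all_codes),
    code = apply(all_codes, 1L, paste0, collapse = ""),
    used = rep(c(1L, 0L), c(nrow(cb$codes), nrow(cb$unused_codes))),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# slots: round-major, channel-minor; %d rounds x %d channels; weight %d; min_hamming %d",
    cb$n_rounds, cb$n_channels, cb$code_weight, cb$min_hamming), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_codebook
#' @param n_rounds,n_channels code geometry; recovered from the header comment
#'   when present.
#' @export
read_codebook <- function(path, n_rounds = NULL, n_channels = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) && is.null(n_rounds)) {
    m <- regmatches(hdr[1], regexec("(\\d+) rounds x (\\d+) channels", hdr[1]))[[1]]
    if (length(m) == 3L) {
      n_rounds <- as.integer(m[2]); n_channels <- as.integer(m[3])
    }
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        colClasses = c("character", "character", "integer"))
  len <- unique(nchar(df$code))
  bad <- which(nchar(df$code) != nchar(df$code[1]) |
                 grepl("[^01]", df$code))
  if (length(bad)) {
    stop(sprintf("malformed code string at row %d", bad[1]), call. = FALSE)
  }
  len <- nchar(df$code[1])
  if (is.null(n_rounds)) { n_rounds <- len %/% 2L; n_channels <- 2L }
  if (n_rounds * n_channels != len) {
    stop("code length does not match n_rounds * n_channels", call. = FALSE)
  }
  mat <- t(vapply(strsplit(df$code, ""), function(s) as.integer(s),
                  integer(len)))
  rownames(mat) <- df$gene
  used <- df$used == 1L
  structure(
    list(genes = df$gene[used],
         codes = mat[used, , drop = FALSE],
         unused_codes = mat[!used, , drop = FALSE],
         n_rounds = n_rounds, n_channels = n_channels,
         code_weight = as.integer(rowSums(mat)[1]),
         min_hamming = NA_integer_),
    class = "codebook")
}
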