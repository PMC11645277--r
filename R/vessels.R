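#' Vessel clustering parameters
#'
#' @param min_cluster_bins clusters with fewer bins are removed (default 5).
#' @param caliber_threshold_bins a vessel is "larger" caliber iff it has more
#'   bins than this (default 30).
#' @param linkage_threshold_px single-linkage cut distance; default 1.5 x the
#'   bin pitch, which makes clusters equal to 8-neighborhood connected
#'   components of the tile grid.
#' @return object of class `vessel_params`.
#' @export
vessel_params <- function(min_cluster_bins = 5L,
                          caliber_threshold_bins = 30L,
                          linkage_threshold_px = NULL) {
  p <- list(
    min_cluster_bins = assert_count(min_cluster_bins, "min_cluster_bins", min = 1L),
    caliber_threshold_bins = assert_count(caliber_threshold_bins,
                                          "caliber_threshold_bins", min = 1L),
    linkage_threshold_px = if (is.null(linkage_threshold_px)) NULL else
      assert_number(linkage_threshold_px, "linkage_threshold_px", min = 0))
  if (p$caliber_threshold_bins < p$min_cluster_bins) {
    stop("caliber_threshold_bins must be >= min_cluster_bins", call. = FALSE)
  }
  class(p) <- "vessel_params"
  p
}

#' Group marker-positive bins into vessel objects
#'
#' Agglomerative single-linkage clustering of bin centroids, cut at
#' `linkage_threshold_px` (default 1.5 x pitch, i.e. diagonal neighbors
#' connect), per ROI. Clusters with fewer than `min_cluster_bins` bins are
#' removed; survivors are labeled by caliber.
#'
#' @param bm a `bin_matrix` already subset to one vessel type's markers
#'   (e.g. arterial: VWF & GJA5 via [subset_by_markers()]).
#' @param params a [vessel_params()].
#' @param vessel_type label stored on each cluster ("artery"/"vein";
#'   default "artery").
#' @return data.frame, one row per retained vessel: `vessel_id`, `roi`,
#'   `vessel_type`, `n_bins`, `caliber`; attribute `membership` maps each
#'   retained bin (row index into `bm`) to its `vessel_id`.
#' @export
cluster_vessels <- function(bm, params = vessel_params(),
                            vessel_type = "artery") {
  stopifnot(inherits(bm, "bin_matrix"))
  thr <- if (is.null(params$linkage_threshold_px)) 1.5 * bm$pitch else
    params$linkage_threshold_px
  empty <- data.frame(vessel_id = integer(0), roi = character(0),
                      vessel_type = character(0), n_bins = integer(0),
                      caliber = character(0))
  if (nrow(bm$counts) == 0L) {
    return(structure(empty,
                     membership = data.frame(bin = integer(0),
                                             vessel_id = integer(0))))
  }
  rows <- list(); memb <- list(); next_id <- 0L
  for (roi in unique(bm$roi)) {
    idx <- which(bm$roi == roi)
    pts <- cbind(bm$x[idx], bm$y[idx])
    cl <- if (length(idx) == 1L) 1L else {
      hc <- stats::hclust(stats::dist(pts), method = "single")
      stats::cutree(hc, h = thr)
    }
    for (g in unique(cl)) {
      sel <- idx[cl == g]
      if (length(sel) < params$min_cluster_bins) next
      next_id <- next_id + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        vessel_id = next_id, roi = roi, vessel_type = vessel_type,
        n_bins = length(sel),
        caliber = classify_caliber(length(sel), params),
        stringsAsFactors = FALSE)
      memb[[length(memb) + 1L]] <- data.frame(bin = sel, vessel_id = next_id)
    }
  }
  if (!length(rows)) {
    return(structure(empty,
                     membership = data.frame(bin = integer(0),
                                             vessel_id = integer(0))))
  }
  structure(do.call(rbind, rows), membership = do.call(rbind, memb))
}

#' Classify vessel caliber from bin count
#'
#' Larger caliber iff the vessel spans more than `caliber_threshold_bins`
#' bins (default 30), smaller otherwise.
#'
#' @param n_bins bin count of a vessel cluster.
#' @param params a [vessel_params()].
#' @return "larger" or "smaller".
#' @export
classify_caliber <- function(n_bins, params = vessel_params()) {
  n_bins <- assert_count(n_bins, "n_bins", min = 0L)
  if (n_bins > params$caliber_threshold_bins) "larger" else "smaller"
}

#' Per-vessel expression statistics for one gene
#'
#' @param vessels output of [cluster_vessels()].
#' @param bm the `bin_matrix` the vessels were clustered from.
#' @param gene gene name.
#' @return data.frame, one row per vessel: `vessel_id`, `n_bins`, `caliber`,
#'   `pct_expressing` (100 x fraction of the vessel's bins with count >= 1)
#'   and `mean_expressing` (mean count over expressing bins only; `NA` when
#'   no bin expresses).
#' @export
vessel_gene_stats <- function(vessels, bm, gene) {
  stopifnot(inherits(bm, "bin_matrix"))
  if (!gene %in% colnames(bm$counts)) {
    stop(sprintf("unknown gene: %s", gene), call. = FALSE)
  }
  memb <- attr(vessels, "membership")
  out <- vessels[, c("vessel_id", "n_bins", "caliber")]
  out$pct_expressing <- NA_real_
  out$mean_expressing <- NA_real_
  for (i in seq_len(nrow(out))) {
    bins <- memb$bin[memb$vessel_id == out$vessel_id[i]]
    cts <- bm$counts[bins, gene]
    expr <- cts >= 1L
    out$pct_expressing[i] <- 100 * sum(expr) / length(cts)
    out$mean_expressing[i] <- if (any(expr)) mean(cts[expr]) else NA_real_
  }
  out
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test: exact enumeration when the
#' smaller group has at most `exact_cutoff` observations and there are no
#' ties, tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param values_a,values_b non-empty numeric vectors.
#' @param exact_cutoff exact-test sample size cutoff (default 8).
#' @return list: `statistic` (rank-sum U for group a), `p_value`, `n_a`,
#'   `n_b`, `exact` (logical).
#' @export
compare_groups <- function(values_a, values_b, exact_cutoff = 8L) {
  if (!length(values_a) || !length(values_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0L
  use_exact <- !has_ties && min(length(values_a), length(values_b)) <= exact_cutoff
  wt <- suppressWarnings(stats::wilcox.test(
    values_a, values_b, alternative = "two.sided",
    exact = use_exact, correct = TRUE))
  p <- wt$p.value
  ## every observation tied across both groups: no evidence either way
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p,
       n_a = length(values_a), n_b = length(values_b), exact = use_exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `p_adj(i) = min over j >= i of m * p(j) / j` on
#' the sorted p-values, capped at 1, returned in the original order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) ||
      any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Compare vessel expression between caliber (or type) groups
#'
#' Runs [compare_groups()] per gene and metric across two vessel groups and
#' BH-adjusts across all tests of the run. Both a per-vessel variant (each
#' vessel contributes one number) and a pooled-bin variant (each bin
#' contributes its count) of the mean-expression comparison are supported
#' via `level`.
#'
#' @param vessels output of [cluster_vessels()] (possibly rbind-ed across
#'   types), with a grouping column selected by `group_by`.
#' @param bm the `bin_matrix`.
#' @param genes genes to test.
#' @param group_by column of `vessels` defining the two groups (default
#'   "caliber").
#' @param level "vessel" (default): vessels are replicates via
#'   [vessel_gene_stats()]; "bin": expressing-bin counts are pooled per
#'   group.
#' @return data.frame: `gene`, `metric`, `group_a`, `group_b`, `statistic`,
#'   `p`, `p_adj`, `n_a`, `n_b`.
#' @export
compare_vessel_groups <- function(vessels, bm, genes,
                                  group_by = "caliber", level = "vessel") {
  stopifnot(group_by %in% names(vessels))
  grp <- vessels[[group_by]]
  levs <- sort(unique(grp))
  if (length(levs) != 2L) {
    stop("grouping column must have exactly two levels", call. = FALSE)
  }
  memb <- attr(vessels, "membership")
  rows <- list()
  for (gene in genes) {
    if (level == "vessel") {
      st <- vessel_gene_stats(vessels, bm, gene)
      for (metric in c("pct_expressing", "mean_expressing")) {
        va <- st[[metric]][grp == levs[1]]
        vb <- st[[metric]][grp == levs[2]]
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        if (!length(va) || !length(vb)) next
        cg <- compare_groups(va, vb)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, metric = metric, group_a = levs[1], group_b = levs[2],
          statistic = cg$statistic, p = cg$p_value,
          n_a = cg$n_a, n_b = cg$n_b, stringsAsFactors = FALSE)
      }
    } else if (level == "bin") {
      pool <- function(lev) {
        ids <- vessels$vessel_id[grp == lev]
        bins <- memb$bin[memb$vessel_id %in% ids]
        cts <- bm$counts[bins, gene]
        cts[cts >= 1L]
      }
      va <- pool(levs[1]); vb <- pool(levs[2])
      if (!length(va) || !length(vb)) next
      cg <- compare_groups(va, vb)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, metric = "mean_expressing_pooled_bins",
        group_a = levs[1], group_b = levs[2],
        statistic = cg$statistic, p = cg$p_value,
        n_a = cg$n_a, n_b = cg$n_b, stringsAsFactors = FALSE)
    } else {
      stop("level must be 'vessel' or 'bin'", call. = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), metric = character(0),
                      group_a = character(0), group_b = character(0),
                      statistic = numeric(0), p = numeric(0),
                      p_adj = numeric(0), n_a = integer(0), n_b = integer(0)))
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res[, c("gene", "metric", "group_a", "group_b", "statistic", "p", "p_adj",
          "n_a", "n_b")]
}
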