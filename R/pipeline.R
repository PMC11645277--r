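#' Pipeline configuration
#'
#' Collects the per-stage parameters of the full analysis: scene and
#' codebook generation (or paths to existing inputs), rendering, detection,
#' registration, decoding, binning and vessel statistics. Every random stage
#' draws from an explicit seed, so a config reruns to identical outputs.
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds derive from it.
#' @param vessels vessel table for [make_vessel_scene()] (or NULL for none).
#' @param field_px,n_planes,pixel_size_um scene geometry.
#' @param n_genes,n_unused codebook size.
#' @param offsets per-round rigid offsets planted at rendering.
#' @param background_rate expected number of uniform background transcripts
#'   drawn from the whole gene panel (default 0); with several hundred,
#'   every imaging round carries registration signal.
#' @param noise_sd,background_level rendering noise model.
#' @param detection a [detection_params()].
#' @param register logical: run ICP registration + resampling (default TRUE
#'   when offsets are present).
#' @param min_score,min_match decoding thresholds.
#' @param pitch bin pitch (px).
#' @param rate_larger,rate_smaller planted per-tile emission rates of the
#'   caliber gene in larger / smaller vessels (defaults 0.6 and 0.2); vessels
#'   count as larger when their ring exceeds the caliber threshold of
#'   `vessel_pars`.
#' @param artery_markers,vein_markers `require_all` marker sets for vessel
#'   typing.
#' @param vessel_pars a [vessel_params()].
#' @param test_genes genes compared between caliber groups.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            vessels = NULL,
                            field_px = c(512L, 512L),
                            n_planes = 6L,
                            pixel_size_um = 0.138,
                            n_genes = 20L,
                            n_unused = 5L,
                            offsets = NULL,
                            background_rate = 0,
                            noise_sd = 0,
                            background_level = 0,
                            detection = detection_params(),
                            register = NULL,
                            min_score = 2,
                            min_match = 0.7,
                            pitch = 50L,
                            rate_larger = 0.6,
                            rate_smaller = 0.2,
                            artery_markers = c("VWF", "GJA5"),
                            vein_markers = c("VWF", "ACKR1"),
                            vessel_pars = vessel_params(),
                            test_genes = "SULF1") {
  cfg <- as.list(environment())
  if (is.null(cfg$register)) cfg$register <- !is.null(offsets)
  class(cfg) <- "pipeline_config"
  cfg
}

## md5 of files for the run manifest
.hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  as.list(stats::setNames(unname(h), basename(paths)))
}

#' Downstream analysis of a pre-decoded transcript table
#'
#' Runs the post-decoding stages only — binning, marker subsetting, vessel
#' clustering, caliber classification and caliber-group statistics — on an
#' existing transcript table (decoded here or elsewhere).
#'
#' @param transcripts data.frame with `x`, `y`, `gene` (0-based px).
#' @param pitch bin pitch in px (default 50).
#' @param vessel_markers `require_all` marker set defining the vessel type of
#'   interest (default arterial: `c("VWF", "GJA5")`).
#' @param vessel_type label for the clustered vessels.
#' @param params a [vessel_params()].
#' @param test_genes genes compared between caliber groups (default
#'   "SULF1").
#' @param roi ROI label for the bins.
#' @return list with `bin_matrix` (marker-subset bins), `vessels`,
#'   `comparisons` (NULL when both caliber classes are not present).
#' @export
analyze_transcripts <- function(transcripts, pitch = 50L,
                                vessel_markers = c("VWF", "GJA5"),
                                vessel_type = "artery",
                                params = vessel_params(),
                                test_genes = "SULF1",
                                roi = "roi1") {
  bm <- bin_transcripts(transcripts, pitch = pitch, roi = roi)
  sub <- subset_by_markers(bm, require_all = vessel_markers)
  vessels <- cluster_vessels(sub, params, vessel_type)
  comparisons <- NULL
  genes <- intersect(test_genes, colnames(sub$counts))
  if (nrow(vessels) && length(genes) &&
      length(unique(vessels$caliber)) == 2L) {
    comparisons <- compare_vessel_groups(vessels, sub, genes)
  }
  list(bin_matrix = sub, vessels = vessels, comparisons = comparisons)
}

#' Run the full pipeline on a synthetic scene
#'
#' Stage order: simulate (codebook + vessel scene + rendered rounds), detect
#' (per-round feature clouds), register (ICP to round 1 + tri-linear
#' resampling; skipped when no offsets are configured), decode, bin, subset
#' by vessel markers, cluster vessels and compare caliber groups. All
#' artifacts are written under `config$out_dir` together with a JSON
#' manifest recording stage parameters and output hashes.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages (default FALSE).
#' @return (invisibly) a list with the in-memory artifacts: `codebook`,
#'   `scene`, `transcripts`, `specificity`, `bin_matrix`, `vessels`,
#'   `comparisons`, and the `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[%s] ", fmt),
                                format(Sys.time(), "%H:%M:%S"), ...))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  ## -- simulate ------------------------------------------------------------
  say("simulate: codebook (%d genes + %d unused) and scene", config$n_genes,
      config$n_unused)
  cb <- make_codebook(codebook_spec(
    n_genes = config$n_genes, n_unused = config$n_unused,
    seed = config$seed))
  markers <- list(pan = "VWF", artery = "GJA5", vein = "ACKR1",
                  caliber = "SULF1")
  cb <- rename_genes(cb, stats::setNames(
    unlist(markers), cb$genes[seq_along(markers)]))
  scene <- make_vessel_scene(
    vessels = config$vessels, field_px = config$field_px,
    n_planes = config$n_planes, pixel_size_um = config$pixel_size_um,
    pitch = config$pitch, markers = markers,
    rate_larger = config$rate_larger, rate_smaller = config$rate_smaller,
    caliber_threshold_bins = config$vessel_pars$caliber_threshold_bins,
    background_rate = config$background_rate, background_genes = cb$genes,
    offsets = config$offsets, noise_sd = config$noise_sd,
    background_level = config$background_level, seed = config$seed + 1L)
  rendered <- render_rounds(scene, cb, seed = config$seed + 2L)
  write_codebook(cb, file.path(config$out_dir, "codebook.csv"))
  write_transcripts(scene$transcripts,
                    file.path(config$out_dir, "truth_transcripts.csv"))

  stacks <- rendered$stacks
  ## -- detect + register ---------------------------------------------------
  if (config$register) {
    say("detect: per-round feature clouds")
    nr <- cb$n_rounds; nc <- cb$n_channels
    clouds <- lapply(seq_len(nr), function(r) {
      detect_round_features(
        stacks[slot_index(r, seq_len(nc), nc)],
        pixel_size_um = config$pixel_size_um, params = config$detection)
    })
    say("register: ICP of rounds 2..%d onto round 1", nr)
    for (r in 2:nr) {
      if (nrow(clouds[[r]]) < 3L || nrow(clouds[[1]]) < 3L) {
        warning(sprintf(
          "round %d: too few features for ICP; using identity transform", r),
          call. = FALSE)
        fit <- list(transform = rigid_transform3d())
      } else {
        fit <- icp_register(clouds[[r]], clouds[[1]])
      }
      write_transform(fit$transform,
                      file.path(config$out_dir,
                                sprintf("transform_round%d.json", r)))
      plan <- resample_plan(dim(stacks[[1]]), fit$transform)
      for (ch in seq_len(nc)) {
        s <- slot_index(r, ch, nc)
        stacks[[s]] <- resample_with_plan(stacks[[s]], plan)
      }
    }
  }

  ## -- decode --------------------------------------------------------------
  say("decode: profiles, matching, grouping, localization")
  dec <- decode_stacks(stacks, cb, min_score = config$min_score,
                       min_match = config$min_match)
  write_transcripts(dec$transcripts,
                    file.path(config$out_dir, "transcripts.csv"))
  if (!is.null(dec$specificity)) {
    jsonlite::write_json(dec$specificity,
                         file.path(config$out_dir, "specificity.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## -- bin + vessels -------------------------------------------------------
  say("bin: pitch %d px", config$pitch)
  bm <- bin_transcripts(dec$transcripts, pitch = config$pitch)
  write_bin_matrix(bm, file.path(config$out_dir, "bin_matrix"))
  say("vessels: artery subset (%s), clustering, caliber stats",
      paste(config$artery_markers, collapse = " & "))
  vessels <- comparisons <- NULL
  art_idx <- intersect(config$artery_markers, colnames(bm$counts))
  if (length(art_idx) == length(config$artery_markers) && nrow(bm$counts)) {
    art <- subset_by_markers(bm, require_all = config$artery_markers)
    vessels <- cluster_vessels(art, config$vessel_pars, "artery")
    utils::write.csv(vessels, file.path(config$out_dir, "vessels.csv"),
                     row.names = FALSE, quote = FALSE)
    genes <- intersect(config$test_genes, colnames(art$counts))
    if (nrow(vessels) && length(genes) &&
        length(unique(vessels$caliber)) == 2L) {
      comparisons <- compare_vessel_groups(vessels, art, genes)
      utils::write.csv(comparisons,
                       file.path(config$out_dir, "comparisons.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }

  ## -- manifest ------------------------------------------------------------
  outputs <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    stages = c("simulate", if (config$register) c("detect", "register"),
               "decode", "bin", "vessels"),
    parameters = config[setdiff(names(config), c("out_dir", "detection",
                                                 "vessel_pars", "vessels"))],
    vessel_table = config$vessels,
    outputs = .hash_files(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  say("done: %d transcripts, %d bins, %d vessels",
      nrow(dec$transcripts), nrow(bm$counts),
      if (is.null(vessels)) 0L else nrow(vessels))
  invisible(list(codebook = cb, scene = scene,
                 transcripts = dec$transcripts,
                 unused_transcripts = dec$unused_transcripts,
                 specificity = dec$specificity, bin_matrix = bm,
                 vessels = vessels, comparisons = comparisons,
                 manifest = manifest))
}
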