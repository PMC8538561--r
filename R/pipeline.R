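#' Full-pipeline configuration
#'
#' Bundles every stage's settings plus dataset shape, seed and output
#' directory. The defaults are desk-scale (small phantom counts and short
#' training) so a full run completes on one CPU; the study-scale dataset
#' shape is `counts = c(400, 200, 200, 200, 400)` at 700 x 600.
#'
#' @param out_dir Run directory (created).
#' @param counts Per-grade phantom counts.
#' @param image_size Square phantom/classifier size for the run.
#' @param seed Master seed, propagated to every stochastic stage.
#' @param spec A [grade_spec()].
#' @param enhancement An [enhancement_config()].
#' @param watershed A [watershed_config()].
#' @param classifier A [densenet_config()].
#' @param train A [train_config()].
#' @param augment Double the dataset by offline augmentation?
#' @param n_seg_train Phantoms used to train the segmentation stages.
#' @param unet_steps,unet_depth,unet_base Mask-network training settings.
#' @param dry_run Validate and return without writing anything?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("fundushr_run_"),
                            counts = c(20L, 10L, 10L, 10L, 20L),
                            image_size = 128L, seed = 1L,
                            spec = grade_spec(),
                            enhancement = enhancement_config(),
                            watershed = watershed_config(),
                            classifier = desk_config(input_size = image_size),
                            train = train_config(epochs = 5L, seed = seed),
                            augment = FALSE, n_seg_train = 10L,
                            unet_steps = 60L, unet_depth = 3L,
                            unet_base = 8L, dry_run = FALSE) {
  stopifnot(length(counts) == 5, all(counts >= 0))
  structure(list(out_dir = out_dir, counts = as.integer(counts),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 spec = spec, enhancement = enhancement,
                 watershed = watershed, classifier = classifier,
                 train = train, augment = isTRUE(augment),
                 n_seg_train = as.integer(n_seg_train),
                 unet_steps = as.integer(unet_steps),
                 unet_depth = as.integer(unet_depth),
                 unet_base = as.integer(unet_base),
                 dry_run = isTRUE(dry_run)),
            class = "pipeline_config")
}

#' Generate (and optionally augment) a synthetic dataset
#'
#' Front door to the phantom generator: writes the dataset and returns its
#' manifest.
#'
#' @param counts Per-grade phantom counts (default: the study's
#'   400/200/200/200/400 distribution).
#' @param spec A [grade_spec()].
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param size Optional square canvas side; default keeps the standard
#'   700 x 600 raster.
#' @param augment Also emit one augmented copy per record?
#' @return Manifest tibble.
#' @export
simulate <- function(counts = c(400L, 200L, 200L, 200L, 400L),
                     spec = grade_spec(), seed = 1L, out_dir, size = NULL,
                     augment = FALSE) {
  h <- if (is.null(size)) 600L else as.integer(size)
  w <- if (is.null(size)) 700L else as.integer(size)
  manifest <- generate_dataset(counts, spec, seed, out_dir,
                               height = h, width = w)
  if (augment) manifest <- augment_dataset(manifest, seed = seed + 1L)
  manifest
}

stage_log <- function(stage, t0, detail = "") {
  message(sprintf("[fundushr] %-16s %6.1fs %s", stage,
                  as.numeric(Sys.time()) - t0, detail))
}

#' Run the full grading pipeline
#'
#' Orchestrates every stage on a synthetic dataset: generate (and optionally
#' augment) phantoms; train the semantic pixel classifier and the mask
#' network on a held-aside subset; enhance; segment instances; train the
#' grading classifier; evaluate on the validation split. All artifacts
#' (manifest, curves, predictions, metric report, frozen config) are written
#' under `cfg$out_dir`; re-running with the same config and seed reproduces
#' them.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list: `manifest`, `classifier` (an `hr_classifier`),
#'   `segmenter`, `unet`, `predictions` tibble, `report` tibble.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$dry_run) {
    message("[fundushr] dry run: configuration valid, nothing written")
    return(invisible(NULL))
  }
  t0 <- as.numeric(Sys.time())
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(cfg$out_dir, "data")

  manifest <- simulate(cfg$counts, cfg$spec, cfg$seed, data_dir,
                       size = cfg$image_size, augment = cfg$augment)
  stage_log("simulate", t0, sprintf("%d records -> %s", nrow(manifest), data_dir))

  # segmentation training set: fresh phantoms, never part of the manifest
  seg <- lapply(seq_len(cfg$n_seg_train), function(i)
    generate_phantom((i - 1L) %% 5L, cfg$spec, seed = cfg$seed + 10000L + i,
                     height = cfg$image_size, width = cfg$image_size))
  seg_imgs <- lapply(seg, `[[`, "image")
  seg_masks <- lapply(seg, `[[`, "mask")
  segmenter <- train_pixel_segmenter(seg_imgs, seg_masks, seed = cfg$seed,
                                     num_trees = 50L, cnn_steps = 20L)
  stage_log("semantic", t0, sprintf("%d training phantoms", length(seg)))

  lesion <- mask_labels()[c("bright_lesion", "dark_lesion")]
  unet <- build_unet(input_size = cfg$image_size, depth = cfg$unet_depth,
                     base_channels = cfg$unet_base, seed = cfg$seed)
  unet <- train_unet(unet, seg_imgs,
                     lapply(seg_masks, function(m)
                       matrix(as.numeric(m %in% lesion), nrow(m), ncol(m))),
                     steps = cfg$unet_steps, seed = cfg$seed)
  stage_log("instance", t0, sprintf("%d mask-net steps", cfg$unet_steps))

  model <- train_classifier(build_densenet(cfg$classifier, seed = cfg$seed),
                            manifest, cfg$train)
  stage_log("classify", t0,
            sprintf("best val acc %.3f", model$best_val_acc))

  val <- manifest[model$val_indices, , drop = FALSE]
  preds <- vector("list", nrow(val))
  for (i in seq_len(nrow(val))) {
    img <- read_image(val$image[i])
    p <- predict_grade(model, img)
    preds[[i]] <- dplyr::bind_cols(
      tibble::tibble(image = val$image[i], true = val$grade[i],
                     predicted = p$grade),
      tibble::as_tibble(as.list(stats::setNames(p$probabilities,
                                                paste0("p", 0:4)))))
  }
  predictions <- dplyr::bind_rows(preds)
  scores <- as.matrix(predictions[, paste0("p", 0:4)])
  report <- metric_report(predictions$true, predictions$predicted, scores)
  stage_log("evaluate", t0,
            sprintf("macro ACC %.3f",
                    report$ACC[report$class == "macro"]))

  utils::write.csv(model$curves, file.path(cfg$out_dir, "curves.csv"),
                   row.names = FALSE)
  utils::write.csv(predictions, file.path(cfg$out_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(report, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(cfg$out_dir, "metrics.json"),
                       dataframe = "rows", digits = NA)
  frozen <- cfg
  frozen$package_version <- as.character(utils::packageVersion("fundushr"))
  yaml::write_yaml(serialize_config(frozen), file.path(cfg$out_dir, "config.yaml"))
  invisible(list(manifest = manifest, classifier = model,
                 segmenter = segmenter, unet = unet,
                 predictions = predictions, report = report))
}

serialize_config <- function(cfg) {
  rapply(unclass(cfg), function(x) {
    if (inherits(x, "fundushr_vc")) unclass(x) else x
  }, how = "replace", classes = "ANY")
}
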