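# One-command end-to-end demonstration on synthetic data: cohort generation,
# gland and lesion segmenter training, two-step inference, fusion-model
# training, and the comparison statistics -- all at configurable desk scale.

#' Run the full pipeline end-to-end on synthetic phantoms
#'
#' Generates a two-center cohort, trains the gland and lesion segmenters,
#' runs two-step cascade inference on a held-out split, trains the
#' multi-modal and image-only pCR classifiers on ground-truth lesion crops,
#' and assembles the evaluation report (per-case segmentation metrics,
#' classifier accuracy/AUC, McNemar and goodness-of-fit tables computed
#' from the demo's own predictions).
#'
#' The defaults are deliberately small so the demo runs on one CPU in a few
#' minutes; they are not the reference training protocol (see
#' [train_schedule()] for that).
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param out_dir Working directory for phantom files.
#' @param n_seg_train,n_seg_test Phantoms for segmenter training/testing.
#' @param n_fus_train,n_fus_test Patients for classifier training/testing.
#' @param seg_epochs,fusion_epochs Training epochs per stage.
#' @param patch_size,seg_depth,seg_base Segmenter patch size and topology.
#' @param cube Fusion-model crop size.
#' @param use_histogram_matching Augment the lesion-segmenter training set
#'   by matching against the other center's histograms.
#' @param verbose Print stage progress.
#' @return A list of class `cascadeseg_demo` with elements `seg_metrics`,
#'   `heart_overlap`, `classifier_metrics`, `mcnemar`, `gof`, `paired_table`,
#'   and `models`.
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("csdemo_"),
                     n_seg_train = 8L, n_seg_test = 4L,
                     n_fus_train = 60L, n_fus_test = 30L,
                     seg_epochs = 12L, fusion_epochs = 15L,
                     patch_size = 16L, seg_depth = 3L, seg_base = 8L,
                     cube = 16L, use_histogram_matching = TRUE,
                     verbose = FALSE) {
  seeds <- split_seed(seed, 6)
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating %d + %d segmentation phantoms", n_seg_train, n_seg_test)
  spec <- phantom_spec()
  seg_seeds <- split_seed(seeds[1], n_seg_train + n_seg_test)
  make_sample <- function(s, center) {
    ph <- generate_phantom(spec, s, center = center)
    ph$z <- zscore_normalize(ph$volume)
    ph
  }
  train_ph <- lapply(seq_len(n_seg_train), function(i) make_sample(seg_seeds[i], 1L))
  test_ph <- lapply(seq_len(n_seg_test),
                    function(i) make_sample(seg_seeds[n_seg_train + i], 2L))

  say("training gland segmenter")
  sched <- train_schedule(max_epochs = seg_epochs)
  cfg <- segnet_config(depth = seg_depth, base_channels = seg_base,
                       patch_size = patch_size)
  gland_ds <- lapply(train_ph, function(p) list(img = p$z$data, lab = p$gland_mask$data))
  gland_model <- train_segmenter(build_segnet(cfg, seeds[2]), gland_ds, sched,
                                 seed = seeds[2], verbose = verbose)

  say("training lesion segmenter on gland crops%s",
      if (use_histogram_matching) " (histogram-matched augmentation)" else "")
  test_hists <- lapply(test_ph, function(p) compute_histogram(p$volume))
  lesion_ds <- list()
  hm_seeds <- split_seed(seeds[3], length(train_ph))
  for (i in seq_along(train_ph)) {
    p <- train_ph[[i]]
    crop <- crop_to_mask(p$volume, p$gland_mask, margin_mm = 5)
    lab <- crop_to_mask_label(p$lesion_mask, p$gland_mask, margin_mm = 5)
    lesion_ds[[length(lesion_ds) + 1L]] <-
      list(img = zscore_normalize(crop$volume)$data, lab = lab)
    if (use_histogram_matching) {
      ref <- test_hists[[1L + (hm_seeds[i] %% length(test_hists))]]
      matched <- match_histogram(crop$volume, ref)
      lesion_ds[[length(lesion_ds) + 1L]] <-
        list(img = zscore_normalize(matched)$data, lab = lab)
    }
  }
  lesion_model <- train_segmenter(build_segnet(cfg, seeds[3]), lesion_ds, sched,
                                  seed = seeds[3], verbose = verbose)

  say("two-step inference on %d held-out phantoms", n_seg_test)
  preds <- lapply(test_ph, function(p) {
    run_two_step(p$volume, gland_model, lesion_model)
  })
  seg_metrics <- evaluate_masks(preds, lapply(test_ph, `[[`, "lesion_mask"))
  heart_overlap <- vapply(seq_along(test_ph), function(i) {
    sum(preds[[i]]$data > 0 & test_ph[[i]]$heart_mask$data > 0)
  }, numeric(1))

  say("generating %d + %d patients for pCR prediction", n_fus_train, n_fus_test)
  fus_dir <- file.path(out_dir, "fusion")
  train_cohort <- generate_cohort(n_fus_train, spec, seed = seeds[4],
                                  out_dir = file.path(fus_dir, "train"))
  test_cohort <- generate_cohort(n_fus_test, spec, seed = seeds[5],
                                 out_dir = file.path(fus_dir, "test"))
  tr <- prepare_fusion_inputs(train_cohort, cube)
  te <- prepare_fusion_inputs(test_cohort, cube)

  say("training multi-modal and image-only classifiers")
  fcfg <- fusion_config(input_cube = cube)
  mm <- train_fusion(build_fusion_net(fcfg, seeds[6]), tr$crops, tr$markers,
                     tr$labels, epochs = fusion_epochs, seed = seeds[6])
  io <- train_fusion(build_fusion_net(fcfg, seeds[6]), tr$crops, tr$markers,
                     tr$labels, epochs = fusion_epochs, seed = seeds[6],
                     image_only = TRUE)
  pred_mm <- predict_pcr_cohort(mm, te)
  pred_io <- predict_pcr_cohort(io, te, image_only = TRUE)

  classifier_metrics <- tibble::tibble(
    model = c("multi_modal", "image_only"),
    accuracy = c(accuracy(te$labels, pred_mm$predicted_label),
                 accuracy(te$labels, pred_io$predicted_label)),
    auc = c(auc(te$labels, pred_mm$p_pcr), auc(te$labels, pred_io$p_pcr))
  )
  tab <- pair_predictions(pred_io$predicted_label, pred_mm$predicted_label)
  mc <- tryCatch(mcnemar_chi2(tab), error = function(e) {
    # fully concordant classifiers: the statistic is undefined
    tibble::tibble(chi2 = NA_real_, p = NA_real_, b = tab$b, c = tab$c,
                   corrected = FALSE)
  })
  truth_counts <- c(sum(te$labels == 1), sum(te$labels == 0))
  safe_gof <- function(pred, name) {
    tryCatch(
      dplyr::mutate(chisq_gof(c(sum(pred == 1), sum(pred == 0)), truth_counts),
                    method = name, .before = 1),
      error = function(e) tibble::tibble(method = name, chi2 = NA_real_,
                                         df = 1L, p = NA_real_))
  }
  gof <- dplyr::bind_rows(safe_gof(pred_io$predicted_label, "image_only"),
                          safe_gof(pred_mm$predicted_label, "multi_modal"))

  structure(list(seg_metrics = seg_metrics, heart_overlap = heart_overlap,
                 classifier_metrics = classifier_metrics,
                 mcnemar = mc, gof = gof, paired_table = tab,
                 models = list(gland = gland_model, lesion = lesion_model,
                               multi_modal = mm, image_only = io),
                 seed = seed),
            class = "cascadeseg_demo")
}

# crop a mask with the bounding box of another mask (same margin logic as
# crop_to_mask, returning the bare label array)
crop_to_mask_label <- function(mask, box_mask, margin_mm = 0) {
  cr <- crop_to_mask(mask, box_mask, margin_mm)
  m <- cr$volume$data
  storage.mode(m) <- "integer"
  m
}

#' @export
print.cascadeseg_demo <- function(x, ...) {
  cat("cascadeseg end-to-end demo (seed", x$seed, ")\n\n")
  cat("Held-out lesion segmentation:\n")
  cat(sprintf("  mean Dice %.3f, mean IoU %.3f; heart-overlap voxels: %s\n",
              mean(x$seg_metrics$dice), mean(x$seg_metrics$iou),
              paste(x$heart_overlap, collapse = ", ")))
  cat("\npCR classification:\n")
  print(x$classifier_metrics)
  cat("\nMcNemar (image-only vs multi-modal):\n")
  print(x$mcnemar)
  cat("\nGoodness-of-fit vs ground truth:\n")
  print(x$gof)
  invisible(x)
}
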