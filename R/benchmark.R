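#' Scaled-down end-to-end tracking benchmark
#'
#' Reproduces the full experiment at desk scale: generate a seeded
#' 30/10/10 synthetic split at half resolution (360 x 270 px, 0.65 mm/px
#' -- the same anatomy at half the pixel budget), train the Siamese
#' tracker at reduced scale (default 500 pairs/epoch for 10 epochs), then
#' run one-pass evaluation on the 10 held-out test sequences and aggregate
#' the kinematic metrics.
#'
#' @param work_dir working directory for the dataset and outputs (several
#'   hundred MB of PNG frames at the default sequence lengths).
#' @param seed integer master seed for generation, training and tracking.
#' @param pairs_per_epoch,epochs training scale.
#' @param n_frames_range optional sequence-length override (used to scale
#'   the in-suite test down; `NULL` keeps the full 330-430 frame draw).
#' @param n_train,n_val,n_test split sizes.
#' @param verbose print progress.
#' @return list with `aggregate`, `reports`, `fit` (training result) and
#'   `manifest`.
#' @export
run_benchmark <- function(work_dir, seed = 1L, pairs_per_epoch = 500L,
                          epochs = 10L, n_frames_range = NULL,
                          n_train = 30L, n_val = 10L, n_test = 10L,
                          verbose = FALSE) {
  scene <- scene_params(frame_width = 360L, frame_height = 270L,
                        mm_per_px = 0.65)
  ds_dir <- file.path(work_dir, "dataset")
  if (verbose) message("generating ", n_train + n_val + n_test,
                       " synthetic sequences ...")
  manifest <- write_dataset(ds_dir, n_train, n_val, n_test, seed = seed,
                            scene = scene, n_frames_range = n_frames_range)
  cfg <- train_config(pairs_per_epoch = pairs_per_epoch, epochs = epochs,
                      eval_checkpoint_epoch = epochs,
                      val_pairs = 50L, seed = seed)
  if (verbose) message("training: ", pairs_per_epoch, " pairs/epoch x ",
                       epochs, " epochs ...")
  fit <- siamfc_train(pair_dataset_from_manifest(manifest, "train"),
                      pair_dataset_from_manifest(manifest, "val"),
                      cfg, verbose = verbose)
  run <- run_experiment(manifest,
                        run_config(tracker = "siamfc", weights = fit,
                                   seed = seed,
                                   out_dir = file.path(work_dir, "eval")),
                        verbose = verbose)
  list(aggregate = run$aggregate, reports = run$reports, fit = fit,
       manifest = manifest)
}

#' Summary scalars of a benchmark run
#'
#' @param bench result of [run_benchmark()].
#' @return named list: mean precision@10px (percent), mean per-sequence
#'   RMSE and AE (pixels).
#' @export
benchmark_headline <- function(bench) {
  s <- bench$aggregate$summary
  g <- function(m) s$mean[s$metric == m]
  list(precision_at_10_pct = 100 * g("precision_at_10"),
       rmse_px = g("rmse"), ae_px = g("ae"))
}
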