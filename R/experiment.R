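#' Run configuration for an end-to-end experiment
#'
#' @param tracker `"siamfc"` or `"dcf"`.
#' @param weights for `"siamfc"`: path to a checkpoint from
#'   [save_weights()] or an in-memory fit / backbone.
#' @param init_box_side initialisation box side in pixels (default 30).
#' @param thresholds precision-curve thresholds (pixels).
#' @param seed integer seed.
#' @param out_dir optional output directory for traces, reports and plots.
#' @return object of class `run_config`.
#' @export
run_config <- function(tracker = c("siamfc", "dcf"), weights = NULL,
                       init_box_side = 30, thresholds = 1:50,
                       seed = 1L, out_dir = NULL) {
  tracker <- match.arg(tracker)
  if (init_box_side <= 0) stop("init_box_side must be positive")
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  structure(list(tracker = tracker, weights = weights,
                 init_box_side = init_box_side, thresholds = thresholds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

resolve_backbone <- function(weights) {
  if (is.null(weights))
    stop("the siamfc tracker needs trained weights: pass a checkpoint ",
         "path from save_weights() or a fit from siamfc_train()")
  if (is.character(weights)) weights <- load_weights(weights)
  if (inherits(weights, "siamfc_backbone")) return(weights)
  if (!is.null(weights$backbone)) return(weights$backbone)
  stop("could not find a backbone in the supplied weights object")
}

#' Run the tracking experiment on the test split
#'
#' For every test sequence the initialisation box is built from the
#' frame-0 ground-truth point only (annotations of later frames are never
#' given to the tracker); the sequence is tracked in one pass, evaluated
#' with the full kinematic suite, and the per-sequence reports are
#' aggregated. When `config$out_dir` is set, traces (CSV), per-sequence
#' reports and the aggregate summary (JSON) are written there.
#'
#' @param manifest dataset manifest (path, directory or list) with a test
#'   split.
#' @param config a [run_config()].
#' @param split which split to evaluate (default `"test"`).
#' @param spec a [patch_spec()] (siamfc only).
#' @param dcf a [dcf_config()] (dcf only).
#' @param verbose print per-sequence progress.
#' @return list with `reports` (per sequence), `aggregate`, `traces`.
#' @export
run_experiment <- function(manifest, config, split = "test",
                           spec = patch_spec(), dcf = dcf_config(),
                           verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  recs <- manifest_split(manifest, split)
  if (!length(recs)) stop("manifest has no '", split, "' sequences")
  calib <- unit_calibration(
    mm_per_px = manifest$calibration$mm_per_px,
    px_per_mm = 1 / manifest$calibration$mm_per_px)
  backbone <- if (config$tracker == "siamfc")
    resolve_backbone(config$weights) else NULL
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  reports <- list(); traces <- list()
  for (r in recs) {
    sq <- load_sequence(r$dir, lazy = TRUE)
    init <- list(center = sq$gt[1, ],
                 size = rep(config$init_box_side, 2))
    t0 <- Sys.time()
    trace <- if (config$tracker == "siamfc")
      track_sequence(sq$frames, init, backbone, spec)
    else
      dcf_track_sequence(sq$frames, init, dcf, seed = config$seed)
    rep_i <- evaluate_trace(trace, sq$gt, sq$events, calib,
                            config$thresholds)
    reports[[r$id]] <- rep_i
    traces[[r$id]] <- trace
    if (verbose)
      message(sprintf("[%s] %s: %d frames in %.1f s, p@10 %.3f rmse %.2f",
                      config$tracker, r$id, sq$n_frames,
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      rep_i$precision_at_10, rep_i$rmse))
    if (!is.null(out)) {
      write_trace(trace, file.path(out, paste0(r$id, "_trace.csv")))
      jsonlite::write_json(
        unclass(rep_i)[setdiff(names(rep_i), "ce_series")],
        file.path(out, paste0(r$id, "_report.json")),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
    }
  }
  agg <- aggregate_reports(reports)
  if (!is.null(out)) {
    jsonlite::write_json(list(tracker = config$tracker,
                              n_sequences = agg$n_sequences,
                              summary = agg$summary,
                              curve = agg$curve),
                         file.path(out, "aggregate.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    utils::write.csv(agg$curve, file.path(out, "precision_curve.csv"),
                     row.names = FALSE)
  }
  list(reports = reports, aggregate = agg, traces = traces)
}
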