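#' Write one sequence as a PNG image-sequence directory
#'
#' Layout: `frames/frame_%06d.png` (8-bit grayscale), `annotations.csv`
#' with header `frame,x,y` (0-based frame indices, pixel coordinates), and
#' `events.json` with the 0-based `hyoid_onset`, `hyoid_offset` and
#' `swallow_end` frame indices.
#'
#' @param seq a `usv_sequence` from [generate_sequence()].
#' @param dir output directory for this sequence.
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir) {
  stopifnot(inherits(seq, "usv_sequence"))
  fdir <- file.path(dir, "frames")
  dir.create(fdir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(seq$frames)) {
    path <- file.path(fdir, sprintf("frame_%06d.png", i - 1L))
    ok <- tryCatch({
      png::writePNG(seq$frames[[i]] / 255, path)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("failed to write ", path, ": ", conditionMessage(ok))
  }
  ann <- data.frame(frame = seq_along(seq$frames) - 1L,
                    x = seq$gt[, 1], y = seq$gt[, 2])
  utils::write.csv(ann, file.path(dir, "annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(seq$events, file.path(dir, "events.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one grayscale frame from a PNG file
#'
#' @param path PNG file path.
#' @return integer matrix with values 0-255 (RGB input is averaged).
#' @export
read_frame_png <- function(path) {
  if (!file.exists(path)) stop("frame not found: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- apply(m[, , 1:3, drop = FALSE], c(1, 2), mean)
  m <- round(m * 255)
  storage.mode(m) <- "integer"
  m
}

read_events_json <- function(path) {
  ev <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("malformed events JSON ", path,
                                          ": ", conditionMessage(e)))
  need <- c("hyoid_onset", "hyoid_offset", "swallow_end")
  if (!all(need %in% names(ev)))
    stop("events JSON ", path, " must contain ",
         paste(need, collapse = ", "))
  lapply(ev[need], as.integer)
}

read_annotations_csv <- function(path) {
  ann <- tryCatch(utils::read.csv(path),
                  error = function(e) stop("malformed annotation CSV ", path,
                                           ": ", conditionMessage(e)))
  if (!all(c("frame", "x", "y") %in% names(ann)))
    stop("annotation CSV ", path, " must have header frame,x,y")
  bad <- which(!is.finite(ann$x) | !is.finite(ann$y))
  if (length(bad))
    stop("annotation CSV ", path, ": non-finite coordinates at line ",
         bad[1] + 1L)
  if (!identical(as.integer(ann$frame), seq_len(nrow(ann)) - 1L))
    stop("annotation CSV ", path,
         ": frame indices must be dense from 0; first problem at line ",
         which(as.integer(ann$frame) != seq_len(nrow(ann)) - 1L)[1] + 1L)
  ann
}

#' Load a sequence from disk
#'
#' Reads a PNG image-sequence directory with its annotation CSV and event
#' JSON (the layout written by [write_sequence()] / [write_dataset()]).
#' With `lazy = TRUE` (default) frames are not held in memory: `frames` is
#' an accessor `function(i)` returning frame `i` (1-based) as an integer
#' matrix, with attribute `n_frames`.
#'
#' @param dir sequence directory.
#' @param lazy load frames on demand rather than into memory.
#' @return list with `frames`, `n_frames`, `gt` (n x 2 matrix), `events`,
#'   `frame_paths`.
#' @export
load_sequence <- function(dir, lazy = TRUE) {
  fdir <- file.path(dir, "frames")
  if (!dir.exists(fdir)) stop("no frames directory under ", dir)
  paths <- sort(list.files(fdir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(paths)) stop("no frames found under ", fdir)
  ann <- read_annotations_csv(file.path(dir, "annotations.csv"))
  if (nrow(ann) > length(paths))
    stop("annotation CSV has ", nrow(ann), " rows but only ", length(paths),
         " frames exist under ", fdir)
  if (nrow(ann) < length(paths))
    stop("missing annotation rows: ", length(paths), " frames but ",
         nrow(ann), " annotations in ", dir)
  events <- read_events_json(file.path(dir, "events.json"))
  dim0 <- dim(read_frame_png(paths[1]))
  getter <- function(i) {
    m <- read_frame_png(paths[i])
    if (!identical(dim(m), dim0))
      stop("frame dimension mismatch in ", paths[i], ": expected ",
           paste(dim0, collapse = "x"))
    m
  }
  frames <- if (lazy) getter else lapply(seq_along(paths), getter)
  if (lazy) attr(frames, "n_frames") <- length(paths)
  list(frames = frames, n_frames = length(paths),
       gt = cbind(x = ann$x, y = ann$y), events = events,
       frame_paths = paths)
}

#' Read a dataset manifest
#'
#' @param path path to a `manifest.json` written by [write_dataset()], or
#'   the dataset directory containing it.
#' @return the manifest list, with `root` set to the manifest's directory.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  man$root <- dirname(normalizePath(path))
  splits <- vapply(man$sequences, function(s) s$split, "")
  if (anyDuplicated(vapply(man$sequences, function(s) s$id, "")))
    stop("manifest has duplicated sequence ids")
  stopifnot(all(splits %in% c("train", "val", "test")))
  man
}

#' Select the sequence records of one split
#'
#' @param manifest a manifest from [read_manifest()] or [write_dataset()].
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return list of sequence records with absolute `dir` paths.
#' @export
manifest_split <- function(manifest, split) {
  split <- match.arg(split, c("train", "val", "test"))
  recs <- Filter(function(s) s$split == split, manifest$sequences)
  lapply(recs, function(s) {
    s$dir <- file.path(manifest$root, s$dir)
    s
  })
}

#' Write / read a tracking trace
#'
#' Traces are CSV files with header `frame,x,y`: one predicted hyoid centre
#' per frame, 0-based frame indices, pixel coordinates.
#'
#' @param trace data frame with columns `frame`, `x`, `y`.
#' @param path CSV file path.
#' @return `write_trace`: `path` invisibly; `read_trace`: the data frame.
#' @export
write_trace <- function(trace, path) {
  stopifnot(all(c("frame", "x", "y") %in% names(trace)))
  utils::write.csv(trace[, c("frame", "x", "y")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path)
  if (!all(c("frame", "x", "y") %in% names(tr)))
    stop("trace CSV ", path, " must have header frame,x,y")
  tr
}

#' Build a training-pair dataset view
#'
#' The trainer consumes datasets as lists of per-sequence records, each
#' with `n_frames`, `gt` (n x 2 matrix) and `get_frame(i)` returning
#' frame `i` (1-based) as an integer matrix. `pair_dataset_from_manifest`
#' builds such a view over one split of an on-disk dataset with lazy
#' frame loading; `pair_dataset_from_sequences` wraps in-memory
#' `usv_sequence` objects.
#'
#' @param manifest a manifest from [read_manifest()] / [write_dataset()].
#' @param split `"train"`, `"val"` or `"test"`.
#' @return list of sequence records.
#' @export
pair_dataset_from_manifest <- function(manifest, split = "train") {
  recs <- manifest_split(manifest, split)
  if (!length(recs)) stop("manifest has no '", split, "' split")
  lapply(recs, function(r) {
    sq <- load_sequence(r$dir, lazy = TRUE)
    list(id = r$id, n_frames = sq$n_frames, gt = sq$gt,
         get_frame = sq$frames)
  })
}

#' @rdname pair_dataset_from_manifest
#' @param seqs list of `usv_sequence` objects.
#' @export
pair_dataset_from_sequences <- function(seqs) {
  lapply(seq_along(seqs), function(k) {
    sq <- seqs[[k]]
    list(id = sprintf("seq_%03d", k), n_frames = length(sq$frames),
         gt = sq$gt, get_frame = function(i) sq$frames[[i]])
  })
}
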