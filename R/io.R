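# Plain-text serialization: region x time CSV tables (regions as rows,
# first column = region label, remaining columns = samples), 6-column
# motion tables, edge-series CSV with the edge-order table, and JSON
# configs.

#' Write a region-by-time signal set to CSV
#'
#' @param signals A [region_signal_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_csv <- function(signals, path) {
  stopifnot(inherits(signals, "region_signal_set"))
  df <- data.frame(region = signals$region_labels, signals$values,
                   check.names = FALSE)
  colnames(df) <- c("region", sprintf("t%06d", seq_len(ncol(signals$values))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a region-by-time signal set from CSV
#'
#' @param path CSV file written by [write_region_csv()] (or any table with a
#'   `region` label column followed by sample columns).
#' @param fs Sampling rate in Hz.
#' @param modality `"fast"` or `"slow"`.
#' @return A [region_signal_set()].
#' @export
read_region_csv <- function(path, fs, modality = c("fast", "slow")) {
  modality <- match.arg(modality)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"region" %in% colnames(df)) {
    stop(sprintf("%s: expected a 'region' column", path), call. = FALSE)
  }
  values <- as.matrix(df[, setdiff(colnames(df), "region"), drop = FALSE])
  storage.mode(values) <- "double"
  region_signal_set(values, fs = fs, modality = modality,
                    region_labels = as.character(df$region))
}

#' Read a 6-column motion-parameter table
#'
#' Whitespace- or comma-separated text with exactly six columns: three
#' translations (mm) then three rotations (radians); an optional header is
#' detected.
#'
#' @param path File path.
#' @return Numeric matrix with 6 columns.
#' @export
read_motion_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- grepl("[A-Za-z]", first)
  m <- as.matrix(utils::read.table(path, sep = sep, header = header))
  if (ncol(m) != 6L) {
    stop(sprintf("%s: motion table must have 6 columns, found %d", path, ncol(m)),
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Write an edge-frame series (frames plus edge-order table) to CSV
#'
#' Two files are produced: `<path>` holding the frames (one row per frame,
#' columns `frame_index` then one column per edge) and `<path>` with
#' extension replaced by `_edges.csv` holding the (i, j) edge-order table.
#'
#' @param frames An [edge_frame_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_series_csv <- function(frames, path) {
  stopifnot(inherits(frames, "edge_frame_series"))
  ei <- edge_index(frames$n_regions)
  df <- data.frame(frame_index = frames$frame_index, frames$frames)
  colnames(df) <- c("frame_index", sprintf("e%d_%d", ei$i, ei$j))
  utils::write.csv(df, path, row.names = FALSE)
  edge_path <- sub("\\.csv$", "_edges.csv", path)
  utils::write.csv(ei, edge_path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated subject to a directory of plain-text files
#'
#' Writes `fast.csv`, `slow.csv`, `ground_truth.json` and `config.json`.
#'
#' @param sim Output of [simulate_bimodal()].
#' @param config The [scenario_config()] used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(sim, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_region_csv(sim$fast, file.path(dir, "fast.csv"))
  write_region_csv(sim$slow, file.path(dir, "slow.csv"))
  gt <- sim$ground_truth
  gt$state_library <- lapply(gt$state_library, function(m) unname(as.data.frame(m)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- config
  cfg$bands <- lapply(cfg$bands, unclass)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load one subject's signal bundle from disk
#'
#' @param fast_path CSV of fast-modality signals ([write_region_csv()] layout).
#' @param slow_path CSV of slow-modality signals.
#' @param fs_fast Fast-modality sampling rate in Hz.
#' @param tr Repetition time of the slow modality in seconds.
#' @param motion_path Optional 6-column motion table.
#' @param artifact_path Optional one-column 0/1 artifact mask (one row per TR).
#' @return List with `fast`, `slow`, `motion` (or NULL), `artifact_mask`
#'   (or NULL).
#' @export
load_subject <- function(fast_path, slow_path, fs_fast, tr,
                         motion_path = NULL, artifact_path = NULL) {
  fast <- read_region_csv(fast_path, fs = fs_fast, modality = "fast")
  slow <- read_region_csv(slow_path, fs = 1 / tr, modality = "slow")
  if (!identical(fast$region_labels, slow$region_labels)) {
    stop("region labels of the two modalities do not match", call. = FALSE)
  }
  motion <- if (!is.null(motion_path)) read_motion_table(motion_path)
  artifact <- if (!is.null(artifact_path)) {
    v <- utils::read.csv(artifact_path)[[1]]
    as.logical(v)
  }
  if (!is.null(motion) && nrow(motion) != ncol(slow$values)) {
    stop("motion table length does not match the number of TR frames", call. = FALSE)
  }
  list(fast = fast, slow = slow, motion = motion, artifact_mask = artifact)
}
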