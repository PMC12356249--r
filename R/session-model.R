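#' @importFrom stats aov approx convolve dist kmeans median p.adjust pnorm
#'   quantile rbinom rlnorm rnorm rpois runif sd setNames t.test var wilcox.test
#' @importFrom utils head tail
NULL

#' Ordered imaging-day labels
#'
#' The experiment spans six acclimation days followed by ten training days,
#' either sensory association training (`SAT`) or pseudotraining (`PSE`).
#' Day ordering is total and shared by every module: ACC1 < ... < ACC6 <
#' SAT1 < ... < SAT10 (or PSE1 < ... < PSE10).
#'
#' @param training `"SAT"` or `"PSE"`.
#' @return Character vector of the 16 day labels in chronological order.
#' @export
day_levels <- function(training = c("SAT", "PSE")) {
  training <- match.arg(training)
  c(paste0("ACC", 1:6), paste0(training, 1:10))
}

#' Order imaging-day labels chronologically
#'
#' @param days character vector of day labels (ACC/SAT/PSE).
#' @return `days` as an ordered factor.
#' @export
day_factor <- function(days) {
  training <- if (any(grepl("^PSE", days))) "PSE" else "SAT"
  lev <- day_levels(training)
  bad <- setdiff(unique(days), lev)
  if (length(bad) > 0L)
    stop("unknown day labels: ", paste(bad, collapse = ", "))
  factor(days, levels = lev, ordered = TRUE)
}

#' Convert a duration in seconds to a frame count
#'
#' Durations are specified in seconds throughout; at the native 5.11 Hz frame
#' rate they are non-integer numbers of frames, so conversion takes the floor.
#'
#' @param t_s duration in seconds.
#' @param frame_rate_hz acquisition rate (Hz).
#' @return Integer number of frames.
#' @export
sec_to_frames <- function(t_s, frame_rate_hz) {
  as.integer(floor(t_s * frame_rate_hz))
}

#' Construct an imaging session
#'
#' One session is one imaging day for one field of view: raw ROI and neuropil
#' fluorescence (arbitrary units), per-frame rigid motion shifts, and the
#' trial schedule. Frame indices are 0-based; a trial onset is the first frame
#' at/after the stimulus onset time.
#'
#' @param animal_id,fov_id identifiers.
#' @param day_label one of [day_levels()].
#' @param roi_traces numeric matrix, cells x frames, raw ROI fluorescence.
#' @param neuropil_traces numeric matrix, same shape, surrounding-tissue
#'   fluorescence.
#' @param frame_shifts integer matrix, frames x 2 (`dx`, `dy`), pixel
#'   displacements from motion registration.
#' @param trial_onsets data.frame with columns `onset_frame` (0-based integer)
#'   and `trial_type` (`"stimulus"` or `"blank"`), strictly increasing onsets.
#' @param frame_rate_hz acquisition rate, default 5.11 Hz.
#' @param cell_ids character identifiers, stable across days.
#' @param red_intensity optional per-cell mean red-channel (mCherry) pixel
#'   intensity, arbitrary units.
#' @return A `sst_session` object.
#' @export
session <- function(animal_id, fov_id, day_label, roi_traces, neuropil_traces,
                    frame_shifts, trial_onsets, frame_rate_hz = 5.11,
                    cell_ids = NULL, red_intensity = NULL) {
  roi_traces <- as.matrix(roi_traces)
  neuropil_traces <- as.matrix(neuropil_traces)
  if (!identical(dim(roi_traces), dim(neuropil_traces)))
    stop("roi_traces and neuropil_traces must share shape")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be positive")
  n_frames <- ncol(roi_traces)
  frame_shifts <- as.matrix(frame_shifts)
  if (nrow(frame_shifts) != n_frames || ncol(frame_shifts) != 2L)
    stop("frame_shifts must be n_frames x 2")
  trial_onsets <- as.data.frame(trial_onsets)
  if (nrow(trial_onsets) > 0L) {
    stopifnot(all(c("onset_frame", "trial_type") %in% names(trial_onsets)))
    of <- trial_onsets$onset_frame
    if (any(diff(of) <= 0)) stop("trial onsets must be strictly increasing")
    if (any(of < 0L) || any(of >= n_frames))
      stop("trial onset frames out of range")
    if (!all(trial_onsets$trial_type %in% c("stimulus", "blank")))
      stop("trial_type must be 'stimulus' or 'blank'")
  }
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(roi_traces)))
  if (length(cell_ids) != nrow(roi_traces))
    stop("cell_ids length must match number of cells")
  if (!is.null(red_intensity)) {
    if (length(red_intensity) != nrow(roi_traces))
      stop("red_intensity length must match number of cells")
    if (any(red_intensity < 0, na.rm = TRUE))
      stop("red_intensity must be nonnegative")
  }
  structure(list(
    animal_id = as.character(animal_id), fov_id = as.character(fov_id),
    day_label = as.character(day_label), frame_rate_hz = frame_rate_hz,
    roi_traces = roi_traces, neuropil_traces = neuropil_traces,
    frame_shifts = frame_shifts, trial_onsets = trial_onsets,
    cell_ids = as.character(cell_ids), red_intensity = red_intensity
  ), class = "sst_session")
}

#' @export
print.sst_session <- function(x, ...) {
  cat(sprintf("<sst_session> %s / %s / %s: %d cells x %d frames, %d trials @ %.2f Hz\n",
              x$animal_id, x$fov_id, x$day_label, nrow(x$roi_traces),
              ncol(x$roi_traces), nrow(x$trial_onsets), x$frame_rate_hz))
  invisible(x)
}

#' Build a cell registry across sessions
#'
#' Cells must be trackable across every imaging day to enter cross-day
#' analyses; cells missing any day present in the experiment are flagged and
#' excluded (with a warning).
#'
#' @param sessions list of [session()] objects.
#' @param true_labels optional named character vector (`cell_id` ->
#'   `"SST-Calb2"`, `"SST-O"` or `"unknown"`).
#' @return data.frame with columns `cell_id`, `true_label`, `tracked`
#'   (present on every day), plus one integer column per day giving the
#'   1-based row index of the cell in that day's session (NA if absent).
#' @export
cell_registry <- function(sessions, true_labels = NULL) {
  days <- vapply(sessions, `[[`, "", "day_label")
  if (anyDuplicated(days))
    stop("multiple sessions share a day label; registries are per FOV")
  all_cells <- unique(unlist(lapply(sessions, `[[`, "cell_ids")))
  idx <- matrix(NA_integer_, nrow = length(all_cells), ncol = length(sessions),
                dimnames = list(all_cells, days))
  for (j in seq_along(sessions)) {
    m <- match(sessions[[j]]$cell_ids, all_cells)
    idx[m, j] <- seq_along(sessions[[j]]$cell_ids)
  }
  tracked <- rowSums(is.na(idx)) == 0L
  if (any(!tracked))
    warning(sum(!tracked), " cell(s) not tracked across all days; ",
            "excluded from cross-day analyses: ",
            paste(head(all_cells[!tracked], 5L), collapse = ", "))
  lab <- rep("unknown", length(all_cells))
  if (!is.null(true_labels)) {
    hit <- match(all_cells, names(true_labels))
    lab[!is.na(hit)] <- unname(true_labels[hit[!is.na(hit)]])
  }
  out <- data.frame(cell_id = all_cells, true_label = lab, tracked = tracked,
                    stringsAsFactors = FALSE)
  ord <- order(day_factor(days))
  cbind(out, as.data.frame(idx[, ord, drop = FALSE]))
}

registry_day_cols <- function(registry) {
  setdiff(names(registry), c("cell_id", "true_label", "tracked"))
}

#' Write an experiment to disk
#'
#' One set of CSV tables per session (ROI traces, neuropil traces, shifts,
#' trial onsets) plus a single JSON manifest holding session metadata, the
#' cell registry and optional red-channel intensities. The round trip through
#' [read_experiment()] is lossless: exact for integer fields, full double
#' precision for traces.
#'
#' @param sessions list of [session()] objects.
#' @param registry optional [cell_registry()] data.frame.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(sessions, registry = NULL, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  manifest <- list(format = "sstactivity-experiment", version = 1L,
                   sessions = list())
  # traces are serialized at %.17g so doubles round-trip bit-exactly
  write_traces <- function(mat, cell_ids, file) {
    m <- matrix(sprintf("%.17g", mat), nrow(mat))
    dt <- data.table::as.data.table(m)
    data.table::setnames(dt, paste0("f", seq_len(ncol(mat)) - 1L))
    dt <- cbind(data.table::data.table(cell_id = cell_ids), dt)
    data.table::fwrite(dt, file, quote = FALSE)
  }
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    stem <- sprintf("session_%03d", i)
    write_traces(s$roi_traces, s$cell_ids,
                 file.path(path, paste0(stem, "_roi.csv")))
    write_traces(s$neuropil_traces, s$cell_ids,
                 file.path(path, paste0(stem, "_neuropil.csv")))
    data.table::fwrite(
      data.table::data.table(dx = s$frame_shifts[, 1], dy = s$frame_shifts[, 2]),
      file.path(path, paste0(stem, "_shifts.csv")))
    data.table::fwrite(s$trial_onsets,
                       file.path(path, paste0(stem, "_trials.csv")))
    manifest$sessions[[i]] <- list(
      stem = stem, animal_id = s$animal_id, fov_id = s$fov_id,
      day_label = s$day_label, frame_rate_hz = s$frame_rate_hz,
      n_cells = nrow(s$roi_traces), n_frames = ncol(s$roi_traces),
      red_intensity = if (is.null(s$red_intensity)) NULL else
        as.list(setNames(s$red_intensity, s$cell_ids)))
  }
  if (!is.null(registry)) {
    reg <- registry
    reg$true_label[is.na(reg$true_label)] <- "unknown"
    data.table::fwrite(reg, file.path(path, "registry.csv"))
    manifest$registry <- "registry.csv"
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an experiment from disk
#'
#' Reads the layout written by [write_experiment()] and re-validates every
#' session. If no registry file is present one is rebuilt from the sessions.
#'
#' @param path directory containing `manifest.json`.
#' @param pool_fovs if `TRUE`, sessions from multiple FOVs of one animal on
#'   the same day are kept separate but registered jointly; cross-FOV pooling
#'   before averaging is left to downstream grouping.
#' @return list with elements `sessions` (list of [session()]) and
#'   `registry` (data.frame).
#' @export
read_experiment <- function(path, pool_fovs = FALSE) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf)
  sessions <- lapply(manifest$sessions, function(m) {
    stem <- m$stem
    tr <- data.table::fread(file.path(path, paste0(stem, "_roi.csv")))
    np <- data.table::fread(file.path(path, paste0(stem, "_neuropil.csv")))
    cell_ids <- tr$cell_id
    roi <- as.matrix(tr[, -1])
    neuropil <- as.matrix(np[, -1])
    dimnames(roi) <- dimnames(neuropil) <- NULL
    sh <- data.table::fread(file.path(path, paste0(stem, "_shifts.csv")))
    onsets <- data.table::fread(file.path(path, paste0(stem, "_trials.csv")))
    red <- if (!is.null(m$red_intensity))
      unlist(m$red_intensity)[cell_ids] else NULL
    session(m$animal_id, m$fov_id, m$day_label, roi, neuropil,
            as.matrix(sh), as.data.frame(onsets),
            frame_rate_hz = m$frame_rate_hz, cell_ids = cell_ids,
            red_intensity = red)
  })
  registry <- if (!is.null(manifest$registry)) {
    as.data.frame(data.table::fread(file.path(path, manifest$registry)))
  } else {
    cell_registry(sessions)
  }
  list(sessions = sessions, registry = registry)
}
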