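#' Neuropil correction
#'
#' Subtracts a scaled surrounding-tissue signal from the ROI trace,
#' `F_corrected = F_ROI - r * F_neuropil`, removing out-of-focus
#' contamination (e.g. from SST processes in other layers). The operation is
#' linear in both inputs.
#'
#' @param roi numeric vector, raw ROI fluorescence.
#' @param neuropil numeric vector of the same length.
#' @param r neuropil coefficient, default 0.7.
#' @return Numeric vector `roi - r * neuropil`.
#' @export
neuropil_correct <- function(roi, neuropil, r = 0.7) {
  if (length(roi) != length(neuropil))
    stop("roi and neuropil must have equal length")
  roi - r * neuropil
}

#' Flag motion-shifted frames
#'
#' A frame is a shifted frame when its registration displacement exceeds the
#' threshold in either direction: `|dx| > threshold_px` or `|dy| >
#' threshold_px` (strict inequality; a 20-px shift is not flagged at the
#' default threshold).
#'
#' @param frame_shifts integer matrix, frames x 2 (`dx`, `dy`).
#' @param threshold_px pixel threshold, default 20.
#' @return Logical vector, one entry per frame.
#' @export
flag_shifted_frames <- function(frame_shifts, threshold_px = 20L) {
  frame_shifts <- as.matrix(frame_shifts)
  abs(frame_shifts[, 1]) > threshold_px | abs(frame_shifts[, 2]) > threshold_px
}

# Runs of TRUE in a logical vector -> data.frame(start, end, length), 1-based.
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Interpolate short shifted runs and invalidate trials with long ones
#'
#' Runs of one or two consecutive shifted frames are replaced by the mean of
#' the nearest preceding and following unshifted values (applied to the
#' fluorescence trace; callers apply the same rule to the shift record).
#' Longer runs are not interpolated: any trial window (-3 s to +5 s around
#' onset) containing a run of three or more shifted frames is marked invalid,
#' and such frames are masked for spontaneous-activity computations. A short
#' run at the trace boundary uses its single available neighbour.
#'
#' The operation is idempotent: re-applying it with the same mask leaves the
#' trace unchanged.
#'
#' @param trace numeric vector (typically neuropil-corrected fluorescence).
#' @param shifted_mask logical vector from [flag_shifted_frames()].
#' @param trial_onsets data.frame with `onset_frame` (0-based), or NULL.
#' @param frame_rate_hz frames per second, used to size the trial window.
#' @param interp_max longest run that is interpolated rather than masked.
#' @return List with `values` (corrected trace), `interpolated` (logical),
#'   `masked` (logical, frames in long runs), `trial_valid` (logical per
#'   trial), `trial_reason` (character per trial, "" if valid).
#' @export
interpolate_or_reject <- function(trace, shifted_mask, trial_onsets = NULL,
                                  frame_rate_hz = 5.11, interp_max = 2L) {
  n <- length(trace)
  stopifnot(length(shifted_mask) == n)
  values <- trace
  interpolated <- logical(n)
  masked <- logical(n)
  runs <- runs_of(shifted_mask)
  good <- which(!shifted_mask)
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    if (runs$length[i] <= interp_max) {
      prev <- good[good < s]
      nxt <- good[good > e]
      nb <- c(if (length(prev)) values[max(prev)],
              if (length(nxt)) values[min(nxt)])
      if (length(nb) == 0L) next  # fully shifted trace: nothing to anchor on
      values[s:e] <- mean(nb)
      interpolated[s:e] <- TRUE
    } else {
      masked[s:e] <- TRUE
    }
  }
  trial_valid <- logical(0)
  trial_reason <- character(0)
  if (!is.null(trial_onsets) && nrow(trial_onsets) > 0L) {
    pre <- sec_to_frames(3, frame_rate_hz)
    post <- sec_to_frames(5, frame_rate_hz)
    long_runs <- runs[runs$length > interp_max, , drop = FALSE]
    trial_valid <- rep(TRUE, nrow(trial_onsets))
    trial_reason <- rep("", nrow(trial_onsets))
    for (t in seq_len(nrow(trial_onsets))) {
      on <- trial_onsets$onset_frame[t] + 1L  # to 1-based
      w0 <- on - pre; w1 <- on + post
      if (nrow(long_runs) > 0L &&
          any(long_runs$start <= w1 & long_runs$end >= w0)) {
        trial_valid[t] <- FALSE
        trial_reason[t] <- "shifted_run"
      }
    }
  }
  list(values = values, interpolated = interpolated, masked = masked,
       trial_valid = trial_valid, trial_reason = trial_reason)
}

#' Trial-locked dF/F window
#'
#' Carves the -3 s to +5 s window around a trial onset and converts it to
#' dF/F with the trial-locked baseline convention: `F0` is the mean of the
#' corrected fluorescence over the 1-s window immediately preceding onset,
#' and `dff = (F - F0) / F0`. A trial whose window does not fit in the trace,
#' or whose baseline is nonpositive (dF/F undefined), is invalid.
#'
#' @param corrected numeric vector of corrected fluorescence.
#' @param onset_frame 0-based onset frame.
#' @param frame_rate_hz frames per second.
#' @param trial_type `"stimulus"` or `"blank"` (carried through).
#' @return List: `trial_type`, `onset_frame`, `dff` (window vector), `time_s`
#'   (frame times relative to onset), `baseline_f0`, `valid`, `reason`,
#'   `onset_index` (1-based position of the onset frame within `dff`).
#' @export
dff_trial <- function(corrected, onset_frame, frame_rate_hz = 5.11,
                      trial_type = "stimulus") {
  pre <- sec_to_frames(3, frame_rate_hz)
  post <- sec_to_frames(5, frame_rate_hz)
  base_n <- sec_to_frames(1, frame_rate_hz)
  on <- onset_frame + 1L
  out <- list(trial_type = trial_type, onset_frame = onset_frame,
              dff = NULL, time_s = NULL, baseline_f0 = NA_real_,
              valid = FALSE, reason = "", onset_index = pre + 1L)
  if (on - pre < 1L || on + post > length(corrected)) {
    out$reason <- "window_out_of_range"
    return(out)
  }
  f0 <- mean(corrected[(on - base_n):(on - 1L)])
  out$baseline_f0 <- f0
  if (!is.finite(f0) || f0 <= 0) {
    out$reason <- "nonpositive_baseline"
    return(out)
  }
  w <- corrected[(on - pre):(on + post)]
  out$dff <- (w - f0) / f0
  out$time_s <- (seq_along(w) - 1L - pre) / frame_rate_hz
  out$valid <- TRUE
  out
}

#' Sliding-percentile dF/F for spontaneous activity
#'
#' The spontaneous-activity baseline is a running 20th percentile of the
#' corrected trace over a centred 1-min window (truncated at the trace
#' edges), and `dff = (F - F0) / F0`. Frames where the baseline is
#' nonpositive are returned non-finite (NA) and excluded downstream.
#'
#' For long traces the percentile is evaluated on a strided grid of window
#' centres and linearly interpolated between them; `stride = 1` reproduces
#' the exact frame-by-frame filter.
#'
#' @param corrected numeric vector.
#' @param frame_rate_hz frames per second.
#' @param window_s sliding-window length in seconds, default 60.
#' @param percentile baseline percentile in [0, 100], default 20.
#' @param stride evaluation stride in frames (interpolated in between).
#' @return List: `dff` (numeric vector, NA where undefined) and `f0`
#'   (baseline vector).
#' @export
dff_spontaneous <- function(corrected, frame_rate_hz = 5.11, window_s = 60,
                            percentile = 20, stride = 1L) {
  n <- length(corrected)
  if (n < 2L) stop("trace must be longer than one frame")
  half <- max(1L, sec_to_frames(window_s / 2, frame_rate_hz))
  centers <- unique(c(seq(1L, n, by = as.integer(stride)), n))
  p <- percentile / 100
  q <- vapply(centers, function(c0) {
    w <- corrected[max(1L, c0 - half):min(n, c0 + half)]
    w <- w[is.finite(w)]
    m <- length(w)
    if (m == 0L) return(NA_real_)
    w <- sort(w, method = "quick")
    h <- (m - 1) * p  # type-7 quantile
    lo <- floor(h)
    w[lo + 1] + (h - lo) * (w[min(lo + 2, m)] - w[lo + 1])
  }, 0)
  f0 <- if (length(centers) == n) q else approx(centers, q, seq_len(n), rule = 2)$y
  dff <- (corrected - f0) / f0
  dff[!is.finite(f0) | f0 <= 0 | !is.finite(corrected)] <- NA_real_
  list(dff = dff, f0 = f0)
}

#' Segment a session into trial windows and spontaneous blocks
#'
#' Trial windows span -3 s to +5 s around each onset. Spontaneous blocks are
#' the complement: the initial block is the 100-s window ending where the
#' first trial window starts, intertrial blocks run from the end of one trial
#' window (onset + 5 s) to the start of the next (next onset - 3 s), and the
#' final block is the 100-s window after the last trial window. Blocks with
#' nonpositive span are dropped. A session without trials yields a single
#' initial block covering the whole trace.
#'
#' @param n_frames session length in frames.
#' @param trial_onsets data.frame (`onset_frame` 0-based, `trial_type`).
#' @param frame_rate_hz frames per second.
#' @param flank_s length of the initial/final spontaneous windows (seconds).
#' @return data.frame of blocks: `kind` (initial/intertrial/final),
#'   `start_frame`, `end_frame` (0-based, inclusive).
#' @export
segment_session <- function(n_frames, trial_onsets, frame_rate_hz = 5.11,
                            flank_s = 100) {
  pre <- sec_to_frames(3, frame_rate_hz)
  post <- sec_to_frames(5, frame_rate_hz)
  flank <- sec_to_frames(flank_s, frame_rate_hz)
  if (is.null(trial_onsets) || nrow(trial_onsets) == 0L) {
    return(data.frame(kind = "initial", start_frame = 0L,
                      end_frame = n_frames - 1L))
  }
  on <- trial_onsets$onset_frame  # 0-based
  win_start <- on - pre
  win_end <- on + post
  blocks <- list()
  first <- win_start[1]
  if (first > 0L)
    blocks[[length(blocks) + 1L]] <-
      data.frame(kind = "initial", start_frame = max(0L, first - flank),
                 end_frame = first - 1L)
  if (length(on) > 1L) {
    for (i in seq_len(length(on) - 1L)) {
      s <- win_end[i] + 1L
      e <- win_start[i + 1L] - 1L
      if (e >= s)
        blocks[[length(blocks) + 1L]] <-
          data.frame(kind = "intertrial", start_frame = s, end_frame = e)
    }
  }
  last <- win_end[length(on)]
  if (last < n_frames - 1L)
    blocks[[length(blocks) + 1L]] <-
      data.frame(kind = "final", start_frame = last + 1L,
                 end_frame = min(n_frames - 1L, last + flank))
  do.call(rbind, blocks)
}

#' Preprocess one session
#'
#' Runs the full per-cell preprocessing chain: neuropil correction, shifted
#' frame interpolation / trial rejection, trial-locked dF/F windows,
#' spontaneous-convention dF/F, and block segmentation. Frames in long
#' shifted runs are NA'd out of the spontaneous dF/F.
#'
#' @param sess a [session()].
#' @param r neuropil coefficient.
#' @param shift_threshold_px shifted-frame threshold in pixels.
#' @param spont_stride stride for the sliding-percentile baseline.
#' @return List with per-cell entries `cells` (each holding `corrected`,
#'   `trials` — list of [dff_trial()] results with shift validity folded in —
#'   and `spont_dff`), plus shared `blocks`, `shifted_mask` and a `qc`
#'   data.frame (cell, trial, valid, reason).
#' @export
preprocess_session <- function(sess, r = 0.7, shift_threshold_px = 20L,
                               spont_stride = 10L) {
  n_frames <- ncol(sess$roi_traces)
  shifted <- flag_shifted_frames(sess$frame_shifts, shift_threshold_px)
  blocks <- segment_session(n_frames, sess$trial_onsets, sess$frame_rate_hz)
  cells <- vector("list", nrow(sess$roi_traces))
  qc <- list()
  for (ci in seq_len(nrow(sess$roi_traces))) {
    corr0 <- neuropil_correct(sess$roi_traces[ci, ], sess$neuropil_traces[ci, ], r)
    ir <- interpolate_or_reject(corr0, shifted, sess$trial_onsets,
                                sess$frame_rate_hz)
    trials <- list()
    if (nrow(sess$trial_onsets) > 0L) {
      for (t in seq_len(nrow(sess$trial_onsets))) {
        tw <- dff_trial(ir$values, sess$trial_onsets$onset_frame[t],
                        sess$frame_rate_hz, sess$trial_onsets$trial_type[t])
        if (tw$valid && !ir$trial_valid[t]) {
          tw$valid <- FALSE
          tw$reason <- ir$trial_reason[t]
        }
        trials[[t]] <- tw
      }
    }
    sp_in <- ir$values
    sp_in[ir$masked] <- NA_real_
    sp <- dff_spontaneous(sp_in, sess$frame_rate_hz, stride = spont_stride)
    cells[[ci]] <- list(corrected = ir$values, trials = trials,
                        spont_dff = sp$dff)
    if (length(trials) > 0L)
      qc[[length(qc) + 1L]] <- data.frame(
        cell_id = sess$cell_ids[ci], day = sess$day_label,
        trial = seq_along(trials),
        trial_type = vapply(trials, `[[`, "", "trial_type"),
        valid = vapply(trials, `[[`, TRUE, "valid"),
        reason = vapply(trials, `[[`, "", "reason"))
  }
  list(cells = setNames(cells, sess$cell_ids), blocks = blocks,
       shifted_mask = shifted, frame_rate_hz = sess$frame_rate_hz,
       day_label = sess$day_label,
       qc = if (length(qc)) do.call(rbind, qc) else NULL)
}
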