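# Shared fixture builders. Everything is generated in code; no data files.

# A minimal hand-built session: constant baseline with optional injected
# square transients, no neuropil, no shifts.
toy_session <- function(n_cells = 1L, n_frames = 400L, onsets = c(120L, 222L),
                        types = c("stimulus", "blank")[seq_along(onsets)],
                        baseline = 100, frame_rate_hz = 5.11,
                        day_label = "ACC4") {
  roi <- matrix(baseline, n_cells, n_frames)
  session(animal_id = "a1", fov_id = "f1", day_label = day_label,
          roi_traces = roi,
          neuropil_traces = matrix(0, n_cells, n_frames),
          frame_shifts = matrix(0L, n_frames, 2L),
          trial_onsets = data.frame(onset_frame = onsets, trial_type = types),
          frame_rate_hz = frame_rate_hz)
}

# A synthetic dff_trial-like object with a prescribed dff window, for direct
# metric tests (time grid matches the -3..+5 s window at the given rate).
toy_trial <- function(dff, frame_rate_hz = 5.11, trial_type = "stimulus",
                      valid = TRUE) {
  pre <- sstactivity::sec_to_frames(3, frame_rate_hz)
  list(trial_type = trial_type, onset_frame = pre, dff = dff,
       time_s = (seq_along(dff) - 1L - pre) / frame_rate_hz,
       baseline_f0 = 1, valid = valid, reason = "",
       onset_index = pre + 1L)
}

# Brute-force topographic prominence: for each strict local maximum walk
# outwards to the nearest strictly higher sample on each side and take the
# minimum en route; prominence is height minus the higher of the two minima.
brute_prominence <- function(x) {
  n <- length(x)
  out <- data.frame(index = integer(0), prominence = numeric(0))
  for (i in seq(2L, n - 1L)) {
    if (!(x[i] > x[i - 1L] && x[i] > x[i + 1L])) next
    left <- x[seq_len(i - 1L)]
    hi <- which(left > x[i])
    lmin <- min(left[seq(if (length(hi)) max(hi) + 1L else 1L, i - 1L)])
    right <- x[seq(i + 1L, n)]
    hi <- which(right > x[i])
    rmin <- min(right[seq_len(if (length(hi)) min(hi) - 1L else length(right))])
    out <- rbind(out, data.frame(index = i,
                                 prominence = x[i] - max(lmin, rmin)))
  }
  out
}
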