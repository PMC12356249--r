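#' Construct a home-cage behaviour log
#'
#' Self-initiated trials with anticipatory licking. Each trial carries its
#' onset time, type, and the water-delivery time: on blank trials (no
#' stimulus, no reward) `water_time_s` is the time water would have been
#' delivered under the trial's schedule, which anchors the anticipatory
#' window so that stimulus and blank licking are comparable.
#'
#' @param trials data.frame with columns `time_s` (trial start),
#'   `trial_type` (`"stimulus"`/`"blank"`), `water_time_s` (actual or
#'   scheduled delivery time), optional `water_delivered` (logical).
#' @param licks numeric vector of lick timestamps (seconds).
#' @return List of class `sst_behavior_log`.
#' @export
behavior_log <- function(trials, licks) {
  trials <- as.data.frame(trials)
  stopifnot(all(c("time_s", "trial_type", "water_time_s") %in% names(trials)))
  if (!all(trials$trial_type %in% c("stimulus", "blank")))
    stop("trial_type must be 'stimulus' or 'blank'")
  if (is.null(trials$water_delivered))
    trials$water_delivered <- trials$trial_type == "stimulus"
  structure(list(trials = trials[order(trials$time_s), ],
                 licks = sort(as.numeric(licks))),
            class = "sst_behavior_log")
}

#' Anticipatory lick frequency per trial
#'
#' Licks occurring in the window immediately before (scheduled) water
#' delivery, divided by the window length: 3 licks in the default 300-ms
#' window is 10 Hz.
#'
#' @param log an [behavior_log()].
#' @param window_s anticipatory window length, default 0.3 s.
#' @return Numeric vector, one frequency (Hz) per trial.
#' @export
anticipatory_lick_freq <- function(log, window_s = 0.3) {
  vapply(log$trials$water_time_s, function(wt)
    sum(log$licks >= wt - window_s & log$licks < wt) / window_s, 0)
}

#' Binned behavioural performance
#'
#' Trials are grouped into fixed bins (4 hours by default); bins with fewer
#' than `min_trials` trials are removed, since blank-trial lick frequency
#' cannot be assessed from one or two trials. Per retained bin the mean
#' anticipatory lick frequency is computed per trial type and performance is
#' their difference, `f_stimulus - f_blank`.
#'
#' @param log an [behavior_log()].
#' @param bin_hours bin width in hours, default 4.
#' @param min_trials minimum trials per retained bin, default 10.
#' @param window_s anticipatory window (s).
#' @return data.frame `bin`, `bin_start_s`, `n_trials`, `f_stimulus`,
#'   `f_blank`, `performance`.
#' @export
behavior_performance <- function(log, bin_hours = 4, min_trials = 10L,
                                 window_s = 0.3) {
  freq <- anticipatory_lick_freq(log, window_s)
  bin_s <- bin_hours * 3600
  bin <- floor(log$trials$time_s / bin_s)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    if (sum(sel) < min_trials) return(NULL)
    fs <- mean(freq[sel & log$trials$trial_type == "stimulus"])
    fb <- mean(freq[sel & log$trials$trial_type == "blank"])
    data.frame(bin = b, bin_start_s = b * bin_s, n_trials = sum(sel),
               f_stimulus = fs, f_blank = fb, performance = fs - fb)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(bin = integer(0), bin_start_s = numeric(0),
                      n_trials = integer(0), f_stimulus = numeric(0),
                      f_blank = numeric(0), performance = numeric(0))
  res
}

#' Per-day learning summary over the last 20% of trials
#'
#' For each day (24-h period of the log), takes the last 20% of the day's
#' trials and computes the mean anticipatory lick frequency per trial type
#' and their difference. These per-day, per-animal pairs are the input to
#' [behavior_daily_test()].
#'
#' @param log an [behavior_log()].
#' @param fraction trailing fraction of each day's trials, default 0.2.
#' @param window_s anticipatory window (s).
#' @return data.frame `day`, `n_trials`, `f_stimulus`, `f_blank`,
#'   `performance`.
#' @export
behavior_daily_summary <- function(log, fraction = 0.2, window_s = 0.3) {
  freq <- anticipatory_lick_freq(log, window_s)
  day <- floor(log$trials$time_s / 86400)
  out <- lapply(sort(unique(day)), function(d) {
    idx <- which(day == d)
    keep <- idx[idx > quantile(idx, 1 - fraction, type = 1)]
    if (length(keep) == 0L) keep <- tail(idx, 1L)
    tt <- log$trials$trial_type[keep]
    if (!any(tt == "stimulus") || !any(tt == "blank")) return(NULL)
    fs <- mean(freq[keep][tt == "stimulus"])
    fb <- mean(freq[keep][tt == "blank"])
    data.frame(day = d, n_trials = length(keep), f_stimulus = fs,
               f_blank = fb, performance = fs - fb)
  })
  do.call(rbind, out)
}

#' Wilcoxon signed-rank test of daily stimulus-vs-blank licking
#'
#' Given per-animal daily summaries (from [behavior_daily_summary()]), runs a
#' paired Wilcoxon signed-rank test of stimulus against blank anticipatory
#' lick frequency for each day, with animals as the paired replicates.
#'
#' @param summaries list of data.frames from [behavior_daily_summary()], one
#'   per animal.
#' @return data.frame `day`, `n_animals`, `V`, `p`.
#' @export
behavior_daily_test <- function(summaries) {
  all <- do.call(rbind, lapply(seq_along(summaries), function(i)
    cbind(animal = i, summaries[[i]])))
  out <- lapply(sort(unique(all$day)), function(d) {
    sub <- all[all$day == d, ]
    if (nrow(sub) < 2L)
      return(data.frame(day = d, n_animals = nrow(sub), V = NA_real_,
                        p = NA_real_))
    wt <- suppressWarnings(
      wilcox.test(sub$f_stimulus, sub$f_blank, paired = TRUE))
    data.frame(day = d, n_animals = nrow(sub), V = unname(wt$statistic),
               p = wt$p.value)
  })
  do.call(rbind, out)
}
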