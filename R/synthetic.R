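#' Training-epoch suppression schedule for Calb2-like cells
#'
#' Multiplicative suppression of the evoked amplitude per training day,
#' anchored at fold changes 0.62 (SAT1), 0.56 (SAT5) and 0.46 (SAT10) — the
#' selective suppression observed in SST-Calb2 neurons — and linearly
#' interpolated for the days in between. ACC days are 1.
#'
#' @param training `"SAT"` or `"PSE"` (labels only; the values are the same).
#' @return Named numeric vector over ACC1..ACC6 and the ten training days.
#' @export
calb2_suppression_schedule <- function(training = "SAT") {
  sat <- approx(x = c(1, 5, 10), y = c(0.62, 0.56, 0.46), xout = 1:10)$y
  setNames(c(rep(1, 6), sat), day_levels(training))
}

#' Flat (no-effect) suppression schedule
#' @param training `"SAT"` or `"PSE"`.
#' @return Named numeric vector of ones over all days.
#' @export
flat_suppression_schedule <- function(training = "SAT") {
  setNames(rep(1, 16), day_levels(training))
}

#' Default synthetic cell classes
#'
#' The two-class population mirroring the labelled dataset: 28 Calb2-like
#' cells with elevated response probability and evoked amplitude and the
#' default training-suppression schedule, and 56 SST-O cells with no
#' training effect. Edit the returned list to build custom populations for
#' [generator_config()].
#'
#' @return List of class-descriptor lists.
#' @export
default_classes <- function() {
  list(
    list(name = "SST-Calb2", n = 28L, label = "SST-Calb2",
         p_response = 0.7, amp_median = 1.0, amp_sdlog = 0.9,
         spont_rate_hz = 0.06, suppression = calb2_suppression_schedule(),
         mcherry_meanlog = log(400), mcherry_sdlog = 0.4),
    list(name = "SST-O", n = 56L, label = "SST-O",
         p_response = 0.35, amp_median = 0.35, amp_sdlog = 0.9,
         spont_rate_hz = 0.03, suppression = flat_suppression_schedule(),
         mcherry_meanlog = log(90), mcherry_sdlog = 0.5))
}

#' Synthetic-experiment configuration
#'
#' Defines the statistical structure of a generated experiment. The defaults
#' mirror the study conditions: 28 Calb2-like and 56 other cells; 16 days
#' (ACC1-6, SAT1-10) at 5.11 Hz; 20 trials per 10-min session delivered
#' every 20 s, stimulus and blank interleaved with equal probability,
#' flanked by 100-s spontaneous windows; per-cell log-normal evoked
#' amplitudes spanning ~100-fold across the population; an elevated response
#' probability and evoked peak in the Calb2-like class; multiplicative
#' training suppression of the evoked amplitude in the Calb2-like class only
#' (anchored at the SAT1/SAT5/SAT10 fold changes 0.62/0.56/0.46), with a
#' persistent per-cell dispersion of the training effect emulating the large
#' cell-to-cell spread of in-vivo fold changes; Poisson
#' spontaneous events; neuropil contamination constructed so that the
#' r = 0.7 correction recovers the clean trace in expectation; occasional
#' motion-shift artifact runs; and mCherry intensity distributions
#' straddling the 200-unit threshold.
#'
#' @param classes list of class descriptors (see [default_classes] in the
#'   source); each has `name`, `n`, `label`, `p_response`, `amp_median`,
#'   `amp_sdlog`, `spont_rate_hz`, `suppression` (named per-day factor),
#'   `mcherry_meanlog`, `mcherry_sdlog`.
#' @param days day labels to simulate.
#' @param frame_rate_hz acquisition rate.
#' @param n_trials trials per session.
#' @param trial_period_s trial spacing (s).
#' @param flank_s spontaneous window length before/after the task (s).
#' @param stim_fraction probability a trial is a stimulus trial.
#' @param tau_r,tau_d indicator kernel rise/decay time constants (s).
#' @param trial_amp_sdlog log-normal trial-to-trial amplitude jitter.
#' @param plasticity_sdlog log-normal SD of the persistent per-cell
#'   multiplicative dispersion of the training-day suppression factor
#'   (mean 1, applied on training days only). Emulates the large
#'   cell-to-cell spread of learning-related fold changes seen in vivo;
#'   0 disables it.
#' @param spont_amp_median,spont_amp_sdlog spontaneous event amplitude
#'   distribution (dF/F).
#' @param noise_sd Gaussian noise SD in dF/F units.
#' @param baseline_meanlog,baseline_sdlog per-cell baseline fluorescence
#'   (arbitrary units, log-normal).
#' @param neuropil_base,neuropil_frac neuropil trace level and slow
#'   fluctuation fraction.
#' @param shift_runs_per_session expected motion-artifact runs per session.
#' @param shift_magnitude_px artifact displacement (pixels).
#' @param suppress_spontaneous if `TRUE` the suppression schedule also scales
#'   spontaneous events (sensitivity analyses); default evoked-only.
#' @param seed integer seed.
#' @return List of class `sst_generator_config`.
#' @export
generator_config <- function(classes = default_classes(),
                             days = day_levels("SAT"),
                             frame_rate_hz = 5.11, n_trials = 20L,
                             trial_period_s = 20, flank_s = 100,
                             stim_fraction = 0.5, tau_r = 0.05, tau_d = 0.7,
                             trial_amp_sdlog = 0.25, plasticity_sdlog = 0.55,
                             spont_amp_median = 0.4,
                             spont_amp_sdlog = 0.5, noise_sd = 0.04,
                             baseline_meanlog = log(300), baseline_sdlog = 0.3,
                             neuropil_base = 100, neuropil_frac = 0.05,
                             shift_runs_per_session = 0.3,
                             shift_magnitude_px = 25L,
                             suppress_spontaneous = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(tau_r < tau_d, stim_fraction >= 0, stim_fraction <= 1)
  for (cl in classes) {
    stopifnot(cl$p_response >= 0, cl$p_response <= 1,
              all(cl$suppression > 0))
    if (!all(days %in% names(cl$suppression)))
      stop("class '", cl$name, "' lacks suppression factors for some days")
  }
  structure(cfg, class = "sst_generator_config")
}

# Calcium-indicator impulse response sampled on the frame grid, unit peak.
transient_kernel <- function(frame_rate_hz, tau_r, tau_d, length_s = 6) {
  t <- seq(0, length_s, by = 1 / frame_rate_hz)
  k <- (1 - exp(-t / tau_r)) * exp(-t / tau_d)
  k / max(k)
}

add_impulses <- function(n_frames, at_frames, amps, kernel) {
  x <- numeric(n_frames)
  for (i in seq_along(at_frames)) {
    f0 <- at_frames[i]
    idx <- f0:min(n_frames, f0 + length(kernel) - 1L)
    x[idx] <- x[idx] + amps[i] * kernel[seq_along(idx)]
  }
  x
}

#' Generate a labelled synthetic experiment
#'
#' Simulates one field of view across all configured days. For every cell and
#' day: Bernoulli trial responses with log-normal amplitude scaled by the
#' day's class suppression factor, Poisson spontaneous events, convolution
#' with the indicator kernel, a baseline-scaled fluorescence trace with
#' Gaussian noise, a slowly fluctuating neuropil channel mixed into the ROI
#' trace at the 0.7 coefficient, and optional motion-shift artifact runs
#' (which also corrupt the fluorescence). The ground-truth ledger records
#' every trial response and generating parameter. Deterministic given the
#' config seed.
#'
#' @param config an [generator_config()].
#' @return List: `sessions` (list of [session()]), `registry`
#'   ([cell_registry()] with true labels), `ledger` (data.frame of per-trial
#'   ground truth), `cell_params` (data.frame of per-cell generating
#'   parameters), `config`.
#' @export
generate_experiment <- function(config = generator_config()) {
  cfg <- config
  set.seed(cfg$seed)
  fr <- cfg$frame_rate_hz
  kernel <- transient_kernel(fr, cfg$tau_r, cfg$tau_d)
  # session timing: 100-s flank, then trials every trial_period_s; the first
  # onset sits 3 s into the task so its window starts exactly at the flank end
  onset_s <- cfg$flank_s + 3 + (seq_len(cfg$n_trials) - 1L) * cfg$trial_period_s
  total_s <- cfg$flank_s + 3 + (cfg$n_trials - 1L) * cfg$trial_period_s + 5 +
    cfg$flank_s
  n_frames <- sec_to_frames(total_s, fr) + 1L
  onset_frames <- vapply(onset_s, sec_to_frames, 0L, frame_rate_hz = fr)
  if (any(onset_frames + sec_to_frames(5, fr) >= n_frames))
    stop("infeasible schedule: trials overlap the session end")
  # per-cell parameters
  cp <- list()
  for (ci in seq_along(cfg$classes)) {
    cl <- cfg$classes[[ci]]
    cp[[ci]] <- data.frame(
      cell_id = sprintf("%s_c%02d", gsub("[^A-Za-z0-9]", "", cl$name),
                        seq_len(cl$n)),
      class_name = cl$name, true_label = cl$label,
      p_response = cl$p_response,
      amp = rlnorm(cl$n, log(cl$amp_median), cl$amp_sdlog),
      spont_rate_hz = cl$spont_rate_hz,
      baseline_f = rlnorm(cl$n, cfg$baseline_meanlog, cfg$baseline_sdlog),
      mcherry = rlnorm(cl$n, cl$mcherry_meanlog, cl$mcherry_sdlog),
      plasticity_jitter = rlnorm(cl$n, -cfg$plasticity_sdlog^2 / 2,
                                 cfg$plasticity_sdlog))
  }
  cell_params <- do.call(rbind, cp)
  n_cells <- nrow(cell_params)
  sessions <- vector("list", length(cfg$days))
  ledger <- list()
  for (di in seq_along(cfg$days)) {
    day <- cfg$days[di]
    types <- ifelse(runif(cfg$n_trials) < cfg$stim_fraction,
                    "stimulus", "blank")
    roi <- matrix(0, n_cells, n_frames)
    npil <- matrix(0, n_cells, n_frames)
    for (ci in seq_len(n_cells)) {
      pars <- cell_params[ci, ]
      supp <- cfg$classes[[match(pars$class_name,
                                 vapply(cfg$classes, `[[`, "", "name"))]]
      f_day <- supp$suppression[[day]]
      # persistent cell-level dispersion of the training effect (mean 1)
      if (!grepl("^ACC", day)) f_day <- f_day * pars$plasticity_jitter
      responded <- types == "stimulus" & runif(cfg$n_trials) < pars$p_response
      amps <- rlnorm(cfg$n_trials, 0, cfg$trial_amp_sdlog) * pars$amp * f_day
      amps[!responded] <- 0
      n_ev <- rpois(1L, pars$spont_rate_hz * total_s)
      ev_frames <- sort(sample.int(n_frames, min(n_ev, n_frames)))
      ev_amps <- rlnorm(length(ev_frames), log(cfg$spont_amp_median),
                        cfg$spont_amp_sdlog)
      if (cfg$suppress_spontaneous) ev_amps <- ev_amps * f_day
      dff <- add_impulses(n_frames, onset_frames[responded] + 1L,
                          amps[responded], kernel) +
        add_impulses(n_frames, ev_frames, ev_amps, kernel)
      f_clean <- pars$baseline_f * (1 + dff)
      np <- cfg$neuropil_base *
        (1 + cfg$neuropil_frac * as.numeric(stats::filter(
          rnorm(n_frames), 0.95, method = "recursive")) * sqrt(1 - 0.95^2))
      noise <- rnorm(n_frames, 0, cfg$noise_sd * pars$baseline_f)
      roi[ci, ] <- f_clean + 0.7 * np + noise
      npil[ci, ] <- np
      ledger[[length(ledger) + 1L]] <- data.frame(
        cell_id = pars$cell_id, day = day, trial = seq_len(cfg$n_trials),
        trial_type = types, responded = responded, amplitude = amps,
        day_factor = f_day)
    }
    shifts <- matrix(0L, n_frames, 2L)
    n_runs <- rpois(1L, cfg$shift_runs_per_session)
    shift_frames <- integer(0)
    for (rn in seq_len(n_runs)) {
      len <- sample.int(5L, 1L, prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
      start <- sample.int(n_frames - len, 1L)
      idx <- start:(start + len - 1L)
      axis <- sample(1:2, 1L)
      shifts[idx, axis] <- cfg$shift_magnitude_px * sample(c(-1L, 1L), 1L)
      shift_frames <- union(shift_frames, idx)
    }
    if (length(shift_frames) > 0L)  # shifted frames read the wrong pixels
      roi[, shift_frames] <- roi[, shift_frames] *
        matrix(runif(n_cells * length(shift_frames), 0.3, 0.7),
               n_cells)
    sessions[[di]] <- session(
      animal_id = "sim1", fov_id = "fov1", day_label = day,
      roi_traces = roi, neuropil_traces = npil, frame_shifts = shifts,
      trial_onsets = data.frame(onset_frame = onset_frames,
                                trial_type = types),
      frame_rate_hz = fr, cell_ids = cell_params$cell_id,
      red_intensity = if (di == 1L) cell_params$mcherry else NULL)
  }
  registry <- cell_registry(sessions,
                            setNames(cell_params$true_label,
                                     cell_params$cell_id))
  list(sessions = sessions, registry = registry,
       ledger = do.call(rbind, ledger), cell_params = cell_params,
       config = cfg)
}

#' Canned synthetic fixtures
#'
#' Small deterministic experiments used by the test suite and documentation:
#' \describe{
#'   \item{`two-cell-smoke`}{2 cells, 2 days, 10 trials — I/O and
#'     preprocessing smoke tests.}
#'   \item{`null-no-effect`}{both classes with all suppression factors 1 —
#'     false-positive-rate checks.}
#'   \item{`three-subtype-clusters`}{three latent classes (one Calb2-like,
#'     two SST-O-like) with distinct response probability and evoked
#'     amplitude, pretraining days only — cluster-count selection.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @return An [generator_config()] (pass to [generate_experiment()]).
#' @export
make_fixture <- function(name, seed = 1L) {
  switch(name,
    "two-cell-smoke" = {
      cls <- default_classes()
      cls[[1]]$n <- 1L; cls[[2]]$n <- 1L
      generator_config(classes = cls, days = c("ACC4", "ACC5"),
                       n_trials = 10L, seed = seed)
    },
    "null-no-effect" = {
      cls <- default_classes()
      cls[[1]]$suppression <- flat_suppression_schedule()
      generator_config(classes = cls, seed = seed)
    },
    "three-subtype-clusters" = {
      cls <- list(
        list(name = "A-Calb2like", n = 20L, label = "SST-Calb2",
             p_response = 0.8, amp_median = 1.2, amp_sdlog = 0.35,
             spont_rate_hz = 0.08, suppression = flat_suppression_schedule(),
             mcherry_meanlog = log(400), mcherry_sdlog = 0.4),
        list(name = "B-Omid", n = 20L, label = "SST-O",
             p_response = 0.45, amp_median = 0.45, amp_sdlog = 0.35,
             spont_rate_hz = 0.04, suppression = flat_suppression_schedule(),
             mcherry_meanlog = log(90), mcherry_sdlog = 0.5),
        list(name = "C-Olow", n = 20L, label = "SST-O",
             p_response = 0.1, amp_median = 0.15, amp_sdlog = 0.35,
             spont_rate_hz = 0.02, suppression = flat_suppression_schedule(),
             mcherry_meanlog = log(90), mcherry_sdlog = 0.5))
      generator_config(classes = cls, days = paste0("ACC", 4:6),
                       n_trials = 20L, seed = seed)
    },
    stop("unknown fixture: ", name))
}
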