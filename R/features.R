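# Population SD (divide by n), the pinned convention for sigma1/sigma2 and
# z-scoring; at the sample sizes involved the difference from the n-1 form is
# negligible but the choice must be fixed.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

trapz <- function(t, y) {
  ok <- is.finite(y) & is.finite(t)
  t <- t[ok]; y <- y[ok]
  if (length(y) < 2L) return(0)
  sum(diff(t) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# Named in-trial periods, in seconds relative to onset.
trial_periods <- list(pretrial = c(-2, 0), response = c(0, 2),
                      posttrial = c(2, 4), full = c(-3, 5))

#' Noise scales for event detection
#'
#' Two noise scales are estimated per cell per session: `sigma1`, the SD of
#' the concatenated 1-s pre-onset baseline dF/F across all valid trials (used
#' to detect responsive trials), and `sigma2`, the SD of the entire session's
#' spontaneous-convention dF/F trace (used to detect spontaneous events).
#' SDs use the population (divide by n) convention.
#'
#' @param trials list of [dff_trial()] results.
#' @param session_spont_dff spontaneous-convention dF/F for the whole session.
#' @return List `sigma1`, `sigma2` (`sigma1` is NA if no trial is valid).
#' @export
compute_sigmas <- function(trials, session_spont_dff) {
  base <- unlist(lapply(trials, function(tw) {
    if (!isTRUE(tw$valid)) return(NULL)
    tw$dff[tw$time_s >= -1 & tw$time_s < 0]
  }))
  sigma1 <- if (length(base) > 0L) pop_sd(base) else NA_real_
  list(sigma1 = sigma1, sigma2 = pop_sd(session_spont_dff))
}

# Peak of the response window (default 0..2 s after onset) of one trial.
response_peak <- function(tw, window_s = c(0, 2)) {
  idx <- tw$time_s >= window_s[1] & tw$time_s <= window_s[2]
  max(tw$dff[idx])
}

#' Response probability
#'
#' Fraction of valid trials whose response-window dF/F peak exceeds
#' `k * sigma1`. Monotone non-increasing in `k`.
#'
#' @param trials list of [dff_trial()] results (pre-filtered to the wanted
#'   trial type; invalid trials are skipped).
#' @param k threshold multiple of `sigma1`.
#' @param sigma1 baseline-noise SD from [compute_sigmas()].
#' @param window_s response window in seconds relative to onset.
#' @return Proportion in [0, 1], or NA if no trial is valid.
#' @export
response_probability <- function(trials, k, sigma1, window_s = c(0, 2)) {
  peaks <- vapply(Filter(function(tw) isTRUE(tw$valid), trials),
                  response_peak, 0, window_s = window_s)
  if (length(peaks) == 0L || !is.finite(sigma1)) return(NA_real_)
  mean(peaks > k * sigma1)
}

#' In-trial activity metrics over a named period
#'
#' Computes the four first-order evoked-activity metrics over a sub-window of
#' the trial: `peak` (max dF/F), `peak_latency` (time of the max relative to
#' the period start, s), `center_of_mass` (positive-rectified dF/F-weighted
#' mean time relative to period start, s; the period midpoint if the signal
#' is nowhere positive), and `auc` (trapezoidal integral, dF/F x s).
#'
#' @param tw a valid [dff_trial()] result.
#' @param period one of `"pretrial"` (-2..0 s), `"response"` (0..2 s),
#'   `"posttrial"` (2..4 s), `"full"` (-3..+5 s), or a numeric length-2
#'   window in seconds relative to onset.
#' @return Named list `peak`, `peak_latency`, `center_of_mass`, `auc`.
#' @export
in_trial_metrics <- function(tw, period = "response") {
  win <- if (is.character(period)) trial_periods[[period]] else period
  if (is.null(win)) stop("unknown period: ", period)
  idx <- which(tw$time_s >= win[1] & tw$time_s <= win[2])
  d <- tw$dff[idx]
  t_rel <- tw$time_s[idx] - win[1]
  i_max <- which.max(d)
  w <- pmax(d, 0)
  com <- if (sum(w) > 0) sum(t_rel * w) / sum(w) else (win[2] - win[1]) / 2
  list(peak = d[i_max], peak_latency = t_rel[i_max],
       center_of_mass = com, auc = trapz(t_rel, d))
}

#' Local maxima and their topographic prominence
#'
#' A sample is a local maximum when it is strictly higher than both
#' neighbours. Its prominence is its height above the higher of the two
#' minima separating it from the nearest strictly higher sample on each side
#' (trace ends count as walls). Non-finite samples split the trace into
#' independent segments.
#'
#' @param x numeric vector.
#' @return data.frame `index`, `height`, `prominence`.
#' @export
find_peak_prominences <- function(x) {
  idx_out <- integer(0)
  prom_out <- numeric(0)
  finite <- is.finite(x)
  segs <- runs_of(finite)
  for (si in seq_len(nrow(segs))) {
    s <- segs$start[si]; e <- segs$end[si]
    if (e - s < 2L) next
    xs <- x[s:e]
    m <- length(xs)
    pks <- which(xs[2:(m - 1L)] > xs[1:(m - 2L)] &
                 xs[2:(m - 1L)] > xs[3:m]) + 1L
    if (length(pks) == 0L) next
    proms <- vapply(pks, function(i) {
      h <- xs[i]
      j <- i - 1L; lmin <- h
      while (j >= 1L && xs[j] <= h) {
        if (xs[j] < lmin) lmin <- xs[j]
        j <- j - 1L
      }
      j <- i + 1L; rmin <- h
      while (j <= m && xs[j] <= h) {
        if (xs[j] < rmin) rmin <- xs[j]
        j <- j + 1L
      }
      h - max(lmin, rmin)
    }, 0)
    idx_out <- c(idx_out, s + pks - 1L)
    prom_out <- c(prom_out, proms)
  }
  data.frame(index = idx_out, height = x[idx_out], prominence = prom_out)
}

#' Detect spontaneous calcium events
#'
#' Events are local maxima of the spontaneous-convention dF/F whose
#' topographic prominence exceeds `k * sigma2`. The event count is
#' non-increasing in `k`.
#'
#' @param block_dff dF/F vector of one spontaneous block.
#' @param k threshold multiple.
#' @param sigma2 session noise scale from [compute_sigmas()].
#' @return data.frame `index`, `height` (peak dF/F), `prominence` of the
#'   detected events (possibly empty).
#' @export
detect_spontaneous_events <- function(block_dff, k, sigma2) {
  pk <- find_peak_prominences(block_dff)
  pk[pk$prominence > k * sigma2, , drop = FALSE]
}

#' The first-order feature grid
#'
#' Instantiates the full combinatorial feature inventory from the main
#' parameter lists: response-probability features (trial type x threshold
#' multiple of sigma1 in {1, 2, 3, 5, 10}), in-trial measurement features
#' (trial type x named period x metric in peak / peak latency / centre of
#' mass / AUC), and spontaneous-activity features (block kind x event metric
#' x threshold multiple of sigma2 in 1..10, plus per-block AUC). The default
#' grid instantiates 110 distinct feature specifications. An edited grid can
#' be loaded from a JSON manifest with the same columns.
#'
#' @param manifest optional path to a JSON manifest to load instead of the
#'   default grid.
#' @return data.frame with columns `spec_id`, `category`, `trial_type`,
#'   `period`, `metric`, `threshold_k`.
#' @export
feature_grid <- function(manifest = NULL) {
  if (!is.null(manifest)) {
    g <- jsonlite::fromJSON(manifest)
    stopifnot(all(c("spec_id", "category", "trial_type", "period", "metric",
                    "threshold_k") %in% names(g)))
    if (anyDuplicated(g$spec_id)) stop("duplicate spec_id in manifest")
    return(as.data.frame(g))
  }
  rp <- expand.grid(trial_type = c("stimulus", "blank", "all"),
                    threshold_k = c(1, 2, 3, 5, 10),
                    stringsAsFactors = FALSE)
  rp <- data.frame(category = "response_probability", trial_type = rp$trial_type,
                   period = "response", metric = "probability",
                   threshold_k = rp$threshold_k)
  it <- expand.grid(trial_type = c("stimulus", "blank"),
                    period = names(trial_periods),
                    metric = c("peak", "peak_latency", "center_of_mass", "auc"),
                    stringsAsFactors = FALSE)
  it <- data.frame(category = "in_trial", trial_type = it$trial_type,
                   period = it$period, metric = it$metric, threshold_k = NA_real_)
  ev <- expand.grid(period = c("initial", "intertrial", "final"),
                    metric = c("event_peak", "event_count"),
                    threshold_k = 1:10, stringsAsFactors = FALSE)
  ev <- data.frame(category = "spontaneous", trial_type = "none",
                   period = ev$period, metric = ev$metric,
                   threshold_k = as.numeric(ev$threshold_k))
  ba <- data.frame(category = "spontaneous", trial_type = "none",
                   period = c("initial", "intertrial", "final"),
                   metric = "block_auc", threshold_k = NA_real_)
  g <- rbind(rp, it, ev, ba)
  g$spec_id <- with(g, paste(category, trial_type, period, metric,
                             ifelse(is.na(threshold_k), "na", threshold_k),
                             sep = "."))
  g[, c("spec_id", "category", "trial_type", "period", "metric", "threshold_k")]
}

# Feature values for one cell on one day. `cell` is an entry of
# preprocess_session()$cells; `blocks` the session block table.
cell_day_features <- function(cell, blocks, frame_rate_hz, grid) {
  trials <- cell$trials
  sig <- compute_sigmas(trials, cell$spont_dff)
  valid <- Filter(function(tw) isTRUE(tw$valid), trials)
  types <- vapply(valid, `[[`, "", "trial_type")
  by_type <- function(tt) if (tt == "all") valid else valid[types == tt]
  # precompute per-type, per-period metric means
  it_cache <- new.env(parent = emptyenv())
  metric_mean <- function(tt, period, metric) {
    key <- paste(tt, period, sep = "|")
    if (is.null(it_cache[[key]])) {
      tws <- by_type(tt)
      it_cache[[key]] <- if (length(tws) == 0L) NULL else
        lapply(tws, in_trial_metrics, period = period)
    }
    ms <- it_cache[[key]]
    if (is.null(ms)) return(NA_real_)
    mean(vapply(ms, `[[`, 0, metric))
  }
  # spontaneous candidates per block kind, computed once
  sp_cache <- lapply(c(initial = "initial", intertrial = "intertrial",
                       final = "final"), function(kind) {
    bl <- blocks[blocks$kind == kind, , drop = FALSE]
    lapply(seq_len(nrow(bl)), function(i) {
      d <- cell$spont_dff[(bl$start_frame[i] + 1L):(bl$end_frame[i] + 1L)]
      list(dff = d, peaks = find_peak_prominences(d))
    })
  })
  vals <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    vals[i] <- switch(g$category,
      response_probability = response_probability(by_type(g$trial_type),
                                                  g$threshold_k, sig$sigma1),
      in_trial = metric_mean(g$trial_type, g$period, g$metric),
      spontaneous = {
        bls <- sp_cache[[g$period]]
        if (length(bls) == 0L) NA_real_
        else if (g$metric == "block_auc") {
          mean(vapply(bls, function(b)
            trapz(seq_along(b$dff) / frame_rate_hz, b$dff), 0))
        } else {
          thr <- g$threshold_k * sig$sigma2
          if (g$metric == "event_count") {
            mean(vapply(bls, function(b) sum(b$peaks$prominence > thr), 0))
          } else {  # event_peak; no-event days contribute 0 by convention
            hts <- unlist(lapply(bls, function(b)
              b$peaks$height[b$peaks$prominence > thr]))
            if (length(hts) == 0L) 0 else mean(hts)
          }
        }
      },
      stop("unknown category"))
  }
  setNames(vals, grid$spec_id)
}

#' Preprocess every session of an experiment
#'
#' @param sessions list of [session()] objects.
#' @param ... passed to [preprocess_session()].
#' @return Named list of [preprocess_session()] results, keyed by day label.
#' @export
preprocess_experiment <- function(sessions, ...) {
  out <- lapply(sessions, preprocess_session, ...)
  setNames(out, vapply(sessions, `[[`, "", "day_label"))
}

#' Build the cells x features matrix
#'
#' Per-unit feature values (per trial, per block or per event) are averaged
#' within each day, and the day values averaged across the requested days
#' (pretraining days ACC4-ACC6 by default). Cells missing any requested day,
#' or with any unresolvable feature after averaging, are excluded.
#'
#' @param preprocessed result of [preprocess_experiment()].
#' @param days day labels to average over.
#' @param grid feature grid, default [feature_grid()].
#' @return List of class `sst_features`: `values` (cells x specs matrix),
#'   `specs` (the grid), `cells`, `excluded`.
#' @export
build_feature_matrix <- function(preprocessed, days = paste0("ACC", 4:6),
                                 grid = feature_grid()) {
  missing_days <- setdiff(days, names(preprocessed))
  if (length(missing_days) > 0L)
    stop("preprocessed sessions missing for: ",
         paste(missing_days, collapse = ", "))
  per_day <- lapply(days, function(d) {
    pp <- preprocessed[[d]]
    vals <- t(vapply(pp$cells, cell_day_features, numeric(nrow(grid)),
                     blocks = pp$blocks, frame_rate_hz = pp$frame_rate_hz,
                     grid = grid))
    rownames(vals) <- names(pp$cells)
    vals
  })
  cells <- Reduce(intersect, lapply(per_day, rownames))
  stacked <- lapply(per_day, function(v) v[cells, , drop = FALSE])
  avg <- Reduce(`+`, stacked) / length(stacked)
  keep <- rowSums(!is.finite(avg)) == 0L
  excluded <- cells[!keep]
  if (length(excluded) > 0L)
    message(length(excluded), " cell(s) excluded from the feature matrix ",
            "(missing day or unresolvable feature)")
  structure(list(values = avg[keep, , drop = FALSE], specs = grid,
                 cells = cells[keep], excluded = excluded),
            class = "sst_features")
}

#' Rank features by class separability
#'
#' Each feature is scored by a two-sample (unpaired, Welch) t-test comparing
#' genetically labelled SST-Calb2 against SST-O cells; features are ordered
#' by ascending p-value. Features with zero variance in both classes are
#' untestable and ranked last.
#'
#' @param fm an `sst_features` object from [build_feature_matrix()].
#' @param labels named character vector or factor of per-cell labels
#'   (`"SST-Calb2"` / `"SST-O"`); names must cover `fm$cells`. Cells labelled
#'   otherwise are ignored.
#' @return data.frame `spec_id`, `t`, `p`, `rank`, ordered by rank.
#' @export
rank_features <- function(fm, labels) {
  lab <- labels[fm$cells]
  use <- lab %in% c("SST-Calb2", "SST-O")
  if (sum(lab[use] == "SST-Calb2") < 2L || sum(lab[use] == "SST-O") < 2L)
    stop("need at least 2 labelled cells per class")
  x <- fm$values[use, , drop = FALSE]
  g <- lab[use]
  stats <- t(vapply(seq_len(ncol(x)), function(j) {
    a <- x[g == "SST-Calb2", j]; b <- x[g == "SST-O", j]
    tt <- tryCatch(t.test(a, b), error = function(e) NULL)
    if (is.null(tt)) c(0, NA_real_) else c(unname(tt$statistic), tt$p.value)
  }, numeric(2)))
  out <- data.frame(spec_id = fm$specs$spec_id, t = stats[, 1], p = stats[, 2])
  out <- out[order(out$p, na.last = TRUE), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top-ranked feature columns
#'
#' @param fm an `sst_features` object.
#' @param ranking result of [rank_features()].
#' @param n number of features to keep (default 30, the number used for
#'   embedding).
#' @return `sst_features` restricted to the top `n` specs, in rank order.
#' @export
top_features <- function(fm, ranking, n = 30L) {
  ids <- head(ranking$spec_id, n)
  j <- match(ids, fm$specs$spec_id)
  structure(list(values = fm$values[, j, drop = FALSE],
                 specs = fm$specs[j, ], cells = fm$cells,
                 excluded = fm$excluded), class = "sst_features")
}
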