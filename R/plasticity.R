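#' Daily mean evoked peak
#'
#' The daily stimulus-evoked activity of a cell: all valid stimulus trials of
#' the day contribute, irrespective of response amplitude. With the default
#' `"peak_of_mean"` method the dF/F traces are averaged across trials and the
#' peak of the day-average trace over the response window is taken; with
#' `"mean_of_peaks"` the per-trial response-window peaks are averaged.
#'
#' @param trials list of [dff_trial()] results for one cell on one day.
#' @param method `"peak_of_mean"` (default) or `"mean_of_peaks"`.
#' @param window_s response window in seconds relative to onset.
#' @return Mean evoked peak (dF/F), or NA if no valid stimulus trial exists.
#' @export
daily_mean_peak <- function(trials, method = c("peak_of_mean", "mean_of_peaks"),
                            window_s = c(0, 2)) {
  method <- match.arg(method)
  use <- Filter(function(tw) isTRUE(tw$valid) && tw$trial_type == "stimulus",
                trials)
  if (length(use) == 0L) return(NA_real_)
  if (method == "mean_of_peaks")
    return(mean(vapply(use, response_peak, 0, window_s = window_s)))
  len <- min(vapply(use, function(tw) length(tw$dff), 0L))
  avg <- rowMeans(vapply(use, function(tw) tw$dff[seq_len(len)], numeric(len)))
  t_s <- use[[1L]]$time_s[seq_len(len)]
  max(avg[t_s >= window_s[1] & t_s <= window_s[2]])
}

# Training-epoch day groups for a set of day labels (SAT or PSE).
epoch_days <- function(days) {
  pfx <- if (any(grepl("^PSE", days))) "PSE" else "SAT"
  lapply(list(c(1, 2), c(5, 6), c(9, 10)), function(i) paste0(pfx, i)) |>
    setNames(paste0(pfx, c("1/2", "5/6", "9/10")))
}

#' Per-cell daily evoked peaks and training-epoch fold changes
#'
#' Computes each cell's daily mean evoked peak, the pretraining baseline
#' (mean of the ACC4-ACC6 daily peaks), and the fold change of each training
#' epoch (SAT1/2, SAT5/6, SAT9/10 - or the PSE equivalents) relative to that
#' baseline: epoch mean peak divided by the baseline. Epochs fall back to
#' whichever of their days is available. Cells with a nonpositive baseline
#' are excluded and flagged.
#'
#' @param preprocessed result of [preprocess_experiment()].
#' @param method passed to [daily_mean_peak()].
#' @return List of class `sst_plasticity`: `daily` (long data.frame cell x
#'   day x mean_peak), `cells` (data.frame cell_id, acc_baseline, one
#'   fold-change column per epoch), `excluded`.
#' @export
plasticity_table <- function(preprocessed, method = "peak_of_mean") {
  days <- names(preprocessed)
  daily <- do.call(rbind, lapply(days, function(d) {
    pp <- preprocessed[[d]]
    data.frame(cell_id = names(pp$cells), day = d,
               mean_peak = vapply(pp$cells, function(cell)
                 daily_mean_peak(cell$trials, method = method), 0))
  }))
  rownames(daily) <- NULL
  wide <- tapply(daily$mean_peak, list(daily$cell_id, daily$day), identity)
  acc <- intersect(paste0("ACC", 4:6), colnames(wide))
  if (length(acc) == 0L) stop("no ACC4-ACC6 sessions available for baseline")
  baseline <- rowMeans(wide[, acc, drop = FALSE], na.rm = TRUE)
  eps <- epoch_days(days)
  cells <- data.frame(cell_id = rownames(wide), acc_baseline = baseline)
  for (en in names(eps)) {
    ed <- intersect(eps[[en]], colnames(wide))
    cells[[paste0("fold_", gsub("/", "_", en))]] <- if (length(ed) == 0L)
      NA_real_
    else rowMeans(wide[, ed, drop = FALSE], na.rm = TRUE) / baseline
  }
  bad <- !is.finite(baseline) | baseline <= 0
  if (any(bad))
    message(sum(bad), " cell(s) with nonpositive ACC baseline excluded")
  structure(list(daily = daily, cells = cells[!bad, , drop = FALSE],
                 excluded = cells$cell_id[bad], epochs = eps),
            class = "sst_plasticity")
}

#' Group mean fold changes by training epoch
#'
#' @param pt an `sst_plasticity` object.
#' @param groups optional named per-cell grouping vector (e.g. predicted or
#'   true subtype); default puts all cells in one group.
#' @return data.frame `group`, `epoch`, `n`, `mean_fold`, `sem`.
#' @export
epoch_fold_changes <- function(pt, groups = NULL) {
  cells <- pt$cells
  grp <- if (is.null(groups)) rep("all", nrow(cells)) else
    as.character(groups[cells$cell_id])
  fold_cols <- grep("^fold_", names(cells), value = TRUE)
  out <- list()
  for (g in unique(grp[!is.na(grp)])) {
    for (fc in fold_cols) {
      v <- cells[[fc]][grp == g & !is.na(grp)]
      v <- v[is.finite(v)]
      out[[length(out) + 1L]] <- data.frame(
        group = g, epoch = sub("^fold_", "", fc), n = length(v),
        mean_fold = mean(v), sem = sd(v) / sqrt(length(v)))
    }
  }
  do.call(rbind, out)
}

#' Group statistics for training-epoch plasticity
#'
#' Paired t-tests comparing each training epoch's mean peak with the
#' ACC4-ACC6 baseline across cells, Bonferroni-corrected over the number of
#' epoch comparisons, plus a one-way repeated-measures ANOVA across imaging
#' days (cells as subjects; any other grouping level can be applied by
#' averaging upstream). Cells missing an epoch are dropped pairwise for that
#' epoch's test.
#'
#' @param pt an `sst_plasticity` object.
#' @param groups optional named per-cell grouping; tests run per group.
#' @return data.frame with per-group, per-epoch `t`, `p_raw`, `p_bonferroni`,
#'   `n`, and an attribute `"anova"` holding the repeated-measures ANOVA
#'   table(s).
#' @export
group_stats <- function(pt, groups = NULL) {
  cells <- pt$cells
  grp <- if (is.null(groups)) rep("all", nrow(cells)) else
    as.character(groups[cells$cell_id])
  eps <- names(pt$epochs)
  fold_cols <- paste0("fold_", gsub("/", "_", eps))
  out <- list()
  anovas <- list()
  for (g in unique(grp[!is.na(grp)])) {
    sub <- cells[grp == g & !is.na(grp), , drop = FALSE]
    m <- length(eps)
    for (i in seq_along(eps)) {
      epoch_peak <- sub[[fold_cols[i]]] * sub$acc_baseline
      ok <- is.finite(epoch_peak) & is.finite(sub$acc_baseline)
      rec <- data.frame(group = g, epoch = eps[i], n = sum(ok),
                        t = NA_real_, p_raw = NA_real_,
                        p_bonferroni = NA_real_)
      if (sum(ok) >= 2L) {
        d <- epoch_peak[ok] - sub$acc_baseline[ok]
        if (all(d == 0)) {
          rec$t <- 0; rec$p_raw <- 1
        } else {
          tt <- t.test(epoch_peak[ok], sub$acc_baseline[ok], paired = TRUE)
          rec$t <- unname(tt$statistic)
          rec$p_raw <- tt$p.value
        }
        rec$p_bonferroni <- min(1, rec$p_raw * m)
      }
      out[[length(out) + 1L]] <- rec
    }
    # repeated-measures ANOVA across days
    dsub <- pt$daily[pt$daily$cell_id %in% sub$cell_id &
                       is.finite(pt$daily$mean_peak), ]
    if (nrow(dsub) > 0L && length(unique(dsub$day)) > 1L &&
        length(unique(dsub$cell_id)) > 1L) {
      dsub$day <- day_factor(dsub$day)
      dsub$cell_id <- factor(dsub$cell_id)
      fit <- aov(mean_peak ~ day + Error(cell_id), data = dsub)
      anovas[[g]] <- summary(fit)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "anova") <- anovas
  res
}

#' Label Calb2-positive cells by red-channel intensity
#'
#' A cell is Calb2-positive when its mean mCherry pixel intensity on the
#' initial imaging day strictly exceeds the threshold (200 arbitrary units by
#' default); an intensity of exactly 200 is negative. Missing intensities
#' yield NA (label unknown).
#'
#' @param red_intensity numeric per-cell intensities (initial imaging day).
#' @param threshold intensity cutoff, default 200.
#' @return Logical vector (NA where intensity is missing).
#' @export
label_calb2_by_intensity <- function(red_intensity, threshold = 200) {
  ifelse(is.na(red_intensity), NA, red_intensity > threshold)
}
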