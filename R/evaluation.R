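# Method-performance machinery: the rule-based surrogate labeller, confusion
# matrices with the five performance measures (fishing = positive class),
# median/MAD aggregation across gears, fishing-time percentages, and the
# sampling-interval degradation experiment.

#' Rule-based surrogate labels (speed threshold + run smoothing)
#'
#' Labels an interval `"fishing"` when its speed is below `vmax_fishing_kmh`
#' (default 7 km/h, the rule the human experts applied), then smooths with a
#' run-length morphological closing/opening: any maximal interior run shorter
#' than `min_run` intervals is flipped to its surrounding label, emulating the
#' experts' "typical shape of a fishing operation" criterion (runs touching
#' the trip edges are truncated and therefore left alone). This is an explicit
#' surrogate for human interpretation, not a reimplementation of it.
#'
#' @param series A [steps_and_angles()] series.
#' @param vmax_fishing_kmh Speed threshold, km/h.
#' @param min_run Minimum run length in intervals; runs shorter than this are
#'   flipped. Default 1 (no smoothing) unless `min_event_s` is given.
#' @param min_event_s Alternative: minimum event duration in seconds,
#'   converted to `min_run` at the series interval.
#' @return A [state_sequence()]; intervals with missing speed get `NA`.
#' @export
speed_threshold_labels <- function(series, vmax_fishing_kmh = 7,
                                   min_run = NULL, min_event_s = NULL) {
  sp <- speed_series(series)
  lab <- ifelse(is.na(sp), NA_character_,
                ifelse(sp < vmax_fishing_kmh, STATE_NAMES[1], STATE_NAMES[2]))
  if (is.null(min_run))
    min_run <- if (!is.null(min_event_s))
      max(1L, floor(min_event_s / series$interval_s)) else 1L
  if (min_run > 1L && any(!is.na(lab))) {
    repeat {
      r <- rle(lab)
      # flip sub-minimum interior runs; boundary runs are truncated by the
      # trip edges, so their true length is unknowable and they are kept
      short <- which(r$lengths < min_run & !is.na(r$values))
      short <- setdiff(short, c(1L, length(r$lengths)))
      if (length(short) == 0) break
      k <- short[which.min(r$lengths[short])]
      other <- if (r$values[k] == STATE_NAMES[1]) STATE_NAMES[2] else STATE_NAMES[1]
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      lab[starts[k]:ends[k]] <- other
    }
  }
  state_sequence(series$trip_id, lab)
}

#' Confusion matrix and the five performance measures
#'
#' Fishing is the positive class. Intervals where either labelling is missing
#' are excluded pairwise (the count of dropped intervals is reported).
#' Measures with a zero denominator are returned as `NA`, never 0:
#' accuracy = (tp+tn)/n, sensitivity = tp/(tp+fn), specificity = tn/(tn+fp),
#' f_prediction = tp/(tp+fp) (positive predictive value),
#' nf_prediction = tn/(tn+fn) (negative predictive value).
#'
#' @param truth,predicted [state_sequence()] objects or character vectors of
#'   equal length.
#' @return A one-row data.frame of class `"confusion_summary"`: `tp`, `fp`,
#'   `tn`, `fn`, `n_dropped`, `accuracy`, `sensitivity`, `specificity`,
#'   `f_prediction`, `nf_prediction`.
#' @export
confusion <- function(truth, predicted) {
  tl <- if (inherits(truth, "state_sequence")) truth$labels else truth
  pl <- if (inherits(predicted, "state_sequence")) predicted$labels else predicted
  if (length(tl) != length(pl))
    stop("truth (", length(tl), ") and predicted (", length(pl),
         ") label lengths differ")
  ok <- !is.na(tl) & !is.na(pl)
  t_f <- tl[ok] == STATE_NAMES[1]
  p_f <- pl[ok] == STATE_NAMES[1]
  tp <- sum(t_f & p_f); fn <- sum(t_f & !p_f)
  fp <- sum(!t_f & p_f); tn <- sum(!t_f & !p_f)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
                    n_dropped = sum(!ok),
                    accuracy = ratio(tp + tn, tp + tn + fp + fn),
                    sensitivity = ratio(tp, tp + fn),
                    specificity = ratio(tn, tn + fp),
                    f_prediction = ratio(tp, tp + fp),
                    nf_prediction = ratio(tn, tn + fn))
  class(out) <- c("confusion_summary", "data.frame")
  out
}

MEASURE_NAMES <- c("accuracy", "sensitivity", "specificity",
                   "f_prediction", "nf_prediction")

#' Median and MAD across gears
#'
#' Aggregates per-gear performance summaries the way the study's tables do:
#' per measure, the median and the median absolute deviation from it
#' (unscaled, `median(|x - median(x)|)`); missing values dropped per measure.
#'
#' @param summaries List of [confusion()] rows (or a data.frame of them).
#' @return data.frame with columns `measure`, `median`, `mad`, `n`.
#' @export
aggregate_median_mad <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  df <- if (is.data.frame(summaries)) summaries else do.call(rbind, summaries)
  do.call(rbind, lapply(MEASURE_NAMES, function(m) {
    x <- df[[m]][!is.na(df[[m]])]
    data.frame(measure = m,
               median = if (length(x)) median(x) else NA_real_,
               mad = if (length(x)) mad(x, constant = 1) else NA_real_,
               n = length(x))
  }))
}

#' Percentage of labelled time spent fishing
#'
#' @param labels A [state_sequence()] or character vector.
#' @return `100 * fishing intervals / labelled intervals`.
#' @export
percent_time_fishing <- function(labels) {
  l <- if (inherits(labels, "state_sequence")) labels$labels else labels
  l <- l[!is.na(l)]
  if (length(l) == 0) stop("no labelled intervals")
  100 * mean(l == STATE_NAMES[1])
}

#' Maximum GPS sampling interval for a fishing event
#'
#' An event must span at least `min_points` positions to contribute steps and
#' turning angles, so the largest usable sampling interval for events of at
#' least `min_event_s` seconds is `floor(min_event_s / min_points)`. With the
#' shortest events (10-minute handline operations) and the 3 points angle
#' computation requires, this gives the 200-s ceiling.
#'
#' @param min_event_s Shortest fishing event, seconds.
#' @param min_points Minimum positions per event (default 3).
#' @return Maximum sampling interval, seconds.
#' @export
max_interval_for_event <- function(min_event_s, min_points = 3) {
  stopifnot(min_event_s > 0, min_points >= 2)
  floor(min_event_s / min_points)
}

#' The default degradation grid
#'
#' 10–60 s in 10-s increments plus 2–10 minutes in 60-s increments: 15
#' settings.
#'
#' @return Integer vector of intervals in seconds.
#' @export
default_sweep_intervals <- function() {
  c(seq(10L, 60L, by = 10L), seq(120L, 600L, by = 60L))
}

#' Sampling-interval degradation experiment
#'
#' For each interval in the grid: decimate every trip from the base interval,
#' recompute step/angle series and reference labels (majority vote within each
#' coarse interval), refit the HMM per gear (initialised from the reference
#' labels at that interval, mirroring the original procedure of fitting to
#' regularized data at each resolution), decode with Viterbi, and score pooled
#' per-gear confusion measures against the reference labels.
#'
#' @param fleet List of simulated trips (from [simulate_fleet()]) or trips
#'   carrying `$truth` state sequences at the base interval.
#' @param intervals_s Interval grid, seconds; every value must be a multiple
#'   of the base interval. Default [default_sweep_intervals()].
#' @param base_interval_s Base interval of the fleet (default 5 s).
#' @param fit_opts List of options passed to [fit_hmm()].
#' @param use_truth_predictor Diagnostic mode: score the reference labels
#'   against themselves instead of the HMM decode (plumbing check; all
#'   measures must be 1).
#' @return A `"metric_table"` data.frame with columns `gear`, `interval_s`,
#'   `measure`, `value`; aggregate rows have `gear = "median"` / `"mad"`.
#' @export
interval_sweep <- function(fleet, intervals_s = default_sweep_intervals(),
                           base_interval_s = 5, fit_opts = list(),
                           use_truth_predictor = FALSE) {
  if (any(intervals_s %% base_interval_s != 0))
    stop("every interval must be a multiple of the base interval (",
         base_interval_s, " s)")
  gears <- unique(vapply(fleet, function(tr) tr$gear, character(1)))
  rows <- list()
  for (iv in intervals_s) {
    k <- iv %/% base_interval_s
    dec <- lapply(fleet, function(tr) {
      d <- decimate(tr, k)
      list(series = steps_and_angles(d),
           ref = state_sequence(tr$trip_id,
                                decimate_labels(tr$truth$labels, k)))
    })
    for (g in gears) {
      sel <- dec[vapply(fleet, function(tr) identical(tr$gear, g), logical(1))]
      series <- lapply(sel, `[[`, "series")
      refs <- lapply(sel, `[[`, "ref")
      if (use_truth_predictor) {
        preds <- refs
      } else {
        init <- initial_params_from_labels(series, refs)
        fit <- do.call(fit_hmm, c(list(series = series, init = init), fit_opts))
        preds <- lapply(series, viterbi_decode, params = fit$params)
      }
      cs <- confusion(unlist(lapply(refs, `[[`, "labels")),
                      unlist(lapply(preds, `[[`, "labels")))
      for (m in MEASURE_NAMES)
        rows[[length(rows) + 1]] <-
          data.frame(gear = g, interval_s = iv, measure = m, value = cs[[m]])
    }
    per_gear <- do.call(rbind, rows)
    per_gear <- per_gear[per_gear$interval_s == iv, ]
    for (m in MEASURE_NAMES) {
      x <- per_gear$value[per_gear$measure == m]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1]] <-
        data.frame(gear = "median", interval_s = iv, measure = m,
                   value = if (length(x)) median(x) else NA_real_)
      rows[[length(rows) + 1]] <-
        data.frame(gear = "mad", interval_s = iv, measure = m,
                   value = if (length(x)) mad(x, constant = 1) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_table", "data.frame")
  out
}

#' Two-means separation diagnostic for speed bimodality
#'
#' Splits a speed sample into two clusters (k-means seeded at the lower/upper
#' quartiles, deterministic) and reports the cluster-centre separation in
#' units of the pooled within-cluster standard deviation. A ratio above 2
#' indicates clearly bimodal speeds.
#'
#' @param speeds_kmh Numeric vector of speeds.
#' @return List with `centers` (sorted), `pooled_sd`, `separation_ratio`.
#' @export
speed_mode_separation <- function(speeds_kmh) {
  x <- speeds_kmh[!is.na(speeds_kmh)]
  stopifnot(length(x) >= 10)
  km <- kmeans(x, centers = matrix(unname(quantile(x, c(0.25, 0.75))), 2, 1))
  o <- order(km$centers)
  v <- vapply(o, function(j) {
    xi <- x[km$cluster == j]
    if (length(xi) > 1) var(xi) else 0
  }, numeric(1))
  pooled <- sqrt(mean(v))
  list(centers = as.numeric(km$centers[o]),
       pooled_sd = pooled,
       separation_ratio = diff(as.numeric(km$centers[o])) / pooled)
}
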