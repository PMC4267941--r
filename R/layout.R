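#' Sampling layout of a diel expression time course
#'
#' Describes how an expression matrix is sampled in time: the interval between
#' consecutive samples, the day (cycle) length, the number of appended days and
#' the length of the light period. The default layout mirrors a common diel
#' RNA-seq design: samples every 3 h across one 24-h light/dark cycle (ZT 0,
#' 3, ..., 21), with two biological replicates appended as two consecutive
#' days, giving 16 columns.
#'
#' @param interval_hours Hours between consecutive samples (default 3).
#' @param day_length_hours Length of one full cycle in hours (default 24).
#'   Must be an integer multiple of `interval_hours`.
#' @param n_days Number of appended days/replicates (default 2).
#' @param light_hours Length of the light period in hours (default 12);
#'   informational only.
#' @return An object of class `sampling_layout`: a list with the four fields
#'   above plus `points_per_day` and `n_samples`.
#' @examples
#' lay <- sampling_layout()
#' lay$n_samples      # 16
#' sample_times(lay)  # 0, 3, ..., 45
#' @export
sampling_layout <- function(interval_hours = 3, day_length_hours = 24,
                            n_days = 2, light_hours = 12) {
  stopifnot(interval_hours > 0, day_length_hours > 0, n_days >= 1,
            light_hours >= 0)
  ppd <- day_length_hours / interval_hours
  if (abs(ppd - round(ppd)) > 1e-9)
    stop("day_length_hours must be an integer multiple of interval_hours")
  ppd <- as.integer(round(ppd))
  structure(list(interval_hours = interval_hours,
                 day_length_hours = day_length_hours,
                 n_days = as.integer(n_days),
                 light_hours = light_hours,
                 points_per_day = ppd,
                 n_samples = ppd * as.integer(n_days)),
            class = "sampling_layout")
}

#' @rdname sampling_layout
#' @param layout A `sampling_layout`.
#' @return `sample_times()`: numeric vector of absolute sampling times in
#'   hours from the first sample (0, interval, 2*interval, ...).
#' @export
sample_times <- function(layout) {
  seq(0, by = layout$interval_hours, length.out = layout$n_samples)
}

#' @rdname sampling_layout
#' @return `sample_zt()`: Zeitgeber time (hours since dawn, modulo day length)
#'   of each sample.
#' @export
sample_zt <- function(layout) {
  sample_times(layout) %% layout$day_length_hours
}

#' @rdname sampling_layout
#' @return `sample_labels()`: character labels `ZT<h>_day<d>` used as column
#'   names of expression matrices.
#' @export
sample_labels <- function(layout) {
  zt <- sample_zt(layout)
  day <- rep(seq_len(layout$n_days), each = layout$points_per_day)
  sprintf("ZT%g_day%d", zt, day)
}

#' @rdname sampling_layout
#' @return `zt_bins()`: the day's ZT bins (0, interval, ..., day length -
#'   interval), the possible phase-cluster labels.
#' @export
zt_bins <- function(layout) {
  seq(0, layout$day_length_hours - layout$interval_hours,
      by = layout$interval_hours)
}

#' @export
print.sampling_layout <- function(x, ...) {
  cat(sprintf(
    "sampling_layout: every %g h over %d day(s) of %g h (%d samples; %g h light)\n",
    x$interval_hours, x$n_days, x$day_length_hours, x$n_samples,
    x$light_hours))
  invisible(x)
}
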