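# Stimulus-locked global mean field power over an electrode subset, interval
# band power, and baseline-normalized condition ratios.

#' Global mean field power of an evoked response
#'
#' Epochs are averaged into the evoked response; GMFP at each time point is
#' the root-mean-square deviation from the instantaneous mean over the
#' electrode subset (Lehmann-Skrandies field power,
#' `sqrt(mean((v_i - mean(v))^2))`). The default window spans -0.25 to 2 s
#' around the stimulus.
#'
#' @param ep an [epochs()] object.
#' @param electrode_subset channel labels to pool (default: all channels; a
#'   conventional 16-electrode frontal set is available from
#'   [frontal_electrodes_1010()]).
#' @param window `c(from, to)` in seconds relative to the stimulus.
#' @return object of class `gmfp_trace`: data.frame with columns `time` and
#'   `gmfp`, with the subset and window as attributes.
#' @export
gmfp <- function(ep, electrode_subset = NULL, window = c(-0.25, 2)) {
  stopifnot(inherits(ep, "epochs"))
  if (is.null(electrode_subset)) electrode_subset <- ep$channel_labels
  missing_ch <- setdiff(electrode_subset, ep$channel_labels)
  if (length(missing_ch))
    stop("missing electrodes: ", paste(missing_ch, collapse = ", "))
  if (window[1] < min(ep$time) - 1e-9 || window[2] > max(ep$time) + 1e-9)
    stop(sprintf("window [%g, %g] s outside the epoch [%g, %g] s",
                 window[1], window[2], min(ep$time), max(ep$time)))
  evoked <- apply(ep$data, c(1, 2), mean)
  sel_ch <- match(electrode_subset, ep$channel_labels)
  sel_t <- which(ep$time >= window[1] - 1e-9 & ep$time <= window[2] + 1e-9)
  v <- evoked[sel_ch, sel_t, drop = FALSE]
  g <- sqrt(colMeans(v^2) - colMeans(v)^2)
  out <- data.frame(time = ep$time[sel_t], gmfp = g)
  attr(out, "electrode_subset") <- electrode_subset
  attr(out, "window") <- window
  attr(out, "fs") <- ep$fs
  class(out) <- c("gmfp_trace", "data.frame")
  out
}

#' Mean band power of a series over an interval
#'
#' Hann-windowed periodogram of the (mean-subtracted) interval, summed over
#' the in-band one-sided bins; for an in-band sinusoid of amplitude `a` the
#' result is its mean power `a^2 / 2`.
#'
#' @param x numeric series, a single-channel [recording()], or a
#'   `gmfp_trace`.
#' @param band `c(low, high)` in Hz.
#' @param fs sampling rate; taken from the input object when available.
#' @param interval optional `c(from, to)` in seconds restricting the
#'   analysis (relative to the object's time axis, or to 0 for bare series).
#' @return scalar band power (signal-variance units).
#' @export
band_power <- function(x, band, fs = NULL, interval = NULL) {
  if (inherits(x, "gmfp_trace")) {
    time <- x$time; fs <- attr(x, "fs"); x <- x$gmfp
  } else if (inherits(x, "recording")) {
    fs <- x$fs; x <- as.numeric(x$data[1, ]); time <- (seq_along(x) - 1) / fs
  } else {
    if (is.null(fs)) stop("fs required for a bare series")
    time <- (seq_along(x) - 1) / fs
  }
  if (!is.null(interval)) {
    if (interval[1] < min(time) - 1e-9 || interval[2] > max(time) + 1e-9)
      stop("interval outside the data")
    x <- x[time >= interval[1] - 1e-9 & time <= interval[2] + 1e-9]
  }
  n <- length(x)
  if (n < 8) stop("interval too short for band power")
  if (band[1] >= band[2] || band[2] > fs / 2) stop("invalid band")
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  X <- stats::fft((x - mean(x)) * w)
  nf <- n %/% 2 + 1
  pw <- 2 * Mod(X[seq_len(nf)])^2 / (n * sum(w^2))
  pw[1] <- pw[1] / 2
  if (n %% 2 == 0) pw[nf] <- pw[nf] / 2
  freqs <- (seq_len(nf) - 1) * fs / n
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  sum(pw[sel])
}

#' Baseline-normalized condition ratio
#'
#' `ratio = (cond / baseline) / (other_cond / other_baseline)`: each
#' condition's band power is first normalized to its own baseline power, and
#' the two normalized values are compared. Invariant to any unit shared by
#' all four powers.
#'
#' @param cond_power,baseline_power band power and baseline band power for
#'   the numerator condition.
#' @param other_cond_power,other_baseline_power same for the denominator
#'   condition.
#' @param conditions labels of the two conditions (e.g. `c("CS+", "CS-")`).
#' @param band optional band annotation (Hz).
#' @return object of class `band_ratio` with the `ratio` and metadata.
#' @export
condition_ratio <- function(cond_power, baseline_power, other_cond_power,
                            other_baseline_power,
                            conditions = c("CS+", "CS-"), band = NULL) {
  pows <- c(cond_power, baseline_power, other_cond_power, other_baseline_power)
  if (any(!is.finite(pows)) || any(pows <= 0))
    stop("all powers must be positive and finite")
  structure(list(ratio = (cond_power / baseline_power) /
                   (other_cond_power / other_baseline_power),
                 numerator_condition = conditions[1],
                 denominator_condition = conditions[2], band = band),
            class = "band_ratio")
}

#' @export
print.band_ratio <- function(x, ...) {
  cat(sprintf("<band_ratio> %s / %s%s = %.4f (baseline-normalized)\n",
              x$numerator_condition, x$denominator_condition,
              if (is.null(x$band)) "" else sprintf(" [%g-%g Hz]", x$band[1], x$band[2]),
              x$ratio))
  invisible(x)
}
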