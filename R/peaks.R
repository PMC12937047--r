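## Chromatogram peak measurement: area/height above a local linear baseline,
## flanking-window noise amplitude, and signal-to-noise.

#' Integrate a chromatographic peak
#'
#' Trapezoidal area above a linear baseline drawn between the window
#' endpoints; height is the maximum baseline-subtracted signal in the window.
#' Adding a constant offset to the trace therefore changes neither value.
#'
#' @param time,intensity Numeric vectors of equal length (minutes,
#'   intensity).
#' @param window `c(start, end)` in minutes; must contain at least 3 points.
#' @return Named numeric: `area` (intensity x min), `height` (intensity).
#' @examples
#' t <- seq(5.2, 6.0, by = 0.002)
#' y <- dnorm(t, 5.6, 0.05)                       # unit-area Gaussian
#' integratePeak(t, y, c(5.4, 5.8))               # area ~ 1, height ~ 7.98
#' @export
integratePeak <- function(time, intensity, window) {
  stopifnot(length(time) == length(intensity), length(window) == 2L,
            window[1] < window[2])
  sel <- which(time >= window[1] & time <= window[2])
  if (length(sel) < 3L)
    stop("integration window contains fewer than 3 points")
  t <- time[sel]
  y <- intensity[sel]
  n <- length(t)
  baseline <- y[1] + (y[n] - y[1]) * (t - t[1]) / (t[n] - t[1])
  corrected <- y - baseline
  c(area = pracma::trapz(t, corrected), height = max(corrected))
}

#' Estimate the baseline noise amplitude around a peak
#'
#' Mean of the peak-to-peak excursions of the two windows flanking the peak,
#' halved to an amplitude about the local baseline. With uniform noise on
#' `[-a, a]` the estimate converges to `a`. A flank truncated by the trace
#' edge triggers a warning and a one-sided estimate.
#'
#' @param time,intensity The trace.
#' @param peakWindow `c(start, end)` of the peak (minutes).
#' @param flankWidth Width of each flanking window (minutes).
#' @return Noise amplitude (intensity units).
#' @export
estimateNoise <- function(time, intensity, peakWindow, flankWidth = 0.5) {
  stopifnot(length(peakWindow) == 2L, flankWidth > 0)
  left <- which(time >= peakWindow[1] - flankWidth & time < peakWindow[1])
  right <- which(time > peakWindow[2] & time <= peakWindow[2] + flankWidth)
  amp <- function(idx) (max(intensity[idx]) - min(intensity[idx])) / 2
  eps <- 1e-9
  fullL <- length(left) >= 2L && min(time) <= peakWindow[1] - flankWidth + eps
  fullR <- length(right) >= 2L && max(time) >= peakWindow[2] + flankWidth - eps
  if (!fullL && !fullR)
    stop("no full flanking baseline window on either side of the peak")
  if (!fullL || !fullR) {
    warning("flanking window truncated by trace edge; one-sided noise estimate")
    return(if (fullL) amp(left) else amp(right))
  }
  mean(c(amp(left), amp(right)))
}

#' Signal-to-noise ratio
#'
#' Peak height divided by the baseline noise amplitude.
#'
#' @param height Peak height.
#' @param noise Baseline noise amplitude.
#' @return S/N (dimensionless); `Inf` with a warning when `noise` is 0.
#' @export
signalToNoise <- function(height, noise) {
  stopifnot(height >= 0, noise >= 0)
  if (noise == 0) {
    warning("zero baseline noise; S/N is infinite")
    return(Inf)
  }
  height / noise
}

#' Measure every peak in a set of rendered traces
#'
#' Applies [integratePeak()], [estimateNoise()] and [signalToNoise()] to each
#' sample/channel trace using fixed windows around the configured retention
#' times (the three channels are known; peak detection is out of scope).
#'
#' @param traces Long trace `data.frame` from [renderChromatograms()] (or
#'   read from CSV): columns `sample_id`, `channel`, `time_min`, `intensity`.
#' @param errors An [ErrorModel-class] supplying retention times and peak
#'   width.
#' @param halfWindow Integration half-window (minutes); default 4 peak
#'   sigmas.
#' @param flankWidth Noise flank width (minutes).
#' @return `data.frame`: `sample_id`, `channel`, `area`, `height`,
#'   `noise`, `snr`.
#' @export
measurePeaks <- function(traces, errors = ErrorModel(),
                         halfWindow = 4 * errors@peakWidthSigma,
                         flankWidth = 0.3) {
  stopifnot(all(c("sample_id", "channel", "time_min", "intensity")
                %in% names(traces)))
  keys <- unique(traces[, c("sample_id", "channel")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    tr <- traces[traces$sample_id == keys$sample_id[i] &
                 traces$channel == keys$channel[i], ]
    rt <- errors@retentionTimes[[keys$channel[i]]]
    win <- c(rt - halfWindow, rt + halfWindow)
    ah <- integratePeak(tr$time_min, tr$intensity, win)
    noise <- estimateNoise(tr$time_min, tr$intensity, win, flankWidth)
    snr <- if (noise > 0) ah[["height"]] / noise else Inf
    out[[i]] <- data.frame(sample_id = keys$sample_id[i],
                           channel = keys$channel[i], area = ah[["area"]],
                           height = ah[["height"]], noise = noise, snr = snr)
  }
  do.call(rbind, out)
}
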