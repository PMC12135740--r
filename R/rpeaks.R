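#' Construct a raw single-lead ECG
#'
#' @param fs sampling frequency in Hz (> 0).
#' @param samples numeric vector of millivolt values, at least 1 s long.
#' @param lead_label free-text lead label.
#' @export
raw_ecg <- function(fs, samples, lead_label = "base-apex") {
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (length(samples) < fs) stop("signal must be at least 1 s", call. = FALSE)
  structure(list(fs = fs, samples = as.numeric(samples),
                 lead_label = lead_label), class = "raw_ecg")
}

#' Read / write a raw ECG CSV with JSON sidecar
#'
#' The signal lives in a two-column CSV (`t_ms,mv`); sampling rate and lead
#' label travel in a sidecar JSON (`<path>.json`) so the CSV stays a plain
#' sampled-signal file.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @export
read_raw_ecg <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"))
  df <- utils::read.csv(path)
  raw_ecg(fs = side$fs, samples = df$mv, lead_label = side$lead_label)
}

#' @rdname read_raw_ecg
#' @param ecg a [raw_ecg()].
#' @export
write_raw_ecg <- function(ecg, path) {
  t_ms <- round((seq_along(ecg$samples) - 1) / ecg$fs * 1000)
  utils::write.csv(data.frame(t_ms = t_ms, mv = ecg$samples), path,
                   row.names = FALSE, quote = FALSE, eol = "\n")
  jsonlite::write_json(list(fs = ecg$fs, lead_label = ecg$lead_label),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# moving-average smoother, centred, via stats::filter
moving_avg <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  y <- stats::filter(x, rep(1 / k, k), sides = 2)
  y <- as.numeric(y)
  y[is.na(y)] <- x[is.na(y)]
  y
}

#' Detect R peaks in a raw single-lead ECG
#'
#' Band-limits the signal to the QRS band (difference of moving averages
#' approximating a 5--40 Hz band-pass), squares it, then picks local
#' maxima above an adaptive threshold with a refractory period.
#' Intended for device-free testing, not as a clinical-grade detector.
#'
#' @param ecg a [raw_ecg()].
#' @param min_rr_ms refractory period in ms (default 250, i.e. 240 bpm).
#' @return strictly increasing beat times in ms. A flat (zero-variance)
#'   signal yields an empty result with a warning.
#' @export
detect_r_peaks <- function(ecg, min_rr_ms = 250) {
  x <- ecg$samples
  if (stats::sd(x) == 0) {
    warning("flat ECG signal; no peaks detected")
    return(numeric(0))
  }
  fs <- ecg$fs
  # high-pass ~5 Hz: subtract a 200 ms moving average;
  # low-pass ~40 Hz: 25 ms moving average
  hp <- x - moving_avg(x, fs * 0.2)
  bp <- moving_avg(hp, fs * 0.025)
  e <- bp^2
  thr <- 0.2 * max(e)
  refr <- round(min_rr_ms / 1000 * fs)
  n <- length(e)
  peaks <- integer(0)
  last <- -Inf
  i <- 2L
  while (i < n) {
    if (e[i] >= thr && e[i] >= e[i - 1] && e[i] >= e[i + 1]) {
      if (i - last >= refr) {
        peaks <- c(peaks, i)
        last <- i
      } else if (e[i] > e[last]) {
        peaks[length(peaks)] <- i   # keep the larger of two close peaks
        last <- i
      }
    }
    i <- i + 1L
  }
  (peaks - 1) / fs * 1000
}
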