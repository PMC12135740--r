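#' Segment fast heart-rate deceleration phases
#'
#' "Fast deceleration" is not numerically defined in the exercise
#' literature; the operational default used here (and reported with every
#' result) is: starting from a smoothed-HR local maximum of at least
#' `min_peak_bpm`, the smoothed HR falls by `drop_bpm` or more within
#' `window_s` seconds. The segment runs from the peak until the smoothed
#' downward slope first flattens above -0.1 bpm/s (or the recording
#' ends). Instantaneous HR (60000/RR) is resampled to a 1 Hz grid and
#' smoothed with a rolling median of span `smooth_s`.
#'
#' @param t a [tachogram()].
#' @param drop_bpm minimum HR drop in beats/min (default 30).
#' @param window_s window in which the drop must occur (default 60).
#' @param smooth_s rolling-median span in seconds (default 10).
#' @param min_peak_bpm minimum HR at the segment start (default 120).
#' @return data.frame of segments: `start_ms`, `end_ms`, `hr_drop`
#'   (beats/min), `drop_rate` (beats/min per s).
#' @export
segment_deceleration <- function(t, drop_bpm = 30, window_s = 60,
                                 smooth_s = 10, min_peak_bpm = 120) {
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      hr_drop = numeric(0), drop_rate = numeric(0))
  bt <- t$beat_time_ms
  span_s <- (bt[length(bt)] - bt[1]) / 1000
  if (span_s < 120) return(empty)
  ok <- !rr_artifact(t)
  if (sum(ok) < 10) return(empty)
  hr <- 60000 / t$rr_ms[ok]
  tt <- (bt[-1][ok] - bt[1]) / 1000          # s from start, terminating beats
  grid <- seq(0, floor(span_s))
  hr_g <- stats::approx(tt, hr, xout = grid, rule = 2)$y
  k <- max(3L, as.integer(smooth_s))
  if (k %% 2 == 0) k <- k + 1L
  sm <- stats::runmed(hr_g, k)
  n <- length(sm)
  if (n < window_s + 2) return(empty)
  out <- empty
  i <- 2L
  while (i < n) {
    is_peak <- sm[i] >= sm[i - 1] && sm[i] >= sm[i + 1] &&
      sm[i] >= min_peak_bpm
    if (is_peak) {
      horizon <- min(n, i + window_s)
      j_min <- i + which.min(sm[(i + 1):horizon])
      if (sm[i] - sm[j_min] >= drop_bpm) {
        # advance the start past any peak plateau to the decline onset
        s0 <- i
        while (s0 < j_min && sm[s0 + 1L] >= sm[i] - 2) s0 <- s0 + 1L
        # extend past the drop until the slope flattens (> -0.1 bpm/s over 5 s)
        j <- j_min
        while (j + 5 <= n && (sm[j + 5] - sm[j]) / 5 <= -0.1) j <- j + 1L
        out <- rbind(out, data.frame(
          start_ms = bt[1] + grid[s0] * 1000,
          end_ms = bt[1] + grid[j] * 1000,
          hr_drop = sm[i] - min(sm[i:j]),
          drop_rate = (sm[i] - min(sm[i:j])) / max(1, grid[j] - grid[s0])))
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  # merge overlapping segments
  if (nrow(out) > 1) {
    keep <- out[1, , drop = FALSE]
    for (k2 in 2:nrow(out)) {
      last <- nrow(keep)
      if (out$start_ms[k2] <= keep$end_ms[last]) {
        keep$end_ms[last] <- max(keep$end_ms[last], out$end_ms[k2])
        keep$hr_drop[last] <- max(keep$hr_drop[last], out$hr_drop[k2])
      } else keep <- rbind(keep, out[k2, ])
    }
    out <- keep
  }
  out
}
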