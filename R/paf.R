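#' Detect paroxysmal atrial fibrillation segments
#'
#' Operationalises the "irregularly irregular" AF signature on the
#' tachogram: a maximal stretch of at least `min_beats` consecutive
#' non-artifact beats is a pAF segment when (a) every beat is covered by
#' a rolling window of `min_beats` RR intervals whose coefficient of
#' variation exceeds `cv_threshold`, (b) the lag-1 autocorrelation of RR
#' within the stretch is small in absolute value (`< max_lag1`), and (c)
#' the irregularity is sustained: at least `min_delta_frac` of successive
#' RR differences within the stretch exceed 5% of the local mean.
#' Condition (b) rejects patterned alternation such as bigeminy, whose
#' CV is high but whose RR sequence is strongly (negatively)
#' autocorrelated; condition (c) rejects isolated ectopy (a premature
#' run raises the rolling CV via two or three level shifts, whereas
#' fibrillation changes cycle length at nearly every beat).
#'
#' @param t a [tachogram()].
#' @param min_beats minimum segment length in beats (default 12).
#' @param cv_threshold rolling-CV threshold (default 0.10).
#' @param max_lag1 absolute lag-1 autocorrelation bound (default 0.3).
#' @param min_delta_frac minimum fraction of successive RR differences
#'   exceeding 5% of the segment mean (default 0.5).
#' @return data.frame of segments: `start_beat`, `end_beat`, `start_ms`,
#'   `end_ms`, `cv`, `lag1`.
#' @export
detect_paf <- function(t, min_beats = 12, cv_threshold = 0.10,
                       max_lag1 = 0.3, min_delta_frac = 0.5) {
  rr <- t$rr_ms
  art <- rr_artifact(t)
  m <- length(rr)
  empty <- data.frame(start_beat = integer(0), end_beat = integer(0),
                      start_ms = numeric(0), end_ms = numeric(0),
                      cv = numeric(0), lag1 = numeric(0))
  if (m < min_beats) return(empty)
  # rolling CV over windows of min_beats RRs, within non-artifact runs
  pass <- rep(FALSE, m - min_beats + 1L)
  cs <- cumsum(rr); cs2 <- cumsum(rr^2); bad <- cumsum(art)
  for (s in seq_len(m - min_beats + 1L)) {
    e <- s + min_beats - 1L
    if ((bad[e] - c(0, bad)[s]) > 0) next
    sx <- cs[e] - c(0, cs)[s]
    sx2 <- cs2[e] - c(0, cs2)[s]
    mu <- sx / min_beats
    v <- sx2 / min_beats - mu^2
    if (v < 0) v <- 0
    pass[s] <- sqrt(v) / mu > cv_threshold
  }
  # a beat belongs to a candidate segment when some passing window covers
  # it; overlapping passing windows merge into one maximal segment
  covered <- rep(FALSE, m)
  for (s in which(pass)) covered[s:(s + min_beats - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- empty
  for (k in which(r$values & r$lengths >= min_beats)) {
    s <- starts[k]; e <- ends[k]
    seg <- rr[s:e]
    mu <- mean(seg)
    cv <- stats::sd(seg) / mu
    lag1 <- if (length(seg) > 2 && stats::sd(seg) > 0)
      stats::cor(seg[-1], seg[-length(seg)]) else 0
    delta_frac <- mean(abs(diff(seg)) > 0.05 * mu)
    if (cv > cv_threshold && abs(lag1) < max_lag1 &&
        delta_frac >= min_delta_frac) {
      out <- rbind(out, data.frame(
        start_beat = s + 1L, end_beat = e + 1L,   # RR i terminates beat i+1
        start_ms = t$beat_time_ms[s], end_ms = t$beat_time_ms[e + 1L],
        cv = cv, lag1 = lag1))
    }
  }
  out
}
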