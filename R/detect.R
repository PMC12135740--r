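#' Local reference RR interval
#'
#' The "surrounding RR average" against which a candidate interval is
#' judged: the median (or mean) of up to `window` nearest eligible RR
#' values, excluding the candidate itself, balanced before/after where
#' possible. Eligible means not artifact and not already labelled
#' premature.
#'
#' @param rr_series numeric RR intervals in ms.
#' @param index candidate position in `rr_series`.
#' @param window maximum number of neighbours (default 11).
#' @param eligible logical mask of usable neighbours (default all).
#' @param statistic `"median"` (default) or `"mean"`.
#' @return reference RR in ms, or `NA` when fewer than 3 usable
#'   neighbours exist.
#' @export
local_reference <- function(rr_series, index, window = 11,
                            eligible = rep(TRUE, length(rr_series)),
                            statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  vals <- neighbour_values(rr_series, index, window, eligible)
  if (length(vals) < 3) return(NA_real_)
  if (statistic == "median") stats::median(vals) else mean(vals)
}

# Nearest eligible neighbours of `index`, excluding the candidate,
# collected by expanding radius so the window stays balanced where the
# series allows; at the final radius extras are trimmed from the side
# holding more values.
neighbour_values <- function(rr_series, index, window, eligible) {
  n <- length(rr_series)
  left <- numeric(0); right <- numeric(0)
  r <- 1L
  while (length(left) + length(right) < window) {
    li <- index - r; ri <- index + r
    got <- FALSE
    if (li >= 1 && eligible[li]) { left <- c(rr_series[li], left); got <- TRUE }
    if (ri <= n && eligible[ri]) { right <- c(right, rr_series[ri]); got <- TRUE }
    if (li < 1 && ri > n) break
    r <- r + 1L
  }
  k <- length(left) + length(right)
  while (k > window) {
    if (length(left) >= length(right)) left <- left[-1]
    else right <- right[-length(right)]
    k <- k - 1L
  }
  c(left, right)
}

#' Flag RR intervals deviating from the local reference
#'
#' Implements the operative premature-complex criterion: an RR interval is
#' flagged when it deviates 5% or more (`threshold`) from the surrounding
#' RR reference. The sign is retained: negative deviations are short
#' (premature candidates), positive ones long (pauses / return cycles).
#' References are recomputed iteratively so that beats already flagged as
#' premature are excluded from their neighbours' references (as a manual
#' reader would exclude obvious ectopy from the "surrounding average").
#'
#' @param t a [tachogram()].
#' @param threshold relative deviation threshold (default 0.05, boundary
#'   inclusive: exactly 5% is flagged).
#' @param window see [local_reference()].
#' @param statistic reference statistic, `"median"` or `"mean"`.
#' @param threshold_mode `"relative"` (default; threshold applies to the
#'   deviation as a fraction of the local reference) or
#'   `"absolute_at_peak"` (threshold is `threshold` times the RR at the
#'   recording's peak heart rate, applied as an absolute ms cut).
#' @param max_iter cap on reference-refinement passes (default 20; the
#'   loop stops at a fixed point, and each pass after the first only
#'   recomputes references near beats whose eligibility changed -- long
#'   runs are peeled from their edges at one to two beats per pass, so
#'   the cap comfortably covers any run the event grammar recognises).
#' @return data.frame with one row per RR interval: `beat` (index of the
#'   terminating beat in the tachogram), `rr`, `ref`, `deviation`
#'   (signed, relative to `ref`), `flagged`, `artifact`,
#'   `ref_undefined`.
#' @export
flag_deviants <- function(t, threshold = 0.05, window = 11,
                          statistic = c("median", "mean"),
                          threshold_mode = c("relative", "absolute_at_peak"),
                          max_iter = 20) {
  statistic <- match.arg(statistic)
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(threshold > 0)
  rr <- t$rr_ms
  m <- length(rr)
  artifact <- rr_artifact(t)
  premature <- rep(FALSE, m)
  prev_premature <- NULL
  ref <- rep(NA_real_, m)
  abs_cut <- NULL
  rmax <- max(abs(window_offsets(window)))
  for (it in seq_len(max_iter)) {
    eligible <- !artifact & !premature
    if (is.null(prev_premature)) {
      ref <- reference_series(rr, eligible, window, statistic)
    } else {
      # only beats whose window saw an eligibility change need new refs
      changed <- which(premature != prev_premature)
      if (!length(changed)) break
      aff <- unique(unlist(lapply(changed, function(i)
        max(1L, i - window - 1L):min(m, i + window + 1L))))
      for (i in aff)
        ref[i] <- local_reference(rr, i, window, eligible, statistic)
    }
    if (threshold_mode == "absolute_at_peak" && is.null(abs_cut)) {
      # RR at peak HR: shortest plausibly-sinus RR (robust: 1st percentile
      # of eligible RR after smoothing)
      sm <- stats::runmed(rr[eligible], 5)
      abs_cut <- threshold * min(sm)
    }
    dev <- (rr - ref) / ref
    if (threshold_mode == "relative") {
      new_prem <- !artifact & !is.na(dev) & dev <= -threshold
    } else {
      new_prem <- !artifact & !is.na(ref) & (ref - rr) >= abs_cut
    }
    # Block extension: inside a long run the balanced window is majority
    # ectopy, so the median sticks to the run value and per-beat flagging
    # stalls after the edges. A detected beat's reference is a cleaner
    # sinus estimate for its immediate neighbours, so a neighbour that is
    # also >= threshold short of it joins the block; the next pass
    # recomputes every affected reference with the block excluded, and
    # the converged flags are self-consistent with their own references.
    new_prem <- extend_flags(rr, new_prem, ref, artifact, threshold,
                             threshold_mode, abs_cut)
    if (identical(new_prem, premature)) break
    prev_premature <- premature
    premature <- new_prem
  }
  dev <- (rr - ref) / ref
  if (threshold_mode == "relative") {
    flagged <- !artifact & !is.na(dev) & abs(dev) >= threshold
  } else {
    flagged <- !artifact & !is.na(ref) & abs(rr - ref) >= abs_cut
  }
  data.frame(beat = seq_len(m) + 1L, rr = rr, ref = ref, deviation = dev,
             flagged = flagged, artifact = artifact,
             ref_undefined = is.na(ref))
}

extend_flags <- function(rr, prem, ref, artifact, threshold,
                         threshold_mode = "relative", abs_cut = NULL) {
  m <- length(rr)
  short_of <- function(j, r) {
    if (threshold_mode == "relative") rr[j] <= r * (1 - threshold)
    else (r - rr[j]) >= abs_cut
  }
  repeat {
    changed <- FALSE
    for (i in which(prem)) {
      if (is.na(ref[i])) next
      for (j in c(i - 1L, i + 1L)) {
        if (j >= 1 && j <= m && !prem[j] && !artifact[j] &&
            short_of(j, ref[i])) {
          prem[j] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) return(prem)
  }
}

# Neighbour offsets the expansion rule selects for an interior index of a
# fully eligible series; used by the vectorised fast path.
window_offsets <- function(window) {
  left <- integer(0); right <- integer(0); r <- 1L
  while (length(left) + length(right) < window) {
    left <- c(-r, left); right <- c(right, r); r <- r + 1L
  }
  while (length(left) + length(right) > window) {
    if (length(left) >= length(right)) left <- left[-1]
    else right <- right[-length(right)]
  }
  c(left, right)
}

# Reference for every index. Interior indices whose full neighbourhood is
# eligible take a vectorised path; edges and indices near ineligible beats
# fall back to the exact per-index rule (identical result by construction).
reference_series <- function(rr, eligible, window, statistic) {
  m <- length(rr)
  ref <- rep(NA_real_, m)
  off <- window_offsets(window)
  rmax <- max(abs(off))
  fast <- rep(FALSE, m)
  if (m > 2 * rmax + 1) {
    bad <- cumsum(!eligible)
    i <- (rmax + 1L):(m - rmax)
    clean <- (bad[i + rmax] - c(0, bad)[i - rmax]) == 0
    fast[i[clean]] <- TRUE
  }
  if (any(fast)) {
    idx <- which(fast)
    X <- vapply(off, function(o) rr[idx + o], numeric(length(idx)))
    if (!is.matrix(X)) X <- matrix(X, nrow = 1)
    ref[idx] <- if (statistic == "median") apply(X, 1, stats::median)
                else rowMeans(X)
  }
  for (i in which(!fast))
    ref[i] <- local_reference(rr, i, window, eligible, statistic)
  ref
}

#' Label each beat from the deviation report
#'
#' Short flags become `premature`; a long flag immediately following a
#' premature beat is its `return_cycle`; isolated long flags are
#' `long_pause` (second-degree AV block behaviour -- a pause is not a
#' premature complex and never counts toward nPC). Beats inside detected
#' paroxysmal-AF segments are relabelled `paf` and excluded from
#' premature-complex logic. The first beat carries no RR and is labelled
#' from its quality alone.
#'
#' @param report output of [flag_deviants()].
#' @param paf_segments optional data.frame from [detect_paf()] with
#'   `start_beat`, `end_beat` columns.
#' @return character vector of labels, one per beat of the tachogram:
#'   `normal`, `premature`, `return_cycle`, `long_pause`, `paf`,
#'   `artifact`.
#' @export
label_beats <- function(report, paf_segments = NULL) {
  m <- nrow(report)
  lab <- rep("normal", m)
  lab[report$artifact] <- "artifact"
  short <- report$flagged & !is.na(report$deviation) & report$deviation < 0
  long  <- report$flagged & !is.na(report$deviation) & report$deviation > 0
  lab[short] <- "premature"
  for (i in which(long)) {
    lab[i] <- if (i > 1 && lab[i - 1] == "premature") "return_cycle"
              else "long_pause"
  }
  labels <- c("normal", lab)          # first beat has no RR
  if (!is.null(paf_segments) && nrow(paf_segments)) {
    for (k in seq_len(nrow(paf_segments))) {
      idx <- paf_segments$start_beat[k]:paf_segments$end_beat[k]
      idx <- idx[labels[idx] != "artifact"]
      labels[idx] <- "paf"
    }
  }
  labels
}
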