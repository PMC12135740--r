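#' Group labelled beats into rhythm events
#'
#' Maximal runs of consecutive `premature` beats map to event kinds:
#' length 1 = `single_pc`, 2 = `couplet`, 3 = `triplet`, more than 3 =
#' `run`. A `return_cycle` beat is not premature, so two premature beats
#' separated by a return cycle form two single PCs, not a couplet.
#' Paroxysmal-AF segments are appended as `paf` events.
#'
#' @param labels per-beat labels from [label_beats()].
#' @param beat_time_ms beat times aligned with `labels` (optional; onset
#'   times are `NA` without them).
#' @param paf_segments optional data.frame from [detect_paf()].
#' @return data.frame of events: `kind`, `run_length`, `start_beat`,
#'   `end_beat`, `onset_ms`, plus placeholder columns `phase`, `pause`,
#'   `morphology` filled by the downstream classifiers.
#' @export
group_events <- function(labels, beat_time_ms = NULL, paf_segments = NULL) {
  r <- rle(labels == "premature")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  kind <- character(0); len <- integer(0); sb <- integer(0); eb <- integer(0)
  for (k in keep) {
    L <- r$lengths[k]
    kind <- c(kind, switch(min(L, 4L), "single_pc", "couplet", "triplet",
                           "run"))
    len <- c(len, L)
    sb <- c(sb, starts[k]); eb <- c(eb, ends[k])
  }
  if (!is.null(paf_segments) && nrow(paf_segments)) {
    kind <- c(kind, rep("paf", nrow(paf_segments)))
    len <- c(len, paf_segments$end_beat - paf_segments$start_beat + 1L)
    sb <- c(sb, paf_segments$start_beat); eb <- c(eb, paf_segments$end_beat)
  }
  onset <- if (is.null(beat_time_ms)) rep(NA_real_, length(sb))
           else beat_time_ms[sb]
  ev <- data.frame(kind = kind, run_length = len, start_beat = sb,
                   end_beat = eb, onset_ms = onset,
                   phase = rep("exercise", length(sb)),
                   pause = rep("not_applicable", length(sb)),
                   morphology = rep("unknown", length(sb)),
                   stringsAsFactors = FALSE)
  ev[order(ev$start_beat), , drop = FALSE]
}

#' Classify the pause following a single premature complex
#'
#' Compares S = coupling interval + return cycle with T = twice the local
#' reference before the event. The pause is compensatory when S is equal
#' or nearly equal to T (|S - T|/T within `tolerance`; ties favour
#' compensatory), non-compensatory when S falls short of T by more than
#' the tolerance, and indeterminate when S markedly exceeds T or the
#' event ends the recording.
#'
#' @param t a [tachogram()].
#' @param event one-row event (from [group_events()]) of kind
#'   `single_pc`.
#' @param tolerance relative tolerance (default 0.05).
#' @param window reference window for the pre-event reference.
#' @param labels per-beat labels (used to exclude non-normal beats from
#'   the reference).
#' @return `"compensatory"`, `"non_compensatory"` or `"indeterminate"`.
#' @export
classify_pause <- function(t, event, tolerance = 0.05, window = 11,
                           labels = NULL) {
  stopifnot(event$kind == "single_pc")
  rr <- t$rr_ms
  i <- event$start_beat - 1L            # RR index of the coupling interval
  if (i + 1L > length(rr)) return("indeterminate")
  coupling <- rr[i]; return_rr <- rr[i + 1L]
  eligible <- !rr_artifact(t)
  if (!is.null(labels)) {
    lab_rr <- labels[-1]
    eligible <- eligible & lab_rr == "normal"
  } else {
    eligible[c(i, i + 1L)] <- FALSE
  }
  ref <- local_reference(rr, i, window, eligible)
  if (is.na(ref)) return("indeterminate")
  S <- coupling + return_rr
  T2 <- 2 * ref
  if (abs(S - T2) / T2 <= tolerance) "compensatory"
  else if (S < T2 * (1 - tolerance)) "non_compensatory"
  else "indeterminate"
}

#' Classify event morphology as narrow or wide
#'
#' Wide when the widest QRS in the event exceeds `wide_ratio` times the
#' median width of the `baseline_beats` preceding normal beats; `unknown`
#' when the tachogram carries no width channel.
#'
#' @param t a [tachogram()].
#' @param event one-row event.
#' @param labels per-beat labels.
#' @param wide_ratio width ratio defining "wide" (default 1.25).
#' @param baseline_beats normal beats used for the baseline (default 10).
#' @export
classify_morphology <- function(t, event, labels, wide_ratio = 1.25,
                                baseline_beats = 10) {
  w <- t$morphology_width
  if (is.null(w)) return("unknown")
  prior <- which(labels == "normal" & seq_along(labels) < event$start_beat)
  prior <- utils::tail(prior, baseline_beats)
  if (length(prior) < 3) return("unknown")
  base <- stats::median(w[prior], na.rm = TRUE)
  ev_w <- max(w[event$start_beat:event$end_beat], na.rm = TRUE)
  if (is.na(base) || is.na(ev_w)) return("unknown")
  if (ev_w > wide_ratio * base) "wide" else "narrow"
}

#' Assign exercise/deceleration phase to events
#'
#' An event is in the deceleration phase when its onset time falls inside
#' a fast-deceleration segment; segment intervals are half-open
#' `[start, end)`.
#'
#' @param events events data.frame.
#' @param segments data.frame from [segment_deceleration()] with
#'   `start_ms`, `end_ms`.
#' @export
assign_phase <- function(events, segments) {
  if (!nrow(events)) return(events)
  events$phase <- "exercise"
  if (!is.null(segments) && nrow(segments)) {
    for (k in seq_len(nrow(segments))) {
      inside <- !is.na(events$onset_ms) &
        events$onset_ms >= segments$start_ms[k] &
        events$onset_ms < segments$end_ms[k]
      events$phase[inside] <- "deceleration"
    }
  }
  events
}

#' Total premature-complex count of an event list
#'
#' Each premature complex counts once: singles 1, couplets 2, triplets 3,
#' runs their length. Paroxysmal AF is an arrhythmia category of its own
#' and contributes 0 to nPC.
#' @param events events data.frame.
#' @export
count_npc <- function(events) {
  if (!nrow(events)) return(0L)
  as.integer(sum(events$run_length[events$kind != "paf"]))
}

#' Assemble the per-workout rhythm profile
#'
#' Three dichotomous categories plus the PC count: `arrhythmia` (any
#' event, pAF included), `arrhythmia_deceleration` (any event during fast
#' heart-rate deceleration), `arrhythmia_complex` (triplet, run of more
#' than 3, or paroxysmal AF; couplets are deliberately non-complex).
#'
#' @param events events data.frame with phases assigned.
#' @return list of class `rhythm_profile`.
#' @export
make_profile <- function(events) {
  complex_kinds <- c("triplet", "run", "paf")
  structure(list(
    events = events,
    nPC = count_npc(events),
    arrhythmia = nrow(events) > 0,
    arrhythmia_deceleration = any(events$phase == "deceleration"),
    arrhythmia_complex = any(events$kind %in% complex_kinds)
  ), class = "rhythm_profile")
}

#' @export
print.rhythm_profile <- function(x, ...) {
  cat(sprintf(
    "<rhythm_profile: nPC=%d, arrhythmia=%s, deceleration=%s, complex=%s, %d event(s)>\n",
    x$nPC, x$arrhythmia, x$arrhythmia_deceleration, x$arrhythmia_complex,
    nrow(x$events)))
  invisible(x)
}

#' Full rhythm analysis of one tachogram
#'
#' Orchestrates deviation flagging, pAF detection, beat labelling, event
#' grouping, pause/morphology classification, deceleration segmentation
#' and phase assignment.
#'
#' @param t a [tachogram()].
#' @param params analysis parameter list, see [default_config()]'s
#'   `detection`, `pause`, `paf`, `deceleration` and `morphology` blocks.
#' @return list with `profile`, `events`, `labels`, `deviations`,
#'   `paf_segments`, `decel_segments`.
#' @export
analyze_tachogram <- function(t, params = default_config()) {
  det <- params$detection
  report <- flag_deviants(t, threshold = det$threshold, window = det$window,
                          statistic = det$reference_statistic,
                          threshold_mode = det$threshold_mode)
  paf <- detect_paf(t, min_beats = params$paf$min_beats,
                    cv_threshold = params$paf$cv_threshold,
                    max_lag1 = params$paf$max_lag1,
                    min_delta_frac = params$paf$min_delta_frac)
  labels <- label_beats(report, paf)
  events <- group_events(labels, t$beat_time_ms, paf)
  decel <- segment_deceleration(t, drop_bpm = params$deceleration$drop_bpm,
                                window_s = params$deceleration$window_s,
                                smooth_s = params$deceleration$smooth_s,
                                min_peak_bpm = params$deceleration$min_peak_bpm)
  events <- assign_phase(events, decel)
  singles <- which(events$kind == "single_pc")
  for (k in singles)
    events$pause[k] <- classify_pause(t, events[k, ],
                                      tolerance = params$pause$tolerance,
                                      window = det$window, labels = labels)
  if (!is.null(t$morphology_width)) {
    for (k in seq_len(nrow(events))) {
      if (events$kind[k] == "paf") next
      events$morphology[k] <- classify_morphology(
        t, events[k, ], labels,
        wide_ratio = params$morphology$wide_ratio,
        baseline_beats = params$morphology$baseline_beats)
    }
  }
  list(profile = make_profile(events), events = events, labels = labels,
       deviations = report, paf_segments = paf, decel_segments = decel)
}
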