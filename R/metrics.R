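#' Peak heart rate of a workout
#'
#' The average rate of the 5 shortest RR intervals after excluding
#' premature complexes (and return cycles, pAF and artifact), the
#' standard surrogate of exercise intensity: `60000 / mean(5 shortest
#' eligible RR)`.
#'
#' @param t a [tachogram()].
#' @param labels per-beat labels from [label_beats()]; an RR is eligible
#'   when its terminating beat is labelled `normal`.
#' @param n_shortest number of intervals averaged (default 5).
#' @return beats/min.
#' @export
hr_peak <- function(t, labels = NULL, n_shortest = 5) {
  rr <- t$rr_ms
  ok <- !rr_artifact(t)
  if (!is.null(labels)) ok <- ok & labels[-1] == "normal"
  rr <- rr[ok]
  if (length(rr) < n_shortest)
    stop("insufficient normal beats for hr_peak (need ", n_shortest, ")",
         call. = FALSE)
  60000 / mean(sort(rr)[seq_len(n_shortest)])
}

#' Mean heart rate of a workout
#'
#' Average heart rate from the initiation of exercise to the end: 60000
#' divided by the duration-weighted mean RR (each interval weighted by
#' its own duration, so a stretch spent at a slow rate counts by the
#' time it occupies). Premature beats are included (the burden is part
#' of the rhythm); artifact intervals are excluded by default.
#'
#' @param t a [tachogram()].
#' @param exclude_artifact drop artifact RRs (default TRUE).
#' @return beats/min.
#' @export
hr_mean <- function(t, exclude_artifact = TRUE) {
  rr <- t$rr_ms
  if (exclude_artifact) rr <- rr[!rr_artifact(t)]
  if (!length(rr)) stop("no usable RR intervals", call. = FALSE)
  60000 * sum(rr) / sum(rr^2)
}

#' Assemble the per-workout cohort row
#'
#' @param t a [tachogram()].
#' @param analysis result of [analyze_tachogram()] for `t`.
#' @param meta a [workout_meta()]; defaults to `t$meta`.
#' @param inclusion_cutoff readability cutoff (default 0.95).
#' @param weighting readability weighting, see [readable_fraction()].
#' @return one-row data.frame (a `WorkoutResult`): metadata, readability,
#'   inclusion, nPC, the three arrhythmia flags, HR metrics and duration.
#' @export
summarize_workout <- function(t, analysis, meta = t$meta,
                              inclusion_cutoff = 0.95,
                              weighting = "duration") {
  if (is.null(meta)) stop("workout metadata required", call. = FALSE)
  rf <- readable_fraction(t, weighting)
  p <- analysis$profile
  hp <- tryCatch(hr_peak(t, analysis$labels),
                 error = function(e)
                   stop("workout ", meta$workout_id, ": ", conditionMessage(e),
                        call. = FALSE))
  row <- meta_as_row(meta)
  row$duration_min <-
    (t$beat_time_ms[n_beats(t)] - t$beat_time_ms[1]) / 60000
  row$readable_fraction <- rf
  row$included <- is_included(rf, inclusion_cutoff)
  row$nPC <- p$nPC
  row$arrhythmia <- p$arrhythmia
  row$arrhythmia_deceleration <- p$arrhythmia_deceleration
  row$arrhythmia_complex <- p$arrhythmia_complex
  row$hr_peak <- hp
  row$hr_mean <- hr_mean(t)
  row
}

#' Write a cohort results CSV
#'
#' One `WorkoutResult` per row; logicals rendered as 0/1.
#' @param results data.frame of workout results.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  for (cl in c("included", "arrhythmia", "arrhythmia_deceleration",
               "arrhythmia_complex", "cardiac"))
    if (cl %in% names(results)) results[[cl]] <- as.integer(results[[cl]])
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE,
                   eol = "\n")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, colClasses = c(horse_id = "character",
                                             workout_id = "character"))
  for (cl in c("included", "arrhythmia", "arrhythmia_deceleration",
               "arrhythmia_complex", "cardiac"))
    if (cl %in% names(df)) df[[cl]] <- as.logical(df[[cl]])
  df
}
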