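#' Workout types recognised by the package
#'
#' The seven exercise types used to classify Eventing workouts, in the
#' canonical order (Flat is the reference level in all models).
#' @export
TYPE_LEVELS <- c("Flat", "Hack", "Trot", "Jumping", "XC_School",
                 "Gallop", "Competition")

#' Construct workout metadata
#'
#' @param horse_id,workout_id identifiers (coerced to character).
#' @param type workout type, one of [TYPE_LEVELS].
#' @param level competition level, integer 1--5.
#' @param season period of the year: 1 = December--March, 2 = April--July,
#'   3 = August--November.
#' @param age horse age in years.
#' @param duration_min recorded duration in minutes (> 0).
#' @param cardiac logical; `TRUE` for horses with previous cardiac signs.
#' @return A `workout_meta` object (named list).
#' @export
workout_meta <- function(horse_id, workout_id, type, level = NA_integer_,
                         season = NA_integer_, age = NA_real_,
                         duration_min = NA_real_, cardiac = NA) {
  type <- as.character(type)
  if (!type %in% TYPE_LEVELS)
    stop("unknown workout type: '", type, "'", call. = FALSE)
  if (!is.na(level) && !level %in% 1:5)
    stop("level must be in 1..5", call. = FALSE)
  if (!is.na(season) && !season %in% 1:3)
    stop("season must be in 1..3", call. = FALSE)
  if (!is.na(duration_min) && duration_min <= 0)
    stop("duration_min must be > 0", call. = FALSE)
  structure(list(horse_id = as.character(horse_id),
                 workout_id = as.character(workout_id),
                 type = type, level = as.integer(level),
                 season = as.integer(season), age = as.numeric(age),
                 duration_min = as.numeric(duration_min),
                 cardiac = as.logical(cardiac)),
            class = "workout_meta")
}

#' Construct an RR tachogram
#'
#' The tachogram is the unit of rhythm analysis: a strictly increasing
#' series of beat times with derived RR intervals, a per-beat quality mask
#' and an optional relative QRS-width measure.
#'
#' @param beat_time_ms strictly increasing beat times in milliseconds
#'   (stored as integers).
#' @param quality logical per-beat readability mask; `NULL` means all
#'   readable.
#' @param morphology_width optional per-beat positive relative QRS width
#'   (1.0 = typical for the recording); `NULL` if the device provides none.
#' @param meta optional [workout_meta()].
#' @return A `tachogram` object with elements `beat_time_ms`, `rr_ms`
#'   (length one less than the beat count; `rr_ms[i]` terminates at beat
#'   `i + 1`), `quality`, `morphology_width`, `meta`.
#' @export
tachogram <- function(beat_time_ms, quality = NULL, morphology_width = NULL,
                      meta = NULL) {
  beat_time_ms <- as.numeric(beat_time_ms)
  n <- length(beat_time_ms)
  if (n < 2) stop("a tachogram needs at least 2 beats", call. = FALSE)
  d <- diff(beat_time_ms)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 1L
    stop("beat times not strictly increasing at beat ", bad, call. = FALSE)
  }
  if (is.null(quality)) quality <- rep(TRUE, n)
  quality <- as.logical(quality)
  if (length(quality) != n)
    stop("quality mask length must equal beat count", call. = FALSE)
  if (!is.null(morphology_width)) {
    morphology_width <- as.numeric(morphology_width)
    if (length(morphology_width) != n)
      stop("morphology_width length must equal beat count", call. = FALSE)
    if (any(!is.na(morphology_width) & morphology_width <= 0))
      stop("morphology_width must be positive", call. = FALSE)
  }
  structure(list(beat_time_ms = round(beat_time_ms), rr_ms = diff(round(beat_time_ms)),
                 quality = quality, morphology_width = morphology_width,
                 meta = meta),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  n <- length(x$beat_time_ms)
  span <- (x$beat_time_ms[n] - x$beat_time_ms[1]) / 60000
  cat(sprintf("<tachogram: %d beats, %.1f min, readable %.1f%%>\n",
              n, span, 100 * readable_fraction(x)))
  if (!is.null(x$meta))
    cat(sprintf("  %s / %s  type=%s\n", x$meta$horse_id, x$meta$workout_id,
                x$meta$type))
  invisible(x)
}

#' Number of beats in a tachogram
#' @param t a [tachogram()].
#' @export
n_beats <- function(t) length(t$beat_time_ms)

#' Per-RR artifact mask
#'
#' An RR interval is unreliable when either of its endpoint beats is
#' flagged unreadable; such intervals are excluded from references,
#' never flagged as premature, and excluded from heart-rate averages.
#' @param t a [tachogram()].
#' @return logical vector aligned with `t$rr_ms`; `TRUE` = artifact.
#' @export
rr_artifact <- function(t) {
  n <- n_beats(t)
  !(t$quality[-n] & t$quality[-1])
}

#' Duration-weighted readable fraction of a recording
#'
#' The fraction of the recorded span covered by readable RR intervals.
#' Each RR inherits the quality of its terminating beat
#' (duration weighting); `weighting = "beats"` instead counts readable
#' RRs.
#'
#' @param t a [tachogram()].
#' @param weighting `"duration"` (default) or `"beats"`.
#' @return proportion in `[0, 1]`.
#' @export
readable_fraction <- function(t, weighting = c("duration", "beats")) {
  weighting <- match.arg(weighting)
  ok <- t$quality[-1]                      # quality of terminating beat
  if (weighting == "duration") sum(t$rr_ms[ok]) / sum(t$rr_ms) else mean(ok)
}

#' Inclusion rule for readable recordings
#'
#' A workout enters the cohort analysis when 95% or more of it is
#' readable (boundary inclusive).
#' @param fraction readable fraction in `[0, 1]`.
#' @param cutoff inclusion threshold (default 0.95).
#' @export
is_included <- function(fraction, cutoff = 0.95) {
  stopifnot(fraction >= 0, fraction <= 1)
  fraction >= cutoff
}

#' Read / write a tachogram CSV
#'
#' Dialect: header `beat_time_ms,rr_ms,quality,morphology_width`, one row
#' per beat, first row's `rr_ms` empty, `quality` in \{0,1\} (an empty
#' quality column is treated as all-readable), UTF-8, LF line endings.
#'
#' @param path file path.
#' @param meta optional [workout_meta()] attached to the result.
#' @return `read_tachogram()` returns a [tachogram()]; `write_tachogram()`
#'   invisibly returns `path`. The pair round-trips exactly (times are
#'   integer milliseconds).
#' @export
read_tachogram <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "numeric")
  req <- c("beat_time_ms", "rr_ms", "quality", "morphology_width")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bt <- df$beat_time_ms
  d <- diff(bt)
  if (any(d <= 0)) {
    # +2: one for the header line, one for 1-based diff offset
    stop("beat times not strictly increasing at row ", which(d <= 0)[1] + 2L,
         call. = FALSE)
  }
  q <- df$quality
  q <- if (all(is.na(q))) NULL else as.logical(q)
  mw <- df$morphology_width
  if (all(is.na(mw))) mw <- NULL
  tachogram(bt, quality = q, morphology_width = mw, meta = meta)
}

#' @rdname read_tachogram
#' @param t a [tachogram()].
#' @export
write_tachogram <- function(t, path) {
  df <- data.frame(beat_time_ms = format(t$beat_time_ms, scientific = FALSE,
                                         trim = TRUE),
                   rr_ms = c("", format(t$rr_ms, scientific = FALSE,
                                        trim = TRUE)),
                   quality = as.integer(t$quality),
                   morphology_width = if (is.null(t$morphology_width)) ""
                                      else t$morphology_width)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read / write cohort workout metadata CSV
#'
#' Columns: `horse_id,workout_id,type,level,season,age,duration_min,cardiac`
#' with `type` spelled exactly as in [TYPE_LEVELS] and `cardiac` in \{0,1\}.
#' @param path file path.
#' @return a data.frame, one row per workout.
#' @export
read_cohort_metadata <- function(path) {
  df <- utils::read.csv(path, colClasses = c(horse_id = "character",
                                             workout_id = "character"))
  req <- c("horse_id", "workout_id", "type", "level", "season", "age",
           "duration_min", "cardiac")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$type), TYPE_LEVELS)
  if (length(bad))
    stop("unknown workout type: '", bad[1], "'", call. = FALSE)
  df$cardiac <- as.logical(df$cardiac)
  df
}

#' @rdname read_cohort_metadata
#' @param df metadata data.frame.
#' @export
write_cohort_metadata <- function(df, path) {
  df$cardiac <- as.integer(df$cardiac)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

meta_as_row <- function(meta) {
  data.frame(horse_id = meta$horse_id, workout_id = meta$workout_id,
             type = meta$type, level = meta$level, season = meta$season,
             age = meta$age, duration_min = meta$duration_min,
             cardiac = meta$cardiac, stringsAsFactors = FALSE)
}
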