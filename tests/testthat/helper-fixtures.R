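# Shared fixture builders. Everything is generated in code; the only
# stored fixtures are the small transcribed summary tables under
# inst/extdata.

extdata <- function(f) system.file("extdata", f, package = "equitach")

# tachogram from an RR series (ms), starting at t0
tacho_from_rr <- function(rr, t0 = 0, quality = NULL, width = NULL,
                          meta = NULL) {
  tachogram(cumsum(c(t0, rr)), quality = quality, morphology_width = width,
            meta = meta)
}

# constant-HR trajectory with the attributes simulate_tachogram expects
flat_trajectory <- function(hr, duration_min) {
  f <- function(t) rep(hr, length(t))
  attr(f, "duration_ms") <- duration_min * 60000
  attr(f, "decel_start_ms") <- NULL
  attr(f, "decel_end_ms") <- NULL
  f
}

toy_horse <- function(cardiac = FALSE, propensity = 1) {
  data.frame(horse_id = "H001", cardiac = cardiac, age = 11, level = 3,
             pc_propensity = propensity, stringsAsFactors = FALSE)
}

toy_plan <- function(type = "Gallop", duration_min = 10,
                     target_hr_peak = 180, injections = list(),
                     seed = 99L) {
  structure(list(workout_id = "W00001", horse_id = "H001", type = type,
                 season = 2L, duration_min = duration_min,
                 target_hr_peak = target_hr_peak, injections = injections,
                 workout_seed = seed), class = "workout_plan")
}

# expand a per-TYPE count fixture into a workout-level results table
# (flags nested so complex and deceleration rows are arrhythmia rows)
expand_table2 <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    n <- r$n
    out <- data.frame(
      horse_id = sprintf("%s-%s-h%03d", r$group, r$type, seq_len(n)),
      workout_id = sprintf("%s-%s-w%03d", r$group, r$type, seq_len(n)),
      type = r$type, level = 3L, season = 2L, age = 11,
      duration_min = 50, cardiac = r$group == "CARDIAC",
      readable_fraction = 1, included = TRUE,
      nPC = as.integer(seq_len(n) <= r$arrhythmia_count),
      arrhythmia = seq_len(n) <= r$arrhythmia_count,
      arrhythmia_deceleration = seq_len(n) <= r$deceleration_count,
      arrhythmia_complex = seq_len(n) <= r$complex_count,
      hr_peak = NA_real_, hr_mean = NA_real_,
      stringsAsFactors = FALSE)
    out
  })
  do.call(rbind, rows)
}

# brute-force run-length oracle for premature-label grouping
oracle_group <- function(prem) {
  kinds <- character(0); lens <- integer(0)
  i <- 1L; n <- length(prem)
  while (i <= n) {
    if (prem[i]) {
      j <- i
      while (j < n && prem[j + 1L]) j <- j + 1L
      L <- j - i + 1L
      kinds <- c(kinds, if (L == 1) "single_pc" else if (L == 2) "couplet"
                 else if (L == 3) "triplet" else "run")
      lens <- c(lens, L)
      i <- j + 1L
    } else i <- i + 1L
  }
  list(kinds = kinds, lens = lens)
}

# analysis with default parameters, premature beat indices extracted
detected_premature <- function(t) {
  an <- analyze_tachogram(t)
  which(an$labels == "premature")
}
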