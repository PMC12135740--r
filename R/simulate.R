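#' Default per-TYPE target peak heart rates (beats/min)
#'
#' Anchored to the cohort medians observed for each workout type in the
#' two groups (previous-cardiac-signs vs none).
#' @export
DEFAULT_TARGET_HR <- list(
  cardiac     = c(Flat = 141, Hack = 141.5, Trot = 148, Jumping = 177,
                  XC_School = 195, Gallop = 206, Competition = 211),
  non_cardiac = c(Flat = 138.5, Hack = 147, Trot = 145, Jumping = 176,
                  XC_School = 192, Gallop = 192, Competition = 215))

DEFAULT_TYPE_WEIGHTS <- c(Flat = 307, Hack = 128, Trot = 41, Jumping = 129,
                          XC_School = 46, Gallop = 324, Competition = 27) / 1002

#' Simulation configuration
#'
#' Defaults describe the cohort the simulator emulates: 62 horses of
#' which 8 carry previous cardiac signs, workout types drawn with the
#' observed frequencies, a baseline single-PC intensity for unaffected
#' horses with a 6.6-fold rate ratio for the cardiac group, and
#' contiguous unreadable (artifact) windows.
#'
#' @param n_horses number of horses.
#' @param cardiac_fraction fraction of horses in the cardiac group
#'   (applied as a fixed count, `round(n_horses * cardiac_fraction)`).
#' @param workouts_per_horse integer range `c(lo, hi)`; each horse's
#'   workout count is drawn uniformly from it.
#' @param type_weights named probabilities over [TYPE_LEVELS] (sum 1).
#' @param base_pc_rate expected single PCs per 1000 beats for horses
#'   without cardiac signs.
#' @param cardiac_rate_ratio multiplicative PC-rate factor for the
#'   cardiac group (default 6.6).
#' @param complex_event_prob per-workout probability of a planned complex
#'   event (triplet or run) for non-cardiac horses; cardiac horses use
#'   `cardiac_complex_ratio` times this.
#' @param cardiac_complex_ratio complex-event multiplier for the cardiac
#'   group (default 2.5).
#' @param couplet_prob per-workout probability of a planned couplet.
#' @param paf_prob per-workout probability of a paroxysmal-AF episode.
#' @param paf_beats_range length range (beats) of injected AF episodes.
#' @param artifact_fraction_range proportion range of unreadable time,
#'   drawn uniformly per workout.
#' @param sinus_cv coefficient of variation of sinus RR (default 0.02).
#' @param sinus_cor lag-1 correlation of the sinus log-RR noise (default
#'   0.99; band-limited variability, see the methods vignette).
#' @param pc_prematurity_range prematurity range for spontaneous single
#'   PCs.
#' @param propensity_sdlog lognormal sd of the per-horse PC propensity.
#' @param duration_log_mean,duration_log_sd lognormal parameters of the
#'   workout duration in minutes (defaults centre the distribution on the
#'   cohort median of ~45-50 min).
#' @param duration_bounds clipping range for duration in minutes.
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_horses = 62, cardiac_fraction = 8 / 62,
                              workouts_per_horse = c(2, 30),
                              type_weights = DEFAULT_TYPE_WEIGHTS,
                              base_pc_rate = 0.1, cardiac_rate_ratio = 6.6,
                              complex_event_prob = 0.01,
                              cardiac_complex_ratio = 2.5,
                              couplet_prob = 0.02, paf_prob = 0.003,
                              paf_beats_range = c(20, 60),
                              artifact_fraction_range = c(0, 0.07),
                              sinus_cv = 0.02, sinus_cor = 0.99,
                              pc_prematurity_range = c(0.08, 0.25),
                              propensity_sdlog = 1,
                              duration_log_mean = log(45),
                              duration_log_sd = 0.4,
                              duration_bounds = c(15, 180), seed = 1L) {
  type_weights <- unlist(type_weights)   # YAML maps arrive as lists
  cfg <- list(n_horses = as.integer(n_horses),
              cardiac_fraction = cardiac_fraction,
              workouts_per_horse = as.integer(unlist(workouts_per_horse)),
              type_weights = type_weights, base_pc_rate = base_pc_rate,
              cardiac_rate_ratio = cardiac_rate_ratio,
              complex_event_prob = complex_event_prob,
              cardiac_complex_ratio = cardiac_complex_ratio,
              couplet_prob = couplet_prob, paf_prob = paf_prob,
              paf_beats_range = as.integer(paf_beats_range),
              artifact_fraction_range = artifact_fraction_range,
              sinus_cv = sinus_cv, sinus_cor = sinus_cor,
              pc_prematurity_range = pc_prematurity_range,
              propensity_sdlog = propensity_sdlog,
              duration_log_mean = duration_log_mean,
              duration_log_sd = duration_log_sd,
              duration_bounds = duration_bounds, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop("invalid simulation config field '", field, "': ", why,
                  call. = FALSE)
  chk(cfg$n_horses >= 1, "n_horses", "must be >= 1")
  chk(cfg$cardiac_fraction >= 0 && cfg$cardiac_fraction <= 1,
      "cardiac_fraction", "must be in [0,1]")
  chk(length(cfg$workouts_per_horse) == 2 &&
        cfg$workouts_per_horse[1] >= 1 &&
        cfg$workouts_per_horse[2] >= cfg$workouts_per_horse[1],
      "workouts_per_horse", "must be an increasing positive range")
  chk(setequal(names(cfg$type_weights), TYPE_LEVELS) &&
        abs(sum(cfg$type_weights) - 1) < 1e-8 && all(cfg$type_weights >= 0),
      "type_weights", "must be probabilities over the 7 types summing to 1")
  chk(cfg$base_pc_rate >= 0, "base_pc_rate", "must be >= 0")
  chk(cfg$cardiac_rate_ratio > 0, "cardiac_rate_ratio", "must be > 0")
  for (f in c("complex_event_prob", "couplet_prob", "paf_prob"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0,1]")
  chk(all(cfg$artifact_fraction_range >= 0) &&
        all(cfg$artifact_fraction_range <= 0.9) &&
        diff(cfg$artifact_fraction_range) >= 0,
      "artifact_fraction_range", "must be an increasing range in [0,0.9]")
  chk(cfg$sinus_cv >= 0, "sinus_cv", "must be >= 0")
  chk(cfg$sinus_cor >= 0 && cfg$sinus_cor < 1, "sinus_cor",
      "must be in [0,1)")
  chk(all(cfg$pc_prematurity_range > 0) &&
        all(cfg$pc_prematurity_range < 1),
      "pc_prematurity_range", "must lie in (0,1)")
  chk(length(cfg$duration_bounds) == 2 && cfg$duration_bounds[1] >= 5 &&
        diff(cfg$duration_bounds) >= 0,
      "duration_bounds", "must be an increasing range with lower bound >= 5 min")
  invisible(cfg)
}

#' Specification of one injected arrhythmic event
#'
#' @param kind `single_pc`, `couplet`, `triplet`, `run` or `paf`.
#' @param run_length consecutive premature beats (must be > 3 for `run`;
#'   forced to 1/2/3 for single/couplet/triplet).
#' @param prematurity fractional RR shortening in (0,1). Sub-threshold
#'   values (< 0.05) are legal and used for specificity testing.
#' @param pause `compensatory`, `non_compensatory` or `not_applicable`.
#' @param morphology `narrow` or `wide`.
#' @param phase_hint `exercise` or `deceleration`.
#' @param onset fractional position in `[0,1]` of the workout.
#' @param paf_beats episode length in beats (kind `paf` only).
#' @export
event_spec <- function(kind, run_length = NA_integer_, prematurity = 0.1,
                       pause = "not_applicable", morphology = "narrow",
                       phase_hint = "exercise", onset = 0.5,
                       paf_beats = 40L) {
  kind <- match.arg(kind, c("single_pc", "couplet", "triplet", "run", "paf"))
  if (kind != "paf" && (prematurity <= 0 || prematurity >= 1))
    stop("prematurity must be in (0,1)", call. = FALSE)
  run_length <- switch(kind, single_pc = 1L, couplet = 2L, triplet = 3L,
                       paf = as.integer(paf_beats),
                       run = as.integer(run_length))
  if (kind == "run" && (is.na(run_length) || run_length <= 3))
    stop("run_length must be > 3 for kind 'run'", call. = FALSE)
  structure(list(kind = kind, run_length = run_length,
                 prematurity = prematurity, pause = pause,
                 morphology = morphology, phase_hint = phase_hint,
                 onset = onset), class = "event_spec")
}

#' Sample a cohort of horses and workout plans
#'
#' @param config a [simulation_config()].
#' @return list with `horses` (data.frame: horse_id, cardiac, age, level,
#'   pc_propensity) and `plans` (list of workout plans: ids, type, season,
#'   duration_min, target_hr_peak, injections, workout_seed).
#' @export
sample_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_horses
  n_cardiac <- round(n * config$cardiac_fraction)
  cardiac <- rep(FALSE, n)
  cardiac[sample.int(n, n_cardiac)] <- TRUE
  horses <- data.frame(
    horse_id = sprintf("H%03d", seq_len(n)),
    cardiac = cardiac,
    age = pmin(19, pmax(6, round(stats::rnorm(n, 11, 3)))),
    level = sample(1:5, n, replace = TRUE,
                   prob = c(15, 13, 12, 12, 10) / 62),
    pc_propensity = stats::rlnorm(n, -config$propensity_sdlog^2 / 2,
                                  config$propensity_sdlog),
    stringsAsFactors = FALSE)
  plans <- list()
  w <- 0L
  for (h in seq_len(n)) {
    wk_range <- seq(config$workouts_per_horse[1],
                    config$workouts_per_horse[2])
    k <- wk_range[sample.int(length(wk_range), 1)]
    for (j in seq_len(k)) {
      w <- w + 1L
      type <- sample(TYPE_LEVELS, 1, prob = config$type_weights[TYPE_LEVELS])
      grp <- if (horses$cardiac[h]) "cardiac" else "non_cardiac"
      target <- DEFAULT_TARGET_HR[[grp]][[type]] + stats::rnorm(1, 0, 8)
      target <- min(240, max(60, target))
      dur <- min(config$duration_bounds[2],
                 max(config$duration_bounds[1],
                     stats::rlnorm(1, config$duration_log_mean,
                                   config$duration_log_sd)))
      inj <- plan_injections(horses[h, ], config)
      plans[[w]] <- structure(list(
        workout_id = sprintf("W%05d", w), horse_id = horses$horse_id[h],
        type = type, season = sample(1:3, 1), duration_min = dur,
        target_hr_peak = target, injections = inj,
        workout_seed = sample.int(.Machine$integer.max, 1)),
        class = "workout_plan")
    }
  }
  list(horses = horses, plans = plans)
}

# planned (non-Poisson) events for one workout
plan_injections <- function(horse, config) {
  inj <- list()
  p_complex <- config$complex_event_prob *
    if (horse$cardiac) config$cardiac_complex_ratio else 1
  prem <- function() stats::runif(1, config$pc_prematurity_range[1],
                                  config$pc_prematurity_range[2])
  if (stats::runif(1) < p_complex) {
    kind <- sample(c("triplet", "run"), 1, prob = c(0.6, 0.4))
    inj[[length(inj) + 1]] <- event_spec(
      kind, run_length = if (kind == "run") sample(4:8, 1) else NA,
      prematurity = prem(),
      morphology = sample(c("narrow", "wide"), 1, prob = c(0.85, 0.15)),
      phase_hint = sample(c("exercise", "deceleration"), 1,
                          prob = c(0.7, 0.3)),
      onset = stats::runif(1, 0.1, 0.9))
  }
  if (stats::runif(1) < config$couplet_prob)
    inj[[length(inj) + 1]] <- event_spec(
      "couplet", prematurity = prem(),
      phase_hint = sample(c("exercise", "deceleration"), 1,
                          prob = c(0.7, 0.3)),
      onset = stats::runif(1, 0.1, 0.9))
  if (stats::runif(1) < config$paf_prob)
    inj[[length(inj) + 1]] <- event_spec(
      "paf", onset = stats::runif(1, 0.3, 0.7),
      paf_beats = {
        pb <- seq(config$paf_beats_range[1], config$paf_beats_range[2])
        pb[sample.int(length(pb), 1)]
      })
  inj
}

#' Simulate a workout heart-rate trajectory
#'
#' Piecewise-linear profile: warm-up ramp, one to three work bouts (the
#' last reaching the target peak exactly, so the trajectory maximum is
#' within the +-5% contract), inter-bout recoveries, and a terminal fast
#' deceleration at 1.5 beats/min per second down to a walking rate --
#' steep enough that every simulated workout contains at least one
#' segment detectable at the default deceleration thresholds.
#'
#' @param plan a workout plan (needs `duration_min`, `target_hr_peak`).
#' @param seed integer seed for bout-structure randomness.
#' @return function `f(t_ms) -> beats/min` defined on `[0, duration_ms]`,
#'   with attributes `duration_ms`, `decel_start_ms`, `decel_end_ms`.
#' @export
simulate_hr_trajectory <- function(plan, seed = plan$workout_seed) {
  T_s <- plan$duration_min * 60
  if (plan$duration_min < 5)
    stop("workout too short to fit exercise phases (< 5 min)",
         call. = FALSE)
  target <- plan$target_hr_peak
  set.seed(seed)
  walk_hr <- 70
  decel_len <- (target - walk_hr) / 1.5
  tail_len <- min(60, 0.05 * T_s)
  warm_len <- min(300, 0.15 * T_s)
  mid <- T_s - warm_len - decel_len - tail_len
  n_bouts <- if (mid < 360) 1L else sample(1:3, 1)
  kt <- c(0, warm_len); kh <- c(80, 0.7 * target)
  # split mid into bouts (2/3) and recoveries (1/3)
  bout_len <- mid * 2 / 3 / n_bouts
  rec_len <- if (n_bouts > 1) mid / 3 / (n_bouts - 1) else 0
  t_cur <- warm_len
  for (b in seq_len(n_bouts)) {
    peak <- if (b == n_bouts) target else stats::runif(1, 0.85, 0.94) * target
    kt <- c(kt, t_cur + 0.4 * bout_len, t_cur + bout_len)
    kh <- c(kh, peak, peak)
    t_cur <- t_cur + bout_len
    if (b < n_bouts) {
      kt <- c(kt, t_cur + rec_len); kh <- c(kh, stats::runif(1, 0.5, 0.6) * target)
      t_cur <- t_cur + rec_len
    }
  }
  if (n_bouts == 1 && mid > 0) { # single long bout absorbs recovery budget
    kt[length(kt)] <- warm_len + mid; kh[length(kh)] <- target
    t_cur <- warm_len + mid
  }
  decel_start <- t_cur
  kt <- c(kt, t_cur + decel_len, T_s); kh <- c(kh, walk_hr, walk_hr)
  f <- stats::approxfun(kt * 1000, kh, rule = 2)
  attr(f, "duration_ms") <- T_s * 1000
  attr(f, "decel_start_ms") <- decel_start * 1000
  attr(f, "decel_end_ms") <- (decel_start + decel_len) * 1000
  f
}

#' Inject one arrhythmic event into an RR series
#'
#' Single PC with compensatory pause: coupling RR = `base_rr * (1 -
#' prematurity)` and return RR = `2 * base_rr - coupling`, so coupling +
#' return equals two base cycles exactly. Non-compensatory: the return
#' cycle is a plain base cycle (sum < 2 base cycles). Couplet/triplet/run:
#' `run_length` consecutive shortened RRs followed by one return cycle.
#' pAF: a contiguous block of i.i.d. RRs uniform on
#' `(0.7, 1.4) * base_rr`. All arithmetic is integer-ms so the
#' compensatory identity holds exactly after serialisation.
#'
#' @param rr_series integer RR series (ms).
#' @param spec an [event_spec()].
#' @param base_rr local base RR in ms (defaults to `rr_series[at]`).
#' @param at index of the first affected RR (defaults to the position
#'   implied by `spec$onset`).
#' @return list: `rr` (modified series), `span` (RR-index range of the
#'   premature/paf intervals, excluding the return cycle).
#' @export
inject_event <- function(rr_series, spec, base_rr = NULL, at = NULL) {
  m <- length(rr_series)
  if (is.null(at)) at <- max(2L, min(m - spec$run_length - 1L,
                                     round(spec$onset * m)))
  if (is.null(base_rr)) base_rr <- rr_series[at]
  k <- spec$run_length
  if (at + k > m)
    stop("event span does not fit within the series", call. = FALSE)
  rr <- rr_series
  if (spec$kind == "paf") {
    rr[at:(at + k - 1L)] <- round(stats::runif(k, 0.7 * base_rr,
                                               1.4 * base_rr))
  } else {
    if (spec$prematurity <= 0 || spec$prematurity >= 1)
      stop("prematurity must be in (0,1)", call. = FALSE)
    coupling <- round(base_rr * (1 - spec$prematurity))
    rr[at:(at + k - 1L)] <- coupling
    rr[at + k] <- if (spec$kind == "single_pc" &&
                      spec$pause == "non_compensatory") base_rr
                  else 2 * base_rr - coupling
  }
  list(rr = rr, span = c(at, at + k - 1L))
}

#' Simulate a tachogram with ground truth
#'
#' Baseline beats follow `RR(t) = 60000 / HR(t)` perturbed by
#' band-limited multiplicative sinus noise; planned events and
#' Poisson-thinned spontaneous single PCs are injected at the horse's
#' intensity (`base_pc_rate * cardiac_rate_ratio^cardiac *
#' pc_propensity`); a contiguous artifact window masks a fraction of the
#' recording drawn from `artifact_fraction_range`.
#'
#' @param trajectory from [simulate_hr_trajectory()].
#' @param horse one-row horse data.frame from [sample_cohort()].
#' @param plan the workout plan.
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to the plan's `workout_seed`).
#' @return list: `tachogram` (a [tachogram()] with metadata and
#'   morphology widths) and `ground_truth` (per-beat labels + event
#'   ledger data.frame).
#' @export
simulate_tachogram <- function(trajectory, horse, plan, config,
                               seed = plan$workout_seed) {
  set.seed(seed + 1L)
  T_ms <- attr(trajectory, "duration_ms")
  sigma <- sqrt(log(1 + config$sinus_cv^2))
  phi <- config$sinus_cor
  # generate baseline beats (preallocated; RR never below 200 ms)
  cap <- ceiling(T_ms / 200) + 8L
  rr <- numeric(cap); times <- numeric(cap)
  t_cur <- 0; z <- 0; m <- 0L
  repeat {
    hr <- trajectory(t_cur)
    step <- 60000 / hr
    if (sigma > 0) {
      z <- phi * z + stats::rnorm(1, 0, sigma * sqrt(1 - phi^2))
      step <- step * exp(z - sigma^2 / 2)
    }
    t_cur <- t_cur + step
    if (t_cur > T_ms) break
    m <- m + 1L
    rr[m] <- step
    times[m + 1L] <- t_cur
  }
  rr <- round(rr[seq_len(m)])
  times <- times[seq_len(m + 1L)]
  # assemble injections: planned events + spontaneous singles
  intensity <- config$base_pc_rate / 1000 *
    (if (horse$cardiac) config$cardiac_rate_ratio else 1) *
    horse$pc_propensity
  specs <- plan$injections
  if (intensity > 0) {
    hits <- which(stats::runif(m) < intensity)
    hits <- hits[hits > 12 & hits < m - 12]
    for (i in hits) {
      specs[[length(specs) + 1]] <- event_spec(
        "single_pc",
        prematurity = stats::runif(1, config$pc_prematurity_range[1],
                                   config$pc_prematurity_range[2]),
        pause = sample(c("compensatory", "non_compensatory"), 1),
        morphology = sample(c("narrow", "wide"), 1, prob = c(0.9, 0.1)),
        onset = i / m)
    }
  }
  # realise events with forward-shift collision resolution
  occupied <- rep(FALSE, m)
  decel_at <- c(attr(trajectory, "decel_start_ms"),
                attr(trajectory, "decel_end_ms"))
  ledger <- list()
  labels_rr <- rep("normal", m)
  for (spec in specs) {
    at <- if (!is.null(decel_at) && identical(spec$phase_hint, "deceleration")) {
      cand <- which(times[-1] >= decel_at[1] & times[-1] < decel_at[2])
      if (length(cand)) cand[max(1L, ceiling(length(cand) / 2))]
      else round(spec$onset * m)
    } else max(2L, min(m - spec$run_length - 1L, round(spec$onset * m)))
    k <- spec$run_length
    pad <- 3L
    shifted <- FALSE
    while (at + k + pad <= m &&
           any(occupied[max(1, at - pad):min(m, at + k + pad)])) {
      at <- at + 1L; shifted <- TRUE
    }
    if (at + k + pad > m || at < 2L) {
      ledger[[length(ledger) + 1]] <- ledger_row(spec, NA, NA, FALSE)
      next
    }
    res <- inject_event(rr, spec, at = at)
    rr <- res$rr
    span <- res$span
    occupied[max(1, span[1] - pad):min(m, span[2] + pad + 1L)] <- TRUE
    labels_rr[span[1]:span[2]] <-
      if (spec$kind == "paf") "paf" else "premature"
    ledger[[length(ledger) + 1]] <- ledger_row(spec, span[1] + 1L,
                                               span[2] + 1L, TRUE,
                                               shifted)
  }
  beat_times <- cumsum(c(0, rr))
  n <- m + 1L
  # artifact window (contiguous), placed avoiding realised events
  quality <- rep(TRUE, n)
  frac <- stats::runif(1, config$artifact_fraction_range[1],
                       config$artifact_fraction_range[2])
  if (frac > 0) {
    win <- frac * beat_times[n]
    idx <- integer(0)
    for (try in 1:50) {
      s <- stats::runif(1, 0, beat_times[n] - win)
      idx <- which(beat_times >= s & beat_times < s + win)
      if (!length(idx)) next
      if (!any(occupied[pmax(1, idx - 1L)])) break
    }
    quality[idx] <- FALSE
  }
  labels <- c("normal", labels_rr)
  labels[!quality] <- "artifact"
  width <- stats::runif(n, 0.97, 1.03)
  ledger_df <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(kind = character(0), run_length = integer(0),
               prematurity = numeric(0), pause = character(0),
               morphology = character(0), phase_hint = character(0),
               onset = numeric(0), start_beat = integer(0),
               end_beat = integer(0), realised = logical(0),
               shifted = logical(0))
  wide_ev <- which(ledger_df$realised & ledger_df$morphology == "wide" &
                     ledger_df$kind != "paf")
  for (k in wide_ev)
    width[ledger_df$start_beat[k]:ledger_df$end_beat[k]] <-
      stats::runif(ledger_df$end_beat[k] - ledger_df$start_beat[k] + 1L,
                   1.45, 1.6)
  meta <- workout_meta(plan$horse_id, plan$workout_id, plan$type,
                       level = horse$level, season = plan$season,
                       age = horse$age,
                       duration_min = beat_times[n] / 60000,
                       cardiac = horse$cardiac)
  t <- tachogram(beat_times, quality = quality, morphology_width = width,
                 meta = meta)
  gt <- list(labels = labels, ledger = ledger_df)
  list(tachogram = t, ground_truth = gt)
}

ledger_row <- function(spec, start_beat, end_beat, realised,
                       shifted = FALSE) {
  data.frame(kind = spec$kind, run_length = spec$run_length,
             prematurity = spec$prematurity, pause = spec$pause,
             morphology = spec$morphology, phase_hint = spec$phase_hint,
             onset = spec$onset, start_beat = start_beat,
             end_beat = end_beat, realised = realised, shifted = shifted,
             stringsAsFactors = FALSE)
}

#' Simulate one workout end to end
#'
#' @param horse one-row horse data.frame.
#' @param plan a workout plan from [sample_cohort()].
#' @param config a [simulation_config()].
#' @return as [simulate_tachogram()].
#' @export
simulate_workout <- function(horse, plan, config) {
  traj <- simulate_hr_trajectory(plan, seed = plan$workout_seed)
  simulate_tachogram(traj, horse, plan, config, seed = plan$workout_seed)
}
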