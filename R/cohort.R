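#' Prevalence as a percentage
#'
#' `100 * count / n`, reported to one decimal place (the renderer drops a
#' trailing ".0" when printing whole percentages).
#' @param count numerator (0 <= count <= n).
#' @param n denominator (> 0).
#' @param digits decimals reported (default 1).
#' @export
prevalence <- function(count, n, digits = 1) {
  if (any(n == 0)) stop("prevalence undefined for n = 0", call. = FALSE)
  if (any(count < 0 | count > n))
    stop("count must lie in [0, n]", call. = FALSE)
  round(100 * count / n, digits)
}

#' Build the group x TYPE summary table
#'
#' For each group (CARDIAC, NON_CARDIAC, and optionally ALL) and each
#' workout type present, plus a Total row per group: medians and ranges
#' of nPC, HR_peak and HR_mean, and counts with percentages of the three
#' arrhythmia flags. Only workouts passing the readability gate
#' (`included`) are used.
#'
#' @param results cohort results data.frame (rows from
#'   [summarize_workout()], or any table with the same columns).
#' @param include_all add the pooled ALL group (default TRUE).
#' @return data.frame of summary rows.
#' @export
build_group_summary <- function(results, include_all = TRUE) {
  if (!nrow(results)) stop("empty results table", call. = FALSE)
  bad <- setdiff(unique(as.character(results$type)), TYPE_LEVELS)
  if (length(bad))
    stop("unknown workout type: '", bad[1], "'", call. = FALSE)
  if ("included" %in% names(results)) results <- results[results$included, ]
  groups <- list(CARDIAC = results[results$cardiac, ],
                 NON_CARDIAC = results[!results$cardiac, ])
  if (include_all) groups$ALL <- results
  out <- list()
  for (g in names(groups)) {
    df <- groups[[g]]
    if (!nrow(df)) next
    types <- TYPE_LEVELS[TYPE_LEVELS %in% unique(as.character(df$type))]
    for (ty in c(types, "Total")) {
      sub <- if (ty == "Total") df else df[df$type == ty, ]
      out[[length(out) + 1]] <- summary_row(g, ty, sub)
    }
  }
  do.call(rbind, out)
}

summary_row <- function(group, type, sub) {
  n <- nrow(sub)
  med <- function(x) if (all(is.na(x))) NA_real_ else
    stats::median(x, na.rm = TRUE)
  rng <- function(x, f) if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  cnt <- function(flag) sum(sub[[flag]], na.rm = TRUE)
  data.frame(
    group = group, type = type, n = n,
    npc_median = med(sub$nPC), npc_min = rng(sub$nPC, min),
    npc_max = rng(sub$nPC, max),
    arrhythmia_count = cnt("arrhythmia"),
    arrhythmia_pct = prevalence(cnt("arrhythmia"), n),
    deceleration_count = cnt("arrhythmia_deceleration"),
    deceleration_pct = prevalence(cnt("arrhythmia_deceleration"), n),
    complex_count = cnt("arrhythmia_complex"),
    complex_pct = prevalence(cnt("arrhythmia_complex"), n),
    hr_peak_median = med(sub$hr_peak), hr_peak_min = rng(sub$hr_peak, min),
    hr_peak_max = rng(sub$hr_peak, max),
    hr_mean_median = med(sub$hr_mean), hr_mean_min = rng(sub$hr_mean, min),
    hr_mean_max = rng(sub$hr_mean, max),
    stringsAsFactors = FALSE)
}

#' Chan interpretation band for Spearman's rho
#'
#' None = 0, Poor = (0, 0.2), Fair = [0.2, 0.6), Moderate = [0.6, 0.8),
#' Strong = [0.8, 1), Perfect = 1; intervals are right-open so each |rho|
#' maps to exactly one band.
#' @param rho correlation in `[-1, 1]`.
#' @export
chan_band <- function(rho) {
  a <- abs(rho)
  if (a == 0) "None"
  else if (a < 0.2) "Poor"
  else if (a < 0.6) "Fair"
  else if (a < 0.8) "Moderate"
  else if (a < 1) "Strong"
  else "Perfect"
}

#' Spearman rank correlation with Chan band
#'
#' Average ranks for ties; two-sided p-value via the large-sample t
#' approximation, or by exact permutation for n <= 9.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list of class `association_result`: `rho`, `p_value`, `band`,
#'   `n`, `method`.
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for constant input", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-10) rho <- sign(rho)   # clamp numerical noise
  if (n <= 9) {
    perms <- perm_matrix(n)
    rho_p <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_p) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    r2 <- min(rho^2, 1 - 1e-12)
    tt <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = p, band = chan_band(rho), n = n,
                 method = method), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("rho = %.3f (%s), p = %.4g (n = %d, %s)\n", x$rho, x$band,
              x$p_value, x$n, x$method))
  invisible(x)
}

perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Screen fixed-effect terms for collinearity
#'
#' Flags any continuous term whose R-squared against the remaining fixed
#' terms exceeds `r2_cutoff` (0.8, i.e. VIF > 5). Mirrors the cohort
#' study's handling of peak heart rate and duration, which track the
#' workout type too closely to enter the same model.
#'
#' @param data model data.frame.
#' @param terms character vector of fixed-effect term names.
#' @param r2_cutoff threshold (default 0.8).
#' @return data.frame `term`, `r2` of flagged terms (0 rows if none).
#' @export
collinearity_screen <- function(data, terms, r2_cutoff = 0.8) {
  out <- data.frame(term = character(0), r2 = numeric(0))
  num <- terms[vapply(terms, function(tm) is.numeric(data[[tm]]) &&
                        length(unique(data[[tm]])) > 2, logical(1))]
  for (tm in num) {
    others <- setdiff(terms, tm)
    if (!length(others)) next
    f <- stats::as.formula(paste(tm, "~", paste(others, collapse = " + ")))
    r2 <- suppressWarnings(summary(stats::lm(f, data = data))$r.squared)
    if (!is.na(r2) && r2 > r2_cutoff)
      out <- rbind(out, data.frame(term = tm, r2 = r2))
  }
  out
}

prep_model_data <- function(results, terms) {
  df <- as.data.frame(results)
  if ("type" %in% names(df))
    df$type <- factor(as.character(df$type), levels = TYPE_LEVELS)
  if ("cardiac" %in% names(df)) df$cardiac <- as.numeric(df$cardiac)
  df
}

fit_mixed_glm <- function(results, outcome, fixed_terms, random, family,
                          screen, ratio_label) {
  df <- prep_model_data(results, fixed_terms)
  if (length(unique(df[[random]])) < 2)
    stop("need at least 2 grouping units for a mixed model", call. = FALSE)
  dropped <- data.frame(term = character(0), r2 = numeric(0))
  if (screen && length(fixed_terms) > 1) {
    dropped <- collinearity_screen(df, fixed_terms)
    fixed_terms <- setdiff(fixed_terms, dropped$term)
  }
  f <- stats::as.formula(paste(outcome, "~",
                               paste(fixed_terms, collapse = " + "),
                               "+ (1 |", random, ")"))
  fit <- suppressMessages(lme4::glmer(f, data = df, family = family))
  pooled <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4)) {
    warning("singular random-effect fit; falling back to pooled GLM")
    pooled <- TRUE
    fp <- stats::as.formula(paste(outcome, "~",
                                  paste(fixed_terms, collapse = " + ")))
    gfit <- stats::glm(fp, data = df, family = family)
    est <- summary(gfit)$coefficients
    ranef_var <- 0
  } else {
    est <- summary(fit)$coefficients
    ranef_var <- as.numeric(lme4::VarCorr(fit)[[random]])
  }
  beta <- est[, 1]; se <- est[, 2]
  if (family == "binomial" && any(abs(beta[-1]) > 15 | se[-1] > 15))
    stop("apparent complete separation; remove the offending term",
         call. = FALSE)
  z <- stats::qnorm(0.975)
  tab <- data.frame(term = rownames(est), estimate = exp(beta),
                    ci_lo = exp(beta - z * se), ci_hi = exp(beta + z * se),
                    p = est[, 4], row.names = NULL)
  names(tab)[2] <- ratio_label
  structure(list(outcome = outcome, terms = tab, ranef_var = ranef_var,
                 random = random, reference = list(type = "Flat"),
                 dropped_terms = dropped, pooled = pooled,
                 family = family), class = "model_result")
}

#' Mixed-effects logistic regression for an arrhythmia flag
#'
#' Random-intercept-per-horse logistic model (Laplace approximation via
#' lme4); estimates reported as odds ratios with Wald 95% CIs. The
#' workout-type factor uses Flat as reference. Continuous confounders are
#' screened for collinearity first and dropped terms reported. On a
#' singular random effect the model falls back to a pooled GLM with a
#' warning and `pooled = TRUE` (the zero-variance limit).
#'
#' @param results cohort results data.frame.
#' @param outcome name of a binary column (e.g. `"arrhythmia"`).
#' @param fixed_terms character vector of fixed-effect columns.
#' @param random grouping column (default `"horse_id"`).
#' @param screen run [collinearity_screen()] first (default TRUE).
#' @return a `model_result` list: `terms` (OR, CI, p), `ranef_var`,
#'   `dropped_terms`, `pooled`.
#' @export
fit_mixed_logistic <- function(results, outcome = "arrhythmia",
                               fixed_terms = c("cardiac", "type"),
                               random = "horse_id", screen = TRUE) {
  vals <- stats::na.omit(unique(as.numeric(results[[outcome]])))
  if (!all(vals %in% c(0, 1)))
    stop("outcome must be binary", call. = FALSE)
  fit_mixed_glm(results, outcome, fixed_terms, random, "binomial", screen,
                "odds_ratio")
}

#' Mixed-effects Poisson regression for the PC count
#'
#' Random-intercept Poisson model for nPC per workout (no exposure
#' offset: the count is modelled per workout as in the source analyses);
#' estimates reported as incidence rate ratios with Wald 95% CIs.
#' @inheritParams fit_mixed_logistic
#' @export
fit_mixed_poisson <- function(results, outcome = "nPC",
                              fixed_terms = c("cardiac", "type"),
                              random = "horse_id", screen = TRUE) {
  y <- results[[outcome]]
  if (any(y < 0 | y != round(y), na.rm = TRUE))
    stop("outcome must be non-negative integers", call. = FALSE)
  if (all(y == 0, na.rm = TRUE))
    stop("degenerate fit: outcome is all zero", call. = FALSE)
  fit_mixed_glm(results, outcome, fixed_terms, random, "poisson", screen,
                "rate_ratio")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("Mixed-effects %s model for %s (random intercept: %s%s)\n",
              x$family, x$outcome, x$random,
              if (x$pooled) "; POOLED fallback" else ""))
  print(x$terms, digits = 3)
  cat(sprintf("random-effect variance: %.4f\n", x$ranef_var))
  if (nrow(x$dropped_terms))
    cat("dropped for collinearity:",
        paste(x$dropped_terms$term, collapse = ", "), "\n")
  invisible(x)
}
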