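test_that("prevalence reproduces printed-precision percentages", {
  expect_equal(prevalence(109, 202), 54.0)
  expect_equal(prevalence(0, 7), 0.0)
  expect_equal(prevalence(13, 737), 1.8)
  expect_error(prevalence(1, 0), "n = 0")
  expect_error(prevalence(5, 3), "count")
  # scale-free
  expect_equal(prevalence(13, 737), prevalence(13 * 3, 737 * 3))
})

test_that("group summary satisfies table conservation", {
  cfg <- simulation_config(n_horses = 8, workouts_per_horse = c(3, 6),
                           seed = 19)
  co <- sample_cohort(cfg)
  set.seed(19)
  n <- length(co$plans)
  res <- do.call(rbind, lapply(co$plans, function(p) {
    h <- co$horses[co$horses$horse_id == p$horse_id, ]
    arr <- runif(1) < 0.4
    data.frame(horse_id = p$horse_id, workout_id = p$workout_id,
               type = p$type, level = h$level, season = p$season,
               age = h$age, duration_min = p$duration_min,
               cardiac = h$cardiac, readable_fraction = 1, included = TRUE,
               nPC = ifelse(arr, rpois(1, 3) + 1L, 0L), arrhythmia = arr,
               arrhythmia_deceleration = arr & runif(1) < 0.3,
               arrhythmia_complex = arr & runif(1) < 0.1,
               hr_peak = runif(1, 120, 230), hr_mean = runif(1, 60, 120))
  }))
  tab <- build_group_summary(res)
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, ]
    tot <- sub[sub$type == "Total", ]
    per <- sub[sub$type != "Total", ]
    expect_equal(sum(per$n), tot$n)
    for (cl in c("arrhythmia_count", "deceleration_count", "complex_count"))
      expect_equal(sum(per[[cl]]), tot[[cl]])
  }
  # ALL = CARDIAC + NON_CARDIAC
  tc <- tab[tab$group == "CARDIAC" & tab$type == "Total", ]
  tn <- tab[tab$group == "NON_CARDIAC" & tab$type == "Total", ]
  ta <- tab[tab$group == "ALL" & tab$type == "Total", ]
  expect_equal(tc$n + tn$n, ta$n)
  expect_equal(tc$arrhythmia_count + tn$arrhythmia_count,
               ta$arrhythmia_count)

  res_bad <- res; res_bad$type[1] <- "Dressage"
  expect_error(build_group_summary(res_bad), "Dressage")

  # single workout without flags: zeros everywhere
  one <- res[1, ]
  one$arrhythmia <- one$arrhythmia_deceleration <-
    one$arrhythmia_complex <- FALSE
  one$nPC <- 0L
  t1 <- build_group_summary(one, include_all = FALSE)
  tot1 <- t1[t1$type == "Total", ]
  expect_equal(tot1$arrhythmia_count, 0L)
  expect_equal(tot1$arrhythmia_pct, 0.0)
})

test_that("Chan bands use right-open intervals", {
  expect_equal(chan_band(0), "None")
  expect_equal(chan_band(0.1), "Poor")
  expect_equal(chan_band(0.2), "Fair")
  expect_equal(chan_band(0.37), "Fair")   # the nPC-age exploratory value
  expect_equal(chan_band(0.6), "Moderate")
  expect_equal(chan_band(-0.7), "Moderate")
  expect_equal(chan_band(0.8), "Strong")
  expect_equal(chan_band(0.999), "Strong")
  expect_equal(chan_band(1), "Perfect")
})

test_that("Spearman association handles ties, transforms and small n", {
  a <- spearman_assoc(1:10, (1:10)^3)
  expect_equal(a$rho, 1)
  expect_equal(a$band, "Perfect")
  # invariance under strictly monotone transforms
  set.seed(3)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(spearman_assoc(x, y)$rho,
               spearman_assoc(exp(x), y^3 + 5 * y)$rho)
  expect_error(spearman_assoc(rep(1, 5), 1:5), "constant")
  # exact permutation p agrees with cor.test's exact method (untied, n=6)
  x6 <- c(3, 1, 4, 1.5, 9, 2.6); y6 <- c(2, 7, 1, 8, 2.8, 1.8)
  ours <- spearman_assoc(x6, y6)
  ref <- cor.test(x6, y6, method = "spearman", exact = TRUE)
  expect_equal(ours$rho, unname(ref$estimate))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$method, "exact permutation")
  # independent pairs: null bound ~ 2.5/sqrt(n)
  set.seed(101)
  z <- spearman_assoc(rnorm(1000), rnorm(1000))
  expect_lt(abs(z$rho), 0.08)
})

test_that("collinearity screen flags near-aliased continuous terms", {
  set.seed(77)
  n <- 210
  df <- data.frame(type = factor(sample(TYPE_LEVELS, n, replace = TRUE),
                                 levels = TYPE_LEVELS))
  type_mean <- c(Flat = 140, Hack = 145, Trot = 146, Jumping = 176,
                 XC_School = 192, Gallop = 195, Competition = 213)
  df$hr_peak <- type_mean[as.character(df$type)] + rnorm(n, 0, 3)
  df$age <- runif(n, 6, 19)
  flagged <- collinearity_screen(df, c("type", "hr_peak", "age"))
  expect_true("hr_peak" %in% flagged$term)
  expect_false("age" %in% flagged$term)
  expect_equal(nrow(collinearity_screen(
    data.frame(a = rnorm(n), b = rnorm(n)), c("a", "b"))), 0L)
  dup <- data.frame(a = rnorm(n)); dup$b <- dup$a
  fl <- collinearity_screen(dup, c("a", "b"))
  expect_equal(sort(fl$term), c("a", "b"))
  expect_equal(fl$r2, c(1, 1), tolerance = 1e-12)
})

test_that("zero-variance mixed fits reduce to the pooled GLM", {
  # perfectly balanced toy: every horse shows the identical outcome
  # pattern, so the horse-variance MLE is exactly zero (singular fit)
  n_h <- 20
  df <- do.call(rbind, lapply(seq_len(n_h), function(h)
    data.frame(horse_id = sprintf("H%02d", h),
               x = c(0, 0, 0, 1, 1, 1), y = c(0, 0, 1, 0, 1, 1))))
  fit <- suppressWarnings(fit_mixed_logistic(df, "y", "x",
                                             random = "horse_id",
                                             screen = FALSE))
  ref <- glm(y ~ x, binomial, df)
  expect_equal(log(fit$terms$odds_ratio), unname(coef(ref)),
               tolerance = 1e-3)
  expect_true(fit$pooled)
  expect_equal(fit$ranef_var, 0)
})

test_that("mixed model guards reject degenerate inputs", {
  df <- data.frame(horse_id = rep(c("a", "b"), each = 5),
                   y = rep(0L, 10), x = rnorm(10), nPC = rep(0L, 10))
  expect_error(fit_mixed_poisson(df, "nPC", "x"), "degenerate")
  df$y2 <- seq(0, 9)
  expect_error(fit_mixed_logistic(df, "y2", "x"), "binary")
  df1 <- data.frame(horse_id = "a", y = c(0, 1, 0, 1), x = rnorm(4))
  expect_error(fit_mixed_logistic(df1, "y", "x"), "grouping")
})

test_that("mixed logistic recovers a known group effect (single replicate)", {
  set.seed(42)
  n_h <- 60; n_w <- 12
  horse <- rep(seq_len(n_h), each = n_w)
  cardiac <- rep(c(rep(1, 12), rep(0, 48)), each = n_w)
  b_h <- rep(rnorm(n_h, 0, 0.5), each = n_w)
  eta <- -1.0 + log(3) * cardiac + b_h
  df <- data.frame(horse_id = sprintf("H%02d", horse), cardiac = cardiac,
                   y = rbinom(n_h * n_w, 1, plogis(eta)))
  fit <- suppressWarnings(fit_mixed_logistic(df, "y", "cardiac",
                                             screen = FALSE))
  row <- fit$terms[fit$terms$term == "cardiac", ]
  # smoke-level recovery: the effect is found, in the right ballpark,
  # and the CI brackets its own point estimate (coverage itself is
  # checked over 100 replicates in the acceptance suite)
  expect_lt(row$p, 0.05)
  expect_lt(abs(log(row$odds_ratio) - log(3)), 1)
  expect_true(row$ci_lo < row$odds_ratio && row$odds_ratio < row$ci_hi)
  expect_gte(fit$ranef_var, 0)
})
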