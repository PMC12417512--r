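# Subgroup assignment, Kaplan-Meier estimation, landmark Z-tests, and the
# outcome-driven threshold optimizer.

test_that("subgroup assignment follows the threshold rule and partitions", {
  expect_equal(as.character(assign_subgroup(32, 10, 26.5)), "sources_ablated")
  expect_equal(as.character(assign_subgroup(10, 10, 26.5)), "no_sources")
  expect_equal(as.character(assign_subgroup(10, 30, 26.5)), "increasing_sources")
  expect_equal(as.character(assign_subgroup(30, 30, 26.5)), "above_threshold")
  # boundary: activity equal to the threshold counts as "at threshold"
  expect_equal(as.character(assign_subgroup(26.5, 26.5, 26.5)), "above_threshold")
  # partition property on a random cohort
  set.seed(9)
  b <- runif(500, 0, 60); f <- runif(500, 0, 60)
  g <- assign_subgroup(b, f, 26.5)
  expect_false(anyNA(g))
  expect_equal(sum(table(g)), 500)
})

test_that("KM curve equals the hand product-limit and empirical survivor", {
  # 4 patients, events at months 2 and 5, no censoring: S(5) = (3/4)(2/3)
  t4 <- c(2, 5, 8, 9); e4 <- c(1, 1, 1, 1)
  km <- km_curve(t4, e4)
  expect_equal(km_at(km, 5)[["surv"]], 0.5)
  ref <- reference_product_limit(t4, e4)
  expect_equal(km$surv, ref$surv)
  # censoring-free data: KM equals the empirical survivor function
  set.seed(21)
  tt <- sample(1:24, 60, replace = TRUE)
  km2 <- km_curve(tt, rep(1, 60))
  for (h in c(3, 12, 20)) {
    expect_equal(km_at(km2, h)[["surv"]], mean(tt > h))
  }
  # all events at month 1
  expect_equal(km_at(km_curve(rep(1, 5), rep(1, 5)), 1)[["surv"]], 0)
  # no events: survival 1 throughout, zero variance
  km3 <- km_curve(rep(12, 10), rep(0, 10))
  expect_equal(km_at(km3, 12), c(surv = 1, var = 0))
  expect_error(km_curve(numeric(0), numeric(0)), "empty group")
})

test_that("Greenwood variance matches the hand formula", {
  t6 <- c(1, 3, 3, 6, 8, 10); e6 <- c(1, 1, 0, 1, 0, 1)
  km <- km_curve(t6, e6)
  # hand Greenwood: Var(S) = S^2 * sum d_i / (n_i (n_i - d_i))
  S <- 1; acc <- 0; n <- 6
  hand <- NULL
  for (ti in sort(unique(t6[e6 == 1]))) {
    n_risk <- sum(t6 >= ti); d <- sum(t6 == ti & e6 == 1)
    S <- S * (1 - d / n_risk)
    acc <- acc + d / (n_risk * (n_risk - d))
    hand <- rbind(hand, c(ti, S, S^2 * acc))
  }
  expect_equal(km$time, hand[, 1])
  expect_equal(km$surv, hand[, 2])
  expect_equal(km$var, hand[, 3])
})

test_that("landmark Z-test reproduces the printed Z -> p arithmetic", {
  p_of <- function(z) 2 * pnorm(-abs(z))
  expect_equal(signif(p_of(2.410), 3), 0.0160)
  expect_equal(signif(p_of(3.213), 3), 0.00131)
  expect_lte(p_of(4.486), 0.001)
  # the same numbers must come out of survival_z_test on curves built to
  # a known survival difference and variance
  a <- structure(list(time = 6, surv = 0.9, var = 0.002), class = "km_curve")
  b <- structure(list(time = 6, surv = 0.7, var = 0.003), class = "km_curve")
  zt <- survival_z_test(a, b, 12)
  expect_equal(zt$z, (0.9 - 0.7) / sqrt(0.005))
  expect_equal(zt$p, p_of(zt$z))
  # symmetry and monotonicity of p in |Z|
  expect_equal(p_of(-2.2), p_of(2.2))
  zs <- seq(0, 5, by = 0.25)
  expect_true(all(diff(p_of(zs)) < 0))
  expect_equal(p_of(0), 1)
})

test_that("degenerate comparisons are handled per contract", {
  a <- structure(list(time = 6, surv = 1, var = 0), class = "km_curve")
  b <- structure(list(time = 6, surv = 1, var = 0), class = "km_curve")
  expect_equal(survival_z_test(a, b, 12)$z, 0)
  expect_equal(survival_z_test(a, b, 12)$p, 1)
  d <- structure(list(time = 6, surv = 0.5, var = 0), class = "km_curve")
  expect_error(survival_z_test(a, d, 12), "degenerate comparison")
})

test_that("optimizer finds the separating boundary of a separable cohort", {
  set.seed(4)
  n <- 160
  act <- c(runif(n / 2, 5, 29), runif(n / 2, 30, 55))
  ev <- as.integer(act >= 30)
  cohort <- data.frame(patient_id = seq_len(n), baseline_activity_pct = act,
                       final_activity_pct = act, event = ev,
                       event_time_months = ifelse(ev == 1, 6, 12),
                       followup_months = 12)
  opt <- optimize_threshold(cohort, n_cycles = 20, subset_size = 110,
                            rng_seed = 2)
  expect_gt(opt$cutoff, 29)
  expect_lte(opt$cutoff, 30)
  # invariant to patient ordering, reproducible under the seed
  perm <- sample(n)
  opt2 <- optimize_threshold(cohort[perm, ], n_cycles = 20, subset_size = 110,
                             rng_seed = 2)
  expect_equal(opt2$cutoff, opt$cutoff)
  expect_equal(opt2$trajectory$cutoff, opt$trajectory$cutoff)
})

test_that("optimizer reports chance-level accuracy on permuted outcomes", {
  cohort <- simulate_cohort(200, rng_seed = 77)
  set.seed(78)
  cohort$event <- sample(cohort$event)
  cohort$event_time_months <- ifelse(cohort$event == 1,
                                     runif(200, 0, 12), 12)
  opt <- optimize_threshold(cohort, n_cycles = 50, subset_size = 110,
                            rng_seed = 79)
  # balanced accuracy of the best cutoff hovers at the permutation null;
  # the grid-search maximum sits slightly above 0.5 by selection
  expect_gt(mean(opt$trajectory$balanced_accuracy), 0.43)
  expect_lt(mean(opt$trajectory$balanced_accuracy) - 0.5, 0.12)
})

test_that("degenerate cohorts yield no cutoff and a warning", {
  cohort <- simulate_cohort(120, p_recur_above = 0, p_recur_below = 0,
                            rng_seed = 3)
  expect_warning(opt <- optimize_threshold(cohort, n_cycles = 5,
                                           subset_size = 110, rng_seed = 3),
                 "no signal")
  expect_true(is.na(opt$cutoff))
})

test_that("subgroup report covers present pairs and flags real hazards", {
  cohort <- simulate_cohort(220, rng_seed = 14)
  rep1 <- subgroup_report(cohort, threshold = 26.5, horizon_months = 12)
  g <- assign_subgroup(cohort$baseline_activity_pct,
                       cohort$final_activity_pct, 26.5)
  expect_equal(nrow(rep1), choose(length(unique(g)), 2))
  expect_true(all(rep1$p >= 0 & rep1$p <= 1))
  # identical groups: copied data must give Z = 0, p = 1
  half <- cohort[1:55, ]
  dup <- rbind(transform(half, baseline_activity_pct = 10,
                         final_activity_pct = 10),
               transform(half, baseline_activity_pct = 40,
                         final_activity_pct = 10))
  repd <- subgroup_report(dup, threshold = 26.5)
  expect_equal(repd$z, rep(0, nrow(repd)))
  expect_equal(repd$p, rep(1, nrow(repd)))
  # log-rank alternative runs and agrees on the null-ish comparison sign
  repl <- subgroup_report(cohort, threshold = 26.5, method = "logrank")
  expect_equal(nrow(repl), nrow(rep1))
})

test_that("same-distribution subgroups rarely test significant, and a 3x
          hazard between realistic group sizes usually does", {
  n_rep <- 50
  null_ps <- numeric(n_rep); alt_ps <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    # null: no_sources vs sources_ablated share the event rate
    nA <- 110; nB <- 27
    evA <- rbinom(nA, 1, 0.2); evB <- rbinom(nB, 1, 0.2)
    coh <- data.frame(
      patient_id = seq_len(nA + nB),
      baseline_activity_pct = c(rep(10, nA), rep(40, nB)),
      final_activity_pct = rep(10, nA + nB),
      event = c(evA, evB),
      event_time_months = ifelse(c(evA, evB) == 1,
                                 runif(nA + nB, 0, 12), 12),
      followup_months = 12)
    rp <- subgroup_report(coh, 26.5)
    null_ps[r] <- rp$p[rp$comparison == "no_sources vs sources_ablated"]
    # alternative: above_threshold with ~3x event hazard vs no_sources
    nC <- 29
    evC <- rbinom(nC, 1, 0.55)
    coh2 <- data.frame(
      patient_id = seq_len(nA + nC),
      baseline_activity_pct = c(rep(10, nA), rep(40, nC)),
      final_activity_pct = c(rep(10, nA), rep(40, nC)),
      event = c(evA, evC),
      event_time_months = ifelse(c(evA, evC) == 1,
                                 runif(nA + nC, 0, 12), 12),
      followup_months = 12)
    rp2 <- subgroup_report(coh2, 26.5)
    alt_ps[r] <- rp2$p[rp2$comparison == "no_sources vs above_threshold"]
  }
  expect_gte(mean(null_ps > 0.05), 0.90)
  expect_gte(mean(alt_ps < 0.05), 0.80)
})
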