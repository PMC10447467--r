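test_that("Kaplan-Meier matches hand computation and the no-event case", {
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$surv_fn(c(0, 3, 10)) == 1))
  # times (1 event, 2 event, 3 censored): S(2) = (2/3)(1/2) = 1/3
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv_fn(2), 1 / 3)
  expect_equal(km$surv_fn(1.5), 2 / 3)
})

test_that("Kaplan-Meier equals the brute-force product limit on random data", {
  set.seed(31)
  for (r in 1:30) {
    n <- sample(5:60, 1)
    tt <- sample(1:15, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6)
    km <- km_estimate(tt, ev)
    at <- c(0.5, 3, 7.2, 12, 15)
    expect_equal(km$surv_fn(at), oracle_km(tt, ev, at), tolerance = 1e-12)
  }
})

test_that("log-rank: degenerate duplication gives statistic 0, toy matches hand O-E/V", {
  tt <- c(1, 3, 5, 7, 9); ev <- c(1, 0, 1, 1, 0)
  r <- log_rank_test(c(tt, tt), c(ev, ev), rep(0:1, each = 5))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
  # hand-computed two-group toy (no ties across groups)
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1); grp <- c(0, 1, 0, 1)
  # event times 1..4; O1 = 2; E1 = 2/4 + 1/3 + 1/2 + 0 = 4/3; V = sum of
  # hypergeometric variances: t=1: (2*2)/(4^2) * (3/3) = 1/4; t=2: (1*2)/9 *1
  # = 2/9; t=3: (1*1)/4 = 1/4; t=4: 0
  O1 <- 2; E1 <- 2/4 + 1/3 + 1/2
  V <- (2 * 2) / 16 + (1 * 2) / 9 + (1 * 1) / 4
  r2 <- log_rank_test(time, event, grp)
  expect_equal(r2$statistic, (O1 - E1)^2 / V, tolerance = 1e-10)
  expect_error(log_rank_test(time, event, rep(1, 4)), "2 groups")
})

test_that("Cox fit recovers a known hazard ratio and covers the null", {
  gen <- generator_config()
  set.seed(32)
  x <- rbinom(800, 1, 0.5)
  rec <- sample_outcome(log(2) * x, gen)
  fit <- cox_fit(rec$time, rec$event, data.frame(x = x))
  expect_true(fit$coefficients$lower[1] < 2 && 2 < fit$coefficients$upper[1])
  # covariate independent of outcome: CI covers 1
  z <- rbinom(800, 1, 0.5)
  fit0 <- cox_fit(rec$time, rec$event, data.frame(z = z))
  expect_true(fit0$coefficients$lower[1] < 1 && 1 < fit0$coefficients$upper[1])
  expect_error(cox_fit(rec$time, rec$event, data.frame(k = rep(1, 800))),
               "constant")
})

test_that("Cox score test at beta = 0 equals the log-rank statistic", {
  set.seed(33)
  n <- 60
  tt <- rexp(n) + cumsum(rep(1e-4, n))   # no ties
  ev <- rbinom(n, 1, 0.7); ev[1:2] <- 1
  x <- rbinom(n, 1, 0.5)
  lr <- log_rank_test(tt, ev, x)
  sc <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = "breslow")
  expect_equal(unname(summary(sc)$sctest["test"]), lr$statistic, tolerance = 1e-6)
})

test_that("time-dependent ROC: perfect ordering gives AUC 1, noise gives ~0.5", {
  set.seed(34)
  n <- 200
  tt <- rexp(n, 0.05)
  ev <- rep(1, n)
  r1 <- time_dependent_roc(-tt, tt, ev, stats::median(tt))
  expect_equal(r1$auc, 1, tolerance = 1e-10)
  r2 <- time_dependent_roc(rnorm(n), tt, ev, stats::median(tt))
  expect_lt(abs(r2$auc - 0.5), 0.12)
  expect_error(time_dependent_roc(rnorm(n), tt, ev, max(tt) * 2), "follow-up")
})

test_that("with no censoring the time-dependent AUC equals the binary AUC", {
  set.seed(35)
  for (r in 1:20) {
    n <- 80
    tt <- rexp(n, 0.05) + 0.01
    ev <- rep(1, n)
    sc <- -tt + rnorm(n, sd = 8)
    horizon <- stats::quantile(tt, 0.6)
    td <- time_dependent_roc(sc, tt, ev, horizon, max_cutoffs = 1e6)
    lab <- as.integer(tt <= horizon)
    expect_equal(td$auc, oracle_auc(sc, lab), tolerance = 1e-10)
  }
})

test_that("DeLong: identical scores give p = 1; AUC equals the U statistic", {
  set.seed(36)
  lab <- rbinom(60, 1, 0.5); lab[1:2] <- c(0, 1)
  s <- rnorm(60)
  r <- delong_compare(s, s, lab)
  expect_equal(r$delta_auc, 0)
  expect_equal(r$p, 1)
  expect_equal(r$auc_a, oracle_auc(s, lab), tolerance = 1e-12)
  expect_error(delong_compare(s, s, rep(1, 60)), "degenerate")
})

test_that("classification report matches arithmetic on a constructed table", {
  # class-1-vs-others: TP 8, FN 2, FP 2, TN 8
  truth <- c(rep(1, 10), rep(2, 10))
  pred <- c(rep(1, 8), 2, 2, rep(2, 8), 1, 1)
  rep <- classification_report(truth, pred)
  pc <- rep$per_class[1, ]
  expect_equal(pc$sensitivity, 0.8)
  expect_equal(pc$specificity, 0.8)
  expect_equal(pc$ppv, 0.8)
  expect_equal(pc$npv, 0.8)
  expect_equal(rep$accuracy, 0.8)
  half <- 1.96 * sqrt(0.8 * 0.2 / 20)
  expect_equal(unname(rep$accuracy_ci["upper"] - rep$accuracy), half,
               tolerance = 1e-12)
  # identity prediction: diagonal confusion, accuracy 1
  t2 <- rep(1:4, each = 5)
  r2 <- classification_report(t2, t2)
  expect_equal(sum(diag(r2$confusion)), 20)
  expect_equal(r2$accuracy, 1)
  expect_error(classification_report(c(0, 1), c(1, 1)), "1..4")
})

test_that("concordance index matches the brute-force pair loop", {
  set.seed(37)
  for (r in 1:30) {
    n <- sample(8:40, 1)
    risk <- rnorm(n)
    tt <- sample(1:20, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.6); if (sum(ev) == 0) ev[1] <- 1
    expect_equal(concordance_index(risk, tt, ev), oracle_cindex(risk, tt, ev),
                 tolerance = 1e-12)
  }
  tt <- rexp(50) + 0.1
  expect_equal(concordance_index(-tt, tt, rep(1, 50)), 1)
})

test_that("NRI is zero for identical models, antisymmetric, and matches hand counts", {
  set.seed(38)
  n <- 100
  tt <- rexp(n, 0.05) + 0.1; ev <- rbinom(n, 1, 0.8)
  s <- rnorm(n)
  r0 <- tmesurv:::nri_point(s, s, tt, ev, stats::median(tt))
  expect_equal(r0$nri, 0)
  a <- rnorm(n); b <- rnorm(n)
  h <- stats::quantile(tt, 0.5)
  expect_equal(tmesurv:::nri_point(a, b, tt, ev, h)$nri,
               -tmesurv:::nri_point(b, a, tt, ev, h)$nri, tolerance = 1e-12)
  # no censoring: matches direct reclassification proportions
  ev1 <- rep(1, n)
  hz <- stats::quantile(tt, 0.6)
  isev <- tt <= hz
  up <- a > b; dn <- a < b
  hand <- (mean(up[isev]) - mean(dn[isev])) +
    (mean(dn[!isev]) - mean(up[!isev]))
  expect_equal(tmesurv:::nri_point(a, b, tt, ev1, hz)$nri, hand, tolerance = 1e-12)
})

test_that("a model with added true signal has positive NRI", {
  set.seed(39)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  tt <- rexp(n, 0.05 * exp(0.8 * x1 + 0.8 * x2))
  cens <- runif(n, 0, 40)
  time <- pmin(tt, cens); ev <- as.integer(tt <= cens)
  r <- nri_timepoint(x1 + x2, x1, time, ev, 15, B = 60L)
  expect_gt(r$nri, 0)
  expect_lt(r$p, 0.05)
})

test_that("Brier score: oracle 0, constant 0.5 gives 0.25, reduces to MSE", {
  n <- 50
  tt <- seq(1, 50); ev <- rep(1, n)
  grid <- c(10, 20, 30)
  oracle <- vapply(grid, function(g) as.numeric(tt > g), numeric(n))
  r <- brier_and_ibs(oracle, tt, ev, grid)
  expect_equal(r$curve$brier, rep(0, 3))
  expect_equal(r$ibs, 0)
  r2 <- brier_and_ibs(matrix(0.5, n, 3), tt, ev, grid)
  expect_equal(r2$curve$brier, rep(0.25, 3), tolerance = 1e-12)
  set.seed(40)
  sp <- matrix(runif(n * 3), n, 3)
  r3 <- brier_and_ibs(sp, tt, ev, grid)
  mse <- vapply(seq_along(grid), function(j)
    mean((as.numeric(tt > grid[j]) - sp[, j])^2), numeric(1))
  expect_equal(r3$curve$brier, mse, tolerance = 1e-12)
  expect_error(brier_and_ibs(sp[, 1:2], tt, ev, c(10, 60)), "follow-up")
})

test_that(".632+ prediction error prefers the model with true signal", {
  set.seed(41)
  n <- 150
  x <- rnorm(n)
  noisevar <- rnorm(n)
  t_ev <- rexp(n, 0.05 * exp(x))
  cens <- runif(n, 0, 40)
  df <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
                   x = x, z = noisevar)
  grid <- c(5, 10, 15, 20)
  pec <- prediction_error_632plus(list(null = ~ z, signal = ~ x), df, grid, B = 30L)
  expect_lt(pec$signal$ibs, pec$null$ibs)
  for (m in pec) {
    expect_true(all(m$curve$err632plus >= 0 & m$curve$err632plus <= 1))
    expect_true(all(m$curve$apparent >= 0 & m$curve$apparent <= 1))
  }
})

test_that("calibration curve sits on the diagonal for oracle predictions", {
  set.seed(42)
  n <- 1500
  x <- rnorm(n)
  rate <- 0.04 * exp(0.9 * x)
  t_ev <- rexp(n, rate)
  cens <- runif(n, 0, 60)
  time <- pmin(t_ev, cens); ev <- as.integer(t_ev <= cens)
  horizon <- 15
  pred <- exp(-rate * horizon)   # true survival at horizon
  cal <- calibration_curve(pred, time, ev, horizon, bins = 5L)
  expect_equal(sum(cal$n), n)
  expect_lt(max(abs(cal$predicted - cal$observed)), 0.07)
  # constant predictions collapse to a single bin at the cohort KM estimate
  cal1 <- calibration_curve(rep(0.5, n), time, ev, horizon)
  expect_equal(nrow(cal1), 1L)
  expect_equal(cal1$observed, km_estimate(time, ev)$surv_fn(horizon))
  expect_error(calibration_curve(pred, time, ev, horizon, bins = 2L), "bins")
})

test_that("chi-square importance proportions sum to 1 and split evenly for equal effects", {
  gen <- generator_config()
  set.seed(43)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  rec <- sample_outcome(0.6 * x1 + 0.6 * x2, gen)
  fit <- cox_fit(rec$time, rec$event, data.frame(x1 = x1, x2 = x2))
  imp <- chi2_importance(fit)
  expect_equal(sum(imp$proportion), 1, tolerance = 1e-12)
  expect_lt(abs(imp$proportion[1] - 0.5), 0.12)
  fit1 <- cox_fit(rec$time, rec$event, data.frame(x1 = x1))
  expect_equal(chi2_importance(fit1)$proportion, 1)
})

test_that("integrated model freezes quantile strata fitted on training data", {
  set.seed(44)
  gen <- generator_config(n_subjects = 400L, seed = 45L)
  co <- generate_cohort(gen, generate_images = FALSE)
  co$dls <- 0.8 * co$true_class + rnorm(400, sd = 0.5)
  tr <- co[1:280, ]; va <- co[281:400, ]
  im <- integrated_model(tr)
  # training occupancy ~ n/8 per stratum
  occ <- table(factor(im$strata, 1:8))
  expect_true(all(abs(occ - 280 / 8) <= 1))
  # strata ordered by linear predictor by construction
  mlp <- tapply(im$train_lp, im$strata, mean)
  expect_true(all(diff(mlp) > 0))
  # frozen application to validation: same coefficients, no refit
  ap <- apply_integrated_model(im, va)
  expect_true(all(ap$stratum %in% 1:8))
  expect_equal(ap$lp,
               unname(stats::predict(im$fit$model, newdata = va, type = "lp")))
  # higher strata have worse outcomes on a large cohort
  cidx <- concordance_index(ap$lp, va$time, va$event)
  expect_gt(cidx, 0.55)
})

test_that("risk dichotomization uses the frozen training median with ties high", {
  rc <- risk_cutoff(c(1, 2, 3, 4, 5))
  expect_equal(rc$cutoff, 3)
  g <- apply_risk_groups(c(2.9, 3, 3.1), rc)
  expect_equal(as.character(g), c("low", "high", "high"))
})
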