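test_that("propensity scores equal the treated fraction for uninformative covariates", {
  set.seed(51)
  n <- 600
  tr <- rbinom(n, 1, 0.4)
  x <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.5))
  ps <- fit_propensity(x, tr)
  expect_lt(abs(mean(ps) - mean(tr)), 0.02)
  expect_true(all(ps > 0 & ps < 1))
  # all-constant covariates (plus noise column to avoid degeneracy) -> equal scores
  x2 <- data.frame(a = rep(1, n))
  ps2 <- suppressWarnings(stats::fitted(stats::glm(tr ~ 1, family = stats::binomial())))
  expect_true(max(abs(ps2 - mean(tr))) < 1e-12)
})

test_that("propensity model recovers known logistic coefficients", {
  set.seed(52)
  n <- 2000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  tr <- rbinom(n, 1, plogis(-0.3 + 0.8 * x1 - 0.5 * x2))
  ps <- fit_propensity(data.frame(x1 = x1, x2 = x2), tr)
  fit <- attr(ps, "model")
  cf <- summary(fit)$coefficients
  for (k in 1:3) {
    truth <- c(-0.3, 0.8, -0.5)[k]
    expect_lt(abs(cf[k, 1] - truth), 2.5 * cf[k, 2])
  }
  expect_error(fit_propensity(data.frame(x = tr), tr), "separation")
})

test_that("nearest matching pairs the enumerated optimum on a 4-subject toy", {
  scores <- c(0.2, 0.8, 0.21, 0.79)
  treat <- c(1, 1, 0, 0)
  set.seed(53)
  m <- match_1to1_nearest(scores, treat)
  pairs <- m$pairs[order(m$pairs$treated), ]
  expect_equal(pairs$treated, c(1L, 2L))
  expect_equal(pairs$control, c(3L, 4L))
  # no subject is reused
  expect_equal(anyDuplicated(c(m$pairs$treated, m$pairs$control)), 0L)
})

test_that("identical score distributions match the whole smaller arm", {
  set.seed(54)
  sc <- runif(30, 0.3, 0.7)
  scores <- c(sc[1:10], sc)
  treat <- c(rep(1, 10), rep(0, 30))
  m <- match_1to1_nearest(scores, treat)
  expect_equal(nrow(m$pairs), 10L)
  expect_error(match_1to1_nearest(scores, rep(1, 40)), "nonempty")
})

test_that("matching improves covariate balance on a confounded simulation", {
  set.seed(55)
  n <- 800
  age <- rnorm(n, 60, 10)
  stage <- rbinom(n, 1, 0.5)
  tr <- rbinom(n, 1, plogis(-0.5 + 0.06 * (age - 60) + 0.9 * stage))
  covs <- data.frame(age = age, stage = stage)
  ps <- fit_propensity(covs, tr)
  m <- match_1to1_nearest(ps, tr, covariates = covs)
  expect_true(all(abs(m$balance$smd_post) <= abs(m$balance$smd_pre) + 0.02))
  expect_lt(mean(abs(m$balance$smd_post)), mean(abs(m$balance$smd_pre)))
})

test_that("stratum treatment effect: permuted labels give HR near 1, null CI covers 1", {
  gen <- generator_config()
  set.seed(56)
  n <- 600
  tr <- rbinom(n, 1, 0.5)
  rec <- sample_outcome(log(0.5) * tr, gen)
  perm <- sample(tr)
  e0 <- stratum_treatment_effect(rec$time, rec$event, perm)
  expect_true(e0$ci[1] < 1 && 1 < e0$ci[2])
  e1 <- stratum_treatment_effect(rec$time, rec$event, tr)
  expect_true(e1$ci[1] < 0.5 && 0.5 < e1$ci[2])
  expect_lt(e1$p, 0.05)
  expect_error(stratum_treatment_effect(rec$time, rep(0, n), tr), "no events")
})

test_that("interaction coefficient flips sign under marker recoding and detects crossover", {
  gen <- generator_config()
  set.seed(57)
  n <- 800
  mk <- rbinom(n, 1, 0.5)
  tr <- rbinom(n, 1, 0.5)
  # opposite treatment effects by marker level
  lp <- tr * ifelse(mk == 1, log(1.6), log(0.5))
  rec <- sample_outcome(lp, gen)
  it <- interaction_test(rec$time, rec$event, mk, tr)
  expect_lt(it$p, 0.05)
  it_flip <- interaction_test(rec$time, rec$event, 1 - mk, tr)
  expect_equal(it$coef, -it_flip$coef, tolerance = 1e-6)
  expect_error(interaction_test(rec$time, rec$event, rep(1, n), tr), "constant")
})

test_that("CPS categorization uses the printed boundaries exactly", {
  expect_equal(as.character(categorize_cps(10)), "high")
  expect_equal(as.character(categorize_cps(1)), "intermediate")
  expect_equal(as.character(categorize_cps(0.5)), "low")
  expect_equal(as.character(categorize_cps(c(0, 0.999, 9.999, 10.001, 50))),
               c("low", "low", "intermediate", "high", "high"))
  expect_error(categorize_cps(-1), "non-negative")
  # exact partition of [0, inf)
  set.seed(58)
  x <- c(runif(200, 0, 30), 1, 10)
  ct <- categorize_cps(x)
  expect_false(any(is.na(ct)))
  expect_equal(sum(table(ct)), length(x))
})

test_that("response tree: separable toy splits on TME class with AUC 1", {
  set.seed(59)
  n <- 120
  cls <- sample(1:4, n, replace = TRUE)
  cps <- runif(n, 0, 30)
  resp <- as.integer(cls %in% c(1, 2))
  tree <- fit_response_tree(cls, categorize_cps(cps), resp)
  sc <- predict_response_tree(tree, cls, categorize_cps(cps))
  expect_equal(oracle_auc(sc, resp), 1)
  expect_equal(sum(tree$leaf_table$n), n)
  # pure-noise outcome: no informative split survives the complexity controls
  resp_n <- rbinom(n, 1, 0.5)
  tree_n <- fit_response_tree(cls, categorize_cps(cps), resp_n)
  sc_n <- predict_response_tree(tree_n, cls, categorize_cps(cps))
  expect_lt(oracle_auc(sc_n, resp_n), 0.7)
  # training-score refinement: tree at least matches single-feature AUCs
  gen <- generator_config(n_subjects = 300L, seed = 60L)
  co <- generate_cohort(gen, generate_images = FALSE)
  tree2 <- fit_response_tree(co$true_class, categorize_cps(co$cps), co$response)
  sc2 <- predict_response_tree(tree2, co$true_class, categorize_cps(co$cps))
  auc_tme <- oracle_auc(stats::ave(co$response, co$true_class), co$response)
  auc_cps <- oracle_auc(stats::ave(co$response, categorize_cps(co$cps)), co$response)
  expect_gte(oracle_auc(sc2, co$response) + 1e-9, max(auc_tme, auc_cps))
})

test_that("single-class outcomes return a trivial stump with a warning", {
  expect_warning(
    tree <- fit_response_tree(rep(1:4, 10), categorize_cps(runif(40, 0, 30)),
                              rep(1, 40)),
    "single-class")
  expect_equal(predict_response_tree(tree, 1, "low"), 1)
})

test_that("response report: ORR identities and composite AUC gain", {
  gen <- generator_config(n_subjects = 400L, seed = 61L)
  co <- generate_cohort(gen, generate_images = FALSE)
  co$predicted_class <- co$true_class
  set.seed(62)
  rep <- response_report(co)
  # group ORRs weighted by group sizes equal the overall ORR
  wts <- table(factor(co$true_class, 1:4)) / nrow(co)
  expect_equal(sum(rep$orr_by_class * as.numeric(wts)), rep$orr_overall,
               tolerance = 1e-12)
  # class + CPS both drive response: composite beats CPS alone
  expect_gt(rep$auc["composite"], rep$auc["cps"])
  # all responders
  co2 <- co; co2$response <- 1
  expect_warning(r2 <- response_report(co2), "single-class")
  expect_equal(r2$orr_overall, 1)
  expect_true(all(r2$orr_by_class == 1))
})
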