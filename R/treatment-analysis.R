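# Chemotherapy-benefit analysis (propensity matching, per-stratum hazard
# ratios, Cox interaction tests) and immunotherapy-response analysis (CPS
# categories, TME x CPS decision tree, response rates and AUC comparisons).

#' Propensity scores for treatment assignment
#'
#' Logistic regression of treatment on the matching covariates (reference set:
#' age, sex, differentiation, CEA, CA19-9, location, T stage, N stage, tumor
#' size, Lauren type).
#'
#' @param covariates Data frame of matching covariates.
#' @param treatment Binary treatment indicator.
#' @return Numeric propensity scores in (0, 1), with the fitted `glm` as
#'   attribute `"model"`.
#' @export
fit_propensity <- function(covariates, treatment) {
  treatment <- as.integer(treatment)
  if (!all(treatment %in% 0:1)) stop("treatment must be binary")
  dat <- cbind(data.frame(.treat = treatment), as.data.frame(covariates))
  fit <- suppressWarnings(stats::glm(.treat ~ ., data = dat, family = stats::binomial()))
  ps <- stats::fitted(fit)
  if (any(ps < 1e-8) || any(ps > 1 - 1e-8) || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE))
    stop("propensity model shows separation")
  structure(as.numeric(ps), model = fit)
}

std_mean_diff <- function(x, treatment) {
  x <- as.numeric(x)
  m1 <- mean(x[treatment == 1]); m0 <- mean(x[treatment == 0])
  s <- sqrt((stats::var(x[treatment == 1]) + stats::var(x[treatment == 0])) / 2)
  if (s == 0) 0 else (m1 - m0) / s
}

#' 1:1 nearest-neighbor propensity matching
#'
#' Greedy nearest matching on the logit propensity scale, without replacement,
#' in seeded random processing order of treated subjects. No caliper by
#' default; `caliper = "auto"` uses 0.2 SD of the logit scores, or supply a
#' numeric logit-scale width.
#'
#' @param scores Propensity scores in (0, 1).
#' @param treatment Binary treatment indicator.
#' @param caliper `NULL` (none), `"auto"`, or a numeric caliper.
#' @param covariates Optional covariate data frame for the balance table.
#' @return A `propensity_match`: `pairs` (treated, control row indices),
#'   `matched` (all matched row indices), and `balance` (standardized mean
#'   differences pre/post) when covariates are given.
#' @export
match_1to1_nearest <- function(scores, treatment, caliper = NULL, covariates = NULL) {
  treatment <- as.integer(treatment)
  tr <- which(treatment == 1); ct <- which(treatment == 0)
  if (length(tr) == 0L || length(ct) == 0L) stop("both arms must be nonempty")
  lg <- stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  cal <- if (is.null(caliper)) Inf else if (identical(caliper, "auto"))
    0.2 * stats::sd(lg) else as.numeric(caliper)
  order_tr <- tr[sample.int(length(tr))]
  avail <- rep(TRUE, length(scores))
  pairs <- matrix(integer(0), ncol = 2)
  for (i in order_tr) {
    cand <- ct[avail[ct]]
    if (length(cand) == 0L) break
    dd <- abs(lg[cand] - lg[i])
    j <- cand[which.min(dd)]
    if (min(dd) <= cal) {
      pairs <- rbind(pairs, c(i, j))
      avail[j] <- FALSE
    }
  }
  if (nrow(pairs) == 0L) stop("no matches within the caliper")
  matched <- c(pairs[, 1], pairs[, 2])
  balance <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    num <- stats::model.matrix(~ . - 1, data = covariates)
    balance <- data.frame(
      variable = colnames(num),
      smd_pre = apply(num, 2, std_mean_diff, treatment = treatment),
      smd_post = apply(num[matched, , drop = FALSE], 2, std_mean_diff,
                       treatment = treatment[matched]))
  }
  structure(list(pairs = data.frame(treated = pairs[, 1], control = pairs[, 2]),
                 matched = matched, caliper = cal, balance = balance),
            class = "propensity_match")
}

#' Within-stratum chemotherapy effect
#'
#' Cox hazard ratio of treatment vs. none within one predicted-TME stratum of
#' a matched cohort, with the log-rank p-value and KM curves per arm.
#'
#' @param time,event Survival records (stratum subjects).
#' @param treatment Binary treatment indicator.
#' @return List with `hr`, `ci`, `p` (Wald), `logrank_p`, `n`, `km` (per-arm
#'   `km_fit`s).
#' @export
stratum_treatment_effect <- function(time, event, treatment) {
  treatment <- as.integer(treatment)
  if (sum(event) == 0L) stop("no events in stratum")
  fit <- cox_fit(time, event, data.frame(treatment = treatment))
  lr <- log_rank_test(time, event, treatment)
  co <- fit$coefficients
  list(hr = co$hr[1], ci = c(co$lower[1], co$upper[1]), p = co$p[1],
       logrank_p = lr$p, n = length(time),
       km = list(treated = km_estimate(time[treatment == 1], event[treatment == 1]),
                 control = km_estimate(time[treatment == 0], event[treatment == 0])))
}

#' Cox interaction test between a marker and treatment
#'
#' Fits `Surv ~ marker * treatment` and reports the Wald test of the product
#' term.
#'
#' @param time,event Survival records.
#' @param marker Numeric or binary marker (e.g. predicted class indicator or
#'   DLS group).
#' @param treatment Binary treatment indicator.
#' @return List with `coef` (interaction log-HR), `se`, `p`, and the full
#'   `cox_fit`.
#' @export
interaction_test <- function(time, event, marker, treatment) {
  marker <- as.numeric(marker); treatment <- as.numeric(treatment)
  df <- data.frame(marker = marker, treatment = treatment,
                   interaction = marker * treatment)
  if (any(vapply(df, function(x) length(unique(x)) < 2L, logical(1))))
    stop("collinear or constant marker/treatment")
  fit <- cox_fit(time, event, df)
  co <- fit$coefficients
  i <- match("interaction", co$term)
  list(coef = co$coef[i], se = co$se[i], p = co$p[i], fit = fit)
}

#' Categorize a PD-L1 combined positive score
#'
#' high: CPS >= 10; intermediate: 10 > CPS >= 1; low: CPS < 1.
#'
#' @param cps Non-negative CPS values.
#' @return Factor with levels low/intermediate/high.
#' @export
categorize_cps <- function(cps) {
  if (any(!is.finite(cps)) || any(cps < 0)) stop("CPS must be non-negative")
  factor(ifelse(cps >= 10, "high", ifelse(cps >= 1, "intermediate", "low")),
         levels = c("low", "intermediate", "high"))
}

#' CART decision tree combining TME class and CPS category
#'
#' Classification tree (Gini impurity, max depth 3, minimum leaf size 10) for
#' objective response from the predicted TME class and CPS category. The
#' predicted score of a subject is its leaf's response rate.
#'
#' @param tme_class Predicted TME classes (1..4).
#' @param cps_category Factor from [categorize_cps()].
#' @param objective_response Binary response indicator (CR/PR = 1).
#' @param max_depth,min_leaf CART complexity controls.
#' @return A `response_tree`: rpart fit, `leaf_table` (leaf response rates and
#'   counts), and `predict(tree, newdata)` support via [predict_response_tree()].
#' @export
fit_response_tree <- function(tme_class, cps_category, objective_response,
                              max_depth = 3L, min_leaf = 10L) {
  n <- length(objective_response)
  if (n < 20L) stop("need >= 20 subjects to fit the response tree")
  df <- data.frame(response = factor(objective_response, levels = 0:1),
                   tme_class = factor(tme_class, levels = 1:4),
                   cps_category = factor(cps_category,
                                         levels = c("low", "intermediate", "high")))
  if (length(unique(objective_response)) < 2L) {
    warning("single-class outcome: returning trivial stump")
    p <- mean(objective_response)
    return(structure(list(fit = NULL, stump = p,
                          leaf_table = data.frame(leaf = 1L, n = n, rate = p)),
                     class = "response_tree"))
  }
  fit <- rpart::rpart(response ~ tme_class + cps_category, data = df,
                      method = "class", parms = list(split = "gini"),
                      control = rpart::rpart.control(maxdepth = max_depth,
                                                     minbucket = min_leaf,
                                                     minsplit = 2L * min_leaf,
                                                     cp = 0, xval = 0))
  wh <- fit$where
  leaf_table <- do.call(rbind, lapply(sort(unique(wh)), function(l) {
    sel <- wh == l
    data.frame(leaf = l, n = sum(sel), rate = mean(objective_response[sel]))
  }))
  structure(list(fit = fit, stump = NULL, leaf_table = leaf_table),
            class = "response_tree")
}

#' Predicted response probability from a fitted response tree
#' @param tree A `response_tree`.
#' @param tme_class,cps_category New feature values.
#' @return Numeric leaf response probabilities.
#' @export
predict_response_tree <- function(tree, tme_class, cps_category) {
  stopifnot(inherits(tree, "response_tree"))
  if (!is.null(tree$stump)) return(rep(tree$stump, length(tme_class)))
  nd <- data.frame(tme_class = factor(tme_class, levels = 1:4),
                   cps_category = factor(cps_category,
                                         levels = c("low", "intermediate", "high")))
  as.numeric(stats::predict(tree$fit, newdata = nd, type = "prob")[, "1"])
}

#' Immunotherapy response report
#'
#' Objective response rates per predicted TME class and per CPS category, and
#' AUCs (with DeLong comparisons) of CPS alone, TME class alone, and the
#' composite tree model for predicting objective response. Subjects with
#' missing response are excluded and counted.
#'
#' @param cohort Data frame with `predicted_class` (or `true_class`), `cps`,
#'   and `response` (0/1, `NA` allowed); optional `setting` column for
#'   per-therapy-setting reports.
#' @param tree Optional fitted `response_tree` for the composite score; if
#'   `NULL`, one is fitted on `cohort`.
#' @return List with `orr_overall`, `orr_by_class`, `orr_by_cps`,
#'   `auc` (cps, tme, composite), `delong_composite_vs_cps`, `n_excluded`.
#' @export
response_report <- function(cohort, tree = NULL) {
  cls_col <- if ("predicted_class" %in% names(cohort)) "predicted_class" else "true_class"
  keep <- !is.na(cohort$response)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) message(sprintf("%d subjects without response excluded", n_excluded))
  co <- cohort[keep, , drop = FALSE]
  cls <- co[[cls_col]]
  cat3 <- categorize_cps(co$cps)
  resp <- as.integer(co$response)

  orr_by_class <- vapply(split(resp, factor(cls, 1:4)), mean, numeric(1))
  orr_by_cps <- vapply(split(resp, cat3), mean, numeric(1))
  if (is.null(tree)) tree <- fit_response_tree(cls, cat3, resp)
  composite <- predict_response_tree(tree, cls, cat3)
  tme_score <- stats::ave(resp, cls)    # class-wise training response rate

  degenerate <- length(unique(resp)) < 2L
  auc_of <- function(score) {
    if (degenerate) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, score, levels = c(0, 1),
                                   direction = "<", quiet = TRUE)))
  }
  dl <- if (degenerate) list(delta_auc = NA_real_, p = NA_real_) else
    delong_compare(composite, co$cps, resp)
  list(orr_overall = mean(resp),
       orr_by_class = orr_by_class,
       orr_by_cps = orr_by_cps,
       auc = c(cps = auc_of(co$cps), tme = auc_of(tme_score),
               composite = auc_of(composite)),
       delong_composite_vs_cps = dl,
       tree = tree,
       n_excluded = n_excluded)
}
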