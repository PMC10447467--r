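# Accuracy and prognosis statistics: KM/log-rank, Cox fits (Breslow ties
# throughout, matching the training loss), time-dependent ROC with DeLong
# comparisons, Harrell's C, calibration, IPCW continuous NRI, IPCW Brier /
# integrated Brier score with .632+ prediction-error curves, Wald chi-square
# variable importance, and the integrated clinical + DLS model.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood standard errors.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event).
#' @return A `km_fit`: data frame `table` (time, n_risk, n_event, surv, se)
#'   and `surv_fn`, a right-continuous step function S(t).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  tab <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    surv = sf$surv, se = sf$std.err * sf$surv)
  fn <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  structure(list(table = tab, surv_fn = fn, n = length(time)), class = "km_fit")
}

# survival probability at t (right-continuous product-limit), small helper
km_at <- function(time, event, t) {
  if (length(time) == 0L) return(NA_real_)
  km_estimate(time, event)$surv_fn(t)
}

#' Log-rank test
#'
#' @param time,event Survival records.
#' @param group Group labels (>= 2 groups, >= 1 event overall).
#' @return List with `statistic` (chi-square), `df`, `p`.
#' @export
log_rank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("log-rank test needs >= 2 groups")
  if (sum(event) == 0L) stop("log-rank test needs >= 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Breslow partial likelihood maximized by Newton-Raphson (via
#' `survival::coxph`, `ties = "breslow"`). Hazard ratios with Wald 95% CIs.
#'
#' @param time,event Survival records.
#' @param covariates Data frame of covariates (all columns enter the model).
#' @return A `cox_fit`: coefficient table (`coef`, `se`, `hr`, `lower`,
#'   `upper`, `z`, `p`), `loglik`, and the underlying `coxph` object as
#'   `model`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (any(vapply(covariates, function(x) length(unique(x)) < 2L, logical(1))))
    stop("constant covariate in Cox model")
  if (sum(event) < ncol(covariates))
    stop("fewer events than covariates")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (warned || any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 20))
    stop("Cox fit failed: non-convergence or monotone likelihood")
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(term = names(b), coef = unname(b), se = unname(se),
                    hr = exp(unname(b)),
                    lower = exp(unname(b) - 1.96 * unname(se)),
                    upper = exp(unname(b) + 1.96 * unname(se)),
                    z = unname(b / se),
                    p = 2 * stats::pnorm(-abs(unname(b / se))))
  structure(list(coefficients = tab, loglik = fit$loglik[2], model = fit),
            class = "cox_fit")
}

#' Dichotomize risk scores at a training-derived cutoff
#'
#' The cutoff is the median of the *training* scores and is then frozen;
#' applying it to validation data never re-estimates it. Ties go to "high".
#'
#' @param train_scores Training-cohort risk scores.
#' @param cohort_id Optional source id.
#' @return A `risk_cutoff` with the frozen `cutoff`.
#' @export
risk_cutoff <- function(train_scores, cohort_id = NA_character_) {
  structure(list(cutoff = stats::median(train_scores),
                 source_cohort_id = cohort_id), class = "risk_cutoff")
}

#' @rdname risk_cutoff
#' @param scores Scores to dichotomize with the frozen cutoff.
#' @param cutoff A `risk_cutoff`.
#' @export
apply_risk_groups <- function(scores, cutoff) {
  stopifnot(inherits(cutoff, "risk_cutoff"))
  factor(ifelse(scores >= cutoff$cutoff, "high", "low"), levels = c("low", "high"))
}

#' Time-dependent ROC (cumulative/dynamic, KM estimator)
#'
#' Cases are events by the horizon, controls are subjects still event-free;
#' censoring is handled by Kaplan-Meier estimates within marker strata:
#' `TPR(c) = (1 - S_c(t)) P(X > c) / (1 - S(t))`,
#' `FPR(c) = S_c(t) P(X > c) / S(t)`, where `S_c` is the KM curve among
#' subjects with marker above `c`. AUC by trapezoid. With no censoring this
#' reduces exactly to the binary ROC on the event-by-horizon indicator.
#'
#' @param risk Risk scores (higher = earlier event expected).
#' @param time,event Survival records.
#' @param horizon Evaluation time (within follow-up, >= 1 event before it).
#' @param max_cutoffs Cutoff thinning bound for large cohorts.
#' @return List with `curve` (cutoff, tpr, fpr), `auc`, `horizon`.
#' @export
time_dependent_roc <- function(risk, time, event, horizon, max_cutoffs = 200L) {
  if (horizon > max(time)) stop("horizon beyond observed follow-up")
  if (sum(event == 1 & time <= horizon) == 0L)
    stop("no events before the horizon")
  S_t <- km_at(time, event, horizon)
  cuts <- sort(unique(risk))
  if (length(cuts) > max_cutoffs)
    cuts <- unique(stats::quantile(risk, seq(0, 1, length.out = max_cutoffs),
                                   type = 1))
  tpr <- fpr <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    sel <- risk > cuts[i]
    p_c <- mean(sel)
    S_c <- if (any(sel)) km_at(time[sel], event[sel], horizon) else 1
    tpr[i] <- (1 - S_c) * p_c / (1 - S_t)
    fpr[i] <- S_c * p_c / S_t
  }
  # integrate along the cutoff path (descending cutoffs = growing nested
  # prediction sets), which is the exact staircase in the absence of censoring
  o <- order(cuts, decreasing = TRUE)
  xs <- c(0, fpr[o], 1); ys <- c(0, tpr[o], 1)
  auc <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  list(curve = data.frame(cutoff = cuts, tpr = tpr, fpr = fpr),
       auc = auc, horizon = horizon)
}

#' DeLong comparison of two paired AUCs
#'
#' Binary-outcome AUCs compared on the same subjects via DeLong's paired
#' placement-value test (two-sided).
#'
#' @param scores_a,scores_b Two risk scores on the same subjects.
#' @param labels Binary outcome (0/1).
#' @return List with `auc_a`, `auc_b`, `delta_auc`, `statistic` (z), `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels are degenerate (single class)")
  ra <- pROC::roc(labels, scores_a, levels = c(0, 1), direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels, scores_b, levels = c(0, 1), direction = "<", quiet = TRUE)
  d <- as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(list(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
                delta_auc = 0, statistic = 0, p = 1))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  z <- unname(tst$statistic)
  p <- tst$p.value
  if (!is.finite(z)) { z <- 0; p <- 1 }
  list(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       delta_auc = d, statistic = z, p = p)
}

#' Multi-class classification report
#'
#' Confusion matrix (rows = truth, columns = prediction), one-vs-others
#' sensitivity/specificity/PPV/NPV and AUC per class, and overall accuracy
#' with a normal-approximation 95% CI.
#'
#' @param truth,predicted Integer labels in 1..4.
#' @param probabilities Optional n x 4 probability matrix for per-class AUCs.
#' @return A `classification_report` list.
#' @export
classification_report <- function(truth, predicted, probabilities = NULL) {
  if (!all(truth %in% 1:4) || !all(predicted %in% 1:4))
    stop("labels must be in 1..4")
  n <- length(truth)
  cm <- table(factor(truth, 1:4), factor(predicted, 1:4))
  acc <- sum(diag(cm)) / n
  half <- 1.96 * sqrt(acc * (1 - acc) / n)
  per_class <- do.call(rbind, lapply(1:4, function(k) {
    tp <- sum(truth == k & predicted == k)
    fn <- sum(truth == k & predicted != k)
    fp <- sum(truth != k & predicted == k)
    tn <- sum(truth != k & predicted != k)
    auc <- NA_real_
    y <- as.integer(truth == k)
    if (length(unique(y)) == 2L) {
      sc <- if (!is.null(probabilities)) probabilities[, k] else as.numeric(predicted == k)
      auc <- as.numeric(pROC::auc(pROC::roc(y, sc, levels = c(0, 1),
                                            direction = "<", quiet = TRUE)))
    }
    data.frame(class = k,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
               auc = auc)
  }))
  structure(list(confusion = cm, per_class = per_class, accuracy = acc,
                 accuracy_ci = c(lower = max(0, acc - half),
                                 upper = min(1, acc + half)), n = n),
            class = "classification_report")
}

#' Harrell's concordance index
#'
#' Fraction of censoring-comparable pairs ordered concordantly by the risk
#' score (higher risk, shorter survival); tied scores count 0.5.
#'
#' @param risk Risk scores.
#' @param time,event Survival records.
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(risk, time, event) {
  cf <- survival::concordance(survival::Surv(time, event) ~ risk, reverse = TRUE)
  comparable <- sum(cf$count[1:3])
  if (comparable == 0) stop("no comparable pairs")
  unname(cf$concordance)
}

# censoring-distribution KM (reverse KM); returns a step function G(t)
censor_km_fn <- function(time, event) {
  km_estimate(time, 1 - event)$surv_fn
}

#' Continuous (category-free) NRI at a horizon, IPCW-weighted
#'
#' Events by the horizon with upward reclassification (new risk > old risk)
#' count positively; event-free subjects with downward reclassification count
#' positively. Censored-before-horizon subjects are handled by inverse
#' probability of censoring weights; CI and p by bootstrap percentiles.
#'
#' @param model_new,model_old Risk scores for the same subjects.
#' @param time,event Survival records.
#' @param horizon Evaluation time, within follow-up.
#' @param B Bootstrap resamples.
#' @return List with `nri`, `nri_events`, `nri_nonevents`, `ci`, `p`.
#' @export
nri_timepoint <- function(model_new, model_old, time, event, horizon, B = 200L) {
  if (horizon > max(time)) stop("horizon beyond observed follow-up")
  point <- nri_point(model_new, model_old, time, event, horizon)
  n <- length(time)
  boot <- replicate(B, {
    i <- sample.int(n, replace = TRUE)
    tryCatch(nri_point(model_new[i], model_old[i], time[i], event[i], horizon)$nri,
             error = function(e) NA_real_)
  })
  boot <- boot[is.finite(boot)]
  ci <- if (length(boot) >= 10) stats::quantile(boot, c(0.025, 0.975)) else c(NA, NA)
  p <- if (length(boot) >= 10)
    min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)) + 1 / length(boot)) else NA_real_
  c(point, list(ci = unname(ci), p = p))
}

nri_point <- function(new, old, time, event, horizon) {
  G <- censor_km_fn(time, event)
  is_event <- time <= horizon & event == 1
  is_nonevent <- time > horizon
  w <- numeric(length(time))
  w[is_event] <- 1 / pmax(G(time[is_event] - 1e-9), 1e-8)
  w[is_nonevent] <- 1 / pmax(G(horizon), 1e-8)
  up <- new > old
  down <- new < old
  we <- w[is_event]; wn <- w[is_nonevent]
  if (sum(we) == 0 || sum(wn) == 0)
    stop("no usable events or non-events at this horizon")
  nri_e <- sum(we * (up[is_event] - down[is_event])) / sum(we)
  nri_ne <- sum(wn * (down[is_nonevent] - up[is_nonevent])) / sum(wn)
  list(nri = nri_e + nri_ne, nri_events = nri_e, nri_nonevents = nri_ne)
}

#' IPCW Brier score curve and integrated Brier score
#'
#' `BS(t) = mean_i [ S_i(t)^2 1(T_i <= t, E_i = 1)/G(T_i-) +
#' (1 - S_i(t))^2 1(T_i > t)/G(t) ]` with G the censoring Kaplan-Meier; the
#' IBS is the trapezoid integral of BS over the grid, normalized by its span.
#'
#' @param surv_prob n x length(grid) matrix of predicted survival
#'   probabilities S_i(t).
#' @param time,event Survival records.
#' @param grid Evaluation times (within follow-up).
#' @return List with `curve` (data frame t, brier) and `ibs`.
#' @export
brier_and_ibs <- function(surv_prob, time, event, grid) {
  surv_prob <- as.matrix(surv_prob)
  if (nrow(surv_prob) != length(time) || ncol(surv_prob) != length(grid))
    stop("surv_prob must be n x length(grid)")
  if (max(grid) > max(time)) stop("grid extends beyond observed follow-up")
  G <- censor_km_fn(time, event)
  bs <- vapply(seq_along(grid), function(j) {
    t <- grid[j]
    mean(brier_terms(surv_prob[, j], time, event, t, G))
  }, numeric(1))
  span <- diff(range(grid))
  ibs <- if (span > 0)
    sum(diff(grid) * (bs[-1] + bs[-length(bs)]) / 2) / span else bs[1]
  list(curve = data.frame(t = grid, brier = bs), ibs = ibs)
}

brier_terms <- function(s_t, time, event, t, G) {
  ev <- time <= t & event == 1
  at_risk <- time > t
  term <- numeric(length(time))
  term[ev] <- s_t[ev]^2 / pmax(G(time[ev] - 1e-9), 1e-8)
  term[at_risk] <- (1 - s_t[at_risk])^2 / pmax(G(t), 1e-8)
  term
}

# predicted survival matrix (subjects x grid) from a coxph fit
cox_surv_matrix <- function(fit, newdata, grid) {
  sf <- survival::survfit(fit, newdata = newdata)
  sm <- if (is.matrix(sf$surv)) sf$surv else matrix(sf$surv, ncol = 1)
  out <- matrix(0, nrow(newdata), length(grid))
  for (i in seq_len(nrow(newdata))) {
    fn <- stats::stepfun(sf$time, c(1, sm[, i]), right = FALSE)
    out[i, ] <- fn(grid)
  }
  out
}

#' .632+ bootstrap prediction-error curves
#'
#' For each candidate Cox model, combines the apparent IPCW Brier curve with
#' the out-of-bag bootstrap curve using the .632+ weighting (no-information
#' error from the permutation argument; relative overfitting clamped to
#' `[0, 1]`). Resamples whose refit fails are dropped with a message.
#'
#' @param models Named list of right-hand-side formulas (e.g.
#'   `list(stage = ~ t_stage + n_stage, dls = ~ dls)`).
#' @param data Data frame with `time`, `event` and model covariates.
#' @param grid Evaluation times.
#' @param B Bootstrap resamples (>= 10).
#' @return Named list per model: `curve` (t, apparent, oob, err632plus) and
#'   `ibs` of the .632+ curve.
#' @export
prediction_error_632plus <- function(models, data, grid, B = 50L) {
  if (B < 10L) stop("B must be >= 10")
  n <- nrow(data)
  G <- censor_km_fn(data$time, data$event)
  out <- list()
  for (nm in names(models)) {
    fml <- stats::as.formula(paste("survival::Surv(time, event)",
                                   paste(deparse(models[[nm]]), collapse = "")))
    full_fit <- survival::coxph(fml, data = data, ties = "breslow", x = TRUE)
    sp_full <- cox_surv_matrix(full_fit, data, grid)
    apparent <- colMeans(vapply(seq_along(grid), function(j)
      brier_terms(sp_full[, j], data$time, data$event, grid[j], G),
      numeric(n)))

    # no-information error: every prediction vs every outcome
    noinf <- vapply(seq_along(grid), function(j) {
      t <- grid[j]
      m1 <- mean(sp_full[, j]); m2 <- mean(sp_full[, j]^2)
      ev <- data$time <= t & data$event == 1
      ar <- data$time > t
      wev <- 1 / pmax(G(data$time[ev] - 1e-9), 1e-8)
      war <- 1 / pmax(G(t), 1e-8)
      (sum(wev) * m2 + sum(war * 1) * (1 - 2 * m1 + m2)) / n
    }, numeric(1))

    err_sum <- matrix(0, n, length(grid))
    err_cnt <- integer(n)
    dropped <- 0L
    for (b in seq_len(B)) {
      i <- sample.int(n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(i))
      if (length(oob) == 0L) next
      fit_b <- tryCatch(
        survival::coxph(fml, data = data[i, , drop = FALSE], ties = "breslow"),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit_b)) { dropped <- dropped + 1L; next }
      sp <- tryCatch(cox_surv_matrix(fit_b, data[oob, , drop = FALSE], grid),
                     error = function(e) NULL)
      if (is.null(sp)) { dropped <- dropped + 1L; next }
      for (j in seq_along(grid)) {
        bt <- brier_terms(sp[, j], data$time[oob], data$event[oob], grid[j], G)
        err_sum[oob, j] <- err_sum[oob, j] + bt
      }
      err_cnt[oob] <- err_cnt[oob] + 1L
    }
    if (dropped > 0L)
      message(sprintf("model '%s': %d bootstrap resamples dropped", nm, dropped))
    used <- err_cnt > 0L
    oob_curve <- colSums(err_sum[used, , drop = FALSE] / err_cnt[used]) / sum(used)
    oob_curve <- pmin(oob_curve, noinf)
    R <- (oob_curve - apparent) / pmax(noinf - apparent, 1e-12)
    R <- pmin(pmax(R, 0), 1)
    w <- 0.632 / (1 - 0.368 * R)
    err632 <- (1 - w) * apparent + w * oob_curve
    span <- diff(range(grid))
    ibs <- if (span > 0)
      sum(diff(grid) * (err632[-1] + err632[-length(err632)]) / 2) / span else err632[1]
    out[[nm]] <- list(curve = data.frame(t = grid, apparent = apparent,
                                         oob = oob_curve, err632plus = err632),
                      ibs = ibs)
  }
  out
}

#' Calibration curve at a horizon
#'
#' Subjects are binned by quantiles of predicted survival probability; per
#' bin, the mean prediction is compared with the KM-observed survival at the
#' horizon (Greenwood 95% CI). Quantile-degenerate (empty) bins are merged
#' with neighbors.
#'
#' @param predicted_surv Predicted survival probabilities at the horizon.
#' @param time,event Survival records.
#' @param horizon Evaluation time.
#' @param bins Number of quantile bins (>= 3).
#' @return Data frame: bin, n, mean predicted, observed KM, lower, upper.
#' @export
calibration_curve <- function(predicted_surv, time, event, horizon, bins = 5L) {
  if (bins < 3L) stop("bins must be >= 3")
  br <- unique(stats::quantile(predicted_surv, seq(0, 1, length.out = bins + 1L)))
  if (length(br) < 2L) {  # constant prediction: one effective bin
    km <- km_estimate(time, event)
    s <- km$surv_fn(horizon)
    return(data.frame(bin = 1L, n = length(time),
                      predicted = mean(predicted_surv), observed = s,
                      lower = NA_real_, upper = NA_real_))
  }
  if (length(br) < bins + 1L)
    message("calibration: empty quantile bins merged with neighbors")
  g <- cut(predicted_surv, br, include.lowest = TRUE)
  do.call(rbind, lapply(seq_along(levels(g)), function(k) {
    sel <- g == levels(g)[k]
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1,
                            conf.type = "plain")
    idx <- findInterval(horizon, sf$time)
    s <- if (idx == 0) 1 else sf$surv[idx]
    lo <- if (idx == 0) 1 else sf$lower[idx]
    hi <- if (idx == 0) 1 else sf$upper[idx]
    data.frame(bin = k, n = sum(sel), predicted = mean(predicted_surv[sel]),
               observed = s, lower = lo, upper = hi)
  }))
}

#' Relative variable importance from Wald chi-squares
#'
#' For each model term of a fitted Cox model, the Wald chi-square
#' `b' V^-1 b` over the term's coefficient block; relative contribution is the
#' term chi-square divided by the total.
#'
#' @param fit A `cox_fit` (multivariable).
#' @return Data frame: term, chisq, df, proportion (sums to 1).
#' @export
chi2_importance <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  m <- fit$model
  b <- stats::coef(m)
  V <- stats::vcov(m)
  asg <- m$assign
  rows <- lapply(names(asg), function(nm) {
    j <- asg[[nm]]
    bb <- b[j]
    chi <- drop(t(bb) %*% solve(V[j, j, drop = FALSE]) %*% bb)
    data.frame(term = nm, chisq = chi, df = length(j))
  })
  out <- do.call(rbind, rows)
  out$proportion <- out$chisq / sum(out$chisq)
  out
}

#' Integrated prognostic model (DLS + clinicopathologic factors)
#'
#' Multivariable Cox model of the deep-learning survival score together with
#' T/N/M stage, CEA, tumor location and differentiation, fitted on the
#' training cohort. The training linear predictor is split into 8
#' equal-quantile risk strata whose cutpoints are frozen and applied unchanged
#' to validation cohorts.
#'
#' @param train Data frame with `time`, `event`, `dls` and the clinical
#'   covariates.
#' @param covariates Character vector of clinical covariate columns.
#' @param n_strata Number of risk strata (default 8).
#' @return An `integrated_model`: `fit` (a `cox_fit`), `cutpoints`, and the
#'   training `strata` assignment.
#' @export
integrated_model <- function(train,
                             covariates = c("t_stage", "n_stage", "m_stage",
                                            "cea", "location", "differentiation"),
                             n_strata = 8L) {
  fit <- cox_fit(train$time, train$event, train[, c("dls", covariates)])
  lp <- unname(stats::predict(fit$model, newdata = train, type = "lp"))
  cutpoints <- stats::quantile(lp, seq_len(n_strata - 1L) / n_strata)
  strata <- findInterval(lp, cutpoints) + 1L
  structure(list(fit = fit, covariates = covariates, cutpoints = cutpoints,
                 n_strata = n_strata, train_lp = lp, strata = strata),
            class = "integrated_model")
}

#' Apply a frozen integrated model to new data
#'
#' @param model An `integrated_model`.
#' @param newdata Data frame with `dls` and the clinical covariates (factor
#'   levels must have been seen in training).
#' @return Data frame with `lp` and `stratum`.
#' @export
apply_integrated_model <- function(model, newdata) {
  stopifnot(inherits(model, "integrated_model"))
  lp <- unname(stats::predict(model$fit$model, newdata = newdata, type = "lp"))
  data.frame(lp = lp, stratum = findInterval(lp, model$cutpoints) + 1L)
}
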