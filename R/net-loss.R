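# Joint training loss: categorical cross-entropy for the TME class
# probabilities plus the negative log Cox partial likelihood (Breslow
# convention for tied event times) for the survival score.

#' Cross-entropy loss for TME classification
#'
#' `-mean_b sum_c Y[b,c] log(Yhat[b,c])` with a clamped log for numerical
#' safety.
#'
#' @param Y One-hot ground-truth matrix (B x 4) or integer class vector.
#' @param Y_hat Predicted probability matrix (B x 4), rows summing to 1.
#' @return Scalar loss.
#' @export
loss_tme <- function(Y, Y_hat) {
  if (is.null(dim(Y_hat))) Y_hat <- matrix(Y_hat, 1)
  if (!is.matrix(Y)) Y <- one_hot(as.integer(Y), ncol(Y_hat))
  if (any(Y_hat < -1e-9) || any(abs(rowSums(Y_hat) - 1) > 1e-6))
    stop("Y_hat rows must be probability vectors")
  -mean(rowSums(Y * log(pmax(Y_hat, 1e-12))))
}

# risk sets and tie groups for the Breslow partial likelihood, on data sorted
# by decreasing time
cox_sorted <- function(risk, time, event) {
  ord <- order(time, decreasing = TRUE)
  h <- risk[ord]; tt <- time[ord]; ev <- event[ord]
  grp <- cumsum(!duplicated(tt))
  grp_end <- vapply(split(seq_along(grp), grp), max, integer(1))
  end_i <- grp_end[grp]
  M <- max(h)
  E <- exp(h - M)
  cs <- cumsum(E)
  denom <- cs[end_i]      # sum over the risk set {j : T_j >= T_i}, scaled by e^-M
  list(ord = ord, h = h, ev = ev, E = E, denom = denom, end_i = end_i, M = M)
}

#' Negative log Cox partial likelihood (training loss)
#'
#' `-sum_{i: E_i = 1} [ h_i - log sum_{j: T_j >= T_i} exp(h_j) ]`, with the
#' Breslow convention for tied event times and a log-sum-exp stabilized
#' denominator. Adding a constant to all risk scores leaves the loss
#' unchanged.
#'
#' @param risk Numeric vector of risk scores (higher = higher hazard).
#' @param time Positive survival/censoring times.
#' @param event Event indicators (1 = event).
#' @return Scalar loss.
#' @export
loss_cox <- function(risk, time, event) {
  if (length(risk) != length(time) || length(time) != length(event))
    stop("risk, time, event must have equal length")
  if (any(time <= 0)) stop("times must be positive")
  if (sum(event) == 0) stop("uninformative batch: no events")
  s <- cox_sorted(risk, time, event)
  -sum((s$h - (log(s$denom) + s$M))[s$ev == 1])
}

# gradient of loss_cox w.r.t. the risk vector (original ordering)
loss_cox_grad <- function(risk, time, event) {
  s <- cox_sorted(risk, time, event)
  n <- length(risk)
  w <- ifelse(s$ev == 1, 1 / s$denom, 0)
  z <- numeric(n)
  agg <- tapply(w, s$end_i, sum)
  z[as.integer(names(agg))] <- agg
  c_k <- rev(cumsum(rev(z)))
  g_sorted <- -s$ev + s$E * c_k
  g <- numeric(n)
  g[s$ord] <- g_sorted
  g
}

#' Total multi-task loss
#'
#' Sum of the cross-entropy classification term and the Cox survival term,
#' with unit weights by default.
#'
#' @inheritParams loss_tme
#' @inheritParams loss_cox
#' @param weights Length-2 weights for (TME, survival); default `c(1, 1)`.
#' @return Scalar loss.
#' @export
total_loss <- function(Y, Y_hat, risk, time, event, weights = c(1, 1)) {
  weights[1] * loss_tme(Y, Y_hat) + weights[2] * loss_cox(risk, time, event)
}

# loss + gradients w.r.t. classification logits and risk outputs for a batch;
# a batch without events contributes only the classification term. With
# cox_norm = "events" the survival term is averaged over the batch's events so
# both task losses sit on a comparable per-subject scale during mini-batch
# training (the exported loss_cox/total_loss operations keep the risk-set sum).
batch_loss_grads <- function(fwd, Y, time, event, weights = c(1, 1),
                             cox_norm = c("sum", "events")) {
  cox_norm <- match.arg(cox_norm)
  B <- nrow(fwd$prob)
  if (!is.matrix(Y)) Y <- one_hot(as.integer(Y), ncol(fwd$prob))
  l_tme <- loss_tme(Y, fwd$prob)
  dz <- weights[1] * (fwd$prob - Y) / B
  if (sum(event) > 0) {
    sc <- if (cox_norm == "events") 1 / sum(event) else 1
    l_cox <- sc * loss_cox(fwd$risk, time, event)
    dh <- weights[2] * sc * loss_cox_grad(fwd$risk, time, event)
  } else {
    l_cox <- 0
    dh <- numeric(B)
  }
  list(loss_tme = l_tme, loss_cox = l_cox,
       total = weights[1] * l_tme + weights[2] * l_cox,
       dz = dz, dh = dh)
}
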