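# Seeded Adam training loop for the multi-task network, with optional
# on-the-fly augmentation of training batches and loss-plateau stopping.

adam_init <- function(params) list(m = tree_zero(params), v = tree_zero(params), t = 0L)

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, st$m, grads)
  st$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, st$v, grads)
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  params <- tree_map3(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                      params, st$m, st$v)
  list(params = params, state = st)
}

#' Train the multi-task network
#'
#' Mini-batch Adam on the joint loss (cross-entropy + Cox partial likelihood).
#' Batches without any event contribute only the classification term.
#' Training stops at `config$epochs` or when the epoch-mean total loss has not
#' improved for `config$patience` epochs; a non-finite loss aborts with the
#' last finite parameters.
#'
#' @param config A [network_config()].
#' @param stacks `(n, 5, S, S)` array of preprocessed slice stacks.
#' @param classes Integer TME labels in 1..4.
#' @param time,event Survival records.
#' @param augment `NULL` (no augmentation) or an [augment_policy()] applied to
#'   every training batch on the fly.
#' @param verbose Print per-epoch losses.
#' @return A trained `tme_network` with a `history` data frame
#'   (per-epoch mean loss components) attached.
#' @export
train_network <- function(config, stacks, classes, time, event,
                          augment = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "network_config"))
  n <- dim(stacks)[1]
  stopifnot(length(classes) == n, length(time) == n, length(event) == n)
  net <- init_network(config)
  opt <- adam_init(net$params)
  Y <- one_hot(as.integer(classes), config$n_classes)

  # the leading fixed average-pool has no parameters: without augmentation its
  # output never changes, so apply it once up front and train from the next layer
  from_layer <- 1L
  if (is.null(augment) && net$arch[[1]]$type == "avgpool") {
    m <- net$arch[[1]]$m
    S <- config$input_size; s2 <- S %/% m; ns <- config$n_slices
    x_all <- stacks
    dim(x_all) <- c(n * ns, S, S, 1L)
    pooled <- avgpool_forward(x_all, m)$out
    dim(pooled) <- c(n, ns, s2, s2)
    stacks <- pooled
    from_layer <- 2L
  }
  hist <- data.frame(epoch = integer(0), loss_tme = numeric(0),
                     loss_cox = numeric(0), total = numeric(0))
  best <- Inf; stall <- 0L
  last_finite <- net$params
  diverged <- FALSE

  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(n)
    sums <- c(tme = 0, cox = 0, total = 0); nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      bidx <- idx[start:min(start + config$batch_size - 1L, n)]
      if (length(bidx) < 2L) next
      xb <- stacks[bidx, , , , drop = FALSE]
      if (!is.null(augment)) {
        for (k in seq_along(bidx)) {
          st <- structure(list(planes = array(xb[k, , , ], dim(xb)[2:4])),
                          class = "slice_stack")
          xb[k, , , ] <- augment_stack(st, augment)$planes
        }
      }
      fwd <- network_forward(net, xb, training = TRUE, from_layer = from_layer)
      net$state$backbone <- fwd$cache$bb$state
      lg <- batch_loss_grads(fwd, Y[bidx, , drop = FALSE],
                             time[bidx], event[bidx], config$loss_weights,
                             cox_norm = config$cox_norm)
      if (!is.finite(lg$total)) { diverged <- TRUE; break }
      grads <- network_backward(net, fwd, lg$dz, lg$dh)
      up <- adam_step(net$params, grads, opt, config$lr)
      net$params <- up$params
      opt <- up$state
      sums <- sums + c(lg$loss_tme, lg$loss_cox, lg$total); nb <- nb + 1L
    }
    if (diverged) {
      warning("training diverged (non-finite loss); returning last finite checkpoint")
      net$params <- last_finite
      break
    }
    last_finite <- net$params
    avg <- sums / max(nb, 1L)
    hist <- rbind(hist, data.frame(epoch = ep, loss_tme = avg[1],
                                   loss_cox = avg[2], total = avg[3]))
    if (verbose)
      message(sprintf("epoch %3d  tme %.4f  cox %.4f  total %.4f",
                      ep, avg[1], avg[2], avg[3]))
    if (avg[3] < best - 1e-6) { best <- avg[3]; stall <- 0L } else stall <- stall + 1L
    if (stall >= config$patience) break
  }
  net$history <- hist
  net$diverged <- diverged
  net
}

#' Save / load a network checkpoint
#'
#' The checkpoint stores weights, normalization state, config and history as
#' one serialized object, with the package version stamped.
#'
#' @param net A `tme_network`.
#' @param path `.rds` file path.
#' @return `path` (save) or a `tme_network` (load).
#' @export
save_checkpoint <- function(net, path) {
  net$version <- as.character(utils::packageVersion("tmesurv"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# Finite-difference verification of the analytic gradients of the total loss
# on one batch. Samples `n_coord` coordinates from every parameter leaf and
# returns the relative error ||analytic - numeric|| / max(||analytic||,
# ||numeric||) over all sampled coordinates (the norm-based form is robust to
# coordinates whose gradient magnitude sits below finite-difference roundoff).
check_gradients <- function(net, stacks, classes, time, event,
                            n_coord = 3L, eps = 1e-5, weights = c(1, 1)) {
  Y <- one_hot(as.integer(classes), net$config$n_classes)
  loss_at <- function(params) {
    net2 <- net
    net2$params <- params
    fwd <- network_forward(net2, stacks, training = TRUE)
    lg <- batch_loss_grads(fwd, Y, time, event, weights, cox_norm = "sum")
    lg$total
  }
  fwd <- network_forward(net, stacks, training = TRUE)
  lg <- batch_loss_grads(fwd, Y, time, event, weights, cox_norm = "sum")
  grads <- network_backward(net, fwd, lg$dz, lg$dh)

  a_all <- numeric(0); fd_all <- numeric(0)
  for (path in tree_paths(net$params)) {
    leaf <- net$params[[path]]
    nco <- min(n_coord, length(leaf))
    for (i in sample.int(length(leaf), nco)) {
      p_plus <- net$params; p_plus[[path]][i] <- p_plus[[path]][i] + eps
      p_minus <- net$params; p_minus[[path]][i] <- p_minus[[path]][i] - eps
      fd <- (loss_at(p_plus) - loss_at(p_minus)) / (2 * eps)
      a_all <- c(a_all, grads[[path]][i])
      fd_all <- c(fd_all, fd)
    }
  }
  sqrt(sum((a_all - fd_all)^2)) / max(sqrt(sum(a_all^2)), sqrt(sum(fd_all^2)))
}
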