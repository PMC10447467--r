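# The multi-task network: per-slice backbone features, two-FC refinement with
# leaky ReLU, gated-attention pooling across slices (one attention row per
# task), a TME classification head on M[1, ] and a cascaded survival head on
# M[2, ] concatenated with the predicted class probabilities.

#' Network configuration
#'
#' @param backbone `"tiny"` (3 conv blocks, 64-dim features; CPU-scale
#'   training) or `"resnet18"` (residual-block reference topology with
#'   256-dim per-slice features).
#' @param n_slices Slices per stack (5).
#' @param input_size In-plane input size (160 for the reference pipeline).
#' @param feature_dim Per-slice feature dimension `d`; defaults to 256 for the
#'   reference backbone and 64 for the tiny backbone.
#' @param n_tasks Number of tasks `N` (attention rows); 2.
#' @param n_classes TME classes; 4.
#' @param leaky_relu_slope Negative-slope of the leaky ReLU.
#' @param attn_dim Hidden width of the gated-attention FC layers.
#' @param surv_hidden Hidden width of the survival head.
#' @param pool0 Fixed average-pool factor applied before the tiny backbone's
#'   conv blocks (the tiny backbone operates at reduced resolution).
#' @param lr Adam learning rate; the reference recipe is 1e-5, the tiny
#'   backbone defaults to 1e-3 (smaller network, CPU-scale runs).
#' @param batch_size Mini-batch size (16 in the reference recipe).
#' @param epochs Maximum training epochs.
#' @param patience Epochs without total-loss improvement before plateau stop.
#' @param detach_cascade If `TRUE`, block gradients through the predicted
#'   class probabilities into the survival head (ablation switch).
#' @param loss_weights Weights of (TME, survival) loss terms; 1:1 by default.
#' @param cox_norm Normalization of the survival term inside training batches:
#'   `"events"` (average over the batch's events, keeping both task losses on
#'   a comparable per-subject scale) or `"sum"` (the raw risk-set sum).
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A `network_config` object.
#' @export
network_config <- function(backbone = c("tiny", "resnet18"),
                           n_slices = 5L, input_size = 160L,
                           feature_dim = NULL, n_tasks = 2L, n_classes = 4L,
                           leaky_relu_slope = 0.01, attn_dim = 32L,
                           surv_hidden = 32L, pool0 = 4L,
                           lr = NULL, batch_size = 16L, epochs = 100L,
                           patience = 20L, detach_cascade = FALSE,
                           loss_weights = c(tme = 1, cox = 1),
                           cox_norm = c("events", "sum"),
                           seed = 1L) {
  cox_norm <- match.arg(cox_norm)
  backbone <- match.arg(backbone)
  if (is.null(feature_dim))
    feature_dim <- if (backbone == "resnet18") 256L else 64L
  if (is.null(lr)) lr <- if (backbone == "resnet18") 1e-5 else 1e-3
  if (n_tasks < 2L) stop("n_tasks must be >= 2")
  if (n_classes != 4L) stop("the TME scheme has 4 classes")
  structure(as.list(environment()), class = "network_config")
}

## ---- architecture definitions ----------------------------------------------

tiny_arch <- function(cfg) {
  s <- cfg$input_size
  if (s %% cfg$pool0 != 0 || (s %/% cfg$pool0) %% 4 != 0)
    stop("input_size must be divisible by pool0 and twice more by 2")
  list(
    list(type = "avgpool", m = cfg$pool0),
    list(type = "conv", k = 3L, stride = 1L, pad = 1L, cin = 1L, cout = 8L),
    list(type = "lrelu"),
    list(type = "avgpool", m = 2L),
    list(type = "conv", k = 3L, stride = 1L, pad = 1L, cin = 8L, cout = 16L),
    list(type = "lrelu"),
    list(type = "avgpool", m = 2L),
    list(type = "conv", k = 3L, stride = 1L, pad = 1L, cin = 16L, cout = 32L),
    list(type = "lrelu"),
    list(type = "gap"),
    list(type = "fc", p = 32L, q = cfg$feature_dim)
  )
}

resnet18_arch <- function(cfg) {
  rb <- function(cin, cout, stride)
    list(type = "resblock", cin = cin, cout = cout, stride = stride,
         down = (stride != 1L || cin != cout))
  list(
    list(type = "conv", k = 7L, stride = 2L, pad = 3L, cin = 1L, cout = 64L),
    list(type = "bn", c = 64L),
    list(type = "lrelu"),
    list(type = "maxpool", m = 2L),
    rb(64L, 64L, 1L), rb(64L, 64L, 1L),
    rb(64L, 128L, 2L), rb(128L, 128L, 1L),
    rb(128L, 256L, 2L), rb(256L, 256L, 1L),
    rb(256L, 512L, 2L), rb(512L, 512L, 1L),
    list(type = "gap"),
    list(type = "fc", p = 512L, q = cfg$feature_dim)
  )
}

init_conv <- function(k, cin, cout)
  list(W = matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout))

init_fc <- function(p, q, sd = sqrt(2 / p))
  list(W = matrix(stats::rnorm(p * q, 0, sd), p, q), b = numeric(q))

init_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c))
init_bn_state <- function(c) list(mean = numeric(c), var = rep(1, c))

init_layer_params <- function(ly) {
  switch(ly$type,
    conv = init_conv(ly$k, ly$cin, ly$cout),
    bn = init_bn(ly$c),
    fc = init_fc(ly$p, ly$q),
    resblock = {
      p <- list(conv1 = init_conv(3L, ly$cin, ly$cout),
                bn1 = init_bn(ly$cout),
                conv2 = init_conv(3L, ly$cout, ly$cout),
                bn2 = init_bn(ly$cout))
      if (ly$down) {
        p$down_conv <- init_conv(1L, ly$cin, ly$cout)
        p$down_bn <- init_bn(ly$cout)
      }
      p
    },
    list())
}

init_layer_state <- function(ly) {
  switch(ly$type,
    bn = init_bn_state(ly$c),
    resblock = {
      s <- list(bn1 = init_bn_state(ly$cout), bn2 = init_bn_state(ly$cout))
      if (ly$down) s$down_bn <- init_bn_state(ly$cout)
      s
    },
    list())
}

#' Initialize the multi-task network
#'
#' @param config A [network_config()].
#' @return A `tme_network` object holding architecture, parameters and
#'   batch-norm running statistics.
#' @export
init_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  arch <- if (config$backbone == "tiny") tiny_arch(config) else resnet18_arch(config)
  d <- config$feature_dim; da <- config$attn_dim
  N <- config$n_tasks; hc <- config$surv_hidden
  params <- list(
    backbone = lapply(arch, init_layer_params),
    refine = list(fc1 = init_fc(d, d, sd = sqrt(1 / d)),
                  fc2 = init_fc(d, d, sd = sqrt(1 / d))),
    attn = list(fc1 = init_fc(d, da, sd = sqrt(1 / d)),
                fc2 = init_fc(d, da, sd = sqrt(1 / d)),
                fc3 = init_fc(da, N, sd = sqrt(1 / da))),
    tme = init_fc(d, config$n_classes, sd = sqrt(1 / d)),
    surv = list(fc1 = init_fc(d + config$n_classes, hc,
                              sd = sqrt(1 / (d + config$n_classes))),
                fc2 = init_fc(hc, 1L, sd = sqrt(1 / hc)))
  )
  state <- list(backbone = lapply(arch, init_layer_state))
  structure(list(config = config, arch = arch, params = params, state = state),
            class = "tme_network")
}

## ---- backbone forward/backward ---------------------------------------------

backbone_stack_forward <- function(net, x, training = FALSE, from = 1L) {
  slope <- net$config$leaky_relu_slope
  caches <- vector("list", length(net$arch))
  state <- net$state$backbone
  for (i in from:length(net$arch)) {
    ly <- net$arch[[i]]; par <- net$params$backbone[[i]]
    r <- switch(ly$type,
      avgpool = avgpool_forward(x, ly$m),
      maxpool = maxpool_forward(x, ly$m),
      conv = conv_forward(x, par$W, par$b, ly$k, ly$stride, ly$pad, training),
      lrelu = list(out = leaky_relu(x, slope),
                   cache = if (training) list(x = x) else NULL),
      bn = {
        z <- bn_forward(x, par$gamma, par$beta, state[[i]], training)
        state[[i]] <- z$state
        z
      },
      gap = gap_forward(x),
      fc = fc_forward(x, par$W, par$b, training),
      resblock = {
        z <- resblock_forward(x, ly, par, state[[i]], training, slope)
        state[[i]] <- z$state
        z
      },
      stop("unknown layer type: ", ly$type))
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches, state = state)
}

backbone_stack_backward <- function(net, caches, dout, to = 1L) {
  slope <- net$config$leaky_relu_slope
  g <- vector("list", length(net$arch))
  dx <- dout
  for (i in rev(to:length(net$arch))) {
    ly <- net$arch[[i]]; par <- net$params$backbone[[i]]
    g[[i]] <- list()
    dx <- switch(ly$type,
      avgpool = avgpool_backward(dx, caches[[i]]),
      maxpool = maxpool_backward(dx, caches[[i]]),
      conv = {
        r <- conv_backward(dx, par$W, caches[[i]], need_dx = (i > to))
        g[[i]] <- list(W = r$dW, b = r$db)
        r$dx
      },
      lrelu = dx * leaky_relu_grad(caches[[i]]$x, slope),
      bn = {
        r <- bn_backward(dx, par$gamma, caches[[i]])
        g[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
        r$dx
      },
      gap = gap_backward(dx, caches[[i]]),
      fc = {
        r <- fc_backward(dx, par$W, caches[[i]])
        g[[i]] <- list(W = r$dW, b = r$db)
        r$dx
      },
      resblock = {
        r <- resblock_backward(dx, ly, par, caches[[i]], slope)
        g[[i]] <- r$grads
        r$dx
      })
  }
  list(dx = dx, grads = g)
}

resblock_forward <- function(x, ly, par, st, training, slope) {
  c1 <- conv_forward(x, par$conv1$W, par$conv1$b, 3L, ly$stride, 1L, training)
  b1 <- bn_forward(c1$out, par$bn1$gamma, par$bn1$beta, st$bn1, training)
  st$bn1 <- b1$state
  a1 <- leaky_relu(b1$out, slope)
  c2 <- conv_forward(a1, par$conv2$W, par$conv2$b, 3L, 1L, 1L, training)
  b2 <- bn_forward(c2$out, par$bn2$gamma, par$bn2$beta, st$bn2, training)
  st$bn2 <- b2$state
  if (ly$down) {
    cd <- conv_forward(x, par$down_conv$W, par$down_conv$b, 1L, ly$stride, 0L, training)
    bd <- bn_forward(cd$out, par$down_bn$gamma, par$down_bn$beta, st$down_bn, training)
    st$down_bn <- bd$state
    idn <- bd$out
  } else {
    cd <- bd <- NULL
    idn <- x
  }
  pre <- b2$out + idn
  out <- leaky_relu(pre, slope)
  cache <- if (training) list(c1 = c1$cache, b1 = b1$cache, b1out = b1$out,
                              c2 = c2$cache, b2 = b2$cache,
                              cd = if (ly$down) cd$cache else NULL,
                              bd = if (ly$down) bd$cache else NULL,
                              pre = pre) else NULL
  list(out = out, cache = cache, state = st)
}

resblock_backward <- function(dout, ly, par, cache, slope) {
  dpre <- dout * leaky_relu_grad(cache$pre, slope)
  rb2 <- bn_backward(dpre, par$bn2$gamma, cache$b2)
  rc2 <- conv_backward(rb2$dx, par$conv2$W, cache$c2)
  da1 <- rc2$dx * leaky_relu_grad(cache$b1out, slope)
  rb1 <- bn_backward(da1, par$bn1$gamma, cache$b1)
  rc1 <- conv_backward(rb1$dx, par$conv1$W, cache$c1)
  grads <- list(conv1 = list(W = rc1$dW, b = rc1$db),
                bn1 = list(gamma = rb1$dgamma, beta = rb1$dbeta),
                conv2 = list(W = rc2$dW, b = rc2$db),
                bn2 = list(gamma = rb2$dgamma, beta = rb2$dbeta))
  if (ly$down) {
    rbd <- bn_backward(dpre, par$down_bn$gamma, cache$bd)
    rcd <- conv_backward(rbd$dx, par$down_conv$W, cache$cd)
    grads$down_conv <- list(W = rcd$dW, b = rcd$db)
    grads$down_bn <- list(gamma = rbd$dgamma, beta = rbd$dbeta)
    dx <- rc1$dx + rcd$dx
  } else {
    dx <- rc1$dx + dpre
  }
  list(dx = dx, grads = grads)
}

## ---- full network forward ---------------------------------------------------

as_stack_array <- function(stacks, cfg) {
  if (inherits(stacks, "slice_stack")) stacks <- stacks$planes
  d <- dim(stacks)
  if (length(d) == 3L) { dim(stacks) <- c(1L, d); d <- dim(stacks) }
  if (d[2] != cfg$n_slices || d[3] != cfg$input_size || d[4] != cfg$input_size)
    stop(sprintf("stack shape mismatch: expected (*, %d, %d, %d)",
                 cfg$n_slices, cfg$input_size, cfg$input_size))
  stacks
}

#' Forward pass of the multi-task network
#'
#' @param net A `tme_network`.
#' @param stacks A `(B, 5, S, S)` array (or a single `(5, S, S)` stack or
#'   `slice_stack`).
#' @param training Cache intermediates for backprop and use batch statistics
#'   in normalization layers.
#' @return List with `prob` (B x 4 class probabilities), `logits`, `risk`
#'   (length-B survival score, the DLS), `A` (B x N x n_slices attention),
#'   `M` (B x N x d pooled features), plus caches when `training = TRUE`.
#' @export
network_forward <- function(net, stacks, training = FALSE, from_layer = 1L) {
  cfg <- net$config
  S <- cfg$input_size
  if (from_layer > 1L) {       # input already passed through the skipped layers
    for (i in seq_len(from_layer - 1L))
      if (net$arch[[i]]$type %in% c("avgpool", "maxpool"))
        S <- S %/% net$arch[[i]]$m
    d <- dim(stacks)
    if (length(d) != 4L || d[2] != cfg$n_slices || d[3] != S || d[4] != S)
      stop("pre-reduced stack shape mismatch")
  } else {
    stacks <- as_stack_array(stacks, cfg)
  }
  B <- dim(stacks)[1]; ns <- cfg$n_slices
  x <- stacks
  dim(x) <- c(B * ns, S, S)           # row r = subject b + B*(slice-1)
  dim(x) <- c(B * ns, S, S, 1L)

  bb <- backbone_stack_forward(net, x, training, from = from_layer)
  raw <- bb$out                        # (B*ns, d)
  p <- net$params
  slope <- cfg$leaky_relu_slope
  pre1 <- sweep(raw %*% p$refine$fc1$W, 2, p$refine$fc1$b, "+")
  h1 <- leaky_relu(pre1, slope)
  pre2 <- sweep(h1 %*% p$refine$fc2$W, 2, p$refine$fc2$b, "+")
  Fmat <- leaky_relu(pre2, slope)

  N <- cfg$n_tasks; d <- cfg$feature_dim
  prob <- matrix(0, B, cfg$n_classes)
  logits <- matrix(0, B, cfg$n_classes)
  risk <- numeric(B)
  A_all <- array(0, c(B, N, ns))
  M_all <- array(0, c(B, N, d))
  subj_caches <- if (training) vector("list", B) else NULL

  for (b in seq_len(B)) {
    rows <- b + B * (seq_len(ns) - 1L)
    f <- Fmat[rows, , drop = FALSE]                          # (ns, d)
    ap <- attention_forward_core(f, p$attn)
    M <- ap$A %*% f                                          # (N, d)
    z <- drop(M[1, ] %*% p$tme$W + p$tme$b)                  # 4 logits
    yhat <- drop(softmax_rows(matrix(z, 1)))
    u <- matrix(c(M[2, ], yhat), 1)                          # (1, d+4)
    pre_s1 <- u %*% p$surv$fc1$W + matrix(p$surv$fc1$b, 1)
    a_s1 <- leaky_relu(pre_s1, slope)
    hh <- drop(a_s1 %*% p$surv$fc2$W + p$surv$fc2$b)

    prob[b, ] <- yhat; logits[b, ] <- z; risk[b] <- hh
    A_all[b, , ] <- ap$A; M_all[b, , ] <- M
    if (training)
      subj_caches[[b]] <- list(f = f, ap = ap, M = M, yhat = yhat,
                               u = u, pre_s1 = pre_s1, a_s1 = a_s1)
  }

  out <- list(prob = prob, logits = logits, risk = risk, A = A_all, M = M_all)
  if (training)
    out$cache <- list(bb = bb, raw = raw, pre1 = pre1, h1 = h1, pre2 = pre2,
                      Fmat = Fmat, subj = subj_caches, B = B,
                      from_layer = from_layer)
  out
}

attention_forward_core <- function(f, attn) {
  p1 <- sweep(f %*% attn$fc1$W, 2, attn$fc1$b, "+")
  p2 <- sweep(f %*% attn$fc2$W, 2, attn$fc2$b, "+")
  tg <- tanh(p1)
  sg <- stats::plogis(p2)
  g <- tg * sg
  logits <- sweep(g %*% attn$fc3$W, 2, attn$fc3$b, "+")   # (ns, N)
  A_cols <- softmax_cols(logits)
  list(A = t(A_cols), A_cols = A_cols, g = g, tg = tg, sg = sg)
}

## ---- full network backward --------------------------------------------------

# dz_ce: (B, 4) gradient of the loss w.r.t. the classification logits
# dh:    length-B gradient of the loss w.r.t. the risk output
network_backward <- function(net, fwd, dz_ce, dh) {
  cfg <- net$config; p <- net$params
  slope <- cfg$leaky_relu_slope
  cache <- fwd$cache
  B <- cache$B; ns <- cfg$n_slices
  d <- cfg$feature_dim; N <- cfg$n_tasks

  g <- tree_zero(p)
  dF <- matrix(0, nrow(cache$Fmat), d)

  for (b in seq_len(B)) {
    sc <- cache$subj[[b]]
    rows <- b + B * (seq_len(ns) - 1L)

    # survival head
    dWs2 <- t(sc$a_s1) * dh[b]
    da1 <- dh[b] * t(p$surv$fc2$W)
    dpre_s1 <- da1 * leaky_relu_grad(sc$pre_s1, slope)
    g$surv$fc2$W <- g$surv$fc2$W + dWs2
    g$surv$fc2$b <- g$surv$fc2$b + dh[b]
    g$surv$fc1$W <- g$surv$fc1$W + crossprod(sc$u, dpre_s1)
    g$surv$fc1$b <- g$surv$fc1$b + drop(dpre_s1)
    du <- dpre_s1 %*% t(p$surv$fc1$W)
    dM2 <- du[1, seq_len(d)]
    dyhat <- if (cfg$detach_cascade) numeric(cfg$n_classes) else
      du[1, d + seq_len(cfg$n_classes)]

    # classification head (CE gradient + softmax-jacobian of the cascade path)
    dz <- dz_ce[b, ] + sc$yhat * (dyhat - sum(dyhat * sc$yhat))
    g$tme$W <- g$tme$W + tcrossprod(sc$M[1, ], dz)
    g$tme$b <- g$tme$b + dz
    dM1 <- drop(p$tme$W %*% dz)

    dM <- matrix(0, N, d)
    dM[1, ] <- dM1; dM[2, ] <- dM2

    # attention pooling
    ap <- sc$ap
    dA <- dM %*% t(sc$f)                       # (N, ns)
    df <- t(ap$A) %*% dM                       # (ns, d)
    dA_cols <- t(dA)                           # (ns, N)
    dlog <- matrix(0, ns, N)
    for (j in seq_len(N)) {
      a <- ap$A_cols[, j]
      dlog[, j] <- a * (dA_cols[, j] - sum(dA_cols[, j] * a))
    }
    g$attn$fc3$W <- g$attn$fc3$W + crossprod(ap$g, dlog)
    g$attn$fc3$b <- g$attn$fc3$b + colSums(dlog)
    dg <- dlog %*% t(p$attn$fc3$W)
    dtg <- dg * ap$sg
    dsg <- dg * ap$tg
    dp1 <- dtg * (1 - ap$tg^2)
    dp2 <- dsg * ap$sg * (1 - ap$sg)
    g$attn$fc1$W <- g$attn$fc1$W + crossprod(sc$f, dp1)
    g$attn$fc1$b <- g$attn$fc1$b + colSums(dp1)
    g$attn$fc2$W <- g$attn$fc2$W + crossprod(sc$f, dp2)
    g$attn$fc2$b <- g$attn$fc2$b + colSums(dp2)
    df <- df + dp1 %*% t(p$attn$fc1$W) + dp2 %*% t(p$attn$fc2$W)

    dF[rows, ] <- dF[rows, ] + df
  }

  # refinement FCs (batched over all slices)
  dpre2 <- dF * leaky_relu_grad(cache$pre2, slope)
  g$refine$fc2$W <- crossprod(cache$h1, dpre2)
  g$refine$fc2$b <- colSums(dpre2)
  dh1 <- dpre2 %*% t(p$refine$fc2$W)
  dpre1 <- dh1 * leaky_relu_grad(cache$pre1, slope)
  g$refine$fc1$W <- crossprod(cache$raw, dpre1)
  g$refine$fc1$b <- colSums(dpre1)
  draw <- dpre1 %*% t(p$refine$fc1$W)

  bbb <- backbone_stack_backward(net, cache$bb$caches, draw, to = cache$from_layer)
  g$backbone <- bbb$grads
  g
}

## ---- exported per-operation wrappers ----------------------------------------

#' Per-slice backbone features
#'
#' @param net A `tme_network`.
#' @param stack A `(5, S, S)` array or `slice_stack`.
#' @return `n_slices x d` matrix of per-slice features.
#' @export
backbone_forward <- function(net, stack) {
  cfg <- net$config
  stacks <- as_stack_array(stack, cfg)
  if (dim(stacks)[1] != 1L) stop("backbone_forward takes a single stack")
  x <- stacks
  dim(x) <- c(cfg$n_slices, cfg$input_size, cfg$input_size, 1L)
  backbone_stack_forward(net, x, training = FALSE)$out
}

#' Refine per-slice features with two leaky-ReLU FC layers
#' @param net A `tme_network`.
#' @param raw `n_slices x d` matrix.
#' @return `n_slices x d` refined feature matrix.
#' @export
refine_features <- function(net, raw) {
  p <- net$params$refine; slope <- net$config$leaky_relu_slope
  h1 <- leaky_relu(sweep(raw %*% p$fc1$W, 2, p$fc1$b, "+"), slope)
  leaky_relu(sweep(h1 %*% p$fc2$W, 2, p$fc2$b, "+"), slope)
}

#' Gated-attention pooling over slices
#'
#' Computes `A = softmax(w3(tanh(w1 f + b1) * sigmoid(w2 f + b2)) + b3)` with
#' the softmax taken across slices separately for each task row, and the
#' pooled feature `M = A f`.
#'
#' @param net A `tme_network`.
#' @param f `n_slices x d` refined feature matrix.
#' @return List with `A` (`N x n_slices`, rows are probability vectors) and
#'   `M` (`N x d`).
#' @export
attention_pool <- function(net, f) {
  ap <- attention_forward_core(f, net$params$attn)
  list(A = ap$A, M = ap$A %*% f)
}

#' TME classification head
#' @param net A `tme_network`.
#' @param m_row0 First-row pooled feature (length d).
#' @return Four class probabilities summing to 1.
#' @export
tme_head <- function(net, m_row0) {
  z <- drop(matrix(m_row0, 1) %*% net$params$tme$W + net$params$tme$b)
  drop(softmax_rows(matrix(z, 1)))
}

#' Cascaded survival head
#' @param net A `tme_network`.
#' @param m_row1 Second-row pooled feature (length d).
#' @param y_hat Predicted class probabilities (length 4).
#' @return Scalar risk score (the DLS); higher = higher hazard.
#' @export
survival_head <- function(net, m_row1, y_hat) {
  p <- net$params$surv; slope <- net$config$leaky_relu_slope
  u <- matrix(c(m_row1, y_hat), 1)
  a1 <- leaky_relu(u %*% p$fc1$W + matrix(p$fc1$b, 1), slope)
  drop(a1 %*% p$fc2$W + p$fc2$b)
}

#' Predict TME classes and survival scores
#'
#' Eval-mode forward pass (no augmentation, running normalization statistics).
#'
#' @param net A trained `tme_network`.
#' @param stacks `(B, 5, S, S)` array, single stack, or `slice_stack`.
#' @param subject_id Optional ids for the output table.
#' @return Data frame with class probabilities `p_class1..4`,
#'   `predicted_class`, and `dls` (the scalar risk score).
#' @export
predict_network <- function(net, stacks, subject_id = NULL) {
  fwd <- network_forward(net, stacks, training = FALSE)
  out <- data.frame(
    p_class1 = fwd$prob[, 1], p_class2 = fwd$prob[, 2],
    p_class3 = fwd$prob[, 3], p_class4 = fwd$prob[, 4],
    predicted_class = max.col(fwd$prob, ties.method = "first"),
    dls = fwd$risk)
  if (!is.null(subject_id)) out <- cbind(subject_id = subject_id, out)
  out
}

#' @export
predict.tme_network <- function(object, newdata, ...) predict_network(object, newdata)

one_hot <- function(classes, k = 4L) {
  m <- matrix(0, length(classes), k)
  m[cbind(seq_along(classes), classes)] <- 1
  m
}
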