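# Layer primitives for the multi-task network, implemented in base R with
# batched im2col convolutions and hand-derived backward passes. Arrays use the
# (batch, height, width, channel) layout; fully connected layers use
# out = x %*% W + b with W of shape (in, out).

leaky_relu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
leaky_relu_grad <- function(x, slope) slope + (1 - slope) * (x > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# columnwise softmax (used for attention over the slice axis)
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

## ---- convolution ----------------------------------------------------------

conv_im2col <- function(xpad, k, stride, oH, oW) {
  d <- dim(xpad)  # (n, pH, pW, C)
  n <- d[1]; C <- d[4]
  cols <- matrix(0, n * oH * oW, k * k * C)
  blk <- 0L
  ri <- function(di) di + (seq_len(oH) - 1L) * stride
  ci <- function(dj) dj + (seq_len(oW) - 1L) * stride
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    sub <- xpad[, ri(di), ci(dj), , drop = FALSE]
    dim(sub) <- c(n * oH * oW, C)
    cols[, blk * C + seq_len(C)] <- sub
    blk <- blk + 1L
  }
  cols
}

conv_forward <- function(x, W, b, k, stride, pad, training) {
  d <- dim(x); n <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  pH <- H + 2L * pad; pW <- Wd + 2L * pad
  oH <- (pH - k) %/% stride + 1L
  oW <- (pW - k) %/% stride + 1L
  xpad <- array(0, c(n, pH, pW, C))
  xpad[, pad + seq_len(H), pad + seq_len(Wd), ] <- x
  cols <- conv_im2col(xpad, k, stride, oH, oW)
  outm <- cols %*% W
  outm <- sweep(outm, 2, b, "+")
  out <- array(outm, c(n, oH, oW, ncol(W)))
  cache <- if (training) list(cols = cols, in_dim = d, pad = pad, k = k,
                              stride = stride, oH = oH, oW = oW) else NULL
  list(out = out, cache = cache)
}

conv_backward <- function(dout, W, cache, need_dx = TRUE) {
  d <- cache$in_dim; n <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  pad <- cache$pad; k <- cache$k; stride <- cache$stride
  oH <- cache$oH; oW <- cache$oW
  doutm <- dout; dim(doutm) <- c(n * oH * oW, dim(dout)[4])
  dW <- crossprod(cache$cols, doutm)
  db <- colSums(doutm)
  if (!need_dx) return(list(dx = NULL, dW = dW, db = db))
  dcols <- doutm %*% t(W)
  pH <- H + 2L * pad; pW <- Wd + 2L * pad
  dxpad <- array(0, c(n, pH, pW, C))
  blk <- 0L
  ri <- function(di) di + (seq_len(oH) - 1L) * stride
  ci <- function(dj) dj + (seq_len(oW) - 1L) * stride
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    block <- dcols[, blk * C + seq_len(C), drop = FALSE]
    dim(block) <- c(n, oH, oW, C)
    dxpad[, ri(di), ci(dj), ] <- dxpad[, ri(di), ci(dj), , drop = FALSE] + block
    blk <- blk + 1L
  }
  dx <- dxpad[, pad + seq_len(H), pad + seq_len(Wd), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

## ---- pooling --------------------------------------------------------------

pool_views <- function(x, m) {
  d <- dim(x)
  lapply(seq_len(m * m) - 1L, function(v) {
    di <- v %% m + 1L; dj <- v %/% m + 1L
    x[, seq(di, d[2], by = m), seq(dj, d[3], by = m), , drop = FALSE]
  })
}

avgpool_forward <- function(x, m) {
  d <- dim(x)
  if (any(d[2:3] %% m != 0)) stop("pooling requires divisible dimensions")
  oH <- d[2] %/% m; oW <- d[3] %/% m
  y <- x
  dim(y) <- c(d[1], m, oH, m, oW, d[4])
  y <- aperm(y, c(1, 3, 5, 6, 2, 4))
  dim(y) <- c(d[1] * oH * oW * d[4], m * m)
  out <- rowMeans(y)
  dim(out) <- c(d[1], oH, oW, d[4])
  list(out = out, cache = list(m = m, in_dim = d, o = c(oH, oW)))
}

avgpool_backward <- function(dout, cache) {
  m <- cache$m
  dx <- dout[, rep(seq_len(cache$o[1]), each = m),
             rep(seq_len(cache$o[2]), each = m), , drop = FALSE] / (m * m)
  dx
}

maxpool_forward <- function(x, m = 2L) {
  if (any(dim(x)[2:3] %% m != 0)) stop("pooling requires divisible dimensions")
  vs <- pool_views(x, m)
  out <- Reduce(pmax, vs)
  masks <- vector("list", length(vs))
  taken <- array(FALSE, dim(out))
  for (i in seq_along(vs)) {   # ties resolved to the first maximal view
    masks[[i]] <- (vs[[i]] == out) & !taken
    taken <- taken | masks[[i]]
  }
  list(out = out, cache = list(m = m, in_dim = dim(x), masks = masks))
}

maxpool_backward <- function(dout, cache) {
  m <- cache$m
  dx <- array(0, cache$in_dim)
  for (v in seq_len(m * m) - 1L) {
    di <- v %% m + 1L; dj <- v %/% m + 1L
    dx[, seq(di, cache$in_dim[2], by = m), seq(dj, cache$in_dim[3], by = m), ] <-
      dout * cache$masks[[v + 1L]]
  }
  dx
}

## ---- batch normalization --------------------------------------------------

bn_forward <- function(x, gamma, beta, state, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x); C <- d[4]
  xm <- x; dim(xm) <- c(prod(d[1:3]), C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean; v <- state$var
    xc <- sweep(xm, 2, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  outm <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  out <- array(outm, d)
  list(out = out,
       cache = if (training) list(xhat = xhat, istd = istd, dims = d) else NULL,
       state = state)
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$dims; C <- d[4]; m <- prod(d[1:3])
  dom <- dout; dim(dom) <- c(m, C)
  dgamma <- colSums(dom * cache$xhat)
  dbeta <- colSums(dom)
  dxhat <- sweep(dom, 2, gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dxm <- sweep(t1 - t2, 2, cache$istd, "*")
  dx <- array(dxm, d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- global average pool and FC -------------------------------------------

gap_forward <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(1, 4, 2, 3))
  m <- matrix(xp, d[1] * d[4], d[2] * d[3])
  out <- matrix(rowMeans(m), d[1], d[4])
  list(out = out, cache = list(in_dim = d))
}

gap_backward <- function(dout, cache) {
  d <- cache$in_dim
  per <- dout / (d[2] * d[3])            # (n, C)
  dx <- array(0, d)
  for (c in seq_len(d[4])) dx[, , , c] <- array(per[, c], d[1:3])
  dx
}

fc_forward <- function(x, W, b, training) {
  out <- sweep(x %*% W, 2, b, "+")
  list(out = out, cache = if (training) list(x = x) else NULL)
}

fc_backward <- function(dout, W, cache) {
  list(dx = dout %*% t(W), dW = crossprod(cache$x, dout), db = colSums(dout))
}

## ---- parameter-tree utilities ---------------------------------------------

tree_map1 <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map1(f, a[[i]])
    out
  } else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_map3 <- function(f, a, b, c) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map3(f, a[[i]], b[[i]], c[[i]])
    out
  } else f(a, b, c)
}

tree_zero <- function(a) tree_map1(function(x) x * 0, a)
tree_add <- function(a, b) tree_map2(`+`, a, b)

# list of leaf paths (each an index vector usable with [[ ]])
tree_paths <- function(a, prefix = integer(0)) {
  if (!is.list(a)) return(list(prefix))
  out <- list()
  for (i in seq_along(a)) out <- c(out, tree_paths(a[[i]], c(prefix, i)))
  out
}
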