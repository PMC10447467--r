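test_that("reference backbone emits 256-dim per-slice features", {
  cfg <- network_config("resnet18", seed = 1L)
  net <- init_network(cfg)
  stack <- array(0, c(5, 160, 160))
  f <- backbone_forward(net, stack)
  expect_equal(dim(f), c(5L, 256L))
  expect_true(all(is.finite(f)))
})

test_that("weight sharing: identical slices give identical per-slice features", {
  cfg <- network_config("tiny", input_size = 40L, pool0 = 2L, seed = 2L)
  net <- init_network(cfg)
  set.seed(3)
  plane <- matrix(runif(40 * 40), 40, 40)
  stack <- array(0, c(5, 40, 40))
  for (i in 1:5) stack[i, , ] <- plane
  f <- backbone_forward(net, stack)
  for (i in 2:5) expect_equal(f[i, ], f[1, ])
  # and repeated forward passes are bit-stable in eval mode
  expect_identical(f, backbone_forward(net, stack))
})

test_that("feature refinement follows the leaky-ReLU FC contract", {
  cfg <- network_config("tiny", seed = 4L)
  net <- init_network(cfg)
  d <- cfg$feature_dim
  # zero weights and biases -> zero output
  net0 <- net
  net0$params$refine$fc1$W[] <- 0; net0$params$refine$fc1$b[] <- 0
  net0$params$refine$fc2$W[] <- 0; net0$params$refine$fc2$b[] <- 0
  raw <- matrix(rnorm(5 * d), 5, d)
  expect_true(all(refine_features(net0, raw) == 0))
  # identity-initialized FCs are the identity on positive inputs
  net1 <- net
  net1$params$refine$fc1$W <- diag(d); net1$params$refine$fc1$b[] <- 0
  net1$params$refine$fc2$W <- diag(d); net1$params$refine$fc2$b[] <- 0
  pos <- matrix(abs(rnorm(5 * d)) + 0.1, 5, d)
  expect_equal(refine_features(net1, pos), pos)
  # negative pre-activations are scaled by the configured slope
  neg <- -pos
  expect_equal(refine_features(net1, neg),
               neg * cfg$leaky_relu_slope^2, tolerance = 1e-12)
})

test_that("attention with a zero final FC is uniform and pools to the slice mean", {
  cfg <- network_config("tiny", seed = 5L)
  net <- init_network(cfg)
  net$params$attn$fc3$W[] <- 0
  net$params$attn$fc3$b[] <- 0
  f <- matrix(rnorm(5 * cfg$feature_dim), 5, cfg$feature_dim)
  ap <- attention_pool(net, f)
  expect_equal(ap$A, matrix(1 / 5, cfg$n_tasks, 5))
  for (r in seq_len(cfg$n_tasks)) expect_equal(ap$M[r, ], colMeans(f))
})

test_that("attention rows are probability vectors for random parameters", {
  set.seed(6)
  for (r in 1:20) {
    cfg <- network_config("tiny", seed = r + 10L)
    net <- init_network(cfg)
    f <- matrix(rnorm(5 * cfg$feature_dim, sd = 3), 5, cfg$feature_dim)
    ap <- attention_pool(net, f)
    expect_equal(rowSums(ap$A), rep(1, cfg$n_tasks), tolerance = 1e-6)
    expect_true(all(ap$A > 0 & ap$A < 1))
  }
})

test_that("a dominant slice logit concentrates the attention on that slice", {
  cfg <- network_config("tiny", seed = 7L)
  net <- init_network(cfg)
  d <- cfg$feature_dim
  net$params$attn$fc1$W[] <- 0; net$params$attn$fc1$W[1, 1] <- 1
  net$params$attn$fc1$b[] <- 0
  net$params$attn$fc2$W[] <- 0; net$params$attn$fc2$b[] <- 100  # gate ~ 1
  net$params$attn$fc3$W[] <- 0; net$params$attn$fc3$W[1, ] <- 50
  net$params$attn$fc3$b[] <- 0
  f <- matrix(0, 5, d); f[3, 1] <- 100
  ap <- attention_pool(net, f)
  expect_gt(min(ap$A[, 3]), 0.999)
  for (r in seq_len(cfg$n_tasks))
    expect_equal(ap$M[r, ], f[3, ], tolerance = 1e-2)
})

test_that("TME head is a softmax over four classes", {
  cfg <- network_config("tiny", seed = 8L)
  net <- init_network(cfg)
  d <- cfg$feature_dim
  net0 <- net; net0$params$tme$W[] <- 0; net0$params$tme$b[] <- 0
  expect_equal(tme_head(net0, rnorm(d)), rep(0.25, 4))
  set.seed(9)
  for (r in 1:10) {
    y <- tme_head(net, rnorm(d, sd = 2))
    expect_equal(sum(y), 1, tolerance = 1e-6)
    expect_true(all(y >= 0))
  }
  # crafted logits (10, 0, 0, 0)
  netc <- net; netc$params$tme$W[] <- 0; netc$params$tme$b <- c(10, 0, 0, 0)
  y <- tme_head(netc, rnorm(d))
  expect_equal(which.max(y), 1L)
  expect_gt(y[1], 0.999)
})

test_that("survival head is scalar, zero at zero weights, with a live cascade path", {
  cfg <- network_config("tiny", seed = 10L)
  net <- init_network(cfg)
  d <- cfg$feature_dim
  net0 <- net
  net0$params$surv$fc1$W[] <- 0; net0$params$surv$fc1$b[] <- 0
  net0$params$surv$fc2$W[] <- 0; net0$params$surv$fc2$b[] <- 0
  expect_identical(survival_head(net0, rnorm(d), rep(0.25, 4)), 0)
  # perturbing the class probabilities changes the risk: the cascade is live
  m1 <- rnorm(d)
  y <- c(0.7, 0.1, 0.1, 0.1)
  h_base <- survival_head(net, m1, y)
  h_pert <- survival_head(net, m1, y + c(-0.2, 0.2, 0, 0))
  expect_gt(abs(h_pert - h_base), 0)
  expect_length(h_base, 1L)
})

test_that("batched prediction is deterministic and returns one risk per subject", {
  cfg <- network_config("tiny", input_size = 40L, pool0 = 2L, seed = 11L)
  net <- init_network(cfg)
  set.seed(12)
  stacks <- array(runif(6 * 5 * 40 * 40), c(6, 5, 40, 40))
  p1 <- predict_network(net, stacks)
  p2 <- predict_network(net, stacks)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 6L)
  expect_equal(rowSums(as.matrix(p1[, paste0("p_class", 1:4)])), rep(1, 6),
               tolerance = 1e-6)
  # batched forward agrees with the per-subject operation chain
  f <- backbone_forward(net, array(stacks[3, , , ], c(5, 40, 40)))
  fr <- refine_features(net, f)
  ap <- attention_pool(net, fr)
  y <- tme_head(net, ap$M[1, ])
  h <- survival_head(net, ap$M[2, ], y)
  expect_equal(unname(unlist(p1[3, paste0("p_class", 1:4)])), unname(y),
               tolerance = 1e-10)
  expect_equal(p1$dls[3], h, tolerance = 1e-10)
})

test_that("stack shape mismatches are rejected", {
  cfg <- network_config("tiny", seed = 13L)
  net <- init_network(cfg)
  expect_error(network_forward(net, array(0, c(4, 160, 160))), "shape mismatch")
  expect_error(network_forward(net, array(0, c(5, 80, 80))), "shape mismatch")
})
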