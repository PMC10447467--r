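# Shared fixtures, built in code at test time.

# synthetic 5-slice stacks with class-dependent texture amplitude, built
# directly at the network input (fast substitute for the full imaging pipeline
# in tests of the training machinery)
make_texture_stacks <- function(n, input_size = 40L, seed = 1L,
                                amplitudes = c(0.02, 0.10, 0.22, 0.38)) {
  set.seed(seed)
  classes <- sample(1:4, n, replace = TRUE)
  stacks <- array(0, c(n, 5L, input_size, input_size))
  for (i in seq_len(n)) {
    base <- runif(1, 0.4, 0.6)
    stacks[i, , , ] <- pmin(pmax(
      base + amplitudes[classes[i]] * rnorm(5 * input_size^2), 0), 1)
  }
  list(stacks = stacks, classes = classes)
}

# survival times monotone in class under proportional hazards
make_outcomes <- function(classes, seed = 2L, base_rate = 0.02,
                          log_hr = c(0, 0.5, 1.0, 1.5), cens = 60) {
  set.seed(seed)
  n <- length(classes)
  t_ev <- rexp(n, base_rate * exp(log_hr[classes]))
  t_c <- runif(n, 0, cens)
  list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}

# an ellipsoid volume + mask pair for preprocessing tests
make_ellipsoid_volume <- function(dims = c(12L, 48L, 48L), center = dims / 2,
                                  radii = c(4, 10, 12), spacing = c(2.5, 0.75, 0.75),
                                  inside = 100, outside = -100) {
  az <- ((seq_len(dims[1]) - center[1]) / radii[1])^2
  ay <- ((seq_len(dims[2]) - center[2]) / radii[2])^2
  ax <- ((seq_len(dims[3]) - center[3]) / radii[3])^2
  mask <- outer(outer(az, ay, "+"), ax, "+") <= 1
  vox <- array(outside, dims)
  vox[mask] <- inside
  list(volume = image_volume(vox, spacing),
       mask = image_volume(mask + 0, spacing))
}

# brute-force negative log Cox partial likelihood (Breslow ties)
oracle_cox_loss <- function(h, time, event) {
  s <- 0
  for (i in which(event == 1)) {
    R <- which(time >= time[i])
    s <- s + (h[i] - log(sum(exp(h[R]))))
  }
  -s
}

# brute-force Kaplan-Meier at given times
oracle_km <- function(time, event, at) {
  ev_times <- sort(unique(time[event == 1]))
  vapply(at, function(t) {
    s <- 1
    for (u in ev_times[ev_times <= t]) {
      d <- sum(time == u & event == 1)
      r <- sum(time >= u)
      s <- s * (1 - d / r)
    }
    s
  }, numeric(1))
}

# brute-force Harrell C (pair loop; ties in score count 0.5; a pair with tied
# times is comparable only when exactly one subject has the event — the
# censored one is known to have survived past it; tied event times are not
# comparable)
oracle_cindex <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) {
      if (event[i] + event[j] != 1L) next
      a <- if (event[i] == 1) i else j     # the event precedes the censoring
      b <- if (event[i] == 1) j else i
    } else {
      a <- if (time[i] < time[j]) i else j # earlier subject
      b <- if (time[i] < time[j]) j else i
      if (event[a] != 1) next              # not comparable
    }
    den <- den + 1
    num <- num + if (risk[a] > risk[b]) 1 else if (risk[a] == risk[b]) 0.5 else 0
  }
  num / den
}

# brute-force Mann-Whitney AUC
oracle_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
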