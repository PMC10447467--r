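test_that("generator config validates its invariants", {
  expect_error(generator_config(class_mixture = c(0.5, 0.5, 0.1, 0.1)), "sum to 1")
  expect_error(generator_config(heterogeneity_scale = c(10, 10, 20, 30)),
               "strictly increasing")
  expect_error(generator_config(censor_window = 0), "censor_window")
  expect_error(generator_config(baseline_hazard = -1), "baseline_hazard")
})

test_that("zero heterogeneity gives a constant-intensity tumor", {
  gen <- generator_config(heterogeneity_scale = c(0, 1, 2, 3) +
                            c(0, 1e-9, 2e-9, 3e-9))
  gen$heterogeneity_scale <- c(0, 1, 2, 3)
  ph <- generate_phantom(gen, 1L, seed = 3L)
  vals <- ph$volume$voxels[ph$mask$voxels == 1]
  expect_equal(stats::var(vals), 0)
})

test_that("phantom generation is deterministic under a fixed seed", {
  gen <- generator_config()
  a <- generate_phantom(gen, 2L, seed = 42L)
  b <- generate_phantom(gen, 2L, seed = 42L)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
})

test_that("intra-mask variance is higher for class 4 than class 1 (n = 50 each)", {
  gen <- generator_config()
  v1 <- v4 <- numeric(50)
  for (i in 1:50) {
    p1 <- generate_phantom(gen, 1L, seed = 1000L + i)
    p4 <- generate_phantom(gen, 4L, seed = 2000L + i)
    v1[i] <- stats::var(p1$volume$voxels[p1$mask$voxels == 1])
    v4[i] <- stats::var(p4$volume$voxels[p4$mask$voxels == 1])
  }
  expect_true(mean(v4) > mean(v1))
  expect_true(mean(v4) > 10 * mean(v1))  # separable by construction
})

test_that("phantoms respect the HU range and mask support, small volumes rejected", {
  gen <- generator_config()
  ph <- generate_phantom(gen, 3L, seed = 7L)
  expect_true(all(ph$volume$voxels >= -200 & ph$volume$voxels <= 300))
  expect_true(all(ph$mask$voxels %in% c(0, 1)))
  expect_gt(sum(ph$mask$voxels), 0)
  gen_small <- gen; gen_small$volume_shape <- c(16L, 96L, 96L)
  expect_error(generate_phantom(gen_small, 1L), ">= 32")
  expect_error(generate_phantom(gen, 5L), "1..4")
})

test_that("IHC panels close the labeling loop at zero noise", {
  thr_t <- list(is_gc = 1.5, postn = 4)
  thr <- structure(list(is_gc_median = 1.5, postn_median = 4,
                        source_cohort_id = "gen"), class = "tme_thresholds")
  set.seed(31)
  for (cls in 1:4) {
    for (r in 1:200) {
      p <- sample_ihc_panel(cls, thr_t, label_noise = 0)
      got <- assign_tme_class(compute_is_gc(p$ihc),
                              compute_postn_score(p$postn_intensity, p$postn_extent),
                              thr)
      expect_identical(got, cls)
    }
  }
})

test_that("label noise moves ~the configured mass off the diagonal", {
  thr_t <- list(is_gc = 1.5, postn = 4)
  thr <- structure(list(is_gc_median = 1.5, postn_median = 4,
                        source_cohort_id = "gen"), class = "tme_thresholds")
  set.seed(32)
  n <- 1000
  mismatch <- 0
  for (r in seq_len(n)) {
    cls <- sample(1:4, 1)
    p <- sample_ihc_panel(cls, thr_t, label_noise = 0.2)
    got <- assign_tme_class(compute_is_gc(p$ihc),
                            compute_postn_score(p$postn_intensity, p$postn_extent),
                            thr)
    mismatch <- mismatch + (got != cls)
  }
  expect_gt(mismatch / n, 0.2 - 3 * sqrt(0.2 * 0.8 / n))
  expect_lt(mismatch / n, 0.2 + 3 * sqrt(0.2 * 0.8 / n))
})

test_that("outcome sampling matches the exponential model", {
  gen <- generator_config(baseline_hazard = 0.05, censor_window = 1e6)
  set.seed(5)
  rec <- sample_outcome(rep(0, 4000), gen)
  expect_true(all(rec$time > 0))
  # censor window effectively infinite: nearly all events
  expect_gt(mean(rec$event), 0.99)
  med <- median(rec$time[rec$event == 1])
  expect_lt(abs(med - log(2) / 0.05), 2)   # analytic exponential median ~13.9
  expect_error(sample_outcome(c(0, Inf), gen), "finite")
  gen$baseline_hazard <- 0
  expect_error(sample_outcome(0, gen), "positive")
})

test_that("Weibull shape changes event-time scale as the closed form predicts", {
  gen <- generator_config(baseline_hazard = 0.05, weibull_shape = 2,
                          censor_window = 1e6)
  set.seed(7)
  rec <- sample_outcome(rep(0, 4000), gen)
  expect_lt(abs(median(rec$time) - sqrt(log(2) / 0.05)), 0.2)
})

test_that("class-wise marginal response rates track the configured targets", {
  gen <- generator_config(n_subjects = 4000L, seed = 13L)
  co <- generate_cohort(gen, generate_images = FALSE)
  orr <- tapply(co$response, co$true_class, mean)
  targets <- c(0.690, 0.533, 0.184, 0.172)
  for (k in 1:4) {
    n_k <- sum(co$true_class == k)
    expect_lt(abs(orr[k] - targets[k]),
              3 * sqrt(targets[k] * (1 - targets[k]) / n_k) + 0.01)
  }
})

test_that("configured log hazard ratio of 2 groups is recovered by a Cox fit", {
  gen <- generator_config(baseline_hazard = 0.02, censor_window = 60)
  set.seed(6)
  grp <- rep(0:1, each = 1000)
  rec <- sample_outcome(log(2) * grp, gen)
  fit <- cox_fit(rec$time, rec$event, data.frame(grp = grp))
  co <- fit$coefficients
  expect_gt(2, co$lower[1])
  expect_lt(2, co$upper[1])
  expect_lt(abs(co$hr[1] - 2), 0.35)
})

test_that("cohort generation is deterministic and respects the censor window", {
  gen <- generator_config(n_subjects = 25L, seed = 99L)
  a <- generate_cohort(gen, generate_images = FALSE)
  b <- generate_cohort(gen, generate_images = FALSE)
  expect_identical(a, b)
  expect_true(all(a$time > 0 & a$time <= gen$censor_window))
  expect_true(all(a$true_class %in% 1:4))
  expect_true(all(a$cps >= 0))
  expect_identical(as.integer(a$response %in% 1), as.integer(a$best_response %in% c("CR", "PR")))
})

test_that("an empty cohort writes an empty manifest without error", {
  gen <- generator_config(n_subjects = 0L)
  d <- tempfile()
  co <- generate_cohort(gen, out_dir = d)
  expect_equal(nrow(co), 0L)
  expect_true(file.exists(file.path(d, "manifest.csv")))
})

test_that("cohort files exist and round-trip through NIfTI", {
  gen <- generator_config(n_subjects = 2L, seed = 8L)
  d <- tempfile()
  co <- generate_cohort(gen, out_dir = d, keep_volumes = TRUE)
  expect_true(all(file.exists(co$volume_path)))
  expect_true(all(file.exists(co$mask_path)))
  v <- read_volume_nifti(co$volume_path[1])
  orig <- attr(co, "volumes")[[1]]$volume
  expect_equal(dim(v$voxels), dim(orig$voxels))
  expect_equal(v$spacing, orig$spacing, tolerance = 1e-6)
  expect_equal(v$voxels, orig$voxels, tolerance = 1e-5)
})
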