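# Seeded phantom cohorts with the statistical structure the downstream
# analyses assume: ellipsoidal tumors whose intra-tumor texture amplitude
# increases with TME class, IHC panels consistent with the IS_GC/POSTN
# quadrants, proportional-hazards outcomes, class-dependent chemotherapy
# effects, and class+CPS-dependent immunotherapy response.

#' Generator configuration for synthetic phantom cohorts
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: four equally mixed TME classes, strictly increasing texture
#' amplitude across classes, exponential event times with hazard monotone in
#' class, uniform administrative censoring over 60 months, the published
#' per-class chemotherapy hazard ratios (0.258, 0.691, 0.831, 1.669), and a
#' response model whose class-wise marginal objective-response rates match the
#' published 69.0/53.3/18.4/17.2%.
#'
#' @param n_subjects Number of subjects.
#' @param volume_shape Voxel grid (z, y, x), each axis >= 32.
#' @param voxel_spacing mm triple (z, y, x).
#' @param class_mixture Four class probabilities summing to 1.
#' @param heterogeneity_scale Per-class intra-tumor noise amplitude (HU),
#'   strictly increasing over classes 1..4.
#' @param texture_sigma In-plane sigmas (voxels) of the two Gaussian-filtered
#'   white-noise fields summed to form the texture.
#' @param baseline_hazard Event rate per month (> 0).
#' @param weibull_shape Weibull shape of event times; 1 = exponential.
#' @param log_hr_per_class Log hazard ratios of classes 1..4 (class 1 = 0).
#' @param censor_window Administrative censoring horizon, months (> 0).
#' @param chemo_log_hr_per_class Per-class log HR of chemotherapy vs. none.
#' @param response_logit_coefs List with `intercept`, `class` (length-4 logit
#'   offsets, class 1 = 0) and `cps_category` (low/intermediate/high offsets).
#' @param cps_mixture List with `probs` (3 category weights) and `ranges`
#'   (3 x 2 matrix of uniform CPS supports spanning low/intermediate/high).
#' @param ihc_thresholds List with target `is_gc` and `postn` medians used to
#'   place sampled scores on the correct quadrant side.
#' @param label_noise Probability that a subject's IHC panel is drawn for a
#'   random *other* class (0 = perfect label closure).
#' @param stage_class_cor Weak logit coupling between stage III and class.
#' @param stage_log_hr Log HR of stage III vs. II in the outcome model.
#' @param seed Base seed; per-subject RNG streams are derived from it.
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(n_subjects = 100L,
                             volume_shape = c(32L, 96L, 96L),
                             voxel_spacing = c(3.0, 1.5, 1.5),
                             class_mixture = rep(0.25, 4),
                             heterogeneity_scale = c(10, 50, 100, 160),
                             texture_sigma = c(1, 3),
                             baseline_hazard = 0.02,
                             weibull_shape = 1,
                             log_hr_per_class = c(0, 0.5, 1.0, 1.5),
                             censor_window = 60,
                             chemo_log_hr_per_class = log(c(0.258, 0.691, 0.831, 1.669)),
                             response_logit_coefs = list(
                               intercept = 0.2255,
                               class = c(0, -0.7118, -2.4351, -2.5207),
                               cps_category = c(0, 0.7, 1.4)),
                             cps_mixture = list(
                               probs = c(0.35, 0.40, 0.25),
                               ranges = rbind(c(0, 1), c(1, 10), c(10, 50))),
                             ihc_thresholds = list(is_gc = 1.5, postn = 4),
                             label_noise = 0,
                             stage_class_cor = 0.2,
                             stage_log_hr = 0.3,
                             seed = 20230823L) {
  if (abs(sum(class_mixture) - 1) > 1e-8) stop("class_mixture must sum to 1")
  if (length(heterogeneity_scale) != 4L ||
      any(diff(heterogeneity_scale) <= 0))
    stop("heterogeneity_scale must be strictly increasing over classes 1..4")
  if (censor_window <= 0) stop("censor_window must be > 0")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (label_noise < 0 || label_noise >= 1) stop("label_noise must be in [0, 1)")
  structure(as.list(environment()), class = "generator_config")
}

per_subject_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) + 1000003 * i) %% 2147483647)
}

#' Generate one tumor phantom
#'
#' An ellipsoidal tumor with random axes on a textured background. The
#' intra-tumor texture is a sum of Gaussian-filtered white-noise fields at two
#' scales, normalized to unit SD and scaled by the class-specific
#' heterogeneity amplitude; intensities are clipped to `[-200, 300]` HU. The
#' mask is the ellipsoid support.
#'
#' @param config A `generator_config`.
#' @param true_class TME class in 1..4 (selects the texture amplitude).
#' @param seed Optional seed; if `NULL` the current RNG state is used.
#' @return List with `volume` and `mask` (`image_volume`s) and `meta`
#'   (center, radii, base intensity).
#' @export
generate_phantom <- function(config, true_class, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!true_class %in% 1:4) stop("true_class must be in 1..4")
  if (any(config$volume_shape < 32)) stop("volume_shape must be >= 32 voxels per axis")
  if (!is.null(seed)) set.seed(seed)
  d <- config$volume_shape
  nz <- d[1]; ny <- d[2]; nx <- d[3]

  # ellipsoid geometry (voxel units)
  rz <- stats::runif(1, 3.5, min(8, nz / 2 - 2))
  ry <- stats::runif(1, 8, min(18, ny / 2 - 2))
  rx <- stats::runif(1, 8, min(18, nx / 2 - 2))
  if (min(rz, ry, rx) < 3)
    stop("degenerate phantom shape: ellipsoid axis below 3 voxels")
  cz <- nz / 2 + stats::runif(1, -0.1, 0.1) * nz
  cy <- ny / 2 + stats::runif(1, -0.1, 0.1) * ny
  cx <- nx / 2 + stats::runif(1, -0.1, 0.1) * nx
  az <- ((seq_len(nz) - cz) / rz)^2
  ay <- ((seq_len(ny) - cy) / ry)^2
  ax <- ((seq_len(nx) - cx) / rx)^2
  mask <- outer(outer(az, ay, "+"), ax, "+") <= 1

  # textured background
  bg <- -100 + 15 * scale_field(
    smooth_noise_field(d, sigma_zyx(config, config$texture_sigma[1])))

  # intra-tumor multi-scale texture
  amp <- config$heterogeneity_scale[true_class]
  base_t <- stats::runif(1, -10, 30)   # centered in the HU window to limit clipping
  if (amp > 0) {
    f1 <- smooth_noise_field(d, sigma_zyx(config, config$texture_sigma[1]))
    f2 <- smooth_noise_field(d, sigma_zyx(config, config$texture_sigma[2]))
    tex <- scale_field(f1 + f2)
    tumor <- base_t + amp * tex
  } else {
    tumor <- array(base_t, d)
  }

  vox <- bg
  vox[mask] <- tumor[mask]
  vox <- pmin(pmax(vox, -200), 300)
  list(volume = image_volume(vox, config$voxel_spacing),
       mask = image_volume(mask + 0, config$voxel_spacing),
       meta = list(center = c(cz, cy, cx), radii = c(rz, ry, rx),
                   base_intensity = base_t))
}

# texture sigma per axis: isotropic in mm, specified in in-plane voxels
sigma_zyx <- function(config, sigma_inplane) {
  sp <- config$voxel_spacing
  c(sigma_inplane * sp[2] / sp[1], sigma_inplane, sigma_inplane)
}

scale_field <- function(f) {
  s <- stats::sd(f)
  if (s == 0) f else (f - mean(f)) / s
}

#' Sample an IHC panel consistent with a TME class
#'
#' Draws marker densities and POSTN grades so that the recomputed IS_GC and
#' POSTN scores fall on the quadrant side matching `true_class` (with
#' probability `1 - label_noise`; under noise the panel is drawn for a random
#' other class). Scores are kept at least a small margin away from the
#' thresholds so that label closure is exact at zero noise.
#'
#' @param true_class TME class in 1..4.
#' @param thresholds List with `is_gc` and `postn` target medians.
#' @param label_noise Probability of drawing the panel for another class.
#' @param seed Optional seed.
#' @return List with `ihc` (density list), `postn_intensity`, `postn_extent`,
#'   `is_gc`, `postn_score`, `effective_class`.
#' @export
sample_ihc_panel <- function(true_class, thresholds = list(is_gc = 1.5, postn = 4),
                             label_noise = 0, seed = NULL) {
  if (!true_class %in% 1:4) stop("true_class must be in 1..4")
  if (!is.null(seed)) set.seed(seed)
  eff <- true_class
  if (label_noise > 0 && stats::runif(1) < label_noise)
    eff <- sample(setdiff(1:4, true_class), 1L)
  hi_is <- eff %in% c(1L, 2L)
  hi_po <- eff %in% c(2L, 4L)

  # IS_GC: draw four densities, then solve the remaining marker exactly so the
  # score lands a margin away from the threshold on the requested side
  t_is <- thresholds$is_gc
  offset <- stats::runif(1, 0.1, 1.5)
  s_target <- if (hi_is) t_is + offset else t_is - offset
  cd3_ct <- stats::runif(1, 0, 30)
  cd8_im <- stats::runif(1, 0, 30)
  cd45ro_ct <- stats::runif(1, 0, 30)
  cd66b_im <- stats::runif(1, 0, 20)
  rest <- 0.021 * cd3_ct + 0.044 * cd8_im + 0.096 * cd45ro_ct - 0.173 * cd66b_im
  cd3_im <- (s_target - rest) / 0.149
  if (cd3_im < 0) {
    cd3_im <- 0
    rest_pos <- 0.021 * cd3_ct + 0.044 * cd8_im + 0.096 * cd45ro_ct
    cd66b_im <- (rest_pos - s_target) / 0.173
  }
  ihc <- list(cd3_im = cd3_im, cd3_ct = cd3_ct, cd8_im = cd8_im,
              cd45ro_ct = cd45ro_ct, cd66b_im = cd66b_im)

  # POSTN: side-dependent grade distributions, rejection-sampled to keep the
  # field-averaged score a margin away from the threshold
  t_po <- thresholds$postn
  for (try in 1:100) {
    if (hi_po) {
      int5 <- sample(1:3, 5, replace = TRUE, prob = c(0.15, 0.45, 0.40))
      ext5 <- sample(0:4, 5, replace = TRUE, prob = c(0.05, 0.10, 0.20, 0.30, 0.35))
    } else {
      int5 <- sample(0:3, 5, replace = TRUE, prob = c(0.40, 0.40, 0.15, 0.05))
      ext5 <- sample(0:4, 5, replace = TRUE, prob = c(0.30, 0.35, 0.20, 0.10, 0.05))
    }
    sc <- mean(int5 * ext5)
    if ((hi_po && sc >= t_po + 0.1) || (!hi_po && sc <= t_po - 0.1)) break
    if (try == 100) { # force the side (practically unreachable)
      if (hi_po) { int5 <- rep(3L, 5); ext5 <- rep(4L, 5) }
      else { int5 <- rep(0L, 5); ext5 <- rep(0L, 5) }
      sc <- mean(int5 * ext5)
    }
  }
  list(ihc = ihc, postn_intensity = int5, postn_extent = ext5,
       is_gc = compute_is_gc(ihc), postn_score = sc, effective_class = eff)
}

#' Sample a survival record from a proportional-hazards model
#'
#' Event times are Weibull with shape `weibull_shape` (exponential by default)
#' and rate `baseline_hazard * exp(linear_predictor)`; censoring is uniform on
#' `(0, censor_window)` and independent of everything else.
#'
#' @param linear_predictor Finite numeric vector (one entry per subject).
#' @param config A `generator_config` (uses `baseline_hazard`,
#'   `weibull_shape`, `censor_window`).
#' @param seed Optional seed.
#' @return Data frame with `time` (months, in `(0, censor_window]`) and
#'   `event` (1 = event observed).
#' @export
sample_outcome <- function(linear_predictor, config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (any(!is.finite(linear_predictor))) stop("linear predictor must be finite")
  if (config$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(linear_predictor)
  e <- stats::rexp(n, 1)
  t_event <- (e / (config$baseline_hazard * exp(linear_predictor)))^(1 / config$weibull_shape)
  t_cens <- stats::runif(n, 0, config$censor_window)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Generate a full phantom cohort
#'
#' Draws per-subject TME classes, phantom volumes/masks (optional), IHC
#' panels, clinical covariates, confounded chemotherapy assignment with
#' class-dependent treatment effects, CPS values, immunotherapy response, and
#' survival outcomes. All randomness derives from per-subject seeds so the
#' manifest is bit-reproducible for a given config.
#'
#' @param config A `generator_config`.
#' @param out_dir Output directory; if non-`NULL`, NIfTI volumes/masks and a
#'   `manifest.csv` are written (the manifest last, so an interrupted run
#'   leaves no manifest).
#' @param generate_images Generate phantom volumes (needed for the imaging
#'   pipeline; can be disabled for statistics-only cohorts).
#' @param keep_volumes Return volumes/masks in memory as attribute `"volumes"`.
#' @return The cohort table (one row per subject).
#' @export
generate_cohort <- function(config, out_dir = NULL,
                            generate_images = !is.null(out_dir),
                            keep_volumes = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_subjects
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  }
  vols <- if (keep_volumes) vector("list", n) else NULL
  rows <- vector("list", n)
  cps_cat_levels <- c("low", "intermediate", "high")

  for (i in seq_len(n)) {
    set.seed(per_subject_seed(config$seed, i))
    cls <- sample.int(4L, 1L, prob = config$class_mixture)
    panel <- sample_ihc_panel(cls, config$ihc_thresholds, config$label_noise)

    # clinical covariates (independent of class except a weak stage coupling)
    age <- round(pmin(pmax(stats::rnorm(1, 60, 10), 25), 90))
    sex <- sample(c("F", "M"), 1L)
    p_iii <- stats::plogis(config$stage_class_cor * (cls - 2.5))
    stage <- if (stats::runif(1) < p_iii) "III" else "II"
    t_stage <- if (stage == "III") sample(2:4, 1L, prob = c(0.2, 0.4, 0.4)) else
      sample(1:3, 1L, prob = c(0.3, 0.5, 0.2))
    n_stage <- if (stage == "III") sample(1:3, 1L, prob = c(0.3, 0.4, 0.3)) else
      sample(0:2, 1L, prob = c(0.5, 0.35, 0.15))
    m_stage <- stats::rbinom(1, 1, 0.05)
    size_cm <- exp(stats::rnorm(1, log(4), 0.4))
    cea <- exp(stats::rnorm(1, log(3), 0.8))
    ca19_9 <- exp(stats::rnorm(1, log(15), 1))
    location <- sample(c("cardia", "body", "antrum"), 1L)
    differentiation <- sample(c("well", "moderate", "poor"), 1L,
                              prob = c(0.2, 0.45, 0.35))
    lauren <- sample(c("intestinal", "diffuse", "mixed"), 1L,
                     prob = c(0.5, 0.35, 0.15))

    # confounded treatment assignment, then class-dependent treatment effect
    p_chemo <- stats::plogis(-0.1 + 0.6 * (stage == "III") - 0.015 * (age - 60))
    chemo <- as.integer(stats::runif(1) < p_chemo)
    lp <- config$log_hr_per_class[cls] +
      chemo * config$chemo_log_hr_per_class[cls] +
      config$stage_log_hr * (stage == "III")
    surv <- sample_outcome(lp, config)

    # CPS and immunotherapy response
    cat_i <- sample.int(3L, 1L, prob = config$cps_mixture$probs)
    cps <- stats::runif(1, config$cps_mixture$ranges[cat_i, 1],
                        config$cps_mixture$ranges[cat_i, 2])
    rc <- config$response_logit_coefs
    logit <- rc$intercept + rc$class[cls] + rc$cps_category[cat_i]
    response <- as.integer(stats::runif(1) < stats::plogis(logit))
    best_response <- if (response == 1L) {
      sample(c("CR", "PR"), 1L, prob = c(0.2, 0.8))
    } else sample(c("SD", "PD"), 1L, prob = c(0.4, 0.6))
    pfs <- sample_outcome(0.5 * config$log_hr_per_class[cls] - 1.0 * response, config)

    vol_path <- mask_path <- NA_character_
    if (generate_images) {
      ph <- generate_phantom(config, cls)
      if (!is.null(out_dir)) {
        vol_path <- file.path(out_dir, "volumes", sprintf("subj%04d_ct.nii.gz", i))
        mask_path <- file.path(out_dir, "volumes", sprintf("subj%04d_mask.nii.gz", i))
        write_volume_nifti(ph$volume, vol_path)
        write_volume_nifti(ph$mask, mask_path)
      }
      if (keep_volumes) vols[[i]] <- ph
    }

    rows[[i]] <- data.frame(
      subject_id = sprintf("subj%04d", i), true_class = cls,
      volume_path = vol_path, mask_path = mask_path,
      cd3_im = panel$ihc$cd3_im, cd3_ct = panel$ihc$cd3_ct,
      cd8_im = panel$ihc$cd8_im, cd45ro_ct = panel$ihc$cd45ro_ct,
      cd66b_im = panel$ihc$cd66b_im,
      postn_intensity_1 = panel$postn_intensity[1],
      postn_intensity_2 = panel$postn_intensity[2],
      postn_intensity_3 = panel$postn_intensity[3],
      postn_intensity_4 = panel$postn_intensity[4],
      postn_intensity_5 = panel$postn_intensity[5],
      postn_extent_1 = panel$postn_extent[1],
      postn_extent_2 = panel$postn_extent[2],
      postn_extent_3 = panel$postn_extent[3],
      postn_extent_4 = panel$postn_extent[4],
      postn_extent_5 = panel$postn_extent[5],
      is_gc = panel$is_gc, postn_score = panel$postn_score,
      age = age, sex = sex, stage = stage, t_stage = t_stage,
      n_stage = n_stage, m_stage = m_stage, size_cm = size_cm,
      cea = cea, ca19_9 = ca19_9, location = location,
      differentiation = differentiation, lauren = lauren,
      chemo = chemo, time = surv$time, event = surv$event,
      cps = cps, cps_category = cps_cat_levels[cat_i],
      response = response, best_response = best_response,
      pfs_time = pfs$time, pfs_event = pfs$event,
      stringsAsFactors = FALSE)
  }

  cohort <- if (n == 0) empty_cohort() else do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(cohort, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  if (keep_volumes) attr(cohort, "volumes") <- vols
  attr(cohort, "config") <- config
  cohort
}

empty_cohort <- function() {
  data.frame(subject_id = character(0), true_class = integer(0),
             time = numeric(0), event = integer(0))
}
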