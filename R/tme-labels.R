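# Ground-truth TME classes from IHC: ImmunoScore (IS_GC) + periostin (POSTN),
# median dichotomization on a training cohort, 4-quadrant class assignment.

#' IS_GC coefficient vector
#'
#' Published weights of the gastric-cancer ImmunoScore, a linear combination of
#' immune-cell densities (cells per field) at the invasive margin (im) and
#' center of tumor (ct).
#'
#' @return Named numeric vector of the five marker coefficients.
#' @export
is_gc_coefficients <- function() {
  c(cd3_im = 0.149, cd3_ct = 0.021, cd8_im = 0.044,
    cd45ro_ct = 0.096, cd66b_im = -0.173)
}

#' Compute the IS_GC immune score
#'
#' Weighted sum of five IHC cell densities:
#' `0.149*CD3_im + 0.021*CD3_ct + 0.044*CD8_im + 0.096*CD45RO_ct - 0.173*CD66b_im`.
#'
#' @param panel A list or data.frame with numeric fields `cd3_im`, `cd3_ct`,
#'   `cd8_im`, `cd45ro_ct`, `cd66b_im` (non-negative densities, cells/field).
#'   A data.frame is scored row-wise.
#' @return Numeric score (vector if `panel` has multiple rows).
#' @examples
#' compute_is_gc(list(cd3_im = 1, cd3_ct = 0, cd8_im = 0, cd45ro_ct = 0, cd66b_im = 0))
#' @export
compute_is_gc <- function(panel) {
  w <- is_gc_coefficients()
  miss <- setdiff(names(w), names(panel))
  if (length(miss) > 0)
    stop("IHC panel is missing fields: ", paste(miss, collapse = ", "))
  vals <- lapply(names(w), function(nm) as.numeric(panel[[nm]]))
  m <- do.call(cbind, vals)
  if (any(!is.finite(m))) stop("IHC densities must be finite")
  if (any(m < 0)) stop("IHC densities must be non-negative")
  drop(m %*% w)
}

#' Compute the POSTN stromal score
#'
#' Periostin staining is graded in five high-power fields; per field, stain
#' intensity (0-3) is multiplied by stain extent (0-4), and the five products
#' are averaged. The score ranges 0 to 12.
#'
#' @param intensity Integer vector of length 5, grades in 0..3.
#' @param extent Integer vector of length 5, grades in 0..4.
#' @return Numeric score in `[0, 12]`.
#' @examples
#' compute_postn_score(c(0, 1, 2, 3, 1), c(4, 2, 3, 4, 4))
#' @export
compute_postn_score <- function(intensity, extent) {
  if (length(intensity) != 5L || length(extent) != 5L)
    stop("POSTN scoring requires exactly 5 fields")
  if (any(!is.finite(intensity)) || any(!is.finite(extent)))
    stop("POSTN grades must be finite")
  if (any(intensity != round(intensity)) || any(extent != round(extent)))
    stop("POSTN grades must be integers")
  if (any(intensity < 0 | intensity > 3))
    stop("stain intensity grades must be in 0..3")
  if (any(extent < 0 | extent > 4))
    stop("stain extent grades must be in 0..4")
  mean(intensity * extent)
}

#' Fit TME dichotomization thresholds on a training cohort
#'
#' Both IS_GC and POSTN are dichotomized into low vs. high at their medians in
#' the training cohort; the thresholds are then frozen and applied unchanged to
#' any validation cohort.
#'
#' @param is_gc_scores Numeric vector of training-cohort IS_GC scores (n >= 2).
#' @param postn_scores Numeric vector of training-cohort POSTN scores (n >= 2).
#' @param cohort_id Optional identifier of the source cohort.
#' @return An object of class `tme_thresholds` with fields `is_gc_median`,
#'   `postn_median`, `source_cohort_id`.
#' @export
fit_tme_thresholds <- function(is_gc_scores, postn_scores, cohort_id = NA_character_) {
  if (length(is_gc_scores) < 2L || length(postn_scores) < 2L)
    stop("threshold fitting needs at least 2 scores per marker")
  if (any(!is.finite(is_gc_scores)) || any(!is.finite(postn_scores)))
    stop("scores must be finite")
  structure(
    list(is_gc_median = stats::median(is_gc_scores),
         postn_median = stats::median(postn_scores),
         source_cohort_id = cohort_id),
    class = "tme_thresholds")
}

#' Assign 4-quadrant TME classes
#'
#' Class 1 = high IS_GC / low POSTN; class 2 = high/high; class 3 = low/low;
#' class 4 = low IS_GC / high POSTN. "High" means at or above the training
#' median (ties go to high, a fixed convention since the published rule does
#' not state tie handling).
#'
#' @param is_gc Numeric vector of IS_GC scores.
#' @param postn Numeric vector of POSTN scores.
#' @param thresholds A `tme_thresholds` object from [fit_tme_thresholds()].
#' @return Integer vector of class labels in 1..4.
#' @export
assign_tme_class <- function(is_gc, postn, thresholds) {
  stopifnot(inherits(thresholds, "tme_thresholds"))
  if (length(is_gc) != length(postn)) stop("score vectors must have equal length")
  hi_is <- is_gc >= thresholds$is_gc_median
  hi_po <- postn >= thresholds$postn_median
  cls <- ifelse(hi_is & !hi_po, 1L,
         ifelse(hi_is & hi_po, 2L,
         ifelse(!hi_is & !hi_po, 3L, 4L)))
  as.integer(cls)
}

#' Score and classify an IHC cohort table
#'
#' Convenience wrapper: takes one row per subject with IHC densities and the
#' ten POSTN grade columns, computes both scores, and (optionally) assigns TME
#' classes with supplied or freshly fitted thresholds.
#'
#' @param df Data frame with columns `cd3_im, cd3_ct, cd8_im, cd45ro_ct,
#'   cd66b_im`, `postn_intensity_1..5`, `postn_extent_1..5`.
#' @param thresholds Optional `tme_thresholds`; if `NULL`, thresholds are fit
#'   on `df` itself (training-cohort use).
#' @return `df` with added columns `is_gc`, `postn_score`, `tme_class`, plus an
#'   attribute `"thresholds"`.
#' @export
label_tme_cohort <- function(df, thresholds = NULL) {
  df$is_gc <- compute_is_gc(df)
  df$postn_score <- vapply(seq_len(nrow(df)), function(i) {
    compute_postn_score(
      as.numeric(df[i, paste0("postn_intensity_", 1:5)]),
      as.numeric(df[i, paste0("postn_extent_", 1:5)]))
  }, numeric(1))
  if (is.null(thresholds))
    thresholds <- fit_tme_thresholds(df$is_gc, df$postn_score, "self")
  df$tme_class <- assign_tme_class(df$is_gc, df$postn_score, thresholds)
  attr(df, "thresholds") <- thresholds
  df
}

#' Persist / load TME thresholds as JSON
#' @param thresholds A `tme_thresholds` object.
#' @param path File path.
#' @return `path` (write) or a `tme_thresholds` object (read).
#' @export
write_tme_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "tme_thresholds"))
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tme_thresholds
#' @export
read_tme_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("is_gc_median", "postn_median", "source_cohort_id")],
            class = "tme_thresholds")
}
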