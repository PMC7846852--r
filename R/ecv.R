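#' Extracellular volume fraction from paired T1 and hematocrit
#'
#' ECV = (1 - hct) * (1/T1_myo_post - 1/T1_myo_pre) /
#'                   (1/T1_blood_post - 1/T1_blood_pre).
#'
#' T1 is in ms throughout; the relaxation-rate ratio cancels the unit, so
#' any common scaling of the four T1 values leaves ECV unchanged. A
#' non-positive blood rate change is an acquisition failure and errors; a
#' negative myocardial rate change returns a flagged negative ECV (with a
#' warning) rather than clipping, surfacing the problem to the caller.
#'
#' @param t1_myo_pre,t1_myo_post native / post-contrast myocardial T1 (ms).
#' @param t1_blood_pre,t1_blood_post native / post-contrast blood T1 (ms).
#' @param hematocrit fraction in (0, 1] (1 is the degenerate no-plasma case).
#' @return ECV as a fraction.
#' @export
compute_ecv <- function(t1_myo_pre, t1_myo_post, t1_blood_pre, t1_blood_post,
                        hematocrit) {
  stopifnot(all(c(t1_myo_pre, t1_myo_post, t1_blood_pre, t1_blood_post) > 0),
            hematocrit > 0, hematocrit <= 1)
  dr1_blood <- 1 / t1_blood_post - 1 / t1_blood_pre
  if (dr1_blood <= 0)
    stop("invalid blood kinetics: post-contrast blood T1 must be shorter than native")
  dr1_myo <- 1 / t1_myo_post - 1 / t1_myo_pre
  if (dr1_myo < 0)
    warning("negative myocardial delta-R1: returning flagged negative ECV")
  (1 - hematocrit) * dr1_myo / dr1_blood
}

#' Post-contrast myocardial T1 implied by a target ECV
#'
#' Closed-form inverse of [compute_ecv] in its \code{t1_myo_post} argument:
#' \code{1/T1_post = 1/T1_pre + ECV/(1 - hct) * deltaR1_blood}. Used by the
#' phantom to plant an exact ground-truth ECV.
#'
#' @param target_ecv desired ECV, in \code{(0, 1 - hematocrit]}.
#' @inheritParams compute_ecv
#' @return post-contrast myocardial T1 in ms.
#' @export
derive_post_t1_myo <- function(target_ecv, hematocrit, t1_myo_pre,
                               t1_blood_pre, t1_blood_post) {
  stopifnot(hematocrit > 0, hematocrit < 1,
            target_ecv > 0, target_ecv <= 1 - hematocrit,
            t1_myo_pre > 0, t1_blood_pre > 0, t1_blood_post > 0)
  dr1_blood <- 1 / t1_blood_post - 1 / t1_blood_pre
  if (dr1_blood <= 0) stop("invalid blood kinetics")
  r1_post <- 1 / t1_myo_pre + target_ecv / (1 - hematocrit) * dr1_blood
  if (r1_post <= 0) stop("parameters imply non-positive post-contrast R1")
  1 / r1_post
}

#' Feasibility of an RV ECV measurement
#'
#' A measurement is feasible when image quality permits distinguishing
#' myocardium from blood (quality grade 1-2), the maximum wall thickness
#' per ROI is at least one pixel (wall grade 1-2), and both the native and
#' the post-contrast map exist.
#'
#' @param quality_grade image-quality grade 1-3 (3 = major artifacts or
#'   insufficient blood/myocardium contrast).
#' @param wall_grade wall-thickness grade 1-3 (3 = thinner than 1 pixel).
#' @param maps_present logical: both native and post maps available.
#' @return list (class \code{feasibility_verdict}) with \code{measurable}
#'   and \code{reasons} (subset of \code{insufficient_contrast},
#'   \code{wall_below_1px}, \code{missing_map}).
#' @export
assess_feasibility <- function(quality_grade, wall_grade, maps_present = TRUE) {
  stopifnot(quality_grade %in% 1:3, wall_grade %in% 1:3)
  reasons <- character(0)
  if (quality_grade > 2) reasons <- c(reasons, "insufficient_contrast")
  if (wall_grade > 2) reasons <- c(reasons, "wall_below_1px")
  if (!isTRUE(maps_present)) reasons <- c(reasons, "missing_map")
  structure(list(measurable = length(reasons) == 0L, reasons = reasons),
            class = "feasibility_verdict")
}

#' @export
print.feasibility_verdict <- function(x, ...) {
  if (x$measurable) cat("measurable\n")
  else cat("not measurable:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Per-subject ECV table
#'
#' Assembles one row per subject x structure x method x orientation from
#' paired native/post maps and the subject's geometry: myocardial T1 from
#' the method's sampler (ROI contour or LOI centerline), blood T1 from the
#' blood-pool ROI, ECV via [compute_ecv]. Subjects whose feasibility
#' verdict fails (quality or wall grade 3, missing map) contribute no row;
#' exclusions are logged in \code{attr(table, "exclusions")}. A missing
#' hematocrit likewise skips the subject with a logged reason.
#'
#' @param subjects list of subject bundles; each bundle is a list with
#'   \code{subject_id}, \code{hematocrit}, \code{quality_grade}
#'   (native-map grade, 1-3), \code{maps} (list \code{native}, \code{post}
#'   of [t1_map]), \code{geometry} ([geometry_set]), and optionally
#'   \code{wall_mask} (supersampled RV mask) + \code{supersample_factor}
#'   for wall grading; without a mask the native map is thresholded at the
#'   blood/myocardium midpoint T1.
#' @param length_weighted passed to [loi_stats].
#' @return data.frame of class \code{ecv_table}; columns subject_id,
#'   structure, method, orientation, the four T1 means, hct, ecv, wall
#'   grade and feasibility.
#' @export
subject_ecv_table <- function(subjects, length_weighted = FALSE) {
  rows <- list()
  excl <- list()
  for (s in subjects) {
    sid <- s$subject_id
    if (is.null(s$hematocrit) || !is.finite(s$hematocrit)) {
      excl[[length(excl) + 1L]] <- data.frame(subject_id = sid,
                                              reason = "missing_hematocrit")
      next
    }
    maps_ok <- !is.null(s$maps$native) && !is.null(s$maps$post)
    if (!maps_ok) {
      excl[[length(excl) + 1L]] <- data.frame(subject_id = sid,
                                              reason = "missing_map")
      next
    }
    geo <- s$geometry
    blood_nm <- names(geo$tissue)[geo$tissue == "blood_pool" &
                                  names(geo$tissue) %in% names(geo$rois)][1]
    if (is.na(blood_nm)) {
      excl[[length(excl) + 1L]] <- data.frame(subject_id = sid,
                                              reason = "missing_blood_roi")
      next
    }
    bl_pre <- roi_stats(s$maps$native, geo$rois[[blood_nm]])
    bl_post <- roi_stats(s$maps$post, geo$rois[[blood_nm]])
    qg <- if (is.null(s$quality_grade)) 1L else s$quality_grade

    for (structure_ in c("RV", "LV")) {
      tag <- paste0(structure_, "_myocardium")
      items <- names(geo$tissue)[geo$tissue == tag]
      rois <- items[items %in% names(geo$rois)]
      lois <- items[items %in% names(geo$lois)]
      if (!length(rois)) next
      # wall grading is evaluated on the method-defining ROI region (RV only)
      wg <- 1L
      if (structure_ == "RV") {
        region <- rasterize_polygon(geo$rois[[rois[1]]], dim(s$maps$native$values))
        wg <- .subject_wall_grade(s, region, bl_pre$mean_t1)
      }
      verdict <- assess_feasibility(qg, wg, maps_ok)
      if (!verdict$measurable) {
        if (structure_ == "RV")
          excl[[length(excl) + 1L]] <-
            data.frame(subject_id = sid,
                       reason = paste(verdict$reasons, collapse = "+"))
        next
      }
      for (method in c("ROI", "LOI")) {
        nm <- if (method == "ROI") rois[1] else lois[1]
        if (method == "LOI" && !length(lois)) next
        sampler <- function(map) {
          if (method == "ROI") roi_stats(map, geo$rois[[nm]])
          else loi_stats(map, geo$lois[[nm]], length_weighted = length_weighted)
        }
        my_pre <- sampler(s$maps$native)
        my_post <- sampler(s$maps$post)
        ecv <- compute_ecv(my_pre$mean_t1, my_post$mean_t1,
                           bl_pre$mean_t1, bl_post$mean_t1, s$hematocrit)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, structure = structure_, method = method,
          orientation = s$maps$native$orientation,
          t1_myo_pre = my_pre$mean_t1, t1_myo_post = my_post$mean_t1,
          t1_blood_pre = bl_pre$mean_t1, t1_blood_post = bl_post$mean_t1,
          hct = s$hematocrit, ecv = ecv,
          wall_grade = wg, quality_grade = qg, measurable = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), structure = character(0),
               method = character(0), orientation = character(0),
               t1_myo_pre = numeric(0), t1_myo_post = numeric(0),
               t1_blood_pre = numeric(0), t1_blood_post = numeric(0),
               hct = numeric(0), ecv = numeric(0), wall_grade = integer(0),
               quality_grade = integer(0), measurable = logical(0))
  attr(tab, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(0), reason = character(0))
  class(tab) <- c("ecv_table", class(tab))
  tab
}

.subject_wall_grade <- function(s, region, t1_blood) {
  if (!is.null(s$wall_mask)) {
    g <- max_wall_thickness_px(s$wall_mask, region, s$supersample_factor)
    return(g$grade)
  }
  # automated fallback: threshold the native map at the blood/myocardium
  # midpoint and upsample the pixel mask (the reading protocol graded
  # thickness visually; this automation is the package's addition)
  map <- s$maps$native
  t1_myo <- stats::median(map$values[cbind(region[, 1] + 1L, region[, 2] + 1L)],
                          na.rm = TRUE)
  mid <- (t1_myo + t1_blood) / 2
  lohi <- sort(c(t1_myo - abs(t1_blood - t1_myo) / 2, mid))
  m <- map$values >= lohi[1] & map$values <= lohi[2] & is.finite(map$values)
  f <- 4L
  big <- m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f)]
  max_wall_thickness_px(big * 1, region, f)$grade
}

#' Cohort summary of an ECV table (mean +/- SD per cell)
#'
#' Averages per-subject ECV (never the ECV of averaged T1s: the mean of
#' per-subject ratios differs from the ratio of means, so cohort cells are
#' built subject-first).
#'
#' @param tab an \code{ecv_table} from [subject_ecv_table].
#' @return data.frame: structure, method, orientation, n, mean/SD of each
#'   T1 column and of ECV.
#' @export
ecv_cohort_summary <- function(tab) {
  key <- interaction(tab$structure, tab$method, tab$orientation, drop = TRUE)
  out <- lapply(split(tab, key), function(g) {
    data.frame(structure = g$structure[1], method = g$method[1],
               orientation = g$orientation[1], n = nrow(g),
               t1_myo_pre_mean = mean(g$t1_myo_pre), t1_myo_pre_sd = stats::sd(g$t1_myo_pre),
               t1_myo_post_mean = mean(g$t1_myo_post), t1_myo_post_sd = stats::sd(g$t1_myo_post),
               ecv_mean = mean(g$ecv), ecv_sd = stats::sd(g$ecv))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
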