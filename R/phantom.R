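#' Specification of a synthetic midventricular short-axis phantom
#'
#' Describes a slice with an LV annulus plus blood pool and a thin
#' crescent-shaped RV free wall of configurable thickness, with tissue T1
#' values typical of 1.5 T myocardium and blood. The RV wall is a
#' concentric annular sector of constant width (so the planted wall
#' thickness is exact); the RV cavity blood fills the gap between the LV
#' epicardium and the RV wall. The post-contrast myocardial T1 is not a
#' free parameter: it is derived from the target ECV via
#' [derive_post_t1_myo], so ground truth is exact by construction.
#'
#' Default tissue values are representative patient means at 1.5 T:
#' native myocardium 1018 ms, native blood 1492 ms, post-contrast blood
#' 531 ms, hematocrit 0.43, target RV ECV 0.31.
#'
#' @param grid (rows, cols), default 192 x 192.
#' @param pixel_spacing mm, default (1.9, 1.9).
#' @param lv_center pixel coordinates of the LV center (continuous,
#'   (row, col)); default grid center.
#' @param lv_cavity_radius_px,lv_wall_thickness_px LV blood-pool radius and
#'   wall width, pixels.
#' @param rv_offset_px (row, col) offset of the RV arc center from
#'   \code{lv_center}.
#' @param rv_mid_radius_px radius of the RV mid-wall arc, pixels.
#' @param rv_wall_thickness_px RV free-wall thickness, pixels (0.25-4).
#' @param rv_angles_deg angular extent (start, end) of the RV sector,
#'   degrees, measured as atan2(row, col) about the RV arc center.
#' @param t1_native_myo,t1_native_blood,t1_post_blood tissue T1 values, ms.
#' @param t1_background background ("remote tissue") T1, ms.
#' @param hematocrit fraction.
#' @param target_ecv_rv,target_ecv_lv planted ground-truth ECVs.
#' @param noise_sd MOLLI signal noise SD (signal units; 0 = noiseless).
#' @param supersample_factor subpixels per pixel per axis (>= 4).
#' @param seed integer seed for all randomness.
#' @param partial_volume_mode \code{"r1_domain"} (area-weighted average of
#'   subpixel R1, then invert — closed form) or \code{"signal_domain"}
#'   (average subpixel MOLLI signals within a pixel, then fit T1).
#' @return \code{phantom_spec} object.
#' @export
phantom_spec <- function(grid = c(192, 192), pixel_spacing = c(1.9, 1.9),
                         lv_center = grid / 2,
                         lv_cavity_radius_px = 11, lv_wall_thickness_px = 5,
                         rv_offset_px = c(0, 0), rv_mid_radius_px = 21,
                         rv_wall_thickness_px = 2,
                         rv_angles_deg = c(200, 340),
                         t1_native_myo = 1018, t1_native_blood = 1492,
                         t1_post_blood = 531, t1_background = 300,
                         hematocrit = 0.43,
                         target_ecv_rv = 0.31, target_ecv_lv = 0.30,
                         noise_sd = 0, supersample_factor = 4L, seed = 1L,
                         partial_volume_mode = c("r1_domain", "signal_domain")) {
  partial_volume_mode <- match.arg(partial_volume_mode)
  stopifnot(rv_wall_thickness_px >= 0.25, rv_wall_thickness_px <= 4,
            supersample_factor >= 4L,
            target_ecv_rv > 0, target_ecv_rv < 1 - hematocrit,
            target_ecv_lv > 0, target_ecv_lv < 1 - hematocrit,
            hematocrit > 0, hematocrit < 1)
  lv_outer <- lv_cavity_radius_px + lv_wall_thickness_px
  rv_inner <- rv_mid_radius_px - rv_wall_thickness_px / 2
  if (rv_inner <= lv_outer + sqrt(sum(rv_offset_px^2)))
    stop("RV wall would overlap the LV: increase rv_mid_radius_px")
  rv_outer_extent <- rv_mid_radius_px + rv_wall_thickness_px / 2 +
    sqrt(sum(rv_offset_px^2))
  if (any(lv_center - rv_outer_extent < 1) ||
      any(lv_center + rv_outer_extent > grid - 1))
    stop("phantom geometry does not fit in the grid")
  structure(list(grid = as.integer(grid), pixel_spacing = pixel_spacing,
                 lv_center = lv_center,
                 lv_cavity_radius_px = lv_cavity_radius_px,
                 lv_wall_thickness_px = lv_wall_thickness_px,
                 rv_offset_px = rv_offset_px,
                 rv_mid_radius_px = rv_mid_radius_px,
                 rv_wall_thickness_px = rv_wall_thickness_px,
                 rv_angles_deg = rv_angles_deg,
                 t1_native_myo = t1_native_myo,
                 t1_native_blood = t1_native_blood,
                 t1_post_blood = t1_post_blood,
                 t1_background = t1_background,
                 hematocrit = hematocrit,
                 target_ecv_rv = target_ecv_rv, target_ecv_lv = target_ecv_lv,
                 noise_sd = noise_sd,
                 supersample_factor = as.integer(supersample_factor),
                 seed = as.integer(seed),
                 partial_volume_mode = partial_volume_mode),
            class = "phantom_spec")
}

# tissue labels on the supersampled grid
.PH_BG <- 0L; .PH_LV_MYO <- 1L; .PH_RV_MYO <- 2L; .PH_BLOOD <- 3L

.phantom_labels <- function(spec) {
  f <- spec$supersample_factor
  nr <- spec$grid[1] * f; nc <- spec$grid[2] * f
  # subpixel centers in map-pixel units
  rr <- ((seq_len(nr) - 0.5) / f)
  cc <- ((seq_len(nc) - 0.5) / f)
  R <- matrix(rr, nr, nc) - spec$lv_center[1]
  C <- matrix(cc, nr, nc, byrow = TRUE) - spec$lv_center[2]
  d_lv <- sqrt(R^2 + C^2)
  lv_outer <- spec$lv_cavity_radius_px + spec$lv_wall_thickness_px
  Rr <- R - spec$rv_offset_px[1]
  Cr <- C - spec$rv_offset_px[2]
  d_rv <- sqrt(Rr^2 + Cr^2)
  ang <- atan2(Rr, Cr) * 180 / pi
  a0 <- spec$rv_angles_deg[1]; a1 <- spec$rv_angles_deg[2]
  rel <- (ang - a0) %% 360
  span <- (a1 - a0) %% 360
  in_sector <- rel <= span
  rv_in <- spec$rv_mid_radius_px - spec$rv_wall_thickness_px / 2
  rv_out <- spec$rv_mid_radius_px + spec$rv_wall_thickness_px / 2
  lab <- matrix(.PH_BG, nr, nc)
  lab[d_lv < spec$lv_cavity_radius_px] <- .PH_BLOOD
  lab[d_lv >= spec$lv_cavity_radius_px & d_lv < lv_outer] <- .PH_LV_MYO
  lab[in_sector & d_lv >= lv_outer & d_rv < rv_in] <- .PH_BLOOD  # RV cavity
  lab[in_sector & d_rv >= rv_in & d_rv < rv_out] <- .PH_RV_MYO
  lab
}

# average f x f blocks of a matrix
.block_mean <- function(M, f) {
  R <- nrow(M) / f; C <- ncol(M) / f
  M1 <- matrix(colSums(matrix(M, nrow = f)), nrow = R)     # R x (f*C)
  t(matrix(colSums(matrix(t(M1), nrow = f)), nrow = C)) / f^2
}

#' Render a synthetic phantom into native/post T1 maps with ground truth
#'
#' Tissue regions are rendered at \code{supersample_factor} resolution;
#' per-pixel T1 follows the selected partial-volume mode. With
#' \code{noise_sd > 0} the pixel is always formed through the MOLLI signal
#' path (mixture signal + noise, then a per-pixel fit), since noise lives
#' in the signal domain.
#'
#' The returned geometry set contains the RV mid-wall centerline LOI
#' (>= 10 mm), an RV ROI hugging the wall (inset \code{min(0.75, t/4)}
#' pixels per side), an LV lateral-wall ROI and mid-wall LOI, and a
#' blood-pool ROI in the LV cavity.
#'
#' @param spec a [phantom_spec].
#' @return list of class \code{phantom_render}: \code{native}, \code{post}
#'   ([t1_map]s), \code{truth} (masks at supersampled resolution,
#'   centerline, true T1s/ECVs/wall thickness), \code{geometry}
#'   ([geometry_set]).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- spec$supersample_factor
  lab <- .phantom_labels(spec)
  t1_post_myo_rv <- derive_post_t1_myo(spec$target_ecv_rv, spec$hematocrit,
                                       spec$t1_native_myo,
                                       spec$t1_native_blood, spec$t1_post_blood)
  t1_post_myo_lv <- derive_post_t1_myo(spec$target_ecv_lv, spec$hematocrit,
                                       spec$t1_native_myo,
                                       spec$t1_native_blood, spec$t1_post_blood)
  # T1 per label (index label + 1): background, LV myo, RV myo, blood
  t1_tab <- list(
    native = c(spec$t1_background, spec$t1_native_myo, spec$t1_native_myo,
               spec$t1_native_blood),
    post = c(spec$t1_background * 0.9, t1_post_myo_lv, t1_post_myo_rv,
             spec$t1_post_blood))
  frac <- lapply(0:3, function(l) .block_mean((lab == l) * 1, f))

  make_map <- function(phase) {
    t1s <- t1_tab[[phase]]
    if (spec$noise_sd == 0 && spec$partial_volume_mode == "r1_domain") {
      r1 <- Reduce(`+`, lapply(1:4, function(i) frac[[i]] / t1s[i]))
      v <- 1 / r1
    } else {
      sim <- .phantom_signal_fit(frac, t1s, spec, phase)
      v <- sim
    }
    t1_map(pmin(v, 5000), pixel_spacing = spec$pixel_spacing, phase = phase,
           orientation = "SAX", subject_id = sprintf("phantom-%d", spec$seed),
           acquisition_delay_min = if (phase == "post") 15 else NA_real_)
  }
  native <- make_map("native")
  post <- make_map("post")

  geometry <- .phantom_geometry(spec)
  truth <- structure(list(
    rv_mask = lab == .PH_RV_MYO, lv_mask = lab == .PH_LV_MYO,
    blood_mask = lab == .PH_BLOOD,
    centerline = geometry$lois[["rv_loi"]],
    wall_thickness_px = spec$rv_wall_thickness_px,
    ecv_rv = spec$target_ecv_rv, ecv_lv = spec$target_ecv_lv,
    t1 = list(native_myo = spec$t1_native_myo,
              native_blood = spec$t1_native_blood,
              post_myo_rv = t1_post_myo_rv, post_myo_lv = t1_post_myo_lv,
              post_blood = spec$t1_post_blood),
    hematocrit = spec$hematocrit,
    supersample_factor = f), class = "phantom_truth")
  structure(list(native = native, post = post, truth = truth,
                 geometry = geometry, spec = spec),
            class = "phantom_render")
}

# pixel formation through the MOLLI signal path. Partial-volume mixing
# happens in the mode the spec selects: signal_domain mixes the subpixel
# tissue signals within the pixel; r1_domain mixes R1 first and simulates
# a single-compartment signal from the mixed T1. Noise is always added in
# the signal domain, then T1 is fitted per pixel.
.phantom_signal_fit <- function(frac, t1s, spec, phase) {
  scheme <- molli_scheme()
  tis <- molli_tis(scheme)
  A <- 1; B <- 1.95
  t1star <- t1s / (B / A - 1)
  dims <- dim(frac[[1]])
  stack <- array(0, c(dims, length(tis)))
  if (spec$partial_volume_mode == "r1_domain") {
    r1 <- Reduce(`+`, lapply(1:4, function(i) frac[[i]] / t1s[i]))
    t1star_mix <- (1 / r1) / (B / A - 1)
    for (k in seq_along(tis))
      stack[, , k] <- A - B * exp(-tis[k] / t1star_mix)
  } else {
    for (k in seq_along(tis)) {
      sk <- matrix(0, dims[1], dims[2])
      for (i in 1:4)
        sk <- sk + frac[[i]] * (A - B * exp(-tis[k] / t1star[i]))
      stack[, , k] <- sk
    }
  }
  if (spec$noise_sd > 0) {
    seed_k <- spec$seed * 2L + (phase == "post")
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed_k)
    stack <- stack + array(stats::rnorm(length(stack), 0, spec$noise_sd),
                           dim(stack))
  }
  fit <- fit_t1_molli(stack, tis)
  v <- fit$t1
  v[!is.finite(v) | v < 0] <- NaN
  v
}

# auto-generated operator geometry for a phantom
.phantom_geometry <- function(spec) {
  ctr_rv <- spec$lv_center + spec$rv_offset_px
  a0 <- spec$rv_angles_deg[1]; a1 <- spec$rv_angles_deg[2]
  span <- (a1 - a0) %% 360
  arc <- function(center, radius, deg0, deg1, step_px = 0.25) {
    n <- max(2L, ceiling(radius * abs(deg1 - deg0) * pi / 180 / step_px) + 1L)
    th <- seq(deg0, deg1, length.out = n) * pi / 180
    cbind(center[1] + radius * sin(th), center[2] + radius * cos(th))
  }
  inset_deg <- 5
  loi_rv <- polyline_loi(arc(ctr_rv, spec$rv_mid_radius_px,
                             a0 + inset_deg, a0 + span - inset_deg))
  t <- spec$rv_wall_thickness_px
  inset <- min(0.75, t / 4)
  r_in <- spec$rv_mid_radius_px - t / 2 + inset
  r_out <- spec$rv_mid_radius_px + t / 2 - inset
  outer_arc <- arc(ctr_rv, r_out, a0 + inset_deg, a0 + span - inset_deg, 0.5)
  inner_arc <- arc(ctr_rv, r_in, a0 + span - inset_deg, a0 + inset_deg, 0.5)
  roi_rv <- polygon_roi(rbind(outer_arc, inner_arc))
  # LV lateral wall: the half of the annulus opposite the RV sector
  lv_mid <- spec$lv_cavity_radius_px + spec$lv_wall_thickness_px / 2
  lv0 <- (a0 + span / 2 + 180 - 80) ; lv1 <- lv0 + 160
  loi_lv <- polyline_loi(arc(spec$lv_center, lv_mid, lv0, lv1))
  lv_in <- spec$lv_cavity_radius_px + 1
  lv_out <- spec$lv_cavity_radius_px + spec$lv_wall_thickness_px - 1
  roi_lv <- polygon_roi(rbind(arc(spec$lv_center, lv_out, lv0, lv1, 0.5),
                              arc(spec$lv_center, lv_in, lv1, lv0, 0.5)))
  th_b <- seq(0, 2 * pi, length.out = 25L)[-25L]
  rb <- max(2, spec$lv_cavity_radius_px - 2)
  roi_blood <- polygon_roi(cbind(spec$lv_center[1] + rb * sin(th_b),
                                 spec$lv_center[2] + rb * cos(th_b)))
  geometry_set(
    rois = list(rv_roi = roi_rv, lv_roi = roi_lv, blood_roi = roi_blood),
    lois = list(rv_loi = loi_rv, lv_loi = loi_lv),
    tissue = c(rv_roi = "RV_myocardium", lv_roi = "LV_myocardium",
               blood_roi = "blood_pool",
               rv_loi = "RV_myocardium", lv_loi = "LV_myocardium"))
}

#' Generate a reproducible synthetic cohort
#'
#' Stands in for a patient study: per-subject ground-truth RV ECV is drawn
#' from a normal distribution (default mean 0.31, SD 0.05 — representative
#' patient-level values) truncated to (0.15, 0.55); hematocrit around
#' 0.43 +/- 0.05 truncated to (0.20, 0.60); native myocardial and blood T1
#' and post-contrast blood T1 drawn around 1018 +/- 30, 1492 +/- 88 and
#' 531 +/- 73 ms; wall thickness uniform over \code{wall_thickness_range}.
#' Everything is seed-deterministic.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param ecv_mean,ecv_sd,ecv_bounds RV ECV draw parameters.
#' @param wall_thickness_range (min, max) wall thickness in pixels.
#' @param noise_sd MOLLI signal noise SD per subject.
#' @param grid phantom grid used for each subject.
#' @param supersample_factor subpixels per pixel.
#' @param seed master seed.
#' @return list of subject bundles as consumed by [subject_ecv_table]:
#'   each has \code{subject_id}, \code{hematocrit}, \code{quality_grade},
#'   \code{maps}, \code{geometry}, \code{wall_mask},
#'   \code{supersample_factor} and \code{truth}.
#' @export
cohort_generator <- function(n_subjects, ecv_mean = 0.31, ecv_sd = 0.05,
                             ecv_bounds = c(0.15, 0.55),
                             wall_thickness_range = c(1, 3),
                             noise_sd = 0.02, grid = c(128, 128),
                             supersample_factor = 4L, seed = 1L) {
  par <- cohort_parameters(n_subjects, ecv_mean = ecv_mean, ecv_sd = ecv_sd,
                           ecv_bounds = ecv_bounds,
                           wall_thickness_range = wall_thickness_range,
                           seed = seed)
  lapply(seq_len(n_subjects), function(i) {
    spec <- phantom_spec(grid = grid, rv_wall_thickness_px = par$wall_px[i],
                         t1_native_myo = par$t1_native_myo[i],
                         t1_native_blood = par$t1_native_blood[i],
                         t1_post_blood = par$t1_post_blood[i],
                         hematocrit = par$hct[i],
                         target_ecv_rv = par$ecv_rv[i],
                         target_ecv_lv = par$ecv_lv[i],
                         noise_sd = noise_sd,
                         supersample_factor = supersample_factor,
                         seed = par$subject_seed[i])
    ph <- render_phantom(spec)
    list(subject_id = par$subject_id[i], hematocrit = par$hct[i],
         quality_grade = 1L,
         maps = list(native = ph$native, post = ph$post),
         geometry = ph$geometry,
         wall_mask = ph$truth$rv_mask * 1,
         supersample_factor = supersample_factor,
         truth = ph$truth)
  })
}

#' Draw the per-subject parameters of a synthetic cohort
#'
#' The sampling stage of [cohort_generator], exposed so the drawn
#' distributions can be examined without rendering any images. All draws
#' are truncated normals (redraw on violation) except wall thickness
#' (uniform); hematocrit is additionally redrawn where the drawn ECV would
#' reach the plasma fraction \code{1 - hct}.
#'
#' @inheritParams cohort_generator
#' @return data.frame: subject_id, ecv_rv, ecv_lv, hct, t1_native_myo,
#'   t1_native_blood, t1_post_blood, wall_px, subject_seed.
#' @export
cohort_parameters <- function(n_subjects, ecv_mean = 0.31, ecv_sd = 0.05,
                              ecv_bounds = c(0.15, 0.55),
                              wall_thickness_range = c(1, 3), seed = 1L) {
  stopifnot(n_subjects >= 1)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  draw_trunc <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= lo | x >= hi))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  ecv <- draw_trunc(n_subjects, ecv_mean, ecv_sd, ecv_bounds[1], ecv_bounds[2])
  hct <- draw_trunc(n_subjects, 0.43, 0.05, 0.20, 0.60)
  # physiological consistency: ECV must stay below the plasma fraction
  while (any(bad <- ecv >= 1 - hct - 0.03))
    hct[bad] <- draw_trunc(sum(bad), 0.43, 0.05, 0.20, 0.60)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    ecv_rv = ecv,
    ecv_lv = pmin(ecv, 1 - hct - 0.03) * 0.95,
    hct = hct,
    t1_native_myo = draw_trunc(n_subjects, 1018, 30, 800, 1300),
    t1_native_blood = draw_trunc(n_subjects, 1492, 88, 1200, 1900),
    t1_post_blood = draw_trunc(n_subjects, 531, 73, 300, 800),
    wall_px = stats::runif(n_subjects, wall_thickness_range[1],
                           wall_thickness_range[2]),
    subject_seed = sample.int(2^30, n_subjects),
    stringsAsFactors = FALSE)
}
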