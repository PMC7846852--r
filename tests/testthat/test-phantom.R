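test_that("noiseless pure-tissue pixels carry the planted tissue T1", {
  for (mode in c("r1_domain", "signal_domain")) {
    spec <- phantom_spec(grid = c(64, 64), rv_wall_thickness_px = 3,
                         supersample_factor = 8, partial_volume_mode = mode)
    ph <- render_phantom(spec)
    # interior LV-cavity pixel: pure blood
    ctr <- round(spec$lv_center)
    expect_lte(abs(ph$native$values[ctr[1], ctr[2]] - spec$t1_native_blood), 0.5)
    expect_lte(abs(ph$post$values[ctr[1], ctr[2]] - spec$t1_post_blood), 0.5)
    # mid-wall RV pixel found from the truth fractions: fully myocardial
    f <- spec$supersample_factor
    frac_rv <- rvecv:::.block_mean(ph$truth$rv_mask * 1, f)
    pure <- which(frac_rv == 1, arr.ind = TRUE)[1, ]
    expect_lte(abs(ph$native$values[pure[1], pure[2]] - spec$t1_native_myo), 0.5)
    expect_lte(abs(ph$post$values[pure[1], pure[2]] - ph$truth$t1$post_myo_rv), 0.5)
  }
})

test_that("r1-domain mixing is the area-weighted R1 average, analytically", {
  spec <- phantom_spec(grid = c(64, 64), rv_wall_thickness_px = 2,
                       supersample_factor = 8)
  ph <- render_phantom(spec)
  f <- spec$supersample_factor
  lab <- rvecv:::.phantom_labels(spec)
  fr <- lapply(0:3, function(l) rvecv:::.block_mean((lab == l) * 1, f))
  t1s <- c(spec$t1_background, spec$t1_native_myo, spec$t1_native_myo,
           spec$t1_native_blood)
  expected <- 1 / Reduce(`+`, lapply(1:4, function(i) fr[[i]] / t1s[i]))
  expect_equal(ph$native$values, pmin(expected, 5000), tolerance = 1e-12)
  # a genuinely mixed myocardium/blood pixel sits between the tissue T1s
  mixed <- which(fr[[3]] > 0.3 & fr[[3]] < 0.7 & fr[[4]] > 0.3, arr.ind = TRUE)[1, ]
  v <- ph$native$values[mixed[1], mixed[2]]
  expect_gt(v, spec$t1_native_myo)
  expect_lt(v, spec$t1_native_blood)
})

test_that("signal-domain mixing differs from r1-domain on boundary pixels only", {
  spec_r1 <- phantom_spec(grid = c(64, 64), rv_wall_thickness_px = 1.5,
                          supersample_factor = 8)
  spec_sig <- phantom_spec(grid = c(64, 64), rv_wall_thickness_px = 1.5,
                           supersample_factor = 8,
                           partial_volume_mode = "signal_domain")
  m_r1 <- render_phantom(spec_r1)$native$values
  m_sig <- render_phantom(spec_sig)$native$values
  f <- 8
  lab <- rvecv:::.phantom_labels(spec_r1)
  fr_blood <- rvecv:::.block_mean((lab == 3) * 1, f)
  fr_myo <- rvecv:::.block_mean((lab == 2) * 1, f)
  pure <- fr_myo == 1 | fr_blood == 1
  mixed <- fr_myo > 0.25 & fr_myo < 0.75 & fr_blood > 0.25
  expect_lt(max(abs(m_r1[pure] - m_sig[pure])), 1)   # agree on pure tissue
  expect_gt(max(abs(m_r1[mixed] - m_sig[mixed])), 5) # modes genuinely differ
  # and the signal-domain blend still lies between the two tissue T1s
  expect_true(all(m_sig[mixed] > spec_r1$t1_native_myo - 1 &
                  m_sig[mixed] < spec_r1$t1_native_blood + 1))
})

test_that("MOLLI simulation honors the signal model and the seed contract", {
  sch <- molli_scheme()
  expect_equal(molli_tis(sch),
               sort(c(120 + 0:2 * 1000, 200 + 0:2 * 1000, 280 + 0:4 * 1000)))
  g <- matrix(1000, 8, 8)
  sim <- simulate_molli(g, sch, A = 1, B = 2, noise_sd = 0)
  t1star <- 1000 / (2 / 1 - 1)
  # long-TI limit approaches A
  expect_lt(abs(sim$stack[1, 1, 11] - (1 - 2 * exp(-sim$tis[11] / t1star))), 1e-12)
  long <- simulate_molli(g, molli_scheme(groups = 1, pause_beats = integer(0),
                                         base_tis_ms = 10000), A = 1, B = 2)
  expect_lt(abs(long$stack[1, 1, 1] - 1), 1e-4)
  # zero crossing at TI = T1* log(B/A)
  tis0 <- t1star * log(2)
  s0 <- 1 - 2 * exp(-tis0 / t1star)
  expect_equal(s0, 0)
  # seed determinism
  a <- simulate_molli(g, sch, noise_sd = 0.05, seed = 7)
  b <- simulate_molli(g, sch, noise_sd = 0.05, seed = 7)
  expect_identical(a$stack, b$stack)
  c_ <- simulate_molli(g, sch, noise_sd = 0.05, seed = 8)
  expect_false(identical(a$stack, c_$stack))
})

test_that("Look-Locker fit recovers noiseless T1 within 1 percent", {
  t1_true <- matrix(seq(200, 1500, length.out = 64), 8, 8)
  sim <- simulate_molli(t1_true, molli_scheme(), A = 1, B = 1.95)
  fit <- fit_t1_molli(sim$stack, sim$tis)
  expect_lt(max(abs(fit$t1 - t1_true) / t1_true), 0.01)
  # A = 1, B = 2 makes the correction factor exactly 1, so T1 = T1*
  sim2 <- simulate_molli(matrix(1000, 8, 8), molli_scheme(), A = 1, B = 2)
  fit2 <- fit_t1_molli(sim2$stack, sim2$tis)
  expect_equal(mean(fit2$t1), mean(fit2$t1star), tolerance = 1e-3)
  expect_lt(max(abs(fit2$t1 - 1000)), 1)
  expect_error(fit_t1_molli(sim$stack[, , 1:2, drop = FALSE], sim$tis[1:2]),
               "at least 3")
})

test_that("misregistration is applied and recovered exactly without noise", {
  spec <- phantom_spec(grid = c(64, 64), rv_wall_thickness_px = 2,
                       supersample_factor = 4)
  t1_grid <- render_phantom(spec)$native$values
  sim <- simulate_molli(t1_grid, molli_scheme())
  shifts <- matrix(0L, 11, 2)
  shifts[3, ] <- c(2L, -1L)
  shifts[7, ] <- c(-5L, 4L)
  # zero shift is the identity
  expect_identical(apply_misregistration(sim$stack, matrix(0L, 11, 2)),
                   sim$stack)
  moved <- apply_misregistration(sim$stack, shifts)
  fixed <- estimate_and_correct_misregistration(moved, max_shift_px = 5)
  expect_equal(fixed$shifts, shifts)
  ok <- is.finite(fixed$stack) & is.finite(sim$stack)
  expect_equal(fixed$stack[ok], sim$stack[ok])
})

test_that("shift recovery survives moderate noise in almost all trials", {
  spec <- phantom_spec(grid = c(48, 48), rv_mid_radius_px = 15,
                       lv_cavity_radius_px = 7, lv_wall_thickness_px = 4,
                       rv_wall_thickness_px = 2, supersample_factor = 4)
  t1_grid <- render_phantom(spec)$native$values
  n_ok <- 0L; n_trials <- 40L
  for (k in seq_len(n_trials)) {
    sim <- simulate_molli(t1_grid, molli_scheme(), noise_sd = 0.02, seed = k)
    set.seed(k)
    shifts <- matrix(sample(-3:3, 22, replace = TRUE), 11, 2)
    shifts[11, ] <- 0L                      # reference frame stays put
    moved <- apply_misregistration(sim$stack, shifts)
    est <- estimate_and_correct_misregistration(moved, max_shift_px = 4)
    if (all(est$shifts == shifts)) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_trials, 0.95)
})

test_that("cohort draws are reproducible and respect their bounds", {
  a <- cohort_parameters(500, seed = 21)
  b <- cohort_parameters(500, seed = 21)
  expect_identical(a, b)
  expect_true(all(a$ecv_rv > 0.15 & a$ecv_rv < 0.55))
  expect_true(all(a$hct > 0.20 & a$hct < 0.60))
  expect_true(all(a$ecv_rv < 1 - a$hct))
  expect_true(all(a$wall_px >= 1 & a$wall_px <= 3))
  # empirical ECV mean within 3 standard errors of the target 0.31
  se <- 0.05 / sqrt(500)
  expect_lt(abs(mean(a$ecv_rv) - 0.31), 3 * se)
  # rendered subjects inherit the drawn parameters deterministically
  c1 <- cohort_generator(2, noise_sd = 0, grid = c(96, 96), seed = 5)
  c2 <- cohort_generator(2, noise_sd = 0, grid = c(96, 96), seed = 5)
  expect_identical(c1[[1]]$maps$native$values, c2[[1]]$maps$native$values)
  expect_identical(c1[[2]]$hematocrit, c2[[2]]$hematocrit)
})

test_that("partial voluming biases thin-wall ECV toward the blood value", {
  walls <- c(0.5, 0.75, 1.5, 3)
  ecvs <- vapply(walls, function(w) {
    ph <- render_phantom(phantom_spec(grid = c(64, 64),
                                      rv_wall_thickness_px = w,
                                      supersample_factor = 8))
    rvecv:::.measure_rv_ecv(ph, "LOI")
  }, 0)
  target <- 0.31
  expect_lt(abs(ecvs[4] - target), 0.005)        # thick wall: accurate
  expect_gt(ecvs[1], ecvs[3])                     # thinner -> more bias
  expect_gt(ecvs[1], target + 0.02)               # biased upward, toward 1-hct
  expect_lt(ecvs[1], 1 - 0.43)                    # but below the blood limit
})
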