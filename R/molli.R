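#' MOLLI acquisition scheme
#'
#' Describes a Modified Look-Locker Inversion recovery scheme in the
#' "3b(3b)3b(3b)5b" shorthand: groups of readout heartbeats per inversion,
#' pause heartbeats between groups, one base inversion time per inversion,
#' and the RR interval. The k-th readout of an inversion train samples
#' \code{TI = base_TI + (k-1) * RR}.
#'
#' @param groups readout counts per inversion, default \code{c(3, 3, 5)}.
#' @param pause_beats pauses between groups, default \code{c(3, 3)}.
#' @param base_tis_ms base TI per inversion (ms), default 120/200/280.
#' @param rr_ms RR interval (ms), default 1000.
#' @return \code{molli_scheme} object.
#' @export
molli_scheme <- function(groups = c(3, 3, 5), pause_beats = c(3, 3),
                         base_tis_ms = c(120, 200, 280), rr_ms = 1000) {
  stopifnot(all(groups >= 1), length(base_tis_ms) == length(groups),
            length(pause_beats) == length(groups) - 1L, rr_ms > 0)
  structure(list(groups = as.integer(groups),
                 pause_beats = as.integer(pause_beats),
                 base_tis_ms = as.numeric(base_tis_ms),
                 rr_ms = as.numeric(rr_ms)),
            class = "molli_scheme")
}

#' Inversion times of a MOLLI scheme, merged and sorted
#'
#' @param scheme a [molli_scheme].
#' @param sorted return the merged TI list in ascending order (the order
#'   the fit consumes) rather than acquisition order.
#' @return numeric vector of TIs in ms.
#' @export
molli_tis <- function(scheme, sorted = TRUE) {
  tis <- unlist(lapply(seq_along(scheme$groups), function(j)
    scheme$base_tis_ms[j] + (seq_len(scheme$groups[j]) - 1L) * scheme$rr_ms))
  if (sorted) sort(tis) else tis
}

#' Simulate a MOLLI image stack from a true-T1 grid
#'
#' Phase-sensitive (signed) inversion-recovery signal
#' \code{S(TI) = A - B * exp(-TI / T1*)} per pixel, with the apparent
#' relaxation time \code{T1* = T1 / (B/A - 1)} so that Look-Locker
#' correction recovers the generating T1 exactly. Additive Gaussian noise
#' of the given SD (signal units) is applied per sample, reproducibly per
#' seed.
#'
#' @param true_t1_grid matrix of generating T1 values (ms), positive.
#' @param scheme a [molli_scheme].
#' @param A,B signal-model parameters (A the recovered plateau, B the
#'   inversion amplitude; B/A > 1).
#' @param noise_sd additive Gaussian noise SD in signal units.
#' @param seed integer seed for the noise stream.
#' @return list: \code{stack} (rows x cols x nTI array), \code{tis} (ms,
#'   ascending), \code{scheme}, \code{A}, \code{B}.
#' @export
simulate_molli <- function(true_t1_grid, scheme = molli_scheme(),
                           A = 1, B = 1.95, noise_sd = 0, seed = 1L) {
  stopifnot(is.matrix(true_t1_grid), all(true_t1_grid > 0), B / A > 1)
  tis <- molli_tis(scheme)
  t1star <- true_t1_grid / (B / A - 1)
  stack <- array(NA_real_, c(dim(true_t1_grid), length(tis)))
  for (k in seq_along(tis))
    stack[, , k] <- A - B * exp(-tis[k] / t1star)
  if (noise_sd > 0) {
    old <- .save_seed()
    on.exit(.restore_seed(old))
    set.seed(seed)
    stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd), dim(stack))
  }
  list(stack = stack, tis = tis, scheme = scheme, A = A, B = B)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Fit T1 per pixel from a MOLLI stack (3-parameter + Look-Locker)
#'
#' Least-squares fit of \code{S(TI) = A - B exp(-TI/T1*)} per pixel by
#' variable projection: for a candidate T1* the optimal (A, B) are linear,
#' so T1* is found by a log-spaced grid search followed by a vectorized
#' golden-section refinement of the profiled residual. The corrected
#' \code{T1 = T1* (B/A - 1)} is returned; pixels with a non-physical fit
#' (A <= 0, B/A <= 1) or fewer than 3 finite samples come back NaN.
#'
#' @param stack rows x cols x nTI array of signed signals (NaN allowed,
#'   e.g. from misregistration edge fill).
#' @param tis inversion times (ms), one per slice of \code{stack}.
#' @param t1star_range search range for the apparent T1* (ms).
#' @param n_grid coarse grid size.
#' @return list: \code{t1} (matrix, ms), \code{t1star}, \code{A}, \code{B}.
#' @export
fit_t1_molli <- function(stack, tis, t1star_range = c(30, 5000),
                         n_grid = 48L) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] == length(tis))
  if (length(tis) < 3L) stop("MOLLI fit needs at least 3 inversion times")
  if (anyDuplicated(tis)) stop("inversion times must be distinct")
  dims <- dim(stack)
  npix <- dims[1] * dims[2]
  S <- matrix(aperm(stack, c(3, 1, 2)), nrow = dims[3])  # nTI x npix
  W <- is.finite(S) * 1
  S0 <- ifelse(W > 0, S, 0)
  nobs <- colSums(W)
  fit_at <- function(t1star_vec) {
    # per-pixel profiled SSE and linear parameters at given T1* values
    E <- exp(-outer(tis, 1 / t1star_vec))          # nTI x npix
    Ew <- E * W
    sx <- colSums(Ew); sxx <- colSums(Ew * E)
    sy <- colSums(S0); sxy <- colSums(S0 * E)
    det <- nobs * sxx - sx^2
    A <- (sy * sxx - sx * sxy) / det
    Bn <- (sy * sx - nobs * sxy) / det            # = B
    sse <- colSums(S0 * S) - A * sy + Bn * sxy
    list(A = A, B = Bn, sse = sse)
  }
  grid <- exp(seq(log(t1star_range[1]), log(t1star_range[2]),
                  length.out = n_grid))
  sse_grid <- matrix(NA_real_, n_grid, npix)
  for (g in seq_len(n_grid))
    sse_grid[g, ] <- fit_at(rep(grid[g], npix))$sse
  best <- max.col(-t(sse_grid), ties.method = "first")
  lo <- log(grid[pmax(best - 1L, 1L)])
  hi <- log(grid[pmin(best + 1L, n_grid)])
  gr <- (sqrt(5) - 1) / 2
  for (it in 1:45) {
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- fit_at(exp(x1))$sse; f2 <- fit_at(exp(x2))$sse
    move_lo <- f1 > f2        # minimum lies in [x1, hi]
    lo <- ifelse(move_lo, x1, lo)
    hi <- ifelse(move_lo, hi, x2)
  }
  t1star <- exp((lo + hi) / 2)
  final <- fit_at(t1star)
  t1 <- t1star * (final$B / final$A - 1)
  bad <- !is.finite(t1) | final$A <= 0 | final$B / final$A <= 1 | nobs < 3
  t1[bad] <- NaN
  list(t1 = matrix(t1, dims[1], dims[2]),
       t1star = matrix(t1star, dims[1], dims[2]),
       A = matrix(final$A, dims[1], dims[2]),
       B = matrix(final$B, dims[1], dims[2]))
}

#' Apply inter-frame misregistration to a MOLLI stack
#'
#' Translates each frame by an integer (row, col) shift, filling exposed
#' edges with NaN — emulating the frame-to-frame body motion that T1-map
#' reconstruction tools let the operator undo by displacing individual
#' TI-sorted images in x or y.
#'
#' @param stack rows x cols x nTI array.
#' @param shifts nTI x 2 integer matrix of (row, col) shifts per frame.
#' @return shifted stack.
#' @export
apply_misregistration <- function(stack, shifts) {
  dims <- dim(stack)
  shifts <- matrix(as.integer(round(shifts)), ncol = 2L)
  stopifnot(nrow(shifts) == dims[3],
            all(abs(shifts) <= floor(min(dims[1:2]) / 4)))
  out <- array(NaN, dims)
  for (k in seq_len(dims[3])) {
    dr <- shifts[k, 1]; dc <- shifts[k, 2]
    src_r <- seq_len(dims[1]) - dr
    src_c <- seq_len(dims[2]) - dc
    ok_r <- src_r >= 1L & src_r <= dims[1]
    ok_c <- src_c >= 1L & src_c <= dims[2]
    out[which(ok_r), which(ok_c), k] <- stack[src_r[ok_r], src_c[ok_c], k]
  }
  out
}

#' Estimate and undo inter-frame misregistration
#'
#' Per-frame integer shift estimated by maximizing the absolute normalized
#' cross-correlation of magnitude images against the last-TI frame
#' (magnitude, because early-TI frames are sign-flipped around the signal
#' null). Exact recovery in the noiseless case; ties broken toward the
#' smallest shift.
#'
#' @param stack rows x cols x nTI array (possibly shifted).
#' @param max_shift_px search radius in pixels.
#' @return list: \code{stack} (aligned), \code{shifts} (estimated nTI x 2,
#'   the shifts that were applied; the inverse is used to realign).
#' @export
estimate_and_correct_misregistration <- function(stack, max_shift_px = 5L) {
  dims <- dim(stack)
  nf <- dims[3]
  ref <- abs(stack[, , nf])
  cand <- as.matrix(expand.grid(dr = -max_shift_px:max_shift_px,
                                dc = -max_shift_px:max_shift_px))
  cand <- cand[order(abs(cand[, 1]) + abs(cand[, 2])), , drop = FALSE]
  shifts <- matrix(0L, nf, 2L)
  for (k in seq_len(nf)) {
    img <- abs(stack[, , k])
    best <- -Inf; best_sh <- c(0L, 0L)
    for (j in seq_len(nrow(cand))) {
      dr <- cand[j, 1]; dc <- cand[j, 2]
      r_img <- max(1, 1 + dr):min(dims[1], dims[1] + dr)
      c_img <- max(1, 1 + dc):min(dims[2], dims[2] + dc)
      a <- img[r_img, c_img]
      b <- ref[r_img - dr, c_img - dc]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 16L) next
      av <- a[ok]; bv <- b[ok]
      if (stats::sd(av) == 0 || stats::sd(bv) == 0) next
      r <- abs(stats::cor(av, bv))
      if (r > best + 1e-12) { best <- r; best_sh <- c(dr, dc) }
    }
    shifts[k, ] <- best_sh
  }
  list(stack = apply_misregistration(stack, -shifts), shifts = shifts)
}
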