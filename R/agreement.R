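#' Correlation between paired measurements
#'
#' Product-moment (Pearson) or rank (Spearman) correlation with a
#' two-sided p-value from the t transform
#' \code{t = r sqrt((n-2)/(1-r^2))} on n-2 degrees of freedom. Non-finite
#' pairs are dropped; zero variance in either vector is an error.
#'
#' @param x,y paired numeric vectors.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return list: \code{r}, \code{p}, \code{n}, \code{method}.
#' @export
ecv_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("correlation needs at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n, method = method)
}

#' Bland-Altman agreement between two methods
#'
#' Differences are taken as \code{d = x - y} (first method minus second;
#' the order is explicit in the output). Bias is the mean difference,
#' \code{sd_diff} the sample SD of the differences, limits of agreement
#' \code{bias +/- 1.96 sd_diff}, and the 95 percent CI of the bias uses
#' the t distribution on n-1 df.
#'
#' @param x,y paired measurements (method 1, method 2).
#' @param names optional length-2 method labels.
#' @return object of class \code{ecv_agreement}: \code{n_pairs},
#'   \code{bias}, \code{sd_diff}, \code{loa_low}, \code{loa_high},
#'   \code{ci_bias_low}, \code{ci_bias_high}, \code{pearson_r},
#'   \code{spearman_rho}, \code{p_pearson}, \code{methods},
#'   \code{differences}, \code{means}.
#' @export
bland_altman <- function(x, y, names = c("method1", "method2")) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("Bland-Altman needs at least 3 finite pairs")
  d <- x - y
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  half <- 1.96 * sd_diff
  ci_half <- stats::qt(0.975, df = n - 1) * sd_diff / sqrt(n)
  cors <- tryCatch(list(
    pe = ecv_correlation(x, y, "pearson"),
    sp = ecv_correlation(x, y, "spearman")),
    error = function(e) list(pe = list(r = NA_real_, p = NA_real_),
                             sp = list(r = NA_real_)))
  structure(list(n_pairs = n, bias = bias, sd_diff = sd_diff,
                 loa_low = bias - half, loa_high = bias + half,
                 ci_bias_low = bias - ci_half, ci_bias_high = bias + ci_half,
                 pearson_r = cors$pe$r, p_pearson = cors$pe$p,
                 spearman_rho = cors$sp$r,
                 methods = names, differences = d, means = (x + y) / 2),
            class = "ecv_agreement")
}

#' @export
print.ecv_agreement <- function(x, digits = 4, ...) {
  cat(sprintf("Bland-Altman: %s - %s (n = %d)\n",
              x$methods[1], x$methods[2], x$n_pairs))
  cat(sprintf("  bias %s (SD %s), 95%% CI [%s, %s]\n",
              signif(x$bias, digits), signif(x$sd_diff, digits),
              signif(x$ci_bias_low, digits), signif(x$ci_bias_high, digits)))
  cat(sprintf("  limits of agreement [%s, %s]\n",
              signif(x$loa_low, digits), signif(x$loa_high, digits)))
  if (is.finite(x$pearson_r))
    cat(sprintf("  Pearson r = %s (p = %.3g)\n",
                signif(x$pearson_r, digits), x$p_pearson))
  invisible(x)
}

#' @export
plot.ecv_agreement <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = paste0("mean of ", x$methods[1], " and ", x$methods[2]),
                 ylab = paste(x$methods[1], "-", x$methods[2]),
                 main = "Bland-Altman", pch = 19, ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Intra- and inter-observer variability table
#'
#' Compares a first rater's repeated readings (intra-observer) and the
#' first vs second rater (inter-observer) for each quantity column, in the
#' usual reading-study layout: one row per comparison x quantity with mean
#' difference (SD), 95 percent CI of the bias, limits of agreement and
#' Pearson r. Subjects present in one table but not the other are excluded
#' and logged in \code{attr(result, "excluded")}.
#'
#' @param rater1_t1,rater1_t2,rater2 data.frames with a \code{subject_id}
#'   column plus one column per quantity (e.g. \code{rv_ecv_roi},
#'   \code{rv_ecv_loi}, \code{lv_ecv}).
#' @param quantities quantity columns to compare; default: all shared
#'   non-id columns.
#' @return data.frame: comparison, quantity, n, bias, sd_diff, ci, LoA, r, p.
#' @export
observer_variability <- function(rater1_t1, rater1_t2, rater2,
                                 quantities = NULL) {
  tabs <- list(rater1_t1 = rater1_t1, rater1_t2 = rater1_t2, rater2 = rater2)
  for (t in tabs) stopifnot("subject_id" %in% names(t))
  if (is.null(quantities))
    quantities <- setdiff(Reduce(intersect, lapply(tabs, names)), "subject_id")
  pairs <- list(intraobserver = c("rater1_t1", "rater1_t2"),
                interobserver = c("rater1_t1", "rater2"))
  rows <- list(); excluded <- list()
  for (cmp in names(pairs)) {
    a <- tabs[[pairs[[cmp]][1]]]; b <- tabs[[pairs[[cmp]][2]]]
    common <- intersect(a$subject_id, b$subject_id)
    dropped <- setdiff(union(a$subject_id, b$subject_id), common)
    if (length(dropped))
      excluded[[length(excluded) + 1L]] <-
        data.frame(comparison = cmp, subject_id = dropped)
    a <- a[match(common, a$subject_id), ]
    b <- b[match(common, b$subject_id), ]
    for (q in quantities) {
      ba <- bland_altman(a[[q]], b[[q]], names = pairs[[cmp]])
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cmp, quantity = q, n = ba$n_pairs,
        bias = ba$bias, sd_diff = ba$sd_diff,
        ci_bias_low = ba$ci_bias_low, ci_bias_high = ba$ci_bias_high,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        r = ba$pearson_r, p = ba$p_pearson, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(comparison = character(0), subject_id = character(0))
  out
}
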