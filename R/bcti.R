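# Beta-content gamma-confidence tolerance intervals (BCTI) on paired score
# differences, accuracy profiles, bias detection and the +/-30% incurred
# sample reanalysis (ISR) benchmark.
#
# The BCTI of a set of paired differences is  mean +/- k * sd,  with k the
# two-sided normal-theory tolerance factor chosen so that a proportion beta
# of the difference population is contained with confidence gamma.  Plotting
# the interval per reported intensity category gives the accuracy profile:
# the interval centre exposes systematic bias between the two sides, the
# width their imprecision.

#' Paired score differences, grouped by reported category
#'
#' Computes side-B minus side-A differences for the complete pairs of a
#' paired set, on the absolute scale (score units) or the percent scale
#' (percent of the pair mean, the scale of repeat-analysis benchmarks):
#' `d = 100 (B - A) / ((A + B)/2)`, with `d = 0` when both scores are 0 —
#' two negative calls are perfect agreement, not a 0/0 indeterminate.
#' Differences are grouped by the reference category (side A's score, or
#' the rounded pair mean), plus a pooled `"all"` group.  Pairs with a
#' missing side are excluded; their count is kept in the `n_excluded`
#' attribute.
#'
#' @param paired A [pair_scores()] result.
#' @param scale `"absolute"` (score units) or `"percent"`.
#' @param group_by `"reference"` (side A's score; default) or
#'   `"pair_mean"` (rounded mean of the two scores).
#' @return An object of class `difference_sets`: named list of
#'   `difference_set` objects (`values`, `scale`, `group_label`, `n`),
#'   one per observed category plus `"all"`.
#' @export
compute_differences <- function(paired, scale = c("absolute", "percent"),
                                group_by = c("reference", "pair_mean")) {
  stopifnot(inherits(paired, "paired_scores"))
  scale <- match.arg(scale)
  group_by <- match.arg(group_by)
  a <- paired$pairs$score_A
  b <- paired$pairs$score_B
  keep <- !is.na(a) & !is.na(b)
  n_excluded <- sum(!keep)
  a <- a[keep]; b <- b[keep]
  if (!length(a))
    stop("no complete pairs to difference", call. = FALSE)

  d <- if (scale == "absolute") as.numeric(b - a) else {
    m <- (a + b) / 2
    ifelse(a == 0 & b == 0, 0, 100 * (b - a) / ifelse(m == 0, NA, m))
  }
  grp <- if (group_by == "reference") a else as.integer(round((a + b) / 2))

  make_set <- function(values, label)
    structure(list(values = as.numeric(values), scale = scale,
                   group_label = label, n = length(values)),
              class = "difference_set")
  labels <- as.character(sort(unique(grp)))
  out <- c(list(all = make_set(d, "all")),
           stats::setNames(lapply(labels, function(g)
             make_set(d[grp == as.integer(g)], g)), labels))
  structure(out, class = "difference_sets", n_excluded = n_excluded,
            group_by = group_by)
}

#' @export
print.difference_sets <- function(x, ...) {
  cat("Paired differences (", x$all$scale, " scale), groups:\n", sep = "")
  for (s in x)
    cat(sprintf("  %-4s n = %3d  mean = %8.3f  sd = %8.3f\n", s$group_label,
                s$n, mean(s$values), stats::sd(s$values)))
  if (attr(x, "n_excluded"))
    cat("  excluded (one side missing):", attr(x, "n_excluded"), "\n")
  invisible(x)
}

#' Two-sided beta-content tolerance factor
#'
#' Factor `k` such that `mean +/- k sd` of a normal sample of size `n`
#' contains at least a proportion `beta` of the population with confidence
#' `gamma`.  `method = "howe"` uses Howe's closed-form approximation
#' `k = z_{(1+beta)/2} sqrt(nu (1 + 1/n) / chisq_{1-gamma, nu})` with
#' `nu = n - 1` degrees of freedom and the lower-tail `1 - gamma`
#' chi-square quantile.  `method = "montecarlo"` calibrates `k` directly:
#' for each of `mc_samples` simulated standard-normal samples the smallest
#' factor whose interval reaches content `beta` is found by bisection, and
#' the `gamma` quantile of those factors is returned (an independent check
#' on the closed form; uses the R random number stream).
#'
#' @param n Sample size (at least 2).
#' @param beta Content proportion in (0, 1).
#' @param gamma Confidence level in (0, 1).
#' @param method `"howe"` (default) or `"montecarlo"`.
#' @param mc_samples Number of Monte-Carlo samples for the calibration.
#' @return The tolerance factor `k` (positive scalar).
#' @examples
#' tolerance_factor(30, beta = 0.95, gamma = 0.90)  # about 2.41
#' @export
tolerance_factor <- function(n, beta = 0.95, gamma = 0.90,
                             method = c("howe", "montecarlo"),
                             mc_samples = 50000L) {
  method <- match.arg(method)
  stopifnot(length(n) == 1, length(beta) == 1, length(gamma) == 1)
  if (is.na(n) || n < 2)
    stop("tolerance factor needs n >= 2 (no dispersion estimate from n < 2)",
         call. = FALSE)
  if (beta <= 0 || beta >= 1 || gamma <= 0 || gamma >= 1)
    stop("beta and gamma must lie strictly in (0, 1)", call. = FALSE)
  z <- stats::qnorm((1 + beta) / 2)
  if (method == "howe") {
    nu <- n - 1
    return(z * sqrt(nu * (1 + 1 / n) / stats::qchisq(1 - gamma, nu)))
  }
  m <- as.integer(mc_samples)
  x <- matrix(stats::rnorm(n * m), nrow = n)
  mu <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * mu^2) / (n - 1))
  # content(k) = pnorm(mu + k s) - pnorm(mu - k s) is increasing in k;
  # k = (z + |mu|)/s always reaches content >= beta, so it bounds the root.
  lo <- numeric(m)
  hi <- (z + abs(mu)) / s
  for (i in 1:70) {
    mid <- (lo + hi) / 2
    ok <- stats::pnorm(mu + mid * s) - stats::pnorm(mu - mid * s) >= beta
    hi[ok] <- mid[ok]
    lo[!ok] <- mid[!ok]
  }
  stats::quantile((lo + hi) / 2, gamma, names = FALSE)
}

#' Beta-content gamma-confidence tolerance interval
#'
#' Interval `mean(values) +/- k sd(values)` with `k` from
#' [tolerance_factor()]; the sample standard deviation uses the n - 1
#' denominator.  A zero-dispersion set yields a degenerate zero-width
#' interval at the mean, flagged rather than rejected.
#'
#' @param values Numeric vector of differences, or a `difference_set`.
#' @param beta,gamma Content and confidence levels in (0, 1).
#' @param method Passed to [tolerance_factor()].
#' @param ... Further arguments to [tolerance_factor()].
#' @return An object of class `tolerance_interval`: `center`, `sd`, `k`,
#'   `lower`, `upper`, `n`, `beta`, `gamma`, `degenerate` flag, and the
#'   group label / scale when built from a `difference_set`.
#' @export
bcti <- function(values, beta = 0.95, gamma = 0.90, method = "howe", ...) {
  group_label <- NA_character_
  scale <- NA_character_
  if (inherits(values, "difference_set")) {
    group_label <- values$group_label
    scale <- values$scale
    values <- values$values
  }
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2)
    stop("a tolerance interval needs at least 2 differences", call. = FALSE)
  center <- mean(values)
  s <- stats::sd(values)
  k <- tolerance_factor(n, beta, gamma, method = method, ...)
  structure(list(center = center, sd = s, k = k,
                 lower = center - k * s, upper = center + k * s,
                 n = n, beta = beta, gamma = gamma,
                 degenerate = s == 0,
                 group_label = group_label, scale = scale),
            class = "tolerance_interval")
}

#' @export
print.tolerance_interval <- function(x, digits = 3, ...) {
  cat(sprintf(
    "BCTI (beta = %.2f, gamma = %.2f, n = %d): [%.*f, %.*f], center %.*f, k = %.*f%s\n",
    x$beta, x$gamma, x$n, digits, x$lower, digits, x$upper,
    digits, x$center, digits, x$k,
    if (x$degenerate) " [degenerate: zero dispersion]" else ""))
  invisible(x)
}

#' Accuracy profile of paired ordinal calls
#'
#' One tolerance interval per reported intensity category and content
#' level: the machine-readable accuracy profile.  Categories with fewer
#' than two complete pairs cannot support an interval and are reported as
#' insufficient.
#'
#' @param paired A [pair_scores()] result.
#' @param betas Content levels (default `c(0.67, 0.95)`).
#' @param gamma Confidence level (default 0.90).
#' @param scale Difference scale, see [compute_differences()].
#' @param comparison `"inter-operator"` (modified ISR) or `"inter-run"`
#'   (conventional ISR); a label carried into outputs.
#' @param group_by Passed to [compute_differences()].
#' @param method Passed to [tolerance_factor()].
#' @return An object of class `accuracy_profile`: data frame `entries`
#'   with columns `group`, `beta`, `gamma`, `n`, `center`, `sd`, `k`,
#'   `lower`, `upper`, `degenerate`, `insufficient`, plus metadata fields.
#' @export
accuracy_profile <- function(paired, betas = c(0.67, 0.95), gamma = 0.90,
                             scale = c("absolute", "percent"),
                             comparison = c("inter-operator", "inter-run"),
                             group_by = "reference", method = "howe") {
  scale <- match.arg(scale)
  comparison <- match.arg(comparison)
  stopifnot(all(betas > 0 & betas < 1), length(betas) >= 1)
  diffs <- compute_differences(paired, scale = scale, group_by = group_by)
  groups <- diffs[setdiff(names(diffs), "all")]

  rows <- list()
  for (g in groups) {
    for (beta in sort(betas)) {
      if (g$n >= 2) {
        ti <- bcti(g, beta = beta, gamma = gamma, method = method)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g$group_label, beta = beta, gamma = gamma, n = g$n,
          center = ti$center, sd = ti$sd, k = ti$k,
          lower = ti$lower, upper = ti$upper,
          degenerate = ti$degenerate, insufficient = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g$group_label, beta = beta, gamma = gamma, n = g$n,
          center = NA_real_, sd = NA_real_, k = NA_real_,
          lower = NA_real_, upper = NA_real_,
          degenerate = FALSE, insufficient = TRUE)
      }
    }
  }
  entries <- do.call(rbind, rows)
  if (all(entries$insufficient))
    stop("no category has the >= 2 complete pairs needed for a profile",
         call. = FALSE)
  structure(list(entries = entries, scale = scale, comparison = comparison,
                 gamma = gamma, betas = sort(betas), group_by = group_by,
                 side_A = paired$side_A, side_B = paired$side_B,
                 n_excluded = attr(diffs, "n_excluded")),
            class = "accuracy_profile")
}

#' @export
print.accuracy_profile <- function(x, digits = 3, ...) {
  cat("Accuracy profile (", x$comparison, ", ", x$scale, " scale, ",
      x$side_A, " vs ", x$side_B, ", gamma = ", x$gamma, ")\n", sep = "")
  print(format(x$entries, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.accuracy_profile <- function(x, ...) {
  cbind(comparison = x$comparison, x$entries, scale = x$scale)
}

#' Plot an accuracy profile
#'
#' Tolerance-interval bounds (y) against reported intensity category (x),
#' one line type per content level; the interval centres trace the
#' between-side bias.
#'
#' @param x An `accuracy_profile`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.accuracy_profile <- function(x, ...) {
  e <- x$entries[!x$entries$insufficient, , drop = FALSE]
  gx <- as.numeric(factor(e$group, levels = unique(x$entries$group)))
  ylab <- if (x$scale == "percent") "difference (% of pair mean)"
          else "difference (score units)"
  graphics::plot(range(gx) + c(-0.5, 0.5), range(c(e$lower, e$upper, 0)),
                 type = "n", xaxt = "n", xlab = "reported intensity score",
                 ylab = ylab, main = paste("Accuracy profile,", x$comparison),
                 ...)
  graphics::axis(1, at = seq_along(unique(x$entries$group)),
                 labels = unique(x$entries$group))
  graphics::abline(h = 0, col = "grey60")
  for (i in seq_along(x$betas)) {
    b <- x$betas[i]
    eb <- e[e$beta == b, , drop = FALSE]
    gxb <- as.numeric(factor(eb$group, levels = unique(x$entries$group)))
    graphics::lines(gxb, eb$lower, lty = i, type = "b", pch = 4)
    graphics::lines(gxb, eb$upper, lty = i, type = "b", pch = 4)
  }
  eb <- e[e$beta == x$betas[1], , drop = FALSE]
  gxb <- as.numeric(factor(eb$group, levels = unique(x$entries$group)))
  graphics::points(gxb, eb$center, pch = 19)
  graphics::legend("topleft", bty = "n", lty = seq_along(x$betas),
                   legend = sprintf("beta = %.2f", x$betas))
  invisible(x)
}

#' Detect per-category operator bias in an accuracy profile
#'
#' A category is flagged biased when the magnitude of its interval centre
#' (the mean side-B minus side-A difference) exceeds `threshold`.  The
#' report also notes opposing-sign centre patterns across adjacent
#' categories — the signature of two readers pulling the same cells
#' towards different grades.
#'
#' @param profile An [accuracy_profile()] result.
#' @param threshold Bias threshold on the profile's difference scale
#'   (default 0.25 score units, a quarter category).
#' @return An object of class `bias_report`: data frame `by_group`
#'   (`group`, `center`, `sign`, `biased`), the `threshold`, the
#'   `opposing` pattern notes, and `any_bias`.
#' @export
detect_bias <- function(profile, threshold = 0.25) {
  stopifnot(inherits(profile, "accuracy_profile"), threshold >= 0)
  e <- profile$entries
  e <- e[e$beta == profile$betas[1] & !e$insufficient, , drop = FALSE]
  if (!nrow(e)) stop("profile has no usable categories", call. = FALSE)
  by_group <- data.frame(
    group = e$group,
    center = e$center,
    sign = sign(e$center),
    biased = abs(e$center) > threshold)
  opposing <- character(0)
  num <- suppressWarnings(as.numeric(by_group$group))
  if (!anyNA(num)) {
    ord <- order(num)
    for (i in seq_len(nrow(by_group) - 1)) {
      g1 <- ord[i]; g2 <- ord[i + 1]
      if (num[g2] - num[g1] == 1 &&
          by_group$sign[g1] * by_group$sign[g2] == -1)
        opposing <- c(opposing, sprintf(
          "opposing bias directions at categories %s (%+.3f) and %s (%+.3f)",
          by_group$group[g1], by_group$center[g1],
          by_group$group[g2], by_group$center[g2]))
    }
  }
  structure(list(by_group = by_group, threshold = threshold,
                 opposing = opposing, any_bias = any(by_group$biased),
                 comparison = profile$comparison, scale = profile$scale),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Bias report (threshold ", x$threshold, " on the ", x$scale,
      " scale)\n", sep = "")
  print(x$by_group, row.names = FALSE)
  if (length(x$opposing)) cat(" ", x$opposing, sep = "\n  ")
  if (!x$any_bias) cat("  no category exceeds the bias threshold\n")
  invisible(x)
}

#' Incurred-sample-reanalysis pass rate
#'
#' Fraction of percent-scale repeat differences within `+/- limit`,
#' judged against the conventional acceptance rule for repeat analysis of
#' quantitative biomarker assays: at least `min_fraction` (default 2/3)
#' of repeats within the +/-30 percent total-error benchmark.
#'
#' @param differences A percent-scale `difference_set` (e.g. the `"all"`
#'   group of [compute_differences()]) or a numeric vector of percent
#'   differences.
#' @param limit Acceptance limit in percent (default 30).
#' @param min_fraction Minimum passing fraction (default 2/3).
#' @return An object of class `isr_result`: `rate`, `pass`, `n`, `limit`,
#'   `min_fraction`.
#' @export
isr_pass_rate <- function(differences, limit = 30, min_fraction = 2 / 3) {
  if (inherits(differences, "difference_set")) {
    if (!is.na(differences$scale) && differences$scale != "percent")
      stop("ISR benchmark needs percent-scale differences", call. = FALSE)
    differences <- differences$values
  }
  differences <- as.numeric(differences)
  if (!length(differences))
    stop("no differences to judge against the ISR limit", call. = FALSE)
  stopifnot(limit >= 0, min_fraction >= 0, min_fraction <= 1)
  rate <- mean(abs(differences) <= limit)
  structure(list(rate = rate, pass = rate >= min_fraction,
                 n = length(differences), limit = limit,
                 min_fraction = min_fraction),
            class = "isr_result")
}

#' @export
print.isr_result <- function(x, ...) {
  cat(sprintf(
    "ISR: %.1f%% of %d repeat differences within +/-%g%% (need %.1f%%): %s\n",
    100 * x$rate, x$n, x$limit, 100 * x$min_fraction,
    if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
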