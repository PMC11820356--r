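#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`: mean difference, sample (n-1) SD, and limits
#' of agreement `mean +- 1.96 * SD`.
#'
#' @param x,y Paired measurements (equal length, at least 3).
#' @return A list of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the per-pair `means`/`diffs` for
#'   plotting.
#' @examples
#' ba <- bland_altman(c(4.5, 5, 5.5), c(4.4, 5.1, 5.4))
#' ba$mean_diff
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = length(d), means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n=%d): mean diff %.3f, LoA [%.3f, %.3f]\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x A [bland_altman()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "Mean of methods",
                 ylab = "Difference", ...)
  graphics::abline(h = c(x$loa_low, x$mean_diff, x$loa_high),
                   lty = c(2, 1, 2))
  invisible(x)
}

#' Descriptive summary row (population-SD convention)
#'
#' @param values Numeric vector, length at least 1.
#' @return A list with `mean` and `sd` (population, divide-by-n).
#' @export
descriptive_row <- function(values) {
  if (!length(values)) stop("empty value sequence")
  m <- mean(values)
  list(mean = m, sd = sqrt(mean((values - m)^2)))
}

# Exact distribution of the positive signed-rank sum W+ for given
# (possibly tied, doubled-to-integer) ranks, by the shift algorithm.
# Equivalent to full enumeration of all 2^n sign assignments.
signed_rank_distribution <- function(ranks2) {
  total <- sum(ranks2)
  p <- numeric(total + 1)
  p[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), p[seq_len(total + 1 - r)])
    p <- (p + shifted) / 2
  }
  p   # p[w+1] = P(2*W+ = w)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (classical treatment); tied absolute
#' differences receive mid-ranks. The null distribution is exact (full
#' enumeration over sign assignments, computed by the shift algorithm)
#' for up to `exact_max` effective pairs, and a normal approximation with
#' tie correction beyond that. The reported statistic is
#' `W = min(W+, W-)`.
#'
#' @param x,y Paired measurements of equal length.
#' @param alternative `"two.sided"` (default), `"greater"` (x > y) or
#'   `"less"`.
#' @param exact_max Largest `n_effective` for the exact distribution,
#'   default 25.
#' @return A list of class `paired_test`: `statistic` (W), `w_plus`,
#'   `p_value`, `n_effective`, `method` (`"exact"` or `"normal"`),
#'   `alternative`.
#' @export
paired_wilcoxon <- function(x, y, alternative = c("two.sided", "greater",
                                                  "less"),
                            exact_max = 25) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (!n) {
    warning("all differences are zero; p = 1")
    return(structure(list(statistic = 0, w_plus = 0, p_value = 1,
                          n_effective = 0L, method = "degenerate",
                          alternative = alternative),
                     class = "paired_test"))
  }
  r <- rank(abs(d))                       # mid-ranks for ties
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))    # doubled mid-ranks are integers
    dist <- signed_rank_distribution(ranks2)
    wp2 <- round(2 * w_plus)
    p_le <- sum(dist[seq_len(wp2 + 1)])
    p_ge <- sum(dist[(wp2 + 1):length(dist)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    method <- "normal"
  }
  structure(list(statistic = w, w_plus = w_plus, p_value = p,
                 n_effective = n, method = method,
                 alternative = alternative),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s, %s): W = %g, p = %.4g (n = %d)\n",
              x$method, x$alternative, x$statistic, x$p_value,
              x$n_effective))
  invisible(x)
}

#' Pre/post HRV improvement test
#'
#' One-sided paired Wilcoxon per time-domain metric with alternative
#' "post > pre".
#'
#' @param pre,post Data frames (or lists) of per-session metric values
#'   with columns/elements `sdnn`, `rmssd`, `pnn50`; equal lengths.
#' @return A named list of [paired_wilcoxon()] results, one per metric.
#' @export
hrv_improvement_test <- function(pre, post) {
  metrics <- c("sdnn", "rmssd", "pnn50")
  out <- lapply(metrics, function(m)
    paired_wilcoxon(post[[m]], pre[[m]], alternative = "greater"))
  names(out) <- metrics
  out
}
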