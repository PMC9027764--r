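#' Two-sample t test with Cohen's d
#'
#' Pooled-variance (Student) or Welch (unequal variances, Satterthwaite df)
#' variant. Cohen's d is always the pooled-SD standardized mean difference.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @param tails 1 or 2. The one-tailed p is the tail beyond `|t|` (half the
#'   two-tailed p).
#' @return list of class `t_test_result`: `t`, `df` (fractional for Welch),
#'   `p`, `tails`, `variant`, `cohen_d`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch"), tails = 2) {
  variant <- match.arg(variant)
  stopifnot(tails %in% c(1, 2))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2 || !all(is.finite(c(x, y))))
    stop("each sample needs >= 2 finite values", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  if (v1 == 0 && v2 == 0)
    stop("zero variance in both samples", call. = FALSE)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (variant == "pooled") {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (mean(x) - mean(y)) / se
  p <- pt(-abs(t), df) * tails
  structure(list(t = t, df = df, p = p, tails = tails, variant = variant,
                 cohen_d = abs(mean(x) - mean(y)) / sqrt(sp2)),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%.4g) = %.4g, p = %.4g (%d-tailed, %s), Cohen's d = %.4g\n",
              x$df, x$t, x$p, x$tails, x$variant, x$cohen_d))
  invisible(x)
}

#' Cohen's d from a t statistic and group sizes
#'
#' `d = |t| * sqrt(1/n1 + 1/n2)`, the standardized mean difference implied
#' by a pooled two-sample t statistic.
#'
#' @param t t statistic.
#' @param n1,n2 group sizes (>= 2).
#' @return Cohen's d.
#' @export
cohen_d_from_t <- function(t, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  abs(t) * sqrt(1 / n1 + 1 / n2)
}
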