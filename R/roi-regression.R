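#' ROI interaction regression of d' on log MMR, group, and their product
#'
#' Ordinary least squares of `dprime ~ log_mmr * group` with the group
#' coded 0 = nonnative, 1 = native, so the interaction coefficient equals
#' the native-group simple slope minus the nonnative-group slope.
#' Coefficient t tests use the residual `n - 4` degrees of freedom.
#'
#' @param dprime per-subject behavioral sensitivity.
#' @param log_mmr per-subject log-transformed ROI/window-averaged MMR.
#' @param group binary group: 0/1, logical, or a factor/character vector
#'   with levels `nonnative` (reference) and `native`.
#' @param roi optional ROI name carried into the result.
#' @return list of class `roi_regression`: `roi`, `coefficients`
#'   (data.frame: term, estimate, se, t, p), `r_squared`, `f_p_value`,
#'   `simple_slopes` (per-group slope, SE, t, p), `n`, `df_residual`.
#' @export
fit_roi_interaction_model <- function(dprime, log_mmr, group, roi = NA_character_) {
  n <- length(dprime)
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)
  if (length(log_mmr) != n || length(group) != n)
    stop("inputs must have equal length", call. = FALSE)
  if (anyNA(dprime) || anyNA(log_mmr) || anyNA(group))
    stop("missing values are not allowed", call. = FALSE)
  g <- if (is.numeric(group) || is.logical(group)) as.numeric(group)
       else as.numeric(factor(as.character(group),
                              levels = c("nonnative", "native"))) - 1
  if (anyNA(g) || length(unique(g)) != 2 || !all(g %in% c(0, 1)))
    stop("group must be binary with both levels present", call. = FALSE)

  Xd <- cbind("(Intercept)" = 1, log_mmr = log_mmr, group = g,
              "log_mmr:group" = log_mmr * g)
  qrX <- qr(Xd)
  if (qrX$rank < 4) {
    dropped <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):4]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- lm(dprime ~ log_mmr * g)
  sm <- summary(fit)
  cf <- coef(sm)
  coefs <- data.frame(term = colnames(Xd), estimate = cf[, 1], se = cf[, 2],
                      t = cf[, 3], p = cf[, 4], row.names = NULL)
  V <- vcov(fit)
  dfres <- fit$df.residual
  slope <- c(nonnative = unname(coef(fit)["log_mmr"]),
             native = unname(coef(fit)["log_mmr"] + coef(fit)["log_mmr:g"]))
  slope_se <- c(nonnative = sqrt(V["log_mmr", "log_mmr"]),
                native = sqrt(V["log_mmr", "log_mmr"] +
                                V["log_mmr:g", "log_mmr:g"] +
                                2 * V["log_mmr", "log_mmr:g"]))
  st <- slope / slope_se
  simple <- data.frame(group = names(slope), slope = unname(slope),
                       se = unname(slope_se), t = unname(st),
                       p = unname(2 * pt(-abs(st), dfres)))
  fstat <- sm$fstatistic
  structure(list(roi = roi, coefficients = coefs,
                 r_squared = sm$r.squared,
                 f_p_value = unname(pf(fstat[1], fstat[2], fstat[3],
                                       lower.tail = FALSE)),
                 simple_slopes = simple, n = n, df_residual = dfres),
            class = "roi_regression")
}

#' @export
print.roi_regression <- function(x, ...) {
  cat(sprintf("<roi_regression> %s: R^2 = %.3f, model p = %.4g (n = %d)\n",
              ifelse(is.na(x$roi), "(unnamed ROI)", x$roi), x$r_squared,
              x$f_p_value, x$n))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Run the interaction regression for each a-priori ROI
#'
#' Convenience wrapper: window-averages the MMR over each ROI's labels and
#' the analysis time window, log-transforms, and fits
#' [fit_roi_interaction_model()] per ROI.
#'
#' @param mmr an [mmr_matrix()].
#' @param scores data.frame from [score_ax()] (needs `subject_id`,
#'   `dprime`).
#' @param rois named list of label index sets.
#' @param window analysis window in seconds (default `c(0.2, 0.5)`).
#' @param clamp_log passed to [log_mmr()] as `clamp`.
#' @return named list of `roi_regression` objects.
#' @export
roi_regression_suite <- function(mmr, scores, rois, window = c(0.2, 0.5),
                                 clamp_log = FALSE) {
  stopifnot(inherits(mmr, "mmr_matrix"))
  idx <- match(mmr$subjects, scores$subject_id)
  if (anyNA(idx))
    stop("scores are missing subjects: ",
         paste(mmr$subjects[is.na(idx)], collapse = ", "), call. = FALSE)
  dp <- scores$dprime[idx]
  grp <- mmr$groups$group[match(mmr$subjects, mmr$groups$subject_id)]
  out <- list()
  for (nm in names(rois)) {
    x <- log_mmr(roi_window_mean(mmr, rois[[nm]], window), clamp = clamp_log)
    out[[nm]] <- fit_roi_interaction_model(dp, x, grp, roi = nm)
  }
  out
}
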