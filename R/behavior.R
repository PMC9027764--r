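#' Signal-detection sensitivity d'
#'
#' `d' = qnorm(h*) - qnorm(f*)` with edge-corrected rates. Two corrections
#' are offered for perfect or empty cells: `"halfcount"` (replace a rate of
#' 0 by `1/(2N)` and 1 by `1 - 1/(2N)`, N the trial count in that
#' denominator; interior rates untouched) and `"loglinear"` (add 0.5 to the
#' count and 1 to the denominator, applied to every rate).
#'
#' @param hit_rate,fa_rate proportions in `[0, 1]`.
#' @param n_different,n_same trial counts behind each rate (>= 1).
#' @param correction `"halfcount"` (default) or `"loglinear"`.
#' @return d' (unitless z difference). Antisymmetric: swapping the rates
#'   (with their counts) flips the sign.
#' @export
dprime <- function(hit_rate, fa_rate, n_different, n_same,
                   correction = c("halfcount", "loglinear")) {
  correction <- match.arg(correction)
  if (any(n_different < 1) || any(n_same < 1))
    stop("trial counts must be >= 1 to apply an edge correction",
         call. = FALSE)
  if (any(hit_rate < 0 | hit_rate > 1 | fa_rate < 0 | fa_rate > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  corr <- function(r, n) {
    if (correction == "halfcount") {
      r <- ifelse(r <= 0, 1 / (2 * n), r)
      ifelse(r >= 1, 1 - 1 / (2 * n), r)
    } else {
      (r * n + 0.5) / (n + 1)
    }
  }
  qnorm(corr(hit_rate, n_different)) - qnorm(corr(fa_rate, n_same))
}

#' Score AX discrimination trials into hit/false-alarm rates and d'
#'
#' Hits are "different" responses on different-pair trials (AB, BA); false
#' alarms are "different" responses on same-pair trials (AA, BB). Responses
#' coded `"none"` (timeouts) are excluded from both numerator and
#' denominator.
#'
#' @param trials data.frame with columns `pair_type` (AA/AB/BB/BA),
#'   `response` (same/different/none) and optionally `subject_id` (one
#'   score row per subject; a single anonymous subject otherwise).
#' @param correction edge correction passed to [dprime()].
#' @return data.frame, one row per subject: `subject_id`, `n_hit`, `n_fa`,
#'   `n_different_trials`, `n_same_trials`, `hit_rate`, `fa_rate`,
#'   `dprime`, and the SDT criterion `c = -(qnorm(h*) + qnorm(f*)) / 2`.
#' @export
score_ax <- function(trials, correction = c("halfcount", "loglinear")) {
  correction <- match.arg(correction)
  if (!all(c("pair_type", "response") %in% names(trials)))
    stop("trials must have columns pair_type and response", call. = FALSE)
  bad_pair <- which(!trials$pair_type %in% c("AA", "AB", "BB", "BA"))
  if (length(bad_pair))
    stop("unknown pair_type '", trials$pair_type[bad_pair[1]],
         "' at row ", bad_pair[1], call. = FALSE)
  bad_resp <- which(!trials$response %in% c("same", "different", "none"))
  if (length(bad_resp))
    stop("unknown response '", trials$response[bad_resp[1]],
         "' at row ", bad_resp[1], call. = FALSE)
  if (is.null(trials$subject_id)) trials$subject_id <- "subject"

  one <- function(tr) {
    tr <- tr[tr$response != "none", , drop = FALSE]
    diff_tr <- tr$pair_type %in% c("AB", "BA")
    n_diff <- sum(diff_tr); n_same <- sum(!diff_tr)
    if (n_diff < 1 || n_same < 1)
      stop("subject '", tr$subject_id[1],
           "': need at least one scored trial of each kind", call. = FALSE)
    n_hit <- sum(diff_tr & tr$response == "different")
    n_fa <- sum(!diff_tr & tr$response == "different")
    h <- n_hit / n_diff; f <- n_fa / n_same
    d <- dprime(h, f, n_diff, n_same, correction)
    corr <- function(r, n) {
      if (correction == "halfcount")
        min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
      else (r * n + 0.5) / (n + 1)
    }
    data.frame(subject_id = tr$subject_id[1], n_hit = n_hit, n_fa = n_fa,
               n_different_trials = n_diff, n_same_trials = n_same,
               hit_rate = h, fa_rate = f, dprime = d,
               criterion = -(qnorm(corr(h, n_diff)) + qnorm(corr(f, n_same))) / 2)
  }
  out <- do.call(rbind, lapply(split(trials, trials$subject_id), one))
  rownames(out) <- NULL
  out[order(out$subject_id), , drop = FALSE]
}
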