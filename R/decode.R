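#' Time-resolved leave-one-out SVR decoding accuracy
#'
#' For each time sample, fits a linear epsilon-SVR predicting per-subject
#' d' from the MMR values of all labels, under leave-one-out
#' cross-validation (all `n` splits), and scores the pooled LOO
#' predictions by the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` (negative values possible).
#'
#' @param mmr an [mmr_matrix()] or `subjects x labels x time` array.
#' @param dprime per-subject response, length = subjects.
#' @param cost,epsilon SVR parameters (defaults C = 1.0, epsilon = 0.1).
#' @return numeric vector of R^2 per time sample (`times` attribute when
#'   time metadata is available).
#' @export
timewise_svr_r2 <- function(mmr, dprime, cost = 1.0, epsilon = 0.1) {
  arr <- if (inherits(mmr, "mmr_matrix")) mmr$data else mmr
  stopifnot(length(dim(arr)) == 3)
  n <- dim(arr)[1]
  if (n < 4) stop("need >= 4 subjects", call. = FALSE)
  if (length(dprime) != n)
    stop("dprime length must equal subject count", call. = FALSE)
  if (var(dprime) == 0) stop("constant response: SS_tot = 0", call. = FALSE)
  Tn <- dim(arr)[3]
  out <- numeric(Tn)
  for (t in seq_len(Tn)) {
    pred <- svr_loo_predict(arr[, , t, drop = TRUE], dprime, cost, epsilon)
    out[t] <- r2_score(dprime, pred)
  }
  if (inherits(mmr, "mmr_matrix")) attr(out, "times") <- evoked_times(mmr)
  out
}

#' Pooled permutation null for the decoding R^2 time course
#'
#' For each time sample, shuffles the correspondence between d' and the MMR
#' spatial patterns across subjects `n_perm_per_time` times, re-running the
#' full LOO-SVR each time; all `T x n_perm_per_time` null R^2 values are
#' pooled into one empirical distribution whose upper `percentile` is the
#' significance threshold (a conservative multiple-comparison control).
#'
#' @inheritParams timewise_svr_r2
#' @param n_perm_per_time permutations per time sample (default 100).
#' @param percentile pooled-null quantile used as threshold (default 0.99).
#' @param seed integer seed (fresh permutations per time sample).
#' @return list: `pool` (all null R^2 values), `threshold`, `per_time`
#'   (`n_perm_per_time x T` matrix), `percentile`.
#' @export
permutation_null_pool <- function(mmr, dprime, n_perm_per_time = 100,
                                  percentile = 0.99, seed = 1L,
                                  cost = 1.0, epsilon = 0.1) {
  if (n_perm_per_time < 1) stop("n_perm_per_time must be >= 1", call. = FALSE)
  arr <- if (inherits(mmr, "mmr_matrix")) mmr$data else mmr
  stopifnot(length(dim(arr)) == 3)
  n <- dim(arr)[1]; Tn <- dim(arr)[3]
  if (var(dprime) == 0) stop("constant response: SS_tot = 0", call. = FALSE)
  set.seed(seed)
  per_time <- matrix(0, n_perm_per_time, Tn)
  for (t in seq_len(Tn)) {
    perms <- t(vapply(seq_len(n_perm_per_time),
                      function(i) sample.int(n), integer(n)))
    K <- tcrossprod(arr[, , t, drop = TRUE])
    per_time[, t] <- svr_perm_loo_r2_cpp(K, as.numeric(dprime), perms,
                                         cost, epsilon, .svr_tol,
                                         .svr_max_iter)
  }
  pool <- as.vector(per_time)
  list(pool = pool,
       threshold = unname(quantile(pool, percentile, type = 7)),
       per_time = per_time, percentile = percentile)
}

#' Final SVR over the significant time window
#'
#' Features default to the time-averaged label vector over the significant
#' samples (keeping dimensionality at `n_labels`); `features = "concat"`
#' concatenates the label vectors of every significant sample instead.
#' Reports pooled LOO predictions, their Pearson correlation with the
#' actual d' (with one- and two-sided t-approximation p values, `n - 2`
#' df), the coefficient of determination, and a per-label contribution map
#' (mean absolute linear-SVR weight across LOO folds; for concatenated
#' features, averaged over that label's time samples).
#'
#' @inheritParams timewise_svr_r2
#' @param significant_times integer sample indices; if empty a structured
#'   null result (`significant = FALSE`) is returned.
#' @param features `"mean"` (default) or `"concat"`.
#' @return list of class `final_svr`: `significant`, `significant_times`,
#'   `predictions`, `pearson_r`, `p_one_sided`, `p_two_sided`, `r_squared`,
#'   `pearson_r_squared`, `weight_map`.
#' @export
final_svr <- function(mmr, dprime, significant_times,
                      features = c("mean", "concat"),
                      cost = 1.0, epsilon = 0.1) {
  features <- match.arg(features)
  arr <- if (inherits(mmr, "mmr_matrix")) mmr$data else mmr
  label_names <- if (inherits(mmr, "mmr_matrix")) mmr$label_names
                 else sprintf("label_%03d", seq_len(dim(arr)[2]))
  if (!length(significant_times))
    return(structure(list(significant = FALSE,
                          significant_times = integer(0),
                          predictions = NULL, pearson_r = NA_real_,
                          p_one_sided = NA_real_, p_two_sided = NA_real_,
                          r_squared = NA_real_,
                          pearson_r_squared = NA_real_,
                          weight_map = NULL), class = "final_svr"))
  n <- dim(arr)[1]; L <- dim(arr)[2]
  sub <- arr[, , significant_times, drop = FALSE]
  X <- if (features == "mean") {
    apply(sub, c(1, 2), mean)
  } else {
    matrix(sub, n, L * length(significant_times))
  }
  # LOO predictions plus per-fold weights for the contribution map
  pred <- numeric(n)
  wabs <- matrix(0, ncol(X), n)
  for (hold in seq_len(n)) {
    fit <- svr_fit(X[-hold, , drop = FALSE], dprime[-hold], cost, epsilon)
    pred[hold] <- drop(X[hold, , drop = FALSE] %*% fit$w) + fit$b
    wabs[, hold] <- abs(fit$w)
  }
  wmean <- rowMeans(wabs)
  weight_map <- if (features == "mean") wmean else
    rowMeans(matrix(wmean, L, length(significant_times)))
  names(weight_map) <- label_names
  r <- cor(dprime, pred)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  structure(list(significant = TRUE,
                 significant_times = as.integer(significant_times),
                 predictions = pred, pearson_r = r,
                 p_one_sided = pt(tstat, n - 2, lower.tail = FALSE),
                 p_two_sided = 2 * pt(-abs(tstat), n - 2),
                 r_squared = r2_score(dprime, pred),
                 pearson_r_squared = r^2,
                 weight_map = weight_map), class = "final_svr")
}

#' Full decoding pipeline for one group
#'
#' Composes [timewise_svr_r2()], [permutation_null_pool()] and
#' [final_svr()]: observed R^2 time course, pooled permutation null with
#' its upper-percentile threshold, significant time samples (observed R^2
#' above threshold), and the final model over those samples. Run it
#' separately per group.
#'
#' @inheritParams permutation_null_pool
#' @param final_features passed to [final_svr()] as `features`.
#' @return list of class `decode_result`: `r2_timecourse`, `null_pool`,
#'   `threshold`, `significant_times`, `times` (seconds, when available),
#'   `final` (a `final_svr`), `svr_params`, `seed`.
#' @export
decode_pipeline <- function(mmr, dprime, n_perm_per_time = 100,
                            percentile = 0.99, seed = 1L,
                            cost = 1.0, epsilon = 0.1,
                            final_features = "mean") {
  r2 <- timewise_svr_r2(mmr, dprime, cost, epsilon)
  null <- permutation_null_pool(mmr, dprime, n_perm_per_time, percentile,
                                seed, cost, epsilon)
  sig <- which(as.numeric(r2) > null$threshold)
  fin <- final_svr(mmr, dprime, sig, features = final_features,
                   cost = cost, epsilon = epsilon)
  structure(list(r2_timecourse = as.numeric(r2),
                 null_pool = null$pool, threshold = null$threshold,
                 significant_times = sig,
                 times = attr(r2, "times"),
                 final = fin,
                 svr_params = list(kernel = "linear", cost = cost,
                                   epsilon = epsilon),
                 percentile = percentile,
                 n_perm_per_time = as.integer(n_perm_per_time),
                 seed = as.integer(seed)),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %d time samples, threshold (p%g) = %.3f, %d significant\n",
              length(x$r2_timecourse), 100 * x$percentile, x$threshold,
              length(x$significant_times)))
  if (x$final$significant)
    cat(sprintf("  final model: r = %.3f (one-sided p = %.3g), R^2 = %.3f\n",
                x$final$pearson_r, x$final$p_one_sided, x$final$r_squared))
  invisible(x)
}
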