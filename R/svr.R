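# Linear epsilon-SVR front end over the kernel-space SMO solver.
# Solver tolerance is fixed at 1e-6 on the KKT violation gap so that
# leave-one-out results are reproducible across runs and platforms.
.svr_tol <- 1e-6
.svr_max_iter <- 200000L

#' Fit a linear epsilon-insensitive support-vector regression
#'
#' Solves the standard epsilon-SVR dual (SMO); with a linear kernel the
#' primal weights are `w = t(X) %*% beta`.
#'
#' @param X numeric matrix `n x p` of features (subjects x labels).
#' @param y numeric response, length `n`.
#' @param cost box constraint C (default 1.0).
#' @param epsilon insensitivity tube half-width (default 0.1).
#' @return list of class `svr_fit`: `w` (length p), `b`, `beta` (dual
#'   coefficients), `fitted`, plus the parameters.
#' @export
svr_fit <- function(X, y, cost = 1.0, epsilon = 0.1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  K <- tcrossprod(X)
  fit <- svr_train_cpp(K, as.numeric(y), cost, epsilon, .svr_tol,
                       .svr_max_iter)
  w <- drop(crossprod(X, fit$beta))
  structure(list(w = w, b = fit$b, beta = fit$beta,
                 fitted = drop(X %*% w) + fit$b,
                 cost = cost, epsilon = epsilon,
                 iterations = fit$iterations),
            class = "svr_fit")
}

#' @export
predict.svr_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$w) + object$b
}

#' Leave-one-out SVR predictions
#'
#' Each subject is predicted by a model trained on all the others (all `n`
#' splits).
#'
#' @inheritParams svr_fit
#' @return numeric vector of LOO predictions, length `n`.
#' @export
svr_loo_predict <- function(X, y, cost = 1.0, epsilon = 0.1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2)
  K <- tcrossprod(X)
  svr_loo_predict_cpp(K, as.numeric(y), cost, epsilon, .svr_tol,
                      .svr_max_iter)
}

# Coefficient of determination on pooled predictions (can be negative).
r2_score <- function(y, pred) {
  sstot <- sum((y - mean(y))^2)
  if (sstot <= 0) stop("constant response: SS_tot = 0", call. = FALSE)
  1 - sum((y - pred)^2) / sstot
}
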