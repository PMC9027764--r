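# Adjacency handling: accepts an edge list (2-column matrix/data.frame of
# undirected label pairs) or a square adjacency matrix (must be symmetric).
# Returns a list of 1-based integer neighbor vectors, one per label.
as_adjacency_list <- function(adjacency, n_labels) {
  if (is.matrix(adjacency) && nrow(adjacency) == ncol(adjacency) &&
      nrow(adjacency) == n_labels) {
    if (!isSymmetric(unname(adjacency * 1)))
      stop("non-symmetric adjacency matrix", call. = FALSE)
    m <- adjacency != 0
    diag(m) <- FALSE
    return(lapply(seq_len(n_labels), function(l) which(m[l, ])))
  }
  edges <- as.matrix(adjacency)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "integer"
  if (any(is.na(edges)) || any(edges < 1) || any(edges > n_labels))
    stop("adjacency edges must reference labels 1..", n_labels, call. = FALSE)
  nb <- vector("list", n_labels)
  for (l in seq_len(n_labels)) nb[[l]] <- integer(0)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    if (a == b) next
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  lapply(nb, function(v) sort(unique(v)))
}

#' Threshold-free cluster enhancement of a labels x time statistic map
#'
#' Integrates suprathreshold cluster extent over a ladder of thresholds:
#' `TFCE(s) = sum_h extent(cluster(s, h))^E * h^H * dh` for
#' `h = dh, 2dh, ..., max(stat)`, with spatiotemporal clusters connected
#' through label adjacency (same time sample) and +/- 1 time sample (same
#' label). Nonnegative statistics expected (use `abs(t)` or `t^2`).
#'
#' @param stat numeric `labels x time` matrix (a vector is treated as one
#'   time sample).
#' @param adjacency label edge list (`label_a`, `label_b`) or symmetric
#'   square matrix.
#' @param E,H extent and height exponents (defaults 0.5 and 2, the
#'   canonical choices).
#' @param dh threshold step; default `max(stat) / 50`.
#' @return enhanced map, same shape as `stat`.
#' @export
tfce_enhance <- function(stat, adjacency, E = 0.5, H = 2, dh = NULL) {
  if (is.null(dim(stat))) stat <- matrix(stat, ncol = 1)
  if (!all(is.finite(stat))) stop("stat must be finite", call. = FALSE)
  if (is.null(dh)) dh <- max(stat) / 50
  if (max(stat) > 0 && dh <= 0) stop("dh must be > 0", call. = FALSE)
  adj <- as_adjacency_list(adjacency, nrow(stat))
  if (max(stat) <= 0) return(stat * 0)
  tfce_enhance_cpp(stat, adj, E, H, dh)
}

#' Spatiotemporal TFCE permutation test for a group difference in MMR
#'
#' Observed statistic per (label, time) sample is the pooled two-sample t
#' on MMR magnitudes, enhanced on `|t|` (two-sided) or `t^2`. Group labels
#' are permuted `n_perm` times; each permuted map is enhanced with the same
#' threshold ladder (step fixed from the observed map), and the max-TFCE
#' null across all samples gives strong familywise control:
#' `p(s) = (1 + #{perm: max TFCE_perm >= TFCE_obs(s)}) / (n_perm + 1)`.
#'
#' @param group_a,group_b numeric arrays `subjects x labels x time` (e.g.
#'   group slices of an [mmr_matrix()]'s `data`).
#' @param adjacency label adjacency (edge list or symmetric matrix).
#' @param n_perm number of permutations (default 1024).
#' @param seed integer seed for the permutation draws.
#' @param E,H,dh TFCE parameters; `dh = NULL` uses `max observed stat / 50`.
#' @param statistic `"t"` (enhance `|t|`) or `"F"` (enhance `t^2`).
#' @return object of class `tfce_map`: `stat`, `tfce`, `p`, `neg_log10_p`
#'   (all `labels x time`), `max_null`, `n_permutations`, `E`, `H`, `dh`,
#'   `statistic`.
#' @export
tfce_permutation_test <- function(group_a, group_b, adjacency,
                                  n_perm = 1024, seed = 1L,
                                  E = 0.5, H = 2, dh = NULL,
                                  statistic = c("t", "F")) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  da <- dim(group_a); db <- dim(group_b)
  if (length(da) != 3 || length(db) != 3 || !all(da[2:3] == db[2:3]))
    stop("group arrays must be subjects x labels x time with matching grids",
         call. = FALSE)
  if (da[1] < 2 || db[1] < 2)
    stop("need >= 2 subjects per group", call. = FALSE)
  L <- da[2]; Tn <- da[3]
  n <- da[1] + db[1]
  dat <- matrix(0, n, L * Tn)
  dat[seq_len(da[1]), ] <- matrix(group_a, da[1], L * Tn)
  dat[da[1] + seq_len(db[1]), ] <- matrix(group_b, db[1], L * Tn)
  grp <- c(rep(0L, da[1]), rep(1L, db[1]))
  set.seed(seed)
  perms <- t(vapply(seq_len(n_perm), function(i) grp[sample.int(n)],
                    integer(n)))
  adj <- as_adjacency_list(adjacency, L)
  res <- tfce_perm_cpp(dat, grp, perms, adj, L, Tn, E, H,
                       if (is.null(dh)) -1 else dh, statistic == "F")
  structure(list(stat = res$stat, tfce = res$tfce, p = res$p,
                 neg_log10_p = -log10(res$p), max_null = res$max_null,
                 n_permutations = as.integer(n_perm), E = E, H = H,
                 dh = res$dh, statistic = statistic),
            class = "tfce_map")
}

#' @export
print.tfce_map <- function(x, ...) {
  cat(sprintf("<tfce_map> %d x %d samples, %d permutations, min p = %.4g (E=%g, H=%g, dh=%.4g, stat=%s)\n",
              nrow(x$p), ncol(x$p), x$n_permutations, min(x$p), x$E, x$H,
              x$dh, x$statistic))
  invisible(x)
}
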