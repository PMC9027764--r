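# Independent oracles used across the suite. Deliberately naive/brute-force
# implementations on paths disjoint from the package's own code.

# Inverse normal CDF by bisection on pnorm (independent of qnorm).
qnorm_bisect <- function(p, tol = 1e-10) {
  vapply(p, function(pp) {
    lo <- -10; hi <- 10
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (pnorm(mid) < pp) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# Student t upper-tail probability by numeric integration of the density
# formula (written out, not via dt()).
t_tail_integrate <- function(t, df) {
  dens <- function(x)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  integrate(dens, abs(t), Inf, rel.tol = 1e-10)$value
}

# Brute-force TFCE by explicit threshold scan + igraph connected components
# on the spatiotemporal graph. stat: labels x time; edges: 2-col label pairs.
tfce_brute <- function(stat, edges, E, H, dh) {
  L <- nrow(stat); Tn <- ncol(stat)
  node <- function(l, t) l + (t - 1) * L
  el <- matrix(0L, 0, 2)
  if (nrow(edges) > 0)
    for (t in seq_len(Tn))
      el <- rbind(el, cbind(node(edges[, 1], t), node(edges[, 2], t)))
  if (Tn > 1)
    for (t in seq_len(Tn - 1))
      el <- rbind(el, cbind(node(seq_len(L), t), node(seq_len(L), t + 1)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, L * Tn - igraph::vcount(g)))
  out <- matrix(0, L, Tn)
  hmax <- max(stat)
  if (hmax <= 0) return(out)
  nsteps <- floor(hmax / dh + 1e-9)
  v <- as.vector(stat)
  for (k in seq_len(nsteps)) {
    h <- dh * k
    keep <- which(v >= h)
    if (!length(keep)) next
    sub <- igraph::induced_subgraph(g, keep)
    comp <- igraph::components(sub)
    ext <- comp$csize[comp$membership]
    out[keep] <- out[keep] + ext^E * h^H * dh
  }
  out
}

# Same brute force at very fine dh: components are recomputed only when
# the suprathreshold set changes (they depend on the set alone), but the
# threshold summation itself still runs step by step.
tfce_brute_memo <- function(stat, edges, E, H, dh) {
  L <- nrow(stat); Tn <- ncol(stat)
  node <- function(l, t) l + (t - 1) * L
  el <- matrix(0L, 0, 2)
  if (nrow(edges) > 0)
    for (t in seq_len(Tn))
      el <- rbind(el, cbind(node(edges[, 1], t), node(edges[, 2], t)))
  if (Tn > 1)
    for (t in seq_len(Tn - 1))
      el <- rbind(el, cbind(node(seq_len(L), t), node(seq_len(L), t + 1)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, L * Tn - igraph::vcount(g)))
  v <- as.vector(stat)
  out <- numeric(L * Tn)
  hmax <- max(v)
  if (hmax <= 0) return(matrix(out, L, Tn))
  cache_key <- ""; keep <- integer(0); ext <- numeric(0)
  for (k in seq_len(floor(hmax / dh + 1e-9))) {
    h <- dh * k
    kp <- which(v >= h)
    key <- paste(kp, collapse = ",")
    if (key != cache_key) {
      cache_key <- key
      keep <- kp
      if (length(keep)) {
        sub <- igraph::induced_subgraph(g, keep)
        comp <- igraph::components(sub)
        ext <- comp$csize[comp$membership]
      }
    }
    if (length(keep))
      out[keep] <- out[keep] + ext^E * h^H * dh
  }
  matrix(out, L, Tn)
}

# A tiny default cohort config used by several tests (reduced grid so each
# test stays fast; statistical structure identical to the default world).
small_cfg <- function(seed, ...) {
  sim_config(n_labels = 40, sample_rate = 50, seed = seed, ...)
}
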