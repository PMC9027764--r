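make_evoked <- function(data, cond, subj = "s01") {
  label_evoked(data, subj, cond, -0.1, 50)
}

test_that("compute_mmr is the elementwise 3-vector norm of the difference", {
  set.seed(21)
  std <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  dev <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  m <- compute_mmr(make_evoked(std, "standard"), make_evoked(dev, "deviant"))
  # brute-force oracle: per-cell loop
  expected <- matrix(0, 5, 4)
  for (l in 1:5) for (t in 1:4) {
    d <- dev[l, t, ] - std[l, t, ]
    expected[l, t] <- sqrt(sum(d * d))
  }
  expect_equal(unname(m[, ]), expected, tolerance = 1e-12)

  # identity and unit/orthogonal difference vectors
  expect_true(all(compute_mmr(make_evoked(std, "standard"),
                              make_evoked(std, "deviant")) == 0))
  dev1 <- std; dev1[, , 1] <- dev1[, , 1] + 1
  expect_equal(unname(compute_mmr(make_evoked(std, "standard"),
                                  make_evoked(dev1, "deviant"))[, ]),
               matrix(1, 5, 4))
  dev2 <- dev1; dev2[, , 2] <- dev2[, , 2] + 1
  expect_equal(unname(compute_mmr(make_evoked(std, "standard"),
                                  make_evoked(dev2, "deviant"))[, ]),
               matrix(sqrt(2), 5, 4))
})

test_that("compute_mmr enforces alignment and basic invariants", {
  set.seed(22)
  a <- array(rnorm(6 * 3 * 3), dim = c(2, 3, 3))
  b <- array(rnorm(6 * 3 * 3), dim = c(2, 3, 3))
  expect_error(compute_mmr(make_evoked(a, "standard", "s01"),
                           make_evoked(b, "deviant", "s02")),
               "subject_id mismatch")
  e1 <- make_evoked(a, "standard"); e2 <- make_evoked(b, "deviant")
  e2$label_names[2] <- "other"
  expect_error(compute_mmr(e1, e2), "label mismatch at position 2")

  # triangle inequality, |k|-homogeneity, and global rotation invariance
  m <- compute_mmr(e1, make_evoked(b, "deviant"))
  norm3 <- function(x) sqrt(x[, , 1]^2 + x[, , 2]^2 + x[, , 3]^2)
  expect_true(all(m <= norm3(a) + norm3(b) + 1e-12))
  bk <- a + 3 * (b - a)
  expect_equal(unname(compute_mmr(e1, make_evoked(bk, "deviant"))[, ]),
               3 * unname(m[, ]), tolerance = 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- function(x) {
    y <- x
    for (l in seq_len(dim(x)[1])) y[l, , ] <- x[l, , ] %*% t(R)
    y
  }
  mrot <- compute_mmr(make_evoked(rot(a), "standard"),
                      make_evoked(rot(b), "deviant"))
  expect_equal(unname(mrot[, ]), unname(m[, ]), tolerance = 1e-10)
})

test_that("average_labels matches an independent group-by mean", {
  set.seed(23)
  vert <- array(rnorm(12 * 5 * 3), dim = c(12, 5, 3))
  map <- sample(c("a", "b", "c"), 12, replace = TRUE)
  av <- average_labels(vert, map, label_names = c("a", "b", "c"))
  for (lab in c("a", "b", "c")) {
    idx <- which(map == lab)
    for (k in 1:3)
      expect_equal(av$data[match(lab, av$label_names), , k],
                   as.vector(colMeans(vert[idx, , k, drop = FALSE])))
  }
  # one vertex per label is the identity; opposite vectors cancel
  one <- average_labels(vert[1:3, , , drop = FALSE], c("x", "y", "z"))
  expect_equal(one$data[1, , ], vert[1, , ])
  opp <- array(0, dim = c(2, 5, 3)); opp[1, , ] <- 1; opp[2, , ] <- -1
  expect_true(all(average_labels(opp, c("q", "q"))$data == 0))
  expect_error(average_labels(vert, map, label_names = c("a", "b", "zzz")),
               "empty label 'zzz'")
})

test_that("roi_window_mean applies the [start, end) convention", {
  # 1 subject, 1 label, times -0.1, -0.08, ..., at 50 Hz
  arr <- array(0, dim = c(1, 2, 51))
  arr[1, 1, ] <- seq_len(51)
  arr[1, 2, ] <- 1
  groups <- data.frame(subject_id = "s01", group = "native")
  m <- mmr_matrix(arr, "s01", groups, -0.1, 50)
  times <- evoked_times(m)
  # constant map
  expect_equal(unname(roi_window_mean(m, 2, c(0.2, 0.5))), 1)
  # exact window contents: closed left, open right (fp-safe comparison:
  # the sample nominally at 0.5 s must stay excluded)
  idx <- which(times >= 0.2 - 1e-9 & times < 0.5 - 1e-9)
  expect_equal(unname(roi_window_mean(m, 1, c(0.2, 0.5))),
               mean(seq_len(51)[idx]))
  # two-sample window {2, 4} -> 3
  arr2 <- array(0, dim = c(1, 1, 51)); arr2[1, 1, ] <- 0
  arr2[1, 1, idx[1]] <- 2; arr2[1, 1, idx[2]] <- 4
  m2 <- mmr_matrix(arr2, "s01", groups, -0.1, 50)
  expect_equal(unname(roi_window_mean(m2, 1, c(times[idx[1]], times[idx[2] + 1]))), 3)
  # random instance vs independent two-step mean
  set.seed(31)
  arr3 <- array(abs(rnorm(3 * 4 * 51)), dim = c(3, 4, 51))
  m3 <- mmr_matrix(arr3, c("s01", "s02", "s03"),
                   data.frame(subject_id = c("s01", "s02", "s03"),
                              group = "native"), -0.1, 50)
  got <- roi_window_mean(m3, c(2, 4), c(0.2, 0.5))
  expect_equal(unname(got),
               apply(arr3[, c(2, 4), idx], 1, mean))
  expect_error(roi_window_mean(m3, c(2, 4), c(0.201, 0.205)), "empty window")
})

test_that("log_mmr guards its floor", {
  expect_equal(log_mmr(1), 0)
  expect_equal(log_mmr(exp(1)), 1)
  set.seed(5); x <- abs(rnorm(50)) + 0.1
  expect_equal(log_mmr(x), log(x))
  expect_error(log_mmr(c(1, 0)), "floor")
  expect_equal(log_mmr(c(1, 0), clamp = TRUE), c(0, log(1e-12)))
})
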