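test_that("sim_config validates every invariant with a field list", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_per_group = 2), "n_per_group")
  expect_error(sim_config(sample_rate = 0), "sample_rate")
  expect_error(sim_config(epoch_window = c(0.1, 0.9)), "epoch_window")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  # overlapping ROI sets are rejected
  rois <- list(left_IFG = 1:3, left_STG = 3:5, right_IFG = 10:12,
               right_STG = 13:15)
  expect_error(sim_config(roi_label_ids = rois), "disjoint")
  # several violations are reported together
  err <- tryCatch(sim_config(n_per_group = 1, noise_sd = -2),
                  error = conditionMessage)
  expect_match(err, "n_per_group")
  expect_match(err, "noise_sd")
})

test_that("cohorts are bitwise deterministic given the seed", {
  cfg <- small_cfg(seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- simulate_cohort(small_cfg(seed = 124))
  expect_false(identical(a$truth$subjects$sensitivity,
                         c$truth$subjects$sensitivity))
})

test_that("noise-free construction identities hold", {
  # 100 Hz grid so the deviant-bump center (0.35 s) is exactly on-grid
  cfg <- sim_config(n_labels = 40, sample_rate = 100, noise_sd = 0,
                    seed = 55)
  co <- simulate_cohort(cfg)
  id <- co$groups$subject_id[1]
  std <- co$evoked[[paste0(id, ".standard")]]
  dev <- co$evoked[[paste0(id, ".deviant")]]
  mmr <- compute_mmr(std, dev)
  times <- evoked_times(std)
  # MMR at the deviant-bump peak equals the planted amplitude exactly
  peak <- which.min(abs(times - mean(cfg$coupling_window)))
  expect_equal(times[peak], 0.35)
  expect_equal(unname(mmr[, peak]), unname(co$truth$amplitudes[1, ]),
               tolerance = 1e-9)
  # in the pre-stimulus baseline the deviant component's Gaussian tail is
  # numerically negligible: the conditions coincide
  early <- which(times < 0)
  expect_lt(max(mmr[, early]), 1e-6)
  expect_equal(std$data[, early, ], dev$data[, early, ], tolerance = 1e-6)
})

test_that("doubling the planted amplitude doubles the window-mean MMR", {
  cfg <- small_cfg(seed = 56, noise_sd = 0)
  co <- simulate_cohort(cfg)
  row <- list(subject_id = "s01", group = "nonnative",
              amplitudes = co$truth$amplitudes[1, ])
  row2 <- row; row2$amplitudes <- 2 * row$amplitudes
  std <- simulate_subject_evoked(cfg, row, "standard", seed = 9)
  d1 <- simulate_subject_evoked(cfg, row, "deviant", seed = 9)
  d2 <- simulate_subject_evoked(cfg, row2, "deviant", seed = 9)
  groups <- data.frame(subject_id = "s01", group = "nonnative")
  m1 <- mmr_matrix(array(compute_mmr(std, d1), c(1, cfg$n_labels, 51)),
                   "s01", groups, cfg$epoch_window[1], cfg$sample_rate)
  m2 <- mmr_matrix(array(compute_mmr(std, d2), c(1, cfg$n_labels, 51)),
                   "s01", groups, cfg$epoch_window[1], cfg$sample_rate)
  expect_equal(unname(roi_window_mean(m2, 1:10, c(0.2, 0.5))),
               2 * unname(roi_window_mean(m1, 1:10, c(0.2, 0.5))),
               tolerance = 1e-9)
})

test_that("cohort structure matches its contract", {
  cfg <- small_cfg(seed = 77, n_per_group = 3)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$groups), 6)
  expect_length(co$evoked, 12) # standard + deviant per subject
  expect_equal(nrow(co$behavior), 6 * 4 * cfg$n_trials_per_pairing)
  expect_equal(dim(co$truth$amplitudes), c(6, cfg$n_labels))
  expect_true(all(co$truth$subjects$sensitivity >= 0)) # truncated at 0
  # behavior table carries group labels consistent with the group table
  merged <- unique(co$behavior[, c("subject_id", "group")])
  expect_identical(merged$group[order(merged$subject_id)],
                   co$groups$group[order(co$groups$subject_id)])
})

test_that("latent structure propagates: planted SDT rates and coupling", {
  # empirical hit/FA rates across many trials converge to Phi(s - c), Phi(-c)
  tr <- simulate_ax_trials(1.8, 1.2, n_per_pairing = 20000, seed = 14)
  diffp <- tr$pair_type %in% c("AB", "BA")
  expect_equal(mean(tr$response[diffp] == "different"), pnorm(1.8 - 1.2),
               tolerance = 0.012)
  expect_equal(mean(tr$response[!diffp] == "different"), pnorm(-1.2),
               tolerance = 0.012)
  # coupled group's log amplitude in coupling ROIs is gamma-linear in s
  cfg <- small_cfg(seed = 15, amp_lognoise_sd = 0, subject_lognoise_sd = 0)
  co <- simulate_cohort(cfg)
  lab <- unlist(cfg$roi_label_ids[cfg$coupling_rois])[1]
  nat <- co$truth$subjects$group == "native"
  la <- log(co$truth$amplitudes[nat, lab])
  s <- co$truth$subjects$sensitivity[nat]
  expect_equal(unname(coef(lm(la ~ s))[2]), cfg$coupling_gamma[["native"]],
               tolerance = 1e-9)
  # uncoupled group amplitudes do not depend on s
  non <- !nat
  expect_equal(unname(sd(log(co$truth$amplitudes[non, lab]))), 0,
               tolerance = 1e-12)
})
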