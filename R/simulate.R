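# Evoked waveform shape: both conditions share two early Gaussian bumps
# (peaks 100 and 130 ms, width 20 ms, amplitudes 3 and 2 a.u.); the deviant
# additionally carries a Gaussian bump centered in the coupling window
# (width 60 ms, unit peak) scaled by the subject- and label-specific planted
# amplitude. All components lie along one fixed random unit 3-orientation
# per label per subject, so the noise-free deviant-minus-standard vector
# magnitude at the bump peak equals the planted amplitude exactly.
.early_bumps <- function(times) {
  3 * exp(-0.5 * ((times - 0.100) / 0.020)^2) +
    2 * exp(-0.5 * ((times - 0.130) / 0.020)^2)
}

.deviant_bump <- function(times, coupling_window) {
  center <- mean(coupling_window)
  width <- diff(coupling_window) / 5
  exp(-0.5 * ((times - center) / width)^2)
}

#' Simulate one subject's label-level evoked response
#'
#' @param config a [sim_config()].
#' @param subject_truth one row of the cohort truth: a list/row with
#'   `subject_id`, `group`, and `amplitudes` (numeric vector of per-label
#'   deviant-component amplitudes).
#' @param condition `"standard"` or `"deviant"`.
#' @param seed subject-level seed; orientations derive from it so both
#'   conditions of one subject share the same per-label orientations, while
#'   condition noise uses distinct child streams.
#' @return a [label_evoked()].
#' @export
simulate_subject_evoked <- function(config, subject_truth, condition, seed) {
  validate_sim_config(config)
  condition <- match.arg(condition, c("standard", "deviant"))
  L <- config$n_labels
  times <- seq(config$epoch_window[1], config$epoch_window[2],
               by = 1 / config$sample_rate)
  nt <- length(times)

  set.seed(child_seed(seed, 0)) # orientations: shared across conditions
  u <- matrix(rnorm(L * 3), L, 3)
  u <- u / sqrt(rowSums(u^2))

  shape <- .early_bumps(times)
  dat <- array(0, dim = c(L, nt, 3))
  for (k in 1:3) dat[, , k] <- outer(u[, k], shape)
  if (condition == "deviant") {
    dshape <- .deviant_bump(times, config$coupling_window)
    amp <- subject_truth$amplitudes
    if (length(amp) != L)
      stop("subject_truth$amplitudes must have length n_labels", call. = FALSE)
    for (k in 1:3) dat[, , k] <- dat[, , k] + outer(amp * u[, k], dshape)
  }
  if (config$noise_sd > 0) {
    set.seed(child_seed(seed, if (condition == "standard") 1 else 2))
    dat <- dat + array(rnorm(L * nt * 3, sd = config$noise_sd),
                       dim = c(L, nt, 3))
  }
  label_evoked(dat, subject_truth$subject_id, condition,
               config$epoch_window[1], config$sample_rate)
}

#' Simulate AX discrimination trials for one subject
#'
#' Equal-variance signal-detection model: on different-pair trials (AB, BA)
#' the decision variable is Normal(sensitivity, 1), on same-pair trials
#' (AA, BB) it is Normal(0, 1); the subject responds "different" iff the
#' variable exceeds the criterion. Trial order is randomized.
#'
#' @param sensitivity latent d' of the subject.
#' @param criterion decision criterion in z units.
#' @param n_per_pairing trials per pairing (AA, AB, BB, BA).
#' @param seed integer seed.
#' @return data.frame with columns `pair_type`, `trial_index`, `response`.
#' @export
simulate_ax_trials <- function(sensitivity, criterion, n_per_pairing = 10,
                               seed = 1L) {
  stopifnot(n_per_pairing >= 1)
  set.seed(seed)
  pairs <- rep(c("AA", "AB", "BB", "BA"), each = n_per_pairing)
  pairs <- sample(pairs)
  different <- pairs %in% c("AB", "BA")
  dv <- rnorm(length(pairs), mean = ifelse(different, sensitivity, 0), sd = 1)
  data.frame(pair_type = pairs,
             trial_index = seq_along(pairs),
             response = ifelse(dv > criterion, "different", "same"))
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject latent sensitivity (normal truncated at 0), SDT
#' criterion, and per-label deviant-component amplitudes
#' `exp(log(base) + eta_i + eps_l + gamma * (s_i - mu_g) * [label in
#' coupling ROIs])`, where `eta_i` is a subject-level lognormal factor
#' shared across labels and the coupling is centered on the group's mean
#' latent sensitivity (so group mean amplitudes stay at their base values).
#' Then generates both conditions' evoked responses and an AX trial table
#' per subject. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `mmr_cohort`: list with `config`, `groups`
#'   (subject_id, group), `behavior` (trial table across subjects), `evoked`
#'   (named list `<subject>.<condition>` of [label_evoked()]), `truth`
#'   (list: `subjects` data.frame, `amplitudes` subjects x labels matrix),
#'   and `adjacency`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  n <- config$n_per_group
  groups <- rep(c("nonnative", "native"), each = n)
  ids <- sprintf("s%02d", seq_len(2 * n))
  L <- config$n_labels
  coupling_labels <- sort(unique(unlist(
    config$roi_label_ids[config$coupling_rois])))

  set.seed(child_seed(config$seed, 1)) # truth draws
  mu <- config$group_means_dprime[groups]
  sdv <- config$group_sds_dprime[groups]
  # normal truncated at 0 via inverse-CDF (single deterministic draw each)
  plo <- pnorm(0, mu, sdv)
  s <- qnorm(plo + runif(2 * n) * (1 - plo), mu, sdv)
  crit <- rnorm(2 * n, config$criterion_mean, config$criterion_sd)
  subj_eta <- rnorm(2 * n, sd = config$subject_lognoise_sd)
  amps <- matrix(0, 2 * n, L)
  for (i in seq_len(2 * n)) {
    g <- groups[i]
    la <- log(config$mmr_base_amplitude[[g]]) + subj_eta[i] +
      rnorm(L, sd = config$amp_lognoise_sd)
    la[coupling_labels] <- la[coupling_labels] +
      config$coupling_gamma[[g]] * (s[i] - config$group_means_dprime[[g]])
    amps[i, ] <- exp(la)
  }
  truth_subjects <- data.frame(subject_id = ids, group = groups,
                               sensitivity = s, criterion = crit)

  evoked <- list()
  behavior <- vector("list", 2 * n)
  for (i in seq_len(2 * n)) {
    row <- list(subject_id = ids[i], group = groups[i], amplitudes = amps[i, ])
    sseed <- child_seed(config$seed, 100 + i)
    for (cond in c("standard", "deviant"))
      evoked[[paste(ids[i], cond, sep = ".")]] <-
        simulate_subject_evoked(config, row, cond, sseed)
    tr <- simulate_ax_trials(s[i], crit[i], config$n_trials_per_pairing,
                             child_seed(config$seed, 500 + i))
    tr <- cbind(subject_id = ids[i], group = groups[i], tr)
    behavior[[i]] <- tr
  }
  structure(list(
    config = config,
    groups = data.frame(subject_id = ids, group = groups),
    behavior = do.call(rbind, behavior),
    evoked = evoked,
    truth = list(subjects = truth_subjects, amplitudes = amps),
    adjacency = make_label_adjacency(L)
  ), class = "mmr_cohort")
}

#' @export
print.mmr_cohort <- function(x, ...) {
  cat(sprintf("<mmr_cohort> %d subjects (%d/group), %d labels, %g Hz, seed %d\n",
              nrow(x$groups), x$config$n_per_group, x$config$n_labels,
              x$config$sample_rate, x$config$seed))
  invisible(x)
}
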