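#' Simulation configuration for synthetic MMR cohorts
#'
#' Describes the "stated world" the generator emulates: two language-background
#' groups (nonnative listeners with a large, behavior-decoupled MMR; native
#' listeners with a smaller MMR whose amplitude is log-linearly coupled to
#' latent discrimination sensitivity in left frontal/temporal labels), an
#' epoch of -100 to 900 ms, and Destrieux-style cortical labels.
#'
#' Group d' means default to 1.67 (nonnative) and 2.26 (native), the values
#' implied by inverse-normal transforming typical published group hit and
#' false-alarm rates for a voice-onset-time contrast; SDs of 0.9 give a
#' standardized group difference near 0.65. The nonnative group gets the
#' larger MMR base amplitude (4 vs 2 dSPM-like arbitrary units), and only the
#' native group's coupling gamma is nonzero.
#'
#' @param n_per_group subjects per group (>= 3).
#' @param n_labels number of cortical labels (default 150).
#' @param roi_label_ids named list of integer label index sets for
#'   `left_IFG`, `right_IFG`, `left_STG`, `right_STG`; sets must be disjoint.
#'   Defaults place left-hemisphere labels in `1:(n_labels/2)`.
#' @param coupling_rois names of the ROI sets in which the MMR amplitude is
#'   coupled to latent sensitivity (default left IFG + left STG).
#' @param epoch_window `c(start, end)` in seconds, start < 0 < end.
#' @param sample_rate sampling rate in Hz (default 200; a desk-scale stand-in
#'   for 1 kHz acquisition).
#' @param group_means_dprime,group_sds_dprime named numeric, latent d' mean/SD
#'   per group (`nonnative`, `native`).
#' @param criterion_mean,criterion_sd SDT decision-criterion distribution
#'   (z units) shared by both groups.
#' @param mmr_base_amplitude named numeric, deviant-component base amplitude
#'   per group (arbitrary source units).
#' @param coupling_gamma named numeric, per-group log-amplitude slope on
#'   latent sensitivity (nonzero only for `native` by default).
#' @param coupling_window `c(start, end)` seconds of the deviant component
#'   (default 0.200-0.500 s).
#' @param amp_lognoise_sd SD of the per-label lognormal amplitude noise.
#' @param subject_lognoise_sd SD of the subject-level lognormal amplitude
#'   factor shared across all labels (global inter-individual differences in
#'   source amplitude / SNR).
#' @param noise_sd additive Gaussian noise SD on each orientation component
#'   of the label time series.
#' @param n_trials_per_pairing AX trials per pairing (default 10).
#' @param seed master seed; all child streams derive from it.
#' @return an object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_per_group = 15,
                       n_labels = 150,
                       roi_label_ids = NULL,
                       coupling_rois = c("left_IFG", "left_STG"),
                       epoch_window = c(-0.100, 0.900),
                       sample_rate = 200,
                       group_means_dprime = c(nonnative = 1.67, native = 2.26),
                       group_sds_dprime = c(nonnative = 0.45, native = 1.10),
                       criterion_mean = 1.30,
                       criterion_sd = 0.30,
                       mmr_base_amplitude = c(nonnative = 4, native = 2),
                       coupling_gamma = c(nonnative = 0, native = 0.4),
                       coupling_window = c(0.200, 0.500),
                       amp_lognoise_sd = 0.2,
                       subject_lognoise_sd = 0.3,
                       noise_sd = 0.25,
                       n_trials_per_pairing = 10,
                       seed = 1L) {
  if (is.null(roi_label_ids)) roi_label_ids <- default_rois(n_labels)
  cfg <- list(
    n_per_group = as.integer(n_per_group), n_labels = as.integer(n_labels),
    roi_label_ids = lapply(roi_label_ids, as.integer),
    coupling_rois = coupling_rois,
    epoch_window = as.numeric(epoch_window), sample_rate = as.numeric(sample_rate),
    group_means_dprime = group_means_dprime, group_sds_dprime = group_sds_dprime,
    criterion_mean = criterion_mean, criterion_sd = criterion_sd,
    mmr_base_amplitude = mmr_base_amplitude, coupling_gamma = coupling_gamma,
    coupling_window = as.numeric(coupling_window),
    amp_lognoise_sd = amp_lognoise_sd,
    subject_lognoise_sd = subject_lognoise_sd, noise_sd = noise_sd,
    n_trials_per_pairing = as.integer(n_trials_per_pairing),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly; otherwise an error listing every offending field.
#' @export
validate_sim_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(cfg$n_per_group >= 3, "n_per_group: must be >= 3")
  chk(cfg$n_labels >= 1, "n_labels: must be >= 1")
  chk(cfg$sample_rate > 0, "sample_rate: must be > 0")
  chk(length(cfg$epoch_window) == 2 &&
        cfg$epoch_window[1] < 0 && cfg$epoch_window[2] > 0,
      "epoch_window: need start < 0 < end")
  chk(cfg$noise_sd >= 0, "noise_sd: must be >= 0")
  chk(cfg$amp_lognoise_sd >= 0, "amp_lognoise_sd: must be >= 0")
  chk(cfg$subject_lognoise_sd >= 0, "subject_lognoise_sd: must be >= 0")
  chk(cfg$n_trials_per_pairing >= 1, "n_trials_per_pairing: must be >= 1")
  roi_names <- c("left_IFG", "right_IFG", "left_STG", "right_STG")
  chk(all(roi_names %in% names(cfg$roi_label_ids)),
      "roi_label_ids: must name left_IFG, right_IFG, left_STG, right_STG")
  ids <- unlist(cfg$roi_label_ids, use.names = FALSE)
  chk(!anyDuplicated(ids), "roi_label_ids: ROI sets must be disjoint")
  chk(all(ids >= 1 & ids <= cfg$n_labels),
      "roi_label_ids: indices must lie in 1..n_labels")
  chk(all(cfg$coupling_rois %in% names(cfg$roi_label_ids)),
      "coupling_rois: must be names of roi_label_ids")
  gn <- c("nonnative", "native")
  for (f in c("group_means_dprime", "group_sds_dprime",
              "mmr_base_amplitude", "coupling_gamma"))
    chk(all(gn %in% names(cfg[[f]])),
        paste0(f, ": must be named with 'nonnative' and 'native'"))
  chk(length(cfg$coupling_window) == 2 &&
        cfg$coupling_window[1] < cfg$coupling_window[2],
      "coupling_window: need start < end")
  if (length(bad))
    stop("invalid simulation config:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(cfg)
}

# Default ROI placement: left hemisphere = labels 1..floor(L/2), right = rest;
# IFG ~3 labels (opercular/triangular/orbital parts), STG ~4 labels (lateral
# STG, planum polare/temporale, transverse temporal), mirrored across
# hemispheres at fixed relative positions.
default_rois <- function(n_labels) {
  hl <- floor(n_labels / 2)
  stopifnot(hl >= 8)
  ifg <- unique(pmax(1L, pmin(hl, round(hl * c(0.12, 0.14, 0.16)))))
  stg <- unique(pmax(1L, pmin(hl, round(hl * c(0.40, 0.42, 0.44, 0.46)))))
  stg <- setdiff(stg, ifg)
  list(left_IFG = as.integer(ifg), left_STG = as.integer(stg),
       right_IFG = as.integer(ifg + hl), right_STG = as.integer(stg + hl))
}

#' Synthetic label adjacency
#'
#' Band-graph adjacency over labels within each hemisphere (labels i and j
#' adjacent iff |i - j| <= `bandwidth` and both lie in the same hemisphere),
#' a stand-in for cortical-parcellation neighbor structure.
#'
#' @param n_labels number of labels.
#' @param bandwidth neighborhood half-width (default 2).
#' @return data.frame with columns `label_a`, `label_b` (undirected edges,
#'   `label_a < label_b`).
#' @export
make_label_adjacency <- function(n_labels, bandwidth = 2) {
  hl <- floor(n_labels / 2)
  hemi <- c(rep(1L, hl), rep(2L, n_labels - hl))
  a <- integer(0); b <- integer(0)
  for (d in seq_len(bandwidth)) {
    i <- seq_len(n_labels - d)
    j <- i + d
    keep <- hemi[i] == hemi[j]
    a <- c(a, i[keep]); b <- c(b, j[keep])
  }
  o <- order(a, b)
  data.frame(label_a = a[o], label_b = b[o])
}
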