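#' Mismatch-response magnitude for one subject
#'
#' Subtracts the standard's 3-component dipole vectors from the deviant's
#' and takes the Euclidean norm over orientation components at every label
#' and time sample.
#'
#' @param standard,deviant matching [label_evoked()] objects (same subject,
#'   labels and time axis).
#' @return nonnegative `labels x time` matrix with a `times` attribute.
#' @export
compute_mmr <- function(standard, deviant) {
  stopifnot(inherits(standard, "label_evoked"), inherits(deviant, "label_evoked"))
  if (standard$subject_id != deviant$subject_id)
    stop("alignment error: subject_id mismatch ('", standard$subject_id,
         "' vs '", deviant$subject_id, "')", call. = FALSE)
  if (!identical(standard$label_names, deviant$label_names)) {
    i <- which(standard$label_names != deviant$label_names)[1]
    stop("alignment error: label mismatch at position ", i, " ('",
         standard$label_names[i], "' vs '", deviant$label_names[i], "')",
         call. = FALSE)
  }
  if (!identical(dim(standard$data), dim(deviant$data)) ||
      standard$time_start != deviant$time_start ||
      standard$sample_rate != deviant$sample_rate)
    stop("alignment error: time axis or shape mismatch", call. = FALSE)
  d <- deviant$data - standard$data
  out <- sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
  if (is.null(dim(out))) out <- matrix(out, nrow = dim(d)[1])
  rownames(out) <- standard$label_names
  attr(out, "times") <- evoked_times(standard)
  out
}

#' Build the subjects x labels x time MMR container from a cohort's evoked set
#'
#' @param evoked named list of [label_evoked()] (`<subject>.<condition>`).
#' @param groups data.frame (`subject_id`, `group`).
#' @return an [mmr_matrix()].
#' @export
compute_mmr_matrix <- function(evoked, groups) {
  ids <- groups$subject_id
  first <- evoked[[paste(ids[1], "standard", sep = ".")]]
  L <- dim(first$data)[1]; nt <- dim(first$data)[2]
  arr <- array(0, dim = c(length(ids), L, nt))
  for (i in seq_along(ids)) {
    std <- evoked[[paste(ids[i], "standard", sep = ".")]]
    dev <- evoked[[paste(ids[i], "deviant", sep = ".")]]
    if (is.null(std) || is.null(dev))
      stop("missing condition for subject '", ids[i], "'", call. = FALSE)
    arr[i, , ] <- compute_mmr(std, dev)
  }
  mmr_matrix(arr, ids, groups, first$time_start, first$sample_rate,
             first$label_names)
}

#' Average vertex-level vector time courses within labels
#'
#' Arithmetic mean per orientation component across the vertices of each
#' label, producing label-level vector time courses.
#'
#' @param vertex_level numeric array `vertices x time x 3`.
#' @param label_map integer or character vector, length `vertices`, mapping
#'   each vertex to its label.
#' @param subject_id,condition,time_start,sample_rate metadata for the
#'   resulting [label_evoked()].
#' @param label_names order of labels in the output; defaults to the sorted
#'   unique values of `label_map`. Every listed label must be non-empty.
#' @return a [label_evoked()] with one row per label.
#' @export
average_labels <- function(vertex_level, label_map, subject_id = "subject",
                           condition = "standard", time_start = 0,
                           sample_rate = 1, label_names = NULL) {
  stopifnot(is.array(vertex_level), length(dim(vertex_level)) == 3,
            dim(vertex_level)[3] == 3)
  if (length(label_map) != dim(vertex_level)[1])
    stop("label_map must map every vertex", call. = FALSE)
  if (is.null(label_names)) label_names <- sort(unique(as.character(label_map)))
  label_map <- as.character(label_map)
  out <- array(0, dim = c(length(label_names), dim(vertex_level)[2], 3))
  for (j in seq_along(label_names)) {
    v <- which(label_map == label_names[j])
    if (!length(v))
      stop("empty label '", label_names[j], "'", call. = FALSE)
    out[j, , ] <- apply(vertex_level[v, , , drop = FALSE], c(2, 3), mean)
  }
  label_evoked(out, subject_id, condition, time_start, sample_rate, label_names)
}

# Map a [start, end) window in seconds onto sample indices of a time axis.
window_indices <- function(times, window) {
  idx <- which(times >= window[1] - 1e-9 & times < window[2] - 1e-9)
  if (!length(idx))
    stop("empty window after discretization: [", window[1], ", ", window[2],
         ") contains no samples", call. = FALSE)
  idx
}

#' Mean MMR over an ROI and time window, per subject
#'
#' The window is closed on the left and open on the right on the sample
#' grid: samples with `window[1] <= t < window[2]` enter the mean.
#'
#' @param mmr an [mmr_matrix()].
#' @param roi_labels label indices (integer) or names (character).
#' @param window `c(start, end)` in seconds.
#' @return named numeric vector of per-subject means.
#' @export
roi_window_mean <- function(mmr, roi_labels, window) {
  stopifnot(inherits(mmr, "mmr_matrix"))
  if (is.character(roi_labels))
    roi_labels <- match(roi_labels, mmr$label_names)
  if (!length(roi_labels) || anyNA(roi_labels) ||
      any(roi_labels < 1 | roi_labels > length(mmr$label_names)))
    stop("roi_labels must be a non-empty set of valid labels", call. = FALSE)
  tidx <- window_indices(evoked_times(mmr), window)
  out <- apply(mmr$data[, roi_labels, tidx, drop = FALSE], 1, mean)
  names(out) <- mmr$subjects
  out
}

#' Natural log transform of positive MMR values
#'
#' @param x positive numeric values (window-averaged MMR magnitudes).
#' @param floor values at or below this raise an error (default `1e-12`)
#'   unless `clamp = TRUE`, in which case they are clamped to the floor
#'   before taking the log (for noisy real data that can reach 0).
#' @param clamp clamp instead of erroring (default FALSE).
#' @return `log(x)`.
#' @export
log_mmr <- function(x, floor = 1e-12, clamp = FALSE) {
  if (any(x <= floor)) {
    if (!clamp)
      stop("log_mmr: values at or below the floor (", floor,
           "); use clamp = TRUE for noisy data", call. = FALSE)
    x <- pmax(x, floor)
  }
  log(x)
}

#' Indices of standards immediately preceding each deviant
#'
#' @param sequence an [generate_oddball_sequence()] result, or a character
#'   vector over `"standard"`/`"deviant"`.
#' @return integer vector, one standard index per deviant (empty for an
#'   all-standard sequence).
#' @export
select_preceding_standards <- function(sequence) {
  labels <- if (inherits(sequence, "oddball_sequence"))
    sequence$trial_labels else as.character(sequence)
  dev <- which(labels == "deviant")
  if (!length(dev)) return(integer(0))
  if (dev[1] == 1)
    stop("deviant at position 1 has no preceding standard", call. = FALSE)
  pre <- dev - 1L
  if (any(labels[pre] != "standard"))
    stop("adjacent deviants: no immediately preceding standard", call. = FALSE)
  pre
}
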