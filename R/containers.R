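#' Label-level evoked response container
#'
#' One subject x one condition: a labels x time x 3 array of free-orientation
#' dipole vector time courses in source-estimate arbitrary units.
#'
#' @param data numeric array `n_labels x n_times x 3`, finite.
#' @param subject_id character scalar.
#' @param condition `"standard"` or `"deviant"`.
#' @param time_start epoch start in seconds (time of the first sample).
#' @param sample_rate sampling rate in Hz.
#' @param label_names character vector, length `n_labels`.
#' @return object of class `label_evoked`.
#' @export
label_evoked <- function(data, subject_id, condition, time_start, sample_rate,
                         label_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3 || dim(data)[3] != 3)
    stop("data must be a labels x time x 3 array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("data contains non-finite values", call. = FALSE)
  condition <- match.arg(condition, c("standard", "deviant"))
  if (is.null(label_names))
    label_names <- sprintf("label_%03d", seq_len(dim(data)[1]))
  if (length(label_names) != dim(data)[1])
    stop("label_names length does not match data", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), condition = condition,
                 data = data, time_start = as.numeric(time_start),
                 sample_rate = as.numeric(sample_rate),
                 label_names = as.character(label_names)),
            class = "label_evoked")
}

#' Time axis of an evoked or MMR container
#'
#' @param x a `label_evoked` or `mmr_matrix`.
#' @return numeric vector of sample times in seconds.
#' @export
evoked_times <- function(x) {
  nt <- if (inherits(x, "label_evoked")) dim(x$data)[2] else dim(x$data)[3]
  x$time_start + (seq_len(nt) - 1) / x$sample_rate
}

#' @export
print.label_evoked <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_evoked> subject %s, %s: %d labels x %d samples x 3, %g Hz, t0 = %g s\n",
              x$subject_id, x$condition, d[1], d[2], x$sample_rate, x$time_start))
  invisible(x)
}

#' Subjects x labels x time MMR magnitude container
#'
#' @param data nonnegative numeric array `n_subjects x n_labels x n_times`.
#' @param subjects character vector of subject ids (rows of `data`).
#' @param groups data.frame with columns `subject_id`, `group` covering all
#'   subjects.
#' @param time_start,sample_rate shared time metadata (seconds, Hz).
#' @param label_names character vector, length `n_labels`.
#' @return object of class `mmr_matrix`.
#' @export
mmr_matrix <- function(data, subjects, groups, time_start, sample_rate,
                       label_names = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(data < 0)) stop("MMR magnitudes must be >= 0", call. = FALSE)
  if (dim(data)[1] != length(subjects))
    stop("subjects length does not match data", call. = FALSE)
  if (!all(subjects %in% groups$subject_id))
    stop("groups table does not cover all subjects", call. = FALSE)
  if (is.null(label_names))
    label_names <- sprintf("label_%03d", seq_len(dim(data)[2]))
  structure(list(data = data, subjects = as.character(subjects),
                 groups = groups, time_start = as.numeric(time_start),
                 sample_rate = as.numeric(sample_rate),
                 label_names = as.character(label_names)),
            class = "mmr_matrix")
}

#' @export
print.mmr_matrix <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mmr_matrix> %d subjects x %d labels x %d samples, %g Hz, t0 = %g s\n",
              d[1], d[2], d[3], x$sample_rate, x$time_start))
  invisible(x)
}

#' Extract one group's slice of an `mmr_matrix`
#'
#' @param mmr an `mmr_matrix`.
#' @param group group label as in the groups table.
#' @return an `mmr_matrix` restricted to that group's subjects.
#' @export
mmr_group_slice <- function(mmr, group) {
  grp <- mmr$groups$group[match(mmr$subjects, mmr$groups$subject_id)]
  keep <- which(grp == group)
  if (!length(keep)) stop("no subjects in group '", group, "'", call. = FALSE)
  mmr_matrix(mmr$data[keep, , , drop = FALSE], mmr$subjects[keep],
             mmr$groups[mmr$groups$group == group, , drop = FALSE],
             mmr$time_start, mmr$sample_rate, mmr$label_names)
}
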