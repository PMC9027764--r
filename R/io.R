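# On-disk formats are plain text throughout: tabular outputs are TSV with
# documented headers, and array containers are long-format TSV whose
# metadata travel in leading `#key=value` comment lines. Values are written
# with %.17g so numeric round-trips are lossless.

.fmt_num <- function(x) sprintf("%.17g", x)

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a flat key = value configuration file
#'
#' INI-style sections (`[simulate]`, `[cluster_test]`, `[decode]`) of
#' `key = value` lines; blank lines and `#` comments ignored. Values are
#' parsed as numeric vectors when possible (comma-separated), else kept as
#' strings.
#'
#' @param path file path.
#' @return nested named list (one element per section).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  cfg <- list(); section <- "global"
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop("config parse error at line ", i, ": expected key = value",
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[section]][[key]] <- if (!anyNA(num)) num else parts
  }
  cfg
}

#' @rdname read_config
#' @param cfg nested named list of sections.
#' @export
write_config <- function(cfg, path) {
  out <- character(0)
  for (sec in names(cfg)) {
    out <- c(out, paste0("[", sec, "]"))
    for (key in names(cfg[[sec]])) {
      v <- cfg[[sec]][[key]]
      v <- if (is.numeric(v)) paste(.fmt_num(v), collapse = ", ")
           else paste(v, collapse = ", ")
      out <- c(out, paste(key, "=", v))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write / read a label-level evoked response as long-format TSV
#'
#' Header comment lines carry `#schema=label_evoked/1`, `#subject_id=`,
#' `#condition=`, `#time_start=`, `#sample_rate=`; columns are `label`,
#' `component` (1..3), `time_index` (1-based), `value`. Label order is
#' preserved (first-appearance order).
#'
#' @param evoked a [label_evoked()].
#' @param path output file.
#' @export
write_label_evoked <- function(evoked, path) {
  stopifnot(inherits(evoked, "label_evoked"))
  d <- dim(evoked$data)
  hdr <- c("#schema=label_evoked/1",
           paste0("#subject_id=", evoked$subject_id),
           paste0("#condition=", evoked$condition),
           paste0("#time_start=", .fmt_num(evoked$time_start)),
           paste0("#sample_rate=", .fmt_num(evoked$sample_rate)))
  # expand in label-major order so labels appear in container order
  grid <- expand.grid(time_index = seq_len(d[2]), component = 1:3,
                      label_i = seq_len(d[1]))
  val <- evoked$data[cbind(grid$label_i, grid$time_index, grid$component)]
  body <- data.frame(label = evoked$label_names[grid$label_i],
                     component = grid$component,
                     time_index = grid$time_index,
                     value = .fmt_num(val))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("label", "component", "time_index", "value"),
                   collapse = "\t"), con)
  writeLines(do.call(paste, c(body, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_label_evoked
#' @export
read_label_evoked <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#", "", h)
    meta[[sub("=.*$", "", kv)]] <- sub("^[^=]*=", "", kv)
  }
  for (field in c("schema", "subject_id", "condition", "time_start",
                  "sample_rate"))
    if (is.null(meta[[field]]))
      stop("corrupted label_evoked header: missing field '", field, "'",
           call. = FALSE)
  if (meta$schema != "label_evoked/1")
    stop("unsupported schema '", meta$schema, "'", call. = FALSE)
  body <- read.delim(text = lines[!grepl("^#", lines)],
                     stringsAsFactors = FALSE)
  need <- c("label", "component", "time_index", "value")
  if (!all(need %in% names(body)))
    stop("corrupted label_evoked body: missing column(s) ",
         paste(setdiff(need, names(body)), collapse = ", "), call. = FALSE)
  labels <- unique(body$label)
  nt <- max(body$time_index)
  arr <- array(NA_real_, dim = c(length(labels), nt, 3))
  arr[cbind(match(body$label, labels), body$time_index, body$component)] <-
    body$value
  if (anyNA(arr)) stop("corrupted label_evoked body: missing cells",
                       call. = FALSE)
  label_evoked(arr, meta$subject_id, meta$condition,
               as.numeric(meta$time_start), as.numeric(meta$sample_rate),
               labels)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `behavior.tsv` (subject_id, group, pair_type, trial_index,
#' response), `truth.tsv`, `truth_amplitudes.tsv` (subject_id, label,
#' amplitude), `adjacency.tsv` (label_a, label_b), `groups.tsv`, and
#' `evoked/<subject>_<condition>.tsv` containers.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mmr_cohort"))
  dir.create(file.path(dir, "evoked"), recursive = TRUE, showWarnings = FALSE)
  .write_tsv(cohort$behavior, file.path(dir, "behavior.tsv"))
  tr <- cohort$truth$subjects
  tr$sensitivity <- .fmt_num(tr$sensitivity)
  tr$criterion <- .fmt_num(tr$criterion)
  .write_tsv(tr, file.path(dir, "truth.tsv"))
  amps <- cohort$truth$amplitudes
  first <- cohort$evoked[[1]]
  long <- data.frame(
    subject_id = rep(cohort$groups$subject_id, each = ncol(amps)),
    label = rep(first$label_names, nrow(amps)),
    amplitude = .fmt_num(as.vector(t(amps))))
  .write_tsv(long, file.path(dir, "truth_amplitudes.tsv"))
  .write_tsv(cohort$adjacency, file.path(dir, "adjacency.tsv"))
  .write_tsv(cohort$groups, file.path(dir, "groups.tsv"))
  for (nm in names(cohort$evoked)) {
    ev <- cohort$evoked[[nm]]
    write_label_evoked(ev, file.path(dir, "evoked",
                                     paste0(ev$subject_id, "_",
                                            ev$condition, ".tsv")))
  }
  invisible(dir)
}

#' Write an MMR container / TFCE map / decode result as long TSV
#'
#' @param mmr an [mmr_matrix()].
#' @param path output file.
#' @export
write_mmr_tsv <- function(mmr, path) {
  stopifnot(inherits(mmr, "mmr_matrix"))
  d <- dim(mmr$data)
  grid <- expand.grid(time_index = seq_len(d[3]), label_i = seq_len(d[2]),
                      subject_i = seq_len(d[1]))
  df <- data.frame(subject_id = mmr$subjects[grid$subject_i],
                   label = mmr$label_names[grid$label_i],
                   time_index = grid$time_index,
                   mmr = .fmt_num(mmr$data[cbind(grid$subject_i, grid$label_i,
                                                 grid$time_index)]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#schema=mmr_matrix/1",
               paste0("#time_start=", .fmt_num(mmr$time_start)),
               paste0("#sample_rate=", .fmt_num(mmr$sample_rate))), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_mmr_tsv
#' @param map a `tfce_map`.
#' @export
write_tfce_tsv <- function(map, path) {
  stopifnot(inherits(map, "tfce_map"))
  L <- nrow(map$stat); Tn <- ncol(map$stat)
  grid <- expand.grid(label = seq_len(L), time_index = seq_len(Tn))
  df <- data.frame(label = grid$label, time_index = grid$time_index,
                   t = .fmt_num(map$stat[as.matrix(grid)]),
                   tfce = .fmt_num(map$tfce[as.matrix(grid)]),
                   p = .fmt_num(map$p[as.matrix(grid)]),
                   neg_log10_p = .fmt_num(map$neg_log10_p[as.matrix(grid)]))
  .write_tsv(df, path)
}
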