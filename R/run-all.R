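#' Default end-to-end pipeline configuration
#'
#' Flat sections suitable for the `key = value` config file: `[simulate]`
#' (scalar generator knobs; ROI label sets are derived from `n_labels` by
#' the default atlas layout), `[cluster_test]` (TFCE permutation test), and
#' `[decode]` (time-resolved SVR). The ROI regression window is the
#' `[roi] window`.
#'
#' @return nested named list.
#' @export
default_run_config <- function() {
  list(
    simulate = list(n_per_group = 15, n_labels = 150,
                    epoch_window = c(-0.1, 0.9), sample_rate = 200,
                    noise_sd = 0.5, n_trials_per_pairing = 10),
    roi = list(window = c(0.2, 0.5)),
    cluster_test = list(n_perm = 1024, E = 0.5, H = 2, statistic = "t"),
    decode = list(n_perm_per_time = 100, percentile = 0.99,
                  cost = 1.0, epsilon = 0.1, final_features = "mean")
  )
}

.required_run_keys <- list(
  simulate = c("n_per_group", "n_labels", "epoch_window", "sample_rate",
               "noise_sd", "n_trials_per_pairing"),
  roi = "window",
  cluster_test = c("n_perm", "E", "H", "statistic"),
  decode = c("n_perm_per_time", "percentile", "cost", "epsilon",
             "final_features")
)

validate_run_config <- function(config) {
  for (sec in names(.required_run_keys)) {
    if (is.null(config[[sec]]))
      stop("config validation error: missing section [", sec, "]",
           call. = FALSE)
    missing <- setdiff(.required_run_keys[[sec]], names(config[[sec]]))
    if (length(missing))
      stop("config validation error: section [", sec, "] missing key(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

.log_stage <- function(stage, msg, quiet = FALSE) {
  if (!quiet)
    message(sprintf("[%s] %s | %s", stage,
                    format(Sys.time(), "%H:%M:%S"), msg))
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> score-behavior -> compute-mmr -> cluster-test -> roi-regress
#' -> svr-decode (per group), writing every stage's TSV outputs and a
#' deterministic JSON run manifest (tool version, config snapshot, master
#' and per-stage child seeds, md5 checksum of every output file; no wall
#' clock enters the manifest, so identical seeds yield byte-identical
#' manifests).
#'
#' @param config nested list as from [default_run_config()] or
#'   [read_config()].
#' @param seed master seed; every stage's randomness derives from it.
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return the manifest (invisibly), also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_all <- function(config = default_run_config(), seed = 1L, out_dir,
                    quiet = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    .log_stage(name, "start", quiet)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seeds <- list(simulate = child_seed(seed, 1),
                cluster_test = child_seed(seed, 2),
                decode_nonnative = child_seed(seed, 3),
                decode_native = child_seed(seed, 4))

  sc <- config$simulate
  cohort <- stage("simulate", {
    cfg <- sim_config(n_per_group = sc$n_per_group, n_labels = sc$n_labels,
                      epoch_window = sc$epoch_window,
                      sample_rate = sc$sample_rate, noise_sd = sc$noise_sd,
                      n_trials_per_pairing = sc$n_trials_per_pairing,
                      seed = seeds$simulate)
    co <- simulate_cohort(cfg)
    write_cohort(co, out_dir)
    co
  })

  scores <- stage("score-behavior", {
    s <- score_ax(cohort$behavior)
    out <- s
    for (col in c("hit_rate", "fa_rate", "dprime", "criterion"))
      out[[col]] <- .fmt_num(out[[col]])
    .write_tsv(out, file.path(out_dir, "scores.tsv"))
    s
  })

  mmr <- stage("compute-mmr", {
    m <- compute_mmr_matrix(cohort$evoked, cohort$groups)
    write_mmr_tsv(m, file.path(out_dir, "mmr.tsv"))
    m
  })

  ct <- config$cluster_test
  stage("cluster-test", {
    grp <- mmr$groups$group[match(mmr$subjects, mmr$groups$subject_id)]
    map <- tfce_permutation_test(
      mmr$data[grp == "nonnative", , , drop = FALSE],
      mmr$data[grp == "native", , , drop = FALSE],
      cohort$adjacency, n_perm = ct$n_perm, seed = seeds$cluster_test,
      E = ct$E, H = ct$H, statistic = ct$statistic)
    write_tfce_tsv(map, file.path(out_dir, "tfce_map.tsv"))
  })

  stage("roi-regress", {
    fits <- roi_regression_suite(mmr, scores, cohort$config$roi_label_ids,
                                 window = config$roi$window)
    rows <- do.call(rbind, lapply(fits, function(f) {
      data.frame(roi = f$roi, r_squared = .fmt_num(f$r_squared),
                 f_p_value = .fmt_num(f$f_p_value),
                 interaction_b = .fmt_num(f$coefficients$estimate[4]),
                 interaction_p = .fmt_num(f$coefficients$p[4]),
                 slope_nonnative = .fmt_num(f$simple_slopes$slope[1]),
                 slope_native = .fmt_num(f$simple_slopes$slope[2]))
    }))
    .write_tsv(rows, file.path(out_dir, "roi_regression.tsv"))
  })

  dc <- config$decode
  for (g in c("nonnative", "native")) stage(paste0("svr-decode-", g), {
    slice <- mmr_group_slice(mmr, g)
    dp <- scores$dprime[match(slice$subjects, scores$subject_id)]
    res <- decode_pipeline(slice, dp, n_perm_per_time = dc$n_perm_per_time,
                           percentile = dc$percentile,
                           seed = seeds[[paste0("decode_", g)]],
                           cost = dc$cost, epsilon = dc$epsilon,
                           final_features = dc$final_features)
    .write_tsv(data.frame(time_index = seq_along(res$r2_timecourse),
                          r2 = .fmt_num(res$r2_timecourse)),
               file.path(out_dir, paste0("decode_", g, "_r2.tsv")))
    .write_tsv(data.frame(r2_null = .fmt_num(res$null_pool)),
               file.path(out_dir, paste0("decode_", g, "_null.tsv")))
    if (res$final$significant)
      .write_tsv(data.frame(label = names(res$final$weight_map),
                            weight = .fmt_num(res$final$weight_map)),
                 file.path(out_dir, paste0("decode_", g, "_weights.tsv")))
    summ <- list(group = g, threshold = res$threshold,
                 significant_times = res$significant_times,
                 pearson_r = res$final$pearson_r,
                 p_one_sided = res$final$p_one_sided,
                 r_squared = res$final$r_squared,
                 svr_params = res$svr_params)
    jsonlite::write_json(summ, file.path(out_dir,
                                         paste0("decode_", g, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  manifest <- stage("manifest", {
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          "manifest.json"))
    checks <- vapply(files, function(f)
      digest::digest(file.path(out_dir, f), algo = "md5", file = TRUE),
      character(1))
    man <- list(tool = "mmrlink",
                version = as.character(packageVersion("mmrlink")),
                schema = "run_manifest/1",
                master_seed = as.integer(seed),
                child_seeds = seeds,
                config = config,
                checksums = as.list(checks))
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })
  .log_stage("done", paste("outputs in", out_dir), quiet)
  invisible(manifest)
}
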