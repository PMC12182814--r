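# Pipeline driver: configuration, stage runners, run manifests. Stages
# mirror the analysis flow: phantom -> strain -> dyssynchrony (per-slice
# mechanics on synthetic cines), cohort -> cluster -> survive (cohort-level
# phenotyping and outcomes), report (figures), all (the full chain).

#' Default pipeline configuration
#'
#' Returns the full nested configuration with every tunable option at its
#' default. Configurations loaded from YAML are validated against this
#' structure: unknown keys are rejected.
#'
#' @param seed master RNG seed used by every stochastic stage.
#' @return nested named list of class `lv_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    alpha = 0.01,
    phantom = list(
      grid_size = 128L, pixel_spacing_mm = 0.5, n_frames = 40L,
      frame_duration_ms = 25, r_endo0_mm = 20, r_epi0_mm = 28,
      contraction_fraction = 0.25, activation_delay_ms = 0,
      noise_sd_mm_s = 0
    ),
    metrics = list(
      srcc_agg = "mean",          # mean|max absolute pairwise lag
      rure_variant = "summed",    # summed|framewise Fourier ratio
      global_rs = "peak_of_mean"  # peak_of_mean|mean_of_peaks
    ),
    cohort = list(
      n_per_phenotype = c(39L, 29L, 56L, 74L),
      base_hazard_per_month = 0.004,
      log_hr = c(log(2.69), 0, 0, 0),
      censor_window_months = 160
    ),
    clustering = list(
      k_range = 2:8,
      include_max_ttp = FALSE,
      gap_B = 25L
    ),
    survival = list(
      scaling = "sd",             # sd|unit covariate scaling
      exclude_prior_pvr = FALSE,
      covariates = c("cluster1_flag", "LVEDVi", "gRS", "LVEF",
                     "LVSVi", "LVESVi")
    )
  ), class = "lv_config")
}

#' Load and validate a YAML pipeline configuration
#'
#' Values present in the file override the defaults; keys not present in
#' [default_config()] are rejected.
#'
#' @param path YAML file.
#' @param seed default seed if the file does not set one.
#' @return an `lv_config` list.
#' @export
load_config <- function(path, seed = 1L) {
  cfg <- default_config(seed)
  user <- yaml::read_yaml(path)
  merge_in <- function(base, upd, prefix = "") {
    for (key in names(upd)) {
      if (!key %in% names(base))
        .stopf("unknown configuration key: %s%s", prefix, key)
      if (is.list(base[[key]]) && is.list(upd[[key]])) {
        base[[key]] <- merge_in(base[[key]], upd[[key]],
                                paste0(prefix, key, "."))
      } else {
        base[[key]] <- upd[[key]]
      }
    }
    base
  }
  structure(merge_in(unclass(cfg), user), class = "lv_config")
}

# stage manifest: package/R versions, seed, config hash, input hashes,
# row counts. No timestamps, so reruns are byte-identical.
.write_manifest <- function(stage, config, out_dir, inputs = character(),
                            counts = list()) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    stage = stage,
    package = "lvmech",
    package_version = as.character(utils::packageVersion("lvmech")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = .md5_string(cfg_json),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[%s] out=%s %s", stage, out_dir,
                  paste(names(counts), unlist(counts), sep = "=", collapse = " ")))
  invisible(manifest)
}

.md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# echo the configuration into the output directory
.echo_config <- function(config, out_dir) {
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
}

#' Run one pipeline stage
#'
#' Stages: `"phantom"` (write 3-slice synthetic cine bundles), `"strain"`
#' (cine bundles -> segmental curves and summaries), `"dyssynchrony"`
#' (curves -> per-slice metrics and the patient feature row), `"cohort"`
#' (synthetic cohort + survival tables), `"cluster"` (standardize, majority-
#' vote k, Ward labels, characterization, figures), `"survive"` (KM,
#' pairwise log-rank, Cox, figures), `"report"` (cohort-level bulls-eye
#' figures), `"all"` (the full chain). Every stage writes its CSV outputs
#' and a JSON run manifest into `out_dir`.
#'
#' @param stage stage name.
#' @param config an `lv_config` (see [default_config()], [load_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the stage's main in-memory results.
#' @export
run_pipeline <- function(stage = c("all", "phantom", "strain", "dyssynchrony",
                                   "cohort", "cluster", "survive", "report"),
                         config = default_config(), out_dir = "lvmech_out") {
  stage <- match.arg(stage)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .echo_config(config, out_dir)
  switch(stage,
    phantom = .stage_phantom(config, out_dir),
    strain = .stage_strain(config, out_dir),
    dyssynchrony = .stage_dyssynchrony(config, out_dir),
    cohort = .stage_cohort(config, out_dir),
    cluster = .stage_cluster(config, out_dir),
    survive = .stage_survive(config, out_dir),
    report = .stage_report(config, out_dir),
    all = {
      res <- list()
      for (s in c("phantom", "strain", "dyssynchrony", "cohort",
                  "cluster", "survive", "report"))
        res[[s]] <- run_pipeline(s, config, out_dir)
      invisible(res)
    })
}

.stage_phantom <- function(config, out_dir) {
  p <- config$phantom
  res <- list()
  for (lv in c("apical", "mid", "basal")) {
    spec <- phantom_spec(
      grid_size = p$grid_size, pixel_spacing_mm = p$pixel_spacing_mm,
      n_frames = p$n_frames, frame_duration_ms = p$frame_duration_ms,
      r_endo0_mm = p$r_endo0_mm, r_epi0_mm = p$r_epi0_mm,
      contraction_fraction = p$contraction_fraction,
      activation_delay_ms = p$activation_delay_ms,
      noise_sd_mm_s = p$noise_sd_mm_s,
      seed = config$seed, slice_level = lv)
    ph <- generate_phantom(spec)
    dir <- file.path(out_dir, "phantom", lv)
    write_cine_bundle(ph$cine, dir, truth = ph$truth,
                      extra_meta = list(seed = config$seed))
    res[[lv]] <- ph
  }
  .write_manifest("phantom", config, out_dir,
                  counts = list(slices = 3L))
  invisible(res)
}

.stage_strain <- function(config, out_dir) {
  curves_all <- list(); summary_all <- list(); res <- list()
  for (lv in c("apical", "mid", "basal")) {
    bundle <- read_cine_bundle(file.path(out_dir, "phantom", lv))
    an <- analyze_cine(bundle$cine,
                       global = config$metrics$global_rs,
                       srcc_agg = config$metrics$srcc_agg,
                       rure_variant = config$metrics$rure_variant)
    curves_all[[lv]] <- as.data.frame(an$curves)
    sm <- an$summary$segments
    sm <- rbind(sm, data.frame(slice = lv, segment = "global",
                               peak_RS_pct = an$summary$global_RS_pct,
                               TTP_ms = NA_real_))
    summary_all[[lv]] <- sm
    res[[lv]] <- an
  }
  .write_csv(do.call(rbind, curves_all), file.path(out_dir, "curves.csv"))
  .write_csv(do.call(rbind, summary_all), file.path(out_dir, "summary.csv"))
  .write_manifest("strain", config, out_dir,
                  inputs = file.path(out_dir, "phantom",
                                     c("apical", "mid", "basal"), "meta.json"),
                  counts = list(rows = sum(vapply(curves_all, nrow, 1L))))
  invisible(res)
}

# rebuild segment_curves objects from curves.csv rows of one slice
.curves_from_df <- function(df) {
  segs <- unique(df$segment)
  nf <- length(unique(df$frame))
  strain <- matrix(df$strain, nrow = length(segs), byrow = TRUE,
                   dimnames = list(segs, NULL))
  rate <- matrix(df$strain_rate, nrow = length(segs), byrow = TRUE)
  dt <- diff(sort(unique(df$time_ms)))[1]
  structure(list(strain = strain, strain_rate = rate,
                 times_ms = sort(unique(df$time_ms)), frame_duration_ms = dt,
                 labels = segs, n_px = rep(1L, length(segs)),
                 slice_level = df$slice[1], channel = "radial"),
            class = "segment_curves")
}

.stage_dyssynchrony <- function(config, out_dir) {
  curves <- utils::read.csv(file.path(out_dir, "curves.csv"))
  out <- list()
  for (lv in unique(curves$slice)) {
    sc <- .curves_from_df(curves[curves$slice == lv, ])
    out[[lv]] <- slice_metrics(sc, srcc_agg = config$metrics$srcc_agg,
                               rure_variant = config$metrics$rure_variant)
  }
  dys <- do.call(rbind, out)
  .write_csv(dys, file.path(out_dir, "dyssynchrony.csv"))
  .write_manifest("dyssynchrony", config, out_dir,
                  inputs = file.path(out_dir, "curves.csv"),
                  counts = list(slices = nrow(dys)))
  invisible(dys)
}

.stage_cohort <- function(config, out_dir) {
  spec <- cohort_spec(
    n_per_phenotype = config$cohort$n_per_phenotype,
    base_hazard_per_month = config$cohort$base_hazard_per_month,
    log_hr = config$cohort$log_hr,
    censor_window_months = config$cohort$censor_window_months,
    seed = config$seed)
  gen <- generate_cohort(spec)
  .write_csv(gen$cohort, file.path(out_dir, "cohort.csv"))
  .write_csv(gen$survival, file.path(out_dir, "survival.csv"))
  .write_manifest("cohort", config, out_dir,
                  counts = list(patients = nrow(gen$cohort),
                                events = sum(gen$survival$event)))
  invisible(gen)
}

.stage_cluster <- function(config, out_dir) {
  cohort <- utils::read.csv(file.path(out_dir, "cohort.csv"))
  feats <- lv_feature_names()
  std <- standardize_features(cohort[, feats])
  sel <- select_k(std$z, k_range = config$clustering$k_range,
                  gap_B = config$clustering$gap_B, seed = config$seed)
  ward <- ward_cluster(std$z, sel$chosen_k)
  labels_df <- data.frame(patient_id = cohort$patient_id[std$kept],
                          label = ward$labels)
  .write_csv(labels_df, file.path(out_dir, "labels.csv"))
  .write_csv(data.frame(index = names(sel$votes), k = as.integer(sel$votes)),
             file.path(out_dir, "votes.csv"))
  .write_csv(data.frame(step = seq_len(nrow(ward$tree$merge)),
                        left = ward$tree$merge[, 1],
                        right = ward$tree$merge[, 2],
                        height = ward$tree$height),
             file.path(out_dir, "linkage.csv"))
  ch <- characterize_clusters(cohort[std$kept, ], ward$labels,
                              vars = setdiff(names(cohort),
                                             c("patient_id", "true_label")),
                              alpha = config$alpha)
  .write_csv(ch$summary, file.path(out_dir, "cluster_summary.csv"))

  grDevices::png(file.path(out_dir, "fig_heatmap.png"), 1200, 900, res = 120)
  plot_cluster_heatmap(std$z, ward$tree, ward$labels)
  grDevices::dev.off()
  for (g in sort(unique(ward$labels))) {
    vals <- colMeans(cohort[std$kept, feats][ward$labels == g,
                                             grep("^peakRS_", feats)])
    grDevices::png(file.path(out_dir, sprintf("fig_bullseye_cluster%d.png", g)),
                   700, 700, res = 110)
    plot_bullseye(vals, title = sprintf("Cluster %d mean peak RS (%%)", g))
    grDevices::dev.off()
  }
  .write_manifest("cluster", config, out_dir,
                  inputs = file.path(out_dir, "cohort.csv"),
                  counts = list(patients = nrow(labels_df),
                                chosen_k = sel$chosen_k))
  invisible(list(selection = sel, ward = ward, characterization = ch))
}

.stage_survive <- function(config, out_dir) {
  surv <- utils::read.csv(file.path(out_dir, "survival.csv"))
  labels_path <- file.path(out_dir, "labels.csv")
  if (file.exists(labels_path)) {
    labels_df <- utils::read.csv(labels_path)
    cohort <- utils::read.csv(file.path(out_dir, "cohort.csv"))
    surv <- merge(surv, labels_df, by = "patient_id")
    cohort <- merge(cohort, labels_df, by = "patient_id")
    # the "cluster 1"-like phenotype: the discovered cluster with the lowest
    # mean mid anteroseptal peak strain (severe septal dysfunction)
    septal <- tapply(cohort$peakRS_mid_anteroseptal, cohort$label, mean)
    c1 <- as.integer(names(septal)[which.min(septal)])
    surv$cluster1_flag <- as.integer(surv$label == c1)
    group <- surv$label
  } else {
    group <- surv$true_label
  }
  if (isTRUE(config$survival$exclude_prior_pvr) &&
      "prior_pvr" %in% names(surv)) {
    keep <- surv$prior_pvr == 0
    surv <- surv[keep, ]; group <- group[keep]
  }
  km <- km_estimate(surv, group)
  lr <- logrank_pairwise(surv, group)
  fit <- cox_fit(surv, config$survival$covariates,
                 scaling = config$survival$scaling)
  .write_csv(km, file.path(out_dir, "km.csv"))
  lr_df <- as.data.frame(as.table(lr$p_value))
  names(lr_df) <- c("group1", "group2", "p_value")
  .write_csv(lr_df[!is.na(lr_df$p_value), ], file.path(out_dir, "logrank.csv"))
  .write_csv(fit$table, file.path(out_dir, "cox.csv"))
  grDevices::png(file.path(out_dir, "fig_km.png"), 900, 700, res = 110)
  plot_km(km)
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "fig_forest.png"), 900, 600, res = 110)
  plot_forest(fit)
  grDevices::dev.off()
  .write_manifest("survive", config, out_dir,
                  inputs = file.path(out_dir, "survival.csv"),
                  counts = list(patients = nrow(surv),
                                events = sum(surv$event)))
  invisible(list(km = km, logrank = lr, cox = fit))
}

.stage_report <- function(config, out_dir) {
  cohort_path <- file.path(out_dir, "cohort.csv")
  if (file.exists(cohort_path)) {
    cohort <- utils::read.csv(cohort_path)
    vals <- colMeans(cohort[, grep("^peakRS_", names(cohort))])
    grDevices::png(file.path(out_dir, "fig_bullseye_cohort.png"),
                   700, 700, res = 110)
    plot_bullseye(vals, title = "Cohort mean peak RS (%)")
    grDevices::dev.off()
  }
  .write_manifest("report", config, out_dir,
                  inputs = cohort_path, counts = list())
  invisible(NULL)
}
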