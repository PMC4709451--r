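# End-to-end driver: simulate -> (localize) -> register -> driftcorr ->
# render -> measure, in one reproducible, fully configured run.

#' Pipeline configuration
#'
#' All stage parameters in one place.  Defaults are the published analysis
#' settings: 101-frame temporal median window, 132 nm camera pixels,
#' 10 nm reconstruction raster, 10 nm display blur, 300 nm line width,
#' 10 nm histogram/profile bins, top fraction q = 0.40.
#'
#' @param ... overrides for any default listed below.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # simulate
    n_synapses = 50,
    separation_nm = 100,
    axis = NULL,
    shape_a = shape_bar(300, 300, 40),
    shape_b = shape_bar(300, 300, 60),
    n_labels_a = 40, n_labels_b = 40,
    linkage_sd_nm = 10,
    field_size_nm = 40000,
    loc_precision_sd = 10,
    mean_locs_per_label = 20,
    n_frames = 30000,
    # drift (simulated + corrected when drift_slope != c(0,0))
    drift_slope_nm_per_frame = c(0, 0),
    rcc_segments = 10,
    rcc_bin_nm = 10,
    # registration: true channel-2 shift applied to simulated channel 2,
    # recovered from simulated bead tables
    channel2_shift_nm = c(0, 0),
    n_beads = 8,
    bead_jitter_sd_nm = 0,
    transform_kind = "affine",
    # localization (movie path; fast path skips these)
    pixel_size_nm = 132,
    median_window = 101,
    threshold_k = 5,
    qc = qc_filter(),
    # render
    raster_nm = 10,
    blur_sigma_nm = 10,
    # measure
    line_width_nm = 300,
    line_length_nm = 1200,
    profile_bin_nm = 10,
    hist_bin_nm = 10,
    q = 0.40)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  modifyList(cfg, over)
}

#' Run the fast-path pipeline end to end
#'
#' Simulates a synapse field and per-channel localization tables, injects
#' and (via beads / RCC) removes the configured channel shift and drift,
#' renders per-channel super-resolution images, measures per-synapse 1D
#' COM distances over truth-derived line ROIs, and applies the
#' top-fraction estimator.  When `out_dir` is given, all tables, models
#' and a JSON summary + manifest are written there; identical config and
#' seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created; must not exist).
#' @return invisible list: `truths`, `table` (processed), `distances`,
#'   `estimate` (an `estimator_result`), `sweep`, `transform`, `trace`,
#'   `images`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  seed <- config$seed
  scfg <- synapse_config(
    separation_nm = config$separation_nm, axis = config$axis,
    shape_a = config$shape_a, shape_b = config$shape_b,
    n_labels_a = config$n_labels_a, n_labels_b = config$n_labels_b,
    linkage_sd_nm = config$linkage_sd_nm,
    field_size_nm = config$field_size_nm)
  truths <- make_synapse_population(scfg, config$n_synapses,
                                    derive_seed(seed, "truth"))
  tabs <- lapply(truths, function(tr) {
    lab <- sample_labels(tr, derive_seed(seed, paste0("labels", tr$id)))
    tab <- emit_localization_table(
      lab, loc_precision_sd = config$loc_precision_sd,
      mean_locs_per_label = config$mean_locs_per_label,
      n_frames = config$n_frames,
      rng_seed = derive_seed(seed, paste0("locs", tr$id)))
    tab$synapse_id <- tr$id
    tab
  })
  table <- do.call(rbind, tabs)

  # inject channel-2 misalignment and sample drift
  shift2 <- config$channel2_shift_nm
  ch2 <- table$channel == 2
  table$x_nm[ch2] <- table$x_nm[ch2] + shift2[1]
  table$y_nm[ch2] <- table$y_nm[ch2] + shift2[2]
  drift <- drift_program(config$drift_slope_nm_per_frame)
  dsh <- drift$shift(table$frame)
  table$x_nm <- table$x_nm + dsh[, 1]
  table$y_nm <- table$y_nm + dsh[, 2]

  # registration from simulated bead tables
  set.seed(derive_seed(seed, "beads"))
  beads1 <- cbind(runif(config$n_beads, 0, config$field_size_nm),
                  runif(config$n_beads, 0, config$field_size_nm))
  beads2 <- sweep(beads1, 2, shift2, "+")
  if (config$bead_jitter_sd_nm > 0)
    beads2 <- beads2 + matrix(rnorm(length(beads2),
                                    sd = config$bead_jitter_sd_nm),
                              ncol = 2)
  transform <- fit_channel_transform(beads1, beads2,
                                     kind = config$transform_kind)
  tab2 <- apply_transform(table[ch2, , drop = FALSE], transform)
  table <- rbind(table[!ch2, , drop = FALSE], tab2)
  table <- table[order(table$frame), , drop = FALSE]
  rownames(table) <- NULL

  # drift correction
  trace <- NULL
  if (any(config$drift_slope_nm_per_frame != 0)) {
    trace <- estimate_drift_rcc(table, config$rcc_segments, config$rcc_bin_nm)
    table <- correct_drift(table, trace)
  }

  images <- lapply(c(1, 2), function(ch) {
    img <- render_sr_image(table[table$channel == ch, , drop = FALSE],
                           raster_nm = config$raster_nm, channel = ch)
    list(raw = img,
         display = sr_gaussian_blur(img, config$blur_sigma_nm))
  })

  rois <- rois_from_truth(truths, length_nm = config$line_length_nm,
                          width_nm = config$line_width_nm)
  distances <- measure_line_distances(table, rois,
                                      bin_nm = config$profile_bin_nm)
  estimate <- top_fraction_mean(distances$distance_nm, q = config$q,
                                hist_bin_nm = config$hist_bin_nm)
  sweep_tab <- cutoff_sweep(distances$distance_nm)

  result <- list(truths = truths, table = table, distances = distances,
                 estimate = estimate, sweep = sweep_tab,
                 transform = transform, trace = trace, images = images)

  if (!is.null(out_dir)) {
    if (dir.exists(out_dir)) stop("output directory already exists: ", out_dir)
    dir.create(out_dir, recursive = TRUE)
    write_localizations(table, file.path(out_dir, "localizations.csv"))
    truth_df <- do.call(rbind, lapply(truths, function(tr) {
      ctr <- true_population_centers(tr)
      data.frame(synapse_id = tr$id,
                 true_com_ax_nm = ctr$a[1], true_com_ay_nm = ctr$a[2],
                 true_com_bx_nm = ctr$b[1], true_com_by_nm = ctr$b[2],
                 axis_x = tr$axis[1], axis_y = tr$axis[2],
                 axis_z = tr$axis[3], separation_nm = tr$separation_nm)
    }))
    data.table::fwrite(truth_df, file.path(out_dir, "truth.csv"))
    data.table::fwrite(distances, file.path(out_dir, "distances.csv"))
    write_model_json(transform, file.path(out_dir, "transform.json"))
    if (!is.null(trace))
      write_model_json(trace, file.path(out_dir, "drift_trace.json"))
    write_rois_json(rois, file.path(out_dir, "rois.json"))
    summary <- list(
      mean_distance_nm = estimate$mean_distance_nm,
      sem_nm = estimate$sem_nm, n_total = estimate$n_total,
      n_used = estimate$n_used, q = estimate$fraction_q,
      histogram = estimate$histogram,
      cutoff_sweep = sweep_tab)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    manifest <- list(
      package = "synstorm",
      version = as.character(packageVersion("synstorm")),
      seed = seed,
      config = config_serializable(config),
      config_hash = config_hash(config),
      created = "run manifest (timestamp omitted for byte-determinism)")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}

config_serializable <- function(config) {
  lapply(config, function(v) {
    if (inherits(v, "synapse_shape") || inherits(v, "qc_filter")) unclass(v)
    else v
  })
}

config_hash <- function(config) {
  s <- paste(deparse(config_serializable(config)), collapse = "")
  # small rolling hash; stable across sessions, no external digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
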