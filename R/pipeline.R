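stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full multi-vital pipeline on a phantom recording
#'
#' Generates the MWIR and LWIR phantom stacks and the PPG trace for the
#' given configuration, then executes every analysis stage: breath
#' visualization (mean subtraction), respiratory rate (time and frequency
#' domain, MWIR, with the LWIR bilateral-nostril average and the PPG as
#' references), inner-canthus segmentation and body temperature, heart
#' rate from the canthus pulse signal, and STIV airflow velocity / flow
#' volume / CO2 volume per nostril. Deterministic given `config$seed`.
#'
#' @param config a [phantom_config()].
#' @param resp_band,pulse_band passbands in Hz.
#' @param threshold_c absolute canthus segmentation threshold (degC); when
#'   `NULL` the `threshold_pct` percentile of the mean image is used.
#' @param threshold_pct percentile threshold, see [segment_hottest()].
#' @param co2_fraction CO2 volume fraction of exhaled air.
#' @param median_window,n_bins STIV parameters, see [stiv_velocity()].
#' @param outdir optional directory; when given, the report is written to
#'   `report.json` and the effective configuration to `config.yaml` there.
#' @return A nested list report carrying every estimate together with the
#'   full effective configuration.
#' @export
run_pipeline <- function(config = phantom_config(),
                         resp_band = c(0.1, 0.4), pulse_band = c(0.8, 1.5),
                         threshold_c = NULL, threshold_pct = 99.5,
                         co2_fraction = 0.04, median_window = 5L,
                         n_bins = 720L, outdir = NULL) {
  stopifnot(inherits(config, "PhantomConfig"))
  rois <- phantom_rois(config)
  mwir <- stage("simulate", generate_mwir_phantom(config))
  lwir <- stage("simulate", generate_lwir_phantom(config))
  ppg <- stage("simulate", generate_ppg(config))
  windows <- mwir$truth$exhalation_windows

  viz <- stage("visualize", mean_subtract(mwir$stack))

  resp <- stage("respiration", {
    mw_sig <- invert(extract_roi_signal(viz, rois$plume, "MWIR exhalation"))
    ref_sig <- average_bilateral(
      extract_roi_signal(lwir$stack, rois$nostrils[[1]], "nostril R"),
      extract_roi_signal(lwir$stack, rois$nostrils[[2]], "nostril L"))
    list(td = estimate_rate(mw_sig, resp_band, "time_domain"),
         fd = estimate_rate(mw_sig, resp_band, "frequency_domain"),
         reference_td = estimate_rate(ref_sig, resp_band, "time_domain"),
         ppg_td = estimate_rate(ppg, resp_band, "time_domain"))
  })

  temp <- stage("temperature", {
    mask <- segment_hottest(temporal_mean_image(mwir$stack),
                            threshold_c = threshold_c,
                            threshold_pct = threshold_pct)
    list(mask = mask, body_temp_C = body_temperature(mwir$stack, mask))
  })

  heart <- stage("heartrate", {
    csig <- canthus_signal(mwir$stack, temp$mask)
    list(td = estimate_rate(csig, pulse_band, "time_domain"),
         ppg_td = estimate_rate(ppg, pulse_band, "time_domain"))
  })

  stiv <- stage("stiv", {
    per_nostril <- lapply(1:2, function(i) {
      sv <- stiv_velocity(mwir$stack, rois$lines[[i]], windows,
                          median_window = median_window, n_bins = n_bins)
      est <- flow_estimate(sv$u_mean, config$nostril_area_m2[i],
                           theta_deg = sv$theta_mean,
                           co2_fraction = co2_fraction)
      list(estimate = est, per_window_u = sv$u, per_window_theta = sv$theta_deg)
    })
    co2_total <- per_nostril[[1]]$estimate$V_CO2 +
      per_nostril[[2]]$estimate$V_CO2
    list(right = per_nostril[[1]], left = per_nostril[[2]],
         co2_total_m3_per_s = co2_total,
         co2_total_m3_per_h = per_hour(co2_total))
  })

  report <- list(
    package_version = as.character(utils::packageVersion("mwirvitals")),
    config = unclass(config),
    parameters = list(resp_band_hz = resp_band, pulse_band_hz = pulse_band,
                      threshold_c = threshold_c,
                      threshold_pct = threshold_pct,
                      co2_fraction = co2_fraction,
                      median_window = median_window, n_bins = n_bins),
    truth = list(resp_rate_bpm = mwir$truth$resp_rate_bpm,
                 heart_rate_bpm = mwir$truth$heart_rate_bpm,
                 body_temp_C = mwir$truth$body_temp_C,
                 plume_velocity_m_per_s = mwir$truth$plume_velocity_m_per_s),
    respiration = list(
      td_bpm = resp$td$rate_bpm, fd_bpm = resp$fd$rate_bpm,
      fd_bin_width_hz = resp$fd$bin_width_hz,
      reference_td_bpm = resp$reference_td$rate_bpm,
      ppg_td_bpm = resp$ppg_td$rate_bpm),
    temperature = list(body_temp_C = temp$body_temp_C,
                       mask_px = sum(temp$mask$mask),
                       mask_components = temp$mask$component_count,
                       threshold = temp$mask$source_threshold),
    heart = list(td_bpm = heart$td$rate_bpm,
                 ppg_td_bpm = heart$ppg_td$rate_bpm),
    stiv = list(
      u_right_m_per_s = stiv$right$estimate$U,
      u_left_m_per_s = stiv$left$estimate$U,
      theta_right_deg = stiv$right$estimate$theta_deg,
      theta_left_deg = stiv$left$estimate$theta_deg,
      v_right_m3_per_s = stiv$right$estimate$V,
      v_left_m3_per_s = stiv$left$estimate$V,
      co2_right_m3_per_s = stiv$right$estimate$V_CO2,
      co2_left_m3_per_s = stiv$left$estimate$V_CO2,
      co2_total_m3_per_s = stiv$co2_total_m3_per_s,
      co2_total_m3_per_h = stiv$co2_total_m3_per_h))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  }
  report
}

#' Write a phantom recording set to disk
#'
#' Materializes the phantom for a configuration: the MWIR and LWIR stacks
#' as multi-page float TIFFs with JSON sidecars, the PPG trace as CSV, the
#' ground truth as JSON and the configuration as YAML.
#'
#' @param config a [phantom_config()].
#' @param outdir output directory (created if absent).
#' @return Invisibly, the named list of file paths written.
#' @export
simulate_phantom <- function(config, outdir) {
  stopifnot(inherits(config, "PhantomConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mwir <- generate_mwir_phantom(config)
  lwir <- generate_lwir_phantom(config)
  ppg <- generate_ppg(config)
  paths <- list(
    mwir = file.path(outdir, "mwir.tiff"),
    lwir = file.path(outdir, "lwir.tiff"),
    ppg = file.path(outdir, "ppg.csv"),
    ground_truth = file.path(outdir, "ground_truth.json"),
    config = file.path(outdir, "config.yaml"))
  write_tiff_stack(mwir$stack, paths$mwir)
  write_tiff_stack(lwir$stack, paths$lwir)
  write_signal_csv(ppg, paths$ppg)
  gt <- mwir$truth
  gt$exhalation_windows <- apply(gt$exhalation_windows, 1L, as.list)
  jsonlite::write_json(unclass(gt), paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(config), paths$config)
  invisible(paths)
}

#' Load a phantom configuration from YAML
#'
#' @param path YAML file with [phantom_config()] fields.
#' @return A validated `PhantomConfig`.
#' @export
read_phantom_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(phantom_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown phantom config fields: ", paste(unknown, collapse = ", "))
  do.call(phantom_config, raw)
}
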