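#' Run the full synthetic demonstration pipeline
#'
#' Generates synthetic fixtures for every assay the package analyzes —
#' brightfield volumetry, radial stain quantification, Gompertz growth,
#' dose-response, clonogenic survival, drug release — runs each analysis
#' stage, and writes CSV/JSON results plus a summary comparing estimates to
#' the generators' ground truth. Deterministic: the same `seed` reproduces
#' every output file bit-identically.
#'
#' @param output_dir writable directory for the result bundle.
#' @param seed master integer seed; per-stage seeds are derived from it by
#'   fixed offsets.
#' @param um_per_px calibration used for the synthetic micrographs.
#' @param n_volumetry number of synthetic brightfield spheroids.
#' @param verbose print per-stage progress to stderr.
#' @return (invisibly) the summary report as a named list; also written as
#'   `summary.json`.
#' @export
run_demo <- function(output_dir, seed = 7L, um_per_px = 1.25,
                     n_volumetry = 6L, verbose = FALSE) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", output_dir,
                  call. = FALSE)
  }
  if (file.access(output_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", output_dir, call. = FALSE)
  }
  seed <- as.integer(seed)
  say <- function(...) if (verbose) message(sprintf(...))

  ## -- volumetry ------------------------------------------------------
  say("stage 1/6: volumetry")
  diam <- seq(300, 550, length.out = n_volumetry)
  morpho <- do.call(rbind, lapply(seq_len(n_volumetry), function(i) {
    g <- gen_brightfield_spheroid(diam[i], um_per_px, image_size_px = 512L,
                                  noise_sd = 3, seed = seed + i)
    m <- measure_spheroid(segment_spheroid(g$image), um_per_px)
    cbind(data.frame(image = sprintf("spheroid_%02d", i),
                     true_diameter_um = diam[i]), m)
  }))
  morpho$diameter_error_pct <-
    100 * abs(morpho$equivalent_diameter_um - morpho$true_diameter_um) /
    morpho$true_diameter_um
  write.csv(morpho, file.path(output_dir, "morphometry.csv"),
            row.names = FALSE)

  ## -- radial quantification ------------------------------------------
  say("stage 2/6: radial quantification")
  rim <- function(f) 0.05 + 0.9 * (f <= 1 / 3)  # proliferation-rim profile
  sec <- gen_stained_section(150, depth_profile = rim, seed = seed + 101L)
  rad <- radial_signal_distribution(sec$image, sec$mask,
                                    threshold = sec$truth$params$threshold)
  radial_df <- data.frame(
    image = "section_rim",
    pct_periphery = rad$pct_periphery,
    pct_intermediate = rad$pct_intermediate,
    pct_core = rad$pct_core,
    total_signal = rad$total_positive_signal,
    threshold = rad$positive_threshold,
    max_depth_px = rad$max_depth_px,
    truth_pct_periphery = 100 * sec$truth$params$region_pos_sums[1] /
      sec$truth$params$total_pos_sum)
  write.csv(radial_df, file.path(output_dir, "radial.csv"),
            row.names = FALSE)

  ## -- growth kinetics -------------------------------------------------
  say("stage 3/6: growth kinetics")
  g_truth <- list(v0 = 4.2e6, alpha = 0.9, beta = 0.25)
  arms <- list(
    control = gen_growth_series(g_truth$v0, g_truth$alpha, g_truth$beta,
                                days = seq(0, 14, length.out = 10),
                                n_replicates = 6L, cv = 0.05,
                                arm = "control", seed = seed + 201L),
    treated = gen_growth_series(g_truth$v0, g_truth$alpha * 0.35,
                                g_truth$beta,
                                days = seq(0, 14, length.out = 10),
                                n_replicates = 6L, cv = 0.05,
                                arm = "treated", seed = seed + 202L))
  growth <- rbind(arms$control$data, arms$treated$data)
  write.csv(growth, file.path(output_dir, "growth.csv"), row.names = FALSE)
  fit_c <- fit_gompertz(arms$control$data$day, arms$control$data$volume_um3)
  cmp <- compare_arms(arms$control$data, arms$treated$data, timepoint = 14)
  growth_json <- list(
    control_fit = as.list(fit_c$params),
    control_plateau = fit_c$plateau,
    control_plateau_se = fit_c$plateau_se,
    truth_plateau = arms$control$truth$params$plateau,
    day14_welch_t = cmp$statistic, day14_p_value = cmp$p_value)
  jsonlite::write_json(growth_json, file.path(output_dir, "growth_fit.json"),
                       auto_unbox = TRUE, digits = NA)

  ## -- dose-response ----------------------------------------------------
  say("stage 4/6: dose-response")
  concs <- 10^seq(-2, 3, length.out = 9)
  plate <- gen_dose_response(ic50 = 10, hill_slope = 1, bottom = 5,
                             concentrations = concs, n_replicates = 3L,
                             noise_sd = 0.02, seed = seed + 301L)
  write.csv(plate$data, file.path(output_dir, "plate.csv"),
            row.names = FALSE)
  dr <- analyze_plate(plate$data)
  dr_json <- list(ic50 = dr$fit$ic50, ic50_reached = dr$fit$ic50_reached,
                  hill_slope = dr$fit$hill_slope, bottom = dr$fit$bottom,
                  truth_ic50 = plate$truth$params$ic50)
  jsonlite::write_json(dr_json,
                       file.path(output_dir, "dose_response_fit.json"),
                       auto_unbox = TRUE, digits = NA)

  ## -- clonogenic -------------------------------------------------------
  say("stage 5/6: clonogenic survival")
  ctrl <- gen_clonogenic(1000L, plating_efficiency = 0.8, sf_true = 1,
                         condition = "untreated", seed = seed + 401L)
  trt <- gen_clonogenic(1000L, plating_efficiency = 0.8, sf_true = 0.25,
                        condition = "treated_20ng", seed = seed + 402L)
  pe <- plating_efficiency(ctrl$record$colonies, ctrl$record$cells_plated)
  sf <- surviving_fraction(trt$record$colonies, trt$record$cells_plated, pe)
  clono <- rbind(cbind(ctrl$record, plating_efficiency = pe,
                       surviving_fraction = 1),
                 cbind(trt$record, plating_efficiency = pe,
                       surviving_fraction = sf))
  write.csv(clono, file.path(output_dir, "clonogenic.csv"),
            row.names = FALSE)

  ## -- release ----------------------------------------------------------
  say("stage 6/6: drug release")
  rel <- gen_release(k = log(2) / 6, f_inf = 1,
                     times = c(0, 1, 2, 4, 6, 8, 12, 24),
                     noise_sd = 0.01, seed = seed + 501L)
  write.csv(rel$data, file.path(output_dir, "release.csv"),
            row.names = FALSE)
  f12 <- release_fraction_at(rel$data, 12)
  jsonlite::write_json(list(fraction_released_12h = f12,
                            half_life_h = rel$truth$params$half_life_h),
                       file.path(output_dir, "release_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  ## -- summary ----------------------------------------------------------
  report <- list(
    seed = seed,
    volumetry = list(
      n = n_volumetry,
      max_diameter_error_pct = max(morpho$diameter_error_pct)),
    radial = list(
      pct_periphery = rad$pct_periphery,
      truth_pct_periphery = unname(radial_df$truth_pct_periphery)),
    growth = list(
      plateau_estimate = fit_c$plateau,
      plateau_truth = arms$control$truth$params$plateau,
      plateau_rel_error = abs(fit_c$plateau -
        arms$control$truth$params$plateau) /
        arms$control$truth$params$plateau,
      day14_p_value = cmp$p_value),
    dose_response = list(
      ic50_estimate = dr$fit$ic50, ic50_truth = plate$truth$params$ic50,
      ic50_reached = dr$fit$ic50_reached),
    clonogenic = list(
      plating_efficiency = pe, surviving_fraction = sf, sf_truth = 0.25),
    release = list(fraction_released_12h = f12))
  jsonlite::write_json(report, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
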