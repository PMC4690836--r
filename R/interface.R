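#' Read a run configuration
#'
#' Flat YAML key/value document with units in the key names (mm, um, Pa,
#' s, mL/min). Missing keys fall back to the canonical fixture and
#' commercial-class device defaults.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    parent_diameter_mm = 4, daughter_diameters_mm = c(3, 3),
    daughter_angles_deg = c(-60, 60), n_daughters = 2,
    dome_diameter_mm = 8, neck_diameter_mm = 5,
    stl_path = NULL, centerline_path = NULL,
    device_diameter_mm = 3.5, device_length_mm = 20, n_strands = 48,
    wire_diameter_um = 30, target_porosity = 0.70,
    catheter_diameter_mm = 1.0,
    deploy_enabled = TRUE, n_release_bands = 10, deploy_max_iters = 1500,
    resolution_cells_per_diameter = 16, dt_s = 0.01, n_cycles = 3,
    site = "ICA", heart_rate_bpm = 75,
    outlet_pressures_pa = NULL, jailed_bias_sweep_pa = c(0, 100, 200, 300),
    distal_resistance_pa_per_m2s = 0, jailed_branch = "daughter_1",
    contrast_enabled = TRUE, diffusivity_m2s = 1.0e-7,
    bolus_start_s = 1.60, bolus_duration_s = 0.80, total_cycles = 5,
    out_dir = "stentflow_run", seed = 1L)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defaults, cfg)
  if (!is.null(merged$stl_path) && !file.exists(merged$stl_path))
    stop("stl_path does not exist: ", merged$stl_path)
  structure(merged, class = "run_config")
}

#' Run the virtual-treatment rehearsal pipeline
#'
#' Executes geometry synthesis, device generation and crimping, virtual
#' deployment, steady device-off/on hemodynamics with the jailed-outlet
#' pressure sweep, and (optionally) pulsatile contrast transport with
#' exponential washout fits, assembling a JSON-serializable report. Stage
#' failures are caught: the report carries the per-stage error and all
#' completed summaries. Identical configurations (and seed) give identical
#' reports; the solvers themselves are deterministic.
#'
#' @param config A [read_run_config()] object, path, or named list.
#' @param verbose Print stage progress.
#' @param last_stage Run the pipeline only through this stage
#'   ("deploy", "flow" or "contrast" = everything).
#' @return A `run_report` (nested list; also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config, verbose = TRUE,
                         last_stage = c("contrast", "flow", "deploy")) {
  last_stage <- match.arg(last_stage)
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(cfg), stages = list())
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    say("stage: %s", name)
    res <- tryCatch(expr, error = function(e) {
      say("  stage %s FAILED: %s", name, conditionMessage(e))
      structure(list(error = conditionMessage(e)), class = "stage_error")
    })
    report$stages[[name]] <<- if (inherits(res, "stage_error"))
      list(error = res$error) else res$summary
    if (inherits(res, "stage_error")) NULL else res$value
  }

  geom <- stage("geometry", {
    g <- if (!is.null(cfg$stl_path)) {
      read_stl(cfg$stl_path, cfg$centerline_path)
    } else {
      make_bifurcation_aneurysm(bifurcation_spec(
        parent_diameter = cfg$parent_diameter_mm,
        daughter_diameters = cfg$daughter_diameters_mm,
        daughter_angles = cfg$daughter_angles_deg,
        n_daughters = cfg$n_daughters,
        dome_diameter = cfg$dome_diameter_mm,
        neck_diameter = cfg$neck_diameter_mm), build_surface = FALSE)
    }
    list(value = g, summary = list(
      source = g$source, n_outlets = sum(vapply(g$caps, function(cp)
        cp$type == "outlet", TRUE))))
  })
  if (is.null(geom)) return(finish_report(report, cfg))

  devm <- stage("device", {
    sp <- device_spec(cfg$device_diameter_mm, cfg$device_length_mm,
                      cfg$n_strands, cfg$wire_diameter_um,
                      cfg$target_porosity)
    m <- generate_device(sp)
    por <- measure_porosity(m)
    list(value = m, summary = list(n_nodes = nrow(m$nodes),
                                   strand_turns = m$strand_turns,
                                   measured_porosity = por))
  })

  crimped <- if (!is.null(devm)) stage("crimp", {
    cr <- crimp_device(devm, cfg$catheter_diameter_mm)
    list(value = cr$mesh, summary = unclass(cr$report))
  })

  deployed <- NULL
  coverage <- 1 - cfg$target_porosity
  if (isTRUE(cfg$deploy_enabled) && !is.null(crimped)) {
    deployed <- stage("deploy", {
      net <- build_spring_network(crimped)
      # parent -> stented daughter path (the branch opposite the jailed one)
      stented <- setdiff(vapply(geom$centerlines, `[[`, "", "name"),
                         c("parent", cfg$jailed_branch))[1]
      cl_par <- geom$centerlines[[1]]$points
      cl_dau <- NULL
      for (b in geom$centerlines) if (b$name == stented) cl_dau <- b$points
      path <- rbind(cl_par, cl_dau[-1, , drop = FALSE])
      s_apex <- polyline_length(cl_par)
      dp <- deploy(net, geom, plan_release_schedule(crimped, cfg$n_release_bands),
                   centerline = path, advance = s_apex,
                   max_iters = cfg$deploy_max_iters)
      ap <- apposition(dp)
      summ <- list(iterations = dp$iterations_used, converged = dp$converged,
                   contact_fraction = mean(dp$contact_flags),
                   apposition_max_mm = ap$max, apposition_mean_mm = ap$mean)
      if (!is.null(geom$dome)) {
        np <- define_neck_plane(geom, offset = 0)
        cov <- tryCatch(local_metal_coverage(dp, np), error = function(e) NA)
        summ$neck_metal_coverage <- cov
      }
      list(value = dp, summary = summ)
    })
    cov_meas <- report$stages$deploy$neck_metal_coverage
    if (!is.null(cov_meas) && is.finite(cov_meas) && cov_meas > 0.05)
      coverage <- cov_meas
  }

  if (last_stage == "deploy") return(finish_report(report, cfg))

  flow_res <- stage("flow", {
    wf <- make_waveform(cfg$site, cfg$heart_rate_bpm)
    res <- cfg$resolution_cells_per_diameter
    Rdist <- rep(cfg$distal_resistance_pa_per_m2s, 2)
    fp0 <- rasterize_domain(geom, res, "2D", dt = cfg$dt_s,
                            n_cycles = cfg$n_cycles,
                            outlet_pressures = cfg$outlet_pressures_pa,
                            outlet_resistances = Rdist)
    np <- define_neck_plane(geom, offset = 0.5)
    f0 <- solve_flow(fp0, wf, steady = TRUE)
    q0 <- aneurysm_inflow(f0, np)
    fp1 <- add_device_screens(fp0, coverage, cfg$wire_diameter_um,
                              cfg$jailed_branch)
    f1 <- solve_flow(fp1, wf, steady = TRUE)
    q1 <- aneurysm_inflow(f1, np)
    red0 <- inflow_reduction(q0$mean, q1$mean)
    # dome wall region, excluding the first millimetre above the neck plane
    # where screen-edge vorticity contaminates the shear estimate
    gx <- rep(fp0$xs, times = fp0$ny); gy <- rep(fp0$ys, each = fp0$nx)
    dome2 <- matrix(in_dome_region(geom, cbind(gx, gy)) &
                      gy > geom$dome$y_neck + 1, fp0$nx, fp0$ny)
    wss0 <- compute_wss(f0, region = dome2)
    wss1 <- compute_wss(f1, region = dome2)
    splits <- list()
    jailed_idx <- which(vapply(fp0$geom$cap_edges2[-1], `[[`, "", "name") ==
                          cfg$jailed_branch)
    for (b in cfg$jailed_bias_sweep_pa) {
      op <- rep(0, length(fp1$outlets)); op[jailed_idx] <- b
      fpb <- add_device_screens(
        rasterize_domain(geom, res, "2D", dt = cfg$dt_s,
                         outlet_pressures = op, outlet_resistances = Rdist),
        coverage, cfg$wire_diameter_um, cfg$jailed_branch)
      fpb$init <- list(u = f1$u[[1]], v = f1$v[[1]], p = f1$p)
      fb <- solve_flow(fpb, wf, steady = TRUE)
      qb <- aneurysm_inflow(fb, np)
      tot <- sum(fb$outlet_flux)
      splits[[as.character(b)]] <- list(
        bias_pa = b, inflow_reduction_pct = inflow_reduction(q0$mean, qb$mean),
        jailed_flux = fb$outlet_flux[jailed_idx],
        stented_fraction = 1 - fb$outlet_flux[jailed_idx] / tot,
        inlet_pressure_pa = fb$inlet_pressure)
    }
    list(value = list(f0 = f0, f1 = f1, np = np, wf = wf, fp0 = fp0),
         summary = list(
           inflow_no_device = q0$mean, inflow_with_device = q1$mean,
           inflow_reduction_pct = red0,
           inlet_pressure_no_device_pa = f0$inlet_pressure,
           inlet_pressure_with_device_pa = f1$inlet_pressure,
           wss_peak_no_device_pa = wss0$peak, wss_peak_with_device_pa = wss1$peak,
           wss_mean_no_device_pa = wss0$mean, wss_mean_with_device_pa = wss1$mean,
           pressure_sweep = splits))
  })

  if (isTRUE(cfg$contrast_enabled) && !is.null(flow_res) &&
      last_stage == "contrast") {
    stage("contrast", {
      wf <- flow_res$wf; np <- flow_res$np
      tp <- transport_params(cfg$diffusivity_m2s, cfg$bolus_start_s,
                             cfg$bolus_duration_s)
      fits <- list()
      for (tag in c("no_device", "with_device")) {
        fp <- rasterize_domain(geom, cfg$resolution_cells_per_diameter, "2D",
                               dt = cfg$dt_s, n_cycles = cfg$total_cycles)
        if (tag == "with_device")
          fp <- add_device_screens(fp, coverage, cfg$wire_diameter_um,
                                   cfg$jailed_branch)
        ffp <- solve_flow(fp, wf, n_cycles = cfg$total_cycles)
        cf <- transport_contrast(ffp, tp)
        rc <- residence_curve(cf)
        utils::write.csv(rc, file.path(cfg$out_dir,
                                       paste0("residence_", tag, ".csv")),
                         row.names = FALSE)
        fits[[tag]] <- suppressWarnings(fit_exponential_decay(rc))
      }
      summ <- list(
        decay_rate_no_device = fits$no_device$rate,
        decay_rate_with_device = fits$with_device$rate,
        r2_no_device = fits$no_device$r_squared,
        r2_with_device = fits$with_device$r_squared,
        decay_rate_reduction_pct = decay_rate_reduction(fits$no_device,
                                                        fits$with_device))
      list(value = fits, summary = summ)
    })
  }
  finish_report(report, cfg)
}

finish_report <- function(report, cfg) {
  cfg_file <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("stentflow")),
    config_md5 = unname(tools::md5sum(cfg_file)))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages:", paste(names(x$stages), collapse = ", "), "\n")
  fl <- x$stages$flow
  if (!is.null(fl$inflow_reduction_pct))
    cat(sprintf("  inflow reduction: %.1f%%\n", fl$inflow_reduction_pct))
  ct <- x$stages$contrast
  if (!is.null(ct$decay_rate_no_device))
    cat(sprintf("  decay rates: %.2f -> %.2f 1/s (R^2 %.3f / %.3f)\n",
                ct$decay_rate_no_device, ct$decay_rate_with_device,
                ct$r2_no_device, ct$r2_with_device))
  invisible(x)
}
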