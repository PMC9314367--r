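# Configured, logged, reproducible pipeline runs: simulate (or load) a
# particle table, analyze it, and write every table the report draws on.

#' Run the full simulate/analyze pipeline from a config
#'
#' The config (YAML file or named list) drives a deterministic run:
#' generation (unless an `input` table is given), filtering, compartment
#' assignment, layer and string analyses, classification, and report export.
#' All reported statistics are re-derivable from the tables written next to
#' the report.
#'
#' Config keys: `seed`, `preset` (`cyanobium` / `halo` / `population`),
#' `n_carboxysomes`, `generator` (named overrides for [generator_config()]),
#' `input` (path to a STAR/CSV table; skips generation), `pixel_size`,
#' `analysis` (named overrides for [analyze_carboxysomes()]), `out_dir`,
#' `placeback` (logical: write CMM markers per compartment).
#'
#' @param config Path to a YAML config or a named list.
#' @param out_dir Output directory (overrides the config key).
#' @return The analysis report (class `cbx_report`), invisibly the written
#'   directory path in attribute `"out_dir"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stopf("config must be a YAML file path or a named list")
  out_dir <- out_dir %||% cfg$out_dir %||% stopf("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  log_lines <- character(0)
  t0 <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) {
    msg <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0, sprintf(fmt, ...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  truth <- NULL
  if (!is.null(cfg$input)) {
    tab <- stage("read", read_particle_table(cfg$input,
                                             pixel_size = cfg$pixel_size))
    say("read %d particles from %s", nrow(tab), cfg$input)
  } else {
    preset <- cfg$preset %||% "cyanobium"
    n <- cfg$n_carboxysomes %||% 1L
    gen_over <- cfg$generator %||% list()
    gen_over$seed <- gen_over$seed %||% seed
    sim <- stage("simulate", {
      if (!preset %in% c("cyanobium", "halo", "population"))
        stopf("unknown preset '%s'", preset)
      gcfg <- do.call(generator_config,
                      c(list(preset = if (preset == "population") "halo" else preset),
                        gen_over))
      switch(preset,
             cyanobium = generate_cyanobium(gcfg, n),
             halo = generate_halo(gcfg, n),
             population = generate_population(gcfg, n))
    })
    tab <- sim$table; truth <- sim$truth
    say("simulated %d particles in %d carboxysome(s), preset %s",
        nrow(tab), n, preset)
    write_particle_table(tab, file.path(out_dir, "particles.csv"))
    write_particle_table(tab, file.path(out_dir, "particles.star"),
                         dialect = "star", pixel_size = cfg$pixel_size %||% 5.36)
    write_ground_truth(truth, out_dir)
  }

  if (nrow(tab) == 0) {
    warning("empty particle table: writing an empty report")
    report <- structure(list(meta = list(seed = seed, n_particles = 0),
                             compartments = NULL, population = NULL),
                        class = "cbx_report")
    jsonlite::write_json(list(meta = report$meta), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(structure(report, out_dir = out_dir)))
  }

  an_over <- cfg$analysis %||% list()
  fit <- stage("analyze", do.call(analyze_carboxysomes, c(list(tab), an_over)))
  fr <- fit$filter_report
  say("filtered: kept %d/%d (low-score %d, unassigned %d, stray %d)",
      fr$kept, fr$input, fr$dropped_low_score, fr$dropped_unassigned,
      fr$dropped_far)
  say("analyzed %d compartment(s), %d string(s)",
      nrow(fit$compartments), length(fit$strings$strings))

  report <- stage("report", build_report(fit, cfg, seed))
  write_analysis_tables(fit, out_dir)
  jsonlite::write_json(report_to_list(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  eff <- cfg; eff$seed <- seed; eff$out_dir <- out_dir
  yaml::write_yaml(eff, file.path(out_dir, "effective_config.yaml"))
  if (isTRUE(cfg$placeback))
    for (cid in fit$compartments$compartment_id) {
      sub <- fit$table[which(fit$table$compartment_id == cid), , drop = FALSE]
      class(sub) <- class(fit$table)
      export_placeback(sub, file.path(out_dir, sprintf(
        "placeback_%s.cmm", gsub("[^A-Za-z0-9_]", "_", cid))), format = "cmm")
    }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  say("done; outputs in %s", out_dir)
  invisible(structure(report, out_dir = out_dir))
}

build_report <- function(fit, cfg, seed) {
  per_comp <- fit$compartments
  per_comp$class <- fit$classes[per_comp$compartment_id]
  cfg_id <- cfg[setdiff(names(cfg), "out_dir")]   # identity, not location
  structure(list(
    meta = list(
      package_version = as.character(utils::packageVersion("cbxpack")),
      config_hash = config_hash(cfg_id), seed = seed,
      n_particles = fit$filter_report$input,
      n_kept = fit$filter_report$kept),
    estimates = as.list(coef(fit)),
    filter = fit$filter_report,
    compartments = per_comp,
    layer_peaks_A = fit$radial$peaks_A,
    layer_spacing_A = fit$radial$peak_spacing_A,
    angular = list(mode_deg = fit$angular$mode_deg,
                   mean_deg = fit$angular$mean_deg),
    neighbors = as.list(fit$neighbors$summary),
    string_stats = fit$string_stats[c("count_mean", "count_sd",
                                      "length_mean", "length_sd",
                                      "frac_in_strings")],
    twist = list(mean_deg = fit$twists$mean_deg, sd_deg = fit$twists$sd_deg),
    coordination_mode = fit$coordination$modal_coordination,
    population = fit$population), class = "cbx_report")
}

report_to_list <- function(report) {
  out <- unclass(report)
  out$compartments <- NULL   # full table lives in compartments.csv
  out$population$class_counts <- as.list(out$population$class_counts)
  out
}

#' @export
print.cbx_report <- function(x, ...) {
  cat("Carboxysome pipeline report\n")
  cat(sprintf("  seed %s, config %s, %d/%d particles kept\n",
              x$meta$seed, x$meta$config_hash, x$meta$n_kept, x$meta$n_particles))
  est <- unlist(x$estimates)
  print(round(est[is.finite(est)], 3))
  invisible(x)
}

write_analysis_tables <- function(fit, out_dir) {
  per_part <- as.data.frame(fit$table)
  per_part$layer <- fit$radial$layer
  per_part$string <- fit$strings$assignment
  per_part$nn_A <- fit$neighbors$nn_A
  utils::write.csv(per_part, file.path(out_dir, "per_particle.csv"),
                   row.names = FALSE)
  comp <- fit$compartments
  comp$class <- fit$classes[comp$compartment_id]
  utils::write.csv(comp, file.path(out_dir, "compartments.csv"),
                   row.names = FALSE)
  if (length(fit$strings$strings)) {
    sdf <- do.call(rbind, lapply(seq_along(fit$strings$strings), function(k) {
      s <- fit$strings$strings[[k]]
      data.frame(string = k, compartment_id = s$compartment_id,
                 length = s$length,
                 ax = s$axis[1], ay = s$axis[2], az = s$axis[3],
                 mean_twist_deg = fit$twists$string_means[k],
                 members = paste(s$particle_ids, collapse = "|"),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(sdf, file.path(out_dir, "strings.csv"), row.names = FALSE)
  }
  hist_df <- data.frame(bin_lo = utils::head(fit$radial$breaks, -1),
                        bin_hi = fit$radial$breaks[-1],
                        count = fit$radial$counts)
  utils::write.csv(hist_df, file.path(out_dir, "radial_histogram.csv"),
                   row.names = FALSE)
  ang_df <- data.frame(bin_lo = utils::head(fit$angular$breaks, -1),
                       bin_hi = fit$angular$breaks[-1],
                       count = fit$angular$counts)
  utils::write.csv(ang_df, file.path(out_dir, "angular_histogram.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
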