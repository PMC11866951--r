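#' Default pipeline configuration
#'
#' Returns the fully-populated default configuration for the synthetic
#' end-to-end run: a 50 x 50 grid of four autocorrelated layers, a species
#' whose log-density is +2 in `temp` and -1 in `precip_cv`, 150 presence
#' records, 1,000 background cells, the standard 48-candidate tuning grid
#' (RM 0.5-4.0 by 0.5 x FC {L, LQ, H, LQH, LQHP, LQHPT}) with 10 repeats of
#' 75/25 splits, fixed suitability bands 0.10/0.30/0.60, change threshold
#' 0.30, and two warming scenarios per period.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed; every stochastic stage derives its own stream.
#' @return Nested named list; see [run_stage()].
#' @export
default_config <- function(out_dir = "nichecast_run", seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    simulate = list(
      n_rows = 50, n_cols = 50, west = 105, north = 27, cell_size = 0.1,
      layers = c("temp", "temp_range", "precip_cv", "soil_ph"),
      autocorr_range = 4,
      truth = list(temp = 2.0, precip_cv = -1.0),
      n_presences = 150,
      scenarios = list(
        list(name = "warm_moderate", period = "2050s",
             shift = list(temp = 0.5), sd_mult = list(temp = 1.1)),
        list(name = "warm_high", period = "2090s",
             shift = list(temp = 1.5), sd_mult = list(temp = 1.25))
      )
    ),
    clean = list(outlier_z = 4),
    screen = list(corr_threshold = 0.7, vif_threshold = 10),
    tune = list(
      rms = seq(0.5, 4, by = 0.5),
      fcs = c("L", "LQ", "H", "LQH", "LQHP", "LQHPT"),
      n_background = 1000, n_knots = 10,
      train_frac = 0.75, repeats = 10
    ),
    classify = list(thresholds = c(0.10, 0.30, 0.60), method = "fixed"),
    change = list(threshold = 0.30),
    mess = list(reference = "occurrences"),
    centroid = list(threshold = 0.30, weighted = FALSE)
  )
}

#' Read a pipeline configuration file
#'
#' YAML configuration; keys missing from the file take the
#' [default_config()] values, and unknown keys are errors (no silent typos).
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  merge_cfg <- function(base, user, prefix = "") {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown)) {
      stop("unknown config key(s): ",
           paste0(prefix, unknown, collapse = ", "))
    }
    for (k in names(user)) {
      if (is.list(base[[k]]) && is.list(user[[k]]) &&
          !is.null(names(base[[k]])) && k != "scenarios" && k != "truth" &&
          k != "shift" && k != "sd_mult") {
        base[[k]] <- merge_cfg(base[[k]], user[[k]], paste0(prefix, k, "."))
      } else {
        base[[k]] <- user[[k]]
      }
    }
    base
  }
  merge_cfg(base, user)
}

pipeline_stages <- c("simulate", "clean", "screen", "tune", "fit", "project",
                     "classify", "change", "mess", "centroid", "report")

# dependency artifacts per stage, relative to out_dir
stage_requires <- list(
  simulate = character(0),
  clean = c("scenarios/current/manifest.csv", "occurrences.csv"),
  screen = "occurrences_clean.csv",
  tune = "screening.json",
  fit = "tuning.csv",
  project = "model.json",
  classify = "suitability_current.asc",
  change = "suitability_current.asc",
  mess = "occurrences_clean.csv",
  centroid = "suitability_current.asc",
  report = "tuning.csv"
)

check_deps <- function(stage, out_dir) {
  need <- stage_requires[[stage]]
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    prereq <- pipeline_stages[vapply(pipeline_stages, function(s) {
      any(vapply(stage_artifacts(s), function(a) a %in% missing, logical(1)))
    }, logical(1))]
    stop(sprintf("stage '%s' is missing artifact(s) %s; run stage '%s' first",
                 stage, paste(missing, collapse = ", "),
                 if (length(prereq)) prereq[1] else "an earlier"))
  }
}

stage_artifacts <- function(stage) {
  switch(stage,
    simulate = c("scenarios/current/manifest.csv", "occurrences.csv"),
    clean = "occurrences_clean.csv",
    screen = "screening.json",
    tune = "tuning.csv",
    fit = "model.json",
    project = "suitability_current.asc",
    classify = "areas_current.csv",
    change = "change_areas.csv",
    mess = "mess_summary.csv",
    centroid = "centroid_track.csv",
    report = "report.json",
    character(0))
}

scenario_names <- function(config) {
  vapply(config$simulate$scenarios, `[[`, character(1), "name")
}

#' Run one pipeline stage
#'
#' Stages, in dependency order: `simulate` (synthetic layers, scenarios and
#' occurrences), `clean`, `screen`, `tune`, `fit`, `project`, `classify`,
#' `change`, `mess`, `centroid`, `report`. Artifacts are plain-text files
#' (ASCII grids, CSV, JSON) under `config$out_dir`; re-running a stage with
#' the same configuration and seed reproduces them.
#'
#' @param stage Stage name.
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @return The stage's main in-memory product, invisibly.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, pipeline_stages)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  check_deps(stage, out)
  seed <- config$seed
  log_line <- function(...) {
    msg <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                   sprintf(...))
    cat(msg, "\n", file = file.path(out, "pipeline.log"), append = TRUE)
  }

  result <- switch(stage,
    simulate = {
      sc <- config$simulate
      spec <- grid_spec(sc$n_rows, sc$n_cols, sc$west, sc$north, sc$cell_size)
      stack <- gen_env_stack(spec, unlist(sc$layers), sc$autocorr_range,
                             seed = sub_seed(seed, "env"))
      write_stack(stack, file.path(out, "scenarios", "current"))
      truth <- synthetic_truth(unlist(sc$truth))
      occ <- sample_presences(stack, truth, sc$n_presences,
                              seed = sub_seed(seed, "presences"))
      write_occurrences(occ, file.path(out, "occurrences.csv"))
      for (s in sc$scenarios) {
        pert <- scenario_perturbation(shift = unlist(s$shift),
                                      sd_mult = unlist(s$sd_mult))
        fut <- perturb_scenario(stack, pert)
        write_stack(fut, file.path(out, "scenarios", s$name),
                    scenario = s$name, period = s$period %||% "future")
      }
      log_line("grid %dx%d, %d layers, %d presences, %d scenario(s)",
               sc$n_rows, sc$n_cols, length(sc$layers), sc$n_presences,
               length(sc$scenarios))
      stack
    },
    clean = {
      stack <- read_stack(file.path(out, "scenarios", "current"))
      occ <- load_occurrences(file.path(out, "occurrences.csv"))
      cleaned <- clean_occurrences(occ, stack, config$clean$outlier_z)
      write_occurrences(cleaned, file.path(out, "occurrences_clean.csv"))
      jsonlite::write_json(attr(cleaned, "report"),
                           file.path(out, "cleaning_report.json"),
                           auto_unbox = TRUE)
      log_line("kept %d of %d records", nrow(cleaned), nrow(occ))
      cleaned
    },
    screen = {
      stack <- read_stack(file.path(out, "scenarios", "current"))
      occ <- load_occurrences(file.path(out, "occurrences_clean.csv"))
      rep <- screen_variables(stack, occ, config$screen$corr_threshold,
                              config$screen$vif_threshold)
      utils::write.csv(rep$rho, file.path(out, "spearman_matrix.csv"))
      jsonlite::write_json(list(
        selected = rep$selected,
        importance = as.list(rep$importance),
        thresholds = rep$thresholds,
        vif = rep$vif
      ), file.path(out, "screening.json"), auto_unbox = TRUE, digits = NA)
      log_line("selected %d of %d variables", length(rep$selected),
               nrow(rep$rho))
      rep
    },
    tune = {
      stack <- read_stack(file.path(out, "scenarios", "current"))
      occ <- load_occurrences(file.path(out, "occurrences_clean.csv"))
      sel <- jsonlite::read_json(file.path(out, "screening.json"),
                                 simplifyVector = TRUE)$selected
      tc <- config$tune
      tuning <- tune_enm(occ, stack, variables = sel,
                         rms = tc$rms, fcs = unlist(tc$fcs),
                         n_background = tc$n_background,
                         n_knots = tc$n_knots, train_frac = tc$train_frac,
                         repeats = tc$repeats, seed = sub_seed(seed, "tune"))
      write_tuning(tuning, file.path(out, "tuning.csv"))
      jsonlite::write_json(list(seed = seed, tune_seed = sub_seed(seed, "tune"),
                                selected = as.list(tuning$selected[c("rm", "fc")])),
                           file.path(out, "tuning_selected.json"),
                           auto_unbox = TRUE)
      log_line("selected fc=%s rm=%g", tuning$selected$fc, tuning$selected$rm)
      tuning
    },
    fit = {
      stack <- read_stack(file.path(out, "scenarios", "current"))
      occ <- load_occurrences(file.path(out, "occurrences_clean.csv"))
      sel <- jsonlite::read_json(file.path(out, "tuning_selected.json"),
                                 simplifyVector = TRUE)
      vars <- jsonlite::read_json(file.path(out, "screening.json"),
                                  simplifyVector = TRUE)$selected
      model <- maxent(occ, stack, variables = vars, fc = sel$selected$fc,
                      rm = sel$selected$rm,
                      n_background = config$tune$n_background,
                      n_knots = config$tune$n_knots,
                      seed = sub_seed(seed, "background"))
      write_maxent(model, file.path(out, "model.json"))
      rc <- do.call(rbind, lapply(vars, function(v) {
        cbind(variable = v, response_curve(model, v))
      }))
      utils::write.csv(rc, file.path(out, "response_curves.csv"),
                       row.names = FALSE)
      log_line("fitted fc=%s rm=%g, %d active features", sel$selected$fc,
               sel$selected$rm, sum(coef(model) != 0))
      model
    },
    project = {
      model <- read_maxent(file.path(out, "model.json"))
      for (nm in c("current", scenario_names(config))) {
        st <- read_stack(file.path(out, "scenarios", nm))
        sm <- predict(model, st, type = "cloglog")
        write_asc(sm$mat, sm$spec,
                  file.path(out, sprintf("suitability_%s.asc", nm)))
      }
      log_line("projected %d scenario(s)", 1 + length(scenario_names(config)))
      invisible(NULL)
    },
    classify = {
      thr <- unlist(config$classify$thresholds)
      for (nm in c("current", scenario_names(config))) {
        g <- read_asc(file.path(out, sprintf("suitability_%s.asc", nm)))
        sm <- suitability_map(g$spec, g$mat)
        if (identical(config$classify$method, "jenks")) {
          thr <- jenks_breaks(sm$mat[sm$mask], 4)
        }
        cm <- classify_suitability(sm, thr)
        write_asc(cm$classes, cm$spec,
                  file.path(out, sprintf("classes_%s.asc", nm)))
        utils::write.csv(area_table(cm),
                         file.path(out, sprintf("areas_%s.csv", nm)),
                         row.names = FALSE)
      }
      log_line("classified at %s", paste(signif(thr, 4), collapse = "/"))
      invisible(NULL)
    },
    change = {
      g0 <- read_asc(file.path(out, "suitability_current.asc"))
      cur <- suitability_map(g0$spec, g0$mat)
      rows <- list()
      for (nm in scenario_names(config)) {
        g1 <- read_asc(file.path(out, sprintf("suitability_%s.asc", nm)))
        cm <- change_map(cur, suitability_map(g1$spec, g1$mat),
                         config$change$threshold)
        write_asc(cm$classes, cm$spec,
                  file.path(out, sprintf("change_%s.asc", nm)))
        rows[[nm]] <- cbind(scenario = nm, cm$areas)
      }
      ctab <- do.call(rbind, rows)
      utils::write.csv(ctab, file.path(out, "change_areas.csv"),
                       row.names = FALSE)
      log_line("change matrices for %d scenario(s)", length(rows))
      ctab
    },
    mess = {
      stack <- read_stack(file.path(out, "scenarios", "current"))
      occ <- load_occurrences(file.path(out, "occurrences_clean.csv"))
      env <- build_envelope(stack, occ, reference = config$mess$reference)
      rows <- list()
      for (nm in scenario_names(config)) {
        st <- read_stack(file.path(out, "scenarios", nm))
        mg <- mess_grid(env, st, scenario = nm)
        write_asc(mg$mess, mg$spec, file.path(out, sprintf("mess_%s.asc", nm)))
        write_asc(mg$mod, mg$spec, file.path(out, sprintf("mod_%s.asc", nm)))
        rows[[nm]] <- data.frame(scenario = nm, mean_mess = mg$mean_mess,
                                 pct_anomaly = mg$pct_anomaly)
      }
      utils::write.csv(data.frame(code = seq_along(env), variable = names(env)),
                       file.path(out, "mod_legend.csv"), row.names = FALSE)
      ms <- do.call(rbind, rows)
      utils::write.csv(ms, file.path(out, "mess_summary.csv"), row.names = FALSE)
      log_line("mean MESS: %s",
               paste(sprintf("%s=%.2f", ms$scenario, ms$mean_mess),
                     collapse = ", "))
      ms
    },
    centroid = {
      pts <- list()
      for (nm in c("current", scenario_names(config))) {
        g <- read_asc(file.path(out, sprintf("suitability_%s.asc", nm)))
        ct <- centroid(suitability_map(g$spec, g$mat),
                       threshold = config$centroid$threshold,
                       weighted = isTRUE(config$centroid$weighted))
        pts[[nm]] <- data.frame(label = nm, lon = ct["lon"], lat = ct["lat"])
      }
      track <- migration(do.call(rbind, pts))
      utils::write.csv(as.data.frame(track),
                       file.path(out, "centroid_track.csv"), row.names = FALSE)
      log_line("centroid displacements: %s",
               paste(sprintf("%s=%.1fkm", track$label[-1],
                             track$dist_from_current_km[-1]), collapse = ", "))
      track
    },
    report = {
      pipeline_report(config)
    }
  )
  invisible(result)
}

#' Run the full pipeline
#'
#' @param config Configuration list; see [default_config()].
#' @return The final report list, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  for (s in pipeline_stages) run_stage(s, config)
  invisible(pipeline_report(config))
}

#' Assemble the pipeline summary report
#'
#' Re-reads the stage artifacts (no recomputation) and writes `report.json`
#' and a human-readable `report.txt` with the headline statistics: tuning
#' table and selected candidate, per-scenario area tables, change-matrix
#' areas, MESS summary and the centroid track, plus provenance (seed and
#' package version).
#'
#' @param config Configuration list.
#' @return Report list, invisibly.
#' @export
pipeline_report <- function(config) {
  out <- config$out_dir
  tuning <- utils::read.csv(file.path(out, "tuning.csv"))
  areas <- lapply(c("current", scenario_names(config)), function(nm) {
    utils::read.csv(file.path(out, sprintf("areas_%s.csv", nm)))
  })
  names(areas) <- c("current", scenario_names(config))
  rpt <- list(
    provenance = list(
      package = "nichecast",
      version = as.character(utils::packageVersion("nichecast")),
      seed = config$seed,
      generated = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
    ),
    tuning = list(
      n_candidates = nrow(tuning),
      selected = tuning[tuning$selected, c("rm", "fc", "aicc", "delta_aicc",
                                           "auc_test_avg", "auc_diff_avg",
                                           "or10_avg")],
      table = tuning
    ),
    areas = areas,
    change = utils::read.csv(file.path(out, "change_areas.csv")),
    mess = utils::read.csv(file.path(out, "mess_summary.csv")),
    centroid_track = utils::read.csv(file.path(out, "centroid_track.csv"))
  )
  jsonlite::write_json(rpt, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  txt <- c(
    "nichecast pipeline report",
    sprintf("seed %s, generated %s", config$seed, rpt$provenance$generated),
    "",
    sprintf("Tuning: %d candidates; selected fc=%s rm=%g (delta AICc %g)",
            nrow(tuning), rpt$tuning$selected$fc, rpt$tuning$selected$rm,
            rpt$tuning$selected$delta_aicc),
    "",
    "Total suitable area (1e4 km^2):",
    vapply(names(areas), function(nm) {
      a <- areas[[nm]]
      sprintf("  %-14s %8.3f (%5.2f%%)", nm,
              a$area_1e4_km2[a$class == "total_suitable"],
              a$percent[a$class == "total_suitable"])
    }, character(1)),
    "",
    "Mean MESS / % anomaly cells:",
    sprintf("  %-14s %8.2f / %5.1f%%", rpt$mess$scenario, rpt$mess$mean_mess,
            rpt$mess$pct_anomaly),
    "",
    "Centroid displacement from current (km):",
    sprintf("  %-14s %8.2f (bearing %5.1f deg)",
            rpt$centroid_track$label[-1],
            rpt$centroid_track$dist_from_current_km[-1],
            rpt$centroid_track$bearing_from_current_deg[-1])
  )
  writeLines(txt, file.path(out, "report.txt"))
  invisible(rpt)
}
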