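#' Configuration-driven end-to-end pipeline
#'
#' One configuration drives one species: occurrence curation and thinning,
#' study-area construction, predictor masking and collinearity filtering,
#' pseudoabsence ensemble modeling, AUC-gated ensembling, MTSS binarization,
#' per-scenario range-change and elevational-shift accounting. Every random
#' decision consumes a child seed derived from the master seed and a stage
#' label, so a rerun with the same configuration reproduces every numeric
#' output.
#'
#' @param species Species label.
#' @param occ Occurrence tibble or path to an occurrence CSV.
#' @param stack `predictor_stack` or path to a directory of `.asc` layers.
#' @param scenarios Named list: RCP label to either a list of future
#'   `predictor_stack`s (one per GCM) or a [scenario_config()] to be
#'   materialized from the masked present stack.
#' @param max_uncertainty_km Accuracy bound for [filter_accuracy()].
#' @param thin_min_dist_km,thin_iterations Spatial thinning settings.
#' @param buffer_deg Study-area buffer (decimal degrees).
#' @param cor_threshold Pairwise correlation threshold for [cor_select()].
#' @param keep_list Variables protected from correlation dropping.
#' @param n_pseudoabsence,n_pa_sets Pseudoabsence design.
#' @param replicates Model replicates per pseudoabsence set.
#' @param split Training fraction.
#' @param algorithms Candidate algorithms; when more than one is given a
#'   pre-selection stage picks the best by mean test AUC.
#' @param preselect_runs Replicates per algorithm in pre-selection.
#' @param auc_gate Ensemble AUC gate.
#' @param hyperparameters Named per-algorithm hyperparameter overrides.
#' @param add_slope Derive a `slope` layer from `altitude` when absent.
#' @param seed Master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(species, occ, stack, scenarios = list(),
                            max_uncertainty_km = 5,
                            thin_min_dist_km = 10, thin_iterations = 1000,
                            buffer_deg = 2.5, cor_threshold = 0.8,
                            keep_list = character(0),
                            n_pseudoabsence = 5000, n_pa_sets = 5,
                            replicates = 10, split = 0.7,
                            algorithms = c("GLM", "GBM", "RF"),
                            preselect_runs = 5, auc_gate = 0.8,
                            hyperparameters = list(), add_slope = TRUE,
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  with(config, {
    if (!is.character(species) || !nzchar(species))
      stop("species label required")
    if (split <= 0 || split >= 1) stop("split must lie strictly in (0, 1)")
    if (cor_threshold <= 0 || cor_threshold > 1)
      stop("cor_threshold must lie in (0, 1]")
    if (auc_gate < 0 || auc_gate > 1) stop("auc_gate must lie in [0, 1]")
    if (n_pseudoabsence < 1 || n_pa_sets < 1 || replicates < 1 ||
        thin_iterations < 1)
      stop("counts must be positive")
    if (buffer_deg <= 0 || thin_min_dist_km <= 0 || max_uncertainty_km <= 0)
      stop("distances must be positive")
  })
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' File paths in the YAML (`occurrences`, `predictors`) are resolved
#' relative to the YAML file. Scenario entries are interpreted as
#' [scenario_config()] fields.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.character(p) && !grepl("^/", p))
    file.path(base, p) else p
  scen <- lapply(names(y$scenarios %||% list()), function(lab) {
    s <- y$scenarios[[lab]]
    scenario_config(rcp_label = lab, deltas = unlist(s$deltas),
                    gcm_noise_sd = s$gcm_noise_sd %||% 0,
                    n_gcms = s$n_gcms %||% 3,
                    seed = s$seed %||% (y$seed %||% 1L))
  })
  names(scen) <- names(y$scenarios %||% list())
  pipeline_config(
    species = y$species,
    occ = resolve(y$occurrences),
    stack = resolve(y$predictors),
    scenarios = scen,
    max_uncertainty_km = y$max_uncertainty_km %||% 5,
    thin_min_dist_km = y$thin_min_dist_km %||% 10,
    thin_iterations = y$thin_iterations %||% 1000,
    buffer_deg = y$buffer_deg %||% 2.5,
    cor_threshold = y$cor_threshold %||% 0.8,
    keep_list = unlist(y$keep_list) %||% character(0),
    n_pseudoabsence = y$n_pseudoabsence %||% 5000,
    n_pa_sets = y$n_pa_sets %||% 5,
    replicates = y$replicates %||% 10,
    split = y$split %||% 0.7,
    algorithms = unlist(y$algorithms) %||% c("GLM", "GBM", "RF"),
    preselect_runs = y$preselect_runs %||% 5,
    auc_gate = y$auc_gate %||% 0.8,
    add_slope = y$add_slope %||% TRUE,
    seed = y$seed %||% 1L)
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory; created if missing. `NULL` skips all file
#'   output.
#' @return (Invisibly) a list with the thinned occurrences, study area,
#'   masked stack, variable-selection report, fitted runs and their
#'   evaluations, averaged importances, ensemble map and threshold, per-RCP
#'   binary maps, range-change and elevation-shift tables, and the log.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  validate_pipeline_config(config)
  seed <- config$seed
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message("[pipeline] ", line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- occurrences ----------------------------------------------------------
  occ <- stage("occurrences", {
    o <- if (is.character(config$occ)) read_occurrences(config$occ)
         else config$occ
    note("occurrences: %d records read", nrow(o))
    o <- filter_accuracy(o, config$max_uncertainty_km)
    note("occurrences: %d records pass the %.3g km accuracy bound",
         nrow(o), config$max_uncertainty_km)
    s <- child_seed(seed, "thin")
    o2 <- thin_spatial(o, config$thin_min_dist_km, config$thin_iterations,
                       seed = s)
    note("occurrences: thinned %d -> %d at %.3g km (seed %d)",
         nrow(o), nrow(o2), config$thin_min_dist_km, s)
    o2
  })

  # -- predictors -----------------------------------------------------------
  stack <- stage("predictors", {
    st <- if (is.character(config$stack)) read_stack(config$stack)
          else config$stack
    if (config$add_slope && !("slope" %in% names(st)) &&
        "altitude" %in% names(st)) {
      st <- predictor_stack(c(st, list(slope = compute_slope(st$altitude))))
      note("predictors: slope derived from altitude")
    }
    st
  })
  area <- stage("study_area", {
    a <- build_study_area(occ, config$buffer_deg, stack[[1]])
    note("study area: %d cells inside the %.3g deg buffer",
         nrow(study_area_cells(a)), config$buffer_deg)
    a
  })
  masked <- stage("crop_mask", crop_mask(stack, area))
  area_cropped <- stage("crop_mask", {
    m <- masked[[1]]$values
    mk <- ifelse(is.na(m), NA_real_, 1)
    structure(list(mask = grid_new(mk, masked[[1]]$origin_lon,
                                   masked[[1]]$origin_lat,
                                   masked[[1]]$cell_size, masked[[1]]$crs),
                   buffer_deg = config$buffer_deg),
              class = "study_area")
  })

  sel <- stage("variable_selection", {
    tab <- sample_stack_cells(masked, seed = child_seed(seed, "varsample"))
    vifs <- multicollinearity_vif(tab)
    cs <- cor_select(tab, config$cor_threshold, config$keep_list)
    note("variables: kept %d of %d (max remaining |r| = %.3f)",
         length(cs$selected), ncol(tab), cs$max_remaining_r)
    cs$report$vif <- vifs[cs$report$variable]
    cs
  })
  model_stack <- predictor_stack(masked[sel$selected])

  # -- modeling -------------------------------------------------------------
  pa_sets <- stage("pseudoabsences", {
    p <- sample_pseudoabsences(area_cropped, occ, config$n_pseudoabsence,
                               config$n_pa_sets, child_seed(seed, "pa"))
    note("pseudoabsences: %d sets of %d cells", length(p), config$n_pseudoabsence)
    p
  })

  algorithm <- stage("preselect", {
    if (length(config$algorithms) > 1) {
      rk <- preselect_algorithms(model_stack, occ, pa_sets,
                                 config$algorithms, config$preselect_runs,
                                 config$split, config$hyperparameters,
                                 seed = child_seed(seed, "preselect"))
      note("preselection: %s chosen (mean AUC %.3f)",
           rk$algorithm[1], rk$mean_auc[1])
      rk$algorithm[1]
    } else config$algorithms
  })

  fitted <- stage("fit", {
    runs <- list(); tables <- list()
    k <- 0
    for (s in seq_along(pa_sets)) {
      for (r in seq_len(config$replicates)) {
        k <- k + 1
        lab <- sprintf("pa%d_rep%d", s, r)
        tb <- assemble_training(model_stack, occ, pa_sets[[s]],
                                split = config$split,
                                seed = child_seed(seed, paste0("split_", lab)))
        run <- fit_model(tb, algorithm,
                         config$hyperparameters[[algorithm]] %||% list(),
                         seed = child_seed(seed, paste0("fit_", lab)),
                         replicate_id = r)
        run <- evaluate_model(run, tb)
        run$importance <- permutation_importance(
          run, tb, seed = child_seed(seed, paste0("imp_", lab)))
        runs[[k]] <- run; tables[[k]] <- tb
      }
    }
    note("modeling: %d runs (%d PA sets x %d replicates) with %s",
         k, length(pa_sets), config$replicates, algorithm)
    list(runs = runs, tables = tables)
  })
  evaluations <- dplyr::bind_rows(lapply(fitted$runs, glance.sdm_run))
  note("modeling: mean test AUC %.3f (min %.3f, max %.3f)",
       mean(evaluations$auc), min(evaluations$auc), max(evaluations$auc))

  # -- ensemble and binarization -------------------------------------------
  gate_pass <- which(evaluations$auc > config$auc_gate)
  importance <- stage("importance", {
    imp <- lapply(fitted$runs[gate_pass], function(r) r$importance)
    if (!length(imp)) imp <- lapply(fitted$runs, function(r) r$importance)
    avg <- Reduce(`+`, imp) / length(imp)
    tibble::tibble(variable = names(avg), importance = as.numeric(avg)) |>
      dplyr::arrange(dplyr::desc(.data$importance))
  })

  present_maps <- stage("project_present",
                        lapply(fitted$runs, predict_map, stack = model_stack))
  evals <- lapply(fitted$runs, function(r) r$evaluation)
  ensemble <- stage("ensemble",
                    ensemble_maps(present_maps, evals, config$auc_gate))
  n_contributing <- attr(ensemble, "n_contributing")
  note("ensemble: %d of %d models above AUC %.2f",
       n_contributing, length(fitted$runs), config$auc_gate)
  thr <- stage("threshold", {
    t <- ensemble_threshold(fitted$runs, fitted$tables, config$auc_gate)
    note("ensemble MTSS threshold %.4f (TSS %.3f)", t$threshold, t$tss)
    t
  })
  present_bin <- mtss_binarize(ensemble, thr$threshold)

  # -- future scenarios -----------------------------------------------------
  scen_out <- stage("scenarios", {
    res <- list()
    for (lab in names(config$scenarios)) {
      sc <- config$scenarios[[lab]]
      gcm_stacks <- if (inherits(sc, "scenario_config")) {
        make_future_scenarios(masked, sc)$gcms
      } else sc
      gcm_bins <- lapply(gcm_stacks, function(fs) {
        fmaps <- lapply(fitted$runs, predict_map,
                        stack = predictor_stack(fs[sel$selected]))
        fens <- suppressMessages(
          ensemble_maps(fmaps, evals, config$auc_gate))
        mtss_binarize(fens, thr$threshold)
      })
      fut_bin <- combine_binary(gcm_bins)
      rc <- dplyr::bind_cols(
        tibble::tibble(species = config$species, scenario = lab),
        range_change(present_bin, fut_bin))
      es <- dplyr::bind_cols(
        tibble::tibble(species = config$species, scenario = lab),
        elevation_shift(present_bin, fut_bin, masked$altitude))
      note("%s: loss %d / stable %d / gain %d (change %.1f%%); %s%.0f m shift",
           lab, rc$loss_cells, rc$stable_cells, rc$gain_cells, rc$pct_change,
           if (es$shift >= 0) "+" else "", es$shift)
      res[[lab]] <- list(binary = fut_bin, range_change = rc,
                         elevation = es)
    }
    res
  })
  range_tbl <- dplyr::bind_rows(lapply(scen_out, `[[`, "range_change"))
  elev_tbl <- dplyr::bind_rows(lapply(scen_out, `[[`, "elevation"))

  # -- outputs --------------------------------------------------------------
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(sel$report, file.path(outdir, "variables.csv"))
    readr::write_csv(evaluations, file.path(outdir, "evaluations.csv"))
    readr::write_csv(importance, file.path(outdir, "importance.csv"))
    if (nrow(range_tbl))
      readr::write_csv(range_tbl, file.path(outdir, "range_change.csv"))
    if (nrow(elev_tbl))
      readr::write_csv(elev_tbl, file.path(outdir, "elevation_shift.csv"))
    write_occurrences(occ, file.path(outdir, "occurrences_thinned.csv"))
    write_asc(ensemble, file.path(outdir, "present_suitability.asc"))
    write_asc(present_bin, file.path(outdir, "present_binary.asc"))
    for (lab in names(scen_out))
      write_asc(scen_out[[lab]]$binary,
                file.path(outdir, sprintf("future_binary_%s.asc", lab)))
    writeLines(log_lines, file.path(outdir, "pipeline_log.txt"))
  }

  invisible(list(
    occurrences = occ, study_area = area, stack = masked,
    variable_report = sel$report, selected = sel$selected,
    max_remaining_r = sel$max_remaining_r,
    algorithm = algorithm, runs = fitted$runs, tables = fitted$tables,
    evaluations = evaluations, importance = importance,
    ensemble = ensemble, n_contributing = n_contributing,
    threshold = thr, present_binary = present_bin,
    scenarios = scen_out, range_change = range_tbl,
    elevation_shift = elev_tbl, log = log_lines))
}
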