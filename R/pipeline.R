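read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_arg("config file not found: ", config)
    if (grepl("\\.ya?ml$", config)) {
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop_arg("config must be a list or a YAML/JSON path")
  config$seed <- as.integer(config$seed %||% 1)
  config
}

#' Bundled demo configuration
#'
#' A desk-scale pipeline configuration (small sample, reduced resampling)
#' used by examples and the end-to-end determinism checks.
#'
#' @return The configuration list.
#' @export
demo_config <- function() {
  read_run_config(system.file("extdata", "demo_config.yaml",
                              package = "traitfactor", mustWork = TRUE))
}

pipeline_stage <- function(name, manifest, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop_arg("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
  list(result = res,
       timing = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end on one configuration: simulate (or load)
#' questionnaire data, cross-validated rank scan, final factorizations at
#' the chosen ranks, subgroup generalizability (when group labels exist),
#' and the directional prediction scan on phenotypes simulated in the
#' fitted 2-factor score plane. Every artifact is written under the output
#' directory and listed, with its MD5 content hash, in `manifest.json`
#' together with the resolved configuration and per-stage timings. All
#' randomness derives from the single master seed, so a rerun of the same
#' configuration is bit-identical.
#'
#' @param config A configuration list or path to a YAML/JSON file; see
#'   [demo_config()] for the expected shape.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop_arg("no output directory given")
  # validate inputs before any compute
  if (!is.null(config$input)) {
    for (p in unlist(config$input)) {
      if (!file.exists(p)) stop_arg("input file not found: ", p)
    }
  } else if (is.null(config$synth)) {
    stop_arg("config needs either 'input' paths or a 'synth' block")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  timings <- list()
  files <- character()

  # ---- stage: data -------------------------------------------------------
  st <- pipeline_stage("data", NULL, {
    if (!is.null(config$input)) {
      rm <- load_responses(config$input$responses, config$input$item_key,
                           config$input$subject_meta)
      list(responses = rm, true_scores = NULL, truth = NULL)
    } else {
      sy <- config$synth
      truth <- build_true_loadings(
        n_items_per_dimension = sy$n_items_per_dimension %||% 6,
        structure = sy$structure %||% "big2_hier",
        cross_loading = sy$cross_loading %||% 0.1,
        seed = derive_seed(seed, 1),
        noise_sd = sy$noise_sd %||% 0.5,
        missing_rate = sy$missing_rate %||% 0,
        acquiescence_sd = sy$acquiescence_sd %||% 0,
        group_spec = if (!is.null(sy$groups)) {
          # YAML 1.1 parses a bare `n` key as a boolean, so group sizes are
          # written as `size`; accept either spelling
          dplyr::bind_rows(lapply(sy$groups, function(g) {
            tibble::tibble(label = g[["label"]],
                           n = g[["n"]] %||% g[["size"]],
                           perturb_sd = g[["perturb_sd"]] %||% 0,
                           noise_mult = g[["noise_mult"]] %||% 1)
          }))
        }
      )
      if (!is.null(truth$group_spec)) {
        simulate_subgroups(truth)
      } else {
        simulate_responses(truth, sy$n_subjects %||% 400)
      }
    }
  })
  timings$data <- st$timing
  sim <- st$result
  if (!is.null(sim$truth)) {
    files <- c(files, write_synthetic(sim, file.path(out_dir, "data")))
  }
  R <- apply_reverse_scoring(sim$responses)

  # ---- stage: rank scan --------------------------------------------------
  rs_cfg <- config$rank_scan %||% list()
  st <- pipeline_stage("rank_scan", NULL, {
    records <- run_crossvalidation(
      R, ranks = unlist(rs_cfg$ranks) %||% 2:8,
      scheme = rs_cfg$scheme %||% "kfold",
      n_reps = rs_cfg$n_reps %||% 1000,
      n_folds = rs_cfg$n_folds %||% 5,
      seed = derive_seed(seed, 2),
      control = list(max_iter = rs_cfg$max_iter %||% 2000)
    )
    list(records = records,
         selection = summarize_rank_selection(records,
                                              seed = derive_seed(seed, 3)))
  })
  timings$rank_scan <- st$timing
  rec_file <- file.path(out_dir, "cv_records.csv")
  write_cv_records(st$result$records, rec_file)
  sel_file <- file.path(out_dir, "rank_selection.json")
  jsonlite::write_json(st$result$selection$summary, sel_file, digits = NA,
                       pretty = TRUE)
  files <- c(files, rec_file, sel_file)
  selection <- st$result$selection

  # ---- stage: fit --------------------------------------------------------
  fit_ranks <- unlist(config$fit$ranks) %||% selection$optimal_ranks
  X <- impute_missing(R)
  st <- pipeline_stage("fit", NULL, {
    models <- lapply(fit_ranks, function(r) fit_opnmf(X, r))
    names(models) <- paste0("rank", fit_ranks)
    models
  })
  timings$fit <- st$timing
  models <- st$result
  for (nm in names(models)) {
    files <- c(files, write_opnmf(models[[nm]],
                                  file.path(out_dir, paste0("model_", nm)),
                                  preprocessing = "item_mean"))
  }

  # ---- stage: subgroup ---------------------------------------------------
  sg_cfg <- config$subgroup
  if (!is.null(sg_cfg) &&
      (sg_cfg$label_field %||% "group") %in% names(R$subject_meta)) {
    st <- pipeline_stage("subgroup", NULL, {
      rank_sg <- sg_cfg$rank %||% fit_ranks[1]
      model_sg <- models[[paste0("rank", rank_sg)]] %||%
        fit_opnmf(X, rank_sg)
      rep <- subgroup_report(model_sg, R,
                             sg_cfg$label_field %||% "group",
                             rank = rank_sg,
                             n_null = sg_cfg$n_null %||% 100,
                             seed = derive_seed(seed, 4))
      reg <- if (nrow(rep) >= 4) explain_generalizability(rep)
      list(report = rep, regressions = reg)
    })
    timings$subgroup <- st$timing
    sg_file <- file.path(out_dir, "subgroup_report.csv")
    readr::write_csv(st$result$report, sg_file)
    files <- c(files, sg_file)
    if (!is.null(st$result$regressions)) {
      reg_file <- file.path(out_dir, "subgroup_regressions.json")
      jsonlite::write_json(st$result$regressions, reg_file, digits = NA,
                           pretty = TRUE)
      files <- c(files, reg_file)
    }
  }

  # ---- stage: direction scan --------------------------------------------
  ds_cfg <- config$direction_scan
  if (!is.null(ds_cfg)) {
    st <- pipeline_stage("direction_scan", NULL, {
      m2 <- models[["rank2"]] %||% fit_opnmf(X, 2)
      H <- t(project_scores(m2, X))
      colnames(H) <- c("SA", "SM")
      sc <- standardize_scores(H)
      ph <- simulate_phenotypes(
        as.matrix(sc[, c("SA", "SM")]),
        theta_true = ds_cfg$theta_true %||% 147,
        n_features = ds_cfg$n_features %||% 40,
        signal_fraction = ds_cfg$signal_fraction %||% 0.5,
        noise_sd = ds_cfg$noise_sd %||% 0.5,
        family_size = ds_cfg$family_size %||% 1,
        seed = derive_seed(seed, 5)
      )
      step <- ds_cfg$angles_step %||% 1
      direction_scan(
        ph, sc, angles = seq(step, 180, by = step),
        n_reps = ds_cfg$n_reps %||% 30,
        n_folds = ds_cfg$n_folds %||% 5,
        n_perm = ds_cfg$n_perm %||% 5000,
        alpha_fdr = ds_cfg$alpha_fdr %||% 0.05,
        seed = derive_seed(seed, 6),
        K_grid = unlist(ds_cfg$K_grid) %||% NULL,
        eta_grid = unlist(ds_cfg$eta_grid) %||% seq(0.05, 1, by = 0.05),
        family_id = ph$family_id
      )
    })
    timings$direction_scan <- st$timing
    files <- c(files, write_direction_scan(
      st$result, file.path(out_dir, "direction_scan")))
  }

  # ---- manifest ----------------------------------------------------------
  files <- unname(files)
  out_norm <- normalizePath(out_dir)
  manifest <- list(
    config = config,
    seed = seed,
    files = lapply(files, function(f) {
      rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", out_norm),
                        "/?"), "", normalizePath(f))
      list(file = rel, md5 = unname(tools::md5sum(f)))
    }),
    timings_sec = lapply(timings, round, 2)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
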