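# End-to-end orchestration: synthetic or file-based inputs, staged
# execution with content-addressed caching, long-format CSV/JSON outputs.

#' Build and validate a pipeline configuration
#'
#' @param mode `"synthetic"` (generate cohort + tractograms from
#'   `params`) or `"real"` (read cohort CSV and, if disconnection columns
#'   are absent, lesion masks, parcellation and tractograms from `paths`).
#' @param seed mandatory integer seed; every stage derives its own
#'   substream from it.
#' @param out_dir output directory (created if needed).
#' @param n synthetic cohort size.
#' @param cohort_mode `"imaging"` or `"tabular"` synthetic generation.
#' @param params list of [cohort_params()] overrides.
#' @param k_bootstrap bootstrap resamples for mediation.
#' @param fdr_q step-down FDR level.
#' @param i_max,j_max region-selection threshold sweep bounds.
#' @param subset_null_k random-subset null draws (0 disables).
#' @param paths named list for real mode: `cohort_csv`, and optionally
#'   `parcellation_nii`, `parcellation_csv`, `masks_dir` (files
#'   `<id>_T1.nii[.gz]`, `<id>_T2.nii[.gz]`), `tractogram_dir` (`.tck`).
#' @param cache reuse stage results keyed on the configuration hash.
#' @param verbose log stage progress to stderr.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"), seed, out_dir,
                            n = 40, cohort_mode = c("imaging", "tabular"),
                            params = list(), k_bootstrap = 200,
                            fdr_q = 0.05, i_max = 9, j_max = 15,
                            subset_null_k = 200, paths = list(),
                            cache = TRUE, verbose = FALSE) {
  mode <- match.arg(mode)
  cohort_mode <- match.arg(cohort_mode)
  assert_that(!missing(seed) && is.finite(seed), "seed is mandatory",
              class = "chacomed_config")
  assert_that(!missing(out_dir), "out_dir is mandatory",
              class = "chacomed_config")
  if (mode == "real") {
    assert_that(!is.null(paths$cohort_csv), "real mode needs paths$cohort_csv",
                class = "chacomed_config")
    for (p in unlist(paths))
      if (!file.exists(p) && !dir.exists(p))
        stop_chacomed("configured path does not exist: ", p,
                      class = "chacomed_config")
  }
  cp <- do.call(cohort_params, c(params, list(seed = as.integer(seed))))
  structure(list(mode = mode, seed = as.integer(seed), out_dir = out_dir,
                 n = n, cohort_mode = cohort_mode, params = cp,
                 k_bootstrap = k_bootstrap, fdr_q = fdr_q, i_max = i_max,
                 j_max = j_max, subset_null_k = subset_null_k,
                 paths = paths, cache = cache, verbose = verbose),
            class = "pipeline_config")
}

config_hash <- function(config, stage) {
  key <- config[setdiff(names(config), c("out_dir", "cache", "verbose"))]
  rlang::hash(list(key, stage))
}

pipeline_log <- function(config, ...) {
  msg <- paste0(...)
  if (config$verbose) message("[chacomed] ", msg)
  cat(msg, "\n", file = file.path(config$out_dir, "run.log"),
      append = TRUE)
}

run_stage <- function(config, stage, fun) {
  cache_file <- file.path(config$out_dir, "cache",
                          paste0(config_hash(config, stage), ".rds"))
  if (config$cache && file.exists(cache_file)) {
    pipeline_log(config, "stage ", stage, ": cached")
    return(readRDS(cache_file))
  }
  pipeline_log(config, "stage ", stage, ": running")
  res <- tryCatch(fun(), error = function(e) {
    pipeline_log(config, "stage ", stage, " FAILED: ", conditionMessage(e))
    stop_chacomed("stage '", stage, "' failed: ", conditionMessage(e),
                  class = "chacomed_stage")
  })
  if (config$cache) saveRDS(res, cache_file)
  res
}

#' Run the full analysis pipeline
#'
#' Stages in dependency order: `simulate` (or load), `chaco`, `scan`,
#' `models`, `select`, `mediate`. Every table is written as long-format
#' CSV and nested results as JSON under `out_dir`; stage results are
#' cached keyed on the configuration hash, so a rerun with an identical
#' config is a cache replay with byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (dependencies are run or read
#'   from cache automatically).
#' @return a `report_bundle` list: `cohort`, `chaco_long`, `scan`,
#'   `models`, `selection`, `mediation`, `files` (paths of all outputs),
#'   `config_hash`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "chaco", "scan", "models",
                                    "select", "mediate")) {
  assert_that(inherits(config, "pipeline_config"), "not a pipeline_config")
  dir.create(file.path(config$out_dir, "cache"), recursive = TRUE,
             showWarnings = FALSE)
  files <- character(0)
  out <- function(name) file.path(config$out_dir, name)
  stages <- match.arg(stages, several.ok = TRUE)
  want <- function(s) s %in% stages

  # --- simulate / load ------------------------------------------------
  sim <- run_stage(config, "simulate", function() {
    if (config$mode == "synthetic") {
      cohort <- generate_cohort(config$params, config$n,
                                seed = derive_seed(config$seed, "cohort"),
                                mode = config$cohort_mode)
      list(cohort = cohort)
    } else {
      cohort <- read_cohort_csv(config$paths$cohort_csv)
      if (!length(dchaco_columns(cohort$table))) {
        assert_that(!is.null(config$paths$parcellation_nii) &&
                      !is.null(config$paths$tractogram_dir) &&
                      !is.null(config$paths$masks_dir),
                    "cohort CSV has no dchaco columns; need parcellation, ",
                    "masks and tractograms to compute ChaCo",
                    class = "chacomed_config")
        parc <- read_parcellation_nifti(config$paths$parcellation_nii,
                                        config$paths$parcellation_csv)
        tcks <- list.files(config$paths$tractogram_dir, "\\.tck$",
                           full.names = TRUE)
        refs <- lapply(tcks, function(f)
          assign_endpoints(read_tck(f, parc$voxel_size_mm), parc))
        patients <- lapply(seq_len(nrow(cohort$table)), function(i) {
          id <- cohort$table$id[i]
          masks <- lapply(c("T1", "T2"), function(tp) {
            f <- list.files(config$paths$masks_dir,
                            paste0("^", id, "_", tp, "\\.nii(\\.gz)?$"),
                            full.names = TRUE)
            assert_that(length(f) == 1, "missing mask for ", id, " ", tp,
                        class = "chacomed_config")
            nii <- read_nifti(f)
            lesion_mask(nii$data > 0, nii$voxel_size_mm)
          })
          pr <- lapply(seq_along(masks), function(k)
            restrict_to_stroke_hemisphere(
              chaco_score(refs, parc, masks[[k]], c("T1", "T2")[k], id),
              masks[[k]], parc))
          list(id = id, masks = masks,
               chaco = setNames(pr, c("T1", "T2")),
               dchaco = chaco_change(pr[[1]], pr[[2]]))
        })
        nreg <- length(patients[[1]]$dchaco)
        dmat <- t(vapply(patients, function(p) as.numeric(p$dchaco),
                         numeric(nreg)))
        colnames(dmat) <- paste0("dchaco_", seq_len(nreg))
        cohort$table <- cbind(cohort$table, as.data.frame(dmat))
        cohort$patients <- patients
        cohort$mode <- "imaging"
      }
      list(cohort = cohort)
    }
  })
  cohort <- sim$cohort
  f <- out("cohort.csv"); write_cohort_csv(cohort, f); files <- c(files, f)

  # --- chaco long table ----------------------------------------------
  chaco_long <- NULL
  if (cohort$mode == "imaging" && want("chaco")) {
    chaco_long <- run_stage(config, "chaco",
                            function() cohort_chaco_long(cohort))
    f <- out("chaco_long.csv")
    write.csv(chaco_long, f, row.names = FALSE); files <- c(files, f)
  }

  # --- rank-based scan ------------------------------------------------
  scan <- NULL
  if (!is.null(chaco_long) && want("scan")) {
    scan <- run_stage(config, "scan", function() region_scan(chaco_long))
    f <- out("region_scan.csv")
    write.csv(scan, f, row.names = FALSE); files <- c(files, f)
  }

  # --- parametric models ---------------------------------------------
  models <- NULL
  if (want("models")) {
    models <- run_stage(config, "models", function() {
      res <- list(outcome_arm = outcome_logistic(cohort, "arm"),
                  outcome_growth = outcome_logistic(cohort, "growth"))
      if (!is.null(chaco_long)) {
        mx <- fit_mixture(chaco_long, zero_part = FALSE)
        res$anova <- mx$wald
        res$interaction <- mx$interaction
        res$arm_ratios <- arm_time_ratios(mx)
      }
      res
    })
    f <- out("outcome_models.csv")
    write.csv(rbind(cbind(model = "arm", models$outcome_arm),
                    cbind(model = "growth", models$outcome_growth)),
              f, row.names = FALSE); files <- c(files, f)
    if (!is.null(models$anova)) {
      f <- out("anova_table.csv")
      write.csv(models$anova, f, row.names = FALSE); files <- c(files, f)
    }
  }

  # --- region selection ----------------------------------------------
  selection <- NULL
  if (want("select")) {
    selection <- run_stage(config, "select", function() {
      ranking <- qualify_and_rank(responsiveness_scan(cohort),
                                  eloquence_scan(cohort))
      specs <- enumerate_models(ranking, config$i_max, config$j_max)
      list(ranking = ranking, specs = specs)
    })
    f <- out("region_ranking.csv")
    write.csv(selection$ranking$table, f, row.names = FALSE)
    files <- c(files, f)
    f <- out("mediation_models.json")
    jsonlite::write_json(
      lapply(selection$specs, function(s)
        list(label = s$label, regions = s$regions,
             provenance = s$provenance)),
      f, auto_unbox = TRUE, null = "null")
    files <- c(files, f)
  }

  # --- mediation ------------------------------------------------------
  mediation <- NULL
  if (want("mediate")) {
    assert_that(!is.null(selection), "mediate stage requires select stage")
    mediation <- run_stage(config, "mediate", function() {
      specs <- selection$specs
      est <- lapply(specs, function(s) estimate_mediation(cohort, s))
      names(est) <- vapply(specs, function(s) s$label, "")
      boot <- bootstrap_effects(cohort, specs, k = config$k_bootstrap,
                                seed = derive_seed(config$seed, "mediate"))
      nies <- vapply(est, function(e) e$nie, 0)
      per_model <- lapply(names(est), function(lb) {
        e <- est[[lb]]
        cis <- lapply(c(nie = "nie", nde = "nde", te = "te", pm = "pm"),
                      function(fld) {
                        ci <- bc_interval(boot[[fld]][, lb], e[[fld]])
                        list(estimate = e[[fld]], lo = ci[["lo"]],
                             hi = ci[["hi"]])
                      })
        c(list(label = lb), cis)
      })
      ratios <- if (length(specs) > 1)
        lapply(names(est)[-1], function(lb)
          c(list(label = lb), nie_ratio(boot, nies, lb)))
      else NULL
      sd_res <- if (length(specs) > 1)
        stepdown_fdr(nies, boot, q = config$fdr_q) else NULL
      subnull <- if (config$subset_null_k > 0 &&
                     length(dchaco_columns(cohort$table)))
        random_subset_null(cohort, k = config$subset_null_k,
                           seed = derive_seed(config$seed, "subset"))
      else NULL
      list(estimates = per_model, ratios = ratios, stepdown = sd_res,
           subset_null = if (!is.null(subnull))
             list(median_nie = median(subnull$nie),
                  growth_only_nie = subnull$growth_only_nie,
                  observed_percentiles =
                    setNames(as.list(subnull$percentile(nies)), names(nies)),
                  n_redrawn = subnull$n_redrawn))
    })
    f <- out("mediation_results.json")
    jsonlite::write_json(
      list(estimates = mediation$estimates, ratios = mediation$ratios,
           stepdown = if (!is.null(mediation$stepdown))
             list(order = mediation$stepdown$order,
                  nie = as.list(mediation$stepdown$nie),
                  thresholds = mediation$stepdown$thresholds,
                  rejected = mediation$stepdown$rejected),
           subset_null = mediation$subset_null),
      f, auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, f)
  }

  pipeline_log(config, "done: ", length(files), " output files")
  structure(list(cohort = cohort, chaco_long = chaco_long, scan = scan,
                 models = models, selection = selection,
                 mediation = mediation, files = files,
                 config_hash = config_hash(config, "bundle")),
            class = "report_bundle")
}

#' Command-line entry point
#'
#' Usage: `Rscript -e 'chacomed::cli_main()' <command> [--config FILE]
#' [--seed INT] [--out DIR] [--n INT] [--k INT] [--verbose]` with command
#' one of `simulate`, `chaco`, `scan`, `models`, `select`, `mediate`,
#' `run-all`. The JSON config file may contain any [pipeline_config()]
#' field; flags override it.
#'
#' @param args character vector (default: command line).
#' @return the report bundle, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  assert_that(length(args) >= 1, "usage: <command> [options]",
              class = "chacomed_config")
  command <- args[[1]]
  valid <- c("simulate", "chaco", "scan", "models", "select", "mediate",
             "run-all")
  assert_that(command %in% valid, "unknown command '", command, "'",
              class = "chacomed_config")
  opts <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[i]
    take <- function() { i <<- i + 1L; rest[i] }
    switch(a,
           "--config" = { opts$config_file <- take() },
           "--seed" = { opts$seed <- as.integer(take()) },
           "--out" = { opts$out_dir <- take() },
           "--n" = { opts$n <- as.integer(take()) },
           "--k" = { opts$k_bootstrap <- as.integer(take()) },
           "--verbose" = { opts$verbose <- TRUE },
           "--quiet" = { opts$verbose <- FALSE },
           stop_chacomed("unknown flag ", a, class = "chacomed_config"))
    i <- i + 1L
  }
  cfg_list <- list()
  if (!is.null(opts$config_file)) {
    cfg_list <- jsonlite::read_json(opts$config_file, simplifyVector = TRUE)
    cfg_list$params <- as.list(cfg_list$params)
  }
  for (nm in c("seed", "out_dir", "n", "k_bootstrap", "verbose"))
    if (!is.null(opts[[nm]])) cfg_list[[nm]] <- opts[[nm]]
  config <- do.call(pipeline_config, cfg_list)
  stages <- if (command == "run-all")
    c("simulate", "chaco", "scan", "models", "select", "mediate")
  else switch(command,
              simulate = "simulate",
              chaco = c("simulate", "chaco"),
              scan = c("simulate", "chaco", "scan"),
              models = c("simulate", "chaco", "models"),
              select = c("simulate", "select"),
              mediate = c("simulate", "select", "mediate"))
  invisible(run_pipeline(config, stages))
}
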