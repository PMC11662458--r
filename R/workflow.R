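# End-to-end orchestration: simulate -> select -> fit -> predict ->
# aggregate -> validate, with per-stage manifests (parameter hash, seed,
# package version) and deterministic per-stage seeds derived from one
# global seed, so any stage can be rerun in isolation and full reruns are
# bit-for-bit reproducible. No timestamps enter any output.

PIPELINE_STAGES <- c("simulate", "select", "fit", "predict", "aggregate", "validate")

#' Deterministic per-stage seed
#'
#' Hashes the stage name into the global seed so stages draw from
#' independent, reproducible streams.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 131 + h * 977) %% 2147483629)
}

validate_pipeline_config <- function(config) {
  allowed <- c("seed", "out_dir", "stages", PIPELINE_STAGES)
  bad <- setdiff(names(config), allowed)
  if (length(bad)) {
    stop("unknown pipeline config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stages <- config$stages %||% PIPELINE_STAGES
  bad_st <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad_st)) {
    stop("unknown stages: ", paste(bad_st, collapse = ", "), call. = FALSE)
  }
  # keep canonical dependency order
  config$stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

params_hash <- function(params) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(params, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

write_stage_manifest <- function(out_dir, stage, params, seed) {
  manifest <- list(stage = stage, seed = seed,
                   config_hash = params_hash(params),
                   version = as.character(utils::packageVersion("agbgeo")))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

stage_resumable <- function(out_dir, stage, params, seed) {
  if (is.null(out_dir)) return(FALSE)
  mf <- file.path(out_dir, paste0(stage, "_manifest.json"))
  st <- file.path(out_dir, paste0("state_", stage, ".rds"))
  if (!file.exists(mf) || !file.exists(st)) return(FALSE)
  old <- jsonlite::read_json(mf, simplifyVector = TRUE)
  identical(old$config_hash, unname(params_hash(params))) &&
    identical(as.integer(old$seed), as.integer(seed))
}

#' Run the analysis pipeline on synthetic data
#'
#' Executes the requested stages in dependency order. `simulate` generates
#' a joint plot + pixel-grid dataset; `select` screens the 17 candidate
#' metrics; `fit` runs the covariate geostatistical MCMC on the selected
#' metrics; `predict` composition-samples pixel AGB summaries; `aggregate`
#' produces management-unit totals; `validate` runs the ten-fold
#' cross-validation. When `out_dir` is set, every stage writes its outputs
#' (CSV/JSON), a manifest with a parameter hash and seed, and a state file
#' used to resume: rerunning with an unchanged manifest skips the stage.
#'
#' @param config nested list (or path to a JSON file): global `seed`,
#'   optional `out_dir`, optional `stages` subset, and one parameter block
#'   per stage (`simulate`: `n_plots`, `extent_km`, `cell_size_m`, `n_mu`
#'   plus [sim_config()] overrides; `fit`/`validate`: `n_iter`, `n_burn`,
#'   `thin`, `k`; `predict`: `mode`; `aggregate`: `pixel_area_ha`).
#' @return named list of stage results (invisible).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- validate_pipeline_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  state <- list()

  load_or_run <- function(stage, params, runner) {
    seed <- stage_seed(config$seed, stage)
    if (stage_resumable(out_dir, stage, params, seed)) {
      message("stage ", stage, ": resumed from manifest")
      return(readRDS(file.path(out_dir, paste0("state_", stage, ".rds"))))
    }
    res <- runner(seed)
    if (!is.null(out_dir)) {
      saveRDS(res, file.path(out_dir, paste0("state_", stage, ".rds")))
      write_stage_manifest(out_dir, stage, params, seed)
    }
    res
  }
  need <- function(stage, what) {
    if (is.null(state[[what]])) {
      stop("stage ", stage, " needs upstream output '", what,
           "'; run the ", what, " stage first", call. = FALSE)
    }
    state[[what]]
  }

  for (stage in config$stages) {
    params <- config[[stage]] %||% list()
    if (stage == "simulate") {
      state$simulate <- load_or_run(stage, params, function(seed) {
        sc_args <- params[setdiff(names(params), c("extent_km", "cell_size_m", "n_mu"))]
        sc_args$seed <- sc_args$seed %||% seed
        sc <- do.call(sim_config, sc_args)
        generate_pixel_grid(sc,
                            extent_km = params$extent_km %||% c(1.5, 1.5),
                            cell_size_m = params$cell_size_m %||% 30,
                            n_mu = params$n_mu %||% 2L,
                            n_plots = sc$n_plots)
      })
      if (!is.null(out_dir)) {
        write_plot_csv(state$simulate$plots, file.path(out_dir, "plots.csv"))
        utils::write.csv(state$simulate$metrics, file.path(out_dir, "metrics.csv"),
                         row.names = FALSE)
        utils::write.csv(state$simulate$grid, file.path(out_dir, "grid.csv"),
                         row.names = FALSE)
        truth <- state$simulate$truth
        jsonlite::write_json(truth[!vapply(truth, is.function, logical(1))],
                             file.path(out_dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    } else if (stage == "select") {
      sim <- need(stage, "simulate")
      state$select <- load_or_run(stage, params, function(seed) {
        select_best(sim$plots$agb_sqrt, sim$metrics)
      })
      if (!is.null(out_dir)) {
        utils::write.csv(state$select$ranking, file.path(out_dir, "ranking.csv"),
                         row.names = FALSE)
        jsonlite::write_json(list(best = state$select$best),
                             file.path(out_dir, "selection.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    } else if (stage == "fit") {
      sim <- need(stage, "simulate")
      sel <- need(stage, "select")
      state$fit <- load_or_run(stage, params, function(seed) {
        cfg <- mcmc_config(n_iter = params$n_iter %||% 25000L,
                           n_burn = params$n_burn %||% 5000L,
                           thin = params$thin %||% 10L,
                           seed = seed)
        run_mcmc(sim$plots, sim$metrics,
                 spec = model_spec("covariate", sel$best), config = cfg)
      })
      if (!is.null(out_dir)) {
        summ <- summarize_posterior(state$fit)
        jsonlite::write_json(summ, file.path(out_dir, "posterior_summary.json"),
                             digits = NA)
        s <- state$fit$samples
        utils::write.csv(data.frame(s$beta, sigma2 = s$sigma2, tau2 = s$tau2,
                                    phi = s$phi, eff_range_km = s$eff_range_km,
                                    check.names = FALSE),
                         file.path(out_dir, "draws.csv"), row.names = FALSE)
      }
    } else if (stage == "predict") {
      sim <- need(stage, "simulate")
      fit <- need(stage, "fit")
      state$predict <- load_or_run(stage, params, function(seed) {
        predict_agb(fit, sim$grid, seed = seed,
                    mode = params$mode %||% "independent")
      })
      if (!is.null(out_dir)) {
        utils::write.csv(state$predict, file.path(out_dir, "pixel_summary.csv"),
                         row.names = FALSE)
      }
    } else if (stage == "aggregate") {
      sim <- need(stage, "simulate")
      fit <- need(stage, "fit")
      state$aggregate <- load_or_run(stage, params, function(seed) {
        use <- !sim$grid$mask_flag
        draws <- composition_predict(fit, sim$grid[use, c("x_km", "y_km")],
                                     new_metrics = sim$grid[use, , drop = FALSE],
                                     seed = seed)
        mu_joint_estimate(back_transform(draws), sim$grid$mu[use],
                          pixel_area_ha = params$pixel_area_ha %||% 0.09)
      })
      if (!is.null(out_dir)) {
        utils::write.csv(state$aggregate, file.path(out_dir, "mu_estimates.csv"),
                         row.names = FALSE)
        jsonlite::write_json(state$aggregate, file.path(out_dir, "mu_estimates.json"),
                             digits = NA)
      }
    } else if (stage == "validate") {
      sim <- need(stage, "simulate")
      sel <- need(stage, "select")
      state$validate <- load_or_run(stage, params, function(seed) {
        cfg <- mcmc_config(n_iter = params$n_iter %||% 6000L,
                           n_burn = params$n_burn %||% 1500L,
                           thin = params$thin %||% 5L,
                           seed = seed)
        cv_run(sim$plots, sim$metrics,
               spec = model_spec("covariate", sel$best),
               config = cfg, k = params$k %||% 10L, seed = seed)
      })
      if (!is.null(out_dir)) {
        v <- state$validate
        jsonlite::write_json(v[c("rmse", "rse_pct", "r2", "bias",
                                 "coverage_pct", "mean_ci_width", "n")],
                             file.path(out_dir, "validation.json"),
                             auto_unbox = TRUE, digits = NA)
        utils::write.csv(v$per_plot, file.path(out_dir, "per_plot.csv"),
                         row.names = FALSE)
      }
    }
  }
  invisible(state)
}
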