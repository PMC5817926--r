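# Configuration and pipeline orchestration: a YAML run configuration ties
# the stages together (simulate -> analyze -> fit), with every output
# carrying the configuration hash and the master seed so reruns are
# reproducible.

.CONFIG_KEYS <- c("seed", "out_dir", "stages", "scheme", "protocol",
                  "simulation", "sweep", "analysis", "fit")

#' Read and validate a YAML run configuration
#'
#' Top-level keys: \code{seed}, \code{out_dir}, \code{stages} (subset of
#' simulate/analyze/fit), \code{scheme} (kinetic_scheme fields),
#' \code{protocol} (force_quench_protocol arguments), \code{simulation}
#' (sim_config fields), \code{sweep} (\code{variable}: t_q, t_ext or
#' extend_force; \code{values}), \code{analysis} (yield_qc fields and
#' \code{bootstrap_B}), \code{fit} (\code{free}, \code{n_starts}).
#' Unknown keys are rejected with their location. All units follow the
#' package convention: seconds, piconewtons, molar.
#'
#' @param path YAML file.
#' @return a named list of class \code{run_config}; the raw text's MD5
#'   hash is stored in \code{attr(, "hash")}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration keys at top level: ",
         paste(unknown, collapse = ", "))
  for (sec in c("scheme", "protocol", "simulation", "sweep", "analysis", "fit")) {
    if (is.null(cfg[[sec]])) next
    ok <- switch(sec,
      scheme = names(formals(kinetic_scheme)),
      protocol = names(formals(force_quench_protocol)),
      simulation = names(formals(sim_config)),
      sweep = c("variable", "values"),
      analysis = c(names(formals(yield_qc)), "bootstrap_B"),
      fit = c("free", "n_starts", "lower", "upper"))
    unknown <- setdiff(names(cfg[[sec]]), ok)
    if (length(unknown))
      stop("unknown keys in section '", sec, "': ",
           paste(unknown, collapse = ", "))
  }
  attr(cfg, "hash") <- unname(tools::md5sum(path))
  class(cfg) <- "run_config"
  cfg
}

#' Run the simulate / analyze / fit pipeline from a configuration
#'
#' Executes the selected stages in order. \code{simulate} generates one
#' refolding dataset per sweep value (CSV) and, for the first few
#' recordings of the first condition, trace TSV files; \code{analyze}
#' computes per-condition pooled yields with bootstrap SEMs and the sweep
#' exponential fit (results JSON); \code{fit} runs the chi-square model
#' fit for the configured free rates (fitted-parameters JSON). Each stage
#' failure aborts with an error naming the stage. With identical
#' configuration and seed the emitted JSON is byte-identical.
#'
#' @param config a \code{run_config} (or path to one).
#' @param render_traces how many recordings of the first condition to
#'   render and write as trace files (0 disables).
#' @return invisibly, a list with the datasets, analysis summary and fit.
#' @export
run_pipeline <- function(config, render_traces = 3) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages %||% c("simulate", "analyze", "fit")
  out_dir <- config$out_dir %||% "fc_results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- attr(config, "hash") %||% "unhashed"
  seed <- config$seed %||% 1
  log_msg <- function(...) message(sprintf("[foldclamp] %s", sprintf(...)))

  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_msg("stage %s done in %.1f s", stage, proc.time()[["elapsed"]] - t0)
    res
  }

  scheme <- do.call(kinetic_scheme, config$scheme %||% list())
  proto_args <- config$protocol %||% list()
  sweep <- config$sweep %||% list(variable = "t_q", values = c(0.5, 1, 2, 5, 10, 15))
  sim_args <- config$simulation %||% list()
  sim_args$seed <- sim_args$seed %||% seed

  out <- list(hash = hash, seed = seed)

  if ("simulate" %in% stages) {
    out$datasets <- run_stage("simulate", {
      datasets <- list()
      for (i in seq_along(sweep$values)) {
        v <- sweep$values[[i]]
        pa <- proto_args
        pa[[sweep$variable]] <- v
        protocol <- do.call(force_quench_protocol, pa)
        cfg_i <- do.call(sim_config, c(sim_args[setdiff(names(sim_args), "seed")],
                                       list(seed = sim_args$seed + i)))
        cond <- sprintf("%s=%g", sweep$variable, v)
        sim <- simulate_experiment(scheme, protocol, cfg_i,
                                   render_traces = (i == 1L && render_traces > 0),
                                   condition = cond)
        f <- file.path(out_dir, sprintf("dataset_%s.csv", gsub("[=.]", "_", cond)))
        write_dataset(sim$dataset, f,
                      metadata = list(config_hash = hash, seed = cfg_i$seed))
        if (i == 1L && render_traces > 0) {
          for (r in seq_len(min(render_traces, length(sim$traces))))
            write_trace(sim$traces[[r]],
                        file.path(out_dir, sprintf("trace_%03d.tsv", r)))
        }
        datasets[[cond]] <- sim$dataset
      }
      datasets
    })
  }

  if ("analyze" %in% stages) {
    out$analysis <- run_stage("analyze", {
      datasets <- out$datasets
      if (is.null(datasets)) stop("no datasets in memory; run the simulate stage")
      an_cfg <- config$analysis %||% list()
      qc <- do.call(yield_qc, an_cfg[setdiff(names(an_cfg), "bootstrap_B")])
      B <- an_cfg$bootstrap_B %||% 500
      sweep_col <- if (sweep$variable %in% c("t_q", "t_ext")) sweep$variable else NULL
      res <- analyze_refolding(datasets, sweep = sweep_col, qc = qc,
                               B = B, seed = seed)
      json <- list(config_hash = hash, seed = seed,
                   conditions = lapply(res$conditions, function(x)
                     x[c("yield", "sem", "n_recordings", "n_domains")]))
      if (!is.null(res$fit) && res$fit$ok)
        json$fit <- list(form = res$fit$form, rate = res$fit$rate,
                         rate_se = res$fit$rate_se,
                         plateau = res$fit$amplitude)
      write_results_json(json, file.path(out_dir, "analysis.json"))
      res
    })
  }

  if ("fit" %in% stages) {
    out$fit <- run_stage("fit", {
      res <- out$analysis
      if (is.null(res)) stop("no analysis in memory; run the analyze stage")
      fit_cfg <- config$fit %||% list()
      sweep_var <- if (sweep$variable == "extend_force") "force" else sweep$variable
      fd <- fit_dataset(data.frame(
        x = res$curve[[1]],
        yield = res$curve$yield, sem = res$curve$sem),
        sweep = sweep_var,
        t_ext = proto_args$t_ext %||% 5,
        extend_force = proto_args$extend_force %||%
          proto_args$unfold_force %||% 120,
        t_q = proto_args$t_q %||% 5)
      spec <- suppressWarnings(fit_spec(
        scheme, list(fd),
        free = fit_cfg$free %||% c("k_on_ext", "k_off_ext"),
        n_starts = fit_cfg$n_starts %||% 8))
      fp <- fit_model(spec, seed = seed)
      json <- list(config_hash = hash, seed = seed,
                   params = as.list(fp$params), Kd = fp$Kd,
                   chisq = fp$chisq, n_points = fp$n_points,
                   converged = fp$converged)
      write_results_json(json, file.path(out_dir, "fitted_params.json"))
      fp
    })
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
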