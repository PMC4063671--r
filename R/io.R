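#' Load a run configuration from YAML
#'
#' Reads a YAML (or JSON) file of overrides and merges it over the package
#' defaults with validation; an empty file yields the default
#' configuration, unknown keys are an error (no silent typos).
#'
#' @param path Path to a YAML file.
#' @return A [priorcue_config()].
#' @export
config_load <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  for (nm in c("unimodal_table", "bimodal_table"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.data.frame(raw[[nm]])
  do.call(priorcue_config, raw)
}

trial_columns <- c("session", "prior_class", "prior_id", "cue_level",
                   "flipped", "location", "target_x", "cue_x",
                   "cue_distance", "response_x", "edge_excluded")

#' Read and write trial datasets as CSV
#'
#' The on-disk dialect is one row per trial with the documented trial
#' record columns (`session, prior_class, prior_id, cue_level, flipped,
#' location, target_x, cue_x, cue_distance, response_x, edge_excluded`
#' plus an optional `subject`). The 100 dot positions are not stored: they
#' are a deterministic function of the prior columns and the
#' configuration. Round-trips are lossless.
#'
#' @param dataset Trial records.
#' @param path File path.
#' @return `read_trials()` returns the data frame; `write_trials()` its
#'   path, invisibly.
#' @export
write_trials <- function(dataset, path) {
  keep <- intersect(c(trial_columns, "subject"), names(dataset))
  utils::write.csv(dataset[keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @param drop_edge Drop rows flagged by the edge filter?
#' @export
read_trials <- function(path, drop_edge = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_columns, names(d))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  bad <- which(!d$prior_class %in% c("gaussian", "unimodal", "bimodal") |
                 !d$prior_id %in% 1:8 | !is.finite(d$cue_x))
  if (length(bad))
    stop("malformed trial row(s) at line(s): ",
         paste(utils::head(bad + 1L), collapse = ", "))
  if (drop_edge) d <- d[!d$edge_excluded, , drop = FALSE]
  d
}

#' Serialize a fit result to JSON
#'
#' Point estimates, DIC and diagnostics (not the raw chains) with
#' parameter names and screen-unit values.
#'
#' @param fit An `mcmc_result`.
#' @param path Output path.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(list(
    model = fit$spec$id,
    theta_hat = as.list(fit$theta_hat),
    dic = fit$dic, p_d = fit$p_d,
    rhat = as.list(fit$rhat),
    n_samples = nrow(fit$samples),
    seed = fit$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions for shell use; see
#' `inst/cli/priorcue.R`. Subcommands: `simulate`, `fit`, `compare`,
#' `recover`, `reconstruct`, `report`.
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return Integer exit code, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: priorcue <command> [--key value ...]",
    "commands:",
    "  simulate    --group G --model M --seed N --out FILE [--config YAML]",
    "  fit         --model M --data FILE --seed N --out FILE [--config YAML]",
    "  compare     --dics FILE --out FILE [--alpha0 A] [--seed N]",
    "  recover     --model M --candidates M1,M2 --subjects N --seed N --out FILE",
    "  reconstruct --data FILE --class C --prior I --seed N --out FILE",
    "  report      --data FILE --out DIR [--config YAML]",
    sep = "\n")
  if (length(argv) == 0L || argv[1] %in% c("--help", "-h")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- argv[1]
  opts <- parse_cli_opts(argv[-1])
  cfg <- if (!is.null(opts$config)) config_load(opts$config) else priorcue_config()
  seed <- as.integer(opts$seed %||% 1L)
  code <- tryCatch({
    switch(cmd,
      simulate = {
        sub <- simulate_subject(opts$group %||% "gaussian",
                                opts$model %||% "SPK-P-L",
                                default_params(opts$model %||% "SPK-P-L"),
                                seed, cfg)
        write_trials(sub$data, opts$out)
        message("wrote ", nrow(sub$data), " trials to ", opts$out)
      },
      fit = {
        d <- read_trials(opts$data)
        fit <- fit_observer(opts$model, d, cfg, seed = seed)
        write_fit(fit, opts$out)
        message(opts$model, " DIC ", round(fit$dic, 1), " -> ", opts$out)
      },
      compare = {
        dm <- as.matrix(utils::read.csv(opts$dics, row.names = 1))
        fit <- bms_fit(dic_to_log_evidence(dm),
                       alpha0 = as.numeric(opts$alpha0 %||% 0.3), seed = seed)
        jsonlite::write_json(lapply(fit[c("model_probs", "exceedance_probs")],
                                    as.list),
                             opts$out, auto_unbox = TRUE, digits = NA)
        message("BMS -> ", opts$out)
      },
      recover = {
        rec <- recovery_experiment(opts$model,
                                   strsplit(opts$candidates, ",")[[1]],
                                   as.integer(opts$subjects %||% 4L),
                                   seed = seed, config = cfg)
        jsonlite::write_json(list(dic = as.data.frame(rec$dic),
                                  model_probs = as.list(rec$bms$model_probs)),
                             opts$out, auto_unbox = TRUE, digits = NA)
        message("recovery -> ", opts$out)
      },
      reconstruct = {
        d <- read_trials(opts$data)
        sub <- list(list(data = d, theta = default_params("SPK-L")))
        rec <- reconstruct_priors(sub, opts$class %||% "gaussian",
                                  as.integer(opts$prior %||% 1L),
                                  seed = seed, config = cfg)
        jsonlite::write_json(list(weights = colMeans(rec$weights),
                                  component_means = rec$component_means,
                                  component_sd = rec$component_sd),
                             opts$out, digits = NA)
        message("reconstruction -> ", opts$out)
      },
      report = {
        d <- read_trials(opts$data)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(condition_slopes(d, cfg),
                         file.path(opts$out, "condition_slopes.csv"),
                         row.names = FALSE)
        utils::write.csv(optimality_summary(d, cfg),
                         file.path(opts$out, "optimality_summary.csv"),
                         row.names = FALSE)
        message("report tables -> ", opts$out)
      },
      { cat(usage, "\n"); stop("unknown command: ", cmd) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
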