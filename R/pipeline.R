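#' Command-line pipeline entry point
#'
#' Dispatches the three pipeline subcommands from a character vector of
#' command-line arguments:
#' \describe{
#'   \item{`simulate --config cfg.yaml --out dir/`}{run the adjustment-model
#'     condition sweep; writes `peaks.csv`, `curves.csv`, `summary.json`.}
#'   \item{`synth --config cfg.yaml --out dir/`}{generate a synthetic
#'     behavioral dataset; writes `trials.csv`, `trajectories.csv`,
#'     `ratings.csv`.}
#'   \item{`analyze --trials f.csv --trajectories f.csv --ratings f.csv
#'     --out dir/`}{run the measurement pipeline; writes
#'     `accuracy_by_group.csv`, `auc_by_time_category.csv`, `rt_cdf.csv`,
#'     `irritation.csv`, `stats.json`.}
#' }
#' Every run writes a `manifest.json` (subcommand, config snapshot, seed,
#' timestamp, outputs, package version) and a `run.log`; re-running with the
#' manifest's config and seed reproduces the outputs. A global `--seed`
#' overrides the config seed.
#'
#' An executable wrapper suitable for `Rscript` ships at
#' `system.file("cli", "rrsat.R", package = "rrsat")`.
#'
#' @param argv Character vector of arguments, e.g.
#'   `c("synth", "--out", "out/")`.
#' @return Invisibly, an integer exit code: 0 on success, 2 on invalid
#'   usage, unreadable config or schema violations.
#' @export
run_pipeline <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(argv) < 1) stop("usage: rrsat <simulate|synth|analyze> [flags]")
    sub <- argv[1]
    opts <- parse_flags(argv[-1])
    if (is.null(opts$out)) stop("--out is required")
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    switch(sub,
      simulate = cmd_simulate(opts),
      synth = cmd_synth(opts),
      analyze = cmd_analyze(opts),
      stop("unknown subcommand: ", sub)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}

parse_flags <- function(args) {
  known <- c("config", "out", "seed", "log-level", "trials", "trajectories",
             "ratings")
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (!key %in% known) stop("unknown flag: --", key)
    if (i + 1 > length(args)) stop("flag --", key, " needs a value")
    opts[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  if (!is.null(opts$seed)) opts$seed <- as.integer(opts$seed)
  opts
}

read_config <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

log_open <- function(out, level = "info") {
  logfile <- file.path(out, "run.log")
  function(msg) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", msg)
    if (!identical(level, "quiet")) message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
}

write_manifest <- function(out, subcommand, config, seed, outputs) {
  manifest <- list(
    subcommand = subcommand,
    config = config,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs,
    package_version = as.character(utils::packageVersion("rrsat"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# Build sim_config objects from a config list: either one condition's fields
# at the top level, or a `conditions:` list of field-sets sharing top-level
# defaults (the condition sweep is expressed as separate arms).
sim_configs_from_list <- function(cfg, seed = NULL) {
  conds <- cfg$conditions
  shared <- cfg[setdiff(names(cfg), "conditions")]
  if (is.null(conds)) conds <- list(list())
  if (is.data.frame(conds)) conds <- split(conds, seq_len(nrow(conds)))
  lapply(conds, function(cond) {
    fields <- utils::modifyList(shared, as.list(cond))
    if (!is.null(seed)) fields$seed <- seed
    do.call(sim_config, fields)
  })
}

cmd_simulate <- function(opts) {
  log <- log_open(opts$out, opts$log_level %||% "info")
  cfg <- read_config(opts$config)
  configs <- sim_configs_from_list(cfg, seed = opts$seed)
  peaks_all <- list()
  curves_all <- list()
  for (k in seq_along(configs)) {
    co <- configs[[k]]
    log(sprintf("simulate: condition %d/%d (c_prop=%g, max_cost=%s, prior=%s)",
                k, length(configs), co$c_prop,
                paste(co$max_cost, collapse = "/"), co$prior))
    pk <- simulate_population(co, keep_curves = TRUE)
    peaks_all[[k]] <- tibble::as_tibble(pk)
    curves_all[[k]] <- dplyr::mutate(attr(pk, "curves"),
                                     c_prop = co$c_prop, prior = co$prior)
  }
  peaks <- dplyr::bind_rows(peaks_all)
  curves <- dplyr::bind_rows(curves_all)
  summary <- peak_summary(peaks)
  utils::write.csv(peaks, file.path(opts$out, "peaks.csv"), row.names = FALSE)
  utils::write.csv(curves, file.path(opts$out, "curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(seq_len(nrow(summary)), function(i) as.list(summary[i, ])),
    file.path(opts$out, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  write_manifest(opts$out, "simulate", cfg,
                 opts$seed %||% configs[[1]]$seed,
                 c("peaks.csv", "curves.csv", "summary.json"))
  log(sprintf("simulate: wrote %d peak rows over %d condition(s)",
              nrow(peaks), length(configs)))
}

cmd_synth <- function(opts) {
  log <- log_open(opts$out, opts$log_level %||% "info")
  cfg <- read_config(opts$config)
  if (!is.null(opts$seed)) cfg$seed <- opts$seed
  config <- do.call(synth_config, cfg)
  log("synth: generating dataset")
  ds <- generate_dataset(config)
  utils::write.csv(ds$trials, file.path(opts$out, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$trajectories, file.path(opts$out, "trajectories.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$ratings, file.path(opts$out, "ratings.csv"),
                   row.names = FALSE)
  write_manifest(opts$out, "synth", cfg, config$seed,
                 c("trials.csv", "trajectories.csv", "ratings.csv"))
  log(sprintf("synth: %d trials, %d trajectory samples, %d ratings",
              nrow(ds$trials), nrow(ds$trajectories), nrow(ds$ratings)))
}

cmd_analyze <- function(opts) {
  log <- log_open(opts$out, opts$log_level %||% "info")
  if (is.null(opts$trials)) stop("--trials is required")
  if (!file.exists(opts$trials)) stop("trials file not found: ", opts$trials)
  trials <- utils::read.csv(opts$trials)
  trajectories <- NULL
  if (!is.null(opts$trajectories)) {
    trajectories <- utils::read.csv(opts$trajectories)
  }
  ratings <- NULL
  if (!is.null(opts$ratings)) ratings <- utils::read.csv(opts$ratings)
  res <- analyze_dataset(trials, trajectories, ratings)
  log(sprintf("analyze: excluded %.2f%% of %d trials as over-6-s outliers",
              100 * res$excluded_fraction,
              round(nrow(res$trials) / (1 - res$excluded_fraction))))
  utils::write.csv(res$accuracy_by_group,
                   file.path(opts$out, "accuracy_by_group.csv"),
                   row.names = FALSE)
  if (!is.null(res$auc_by_category)) {
    utils::write.csv(res$auc_by_category,
                     file.path(opts$out, "auc_by_time_category.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(res$rt_cdf, file.path(opts$out, "rt_cdf.csv"),
                   row.names = FALSE)
  if (!is.null(res$irritation)) {
    utils::write.csv(res$irritation, file.path(opts$out, "irritation.csv"),
                     row.names = FALSE)
  }
  stats_json <- lapply(res$stats, function(s) {
    g <- as.list(glance(s))
    if (!is.null(s$pairwise)) {
      g$pairwise <- lapply(seq_len(nrow(s$pairwise)),
                           function(i) as.list(s$pairwise[i, ]))
    }
    g
  })
  stats_json$excluded_fraction <- res$excluded_fraction
  jsonlite::write_json(stats_json, file.path(opts$out, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- c("accuracy_by_group.csv", "rt_cdf.csv", "stats.json")
  if (!is.null(res$auc_by_category)) {
    outputs <- c(outputs, "auc_by_time_category.csv")
  }
  if (!is.null(res$irritation)) outputs <- c(outputs, "irritation.csv")
  write_manifest(opts$out, "analyze",
                 list(trials = opts$trials,
                      trajectories = opts$trajectories,
                      ratings = opts$ratings),
                 opts$seed, outputs)
  log("analyze: done")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
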