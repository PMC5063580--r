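#' Assemble a pipeline run configuration
#'
#' Either the three input paths (`binary`, `climate`, `geometry`) or a
#' [scenario_config()] (`scenario`) must be supplied; with a scenario the
#' inputs are simulated at run time. The northwest/southwest split used for
#' the sub-regional climate indices can be given explicitly; by default the
#' two regions with the smallest northings form the southwest group.
#'
#' @param binary,climate,geometry Input CSV paths (see
#'   [read_binary_matrix()], [read_climate_matrix()], [read_region_set()]).
#' @param scenario Optional [scenario_config()] used instead of file inputs.
#' @param southwest_regions Optional character vector of southwest region
#'   ids.
#' @param min_regions,min_run,max_bridge Synchronous-period parameters
#'   (see [detect_synchronous_periods()]).
#' @param t_max,n_sim K/L envelope parameters (see [circular_envelope()]).
#' @param n_perm Mantel permutations (see [mantel_test()]).
#' @param n_boot,pre_k SEA parameters (see [sea()], [pre_event_years()]).
#' @param alpha Two-sided significance level for all envelopes/CIs.
#' @param seed Integer master seed; all randomness in the run flows from it.
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `run_config`.
#' @export
run_config <- function(binary = NULL, climate = NULL, geometry = NULL,
                       scenario = NULL, southwest_regions = NULL,
                       min_regions = 3L, min_run = 2L, max_bridge = 0L,
                       t_max = 25L, n_sim = 1000L, n_perm = 10000L,
                       n_boot = 1000L, pre_k = 5L, alpha = 0.05,
                       seed = 1L, out_dir = "wsbsync-run") {
  stopifnot(min_regions >= 1L, min_run >= 1L, max_bridge >= 0L, t_max >= 1L,
            n_sim >= 1L, n_perm >= 1L, n_boot >= 1L, pre_k >= 1L,
            alpha > 0, alpha < 0.5)
  if (is.null(scenario) &&
      (is.null(binary) || is.null(climate) || is.null(geometry))) {
    stop("provide either a scenario or all three input paths ",
         "(binary, climate, geometry)")
  }
  structure(
    list(binary = binary, climate = climate, geometry = geometry,
         scenario = scenario, southwest_regions = southwest_regions,
         min_regions = as.integer(min_regions), min_run = as.integer(min_run),
         max_bridge = as.integer(max_bridge), t_max = as.integer(t_max),
         n_sim = as.integer(n_sim), n_perm = as.integer(n_perm),
         n_boot = as.integer(n_boot), pre_k = as.integer(pre_k),
         alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat keys mirroring the arguments of [run_config()]; unknown keys are an
#' error. A `scenario` cannot be expressed in the file (build it in R);
#' file-based configs must name the three input paths.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file values (e.g. from CLI
#'   flags).
#' @return A `run_config` object.
#' @export
load_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

log_stage <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE)
}

write_pairwise_csv <- function(m, path) {
  df <- data.frame(region_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full synchrony analysis pipeline
#'
#' Sequences the whole analysis on one input set: synchronous-period
#' detection and tabulation, circular-shift K/L envelopes for the three
#' event types, outbreak/climate similarity and distance matrices,
#' distance-decay regressions, the Mantel and partial Mantel tests,
#' superposed epoch analyses for initiations and cessations against the
#' all-region, northwest and southwest climate indices, and the two Welch-t
#' group contrasts. All artifacts are written as CSV under
#' `config$out_dir`, along with a machine-readable `summary.json` and a
#' `run.log` echoing every parameter; the function also returns the results
#' invisibly. All randomness flows from `config$seed`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list with all intermediate and final results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  on_err <- function(stage) {
    function(e) stop("pipeline stage '", stage, "' failed: ",
                     conditionMessage(e), call. = FALSE)
  }
  par_str <- paste0("seed=", config$seed, " min_regions=", config$min_regions,
                    " min_run=", config$min_run, " max_bridge=",
                    config$max_bridge, " t_max=", config$t_max, " n_sim=",
                    config$n_sim, " n_perm=", config$n_perm, " n_boot=",
                    config$n_boot, " pre_k=", config$pre_k, " alpha=",
                    config$alpha)
  log_stage(log_path, "run_pipeline ", par_str)
  set.seed(config$seed)

  ## inputs
  inputs <- tryCatch({
    if (!is.null(config$scenario)) {
      log_stage(log_path, "simulating scenario inputs")
      simulate_scenario(config$scenario)
    } else {
      log_stage(log_path, "reading inputs: ", config$binary, ", ",
                config$climate, ", ", config$geometry)
      outbreaks <- read_binary_matrix(config$binary)
      climate <- read_climate_matrix(config$climate)
      regions <- read_region_set(config$geometry)
      list(outbreaks = outbreaks, climate = climate, regions = regions,
           period = common_period(c(outbreaks, climate)))
    }
  }, error = on_err("inputs"))
  outbreaks <- inputs$outbreaks
  climate <- inputs$climate
  regions <- inputs$regions
  period <- inputs$period
  ids <- names(outbreaks)
  sw <- config$southwest_regions
  if (is.null(sw)) {
    sw <- regions$region_id[order(regions$north_km)][1:2]
  }
  nw <- setdiff(ids, sw)

  ## synchronous periods
  results <- list(period = period)
  results$counts <- count_regions(outbreaks, period)
  results$periods <- tryCatch(
    period_table(detect_synchronous_periods(
      results$counts, outbreaks, period,
      min_regions = config$min_regions, min_run = config$min_run,
      max_bridge = config$max_bridge
    )),
    error = on_err("synchrony_detection"))
  log_stage(log_path, "detected ", nrow(results$periods),
            " synchronous periods")
  utils::write.csv(results$periods, file.path(config$out_dir, "periods.csv"),
                   row.names = FALSE)

  ## Ripley K/L envelopes
  results$ripley <- list()
  for (ev in c("outbreak_years", "initiations", "cessations")) {
    env <- tryCatch(
      circular_envelope(outbreaks, ev, period, t_max = config$t_max,
                        n_sim = config$n_sim, alpha = config$alpha),
      error = on_err(paste0("ripley_", ev)))
    results$ripley[[ev]] <- env
    utils::write.csv(env$table,
                     file.path(config$out_dir, paste0("ripley_", ev, ".csv")),
                     row.names = FALSE)
    log_stage(log_path, "ripley ", ev, ": significant windows ",
              paste(env$table$t[env$table$significant], collapse = ","))
  }

  ## similarity, distance decay, Mantel
  results$similarity <- tryCatch({
    osim <- outbreak_similarity_matrix(outbreaks, period)
    csim <- climate_similarity_matrix(climate, period)
    dist <- centroid_distances(regions)
    list(
      outbreak = osim, climate = csim, distance = dist,
      decay_outbreak = distance_decay_regression(osim, dist),
      decay_climate = distance_decay_regression(csim, dist),
      mantel_outbreak_distance = mantel_test(osim, dist, config$n_perm),
      mantel_climate_distance = mantel_test(csim, dist, config$n_perm),
      mantel_outbreak_climate = mantel_test(osim, csim, config$n_perm),
      partial_outbreak_climate_given_distance =
        partial_mantel_test(osim, csim, dist, config$n_perm),
      partial_outbreak_distance_given_climate =
        partial_mantel_test(osim, dist, csim, config$n_perm)
    )
  }, error = on_err("similarity_mantel"))
  write_pairwise_csv(results$similarity$outbreak,
                     file.path(config$out_dir, "outbreak_similarity.csv"))
  write_pairwise_csv(results$similarity$climate,
                     file.path(config$out_dir, "climate_similarity.csv"))
  write_pairwise_csv(results$similarity$distance,
                     file.path(config$out_dir, "distances.csv"))
  log_stage(log_path, "mantel outbreak~climate r = ",
            signif(results$similarity$mantel_outbreak_climate$r, 3))

  ## superposed epoch analyses
  indices <- list(
    all = build_index(climate, ids, "all", period),
    northwest = build_index(climate, nw, "northwest", period),
    southwest = build_index(climate, sw, "southwest", period)
  )
  results$sea <- list()
  if (nrow(results$periods) >= 1L) {
    for (lab in names(indices)) {
      anom <- compute_anomalies(indices[[lab]], period)
      for (ev in c("initiations", "cessations")) {
        events <- if (ev == "initiations") results$periods$start else
          results$periods$end
        s <- tryCatch(
          sea(anom, events, period, n_boot = config$n_boot,
              alpha = config$alpha),
          error = on_err(paste0("sea_", ev, "_", lab)))
        results$sea[[paste(ev, lab, sep = "_")]] <- s
        utils::write.csv(
          s$table,
          file.path(config$out_dir, paste0("sea_", ev, "_", lab, ".csv")),
          row.names = FALSE)
      }
    }
    log_stage(log_path, "sea: 6 analyses complete")

    ## Welch-t group contrasts per index
    results$group_comparisons <- tryCatch({
      rows <- lapply(names(indices), function(lab) {
        gc <- group_comparisons(indices[[lab]], results$periods, period,
                                k = config$pre_k)
        gc$index <- lab
        gc
      })
      do.call(rbind, rows)
    }, error = on_err("group_comparisons"))
    utils::write.csv(results$group_comparisons,
                     file.path(config$out_dir, "group_comparisons.csv"),
                     row.names = FALSE)
  } else {
    log_stage(log_path, "no synchronous periods; SEA and contrasts skipped")
  }

  ## machine-readable summary
  psum <- summarize_episodes(results$periods)
  summary <- list(
    parameters = list(
      seed = config$seed, min_regions = config$min_regions,
      min_run = config$min_run, max_bridge = config$max_bridge,
      t_max = config$t_max, n_sim = config$n_sim, n_perm = config$n_perm,
      n_boot = config$n_boot, pre_k = config$pre_k, alpha = config$alpha
    ),
    period = list(start = period$start_year, end = period$end_year,
                  n = period$n),
    n_synchronous_periods = psum$n_episodes,
    mean_period_duration = psum$mean_duration,
    mean_quiescent = psum$mean_quiescent,
    years_with_3plus = fraction_years_with_at_least(results$counts, 3L),
    years_with_4plus = fraction_years_with_at_least(results$counts, 4L),
    mantel = lapply(
      results$similarity[grep("mantel|partial", names(results$similarity))],
      function(m) m[c("r", "p")]
    ),
    decay_r_squared = list(
      outbreak = results$similarity$decay_outbreak$r_squared,
      climate = results$similarity$decay_climate$r_squared
    ),
    ripley_significant_windows = lapply(results$ripley, function(e) {
      e$table$t[e$table$significant]
    })
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(log_path, "summary written to ",
            file.path(config$out_dir, "summary.json"))
  invisible(results)
}
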