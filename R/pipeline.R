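# Pipeline orchestration ----------------------------------------------------

pipeline_defaults <- function() {
  list(
    kernel = list(tau_s = 0.01),
    cox = list(alpha = 0.05, correction = "none", min_events = 30,
               mode = "joint", split_isis_at_boundaries = FALSE),
    motifs = list(n_null = 1000, swap_factor = 100),
    p1 = list(tol = 1e-6, max_iter = 500, reciprocity = TRUE),
    outliers = list(ceiling_hz = 20, floor_hz = 0),
    synthetic = list(n_nodes = 29, n_stimuli = 6, density = 0.1,
                     weight_range = c(0.8, 1.5), isi_family = "gamma",
                     gamma_shape = 2, rate_hz = 8, n_trials = 20,
                     trial_s = 6, gap_s = 1),
    seed = 1,
    out_dir = "spikegraph_out")
}

#' Validate a pipeline run configuration
#'
#' Reads a JSON or YAML configuration (or takes a list), checks it against
#' the schema, fills documented defaults, and returns the normalized
#' configuration.  A configuration must provide either `input` (paths
#' `spikes` and `schedule`) or `synthetic` (parameters for
#' [simulate_stimulus_session()]).  Unknown keys and out-of-range values
#' are reported together as one itemized error.
#'
#' @param config path to a `.json`/`.yaml` file, or a named list.
#' @return validated configuration list of class `spikegraph_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a file path or list", call. = FALSE)
  defs <- pipeline_defaults()
  known <- c(names(defs), "input")
  errs <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  for (blk in intersect(names(config), names(defs))) {
    if (is.list(defs[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(defs[[blk]]))
      if (length(bad))
        errs <- c(errs, paste0("unknown key(s) in `", blk, "`: ",
                               paste(bad, collapse = ", ")))
    }
  }
  cfg <- utils::modifyList(defs, config[intersect(names(config), known)])
  if (!is.null(config$input)) {
    if (is.null(config$input$spikes) || is.null(config$input$schedule))
      errs <- c(errs, "`input` requires `spikes` and `schedule` paths")
    cfg$input <- config$input
    cfg$synthetic <- NULL
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(cfg$kernel$tau_s > 0, "`kernel.tau_s` must be > 0")
  chk(cfg$cox$alpha > 0 && cfg$cox$alpha < 1, "`cox.alpha` must be in (0, 1)")
  chk(cfg$cox$correction %in% c("none", "bonferroni", "bh"),
      "`cox.correction` must be none|bonferroni|bh")
  chk(cfg$cox$min_events >= 2, "`cox.min_events` must be >= 2")
  chk(cfg$motifs$n_null >= 100, "`motifs.n_null` must be >= 100")
  chk(cfg$motifs$swap_factor >= 1, "`motifs.swap_factor` must be >= 1")
  chk(cfg$outliers$ceiling_hz > cfg$outliers$floor_hz,
      "`outliers.ceiling_hz` must exceed `outliers.floor_hz`")
  if (!is.null(cfg$synthetic)) {
    chk(cfg$synthetic$n_nodes >= 3, "`synthetic.n_nodes` must be >= 3")
    chk(cfg$synthetic$density >= 0 && cfg$synthetic$density <= 1,
        "`synthetic.density` must be in [0, 1]")
    chk(cfg$synthetic$trial_s > 0, "`synthetic.trial_s` must be > 0")
    chk(cfg$synthetic$gap_s >= 0, "`synthetic.gap_s` must be >= 0")
    chk(cfg$synthetic$n_trials >= 1, "`synthetic.n_trials` must be >= 1")
    chk(all(cfg$synthetic$rate_hz > 0), "`synthetic.rate_hz` must be > 0")
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  class(cfg) <- "spikegraph_config"
  cfg
}

#' Run the full per-stimulus analysis pipeline
#'
#' Executes, for every stimulus: trial extraction and concatenation, Cox
#' connectivity estimation, graph metrics, motif significance, and the P1
#' fit; then the cross-stimulus activity summaries (rate table, top-5
#' rankings, pairwise stimulus correlations).  Outlier channels flagged on
#' the per-stimulus rate table are excluded before estimation.  A failure
#' in one stimulus is recorded and does not abort the others.  All outputs
#' are written to `config$out_dir` together with a `manifest.json`
#' recording the configuration, seed and package version.
#'
#' @param config a [validate_config()] result, config list, or path.
#' @return (invisibly) a `spikegraph_report` list with per-stimulus results
#'   and cross-stimulus summaries.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "spikegraph_config")) config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  kernel <- influence_kernel(config$kernel$tau_s)
  # --- load or synthesize the session -------------------------------------
  truth <- NULL
  if (!is.null(config$input)) {
    spikes <- read_spike_table(config$input$spikes)
    schedule <- read_schedule(config$input$schedule)
  } else {
    syn <- config$synthetic
    seeds <- derive_seeds(config$seed, syn$n_stimuli)
    truth <- lapply(seq_len(syn$n_stimuli), function(k)
      make_ground_truth_graph(syn$n_nodes, syn$density, syn$weight_range,
                              seed = seeds[k]))
    names(truth) <- as.character(seq_len(syn$n_stimuli))
    sess <- simulate_stimulus_session(
      truth, n_trials = syn$n_trials, trial_s = syn$trial_s, gap_s = syn$gap_s,
      baseline = baseline_config(syn$isi_family, syn$rate_hz, syn$gamma_shape),
      kernel = kernel, seed = config$seed)
    spikes <- sess$spikes
    schedule <- sess$schedule
    write_spike_table(spikes, file.path(config$out_dir, "session_spikes.csv"))
    write_schedule(schedule, file.path(config$out_dir, "session_schedule.csv"))
    for (s in names(truth))
      write_truth_graph(truth[[s]],
                        file.path(config$out_dir, paste0("truth_", s, ".csv")))
  }
  stim_ids <- unique(schedule$stimulus_id)
  segments <- lapply(stim_ids, function(s)
    extract_stimulus_segments(spikes, schedule, s))
  names(segments) <- as.character(stim_ids)
  # --- outlier screen on the full rate table ------------------------------
  rates_all <- rate_table(segments)
  outliers <- flag_outlier_channels(rates_all, config$outliers$ceiling_hz,
                                    config$outliers$floor_hz)
  if (length(outliers)) {
    message("excluding outlier channel(s): ", paste(outliers, collapse = ", "))
    segments <- lapply(segments, drop_channels, ids = outliers)
  }
  write.csv(data.frame(channel = rownames(rates_all), rates_all,
                       check.names = FALSE),
            file.path(config$out_dir, "rate_table.csv"), row.names = FALSE)
  # --- per-stimulus stages -------------------------------------------------
  seeds <- derive_seeds(config$seed + 1, length(stim_ids))
  per_stimulus <- list()
  failures <- character(0)
  for (k in seq_along(stim_ids)) {
    s <- as.character(stim_ids[k])
    res <- tryCatch({
      seg <- segments[[s]]
      split_at <- if (isTRUE(config$cox$split_isis_at_boundaries))
        attr(seg, "boundaries") else NULL
      conn <- estimate_connectivity(seg, kernel, config$cox$alpha,
                                    config$cox$correction,
                                    config$cox$min_events,
                                    mode = config$cox$mode,
                                    split_at = split_at)
      write_adjacency(conn, file.path(config$out_dir, paste0("adjacency_", s, ".csv")))
      rep <- connectivity_report(conn)
      write.csv(rep, file.path(config$out_dir, paste0("cox_fits_", s, ".csv")),
                row.names = FALSE)
      metrics <- graph_metrics_report(conn)
      motifs <- motif_significance(conn, config$motifs$n_null,
                                   config$motifs$swap_factor, seed = seeds[k])
      write.csv(motifs$table,
                file.path(config$out_dir, paste0("motifs_", s, ".csv")),
                row.names = FALSE)
      p1 <- fit_p1(conn, config$p1$tol, config$p1$max_iter,
                   config$p1$reciprocity)
      write.csv(data.frame(node = names(p1$alpha), alpha = unname(p1$alpha),
                           beta_attr = unname(p1$beta_attr),
                           finite = is.finite(p1$alpha) & is.finite(p1$beta_attr)),
                file.path(config$out_dir, paste0("p1_", s, ".csv")),
                row.names = FALSE)
      jsonlite::write_json(
        list(stimulus = s,
             density = metrics$density,
             char_path_length = metrics$char_path_length,
             global_efficiency = metrics$global_efficiency,
             global_clustering = metrics$global_clustering,
             high_degree_nodes = metrics$high_degree_nodes,
             hubs = metrics$hubs,
             p1 = list(theta = p1$theta, rho = p1$rho,
                       converged = p1$converged)),
        file.path(config$out_dir, paste0("metrics_", s, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      list(connectivity = conn, metrics = metrics, motifs = motifs, p1 = p1)
    }, error = function(e) {
      warning("stimulus ", s, " failed: ", conditionMessage(e), call. = FALSE)
      failures <<- c(failures, s)
      list(error = conditionMessage(e))
    })
    per_stimulus[[s]] <- res
  }
  # --- cross-stimulus activity summaries ----------------------------------
  rates <- rate_table(segments)
  top5 <- lapply(stats::setNames(colnames(rates), colnames(rates)),
                 function(s) top_active(rates, s, k = min(5, nrow(rates))))
  correlations <- stimulus_correlations(rates)
  write.csv(data.frame(stimulus = rownames(correlations), correlations,
                       check.names = FALSE),
            file.path(config$out_dir, "stimulus_correlations.csv"),
            row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("spikegraph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    outlier_channels = outliers,
    failed_stimuli = failures)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- structure(list(per_stimulus = per_stimulus,
                           rates = rates, top_active = top5,
                           correlations = correlations,
                           outliers = outliers, truth = truth,
                           failures = failures, config = config),
                      class = "spikegraph_report")
  if (length(failures))
    warning("pipeline completed with failed stimuli: ",
            paste(failures, collapse = ", "), call. = FALSE)
  invisible(report)
}

#' @export
print.spikegraph_report <- function(x, ...) {
  cat("<spikegraph_report> ", length(x$per_stimulus), " stimuli",
      if (length(x$failures)) paste0(" (", length(x$failures), " failed)"),
      "\n", sep = "")
  for (s in names(x$per_stimulus)) {
    r <- x$per_stimulus[[s]]
    if (!is.null(r$error)) {
      cat("  stimulus ", s, ": FAILED (", r$error, ")\n", sep = "")
    } else {
      cat("  stimulus ", s, ": density ", round(r$metrics$density, 4),
          ", CPL ", round(r$metrics$char_path_length, 3),
          ", hubs ", paste(r$metrics$hubs, collapse = "/"), "\n", sep = "")
    }
  }
  invisible(x)
}
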