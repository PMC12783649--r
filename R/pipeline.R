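# Config-driven orchestration of the full workflow: ingest -> feature
# selection -> universal dataset -> graph learning -> time-resolved
# rescoring -> signal ranking/selection/ordering, with optional PCA
# state analysis and evolutionary scoring. Every stage writes plain-text
# artifacts sufficient to resume downstream stages.

PIPELINE_DEFAULTS <- list(
  contacts = NULL,            # list of GetContacts-format files
  fingerprints = NULL,        # or list of fingerprint files
  traces = NULL,              # per-trajectory transition-proxy files
  msa = NULL,                 # aligned FASTA (optional stage)
  msa_labels = NULL,          # sidecar CSV id -> class
  msa_positions = NULL,       # positions for specificity classification
  msa_target_class = NULL,
  synthetic = FALSE,          # generate the bundled synthetic ensemble
  synthetic_args = list(),
  n_frames = NULL,            # frames per contacts file (ingest)
  collapse_types = TRUE,
  neighbor_min_separation = 1L,
  mi_filter_bits = 0.01,
  combine_mode = "intersection",
  sampling = "enriched",      # or "concatenate"
  region_frames = 5000L,
  n_per_traj = 1200L,
  smoothing_window = 101L,
  transitions = NULL,         # optional externally supplied t* overrides
  max_parents = 3L,
  restarts = 2L,
  window_sizes = seq(150L, 1050L, by = 150L),
  stride = 10L,
  peak_threshold_bits = 1.0,
  evolution_threshold_bits = 2.0,
  max_peaks = 2L,
  require_all_trajectories = TRUE,
  n_states = 3L,
  run_states = FALSE,
  seed = 1L,
  output_dir = "drumbeat_out"
)

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills defaults
#' (0.01-bit MI filter, 1.0-bit peak threshold, 2.0-bit evolution
#' handoff, window grid 150-1050, sampling region 5000 frames), rejects
#' unknown keys, and reports all type/bound violations at once.
#'
#' @param config path to a YAML file, or a named list.
#' @return normalized configuration list of class
#'   \code{"pipeline_config"}.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config)
  problems <- character(0)
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(is.numeric(cfg$mi_filter_bits) && cfg$mi_filter_bits >= 0,
      "mi_filter_bits: must be a non-negative number")
  chk(is.numeric(cfg$peak_threshold_bits) && cfg$peak_threshold_bits >= 0,
      "peak_threshold_bits: must be a non-negative number")
  chk(is.numeric(cfg$evolution_threshold_bits) &&
        cfg$evolution_threshold_bits >= 0,
      "evolution_threshold_bits: must be a non-negative number")
  chk(cfg$neighbor_min_separation >= 1,
      "neighbor_min_separation: must be >= 1")
  chk(cfg$combine_mode %in% c("intersection", "union"),
      "combine_mode: must be 'intersection' or 'union'")
  chk(cfg$sampling %in% c("enriched", "concatenate"),
      "sampling: must be 'enriched' or 'concatenate'")
  chk(cfg$region_frames >= 1, "region_frames: must be >= 1")
  chk(cfg$n_per_traj >= 1, "n_per_traj: must be >= 1")
  chk(cfg$max_parents >= 1, "max_parents: must be >= 1")
  chk(cfg$stride >= 1, "stride: must be >= 1")
  chk(all(cfg$window_sizes %% 2 == 0) && !is.unsorted(cfg$window_sizes),
      "window_sizes: must be even and ascending")
  chk(cfg$max_peaks >= 1, "max_peaks: must be >= 1")
  chk(cfg$n_states >= 1, "n_states: must be >= 1")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed: must be an integer")
  for (key in c("contacts", "fingerprints", "traces", "msa", "msa_labels")) {
    for (p in cfg[[key]]) {
      chk(file.exists(p), paste0(key, ": missing file ", p))
    }
  }
  chk(isTRUE(cfg$synthetic) || !is.null(cfg$contacts) ||
        !is.null(cfg$fingerprints),
      "inputs: provide 'contacts', 'fingerprints', or synthetic: true")
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

log_stage <- function(report, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  c(report, line)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages in order, writing every stage artifact plus a
#' manifest (parameters, seeds, stage timings) under
#' \code{output_dir}. Rerunning with the same configuration and inputs
#' reproduces all outputs bit-exactly; any stage failure aborts with
#' the stage name, leaving a FAILED marker.
#'
#' @param config a [validate_config()] result, a list, or a YAML path.
#' @return invisible list with the main in-memory results (contact set,
#'   graph, ranking, key TRACs, ordering report) and the manifest path.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = cfg[setdiff(names(cfg), "synthetic_args")],
                   stages = list())
  report <- character(0)
  t_all <- Sys.time()
  stage <- "ingest"
  result <- tryCatch({
    # ---- ingest ----------------------------------------------------------
    t0 <- Sys.time()
    if (isTRUE(cfg$synthetic)) {
      syn <- do.call(generate_ensemble,
                     utils::modifyList(list(seed = cfg$seed),
                                       cfg$synthetic_args))
      ensemble <- syn$ensemble
      traces <- syn$traces
    } else if (!is.null(cfg$fingerprints)) {
      ensemble <- lapply(cfg$fingerprints, read_fingerprint)
      traces <- lapply(cfg$traces, read_trace)
    } else {
      if (is.null(cfg$n_frames)) {
        stop("n_frames is required when ingesting contact records",
             call. = FALSE)
      }
      ensemble <- lapply(seq_along(cfg$contacts), function(i) {
        binarize(read_getcontacts(cfg$contacts[[i]]), cfg$n_frames,
                 collapse_types = cfg$collapse_types,
                 trajectory_id = sprintf("traj%02d", i))
      })
      traces <- lapply(cfg$traces, read_trace)
    }
    manifest$stages$ingest <- list(
      n_trajectories = length(ensemble),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    report <- log_stage(report, stage,
                        sprintf("%d trajectories", length(ensemble)))

    # ---- feature selection ----------------------------------------------
    stage <- "select"
    t0 <- Sys.time()
    fs <- select_features(ensemble,
                          min_separation = cfg$neighbor_min_separation,
                          threshold = cfg$mi_filter_bits,
                          mode = cfg$combine_mode)
    utils::write.csv(fs$report, file.path(out, "feature_selection.csv"),
                     row.names = FALSE)
    restricted <- lapply(ensemble, restrict_contacts, labels = fs$contacts,
                         zero_fill = cfg$combine_mode == "union")
    manifest$stages$select <- list(
      n_contacts = length(fs$contacts),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    report <- log_stage(report, stage,
                        sprintf("%d contacts retained", length(fs$contacts)))

    # ---- universal dataset ----------------------------------------------
    stage <- "dataset"
    t0 <- Sys.time()
    if (cfg$sampling == "enriched") {
      transitions <- if (!is.null(cfg$transitions)) {
        as.integer(cfg$transitions)
      } else {
        if (is.null(traces) || !length(traces)) {
          stop("enriched sampling needs transition-proxy traces or ",
               "explicit 'transitions'", call. = FALSE)
        }
        vapply(traces, detect_transition, integer(1),
               smoothing_window = cfg$smoothing_window)
      }
      dataset <- enriched_sample(restricted, transitions,
                                 region = cfg$region_frames,
                                 n_per_traj = cfg$n_per_traj,
                                 seed = cfg$seed)
    } else {
      transitions <- NULL
      dataset <- concatenate_ensemble(restricted,
                                      zero_fill = cfg$combine_mode == "union")
    }
    write_universal_dataset(dataset, file.path(out, "universal_dataset"))
    manifest$stages$dataset <- list(
      n_rows = nrow(dataset$values), transitions = as.list(transitions),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    report <- log_stage(report, stage,
                        sprintf("%d rows (%s)", nrow(dataset$values),
                                cfg$sampling))

    # ---- graph learning --------------------------------------------------
    stage <- "learn"
    t0 <- Sys.time()
    graph <- learn_structure(dataset, max_parents = cfg$max_parents,
                             restarts = cfg$restarts, seed = cfg$seed,
                             on_constant = "drop")
    graph <- edge_strengths(graph, dataset)
    write_graph_tsv(graph, file.path(out, "universal_graph"))
    manifest$stages$learn <- list(
      n_edges = nrow(graph$edges), score = graph$score,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    report <- log_stage(report, stage,
                        sprintf("%d edges, score %.1f", nrow(graph$edges),
                                graph$score))

    # ---- time-resolved rescoring ----------------------------------------
    stage <- "rescore"
    t0 <- Sys.time()
    grid <- window_grid(cfg$window_sizes, cfg$stride)
    tr_list <- lapply(restricted, trac_traces, graph = graph, grid = grid)
    for (tr in tr_list) {
      write_trac_csv(tr, file.path(out, paste0("trac_", tr$trajectory_id)))
    }
    manifest$stages$rescore <- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    report <- log_stage(report, stage,
                        sprintf("%d trajectories rescored", length(tr_list)))

    # ---- signals ---------------------------------------------------------
    stage <- "signals"
    t0 <- Sys.time()
    ranking <- rank_contacts(tr_list, threshold = cfg$peak_threshold_bits)
    write_ranking_csv(ranking, file.path(out, "ranking.csv"))
    peaksets <- ensemble_peaks(tr_list, threshold = cfg$peak_threshold_bits)
    key <- select_key_tracs(ranking, peaksets,
                            amplitude_threshold = cfg$peak_threshold_bits,
                            require_all_trajectories =
                              cfg$require_all_trajectories,
                            max_peaks = cfg$max_peaks)
    writeLines(key, file.path(out, "key_tracs.txt"))
    ordering <- NULL
    top2 <- utils::head(intersect(ranking$ranking$node, key), 2L)
    if (length(top2) == 2L) {
      ord <- classify_order(peaksets[[top2[1L]]], peaksets[[top2[2L]]])
      ordering <- data.frame(node_a = top2[1L], node_b = top2[2L],
                             order = as.character(ord),
                             n_excluded = attr(ord, "n_excluded"),
                             stringsAsFactors = FALSE)
      utils::write.csv(ordering, file.path(out, "ordering.csv"),
                       row.names = FALSE)
    }
    manifest$stages$signals <- list(
      n_key_tracs = length(key),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    report <- log_stage(report, stage,
                        sprintf("%d key TRACs", length(key)))

    # ---- optional PCA states --------------------------------------------
    states <- NULL
    if (isTRUE(cfg$run_states) && length(key) >= 1L) {
      stage <- "states"
      t0 <- Sys.time()
      subnet <- unique(c(key, unlist(lapply(key, graph_neighbors,
                                            graph = graph))))
      states <- lapply(restricted, function(fp) {
        pr <- pca_project(restrict_contacts(fp, subnet), k = 2L)
        lab <- assign_states(pr, n_states = cfg$n_states, seed = cfg$seed)
        write_states_csv(pr, file.path(out, paste0("states_",
                                                   fp$trajectory_id)),
                         labels = lab)
        list(projection = pr, labels = lab)
      })
      manifest$stages$states <- list(
        n_contacts = length(subnet),
        seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
      report <- log_stage(report, "states", "PCA state assignment written")
    }

    # ---- optional evolution ---------------------------------------------
    evolution <- NULL
    if (!is.null(cfg$msa)) {
      stage <- "evolve"
      t0 <- Sys.time()
      msa <- read_labeled_msa(cfg$msa, cfg$msa_labels)
      profile <- conservation_score(msa)
      write_conservation_csv(profile, file.path(out, "conservation.csv"))
      evolution <- list(profile = profile)
      if (!is.null(cfg$msa_positions) && !is.null(cfg$msa_target_class)) {
        spec <- classify_positions(msa, as.integer(cfg$msa_positions),
                                   cfg$msa_target_class)
        rho <- specificity_ratio(spec)
        utils::write.csv(data.frame(class = cfg$msa_target_class,
                                    n_conserved = spec$n_conserved,
                                    n_specific = spec$n_specific,
                                    rho = rho),
                         file.path(out, "specificity.csv"),
                         row.names = FALSE)
        evolution$specificity <- spec
      }
      manifest$stages$evolve <- list(
        seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
      report <- log_stage(report, "evolve", "conservation profile written")
    }

    list(contacts = fs$contacts, dataset = dataset, graph = graph,
         traces = tr_list, ranking = ranking, key_tracs = key,
         ordering = ordering, states = states, evolution = evolution)
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(out, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all,
                                                units = "secs"))
  manifest$log <- report
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  result$manifest <- file.path(out, "manifest.yaml")
  invisible(result)
}
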