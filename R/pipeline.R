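#' Pipeline configuration
#'
#' Collects and validates every tunable of the end-to-end encoding
#' manifold pipeline; unknown fields are rejected so typos cannot silently
#' fall back to defaults. The effective configuration is written to the
#' run's provenance file.
#'
#' @param seed Master seed for every stochastic stage.
#' @param bin_width PSTH bin width, seconds.
#' @param normalize Per-neuron max normalization before factorization.
#' @param align Factor out direction preference (one circular shift per
#'   neuron) before building the tensor.
#' @param ranks Candidate CP ranks; a single value skips rank selection.
#' @param n_restarts,eps_elbow,s_min,max_iter,tol NTF settings (see
#'   [ntf_decompose()], [select_rank()]).
#' @param k,theta,max_passes Data-graph settings (see [build_graph()]).
#' @param m,t,alpha Diffusion-map settings (see [diffusion_map()]).
#' @param min_cluster_size,k_dim Topology settings (see
#'   [topology_summary()]).
#' @param baseline_rate,alpha_sig Selectivity settings; profiles are only
#'   computed when `baseline_rate` is supplied and un-normalized rates are
#'   available.
#' @param out_dir Output directory for run artifacts (`NULL`: no files).
#' @return A validated `pipeline_config` (named list).
#' @export
pipeline_config <- function(seed = 1, bin_width = 0.05, normalize = TRUE,
                            align = TRUE, ranks = 1:12, n_restarts = 10,
                            eps_elbow = 0.01, s_min = 0.9, max_iter = 500,
                            tol = 1e-8, k = 10, theta = 0.1, max_passes = 5,
                            m = 10, t = 1, alpha = 1,
                            min_cluster_size = NULL, k_dim = 15,
                            baseline_rate = NULL, alpha_sig = 0.05,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(bin_width > 0, all(ranks >= 1), n_restarts >= 1,
            eps_elbow >= 0, s_min >= 0, s_min <= 1,
            k >= 1, theta >= 0, theta <= 1, m >= 1,
            alpha >= 0, alpha <= 1, alpha_sig > 0, alpha_sig < 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full encoding-manifold pipeline
#'
#' Executes response-map construction, nonnegative tensor factorization,
#' data-graph construction, diffusion embedding, topology analysis and
#' (optionally) selectivity profiling, writing every intermediate artifact
#' plus a provenance record to `config$out_dir`. A failure in any stage
#' raises an error naming the stage; artifacts of completed stages remain
#' on disk.
#'
#' @param input A [spike_data] object, a [response_maps] object, or a path
#'   to a spike CSV (then `ensemble` is required).
#' @param config A [pipeline_config()].
#' @param ensemble Stimulus ensemble, required when `input` is a CSV path.
#' @return List with `maps`, `tensor`, `model`, `rank_diagnostics`,
#'   `graph`, `embedding`, `topology`, `profiles` (or `NULL`), `config`,
#'   `out_dir`, `timings` (seconds per stage).
#' @export
run_pipeline <- function(input, config = pipeline_config(), ensemble = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  timings <- numeric(0)
  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    el <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- el
    log_lines <<- c(log_lines, sprintf("%s: %.2f s", name, el))
    res
  }

  maps_raw <- stage("responses", {
    if (is.character(input)) {
      if (is.null(ensemble)) stop("ensemble required when input is a file")
      input <- read_spikes(input, ensemble)
    }
    if (inherits(input, "spike_data")) bin_psth(input, config$bin_width)
    else if (inherits(input, "response_maps")) input
    else stop("input must be spike_data, response_maps or a CSV path")
  })
  maps <- stage("preprocess", {
    m <- maps_raw
    if (config$normalize) m <- normalize_maps(m)
    if (config$align) m <- align_directions(m)
    m
  })
  tensor <- stage("tensor", build_tensor(maps))
  rank_diag <- NULL
  model <- stage("ntf", {
    if (length(config$ranks) > 1) {
      sel <- select_rank(tensor, candidates = config$ranks,
                         n_restarts = config$n_restarts, seed = config$seed,
                         eps_elbow = config$eps_elbow, s_min = config$s_min,
                         max_iter = config$max_iter, tol = config$tol)
      rank_diag <- sel$diagnostics
      sel$model
    } else {
      ntf_decompose(tensor, R = config$ranks, n_restarts = config$n_restarts,
                    seed = config$seed, max_iter = config$max_iter,
                    tol = config$tol)
    }
  })
  if (!is.null(out_dir)) write_factor_model(model, file.path(out_dir, "ntf"))
  graph <- stage("graph", build_graph(model, k = config$k,
                                      theta = config$theta,
                                      max_passes = config$max_passes))
  if (!is.null(out_dir)) write_graph_edges(graph,
                                           file.path(out_dir, "graph_edges.csv"))
  embedding <- stage("diffusion", diffusion_map(graph, m = config$m,
                                                t = config$t,
                                                alpha = config$alpha))
  if (!is.null(out_dir)) write_embedding(embedding,
                                         file.path(out_dir, "embedding.csv"))
  topology <- stage("topology",
                    topology_summary(embedding,
                                     min_cluster_size = config$min_cluster_size,
                                     k_dim = config$k_dim))
  if (!is.null(out_dir)) write_topology_report(topology, out_dir)
  profiles <- NULL
  if (!is.null(config$baseline_rate) && !isTRUE(maps_raw$normalized)) {
    profiles <- stage("selectivity",
                      selectivity_profiles(maps_raw, config$baseline_rate,
                                           config$alpha_sig))
    if (!is.null(out_dir)) {
      utils::write.csv(cbind(profiles, as.data.frame(embedding$coordinates)),
                       file.path(out_dir, "selectivity.csv"),
                       row.names = FALSE)
    }
  }
  if (!is.null(out_dir)) {
    prov <- list(
      package_version = as.character(utils::packageVersion("encmanifold")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass(config),
      selected_rank = model$rank,
      timings_s = as.list(timings))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(maps = maps, tensor = tensor, model = model,
       rank_diagnostics = rank_diag, graph = graph, embedding = embedding,
       topology = topology, profiles = profiles, config = config,
       out_dir = out_dir, timings = timings)
}
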