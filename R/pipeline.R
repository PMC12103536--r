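# End-to-end pipeline: prepare the search space, find core pathways, expand
# and converge the balanced subnetwork, integrate it into the host model,
# enumerate and rank feasible pathways, and persist every stage's output.

#' Default pipeline configuration
#'
#' Returns the full configuration list with defaults; values from `config`
#' override them.  Sections mirror the pipeline's user-facing parameters:
#' precursor selection (`n`, `substructure`), network filtering
#' (`car_threshold`, `lambda`, `beta`), core search (`k`, `max_len`),
#' expansion (`k_cosub`, `extra_steps`), enumeration (`theta_grid`,
#' `objective`, `W`, `K`, `uptake`), thermodynamics (`enabled`,
#' temperature/pH/ionic strength, concentration bounds).
#'
#' @param config partial configuration list (e.g. from a YAML file).
#' @return complete configuration list.
#' @export
default_config <- function(config = list()) {
  defaults <- list(
    seed = 1L,
    database = list(path = NULL, format = "tsv", fixture = NULL),
    host = list(path = NULL, format = "cobra-json", fixture = NULL,
                substrate_exchange = NA),
    target = NULL,
    precursors = list(ids = NULL, n = 5L, substructure = NULL),
    network = list(car_threshold = 0, lambda = 1, beta = 1),
    core = list(k = 5L, max_len = 10L),
    expansion = list(k_cosub = 3L, extra_steps = 0L),
    enumeration = list(theta_grid = c(0.25, 0.5, 0.75, 1.0), theta = 0.5,
                       objective = "size", W = 2, K = 20L, uptake = 10),
    thermo = list(enabled = FALSE, temperature = 298, pH = 7,
                  ionic_strength = 0.15))
  merge <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) merge(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  cfg <- merge(defaults, config)
  th <- c(cfg$enumeration$theta, cfg$enumeration$theta_grid)
  if (any(th < 0 | th > 1)) stop("config error: theta values must lie in [0, 1]")
  if (cfg$network$car_threshold < 0 || cfg$network$car_threshold > 1)
    stop("config error: car_threshold must lie in [0, 1]")
  if (is.null(cfg$target)) stop("config error: target compound is required")
  cfg
}

#' Run the full pathway-design pipeline
#'
#' Executes the five stages in order -- (1) search-space preparation,
#' (2) core linear pathway search, (3) balanced-cosubstrate subnetwork
#' expansion and convergence, (4) integration into the host model,
#' (5) pathway enumeration and ranking -- persisting each stage's output in
#' `out_dir` together with a machine-readable manifest (config hash, stage
#' statuses, boundary trace, pathway counts).  Deterministic for a fixed
#' configuration.
#'
#' @param config configuration list or path to a YAML file
#'   (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly; outputs on disk:
#'   `subnetwork.json`, `subnetwork.gdf`, `integrated_model.json`,
#'   `pathways.tsv`, `pathways.json`, `topology.json`, `pareto.tsv`,
#'   `manifest.json`, `log.txt`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg_path <- NULL
  if (is.character(config)) { cfg_path <- config; config <- yaml::read_yaml(config) }
  cfg <- default_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  cat("", file = logf)
  manifest <- list(stages = list(), config_hash = {
    tmp <- if (is.null(cfg_path)) {
      tf <- tempfile(); yaml::write_yaml(cfg, tf); tf
    } else cfg_path
    unname(tools::md5sum(tmp))
  })
  say <- function(...) cat(format(Sys.time(), "%H:%M:%S"), paste0(...), "\n",
                           file = logf, append = TRUE)
  stage <- function(name, expr) {
    say("stage ", name, " start")
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      .write_manifest(manifest, out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    say("stage ", name, " done")
    res
  }

  # stage 1: prepare search space
  prep <- stage("prepare", {
    db <- if (!is.null(cfg$database$fixture)) make_fixture(cfg$database$fixture, cfg$seed)
          else load_database(cfg$database$path, cfg$database$format)
    host <- if (!is.null(cfg$host$fixture)) make_fixture(cfg$host$fixture, cfg$seed)
            else load_host(cfg$host$path, cfg$host$format,
                           substrate_exchange = cfg$host$substrate_exchange)
    mapping <- map_metabolites(host, db)
    graph <- build_graph(db, car_threshold = cfg$network$car_threshold,
                         lambda = cfg$network$lambda, beta = cfg$network$beta)
    list(db = db, host = host, mapping = mapping, graph = graph)
  })
  db <- prep$db; host <- prep$host; mapping <- prep$mapping; graph <- prep$graph

  # stage 2: core pathway search
  sn <- stage("core", {
    pre <- cfg$precursors$ids
    if (is.null(pre)) {
      pre <- select_precursors(db$compounds[[cfg$target]], db,
                               pool = setdiff(mapping$host_set, cfg$target),
                               n = cfg$precursors$n,
                               substructure = cfg$precursors$substructure)
      if (!length(pre)) pre <- setdiff(mapping$host_set, cfg$target)
    }
    extract_core(graph, db, cfg$target, precursors = pre,
                 host_set = mapping$host_set,
                 k = cfg$core$k, max_len = cfg$core$max_len)
  })

  # stage 3: expansion + convergence
  sn <- stage("expand", {
    sn <- expand_subnetwork(sn, graph, db, extra_steps = cfg$expansion$extra_steps,
                            k_cosub = cfg$expansion$k_cosub,
                            max_len = cfg$core$max_len)
    sn <- converge_subnetwork(sn, db)
    if (sn$status == "failed")
      stop("subnetwork convergence removed every route to the target")
    write_subnetwork_json(sn, file.path(out_dir, "subnetwork.json"))
    write_gdf(sn, file.path(out_dir, "subnetwork.gdf"))
    topo <- subnetwork_topology(sn, db)
    jsonlite::write_json(topo, file.path(out_dir, "topology.json"),
                         auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    sn
  })
  manifest$boundary_trace <- sn$rounds
  manifest$n_omitted <- length(sn$omitted)

  # stage 4: integration
  model <- stage("integrate", {
    model <- integrate_subnetwork(host, sn, db, cfg$target, mapping = mapping)
    write_model_json(model, file.path(out_dir, "integrated_model.json"))
    model
  })

  # stage 5: enumeration + ranking
  stage("enumerate", {
    vmax <- max_production(model, uptake = cfg$enumeration$uptake)$vmax
    pws <- enumerate_pathways(model, theta = cfg$enumeration$theta,
                              objective = cfg$enumeration$objective,
                              W = cfg$enumeration$W, K = cfg$enumeration$K,
                              uptake = cfg$enumeration$uptake, vmax = vmax, db = db)
    ctx <- thermo_context(temperature = cfg$thermo$temperature, pH = cfg$thermo$pH,
                          ionic_strength = cfg$thermo$ionic_strength)
    if (isTRUE(cfg$thermo$enabled)) {
      for (i in seq_along(pws))
        pws[[i]]$thermo_feasible <- tfa_check(model, pws[[i]], db = db, ctx = ctx,
                                              theta = cfg$enumeration$theta, vmax = vmax,
                                              uptake = cfg$enumeration$uptake)$feasible
    }
    report <- rank_report(pws)
    utils::write.table(report, file.path(out_dir, "pathways.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "pathways.json"),
                         auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    pareto <- pareto_sweep(model, thetas = cfg$enumeration$theta_grid,
                           with_thermo = isTRUE(cfg$thermo$enabled), db = db,
                           ctx = ctx, uptake = cfg$enumeration$uptake)
    utils::write.table(pareto, file.path(out_dir, "pareto.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$n_pathways <- length(pws)   # evaluated in run_pipeline's frame
    manifest$vmax <- vmax
    invisible(NULL)
  })

  .write_manifest(manifest, out_dir)
  say("pipeline complete")
  invisible(manifest)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
}
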