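#' Workflow configuration defaults
#'
#' Returns the default configuration for [run_workflow()], optionally merged
#' with overrides from a named list or a YAML file. Every seed is explicit;
#' referenced input paths are checked at validation time.
#'
#' @param workflow one of `"full-synthetic"`, `"bemd-toy"`, `"fel"`,
#'   `"cluster"`, `"analyze-ensemble"`, `"unfold-pathways"`,
#'   `"make-fixtures"`.
#' @param overrides named list (or path to a YAML file) of settings to
#'   merge over the defaults.
#' @return config list.
#' @export
workflow_config <- function(workflow = "full-synthetic", overrides = list()) {
  if (is.character(overrides) && length(overrides) == 1)
    overrides <- yaml::read_yaml(overrides)
  base <- list(
    workflow = workflow,
    seed = 1,
    out_dir = "quadfold-out",
    overwrite = FALSE,
    # synthetic sizes (kept modest; scale up freely)
    n_frames = 200, stride_ns = 0.5,
    # engine
    landscape = "two_basin_2d",
    landscape_params = list(),
    schedule = list(dt = 1e-4, tau_g = 0.05, exchange_stride = 0.01,
                    total_time = 60, output_stride = 100),
    cv_dims = c(1, 2), n_neutral = 2, widths = c(0.1, 0.2), height = 0.2,
    temperature = 300,
    # analysis
    bins = 16, min_barrier = kB * 300, equil_frac = 0.2, fel_min_count = 20,
    cluster_threshold = 0.3, unfold_threshold = 0.45,
    hbond_cutoff = 0.35, ion_cutoff = 0.35,
    # inputs for file-based workflows
    native_pdb = NULL, trajectory_pdb = NULL, trajectory_pdbs = NULL,
    cv_trace_csv = NULL, cv_columns = c("q", "n_ion"))
  cfg <- utils::modifyList(base, overrides)
  cfg$workflow <- workflow
  cfg
}

validate_config <- function(cfg) {
  needed <- switch(cfg$workflow,
    "cluster" = "trajectory_pdb",
    "analyze-ensemble" = c("native_pdb", "trajectory_pdb"),
    "unfold-pathways" = "trajectory_pdbs",
    "fel" = "cv_trace_csv",
    character(0))
  for (f in needed) {
    p <- cfg[[f]]
    if (is.null(p)) stopf("workflow '%s' requires config field '%s'",
                          cfg$workflow, f)
    for (pp in unlist(p))
      if (!file.exists(pp)) stopf("input file not found: %s", pp)
  }
  if (is.null(cfg$seed)) stopf("config must set an explicit seed")
  invisible(TRUE)
}

#' Run a named analysis workflow
#'
#' Wires the package's stages into reproducible end-to-end runs:
#'
#' * `full-synthetic` — generate a toy quadruplex, a planted intermediate
#'   ensemble and an unfolding set, run a small BEMD toy simulation, then
#'   produce the FEL, basins, cluster table, hydrogen-bond map, ion-binding
#'   profile, syn/anti table and pathway graph.
#' * `bemd-toy` — BEMD on an analytic landscape: traces, kernels, exchange
#'   log, neutral-replica FEL, basins, exchange diagnostics.
#' * `fel` — histogram FEL + basins from a CV trace CSV.
#' * `cluster` — leader clustering of a multi-model PDB trajectory.
#' * `analyze-ensemble` — H-bond map, ion profile and syn/anti table of a
#'   trajectory against a native structure.
#' * `unfold-pathways` — stage labelling by clustering + pathway graph over
#'   several trajectories.
#' * `make-fixtures` — write the synthetic native / ensemble / unfolding
#'   PDB files.
#'
#' All outputs are written under `config$out_dir` together with a manifest
#' (file list + MD5 checksums + the echoed config) and a machine-readable
#' `summary.json`. Identical configs and seeds give identical outputs.
#'
#' @param config list from [workflow_config()] (or overrides merged into
#'   it; a bare workflow name is also accepted).
#' @return (invisibly) list with `outputs`, `summary` and `files`.
#' @export
run_workflow <- function(config = "full-synthetic") {
  if (is.character(config)) config <- workflow_config(config)
  cfg <- config
  validate_config(cfg)
  t0 <- Sys.time()
  outputs <- switch(cfg$workflow,
    "full-synthetic" = wf_full_synthetic(cfg),
    "bemd-toy" = wf_bemd_toy(cfg),
    "fel" = wf_fel(cfg),
    "cluster" = wf_cluster(cfg),
    "analyze-ensemble" = wf_analyze(cfg),
    "unfold-pathways" = wf_unfold(cfg),
    "make-fixtures" = wf_fixtures(cfg),
    stopf("unknown workflow '%s'", cfg$workflow))
  files <- write_report(outputs, cfg)
  message(sprintf("workflow '%s' finished in %.1f s (%d files in %s)",
                  cfg$workflow, as.numeric(Sys.time() - t0, units = "secs"),
                  length(files), cfg$out_dir))
  invisible(list(outputs = outputs$objects, summary = outputs$summary,
                 files = files))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

wf_bemd_toy <- function(cfg) {
  land <- make_analytic_landscape(cfg$landscape, cfg$landscape_params)
  bemd <- stage("bemd", run_bemd(land, cv_dims = cfg$cv_dims,
                                 n_neutral = cfg$n_neutral,
                                 schedule = cfg$schedule,
                                 widths = cfg$widths, height = cfg$height,
                                 temperature = cfg$temperature,
                                 seed = cfg$seed))
  neutral <- which(bemd$roles == "neutral")
  samples <- do.call(rbind, bemd$traces[neutral])
  f <- stage("fel", estimate_fel(samples, axes = paste0("x", seq_len(land$dimension)),
                                 bins = cfg$bins,
                                 temperature = cfg$temperature,
                                 equil_frac = cfg$equil_frac,
                                 min_count = cfg$fel_min_count))
  basins <- stage("basins", identify_basins(f, cfg$min_barrier))
  diag <- stage("diagnostics",
                exchange_diagnostics(bemd$exchange_log,
                                     n_replicas = length(bemd$traces)))
  traces <- do.call(rbind, lapply(seq_along(bemd$traces), function(r) {
    m <- bemd$traces[[r]]
    data.frame(replica = r, role = bemd$roles[r],
               time_ns = attr(m, "times"),
               setNames(as.data.frame(unclass(m)),
                        paste0("x", seq_len(ncol(m)))))
  }))
  kernels <- do.call(rbind, lapply(seq_along(bemd$biases), function(r) {
    k <- bemd$biases[[r]]$kernels
    if (nrow(k) == 0) return(NULL)
    cbind(replica = r, k)
  }))
  list(objects = list(bemd = bemd, fel = f, basins = basins,
                      diagnostics = diag),
       tables = list(cv_traces = traces, kernels = kernels,
                     exchange_log = bemd$exchange_log,
                     exchange_diagnostics = diag$per_replica,
                     basin_minima = basins$minima),
       fels = list(fel = f),
       summary = list(workflow = "bemd-toy", seed = cfg$seed,
                      n_basins = basins$n_basins,
                      mean_acceptance = mean(bemd$exchange_log$accepted),
                      n_exchanges = nrow(bemd$exchange_log)))
}

wf_fel <- function(cfg) {
  tr <- read.csv(cfg$cv_trace_csv)
  cols <- intersect(cfg$cv_columns, names(tr))
  if (length(cols) < 1) stopf("cv_trace_csv lacks columns %s",
                              paste(cfg$cv_columns, collapse = ", "))
  f <- estimate_fel(as.matrix(tr[, cols, drop = FALSE]), axes = cols,
                    bins = cfg$bins, temperature = cfg$temperature,
                    equil_frac = cfg$equil_frac)
  basins <- identify_basins(f, cfg$min_barrier)
  list(objects = list(fel = f, basins = basins),
       tables = list(basin_minima = basins$minima),
       fels = list(fel = f),
       summary = list(workflow = "fel", n_basins = basins$n_basins))
}

wf_cluster <- function(cfg) {
  traj <- read_trajectory(cfg$trajectory_pdb, quiet = TRUE)
  cl <- leader_cluster(traj, threshold = cfg$cluster_threshold)
  tab <- data.frame(frame = seq_along(cl$membership),
                    cluster = cl$membership)
  pops <- data.frame(cluster = seq_along(cl$representatives),
                     representative_frame = cl$representatives,
                     population = cl$populations)
  list(objects = list(clusters = cl),
       tables = list(cluster_membership = tab, cluster_populations = pops),
       summary = list(workflow = "cluster",
                      n_clusters = length(cl$representatives),
                      threshold_nm = cfg$cluster_threshold))
}

analyze_tables <- function(traj, native, cfg) {
  hb <- hbond_map(traj, native = native, cutoff = cfg$hbond_cutoff)
  ion <- ion_binding_profile(traj, cutoff = cfg$ion_cutoff)
  glyco <- glycosidic_summary(traj)
  hb_df <- as.data.frame(as.table(hb$probability))
  names(hb_df) <- c("resno_i", "resno_j", "probability")
  if (!is.null(hb$native))
    hb_df$native <- as.vector(hb$native)
  ion_df <- data.frame(resno = as.integer(names(ion$probability)),
                       binding_probability = as.numeric(ion$probability))
  list(hb = hb, ion = ion, glyco = glyco, hb_df = hb_df, ion_df = ion_df)
}

wf_analyze <- function(cfg) {
  native <- read_structure(cfg$native_pdb, quiet = TRUE)
  traj <- read_trajectory(cfg$trajectory_pdb, quiet = TRUE)
  a <- analyze_tables(traj, native, cfg)
  list(objects = list(hbond_map = a$hb, ion_profile = a$ion),
       tables = list(hbond_map = a$hb_df, ion_profile = a$ion_df,
                     syn_anti = a$glyco),
       summary = list(workflow = "analyze-ensemble",
                      mean_bound_ions = a$ion$mean_bound,
                      n_fluctuating = sum(a$glyco$classification ==
                                            "fluctuating")))
}

wf_unfold <- function(cfg) {
  trajs <- lapply(unlist(cfg$trajectory_pdbs), read_trajectory, quiet = TRUE)
  lab <- label_stages_by_clustering(trajs, threshold = cfg$unfold_threshold)
  pg <- build_pathway_graph(lab$label_sequences)
  list(objects = list(pathways = pg, clusters = lab$clusters),
       tables = list(pathway_edges = pg$edges, pathway_paths = pg$paths),
       pathways = list(pathway_graph = pg),
       summary = list(workflow = "unfold-pathways",
                      n_trajectories = pg$n_trajectories,
                      dominant_path_count = max(pg$paths$count)))
}

wf_fixtures <- function(cfg) {
  native <- make_toy_quadruplex()
  spec <- default_ensemble_spec(native, seed = cfg$seed,
                                n_frames = cfg$n_frames,
                                stride_ns = cfg$stride_ns)
  ens <- make_intermediate_ensemble(spec, native)
  unf <- make_unfolding_set(native, seed = cfg$seed)
  list(objects = list(native = native, ensemble = ens, unfolding = unf),
       structures = c(list(native = native, ensemble = ens),
                      setNames(unf$trajectories,
                               paste0("unfolding_", seq_along(unf$trajectories)))),
       summary = list(workflow = "make-fixtures", seed = cfg$seed,
                      n_frames = n_frames(ens),
                      n_unfolding = length(unf$trajectories)))
}

wf_full_synthetic <- function(cfg) {
  native <- stage("generate", make_toy_quadruplex())
  spec <- default_ensemble_spec(native, seed = cfg$seed,
                                n_frames = cfg$n_frames,
                                stride_ns = cfg$stride_ns)
  ens <- stage("generate", make_intermediate_ensemble(spec, native))
  contacts <- stage("cv", build_native_contacts(native))
  cvs <- stage("cv", cv_trace(ens, native, contacts))
  f <- stage("fel", estimate_fel(as.matrix(cvs[, c("q", "n_ion")]),
                                 axes = c("q", "n_ion"), bins = cfg$bins,
                                 temperature = cfg$temperature,
                                 equil_frac = 0))
  basins <- stage("basins", identify_basins(f, cfg$min_barrier))
  cl <- stage("cluster", leader_cluster(ens,
                                        threshold = cfg$cluster_threshold))
  a <- stage("ensemble-statistics", analyze_tables(ens, native, cfg))
  unf <- stage("unfolding", make_unfolding_set(native, seed = cfg$seed))
  lab <- stage("unfolding", label_stages_by_clustering(
    unf$trajectories, threshold = cfg$unfold_threshold))
  pg <- stage("unfolding", build_pathway_graph(lab$label_sequences))
  bemd_cfg <- utils::modifyList(cfg, list(landscape = "two_basin_2d"))
  bemd_out <- stage("bemd", wf_bemd_toy(bemd_cfg))
  pops <- data.frame(cluster = seq_along(cl$representatives),
                     representative_frame = cl$representatives,
                     population = cl$populations)
  list(objects = list(native = native, ensemble = ens, fel = f,
                      basins = basins, clusters = cl, hbond_map = a$hb,
                      ion_profile = a$ion, pathways = pg,
                      bemd = bemd_out$objects$bemd),
       tables = c(list(cv_traces = cvs, basin_minima = basins$minima,
                       cluster_populations = pops, hbond_map = a$hb_df,
                       ion_profile = a$ion_df, syn_anti = a$glyco,
                       pathway_edges = pg$edges,
                       pathway_paths = pg$paths),
                  bemd_out$tables["exchange_diagnostics"]),
       fels = list(fel = f, bemd_fel = bemd_out$fels$fel),
       pathways = list(pathway_graph = pg),
       structures = list(native = native),
       summary = list(workflow = "full-synthetic", seed = cfg$seed,
                      n_frames = n_frames(ens),
                      n_basins_ensemble = basins$n_basins,
                      n_clusters = length(cl$representatives),
                      mean_bound_ions = a$ion$mean_bound,
                      n_fluctuating = sum(a$glyco$classification ==
                                            "fluctuating"),
                      dominant_path_count = max(pg$paths$count),
                      bemd_n_basins = bemd_out$summary$n_basins,
                      bemd_mean_acceptance = bemd_out$summary$mean_acceptance))
}

#' Write workflow outputs and a manifest
#'
#' Serialises every stage output (tables as CSV with units in headers,
#' surfaces as JSON + CSV, pathway graphs as JSON + DOT, structures as PDB)
#' into `config$out_dir`, plus `summary.json` and a `manifest.json` listing
#' each written file with its MD5 checksum and the echoed configuration.
#' Existing files are only replaced when `config$overwrite` is TRUE.
#'
#' @param outputs internal stage-output bundle (as produced by the
#'   workflow implementations).
#' @param config the workflow config.
#' @return character vector of written file paths.
#' @export
write_report <- function(outputs, config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  target <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p) && !isTRUE(config$overwrite))
      stopf("output file exists (set overwrite: true to replace): %s", p)
    files <<- c(files, p)
    p
  }
  for (nm in names(outputs$tables)) {
    tab <- outputs$tables[[nm]]
    if (is.null(tab) || nrow(tab) == 0) next
    write.csv(tab, target(paste0(nm, ".csv")), row.names = FALSE)
  }
  for (nm in names(outputs$fels)) {
    f <- outputs$fels[[nm]]
    write_fel(f, json_file = target(paste0(nm, ".json")),
              csv_file = target(paste0(nm, ".csv")))
  }
  for (nm in names(outputs$pathways)) {
    pg <- outputs$pathways[[nm]]
    jsonlite::write_json(list(nodes = pg$nodes, edges = pg$edges,
                              paths = pg$paths),
                         target(paste0(nm, ".json")), digits = 10,
                         auto_unbox = TRUE)
    pathway_graph_to_dot(pg, target(paste0(nm, ".dot")))
  }
  for (nm in names(outputs$structures))
    write_structure_pdb(outputs$structures[[nm]],
                        target(paste0(nm, ".pdb")))
  jsonlite::write_json(outputs$summary, target("summary.json"),
                       digits = 10, auto_unbox = TRUE)
  cfg_echo <- config
  cfg_echo$overwrite <- NULL
  manifest <- list(
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))),
    config = cfg_echo[!vapply(cfg_echo, is.null, TRUE)])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = 10, auto_unbox = TRUE)
  c(files, file.path(out_dir, "manifest.json"))
}
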