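#' Pipeline configuration
#'
#' Nests the per-module configurations with run-level settings. Fully
#' serializable (YAML/JSON); a saved config plus seed reproduces a run
#' bit-identically for the deterministic stages.
#'
#' @param sim an [sim_config()].
#' @param classifier a [classifier_config()].
#' @param n_cells simulated cells in a demo run (default 3).
#' @param n_tracks trajectories per cell (default 150).
#' @param out_dir output directory.
#' @param seed run-level integer seed.
#' @param verbosity 0 = silent, 1 = stage messages to stderr.
#' @return list of class `sptfa_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), classifier = classifier_config(),
                            n_cells = 3L, n_tracks = 150L,
                            out_dir = tempfile("sptfa_run_"),
                            seed = 1L, verbosity = 1L) {
  structure(list(sim = sim, classifier = classifier,
                 n_cells = as.integer(n_cells), n_tracks = as.integer(n_tracks),
                 out_dir = out_dir, seed = as.integer(seed),
                 verbosity = as.integer(verbosity)),
            class = "sptfa_pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return an `sptfa_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  sim_args <- lst$sim %||% list()
  cls_args <- lst$classifier %||% list()
  top <- lst[setdiff(names(lst), c("sim", "classifier"))]
  do.call(pipeline_config,
          c(list(sim = do.call(sim_config, sim_args),
                 classifier = do.call(classifier_config, cls_args)),
            top))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_as_list <- function(config) {
  if (is.list(config)) lapply(unclass(config), config_as_list)
  else unclass(config)
}

# small stable string hash (31-polynomial mod 2^31 - 1) for run manifests;
# covers the scientific configuration only (not output paths / verbosity)
config_hash <- function(config) {
  lst <- config_as_list(config)
  lst <- lst[setdiff(names(lst), c("out_dir", "verbosity"))]
  s <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA)
  h <- 7
  for (ch in utf8ToInt(as.character(s)))
    h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

log_stage <- function(verbosity, ...) {
  if (verbosity > 0) message("[sptfa] ", ...)
}

run_stage <- function(name, verbosity, expr) {
  log_stage(verbosity, "stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full demo pipeline
#'
#' Chains synthetic-data generation, ingest, region sorting,
#' classification and per-cell aggregation for `n_cells` simulated cells,
#' writing per-trajectory CSV, per-cell and pooled JSON summaries and a
#' machine-readable run manifest (package version, config hash, seed).
#'
#' @param config an [pipeline_config()].
#' @return list: `classifications` (data.frame), `summary`
#'   (from [aggregate_cells()]), `masks`, `manifest`, `out_dir`.
#' @export
run_full <- function(config = pipeline_config()) {
  v <- config$verbosity
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  masks <- run_stage("mask generation", v,
                     simulate_mask_set(config$sim$field_size,
                                       seed = config$seed))
  all_cls <- list()
  for (ci in seq_len(config$n_cells)) {
    cell <- sprintf("cell%02d", ci)
    sim <- config$sim
    sim$rng_seed <- (config$seed * 1009L + ci) %% .Machine$integer.max
    ds <- run_stage(paste0("simulate ", cell), v,
                    simulate_dataset(sim, masks, n_tracks = config$n_tracks))
    path <- file.path(config$out_dir, paste0(cell, "_locs.csv"))
    write_localizations(ds$table, path)
    tab <- run_stage(paste0("ingest ", cell), v,
                     read_localizations(path,
                                        frame_interval = sim$frame_interval))
    trajs <- run_stage(paste0("build trajectories ", cell), v,
                       build_trajectories(tab))
    cls <- run_stage(paste0("classify ", cell), v,
                     classify_all(trajs, config$classifier, masks = masks,
                                  cell_id = cell))
    all_cls[[cell]] <- cls
  }
  classifications <- do.call(rbind, c(all_cls, list(make.row.names = FALSE)))
  summary <- run_stage("aggregate", v, aggregate_cells(classifications))
  utils::write.csv(classifications,
                   file.path(config$out_dir, "trajectories.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summary$pooled,
                       file.path(config$out_dir, "pooled_summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(package = "sptfa",
                   version = as.character(utils::packageVersion("sptfa")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   n_cells = config$n_cells, n_tracks = config$n_tracks)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(classifications = classifications, summary = summary, masks = masks,
       manifest = manifest, out_dir = config$out_dir)
}

#' Two-sided Mann-Whitney / Wilcoxon rank-sum comparison
#'
#' Thin wrapper over [stats::wilcox.test()] (exact for small samples
#' without ties, normal approximation with tie correction otherwise), the
#' convenience statistic used for group comparisons in figure panels. No
#' multiple-testing correction is applied.
#'
#' @param values_a,values_b numeric vectors (both nonempty).
#' @return two-sided p-value.
#' @export
compare_groups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("empty group")
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided")$p.value)
}
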