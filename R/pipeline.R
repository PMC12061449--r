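#' Default run configuration
#'
#' One configuration object drives the whole pipeline; it is validated
#' before any stage runs and serialized into the run manifest.
#'
#' @param seed Master seed (all stage seeds derive from it).
#' @param out_dir Output directory for rasters, tables and the manifest.
#' @param truth A `synthetic_truth` describing the scene (the pipeline's
#'   demo profile runs on synthetic data).
#' @param season Growing-season months.
#' @param strata_k,strata_method Stratification for the detectors.
#' @param min_stratum_n Minimum overlay-stratum size.
#' @param aggregation Fine cells per analysis-cell side for the
#'   density-increase response.
#' @param span_convention `"difference"` or `"inclusive"` (see
#'   [year_span()]).
#' @param sectors Sector boundary list (see [default_sectors()]).
#' @param sector_mask Sector names excluded from analysis (e.g.
#'   `"eastern"` for a study-area exclusion).
#' @param prune_threshold Absolute correlation for [prune_correlated()].
#' @param min_cells Minimum response cells per sector for the detectors.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("treelineq_run_"),
                       truth = NULL, season = 6:9, strata_k = 5L,
                       strata_method = "quantile", min_stratum_n = 2L,
                       aggregation = 10L,
                       span_convention = "inclusive",
                       sectors = default_sectors(),
                       sector_mask = "eastern",
                       prune_threshold = 0.90, min_cells = 30L) {
  if (is.null(truth)) truth <- synthetic_truth(seed = seed)
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$strata_k < 2L) stop("config invalid: strata_k must be >= 2")
  if (!cfg$strata_method %in% c("quantile", "equal", "natural"))
    stop("config invalid: unknown strata_method")
  if (cfg$aggregation < 1L) stop("config invalid: aggregation must be >= 1")
  if (!cfg$span_convention %in% c("difference", "inclusive"))
    stop("config invalid: unknown span_convention")
  if (cfg$prune_threshold <= 0 || cfg$prune_threshold > 1)
    stop("config invalid: prune_threshold outside (0, 1]")
  if (!all(cfg$sector_mask %in% c(names(cfg$sectors), character(0))))
    stop("config invalid: sector_mask names unknown")
  invisible(TRUE)
}

#' Read a run configuration from YAML
#'
#' Scalar fields of [run_config()] (and of the embedded truth ledger,
#' under a `truth:` block) can be supplied in a YAML file.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  truth <- if (!is.null(y$truth)) do.call(synthetic_truth, y$truth) else NULL
  y$truth <- NULL
  do.call(run_config, c(y, list(truth = truth)))
}

#' Run the full analysis pipeline
#'
#' Executes terrain derivation, climate factor derivation with correlation
#' pruning, change analysis and the factor/interaction detectors on the
#' configured synthetic scene, writing every product (ASCII grids, CSV
#' tables, JSON manifest) under `config$out_dir`. Reruns with an identical
#' configuration reproduce the outputs exactly.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory results (`scene`,
#'   `factors`, `change`, `response`, `detectors`, `summary`) and `paths`.
#' @export
run_pipeline <- function(config = run_config()) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  msg <- function(...) message("[treelineq] ", sprintf(...))

  msg("stage simulate: %dx%d grid, seed %d",
      config$truth$nrow, config$truth$ncol, config$truth$seed)
  scene <- simulate_scene(config$truth, config$season)

  msg("stage terrain/climate: pruning factors at |r| > %g",
      config$prune_threshold)
  pruned <- prune_correlated(scene$factors, config$prune_threshold)
  factors <- pruned$kept

  msg("stage change: %d -> %d", min(scene$series$years),
      max(scene$series$years))
  sectors <- assign_aspect_sector(scene$dem, scene$summit, config$sectors,
                                  mask = config$sector_mask)
  ch <- change_map(scene$series, min(scene$series$years),
                   max(scene$series$years))
  summ <- sector_summary(scene$series, sectors, scene$dem,
                         config$span_convention)
  sdist <- slope_distribution(scene$series, scene$terrain$slope_class)
  dens <- density_increase(ch, config$aggregation)
  resp <- as_response_table(dens)

  msg("stage detect: %d factors, k = %d (%s)", length(factors),
      config$strata_k, config$strata_method)
  det <- run_detectors(resp, factors, sectors, k = config$strata_k,
                       method = config$strata_method,
                       min_stratum_n = config$min_stratum_n,
                       min_cells = config$min_cells)

  paths <- list()
  wcsv <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wasc <- function(grid, name) {
    p <- file.path(config$out_dir, paste0(name, ".asc"))
    write_ascii_grid(grid, p)
    paths[[name]] <<- p
  }
  wasc(scene$dem, "dem")
  wasc(scene$terrain$twi, "twi")
  wasc(ch, "change_map")
  wasc(dens, "density_increase")
  wcsv(summ$areas, "sector_areas")
  wcsv(summ$rates, "sector_rates")
  wcsv(sdist, "slope_distribution")
  wcsv(det$factor_q, "factor_q")
  wcsv(det$interaction_q, "interaction_q")
  if (nrow(pruned$dropped)) wcsv(pruned$dropped, "pruned_factors")

  manifest <- list(
    package = "treelineq",
    seed = config$truth$seed,
    grid = c(config$truth$nrow, config$truth$ncol),
    cell_size = config$truth$cell_size,
    years = config$truth$years,
    season = config$season,
    strata = list(method = config$strata_method, k = config$strata_k,
                  min_stratum_n = config$min_stratum_n),
    aggregation = config$aggregation,
    span_convention = config$span_convention,
    sector_mask = config$sector_mask,
    factors_kept = names(factors),
    factors_dropped = pruned$dropped$dropped,
    change_areas_hm2 = as.list(attr(ch, "areas_hm2"))
  )
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$manifest <- mp

  invisible(list(scene = scene, factors = factors, change = ch,
                 response = resp, detectors = det, summary = summ,
                 slope_distribution = sdist, pruned = pruned,
                 sectors = sectors, paths = paths))
}
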