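config_defaults <- function() {
  list(task = NULL, input = NULL, inputs = NULL, selections = NULL,
       output_dir = ".", hwhm = 0.04, t_max = 100, dt = 0.1, n_max = 10,
       grid = NULL, initial = 1L, coupling_classes = NULL,
       hems_blocks = 3L, hems_keep = NULL, cutoff_nm = 0.10,
       weights = NULL, x_column = NULL, y_column = NULL,
       generator = NULL, generator_args = list(),
       normalize = TRUE, prefactor = FALSE, seed = 1L)
}

#' Run configuration for the command-line pipeline
#'
#' Validated configuration with the package's standard defaults:
#' Gaussian broadening HWHM 0.04 eV, 100 fs propagation, 0.10 nm RMSD
#' clustering cutoff. Unknown keys are rejected by name.
#'
#' @param ... configuration fields (see `vibronic:::config_defaults()`
#'   for the full set).
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  if (!is.null(cfg$task) &&
      !cfg$task %in% c("synth", "spectrum", "populations", "hems", "cluster",
                       "descriptors", "correlate", "average"))
    stop("unknown task: ", cfg$task, call. = FALSE)
  if (cfg$hwhm <= 0 || cfg$t_max <= 0 || cfg$dt <= 0 || cfg$cutoff_nm <= 0)
    stop("hwhm, t_max, dt and cutoff_nm must be positive", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` needs the yaml package).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  run_config(lst)
}

config_grid <- function(cfg) {
  if (is.null(cfg$grid)) return(NULL)
  if (length(cfg$grid) != 3L)
    stop("grid must be c(lo, hi, step) in eV", call. = FALSE)
  seq(cfg$grid[1], cfg$grid[2], by = cfg$grid[3])
}

out_path <- function(cfg, name) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$output_dir, name)
}

#' Execute one pipeline stage
#'
#' Dispatches on `config$task`, runs the corresponding package
#' functions, writes the stage outputs under `config$output_dir` and a
#' `manifest.json` recording the configuration, the produced files and
#' their checksums. Given the same configuration and inputs the outputs
#' are bitwise identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (is.null(config$task)) stop("config$task is required", call. = FALSE)
  outputs <- switch(
    config$task,
    synth = stage_synth(config),
    spectrum = stage_spectrum(config),
    populations = stage_populations(config),
    hems = stage_hems(config),
    cluster = stage_cluster(config),
    descriptors = stage_descriptors(config),
    correlate = stage_correlate(config),
    average = stage_average(config))
  manifest <- list(task = config$task,
                   config = unclass(config),
                   outputs = outputs,
                   checksums = as.list(tools::md5sum(unlist(outputs))))
  jsonlite::write_json(manifest, out_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

stage_synth <- function(cfg) {
  if (is.null(cfg$generator)) stop("synth needs config$generator", call. = FALSE)
  gen <- switch(cfg$generator,
                displaced_monomer = make_displaced_monomer,
                jt_monomer = make_jt_monomer,
                kasha_ct_dimer = make_kasha_ct_dimer,
                stacked_trajectory = make_stacked_trajectory,
                stop("unknown generator: ", cfg$generator, call. = FALSE))
  args <- cfg$generator_args
  if (cfg$generator == "stacked_trajectory" && is.null(args$seed))
    args$seed <- cfg$seed
  obj <- do.call(gen, args)
  if (inherits(obj, "lvc_hamiltonian")) {
    p <- out_path(cfg, paste0(cfg$generator, ".lvc.json"))
    write_lvc(obj, p)
    list(model = p)
  } else {
    p <- out_path(cfg, paste0(cfg$generator, ".xyz"))
    s <- out_path(cfg, paste0(cfg$generator, ".selections.json"))
    write_trajectory_xyz(obj, p)
    write_selections(obj$selections, s)
    list(trajectory = p, selections = s)
  }
}

load_model <- function(cfg) {
  if (is.null(cfg$input)) stop("config$input (LVC parameter file) is required",
                               call. = FALSE)
  H <- read_lvc(cfg$input)
  if (!is.null(cfg$coupling_classes))
    H <- toggle_couplings(H, cfg$coupling_classes)
  H
}

stage_spectrum <- function(cfg) {
  H <- load_model(cfg)
  spec <- lvc_spectrum(H, n_max = cfg$n_max, t_max = cfg$t_max, dt = cfg$dt,
                       hwhm = cfg$hwhm, grid = config_grid(cfg),
                       prefactor = cfg$prefactor)
  p <- out_path(cfg, "spectrum.csv")
  write_spectrum_csv(spec, p, normalize = cfg$normalize)
  list(spectrum = p, metadata = paste0(p, ".json"))
}

stage_populations <- function(cfg) {
  H <- load_model(cfg)
  res <- propagate(H, build_basis(H, cfg$n_max), initial = cfg$initial,
                   t_max = cfg$t_max, dt = cfg$dt)
  p <- out_path(cfg, "populations.csv")
  write_populations_csv(res, p)
  c_ <- out_path(cfg, "correlations.csv")
  write_correlations_csv(res, c_)
  list(populations = p, correlations = c_)
}

stage_hems <- function(cfg) {
  H <- load_model(cfg)
  hier <- build_hierarchy(H, n_blocks = cfg$hems_blocks)
  keep <- if (is.null(cfg$hems_keep)) hier$n_blocks else cfg$hems_keep
  Hred <- hems_truncate(hier, H, keep)
  ph <- out_path(cfg, "hierarchy.json")
  pm <- out_path(cfg, "reduced.lvc.json")
  write_hierarchy(hier, ph)
  write_lvc(Hred, pm)
  list(hierarchy = ph, reduced_model = pm)
}

load_ensemble <- function(cfg) {
  if (is.null(cfg$input) || is.null(cfg$selections))
    stop("cluster/descriptors need config$input and config$selections",
         call. = FALSE)
  read_trajectory(cfg$input, cfg$selections)
}

stage_cluster <- function(cfg) {
  ens <- load_ensemble(cfg)
  cl <- daura_cluster(pairwise_rmsd(ens), cutoff = cfg$cutoff_nm)
  p <- out_path(cfg, "clusters.csv")
  write_clusters(cl, p, out_path(cfg, "clusters.json"))
  list(assignments = p, summary = out_path(cfg, "clusters.json"))
}

stage_descriptors <- function(cfg) {
  ens <- load_ensemble(cfg)
  df <- descriptor_table(ens)
  p <- out_path(cfg, "descriptors.csv")
  utils::write.csv(df, p, row.names = FALSE)
  list(descriptors = p)
}

stage_correlate <- function(cfg) {
  if (is.null(cfg$input) || is.null(cfg$x_column) || is.null(cfg$y_column))
    stop("correlate needs config$input (CSV) plus x_column and y_column",
         call. = FALSE)
  df <- utils::read.csv(cfg$input)
  fit <- linear_correlation(df[[cfg$x_column]], df[[cfg$y_column]])
  p <- out_path(cfg, "correlation.json")
  jsonlite::write_json(fit, p, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  list(correlation = p)
}

stage_average <- function(cfg) {
  if (is.null(cfg$inputs) || is.null(cfg$weights))
    stop("average needs config$inputs (spectrum CSVs) and config$weights",
         call. = FALSE)
  specs <- lapply(cfg$inputs, function(p) {
    df <- utils::read.csv(p)
    structure(list(grid = df$energy_ev,
                   components = matrix(df$total, dimnames = list(NULL, "total")),
                   total = df$total, gamma = NA_real_, hwhm = NA_real_,
                   prefactor = FALSE),
              class = "vibronic_spectrum")
  })
  avg <- weighted_average_spectrum(specs, cfg$weights)
  p <- out_path(cfg, "average_spectrum.csv")
  write_spectrum_csv(avg, p, normalize = cfg$normalize)
  list(average_spectrum = p, metadata = paste0(p, ".json"))
}
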