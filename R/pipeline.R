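# Orchestration: run configuration, provenance, and the simulate -> fit ->
# summarize stages tying the modules together. A thin command-line front-end
# over these functions ships in inst/scripts/afmcell.

#' Build and validate a run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param preset_file Cohort preset YAML (default: the packaged presets).
#' @param presets Character vector of two preset names (control, activated).
#' @param model Fit model: `"hertz"`, `"ting"`, or `"both"`.
#' @param use_bec Apply the bottom-effect correction during fitting.
#' @param fit_range Indentation fit window (fractions of maximum).
#' @param rate_hz Simulation sampling rate.
#' @param seed Run seed (drives every stochastic step).
#' @param input_dir Directory of existing `.fvm.rds` containers for
#'   [run_fit()] when not simulating.
#' @return Validated list of class `run_config` with a provenance hash.
#' @export
run_config <- function(out_dir = "afmcell_run", preset_file = NULL,
                       presets = c("m1_control", "m1_pma"),
                       model = c("hertz", "ting", "both"), use_bec = TRUE,
                       fit_range = c(0.1, 0.9), rate_hz = 10000, seed = 1,
                       input_dir = NULL) {
  model <- match.arg(model)
  if (is.null(preset_file))
    preset_file <- system.file("extdata", "cohort_presets.yaml",
                               package = "afmcell")
  if (!file.exists(preset_file))
    abort_config(sprintf("preset file not found: '%s'", preset_file))
  if (length(presets) != 2) abort_config("exactly two preset names required")
  avail <- names(load_cohort_presets(preset_file))
  if (!all(presets %in% avail))
    abort_config(sprintf("unknown preset(s): %s (available: %s)",
                         paste(setdiff(presets, avail), collapse = ", "),
                         paste(avail, collapse = ", ")))
  if (!is.numeric(seed) || length(seed) != 1) abort_config("seed must be one integer")
  cfg <- list(out_dir = out_dir, preset_file = preset_file, presets = presets,
              model = model, use_bec = use_bec, fit_range = fit_range,
              rate_hz = rate_hz, seed = as.integer(seed),
              input_dir = input_dir)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

# md5 of the serialized configuration, for output provenance
config_hash <- function(cfg) {
  cfg$hash <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(cfg[order(names(cfg))], tf)
  ser <- serialize(cfg[order(names(cfg))], NULL, version = 2)
  tf2 <- tempfile()
  on.exit(unlink(tf2), add = TRUE)
  writeBin(ser, tf2)
  unname(tools::md5sum(tf2))
}

.write_provenance <- function(cfg, stage) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(cfg[setdiff(names(cfg), "hash")],
            list(stage = stage, config_hash = cfg$hash,
                 package_version = as.character(utils::packageVersion("afmcell"))))
  yaml::write_yaml(prov, file.path(cfg$out_dir,
                                   sprintf("provenance_%s.yaml", stage)))
}

#' Simulate cohort containers from presets
#'
#' Draws the two configured cohorts and writes one force-volume container
#' per cell plus a ground-truth table (`truth.csv`) to the output directory.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the paths of the written containers.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pres <- load_cohort_presets(cfg$preset_file)
  cohort <- simulate_cohort(pres[[cfg$presets[1]]], pres[[cfg$presets[2]]],
                            seed = cfg$seed, rate_hz = cfg$rate_hz)
  paths <- character(length(cohort))
  for (i in seq_along(cohort)) {
    paths[i] <- file.path(cfg$out_dir, sprintf("cell_%03d.fvm.rds", i))
    write_fv_map(cohort[[i]], paths[i])
  }
  truth <- attr(cohort, "draws")
  truth$config_hash <- cfg$hash
  write.table(truth, file.path(cfg$out_dir, "truth.csv"), sep = ",",
              row.names = FALSE)
  .write_provenance(cfg, "simulate")
  invisible(paths)
}

#' Fit all containers of a run
#'
#' Processes every `.fvm.rds` container in the input (or output) directory:
#' contact detection, topography, tilt correction, per-pixel fits and
#' per-cell aggregation. Writes `cell_records.csv` and `pixel_fits.csv`;
#' every pixel is accounted for by a status.
#'
#' @param cfg A [run_config()].
#' @return The cell-records data.frame, invisibly.
#' @export
run_fit <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  src <- cfg$input_dir %||% cfg$out_dir
  files <- sort(list.files(src, pattern = "\\.fvm\\.rds$", full.names = TRUE))
  if (!length(files)) abort_config(sprintf("no containers found in '%s'", src))
  records <- list()
  pixels <- list()
  for (i in seq_along(files)) {
    map <- read_fv_map(files[i])
    map <- fit_map(map, model = cfg$model, use_bec = cfg$use_bec,
                   fit_range = cfg$fit_range)
    px <- map$fits
    px$cell_id <- i
    pixels[[i]] <- px
    rec <- tryCatch(aggregate_cell(map, cell_id = i),
                    afmcellError = function(e) NULL)
    if (!is.null(rec)) records[[length(records) + 1]] <- rec
  }
  pixdf <- do.call(rbind, pixels)
  write.table(pixdf, file.path(cfg$out_dir, "pixel_fits.csv"), sep = ",",
              row.names = FALSE)
  recdf <- if (length(records)) do.call(rbind, records) else
    data.frame(cell_id = integer(), condition = character(),
               ym_kpa = numeric(), e1_kpa = numeric(), alpha = numeric(),
               eta_pas = numeric(), height_um = numeric(),
               n_pixels = integer(), n_excluded = integer())
  recdf$config_hash <- cfg$hash
  write.table(recdf, file.path(cfg$out_dir, "cell_records.csv"), sep = ",",
              row.names = FALSE)
  .write_provenance(cfg, "fit")
  invisible(recdf)
}

#' Summarize a fitted run
#'
#' Reads `cell_records.csv`, computes the per-group summary and fold
#' changes, writes `summary_groups.csv` / `summary_folds.csv` /
#' `summary_tests.csv`, and renders height and modulus maps of the first
#' container as PNG images.
#'
#' @param cfg A [run_config()].
#' @return The [cohort_summary()] list, invisibly.
#' @export
run_summarize <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  rec_path <- file.path(cfg$out_dir, "cell_records.csv")
  if (!file.exists(rec_path)) abort_config("cell_records.csv not found; run_fit first")
  records <- read.delim(rec_path, sep = ",", stringsAsFactors = FALSE)
  if (!nrow(records)) abort_config("no cell records to summarize")
  summ <- cohort_summary(records)
  write.table(summ$groups, file.path(cfg$out_dir, "summary_groups.csv"),
              sep = ",", row.names = FALSE)
  if (!is.null(summ$folds))
    write.table(summ$folds, file.path(cfg$out_dir, "summary_folds.csv"),
                sep = ",", row.names = FALSE)
  if (!is.null(summ$tests))
    write.table(summ$tests, file.path(cfg$out_dir, "summary_tests.csv"),
                sep = ",", row.names = FALSE)
  src <- cfg$input_dir %||% cfg$out_dir
  f1 <- sort(list.files(src, pattern = "\\.fvm\\.rds$", full.names = TRUE))
  if (length(f1)) {
    map <- read_fv_map(f1[1])
    if (is.null(map$fits))
      map <- fit_map(map, model = "hertz", use_bec = cfg$use_bec)
    render_map_png(map$height_um, file.path(cfg$out_dir, "height_map.png"),
                   "height (um)")
    ym <- matrix(NA_real_, map$nrow, map$ncol)
    ym[cbind(map$fits$row, map$fits$col)] <- map$fits$ym_pa / 1000
    ym[!is.finite(ym)] <- 0
    render_map_png(ym, file.path(cfg$out_dir, "ym_map.png"),
                   "apparent YM (kPa)")
  }
  .write_provenance(cfg, "summarize")
  invisible(summ)
}

#' Run the full pipeline (simulate, fit, summarize)
#'
#' @param cfg A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_all <- function(cfg) {
  run_simulate(cfg)
  run_fit(cfg)
  run_summarize(cfg)
}
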