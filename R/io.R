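# File formats: per-curve delimited text with a commented metadata header,
# a single-file force-volume container, delimited matrix exports, and
# delimited assay inputs.

#' Write a force curve as delimited text
#'
#' Tab-separated columns `t_s`, `z_nm`, `force_nN` (or `deflection_V` for raw
#' curves) and `phase` (`approach`/`retract`), preceded by a commented
#' YAML-style metadata header (`# key: value`) carrying the calibration
#' constants (`spring_constant_N_per_m`, `sensitivity_nm_per_V`,
#' `tip_radius_nm`, `poisson_nu`, `i_turn`).
#'
#' @param curve A [force_curve()].
#' @param path Output file path.
#' @export
write_curve_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  meta <- c(spring_constant_N_per_m = curve$spring_constant,
            sensitivity_nm_per_V = curve$sensitivity_nm_per_V %||% NA,
            tip_radius_nm = curve$probe$radius_nm,
            poisson_nu = curve$probe$poisson_nu,
            i_turn = curve$i_turn)
  hdr <- sprintf("# %s: %s", names(meta), vapply(meta, format, ""))
  phase <- rep(c("approach", "retract"),
               c(curve$i_turn, length(curve$t_s) - curve$i_turn))
  df <- data.frame(t_s = curve$t_s, z_nm = curve$z_nm)
  if (!is.null(curve$force_nN)) df$force_nN <- curve$force_nN
  if (!is.null(curve$deflection_V)) df$deflection_V <- curve$deflection_V
  df$phase <- phase
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a force curve from delimited text
#'
#' Counterpart of [write_curve_tsv()]. Metadata may also be supplied (or
#' overridden) through `meta`, a named list with the keys documented there.
#'
#' @param path Input file path.
#' @param meta Optional named list overriding header metadata.
#' @return A [force_curve()].
#' @export
read_curve_tsv <- function(path, meta = list()) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv <- modifyList(kv, meta)
  num <- function(key, default = NULL) {
    v <- kv[[key]]
    if (is.null(v) || (is.character(v) && v %in% c("NA", ""))) default
    else as.numeric(v)
  }
  k <- num("spring_constant_N_per_m")
  if (is.null(k)) abort_config("spring_constant_N_per_m missing from header/meta")
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  i_turn <- num("i_turn", default = {
    if ("phase" %in% names(df)) max(which(df$phase == "approach"))
    else which.max(df$z_nm)
  })
  force_curve(
    t_s = df$t_s, z_nm = df$z_nm,
    force_nN = if ("force_nN" %in% names(df)) df$force_nN else NULL,
    deflection_V = if ("deflection_V" %in% names(df)) df$deflection_V else NULL,
    i_turn = i_turn, spring_constant = k,
    sensitivity_nm_per_V = num("sensitivity_nm_per_V"),
    probe = indenter(radius_nm = num("tip_radius_nm", 70),
                     poisson_nu = num("poisson_nu", 0.5)))
}

#' Write / read a force-volume map container
#'
#' Single-file container for an `fv_map`: curves, grid geometry, probe
#' metadata, optional mask and fit results, serialized with R's native
#' format. Matrices (height, modulus) are additionally exportable as
#' delimited text via [write_matrix_tsv()].
#'
#' @param map An `fv_map`.
#' @param path File path (conventionally `.fvm.rds`).
#' @return `read_fv_map()` returns the `fv_map`.
#' @export
write_fv_map <- function(map, path) {
  stopifnot(inherits(map, "fv_map"))
  saveRDS(map, path)
  invisible(path)
}

#' @rdname write_fv_map
#' @export
read_fv_map <- function(path) {
  map <- readRDS(path)
  if (!inherits(map, "fv_map")) abort_config("file does not contain an fv_map")
  map
}

#' Export a matrix as delimited text
#'
#' @param m Numeric matrix (e.g. a height map).
#' @param path Output file path.
#' @export
write_matrix_tsv <- function(m, path) {
  write.table(unclass(m), path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a plate-reader kinetics trace from delimited text
#'
#' Expects columns `time_s` and `signal`; an optional commented header line
#' `# t_act_s: <value>` records the activator-addition time.
#'
#' @param path Input file path.
#' @param t_act_s Activator time override (s).
#' @return A `kinetics_trace` data.frame.
#' @export
read_kinetics_tsv <- function(path, t_act_s = NULL) {
  lines <- readLines(path, n = 20)
  if (is.null(t_act_s)) {
    h <- grep("^#\\s*t_act_s:", lines, value = TRUE)
    if (length(h)) t_act_s <- as.numeric(sub("^#\\s*t_act_s:\\s*", "", h[1]))
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "signal") %in% names(df)))
  class(df) <- c("kinetics_trace", "data.frame")
  attr(df, "t_act_s") <- t_act_s
  df
}

#' Read a flow-cytometry event list from delimited text
#'
#' One intensity per line (column `intensity`).
#'
#' @param path Input file path.
#' @return Numeric vector of class `cytometry_sample`.
#' @export
read_cytometry_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot("intensity" %in% names(df))
  structure(as.numeric(df$intensity), class = "cytometry_sample")
}

#' Render a height or parameter map to an image file
#'
#' @param m Numeric matrix (um or kPa).
#' @param path Output PNG path.
#' @param main Plot title.
#' @export
render_map_png <- function(m, path, main = "") {
  grDevices::png(path, width = 640, height = 600)
  on.exit(grDevices::dev.off())
  graphics::image(t(unclass(m))[, nrow(m):1, drop = FALSE],
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = main)
  invisible(path)
}
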