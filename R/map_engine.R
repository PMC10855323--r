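# Force-volume map processing: per-pixel contact detection, topography,
# tilt correction, central-part filtering, per-cell and cohort aggregation.

map_index <- function(map, r, cc) (r - 1) * map$ncol + cc

# least-squares plane z = a + bx + cy over selected pixels (pixel coords)
.fit_plane <- function(h, use) {
  idx <- which(use & is.finite(h))
  if (length(idx) < 3) return(NULL)
  rr <- (idx - 1) %% nrow(h) + 1
  cc <- (idx - 1) %/% nrow(h) + 1
  X <- cbind(1, rr, cc)
  if (qr(X)$rank < 3) return(NULL)
  cf <- qr.solve(X, h[idx])
  all_r <- matrix(seq_len(nrow(h)), nrow(h), ncol(h))
  all_c <- matrix(rep(seq_len(ncol(h)), each = nrow(h)), nrow(h), ncol(h))
  cf[1] + cf[2] * all_r + cf[3] * all_c
}

#' Detect contact points across a force-volume map
#'
#' Runs [detect_contact_point()] on every pixel; failures are recorded, not
#' raised. Adds a `contacts` data.frame to the map.
#'
#' @param map An `fv_map` (see [simulate_cell_map()] or [read_fv_map()]).
#' @return The map with `$contacts` (`row`, `col`, `z0_nm`, `offset_nN`,
#'   `slope_nN_per_nm`, `status`).
#' @export
detect_contacts <- function(map) {
  stopifnot(inherits(map, "fv_map"))
  n <- map$nrow * map$ncol
  res <- data.frame(row = rep(seq_len(map$nrow), each = map$ncol),
                    col = rep(seq_len(map$ncol), map$nrow),
                    z0_nm = NA_real_, offset_nN = NA_real_,
                    slope_nN_per_nm = NA_real_, status = "no_contact",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    est <- tryCatch(detect_contact_point(map$curves[[i]]),
                    afmcellError = function(e) NULL)
    if (!is.null(est)) {
      res$z0_nm[i] <- est$z0_nm
      res$offset_nN[i] <- est$offset_nN
      res$slope_nN_per_nm[i] <- est$slope_nN_per_nm
      res$status[i] <- "ok"
    }
  }
  map$contacts <- res
  map
}

#' Reconstruct topography from contact points
#'
#' Local height is the contact position relative to the substrate reference
#' plane (taller surface = contact reached earlier in the ramp). The
#' reference plane is fit over masked substrate pixels when a mask is
#' available, otherwise over the lowest height decile.
#'
#' @param map An `fv_map`; contacts are detected on the fly if absent.
#' @param substrate Optional logical matrix marking substrate pixels.
#' @return A numeric matrix of heights in um (class `height_map`, attribute
#'   `pixel_um`); NA where no contact was found.
#' @export
reconstruct_topography <- function(map, substrate = NULL) {
  stopifnot(inherits(map, "fv_map"))
  if (is.null(map$contacts)) map <- detect_contacts(map)
  ok <- map$contacts$status == "ok"
  if (!any(ok)) abort_empty_map("all pixels are NoContact")
  h <- matrix(NA_real_, map$nrow, map$ncol)
  h[cbind(map$contacts$row, map$contacts$col)] <- -map$contacts$z0_nm / 1000
  if (is.null(substrate)) {
    thr <- quantile(h, 0.1, na.rm = TRUE)
    substrate <- !is.na(h) & h <= thr
  }
  pl <- .fit_plane(h, substrate)
  if (is.null(pl)) {
    h <- h - median(h[substrate], na.rm = TRUE)
  } else {
    h <- h - pl
  }
  structure(h, class = c("height_map", "matrix"), pixel_um = map$pixel_um)
}

#' Global tilt correction of a height map
#'
#' Subtracts the best-fit plane over substrate pixels. With fewer than three
#' non-collinear substrate pixels the map is returned unchanged with a
#' warning (the correction is applied "if needed").
#'
#' @param height Height matrix (um), e.g. from [reconstruct_topography()].
#' @param substrate Optional logical matrix of substrate pixels; default is
#'   the lowest height decile.
#' @return The corrected height matrix (same class/attributes).
#' @export
correct_tilt <- function(height, substrate = NULL) {
  h <- unclass(height)
  if (is.null(substrate)) {
    thr <- quantile(h, 0.1, na.rm = TRUE)
    substrate <- !is.na(h) & h <= thr
  }
  pl <- .fit_plane(h, substrate)
  if (is.null(pl)) {
    warning("fewer than 3 non-collinear substrate pixels; tilt correction skipped")
    return(height)
  }
  out <- h - pl
  attributes(out) <- attributes(height)
  out
}

#' Central-part filter: keep the top half of a cell's pixels by height
#'
#' Retains exactly `ceiling(n / 2)` of the `n` cell pixels with the highest
#' local height; ties are broken by stable pixel index order (lower index
#' wins). The discarded lower periphery is excluded from mechanical
#' aggregation.
#'
#' @param height Numeric vector of cell-pixel heights, or a height matrix.
#' @param mask Logical matrix of cell pixels (required for matrix input).
#' @return Logical vector (or matrix) marking retained pixels.
#' @export
central_part_filter <- function(height, mask = NULL) {
  if (is.matrix(height) || inherits(height, "height_map")) {
    h <- unclass(height)
    if (is.null(mask)) abort_config("mask required for matrix input")
    if (!any(mask)) abort_empty_cell("empty cell mask")
    idx <- which(mask)
    keep_v <- central_part_filter(h[idx])
    out <- matrix(FALSE, nrow(h), ncol(h))
    out[idx[keep_v]] <- TRUE
    return(out)
  }
  n <- length(height)
  if (n < 2) abort_empty_cell("need at least 2 cell pixels")
  k <- ceiling(n / 2)
  ord <- order(-height, seq_len(n))
  keep <- logical(n)
  keep[ord[seq_len(k)]] <- TRUE
  keep
}

#' Derive a cell mask from topography
#'
#' Cell pixels are those higher than max(3x the substrate roughness,
#' `min_um`) above the substrate; substrate statistics come from the lowest
#' height decile.
#'
#' @param height Height matrix (um).
#' @param min_um Minimum absolute height for a cell pixel.
#' @return Logical matrix.
#' @export
derive_cell_mask <- function(height, min_um = 0.15) {
  h <- unclass(height)
  thr0 <- quantile(h, 0.1, na.rm = TRUE)
  sub <- !is.na(h) & h <= thr0
  rough <- sd(h[sub], na.rm = TRUE)
  if (!is.finite(rough)) rough <- 0
  !is.na(h) & h > max(3 * rough, min_um)
}

#' Fit every pixel of a force-volume map
#'
#' Full map pipeline: contact detection, topography reconstruction with tilt
#' correction, cell-mask derivation (unless supplied), then per-pixel Hertz
#' and/or Ting fits over cell pixels. When `use_bec` is TRUE the local
#' reconstructed height provides the per-pixel sample thickness for the
#' bottom-effect correction.
#'
#' @param map An `fv_map`.
#' @param model `"hertz"`, `"ting"`, or `"both"`.
#' @param mask Optional logical cell mask (default: derived from topography;
#'   a synthetic map's ground-truth mask is NOT used).
#' @param use_bec Apply the bottom-effect correction with the reconstructed
#'   local thickness.
#' @param bec A [bec_model()].
#' @param fit_range Indentation window (fractions of maximum).
#' @return The map with `$height_um` (tilt-corrected height matrix),
#'   `$mask`, and `$fits` (per-pixel data.frame with `status` one of
#'   `ok`, `substrate`, `no_contact`, `failed`).
#' @export
fit_map <- function(map, model = c("hertz", "ting", "both"), mask = NULL,
                    use_bec = TRUE, bec = bec_model(),
                    fit_range = c(0.1, 0.9)) {
  model <- match.arg(model)
  if (is.null(map$contacts)) map <- detect_contacts(map)
  height <- reconstruct_topography(map)
  height <- correct_tilt(height)
  if (is.null(mask)) mask <- derive_cell_mask(height)
  fits <- map$contacts[c("row", "col", "z0_nm", "status")]
  fits$height_um <- height[cbind(fits$row, fits$col)]
  fits$ym_pa <- NA_real_
  fits$e1_pa <- NA_real_
  fits$alpha <- NA_real_
  fits$eta_pas <- NA_real_
  fits$rms_nN <- NA_real_
  n <- nrow(fits)
  for (i in seq_len(n)) {
    if (fits$status[i] != "ok") next
    if (!mask[fits$row[i], fits$col[i]]) {
      fits$status[i] <- "substrate"
      next
    }
    th <- if (use_bec) max(fits$height_um[i], 0.05) * 1000 else Inf
    cur <- map$curves[[i]]
    res <- tryCatch({
      if (model %in% c("hertz", "both")) {
        hz <- fit_hertz(cur, thickness = th, bec = bec,
                        fit_range = fit_range)
        fits$ym_pa[i] <- hz$E_pa
        fits$rms_nN[i] <- hz$rms_nN
        fits$z0_nm[i] <- hz$contact$z0_nm
      }
      if (model %in% c("ting", "both")) {
        tg <- fit_ting(cur, thickness = th, bec = bec,
                       fit_range = fit_range)
        if (!is.null(tg$params)) {
          fits$e1_pa[i] <- tg$params$E1
          fits$alpha[i] <- tg$params$alpha
          fits$eta_pas[i] <- tg$params$eta
          fits$rms_nN[i] <- tg$rms_nN
        }
        if (is.na(fits$ym_pa[i])) fits$ym_pa[i] <- tg$E_pa
      }
      "ok"
    }, noContactError = function(e) "no_contact",
       afmcellError = function(e) "failed")
    fits$status[i] <- res
    if (res == "ok" && model == "hertz" && !is.finite(fits$ym_pa[i]))
      fits$status[i] <- "failed"
  }
  map$height_um <- height
  map$mask <- mask
  map$fits <- fits
  map
}

#' Aggregate a fitted map into one cell record
#'
#' Applies the central-part filter over the cell mask, then takes arithmetic
#' means of the fitted parameters over retained, successfully fitted pixels.
#' Cell height is the maximum tilt-corrected height over the cell (`"apex"`)
#' or the mean over the cell (`"mean"`).
#'
#' @param map A map processed by [fit_map()].
#' @param cell_id Identifier stored in the record.
#' @param condition Condition label (default: the map's label).
#' @param height_stat `"apex"` (default) or `"mean"`.
#' @return One-row data.frame: `cell_id`, `condition`, `ym_kpa`, `e1_kpa`,
#'   `alpha`, `eta_pas`, `height_um`, `n_pixels` (retained + fitted),
#'   `n_excluded`.
#' @export
aggregate_cell <- function(map, cell_id = 1L, condition = map$label,
                           height_stat = c("apex", "mean")) {
  height_stat <- match.arg(height_stat)
  if (is.null(map$fits)) abort_config("run fit_map() before aggregate_cell()")
  mask <- map$mask
  if (is.null(mask) || !any(mask)) abort_empty_cell("empty cell mask")
  keep <- central_part_filter(map$height_um, mask)
  fits <- map$fits
  sel <- keep[cbind(fits$row, fits$col)] & fits$status == "ok"
  if (!any(sel)) abort_empty_cell("no retained fitted pixels")
  hcell <- map$height_um[mask]
  height <- if (height_stat == "apex") max(hcell, na.rm = TRUE)
            else mean(hcell, na.rm = TRUE)
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  data.frame(cell_id = cell_id, condition = as.character(condition),
             ym_kpa = mean_or_na(fits$ym_pa[sel]) / 1000,
             e1_kpa = mean_or_na(fits$e1_pa[sel]) / 1000,
             alpha = mean_or_na(fits$alpha[sel]),
             eta_pas = mean_or_na(fits$eta_pas[sel]),
             height_um = height,
             n_pixels = sum(sel),
             n_excluded = sum(keep[cbind(fits$row, fits$col)] & !sel),
             stringsAsFactors = FALSE)
}

# default fold orientation per variable: stiffness-type variables are
# reported as activated/control increases, height and fluidity (alpha) as
# control/activated decreases
.fold_direction <- c(ym_kpa = "act_over_ctrl", e1_kpa = "act_over_ctrl",
                     eta_pas = "act_over_ctrl", alpha = "ctrl_over_act",
                     height_um = "ctrl_over_act")

#' Summarise cell records by condition
#'
#' Per-group mean, SD and n for each mechanical variable, plus fold changes
#' between a control and an activated condition: modulus-type variables as
#' activated/control, height and power-law exponent as control/activated
#' (fold *decrease*). Two-sample significance tests are delegated to
#' standard routines (Welch t and Mann-Whitney) and reported as-is.
#'
#' @param records data.frame of rows from [aggregate_cell()].
#' @param control,activated Condition labels; default the first and second
#'   unique condition in `records`.
#' @param variables Variables to summarise.
#' @return List with `groups` (long data.frame: condition, variable, mean,
#'   sd, n), `folds` (variable, fold, direction), `tests` (variable,
#'   p_t, p_wilcox). Groups with fewer than 2 cells are dropped with a
#'   warning; folds/tests need both groups present.
#' @export
cohort_summary <- function(records, control = NULL, activated = NULL,
                           variables = c("ym_kpa", "e1_kpa", "alpha",
                                         "eta_pas", "height_um")) {
  stopifnot(is.data.frame(records), "condition" %in% names(records))
  variables <- intersect(variables, names(records))
  conds <- unique(records$condition)
  sizes <- table(records$condition)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping group(s) with < 2 cells: ",
            paste(small, collapse = ", "))
    records <- records[!records$condition %in% small, , drop = FALSE]
    conds <- setdiff(conds, small)
  }
  groups <- do.call(rbind, lapply(conds, function(g) {
    sub <- records[records$condition == g, , drop = FALSE]
    do.call(rbind, lapply(variables, function(v) {
      x <- sub[[v]]
      data.frame(condition = g, variable = v,
                 mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE),
                 n = sum(!is.na(x)), stringsAsFactors = FALSE)
    }))
  }))
  folds <- NULL
  tests <- NULL
  if (is.null(control) && length(conds) >= 1) control <- conds[1]
  if (is.null(activated) && length(conds) >= 2) activated <- conds[2]
  if (!is.null(control) && !is.null(activated) &&
      all(c(control, activated) %in% conds)) {
    xs <- records[records$condition == control, , drop = FALSE]
    ys <- records[records$condition == activated, , drop = FALSE]
    folds <- do.call(rbind, lapply(variables, function(v) {
      mc <- mean(xs[[v]], na.rm = TRUE)
      ma <- mean(ys[[v]], na.rm = TRUE)
      dir <- if (v %in% names(.fold_direction)) .fold_direction[[v]]
             else "act_over_ctrl"
      fold <- if (dir == "act_over_ctrl") ma / mc else mc / ma
      data.frame(variable = v, fold = fold, direction = dir,
                 stringsAsFactors = FALSE)
    }))
    tests <- do.call(rbind, lapply(variables, function(v) {
      a <- xs[[v]]; b <- ys[[v]]
      ok <- sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2 &&
        (sd(a, na.rm = TRUE) > 0 || sd(b, na.rm = TRUE) > 0)
      data.frame(
        variable = v,
        p_t = if (ok) tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
              else NA_real_,
        p_wilcox = if (ok) tryCatch(
          suppressWarnings(wilcox.test(a, b)$p.value),
          error = function(e) NA_real_) else NA_real_,
        stringsAsFactors = FALSE)
    }))
  }
  list(groups = groups, folds = folds, tests = tests,
       control = control, activated = activated)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
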