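# Ground-truth generators: single F-Z curves, force-volume maps of phantom
# cells, condition cohorts and assay data. Every generator is deterministic
# under its seed and embeds the ground truth in the returned object.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Specification for one synthetic force curve
#'
#' Acquisition defaults follow the live-cell fast-force-volume protocol:
#' 3 um vertical ramp at 183 um/s, 1 nN trigger force (the upper end of the
#' protocol's 0.5-1 nN range, which favours viscoelastic identifiability),
#' 0.1 N/m cantilever, 300 kHz digitisation.
#'
#' @param params A [plr_params()] ground truth.
#' @param probe An [indenter()].
#' @param thickness_nm Local sample thickness (drives the bottom-effect
#'   correction; `Inf` for semi-infinite).
#' @param bec A [bec_model()] used in generation when `thickness_nm` finite.
#' @param ramp_nm,speed_nm_s Vertical ramp distance and piezo speed.
#' @param rate_hz Sampling rate.
#' @param z_start_nm,contact_z_nm Absolute piezo positions of ramp start and
#'   of the undeformed surface.
#' @param spring_constant Cantilever spring constant, N/m.
#' @param sensitivity_nm_per_V Deflection sensitivity used to synthesise raw
#'   deflection channels.
#' @param trigger_nN Relative trigger force at which the ramp reverses.
#' @param baseline_offset_nN,baseline_slope_nN_per_nm Baseline contamination.
#' @param noise_nN Additive Gaussian force noise RMS (20 pN default).
#' @param seed RNG seed recorded in the provenance.
#' @return An object of class `curve_spec`.
#' @export
curve_spec <- function(params = plr_params(3000, 0.2, 0),
                       probe = indenter(), thickness_nm = Inf,
                       bec = bec_model(), ramp_nm = 3000,
                       speed_nm_s = 183000, rate_hz = 300000,
                       z_start_nm = 0, contact_z_nm = 1500,
                       spring_constant = 0.1, sensitivity_nm_per_V = 50,
                       trigger_nN = 1, baseline_offset_nN = 0,
                       baseline_slope_nN_per_nm = 0, noise_nN = 0.02,
                       seed = NULL) {
  stopifnot(inherits(params, "plr_params"), inherits(probe, "indenter"))
  if (speed_nm_s <= 0 || rate_hz <= 0) abort_domain("ramp speed and rate must be > 0")
  if (noise_nN < 0) abort_domain("noise RMS must be >= 0")
  structure(as.list(environment()), class = "curve_spec")
}

#' Simulate one force curve from a ground-truth specification
#'
#' Forward Ting model coupled quasi-statically to the cantilever (force
#' balance `k d = F(delta)`, `delta = (z - z0) - d`); the ramp turns around
#' at the trigger force. Baseline offset/tilt and seeded Gaussian noise are
#' added to the force channel; a raw deflection channel (V) is synthesised
#' from the sensitivity. Ground truth is attached as attribute `"truth"`.
#'
#' @param spec A [curve_spec()].
#' @return A [force_curve()] with attribute `truth` (spec, true contact
#'   position, indentation history, turnaround index).
#' @export
simulate_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  if (spec$contact_z_nm >= spec$z_start_nm + spec$ramp_nm)
    abort_domain("contact position beyond ramp end: curve never touches")
  dt <- 1 / spec$rate_hz
  max_n <- ceiling(2.5 * spec$ramp_nm / spec$speed_nm_s * spec$rate_hz) + 10
  sim <- ting_simulate_cpp(
    spec$z_start_nm, spec$contact_z_nm, spec$speed_nm_s, dt, spec$ramp_nm,
    spec$spring_constant, spec$params$E1, spec$params$alpha, spec$params$eta,
    hertz_prefactor(spec$probe), spec$probe$radius_nm, spec$thickness_nm,
    if (is.finite(spec$thickness_nm)) spec$bec$coefficients else numeric(0),
    spec$trigger_nN, as.integer(max_n), 0.8)
  f_clean <- spec$spring_constant * sim$defl
  n <- length(f_clean)
  noise <- with_seed(spec$seed, rnorm(n, 0, spec$noise_nN))
  force <- f_clean + spec$baseline_offset_nN +
    spec$baseline_slope_nN_per_nm * sim$z + noise
  cur <- force_curve(
    t_s = sim$t, z_nm = sim$z, force_nN = force, i_turn = sim$i_turn,
    spring_constant = spec$spring_constant,
    sensitivity_nm_per_V = spec$sensitivity_nm_per_V, probe = spec$probe,
    meta = list(ramp_nm = spec$ramp_nm, speed_nm_s = spec$speed_nm_s,
                trigger_nN = spec$trigger_nN))
  attr(cur, "truth") <- list(
    spec = spec, z0_nm = spec$contact_z_nm, delta_nm = sim$delta,
    i_turn = sim$i_turn, i_contact = sim$i_contact,
    t_contact = sim$t_contact, force_clean_nN = f_clean)
  cur
}

# Rigid-substrate curve: deflection equals piezo travel past contact.
simulate_rigid_curve <- function(spec) {
  dt <- 1 / spec$rate_hz
  d_trig <- spec$trigger_nN / spec$spring_constant
  z_turn <- min(spec$contact_z_nm + d_trig, spec$z_start_nm + spec$ramp_nm)
  t_turn <- (z_turn - spec$z_start_nm) / spec$speed_nm_s
  # one extra sample so the (steep) contact event is actually sampled even
  # when the trigger deflection is smaller than the z sampling step
  n_app <- max(2, ceiling(t_turn / dt) + 1)
  t_app <- seq(0, by = dt, length.out = n_app)
  z_app <- spec$z_start_nm + spec$speed_nm_s * t_app
  t_ret <- seq(t_app[n_app] + dt, by = dt, length.out = n_app)
  z_ret <- z_app[n_app] - spec$speed_nm_s * (t_ret - t_app[n_app])
  tt <- c(t_app, t_ret); zz <- c(z_app, z_ret)
  d <- pmax(zz - spec$contact_z_nm, 0)
  f_clean <- spec$spring_constant * d
  noise <- with_seed(spec$seed, rnorm(length(tt), 0, spec$noise_nN))
  force <- f_clean + spec$baseline_offset_nN +
    spec$baseline_slope_nN_per_nm * zz + noise
  cur <- force_curve(tt, zz, force_nN = force, i_turn = n_app,
                     spring_constant = spec$spring_constant,
                     sensitivity_nm_per_V = spec$sensitivity_nm_per_V,
                     probe = spec$probe,
                     meta = list(rigid = TRUE, trigger_nN = spec$trigger_nN))
  attr(cur, "truth") <- list(spec = spec, z0_nm = spec$contact_z_nm,
                             rigid = TRUE)
  cur
}

# Convert a target apparent Young's modulus into the PLR scale E1.
# For a constant-rate triangular ramp the approach force of a PLR material is
# F(t) = C E1 (3/2) B(3/2, 1-alpha) v^{3/2} t^{3/2-alpha}, so the apparent
# Hertz modulus at the trigger point is E_app = E1 (3/2) B(3/2,1-a) tc^-a.
plr_from_apparent_ym <- function(ym_pa, alpha, eta = 0, probe = indenter(),
                                 trigger_nN = 0.5, speed_nm_s = 183000) {
  bfac <- 1.5 * beta(1.5, 1 - alpha)
  C <- hertz_prefactor(probe)
  d_trig <- (trigger_nN / (C * ym_pa))^(2 / 3)
  tc <- d_trig / speed_nm_s
  plr_params(E1 = ym_pa * tc^alpha / bfac, alpha = alpha, eta = eta)
}

#' Simulate a force-volume map of a spherical-cap phantom cell
#'
#' A spherical-cap cell (apex height, base radius) sits bonded on a rigid
#' substrate. Per-pixel thickness follows the cap geometry and drives the
#' bottom-effect correction; substrate pixels are rigid. Each pixel's ramp
#' window tracks the local surface (closed-loop force-volume acquisition), so
#' contact positions carry the topography. An optional plane tilt can be
#' added to emulate a non-level stage.
#'
#' @param grid Number of pixels per side (>= 8).
#' @param fov_um Physical field of view (square side), um.
#' @param apex_um Cap apex height, um (0 for a substrate-only map).
#' @param base_radius_um Cap base radius, um.
#' @param mechanics Either a [plr_params()] (used directly as E1/alpha/eta)
#'   or a list `list(ym_kpa =, alpha =, eta =)` interpreted as a target
#'   apparent Young's modulus (converted internally to E1).
#' @param tilt_nm_per_um Length-2 plane slope (x, y) added to the surface.
#' @param probe,spring_constant,noise_nN,trigger_nN,rate_hz,speed_nm_s,ramp_nm
#'   Acquisition parameters (see [curve_spec()]); maps default to a 10 kHz
#'   sampling rate to keep memory bounded.
#' @param bec A [bec_model()] used in generation over cell pixels.
#' @param seed RNG seed (per-pixel noise seeds are derived from it).
#' @param label Condition label stored with the map.
#' @return An object of class `fv_map`: fields `curves` (row-major list),
#'   `nrow`, `ncol`, `pixel_um`, `probe`, `spring_constant`, `label`, and
#'   `truth` (height map um, thickness map, mechanics, seed).
#' @export
simulate_cell_map <- function(grid = 16, fov_um = 40, apex_um = 4,
                              base_radius_um = 12,
                              mechanics = list(ym_kpa = 3, alpha = 0.2, eta = 0),
                              tilt_nm_per_um = c(0, 0), probe = indenter(),
                              spring_constant = 0.1, noise_nN = 0.02,
                              trigger_nN = 0.5, rate_hz = 10000,
                              speed_nm_s = 183000, ramp_nm = 3000,
                              bec = bec_model(), seed = NULL, label = NA) {
  if (grid < 8) abort_domain("grid must be at least 8 x 8")
  if (apex_um > 0 && 2 * base_radius_um > fov_um * sqrt(2))
    abort_domain("cap does not fit in the field of view")
  if (inherits(mechanics, "plr_params")) {
    pars <- mechanics
    ym_target <- NA_real_
  } else {
    pars <- plr_from_apparent_ym(mechanics$ym_kpa * 1000, mechanics$alpha,
                                 if (is.null(mechanics$eta)) 0 else mechanics$eta,
                                 probe, trigger_nN, speed_nm_s)
    ym_target <- mechanics$ym_kpa * 1000
  }
  px <- fov_um / grid
  ax <- (seq_len(grid) - (grid + 1) / 2) * px # pixel centres, um
  thick <- matrix(0, grid, grid)
  if (apex_um > 0) {
    Rs <- (base_radius_um^2 + apex_um^2) / (2 * apex_um)
    for (r in seq_len(grid)) for (cc in seq_len(grid)) {
      rad2 <- ax[r]^2 + ax[cc]^2
      if (rad2 < base_radius_um^2)
        thick[r, cc] <- sqrt(Rs^2 - rad2) - (Rs - apex_um)
    }
  }
  surf_um <- thick + outer(ax, rep(1, grid)) * tilt_nm_per_um[1] / 1000 +
    outer(rep(1, grid), ax) * tilt_nm_per_um[2] / 1000
  z_ref <- 0 # substrate contact reference (absolute piezo position)
  seeds <- with_seed(seed, sample.int(2^31 - 2, grid * grid))
  curves <- vector("list", grid * grid)
  for (r in seq_len(grid)) for (cc in seq_len(grid)) {
    i <- (r - 1) * grid + cc
    h_nm <- thick[r, cc] * 1000
    z0 <- z_ref - surf_um[r, cc] * 1000
    sp <- curve_spec(params = pars, probe = probe, thickness_nm = Inf,
                     bec = bec, ramp_nm = ramp_nm, speed_nm_s = speed_nm_s,
                     rate_hz = rate_hz, z_start_nm = z0 - 0.8 * ramp_nm,
                     contact_z_nm = z0, spring_constant = spring_constant,
                     trigger_nN = trigger_nN, noise_nN = noise_nN,
                     seed = seeds[i])
    if (h_nm < 25) {
      curves[[i]] <- simulate_rigid_curve(sp)
    } else {
      sp$thickness_nm <- h_nm
      curves[[i]] <- simulate_curve(sp)
    }
  }
  structure(list(curves = curves, nrow = grid, ncol = grid,
                 pixel_um = px, fov_um = fov_um, probe = probe,
                 spring_constant = spring_constant, label = label,
                 truth = list(height_um = surf_um, thickness_um = thick,
                              mask = thick > 0, params = pars,
                              ym_app_pa = ym_target, apex_um = apex_um,
                              tilt_nm_per_um = tilt_nm_per_um, seed = seed)),
            class = "fv_map")
}

#' @export
print.fv_map <- function(x, ...) {
  cat(sprintf("<fv_map> %d x %d pixels, %.3g x %.3g um, label: %s\n",
              x$nrow, x$ncol, x$fov_um, x$fov_um, as.character(x$label)))
  invisible(x)
}

#' Cohort preset: per-cell parameter distributions for one condition
#'
#' Apparent Young's modulus is drawn from a lognormal matched to the given
#' mean/sd; the power-law exponent from a truncated normal on
#' `[0.02, 0.8]`; apex height from a lognormal with median `apex_um` and
#' log-sd `apex_sdlog`.
#'
#' @param label Condition label.
#' @param ym_mean_kpa,ym_sd_kpa Mean and SD of the apparent YM (kPa).
#' @param alpha_mean,alpha_sd Power-law exponent distribution.
#' @param apex_um Median apex height (um).
#' @param apex_sdlog Log-scale SD of apex height.
#' @param cells Cells per group.
#' @param grid,fov_um,base_radius_um Map geometry per cell.
#' @return An object of class `cohort_preset`.
#' @export
cohort_preset <- function(label, ym_mean_kpa, ym_sd_kpa, alpha_mean = 0.2,
                          alpha_sd = 0.05, apex_um = 4, apex_sdlog = 0.08,
                          cells = 20, grid = 16, fov_um = 40,
                          base_radius_um = 12) {
  if (ym_mean_kpa <= 0 || ym_sd_kpa < 0) abort_domain("bad modulus preset")
  structure(as.list(environment()), class = "cohort_preset")
}

# lognormal parameters matched to arithmetic mean/sd
.lnorm_match <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

.draw_cell <- function(preset) {
  ln <- .lnorm_match(preset$ym_mean_kpa, preset$ym_sd_kpa)
  ym <- rlnorm(1, ln$meanlog, ln$sdlog)
  repeat {
    a <- rnorm(1, preset$alpha_mean, preset$alpha_sd)
    if (a >= 0.02 && a <= 0.8) break
  }
  apex <- rlnorm(1, log(preset$apex_um), preset$apex_sdlog)
  list(ym_kpa = ym, alpha = a, apex_um = apex)
}

#' Load the versioned cohort presets
#'
#' Reads `inst/extdata/cohort_presets.yaml`, which records, per condition,
#' which numbers are study-derived and which are declared assumptions.
#'
#' @param path Path to a presets YAML file (default: the packaged file).
#' @return Named list of [cohort_preset()] objects.
#' @export
load_cohort_presets <- function(path = system.file("extdata",
                                                   "cohort_presets.yaml",
                                                   package = "afmcell")) {
  if (!nzchar(path) || !file.exists(path))
    abort_config(sprintf("preset file not found: '%s'", path))
  raw <- yaml::read_yaml(path)
  lapply(raw$presets, function(p)
    cohort_preset(label = p$label, ym_mean_kpa = p$ym_mean_kpa,
                  ym_sd_kpa = p$ym_sd_kpa, alpha_mean = p$alpha_mean,
                  alpha_sd = p$alpha_sd, apex_um = p$apex_um,
                  apex_sdlog = p$apex_sdlog,
                  cells = if (is.null(p$cells)) 20 else p$cells))
}

#' Simulate a two-condition cohort of phantom cells
#'
#' Draws independent cells from a control and an activated preset and
#' simulates one force-volume map per cell. Full provenance (seed and
#' per-cell draws) is attached.
#'
#' @param control,activated [cohort_preset()] objects.
#' @param seed RNG seed.
#' @param rate_hz Per-curve sampling rate passed to [simulate_cell_map()].
#' @param noise_nN Force noise RMS.
#' @return List of [simulate_cell_map()] results (class `fv_cohort`), with
#'   attribute `draws` (per-cell ground truth data.frame).
#' @export
simulate_cohort <- function(control, activated, seed = 1, rate_hz = 10000,
                            noise_nN = 0.02) {
  stopifnot(inherits(control, "cohort_preset"),
            inherits(activated, "cohort_preset"))
  if (control$cells < 2 || activated$cells < 2)
    abort_domain("at least 2 cells per group are required")
  maps <- list()
  draws <- list()
  with_seed(seed, {
    k <- 0
    for (preset in list(control, activated)) {
      for (ci in seq_len(preset$cells)) {
        k <- k + 1
        d <- .draw_cell(preset)
        ms <- sample.int(2^31 - 2, 1)
        maps[[k]] <- simulate_cell_map(
          grid = preset$grid, fov_um = preset$fov_um, apex_um = d$apex_um,
          base_radius_um = preset$base_radius_um,
          mechanics = list(ym_kpa = d$ym_kpa, alpha = d$alpha, eta = 0),
          rate_hz = rate_hz, noise_nN = noise_nN, seed = ms,
          label = preset$label)
        draws[[k]] <- data.frame(cell = k, label = preset$label,
                                 ym_kpa = d$ym_kpa, alpha = d$alpha,
                                 apex_um = d$apex_um, seed = ms)
      }
    }
  })
  structure(maps, class = "fv_cohort", draws = do.call(rbind, draws),
            seed = seed)
}

# ---- assay generators --------------------------------------------------------

#' Simulate a chemiluminescence/fluorescence kinetics trace
#'
#' A log-normal-shaped burst starting at the activator-addition time on a
#' flat baseline, with seeded Gaussian noise. The analytic area of the
#' noiseless burst up to any end time is available in closed form (attribute
#' `truth$auc(t_end)`).
#'
#' @param duration_s,dt_s Trace length and sampling step.
#' @param t_act_s Activator-addition time (within the trace).
#' @param peak_time_s Time of the burst maximum after activation.
#' @param amplitude Peak height above baseline (>= 0).
#' @param width Log-scale width of the burst (dimensionless).
#' @param baseline Constant pre-activation signal.
#' @param noise_sd Additive noise SD.
#' @param seed RNG seed.
#' @return A data.frame (`time_s`, `signal`) of class `kinetics_trace` with
#'   attributes `t_act_s` and `truth` (closed-form AUC function and
#'   parameters).
#' @export
simulate_kinetics_trace <- function(duration_s = 3600, dt_s = 10,
                                    t_act_s = 300, peak_time_s = 900,
                                    amplitude = 1000, width = 0.6,
                                    baseline = 50, noise_sd = 0,
                                    seed = NULL) {
  if (amplitude < 0) abort_domain("amplitude must be >= 0")
  if (t_act_s >= duration_s) abort_domain("activator time beyond trace end")
  if (peak_time_s + t_act_s >= duration_s)
    warning("burst peak lies beyond the trace end")
  tt <- seq(0, duration_s, by = dt_s)
  shape <- function(x) {
    out <- numeric(length(x))
    pos <- x > 0
    out[pos] <- exp(-(log(x[pos] / peak_time_s))^2 / (2 * width^2))
    out
  }
  sig <- baseline + amplitude * shape(tt - t_act_s)
  sig <- sig + with_seed(seed, rnorm(length(tt), 0, noise_sd))
  # closed form: int_0^T A exp(-(ln(x/tp))^2 / 2w^2) dx
  #            = A tp w sqrt(2 pi) e^{w^2/2} Phi((ln(T/tp) - w^2)/w)
  auc_fun <- function(t_end) {
    Te <- t_end - t_act_s
    if (Te <= 0) return(0)
    amplitude * peak_time_s * width * sqrt(2 * pi) * exp(width^2 / 2) *
      pnorm((log(Te / peak_time_s) - width^2) / width)
  }
  out <- data.frame(time_s = tt, signal = sig)
  class(out) <- c("kinetics_trace", "data.frame")
  attr(out, "t_act_s") <- t_act_s
  attr(out, "truth") <- list(auc = auc_fun, amplitude = amplitude,
                             peak_time_s = peak_time_s, width = width,
                             baseline = baseline, seed = seed)
  out
}

#' Simulate a flow-cytometry intensity sample
#'
#' Two-component log-normal mixture: a negative (non-phagocytic) and a
#' positive (phagocytic) mode. Modes closer than 0.1 log10-decade trigger a
#' warning flag in the truth record.
#'
#' @param n_events Number of events (>= 100).
#' @param negative_mfi,positive_mfi Median intensities of the two modes.
#' @param positive_fraction Fraction of events in the positive mode, in
#'   \[0, 1\].
#' @param sdlog Log-scale SD of each mode.
#' @param seed RNG seed.
#' @return Numeric vector of intensities (class `cytometry_sample`) with
#'   attribute `truth` (fractions, modes, component labels, overlap flag).
#' @export
simulate_cytometry_sample <- function(n_events = 10000, negative_mfi = 100,
                                      positive_mfi = 3000,
                                      positive_fraction = 0.5, sdlog = 0.25,
                                      seed = NULL) {
  if (n_events < 100) abort_domain("n_events must be >= 100")
  if (positive_fraction < 0 || positive_fraction > 1)
    abort_domain("positive_fraction must lie in [0, 1]")
  overlap <- log10(positive_mfi / negative_mfi) < 0.1
  if (overlap) warning("positive and negative modes closer than 0.1 decade")
  out <- with_seed(seed, {
    pos <- runif(n_events) < positive_fraction
    x <- numeric(n_events)
    x[pos] <- rlnorm(sum(pos), log(positive_mfi), sdlog)
    x[!pos] <- rlnorm(sum(!pos), log(negative_mfi), sdlog)
    list(x = x, pos = pos)
  })
  structure(out$x, class = "cytometry_sample",
            truth = list(positive = out$pos,
                         positive_fraction = positive_fraction,
                         negative_mfi = negative_mfi,
                         positive_mfi = positive_mfi,
                         overlap_warning = overlap, seed = seed))
}
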