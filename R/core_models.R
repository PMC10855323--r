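# Closed-form contact mechanics and rheology: spherical Hertz force,
# power-law relaxation modulus, bottom-effect correction factor.

#' Spherical indenter description
#'
#' @param radius_nm Tip radius R in nm. The probes used for live-cell
#'   nanomechanics (pre-calibrated short paddle cantilevers) have a nominal
#'   tip radius around 70 nm, which is the default; override per dataset.
#' @param poisson_nu Poisson's ratio of the sample (dimensionless). Cells are
#'   conventionally treated as incompressible, `nu = 0.5`.
#' @return An object of class `indenter`.
#' @export
indenter <- function(radius_nm = 70, poisson_nu = 0.5) {
  if (!is.numeric(radius_nm) || length(radius_nm) != 1 || radius_nm <= 0)
    abort_domain("indenter radius must be a single positive number (nm)")
  if (!is.numeric(poisson_nu) || poisson_nu < 0 || poisson_nu > 0.5 + 1e-9)
    abort_domain("poisson_nu must lie in [0, 0.5]")
  structure(list(radius_nm = radius_nm, poisson_nu = poisson_nu),
            class = "indenter")
}

#' Power-law rheology parameters
#'
#' The relaxation modulus is `E(t) = E1 * t^-alpha` plus a Newtonian viscous
#' term `eta * delta_D(t)` (Dirac delta); the Dirac term is represented by
#' `eta` and handled inside the Ting solver, not in pointwise evaluation.
#'
#' @param E1 Relaxation modulus at t = 1 s, in Pa (scale factor). Must be > 0.
#' @param alpha Power-law exponent in \[0, 1\]: 0 is solid-like (no
#'   relaxation), 1 is fluid-like.
#' @param eta Newtonian viscosity in Pa*s, >= 0.
#' @return An object of class `plr_params`.
#' @export
plr_params <- function(E1, alpha = 0, eta = 0) {
  if (!is.numeric(E1) || length(E1) != 1 || E1 <= 0)
    abort_domain("E1 must be a single positive modulus (Pa)")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    abort_domain("alpha must lie in [0, 1]")
  if (!is.numeric(eta) || eta < 0)
    abort_domain("eta must be >= 0 (Pa*s)")
  structure(list(E1 = E1, alpha = alpha, eta = eta), class = "plr_params")
}

# Bonded spherical-indenter correction series in chi = sqrt(R*delta)/h,
# incompressible (nu = 0.5) bonded-sample coefficients (Dimitriadis-type).
.bec_bonded_coef <- c(1.133, 1.497, 1.469, 0.755)

#' Bottom-effect correction model
#'
#' Multiplicative correction to spherical contact forces accounting for the
#' finite thickness of a sample bonded to a rigid substrate. The
#' `"bonded_sphere_polynomial"` kind is a truncated series in
#' `chi = sqrt(R * delta) / h` with the incompressible bonded-sample
#' coefficients (1.133, 1.497, 1.469, 0.755); `"none"` is the semi-infinite
#' case (factor identically 1).
#'
#' @param kind `"bonded_sphere_polynomial"` or `"none"`.
#' @param coefficients Series coefficients for powers 1..k of chi.
#' @return An object of class `bec_model`.
#' @export
bec_model <- function(kind = c("bonded_sphere_polynomial", "none"),
                      coefficients = .bec_bonded_coef) {
  kind <- match.arg(kind)
  if (kind == "none") coefficients <- numeric(0)
  structure(list(kind = kind, coefficients = as.numeric(coefficients)),
            class = "bec_model")
}

#' Bottom-effect correction factor
#'
#' @param delta Indentation depth(s), nm (>= 0).
#' @param thickness Local sample thickness h, nm (> 0; `Inf` allowed).
#' @param indenter An [indenter()].
#' @param bec A [bec_model()].
#' @return Dimensionless factor(s) >= 1; identically 1 for `kind = "none"`
#'   and in the semi-infinite limit.
#' @export
bec_factor <- function(delta, thickness, indenter = afmcell::indenter(),
                       bec = bec_model()) {
  if (any(delta < 0)) abort_domain("delta must be >= 0")
  if (any(thickness <= 0)) abort_domain("thickness must be > 0")
  if (any(is.finite(thickness) & delta >= thickness))
    abort_domain("delta >= thickness: full penetration of the sample")
  if (bec$kind == "none" || length(bec$coefficients) == 0)
    return(rep(1, length(delta)))
  chi <- sqrt(indenter$radius_nm * delta) / thickness
  f <- rep(1, length(delta))
  p <- rep(1, length(delta))
  for (ci in bec$coefficients) {
    p <- p * chi
    f <- f + ci * p
  }
  f
}

# Geometric prefactor C such that F[nN] = C * E[Pa] * delta[nm]^{3/2};
# the 1e-9 converts Pa*nm^2 to nN.
hertz_prefactor <- function(indenter) {
  4 * sqrt(indenter$radius_nm) / (3 * (1 - indenter$poisson_nu^2)) * 1e-9
}

#' Hertz force for a spherical indenter
#'
#' `F = 4 sqrt(R) / (3 (1 - nu^2)) * fBEC(delta) * E * delta^{3/2}`, with the
#' bottom-effect correction factor `fBEC` for finite sample thickness.
#'
#' @param delta Indentation depth(s), nm (>= 0).
#' @param E Elastic modulus, Pa (> 0).
#' @param indenter An [indenter()].
#' @param thickness Sample thickness, nm (default `Inf`, semi-infinite).
#' @param bec A [bec_model()]; ignored when `thickness` is infinite.
#' @return Force(s) in nN; strictly increasing in `delta`, linear in `E`.
#' @examples
#' hertz_force(100, 2800, indenter(radius_nm = 5000)) # ~0.352 nN
#' @export
hertz_force <- function(delta, E, indenter = afmcell::indenter(),
                        thickness = Inf, bec = bec_model("none")) {
  if (any(delta < 0)) abort_domain("delta must be >= 0")
  if (!is.numeric(E) || any(E <= 0)) abort_domain("E must be > 0")
  if (any(thickness <= 0)) abort_domain("thickness must be > 0")
  f <- bec_factor(delta, thickness, indenter, bec)
  hertz_prefactor(indenter) * f * E * delta^1.5
}

#' Power-law relaxation modulus
#'
#' Pointwise `E(t) = E1 * t^-alpha`. The Dirac viscous term is excluded from
#' pointwise evaluation and handled inside the Ting solver.
#'
#' @param t Time(s) in s, > 0.
#' @param params A [plr_params()].
#' @return Modulus in Pa; constant for `alpha = 0`, `E1 / t` at `alpha = 1`.
#' @export
relaxation_modulus <- function(t, params) {
  if (any(t <= 0)) abort_domain("t must be > 0")
  params$E1 * t^(-params$alpha)
}
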