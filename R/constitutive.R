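# Material laws for the ring model. Units: tissue stresses kPa, Nitinol MPa,
# strains and stretches dimensionless. Pressures are converted from mmHg to kPa
# once, at the module boundary (see mmhg_to_kpa).

#' Yeoh hyperelastic parameters
#'
#' Container for the three coefficients of the cubic reduced-polynomial
#' (Yeoh) strain-energy function
#' \deqn{W = c_{10}(\bar I_1 - 3) + c_{20}(\bar I_1 - 3)^2 + c_{30}(\bar I_1 - 3)^3}
#' used for the (incompressible, isotropic) dissected aortic wall.
#'
#' @param c10,c20,c30 Material coefficients in kPa. `c10` must be positive
#'   (it sets the small-strain shear modulus, `mu0 = 2*c10`); `c20` and `c30`
#'   must be finite.
#' @return An object of class `yeoh_params`.
#' @examples
#' yeoh_params(17.5, 58.9, 116.1)
#' @export
yeoh_params <- function(c10, c20, c30) {
  stopifnot(is.numeric(c10), is.numeric(c20), is.numeric(c30),
            length(c10) == 1L, length(c20) == 1L, length(c30) == 1L)
  if (!is.finite(c10) || c10 <= 0)
    stop("c10 must be finite and > 0 (got ", c10, ")")
  if (!is.finite(c20) || !is.finite(c30))
    stop("c20 and c30 must be finite")
  structure(list(c10 = c10, c20 = c20, c30 = c30), class = "yeoh_params")
}

#' @export
print.yeoh_params <- function(x, ...) {
  cat(sprintf("Yeoh parameters: c10 = %.4g, c20 = %.4g, c30 = %.4g kPa\n",
              x$c10, x$c20, x$c30))
  invisible(x)
}

#' Yeoh strain-energy density
#'
#' @param I1bar First deviatoric strain invariant (>= 3). May be a vector.
#' @param params A [yeoh_params()] object.
#' @return Strain-energy density in kPa; zero at the undeformed state
#'   (`I1bar = 3`).
#' @export
yeoh_energy <- function(I1bar, params) {
  stopifnot(inherits(params, "yeoh_params"))
  if (any(I1bar < 3 - 1e-12))
    stop("I1bar must be >= 3 (undeformed state has I1bar = 3)")
  x <- pmax(I1bar - 3, 0)
  params$c10 * x + params$c20 * x^2 + params$c30 * x^3
}

# dW/dI1 at a given I1 (kPa)
yeoh_dW <- function(I1, params) {
  x <- I1 - 3
  params$c10 + 2 * params$c20 * x + 3 * params$c30 * x^2
}

#' Uniaxial Cauchy stress for an incompressible Yeoh material
#'
#' Uniaxial-tension specialization: with axial stretch `lam` the lateral
#' stretches are `1/sqrt(lam)`, so `I1 = lam^2 + 2/lam` and
#' \deqn{\sigma = 2(\lambda^2 - \lambda^{-1})\, \partial W/\partial I_1.}
#'
#' @param lam Axial stretch (> 0). May be a vector.
#' @param params A [yeoh_params()] object.
#' @return Cauchy stress in kPa; zero at `lam = 1`.
#' @examples
#' yeoh_uniaxial_cauchy(1.2, yeoh_params(17.5, 58.9, 116.1))
#' @export
yeoh_uniaxial_cauchy <- function(lam, params) {
  stopifnot(inherits(params, "yeoh_params"))
  if (any(lam <= 0)) stop("stretch must be > 0")
  I1 <- lam^2 + 2 / lam
  2 * (lam^2 - 1 / lam) * yeoh_dW(I1, params)
}

#' Hoop Cauchy stress of a thin incompressible ring (plane strain)
#'
#' Membrane-ring kinematics: circumferential stretch `lam_theta`, fixed axial
#' stretch 1, radial stretch `1/lam_theta` by incompressibility, so
#' `I1 = lam_theta^2 + 1 + lam_theta^-2` and
#' \deqn{\sigma_\theta = 2(\lambda_\theta^2 - \lambda_\theta^{-2})\,
#'   \partial W/\partial I_1.}
#' The small-strain slope is `8*c10` per unit `(lam_theta - 1)`.
#'
#' @inheritParams yeoh_uniaxial_cauchy
#' @param lam_theta Circumferential stretch (> 0). May be a vector.
#' @return Hoop Cauchy stress in kPa.
#' @export
yeoh_ring_hoop_cauchy <- function(lam_theta, params) {
  stopifnot(inherits(params, "yeoh_params"))
  if (any(lam_theta <= 0)) stop("stretch must be > 0")
  I1 <- lam_theta^2 + 1 + lam_theta^-2
  2 * (lam_theta^2 - lam_theta^-2) * yeoh_dW(I1, params)
}

#' Linear-elastic parameters (intimal flap)
#'
#' @param E Young's modulus in kPa (> 0). Default 277 kPa, the literature
#'   value for the dissected intimal flap.
#' @param nu Poisson's ratio, in (-1, 0.5). Default 0.49 (near-incompressible).
#'   Carried for completeness; the 1D ring model uses only `E`.
#' @return An object of class `linear_elastic_params`.
#' @export
linear_elastic_params <- function(E = 277, nu = 0.49) {
  if (!is.finite(E) || E <= 0) stop("E must be finite and > 0")
  if (!is.finite(nu) || nu <= -1 || nu >= 0.5)
    stop("nu must lie in (-1, 0.5)")
  structure(list(E = E, nu = nu), class = "linear_elastic_params")
}

#' 1D linear-elastic stress
#'
#' @param eps Strain (any sign). May be a vector.
#' @param params A [linear_elastic_params()] object.
#' @return Stress `E * eps` in kPa.
#' @export
linear_stress <- function(eps, params) {
  stopifnot(inherits(params, "linear_elastic_params"))
  params$E * eps
}

#' Superelastic Nitinol parameters
#'
#' Constants of the flag-shaped 1D superelastic model of the stent wire:
#' austenite/martensite elastic moduli and Poisson ratios, the transformation
#' strain, and the four plateau stresses (forward transformation start/end on
#' loading, reverse start/end on unloading). The compressive onset
#' `sigma_CLs` is stored and validated but unused: the ring model loads the
#' wire in tension only. Temperature and density are metadata (the model is
#' quasi-static and isothermal).
#'
#' Defaults are the standard Nitinol constants used for self-expanding
#' stent-graft wire.
#'
#' @param E_A,E_M Austenite / martensite elastic moduli (MPa, > 0).
#' @param nu_A,nu_M Poisson's ratios (unused in 1D; validated).
#' @param eps_L Transformation strain, in (0, 1).
#' @param sigma_Ls,sigma_LE Forward (loading) plateau start / end stresses
#'   (MPa), `sigma_Ls < sigma_LE`.
#' @param sigma_Us,sigma_UE Reverse (unloading) plateau start / end stresses
#'   (MPa), `sigma_UE < sigma_Us < sigma_Ls`.
#' @param sigma_CLs Compressive transformation onset (MPa, metadata).
#' @param T_ref Reference temperature (deg C, metadata).
#' @param rho Density (g/cm^3, metadata).
#' @return An object of class `nitinol_params`.
#' @export
nitinol_params <- function(E_A = 51700, nu_A = 0.3,
                           E_M = 47800, nu_M = 0.3,
                           eps_L = 0.063,
                           sigma_Ls = 600, sigma_LE = 670,
                           sigma_Us = 288, sigma_UE = 254,
                           sigma_CLs = 900,
                           T_ref = 37, rho = 6.5) {
  if (E_A <= 0 || E_M <= 0) stop("elastic moduli must be > 0")
  if (!(eps_L > 0 && eps_L < 1)) stop("eps_L must lie in (0, 1)")
  if (!(sigma_Ls < sigma_LE))
    stop("forward plateau requires sigma_Ls < sigma_LE")
  if (!(sigma_UE < sigma_Us && sigma_Us < sigma_Ls))
    stop("plateaus require sigma_UE < sigma_Us < sigma_Ls")
  structure(list(E_A = E_A, nu_A = nu_A, E_M = E_M, nu_M = nu_M,
                 eps_L = eps_L,
                 sigma_Ls = sigma_Ls, sigma_LE = sigma_LE,
                 sigma_Us = sigma_Us, sigma_UE = sigma_UE,
                 sigma_CLs = sigma_CLs, T_ref = T_ref, rho = rho),
            class = "nitinol_params")
}

#' @export
print.nitinol_params <- function(x, ...) {
  cat(sprintf(paste0(
    "Superelastic Nitinol: E_A = %g, E_M = %g MPa, eps_L = %g\n",
    "  loading plateau %g -> %g MPa, unloading plateau %g -> %g MPa\n"),
    x$E_A, x$E_M, x$eps_L, x$sigma_Ls, x$sigma_LE, x$sigma_Us, x$sigma_UE))
  invisible(x)
}

#' Superelastic wire state
#'
#' History-dependent 1D state of a Nitinol wire: total strain, stress (MPa),
#' martensite volume fraction `xi` in \[0, 1\] and a branch flag.
#'
#' @param strain Total strain.
#' @param stress Stress, MPa.
#' @param xi Martensite fraction in \[0, 1\].
#' @param branch One of `"elastic-austenite"`, `"forward-transforming"`,
#'   `"elastic-mixture"`, `"reverse-transforming"`, `"elastic-martensite"`.
#' @return An object of class `nitinol_state`.
#' @export
nitinol_state <- function(strain = 0, stress = 0, xi = 0,
                          branch = "elastic-austenite") {
  branches <- c("elastic-austenite", "forward-transforming",
                "elastic-mixture", "reverse-transforming",
                "elastic-martensite")
  branch <- match.arg(branch, branches)
  if (!is.finite(xi) || xi < 0 || xi > 1)
    stop("invalid state: martensite fraction xi must lie in [0, 1]")
  structure(list(strain = strain, stress = stress, xi = xi, branch = branch),
            class = "nitinol_state")
}

#' @export
print.nitinol_state <- function(x, ...) {
  cat(sprintf("Nitinol state: eps = %.5g, sigma = %.5g MPa, xi = %.4f (%s)\n",
              x$strain, x$stress, x$xi, x$branch))
  invisible(x)
}

# Voigt-style mixture modulus (MPa)
nitinol_modulus <- function(xi, params) {
  params$E_A + xi * (params$E_M - params$E_A)
}

# plateau stresses as linear functions of xi (MPa)
nitinol_sigma_fwd <- function(xi, params)
  params$sigma_Ls + xi * (params$sigma_LE - params$sigma_Ls)
nitinol_sigma_rev <- function(xi, params)
  params$sigma_UE + xi * (params$sigma_Us - params$sigma_UE)

# Solve xi in [0,1] such that on a plateau (sig0 + xi*dsig stress law)
#   eps = sigma(xi)/E(xi) + xi*eps_L.
# Quadratic in xi; closed form with a uniroot fallback. Returns NA when the
# target strain lies outside the plateau's strain range.
nitinol_solve_xi <- function(eps, sig0, dsig, params) {
  eA <- params$E_A; dE <- params$E_M - params$E_A; eL <- params$eps_L
  f <- function(xi) (sig0 + xi * dsig) / (eA + xi * dE) + xi * eL - eps
  if (f(0) > 1e-14 || f(1) < -1e-14) return(NA_real_)
  # (eps - xi*eL)(eA + xi*dE) = sig0 + xi*dsig
  a <- -eL * dE
  b <- eps * dE - eL * eA - dsig
  c0 <- eps * eA - sig0
  disc <- b^2 - 4 * a * c0
  xi <- NA_real_
  if (abs(a) > 1e-12 && disc >= 0) {
    roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
    ok <- roots[roots >= -1e-10 & roots <= 1 + 1e-10]
    if (length(ok)) xi <- min(max(ok[1], 0), 1)
  }
  if (is.na(xi) || abs(f(xi)) > 1e-9) {
    xi <- stats::uniroot(f, c(0, 1), tol = 1e-14)$root
  }
  xi
}

#' Advance the superelastic wire state by a strain increment
#'
#' Strain-controlled incremental driver of the flag-shaped 1D superelastic
#' law. On loading the response is elastic in austenite up to the forward
#' plateau onset, transforms along the (linearly hardening) forward plateau
#' with the martensite fraction rising 0 to 1 and inelastic strain
#' `xi * eps_L`, and is elastic in martensite beyond. On unloading it is
#' elastic down to the reverse plateau, recovers the transformation strain
#' along the reverse plateau, and returns to austenite with full strain
#' recovery at zero stress. Within any branch the total strain decomposes as
#' `strain = stress/E(xi) + xi*eps_L` with the linear mixture modulus
#' `E(xi) = E_A + xi*(E_M - E_A)`.
#'
#' The step is resolved from the final strain alone within each regime, so
#' sub-stepping an increment does not change the result (path independence on
#' monotone segments).
#'
#' @param state A [nitinol_state()].
#' @param d_eps Strain increment (signed; small relative to the plateau
#'   width for a faithful incremental history).
#' @param params A [nitinol_params()].
#' @return The updated [nitinol_state()].
#' @examples
#' s <- nitinol_step(nitinol_state(), 0.005, nitinol_params())
#' s$stress  # 0.005 * 51700 = 258.5 MPa, still austenite
#' @export
nitinol_step <- function(state, d_eps, params) {
  stopifnot(inherits(state, "nitinol_state"), inherits(params, "nitinol_params"))
  if (!is.finite(state$xi) || state$xi < 0 || state$xi > 1)
    stop("invalid state: martensite fraction xi must lie in [0, 1]")
  eps <- state$strain + d_eps
  if (eps < -1e-12)
    stop("compressive total strain is outside the tensile-only wire model")
  xi <- state$xi
  eL <- params$eps_L
  sig_trial <- nitinol_modulus(xi, params) * (eps - xi * eL)

  fwd_lo <- nitinol_sigma_fwd(xi, params)   # forward plateau at current xi
  rev_hi <- nitinol_sigma_rev(xi, params)   # reverse plateau at current xi

  if (sig_trial > fwd_lo + 1e-12 && xi < 1) {
    # forward transformation (or completion into elastic martensite)
    xin <- nitinol_solve_xi(eps, params$sigma_Ls,
                            params$sigma_LE - params$sigma_Ls, params)
    if (is.na(xin)) { # beyond end of transformation
      xin <- 1
      sig <- params$E_M * (eps - eL)
      branch <- "elastic-martensite"
    } else {
      sig <- nitinol_sigma_fwd(xin, params)
      branch <- "forward-transforming"
    }
    return(nitinol_state(eps, sig, xin, branch))
  }
  if (sig_trial < rev_hi - 1e-12 && xi > 0) {
    # reverse transformation (or completion into elastic austenite)
    xin <- nitinol_solve_xi(eps, params$sigma_UE,
                            params$sigma_Us - params$sigma_UE, params)
    if (is.na(xin)) { # fully reverted
      xin <- 0
      sig <- params$E_A * eps
      branch <- "elastic-austenite"
    } else {
      sig <- nitinol_sigma_rev(xin, params)
      branch <- "reverse-transforming"
    }
    return(nitinol_state(eps, sig, xin, branch))
  }
  branch <- if (xi <= 0) "elastic-austenite"
            else if (xi >= 1) "elastic-martensite"
            else "elastic-mixture"
  nitinol_state(eps, sig_trial, xi, branch)
}

#' Drive the wire state to a target strain
#'
#' Convenience wrapper around [nitinol_step()] that sub-steps the path from
#' the current strain to `eps_target` in increments of at most `d_eps_max`.
#'
#' @inheritParams nitinol_step
#' @param eps_target Final total strain (>= 0).
#' @param d_eps_max Maximum sub-step size.
#' @return The final [nitinol_state()].
#' @export
nitinol_drive <- function(state, eps_target, params, d_eps_max = 1e-4) {
  d <- eps_target - state$strain
  n <- max(1L, ceiling(abs(d) / d_eps_max))
  h <- d / n
  for (i in seq_len(n)) state <- nitinol_step(state, h, params)
  # kill accumulated floating-point drift in strain
  state$strain <- eps_target
  state
}

#' Strain at a prescribed stress (stress-controlled query)
#'
#' Root-finds the strain-controlled law: returns the strain at which driving
#' the given state monotonically reaches `sigma_target`.
#'
#' @inheritParams nitinol_step
#' @param sigma_target Target stress, MPa (on the loading direction from the
#'   current state).
#' @param eps_max Upper search bound for the strain.
#' @return Strain value.
#' @export
nitinol_strain_at_stress <- function(state, sigma_target, params,
                                     eps_max = 0.12) {
  f <- function(eps) nitinol_drive(state, eps, params)$stress - sigma_target
  lo <- state$strain
  if (f(lo) > 0) stop("target stress below current stress; query is monotone")
  stats::uniroot(f, c(lo, eps_max), tol = 1e-10)$root
}
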