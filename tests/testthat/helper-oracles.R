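# Independent oracles used across the suite.

# Central finite difference of the strain energy along the incompressible
# uniaxial path: sigma = lam * dW/dlam with I1(lam) = lam^2 + 2/lam.
fd_uniaxial_stress <- function(lam, params, h = 1e-6) {
  W <- function(l) yeoh_energy(l^2 + 2 / l, params)
  lam * (W(lam + h) - W(lam - h)) / (2 * h)
}

# Same along the plane-strain ring path: I1(lam) = lam^2 + 1 + lam^-2.
fd_hoop_stress <- function(lam, params, h = 1e-6) {
  W <- function(l) yeoh_energy(l^2 + 1 + l^-2, params)
  lam * (W(lam + h) - W(lam - h)) / (2 * h)
}

# Analytic (polygonal) dissipation of one full superelastic cycle
# 0 -> eps_max (xi = 1) -> 0, treating the two plateaus as straight lines
# between their corner points in the strain-stress plane. MPa units.
nitinol_loop_area_analytic <- function(np, eps_max) {
  eLs <- np$sigma_Ls / np$E_A                    # forward plateau start
  eLE <- np$sigma_LE / np$E_M + np$eps_L         # forward plateau end
  eUs <- np$sigma_Us / np$E_M + np$eps_L         # reverse plateau start
  eUE <- np$sigma_UE / np$E_A                    # reverse plateau end
  stopifnot(eps_max >= eLE)
  sig_max <- np$E_M * (eps_max - np$eps_L)
  x <- c(0, eLs, eLE, eps_max, eUs, eUE, 0)
  y <- c(0, np$sigma_Ls, np$sigma_LE, sig_max, np$sigma_Us, np$sigma_UE, 0)
  n <- length(x); i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y) / 2)
}

# Trapezoidal loop area traced by the incremental model itself.
nitinol_loop_area_model <- function(np, eps_max, d_eps = 1e-4) {
  eps_path <- c(seq(0, eps_max, by = d_eps), seq(eps_max, 0, by = -d_eps))
  s <- nitinol_state()
  sig <- numeric(length(eps_path))
  for (i in seq_along(eps_path)) {
    s <- nitinol_step(s, eps_path[i] - s$strain, np)
    sig[i] <- s$stress
  }
  # signed area of the closed strain-stress loop
  abs(sum(diff(eps_path) * (sig[-1] + sig[-length(sig)]) / 2))
}

# Random rigid-body transform of an n x 3 point set.
rigid_transform <- function(p, seed = 1) {
  set.seed(seed)
  ang <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  t(R %*% t(p)) + matrix(stats::runif(3, -50, 50), nrow(p), 3, byrow = TRUE)
}

# Shared default-patient fixture, computed once per session on first use.
.fixture_env <- new.env(parent = emptyenv())
default_patient <- function() {
  if (!exists("fx", .fixture_env)) {
    vessel <- generate_vessel(seed = 1)
    ps <- prestress_fixed_point(vessel)
    sg <- stent_graft()
    deps <- lapply(c(A = "A", B = "B", C = "C"), function(v)
      deploy(sg, vessel, deployment_config(variant = v), prestress = ps))
    assign("fx", list(vessel = vessel, prestress = ps, sg = sg,
                      deployments = deps), .fixture_env)
  }
  get("fx", .fixture_env)
}
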