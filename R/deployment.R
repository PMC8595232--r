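# Crimp -> pre-dilation -> release -> load swap, as per-station radial
# equilibrium between the superelastic stent ring (with graft expansion cap),
# optional graft internal pressure, and the (optionally pre-stressed) vessel
# ring. Delivery kinematics reduce to direct placement of crimped rings at
# their landing stations: the ring model has no axial mechanics, so the
# delivery path cannot affect the radial equilibrium.

#' Stent-graft device specification
#'
#' Defaults describe a 28-28-150 mm self-expanding device: nine Z-stent
#' struts of superelastic Nitinol wire, a 0.1 mm fabric graft limiting
#' expansion to the nominal diameter, and a bare (uncovered) proximal stent.
#'
#' @param nominal_diameter Nominal (fully expanded) diameter, mm.
#' @param length Covered length, mm.
#' @param n_struts Number of strut rings (>= 1).
#' @param strut_apexes_per_end Apex points forming each strut-end crown.
#' @param wire [nitinol_params()] of the stent wire.
#' @param graft_thickness Fabric thickness, mm (metadata in the ring model).
#' @param bare_proximal Is the proximal stent bare (uncovered)?
#' @return An object of class `stent_graft` with strut-end labels
#'   `P1..P<n>` / `D1..D<n>`.
#' @export
stent_graft <- function(nominal_diameter = 28, length = 150, n_struts = 9,
                        strut_apexes_per_end = 5, wire = nitinol_params(),
                        graft_thickness = 0.1, bare_proximal = TRUE) {
  if (n_struts < 1) stop("n_struts must be >= 1")
  if (nominal_diameter <= 0) stop("nominal_diameter must be > 0")
  stopifnot(inherits(wire, "nitinol_params"))
  structure(list(nominal_diameter = nominal_diameter, length = length,
                 n_struts = n_struts,
                 strut_apexes_per_end = strut_apexes_per_end,
                 wire = wire, graft_thickness = graft_thickness,
                 bare_proximal = bare_proximal,
                 end_labels = c(paste0("P", 1:n_struts),
                                paste0("D", 1:n_struts))),
            class = "stent_graft")
}

#' @export
print.stent_graft <- function(x, ...) {
  cat(sprintf(paste0("Stent-graft: %g-%g-%g mm, %d struts%s, graft %g mm\n"),
              x$nominal_diameter, x$nominal_diameter, x$length, x$n_struts,
              if (x$bare_proximal) " (proximal bare stent)" else "",
              x$graft_thickness))
  invisible(x)
}

#' Deployment configuration
#'
#' @param variant Loading variant: `"A"` (no pre-stress, no graft pressure),
#'   `"B"` (pre-stress, no graft pressure), `"C"` (pre-stress and graft
#'   internal pressure).
#' @param lumen_pressure Diastolic pressure, mmHg.
#' @param crimp_diameter Crimped (sheathed) device diameter, mm.
#' @param sheath_diameter Initial sheath diameter, mm (metadata).
#' @param predilation_from,predilation_to Pre-dilation balloon diameters, mm.
#' @param landing_offset Arclength of the proximal device end on the
#'   centreline, mm.
#' @param kappa Ring-to-wire strain geometry factor: representative wire
#'   strain is `kappa * (R_nom - r) / R_nom`.
#' @param alpha Wire-stress-to-radial-pressure factor, kPa of outward
#'   pressure per MPa of wire stress.
#' @param cap_stiffness Graft cap penalty, kPa of inward pressure per mm of
#'   radius beyond nominal.
#' @return An object of class `deployment_config`.
#' @export
deployment_config <- function(variant = c("C", "A", "B"), lumen_pressure = 80,
                              crimp_diameter = 7, sheath_diameter = 29,
                              predilation_from = 6, predilation_to = 8,
                              landing_offset = 30,
                              kappa = 0.1, alpha = 0.05,
                              cap_stiffness = 1e4) {
  variant <- match.arg(variant)
  if (predilation_to <= predilation_from)
    stop("predilation_to must exceed predilation_from")
  structure(list(variant = variant, lumen_pressure = lumen_pressure,
                 crimp_diameter = crimp_diameter,
                 sheath_diameter = sheath_diameter,
                 predilation_from = predilation_from,
                 predilation_to = predilation_to,
                 landing_offset = landing_offset,
                 kappa = kappa, alpha = alpha,
                 cap_stiffness = cap_stiffness),
            class = "deployment_config")
}

# strut-end arclength positions: strut i spans [P_i, D_i]; the distal end of
# each strut sits 0.9 pitch beyond its proximal end so P/D ends interleave
strut_end_positions <- function(sg, config) {
  pitch <- sg$length / sg$n_struts
  p <- config$landing_offset + (seq_len(sg$n_struts) - 1) * pitch
  d <- p + 0.9 * pitch
  data.frame(label = c(paste0("P", seq_len(sg$n_struts)),
                       paste0("D", seq_len(sg$n_struts))),
             s = c(p, d), stringsAsFactors = FALSE)
}

# wire strain implied by a ring radius (crimping strain measure)
ring_wire_strain <- function(radius, sg, config) {
  Rn <- sg$nominal_diameter / 2
  eps <- config$kappa * (Rn - radius) / Rn
  if (any(eps > 0.11))
    stop("radius implies wire strain beyond the validity of the 1D model")
  pmax(eps, 0)
}

#' Radial pressure exerted by one stent ring (with graft cap)
#'
#' The ring's representative wire strain is
#' `eps = kappa * (R_nom - r)/R_nom`, driven through the history-dependent
#' superelastic law from the supplied state (crimping loads along the
#' forward plateau — radial resistive force; release unloads along the
#' reverse plateau — chronic outward force). Outward pressure is
#' `alpha * wire stress`; radii beyond nominal engage a steep linear graft
#' penalty (negative, inward pressure).
#'
#' @param radius Current ring radius, mm (> 0).
#' @param state [nitinol_state()] carrying the ring's loading history.
#' @param sg A [stent_graft()].
#' @param config A [deployment_config()].
#' @return List with `pressure` (kPa, outward positive) and the updated
#'   `state`.
#' @export
stent_radial_pressure <- function(radius, state, sg, config) {
  if (radius <= 0) stop("radius must be > 0")
  Rn <- sg$nominal_diameter / 2
  eps <- ring_wire_strain(radius, sg, config)
  state <- nitinol_drive(state, eps, sg$wire, d_eps_max = 2e-4)
  p <- config$alpha * state$stress
  if (radius > Rn) p <- p - config$cap_stiffness * (radius - Rn)
  list(pressure = p, state = state)
}

#' Pre-dilate the narrowed true lumen
#'
#' Every station whose lumen diameter is below the balloon target has its
#' reference radius raised to the target radius (the new reference
#' configuration for subsequent equilibrium); all other stations are
#' unchanged. No station radius ever decreases.
#'
#' @param vessel A `vessel_model`.
#' @param config A [deployment_config()].
#' @return The modified `vessel_model`.
#' @export
predilate <- function(vessel, config) {
  stopifnot(inherits(vessel, "vessel_model"))
  r_target <- config$predilation_to / 2
  vessel$stations$ct_radius <- pmax(vessel$stations$ct_radius, r_target)
  vessel
}

# wall resisting pressure at a strut-end station, as a function of ring
# radius r (mm); returns a function of r
make_wall_pressure <- function(station, sigma0, wall_params, variant) {
  lam_pre <- if (variant %in% c("B", "C"))
    prestretch_from_sigma0(sigma0, wall_params) else 1
  flap <- if (isTRUE(station$flap_present))
    list(thickness = station$flap_thickness, E = station$flap_E) else NULL
  r_ref <- station$ct_radius; h0 <- station$h0
  function(r) wall_ring_pressure(r / r_ref, r_ref, h0, wall_params,
                                 lam_pre = lam_pre, flap = flap,
                                 model = "prestretch")
}

# solve one strut end: contact equilibrium between released ring (+ graft
# pressure) and the wall; unilateral contact (separation allowed)
solve_strut_end <- function(station, sigma0, sg, config, crimped_state,
                            p_graft, wall_params) {
  Rn <- sg$nominal_diameter / 2
  P_wall <- make_wall_pressure(station, sigma0, wall_params, config$variant)
  p_stent <- function(r)
    stent_radial_pressure(r, crimped_state, sg, config)$pressure
  g <- function(r) p_stent(r) + p_graft - P_wall(r)

  r_lo <- config$crimp_diameter / 2 * 0.99
  r_hi <- Rn + 1.5
  # bracket: g is decreasing (stent unload curve falls with r, wall rises)
  if (g(r_lo) < 0)
    stop(sprintf("no deployment equilibrium at station s = %.1f mm (label %s)",
                 station$s, station$label))
  root <- stats::uniroot(g, c(r_lo, r_hi), tol = 1e-9)$root

  contact <- P_wall(root) > 1e-9   # implied contact pressure must push inward
  if (!contact) {
    # separated: stent+graft free-expand against the cap alone; the wall sits
    # at its own equilibrium under zero lumen pressure (shielded, gap)
    g_free <- function(r) p_stent(r) + p_graft -
      config$cap_stiffness * pmax(r - Rn, 0)
    root <- stats::uniroot(g_free, c(r_lo, r_hi), tol = 1e-9)$root
    f_wall <- function(r) P_wall(r)
    # wall recoil radius: P_wall = 0
    rw <- tryCatch(stats::uniroot(f_wall, c(0.2 * station$ct_radius,
                                            4 * station$ct_radius),
                                  tol = 1e-9)$root,
                   error = function(e) station$ct_radius)
    wall_radius <- max(rw, root)   # wall cannot recoil through the graft
    if (wall_radius <= root + 1e-9) contact <- TRUE
  } else {
    wall_radius <- root
  }
  released <- stent_radial_pressure(root, crimped_state, sg, config)
  list(radius = root, wall_radius = wall_radius, contact = contact,
       state = released$state,
       wall_stress_post = if (contact && wall_radius <= root + 1e-6)
         wall_hoop_at(station, sigma0, wall_params, config$variant, wall_radius)
       else wall_hoop_at(station, sigma0, wall_params, config$variant,
                         wall_radius))
}

# total wall hoop Cauchy stress when held at radius r
wall_hoop_at <- function(station, sigma0, wall_params, variant, r) {
  lam_pre <- if (variant %in% c("B", "C"))
    prestretch_from_sigma0(sigma0, wall_params) else 1
  yeoh_ring_hoop_cauchy(lam_pre * r / station$ct_radius, wall_params)
}

#' Deploy the stent-graft into the vessel
#'
#' Runs the full sequence for one loading variant: pre-stress recovery (B/C),
#' pre-dilation of the narrowed true lumen, per-end crimping of the stent
#' rings to the sheathed diameter (loading the wire along the forward
#' plateau), placement along the centreline from the landing offset, and
#' release into radial equilibrium `P_graft + P_stent(r) = P_wall(r)` at
#' each strut-end station. Variant A treats the vessel as stress-free at the
#' imaged geometry with no graft pressure; variant B applies the recovered
#' pre-stress with the lumen pressure removed; variant C additionally
#' pressurizes the graft interior at the diastolic pressure (the bare
#' proximal end P1 is not covered by fabric and receives no graft pressure).
#'
#' @param sg A [stent_graft()].
#' @param vessel A `vessel_model`.
#' @param config A [deployment_config()].
#' @param prestress Optional precomputed `prestress_result` for variants B/C
#'   (computed on the undilated vessel when omitted).
#' @return An object of class `deployment_result`: `ends` data frame (label,
#'   arclength, deployed radius, wall radius, contact flag, local open area,
#'   centre coordinates, wall hoop stress pre/post), `apex_points` (named
#'   list of matrices), `variant`, and the configs used.
#' @export
deploy <- function(sg, vessel, config = deployment_config(),
                   prestress = NULL) {
  stopifnot(inherits(sg, "stent_graft"), inherits(vessel, "vessel_model"),
            inherits(config, "deployment_config"))
  ends <- strut_end_positions(sg, config)
  st <- vessel$stations
  if (max(ends$s) > max(st$s))
    stop("device extends beyond the vessel centreline; reduce landing_offset")

  sigma0_field <- rep(0, nrow(st))
  if (config$variant %in% c("B", "C")) {
    if (is.null(prestress))
      prestress <- prestress_fixed_point(vessel, config$lumen_pressure)
    sigma0_field <- prestress$sigma0_field
  }
  vessel_d <- predilate(vessel, config)
  std <- vessel_d$stations

  # crimp once: virgin wire loaded to the sheathed diameter
  eps_crimp <- ring_wire_strain(config$crimp_diameter / 2, sg, config)
  crimped <- nitinol_drive(nitinol_state(), eps_crimp, sg$wire,
                           d_eps_max = 2e-4)

  p_graft_full <- if (config$variant == "C")
    mmhg_to_kpa(config$lumen_pressure) else 0

  rows <- vector("list", nrow(ends))
  apex <- vector("list", nrow(ends))
  for (i in seq_len(nrow(ends))) {
    j <- which.min(abs(std$s - ends$s[i]))
    station <- as.list(std[j, ])
    station$label <- ends$label[i]
    p_graft <- if (ends$label[i] == "P1" && sg$bare_proximal) 0 else p_graft_full
    sol <- solve_strut_end(station, sigma0_field[j], sg, config, crimped,
                           p_graft, vessel$wall_params)
    pre_sig <- if (config$variant %in% c("B", "C")) sigma0_field[j] else 0
    centre <- c(station$cx, station$cy, station$cz)
    tangent <- c(station$tx, station$ty, station$tz)
    pts <- circle_points(centre, tangent, sol$radius, sg$strut_apexes_per_end)
    apex[[i]] <- pts
    rows[[i]] <- data.frame(
      label = ends$label[i], s = ends$s[i], station_s = station$s,
      section = station$section,
      radius = sol$radius, wall_radius = sol$wall_radius,
      contact = sol$contact,
      loa = local_open_area(pts),
      cx = centre[1], cy = centre[2], cz = centre[3],
      wall_stress_pre = pre_sig, wall_stress_post = sol$wall_stress_post,
      stringsAsFactors = FALSE)
  }
  ends_df <- do.call(rbind, rows)
  names(apex) <- ends_df$label
  structure(list(ends = ends_df, apex_points = apex,
                 variant = config$variant, config = config,
                 sg = sg, prestress = prestress),
            class = "deployment_result")
}

#' @export
print.deployment_result <- function(x, ...) {
  cat(sprintf("Deployment result (model %s): %d strut ends\n",
              x$variant, nrow(x$ends)))
  agg <- stats::aggregate(cbind(radius, loa) ~ section, data = x$ends, FUN = mean)
  for (k in seq_len(nrow(agg)))
    cat(sprintf("  %-11s mean radius %6.2f mm, mean LOA %7.1f mm^2\n",
                agg$section[k], agg$radius[k], agg$loa[k]))
  invisible(x)
}

#' Per-section wall hoop-stress report
#'
#' Summarizes the wall hoop stress at the strut-end stations before and
#' after deployment per landing section (mean, 10th and 90th percentile) and
#' flags the direction of change.
#'
#' @param result A `deployment_result`.
#' @param vessel The `vessel_model` used (unmodified; retained for the
#'   zero-load identity check).
#' @return Data frame, one row per landing section.
#' @export
wall_stress_report <- function(result, vessel) {
  stopifnot(inherits(result, "deployment_result"))
  e <- result$ends
  out <- do.call(rbind, lapply(split(e, e$section), function(d) {
    data.frame(section = d$section[1], n_ends = nrow(d),
               pre_mean = mean(d$wall_stress_pre),
               post_mean = mean(d$wall_stress_post),
               post_p10 = unname(stats::quantile(d$wall_stress_post, 0.10)),
               post_p90 = unname(stats::quantile(d$wall_stress_post, 0.90)),
               direction = ifelse(mean(d$wall_stress_post) >
                                    mean(d$wall_stress_pre),
                                  "increase", "decrease"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(match(out$section, c("healthy", "entry_tear", "dissection"))), ]
}
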