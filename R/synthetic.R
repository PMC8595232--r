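# Synthetic stand-in for CT-derived anatomy: a station-wise vessel with three
# contiguous landing sections (healthy aorta, aneurysmal entry tear, dissected
# segment with a narrowed true lumen), synthetic strip-test data, and
# reference strut-end configurations with known open areas.

#' Default anatomy configuration for the synthetic dissected vessel
#'
#' Radii are generator defaults chosen so a 28 mm device is oversized in the
#' healthy descending aorta and strongly compressed in the dissection: healthy
#' lumen radius 13 mm, entry-tear aneurysmal bulge 15 mm, true lumen tapering
#' to a 3.25 mm radius (6.5 mm diameter) at the narrowest station. Wall
#' thickness 1.5 mm throughout; an intimal flap (0.6-1.6 mm thick, 277 kPa)
#' is present in the dissection section.
#'
#' @return A named list of anatomy parameters (lengths in mm, pressures mmHg).
#' @export
default_vessel_config <- function() {
  list(length = 220, ds = 2.5,
       healthy_end = 70, entry_end = 105,     # section boundaries (arclength)
       r_healthy = 13, r_entry = 15, r_min = 3.25, s_min = 150,
       r_distal = NULL,                        # default: max(5, r_min)
       h0 = 1.5, flap_E = 277,
       flap_range = c(0.6, 1.6),
       lumen_pressure = 80,
       centreline_curvature = 0,              # 1/mm; 0 = straight
       radius_noise_sd = 0)                   # mm, smooth multiplicative noise
}

# smooth cosine blend between 0 at x<=a and 1 at x>=b
.blend <- function(x, a, b) {
  t <- pmin(pmax((x - a) / (b - a), 0), 1)
  0.5 - 0.5 * cos(pi * t)
}

#' Generate the reduced-order synthetic vessel
#'
#' Builds an ordered table of centreline stations with a smooth radius
#' profile over three contiguous sections: proximal healthy aorta, locally
#' enlarged entry-tear region, and a dissection section tapering to the
#' narrowed true lumen. Deterministic for a fixed `(config, seed)` pair.
#'
#' @param config Anatomy parameters; see [default_vessel_config()]. A partial
#'   list is merged over the defaults.
#' @param seed Integer seed for the (optional) smooth radius noise.
#' @return An object of class `vessel_model`: list with `stations` (data
#'   frame), `lumen_pressure` (mmHg), `prestress` (kPa per station, zeros),
#'   `wall_params` ([yeoh_params()], the averaged dissected-aorta set) and
#'   `flap_params`.
#' @export
generate_vessel <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(default_vessel_config(), config)
  if (cfg$r_healthy <= 0 || cfg$r_entry <= 0 || cfg$r_min <= 0)
    stop("config error: radii must be positive")
  if (!(0 < cfg$healthy_end && cfg$healthy_end < cfg$entry_end &&
        cfg$entry_end < cfg$length))
    stop("config error: section boundaries must be ordered within the vessel")

  s <- seq(0, cfg$length, by = cfg$ds)
  section <- ifelse(s < cfg$healthy_end, "healthy",
                    ifelse(s < cfg$entry_end, "entry_tear", "dissection"))

  # radius profile: healthy plateau, cosine bulge centred in the entry-tear
  # section, taper to the minimum at s_min, mild distal recovery
  mid <- (cfg$healthy_end + cfg$entry_end) / 2
  half <- (cfg$entry_end - cfg$healthy_end) / 2
  bump <- (cfg$r_entry - cfg$r_healthy) *
    pmax(0, cos(pi * (s - mid) / (2 * half)))^2 * (abs(s - mid) <= half)
  r <- cfg$r_healthy + bump
  # taper from healthy radius at entry_end down to r_min at s_min
  tap <- .blend(s, cfg$entry_end, cfg$s_min)
  r <- r * (1 - tap) + (cfg$r_healthy + (cfg$r_min - cfg$r_healthy) *
                          .blend(s, cfg$entry_end, cfg$s_min)) * tap
  # mild distal recovery beyond the narrowest station
  r_distal <- if (is.null(cfg$r_distal)) max(5, cfg$r_min) else cfg$r_distal
  rec <- .blend(s, cfg$s_min, cfg$length)
  r <- ifelse(s > cfg$s_min, cfg$r_min + (r_distal - cfg$r_min) * rec, r)

  if (cfg$radius_noise_sd > 0) {
    set.seed(as.integer(seed))
    raw <- stats::rnorm(length(s), 0, cfg$radius_noise_sd)
    noise <- stats::filter(raw, rep(1 / 5, 5), circular = TRUE)
    r <- pmax(r + as.numeric(noise), 0.6 * cfg$r_min)
  }

  # centreline: straight along z, optional circular-arc curvature in x-z
  if (cfg$centreline_curvature > 0) {
    R <- 1 / cfg$centreline_curvature
    cx <- R * (1 - cos(s / R)); cz <- R * sin(s / R)
    tx <- sin(s / R); tz <- cos(s / R)
  } else {
    cx <- rep(0, length(s)); cz <- s
    tx <- rep(0, length(s)); tz <- rep(1, length(s))
  }

  flap_present <- section == "dissection"
  # flap thickness varies smoothly across the stated 0.6-1.6 mm range
  fr <- cfg$flap_range
  flap_thickness <- ifelse(flap_present,
                           mean(fr) + diff(fr) / 2 * sin(2 * pi * (s - cfg$entry_end) /
                                                           (cfg$length - cfg$entry_end)),
                           NA_real_)

  stations <- data.frame(
    s = s, cx = cx, cy = 0, cz = cz, tx = tx, ty = 0, tz = tz,
    ct_radius = r, h0 = cfg$h0, section = section,
    flap_present = flap_present, flap_thickness = flap_thickness,
    flap_E = ifelse(flap_present, cfg$flap_E, NA_real_),
    stringsAsFactors = FALSE)

  structure(list(stations = stations,
                 lumen_pressure = cfg$lumen_pressure,
                 prestress = rep(0, nrow(stations)),
                 wall_params = yeoh_params(17.5, 58.9, 116.1),
                 flap_params = linear_elastic_params(cfg$flap_E, 0.49),
                 config = cfg, seed = as.integer(seed)),
            class = "vessel_model")
}

#' @export
print.vessel_model <- function(x, ...) {
  st <- x$stations
  cat(sprintf(paste0(
    "Synthetic dissected vessel: %d stations over %.0f mm\n",
    "  sections: %s\n  lumen radius %.2f-%.2f mm (min diameter %.2f mm), ",
    "wall %.2f mm, pressure %g mmHg\n"),
    nrow(st), max(st$s),
    paste(sprintf("%s (n=%d)", names(table(st$section)), table(st$section)),
          collapse = ", "),
    min(st$ct_radius), max(st$ct_radius), 2 * min(st$ct_radius),
    st$h0[1], x$lumen_pressure))
  invisible(x)
}

#' Generate synthetic uniaxial strip-test records
#'
#' Inverts the strip-test processing pipeline: Cauchy stress from the
#' incompressible uniaxial Yeoh law is converted back to a force-displacement
#' series at the standard protocol geometry (25 mm grips, 10 mm wide strips),
#' with optional multiplicative Gaussian noise on the force. At zero noise,
#' [to_stress_stretch()] followed by [fit_yeoh()] recovers `params` exactly.
#'
#' @param params Generating [yeoh_params()].
#' @param n_samples Number of samples (default 12, the tissue-bank size the
#'   protocol emulates).
#' @param noise_sd Relative (multiplicative) Gaussian noise SD on force
#'   (>= 0).
#' @param lam_max Maximum stretch (> 1).
#' @param n_points Points per curve.
#' @param seed Integer seed.
#' @param width0,thickness0 Strip cross-section (mm).
#' @return A list of [tensile_sample()] objects.
#' @export
generate_tensile_data <- function(params, n_samples = 12, noise_sd = 0,
                                  lam_max = 1.3, n_points = 50, seed = 1L,
                                  width0 = 10, thickness0 = 2) {
  stopifnot(inherits(params, "yeoh_params"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (lam_max <= 1) stop("lam_max must be > 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  L0 <- 25; preload <- 0.05
  A0 <- width0 * thickness0
  lam <- seq(1, lam_max, length.out = n_points)
  lapply(seq_len(n_samples), function(i) {
    sig <- yeoh_uniaxial_cauchy(lam, params)            # kPa
    if (noise_sd > 0)
      sig <- sig * (1 + stats::rnorm(n_points, 0, noise_sd))
    F <- sig / 1000 * A0 / lam + preload                # N
    tensile_sample(sprintf("synthetic-%02d", i),
                   displacement_mm = L0 * (lam - 1), force_N = F,
                   width0 = width0, thickness0 = thickness0,
                   grip_distance0 = L0, preload = preload)
  })
}

#' Build reference strut-end apex configurations with known open areas
#'
#' For each strut end, places apex points on a circle normal to the local
#' centreline tangent, with the circle area equal to the requested target.
#' The resulting point sets have analytically known open area and centre, so
#' they serve as ground truth for the configuration metrics.
#'
#' @param loa_targets Named numeric vector of target areas (mm^2), names are
#'   strut-end labels (e.g. `P1`, `D5`).
#' @param centres Data frame with columns `label, cx, cy, cz, tx, ty, tz`
#'   giving each end's centre point and tangent.
#' @param n_points Apex points per end (default 5; use more for dense
#'   circles).
#' @return Named list of `n_points x 3` matrices of apex coordinates (mm).
#' @export
reference_stent_configuration <- function(loa_targets, centres, n_points = 5) {
  if (any(loa_targets <= 0)) stop("target areas must be positive")
  stopifnot(all(c("label", "cx", "cy", "cz", "tx", "ty", "tz") %in% names(centres)))
  out <- lapply(names(loa_targets), function(lb) {
    row <- centres[centres$label == lb, , drop = FALSE]
    if (nrow(row) != 1) stop("no centre entry for end ", lb)
    r <- sqrt(loa_targets[[lb]] / pi)
    circle_points(c(row$cx, row$cy, row$cz), c(row$tx, row$ty, row$tz),
                  r, n_points)
  })
  names(out) <- names(loa_targets)
  out
}

# n points on a circle of radius r centred at `centre`, in the plane with
# unit normal `normal`
circle_points <- function(centre, normal, r, n) {
  nrm <- normal / sqrt(sum(normal^2))
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * nrm) * nrm; u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  t(vapply(th, function(a) centre + r * (cos(a) * u + sin(a) * v), numeric(3)))
}

#' Export vessel stations to CSV
#'
#' @param vessel A `vessel_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vessel_csv <- function(vessel, path) {
  stopifnot(inherits(vessel, "vessel_model"))
  st <- vessel$stations
  st$prestress_kpa <- vessel$prestress
  utils::write.csv(st, path, row.names = FALSE)
  invisible(path)
}
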