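# Uniaxial strip-test processing and Yeoh parameter fitting.
#
# Protocol emulated: circumferential strips clamped at 25 mm grip distance,
# preconditioned to 0.05 N, pulled to failure; stretch computed from grip
# distance, Cauchy stress from force, initial cross-section and stretch under
# the incompressibility assumption (A = A0 / lambda).

#' A uniaxial tensile strip-test record
#'
#' @param sample_id Character identifier.
#' @param displacement_mm Grip displacement series (mm, non-decreasing).
#' @param force_N Measured force series (N), same length.
#' @param width0,thickness0 Initial strip cross-section (mm).
#' @param grip_distance0 Initial grip distance L0 (mm, default 25).
#' @param preload Preconditioning force (N, default 0.05); the stretch and
#'   stress reference is taken where the force first reaches this value.
#' @return An object of class `tensile_sample`.
#' @export
tensile_sample <- function(sample_id, displacement_mm, force_N,
                           width0, thickness0,
                           grip_distance0 = 25, preload = 0.05) {
  stopifnot(length(displacement_mm) == length(force_N))
  if (grip_distance0 <= 0) stop("grip_distance0 must be > 0")
  if (width0 * thickness0 <= 0) stop("data error: zero cross-section")
  if (any(diff(displacement_mm) < 0))
    stop("data error: displacement series must be non-decreasing")
  structure(list(sample_id = as.character(sample_id),
                 displacement_mm = as.numeric(displacement_mm),
                 force_N = as.numeric(force_N),
                 width0 = width0, thickness0 = thickness0,
                 grip_distance0 = grip_distance0, preload = preload),
            class = "tensile_sample")
}

#' Convert a strip-test record to a Cauchy stress-stretch curve
#'
#' The reference grip distance is the one at which the force first reaches the
#' preconditioning load; stretch is the current grip distance over that
#' reference. Cauchy stress is `F * lambda / A0` (incompressible area
#' reduction), with the preload force subtracted so the reference point sits
#' at (1, ~0). Units: kPa.
#'
#' @param sample A [tensile_sample()].
#' @return An object of class `stress_stretch_curve` with fields `lam`
#'   (strictly increasing), `sigma` (kPa) and `yield_index`
#'   (see [detect_yield()]).
#' @export
to_stress_stretch <- function(sample) {
  stopifnot(inherits(sample, "tensile_sample"))
  i0 <- which(sample$force_N >= sample$preload)[1]
  if (is.na(i0))
    stop("data error: force never reaches the preconditioning load")
  L0 <- sample$grip_distance0
  Lref <- L0 + sample$displacement_mm[i0]
  idx <- i0:length(sample$force_N)
  lam <- (L0 + sample$displacement_mm[idx]) / Lref
  A0 <- sample$width0 * sample$thickness0              # mm^2
  sig <- (sample$force_N[idx] - sample$force_N[i0]) * lam / A0 * 1000  # kPa
  keep <- c(TRUE, diff(lam) > 0)                       # drop duplicate stretches
  curve <- structure(list(lam = lam[keep], sigma = sig[keep],
                          yield_index = NA_integer_,
                          sample_id = sample$sample_id),
                     class = "stress_stretch_curve")
  # very short records have no detectable yield; fit the whole range
  curve$yield_index <- if (length(curve$sigma) >= 5) detect_yield(curve)
                       else length(curve$sigma)
  curve
}

#' Locate the yield point of a stress-stretch curve
#'
#' The yield point is taken as the first occurrence of the global stress
#' maximum — the onset of tearing in a strip test. Points beyond it are
#' excluded from fitting. A strictly rising curve has no interior maximum;
#' the last index is returned and flagged (`attr(, "no_interior_max")`).
#'
#' @param curve A `stress_stretch_curve` (>= 5 points).
#' @return Integer index into the curve; see Details for the flag.
#' @export
detect_yield <- function(curve) {
  stopifnot(inherits(curve, "stress_stretch_curve"))
  n <- length(curve$sigma)
  if (n < 5) stop("need at least 5 points to locate a yield point")
  k <- which.max(curve$sigma)   # first occurrence on ties
  if (k == n) attr(k, "no_interior_max") <- TRUE
  k
}

#' Fit Yeoh parameters to a stress-stretch curve
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of the incompressible uniaxial Yeoh Cauchy stress
#' against the measured curve, restricted to the range from zero stretch to
#' the yield point. `c10` is bounded below at a small positive value; `c20`
#' and `c30` are free. Three additional jittered starts (fixed internal seed)
#' guard against local minima; the lowest-SSR fit is kept.
#'
#' @param curve A `stress_stretch_curve`.
#' @param init Initial coefficients, default `c(10, 10, 10)` kPa.
#' @param yield_index Optional explicit override of the fitted range.
#' @param n_starts Number of jittered restarts (>= 1).
#' @return An object of class `yeoh_fit` with fields `params`
#'   ([yeoh_params()]), `r_squared`, `residuals` (kPa), `fitted_range`.
#' @export
fit_yeoh <- function(curve, init = c(10, 10, 10), yield_index = NULL,
                     n_starts = 3) {
  stopifnot(inherits(curve, "stress_stretch_curve"))
  k <- if (is.null(yield_index)) curve$yield_index else as.integer(yield_index)
  lam <- curve$lam[1:k]
  sig <- curve$sigma[1:k]
  if (length(lam) < 4) stop("need at least 4 points up to the yield point")

  starts <- list(as.numeric(init))
  if (n_starts > 1) {
    rs <- local({ # fixed, self-contained jitter; does not touch the user RNG
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
              else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
      set.seed(20210824L)
      lapply(seq_len(n_starts - 1L),
             function(i) as.numeric(init) * stats::runif(3, 0.4, 2.5))
    })
    starts <- c(starts, rs)
  }

  best <- NULL
  errs <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        sig ~ yeoh_uniaxial_cauchy(lam, yeoh_params(c10, c20, c30)),
        start = list(c10 = s[1], c20 = s[2], c30 = s[3]),
        lower = c(1e-8, -Inf, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) e)
    if (inherits(fit, "error")) { errs <- c(errs, conditionMessage(fit)); next }
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) best <- fit
  }
  if (is.null(best))
    stop("Yeoh fit failed to converge from any start: ",
         paste(unique(errs), collapse = "; "))

  co <- stats::coef(best)
  res <- stats::resid(best)
  ss_res <- sum(res^2)
  ss_tot <- sum((sig - mean(sig))^2)
  structure(list(params = yeoh_params(co[["c10"]], co[["c20"]], co[["c30"]]),
                 r_squared = 1 - ss_res / ss_tot,
                 residuals = as.numeric(res),
                 fitted_range = c(1L, k),
                 sample_id = curve$sample_id),
            class = "yeoh_fit")
}

#' @export
print.yeoh_fit <- function(x, ...) {
  cat(sprintf("Yeoh fit (%s): c10 = %.4g, c20 = %.4g, c30 = %.4g kPa, R^2 = %.6f\n",
              x$sample_id %||% "?", x$params$c10, x$params$c20, x$params$c30,
              x$r_squared))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average fitted Yeoh parameters across samples
#'
#' Arithmetic mean of each coefficient (the per-sample parameters are
#' averaged, not the curves). The mean R^2 is attached as an attribute.
#'
#' @param fits A list of `yeoh_fit` objects (>= 1).
#' @return A [yeoh_params()] object with attribute `mean_r_squared`.
#' @export
average_params <- function(fits) {
  if (length(fits) < 1) stop("need at least one fit to average")
  stopifnot(all(vapply(fits, inherits, logical(1), "yeoh_fit")))
  m <- vapply(fits, function(f) c(f$params$c10, f$params$c20, f$params$c30),
              numeric(3))
  out <- yeoh_params(mean(m[1, ]), mean(m[2, ]), mean(m[3, ]))
  attr(out, "mean_r_squared") <- mean(vapply(fits, `[[`, numeric(1), "r_squared"))
  out
}

#' Read tensile samples from delimited files
#'
#' Expects a manifest CSV with columns `sample_id, file, width0, thickness0,
#' grip_distance0` and per-sample CSVs with columns
#' `displacement_mm, force_N`. Paths in `file` are resolved relative to the
#' manifest location.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A list of [tensile_sample()] objects.
#' @export
read_tensile_samples <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "file", "width0", "thickness0")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    d <- utils::read.csv(file.path(base, man$file[i]), stringsAsFactors = FALSE)
    tensile_sample(man$sample_id[i], d$displacement_mm, d$force_N,
                   width0 = man$width0[i], thickness0 = man$thickness0[i],
                   grip_distance0 = if ("grip_distance0" %in% names(man))
                     man$grip_distance0[i] else 25)
  })
}

#' Fit all samples and average
#'
#' Convenience pipeline: converts each sample to a stress-stretch curve, fits
#' Yeoh parameters per sample, and averages them.
#'
#' @param samples List of [tensile_sample()] objects.
#' @param ... Passed to [fit_yeoh()].
#' @return List with `fits` (per-sample), `mean_params` ([yeoh_params()]),
#'   and a `table` data frame (one row per sample plus an averaged row).
#' @export
fit_tissue <- function(samples, ...) {
  fits <- lapply(samples, function(s) fit_yeoh(to_stress_stretch(s), ...))
  mp <- average_params(fits)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(sample_id = f$sample_id, c10 = f$params$c10,
               c20 = f$params$c20, c30 = f$params$c30,
               r_squared = f$r_squared)))
  tab <- rbind(tab, data.frame(sample_id = "mean", c10 = mp$c10, c20 = mp$c20,
                               c30 = mp$c30,
                               r_squared = attr(mp, "mean_r_squared")))
  list(fits = fits, mean_params = mp, table = tab)
}
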