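# End-to-end pipeline: fit tissue -> synthesize vessel -> pre-stress ->
# deploy -> validate. Deterministic for a fixed seed; every output embeds
# the seed and a configuration hash.

#' Run the full simulation pipeline
#'
#' Stages: (1) generate synthetic strip-test data and fit/average the Yeoh
#' wall parameters; (2) generate the synthetic dissected vessel; (3) recover
#' the diastolic pre-stress field; (4) deploy the device under the requested
#' variant(s); (5) validate each deployment against a reference
#' configuration (by default the variant-C result, mimicking a follow-up
#' scan registration-free comparison). The vessel and pre-stress artifacts
#' are shared across variants. Idempotent for a fixed seed.
#'
#' @param variants Character subset of `c("A", "B", "C")`.
#' @param seed Integer seed used for every stochastic stage.
#' @param vessel_config Passed to [generate_vessel()].
#' @param sg A [stent_graft()].
#' @param noise_sd Relative noise for the synthetic tensile data.
#' @param out_dir Optional directory: when given, per-stage CSV/JSON
#'   artifacts are written there.
#' @param reference Optional named list of reference apex-point matrices;
#'   default is the variant-C deployed configuration.
#' @return A list with `tissue` (fit table), `vessel`, `prestress`,
#'   `deployments` (one `deployment_result` per variant), `reports`
#'   (one `validation_report` per non-reference variant), `seed`,
#'   `config_hash`.
#' @export
run_pipeline <- function(variants = c("A", "B", "C"), seed = 1L,
                         vessel_config = list(), sg = stent_graft(),
                         noise_sd = 0, out_dir = NULL, reference = NULL) {
  variants <- match.arg(variants, c("A", "B", "C"), several.ok = TRUE)
  seed <- as.integer(seed)

  # stage 1: tissue fitting on synthetic strip tests
  samples <- generate_tensile_data(yeoh_params(17.5, 58.9, 116.1),
                                   n_samples = 12, noise_sd = noise_sd,
                                   seed = seed)
  tissue <- fit_tissue(samples)

  # stage 2: vessel
  vessel <- generate_vessel(vessel_config, seed = seed)
  vessel$wall_params <- tissue$mean_params

  # stage 3: pre-stress (shared across variants)
  ps <- prestress_fixed_point(vessel)

  # stage 4: deployments
  deployments <- lapply(variants, function(v)
    deploy(sg, vessel, deployment_config(variant = v), prestress = ps))
  names(deployments) <- variants

  # stage 5: validation against the reference configuration
  if (is.null(reference)) {
    ref_dep <- if ("C" %in% variants) deployments[["C"]]
    else deployments[[length(deployments)]]
    reference <- ref_dep$apex_points
  }
  reports <- lapply(deployments, function(d)
    validation_report(d$apex_points, reference,
                      default_section_map(sg$n_struts)))

  cfg_hash <- config_hash(list(variants = variants, seed = seed,
                               vessel_config = vessel_config,
                               noise_sd = noise_sd,
                               sg = sg[c("nominal_diameter", "length",
                                         "n_struts")]))
  out <- list(tissue = tissue$table, vessel = vessel, prestress = ps,
              deployments = deployments, reports = reports,
              seed = seed, config_hash = cfg_hash)

  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# short deterministic hash of a configuration list (no digest dependency:
# sum over serialized bytes in a simple rolling scheme)
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) { df$seed <- out$seed; df$config_hash <- out$config_hash; df }
  utils::write.csv(stamp(out$tissue),
                   file.path(out_dir, "tissue_fits.csv"), row.names = FALSE)
  write_vessel_csv(out$prestress$vessel, file.path(out_dir, "vessel.csv"))
  utils::write.csv(data.frame(iteration = seq_along(out$prestress$deviation_history),
                              max_deviation_mm = out$prestress$deviation_history,
                              seed = out$seed, config_hash = out$config_hash),
                   file.path(out_dir, "prestress_convergence.csv"),
                   row.names = FALSE)
  for (v in names(out$deployments)) {
    utils::write.csv(stamp(out$deployments[[v]]$ends),
                     file.path(out_dir, sprintf("deployment_%s.csv", v)),
                     row.names = FALSE)
    write_apex_xyz(out$deployments[[v]]$apex_points,
                   file.path(out_dir, sprintf("apex_points_%s.csv", v)))
  }
  mean_row <- out$tissue[out$tissue$sample_id == "mean", , drop = FALSE]
  summary <- list(seed = out$seed, config_hash = out$config_hash,
                  mean_params = as.list(mean_row[1, c("c10", "c20", "c30")]),
                  prestress = list(converged = out$prestress$converged,
                                   n_iterations = out$prestress$n_iterations,
                                   max_deviation_mm = out$prestress$max_deviation),
                  sections = lapply(out$reports, function(r)
                    r$per_section$e_loa))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write apex point clouds as a labelled CSV
#'
#' Columns `label, point_index, x, y, z` — the exchange format consumed by
#' [read_apex_csv()] and the validation stage.
#'
#' @param apex Named list of n x 3 matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_apex_xyz <- function(apex, path) {
  df <- do.call(rbind, lapply(names(apex), function(lb) {
    m <- apex[[lb]]
    data.frame(label = lb, point_index = seq_len(nrow(m)),
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read apex point clouds from a labelled CSV
#'
#' @param path CSV with columns `label, point_index, x, y, z`.
#' @return Named list of n x 3 matrices ordered by `point_index`.
#' @export
read_apex_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "point_index", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("apex CSV must have columns: ", paste(need, collapse = ", "))
  sp <- split(df, df$label)
  out <- lapply(sp, function(d) {
    d <- d[order(d$point_index), ]
    as.matrix(d[, c("x", "y", "z")])
  })
  out[unique(df$label)]
}
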