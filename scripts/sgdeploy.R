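#!/usr/bin/env Rscript
# Thin command-line wrapper over the stentring package.
#
#   Rscript scripts/sgdeploy.R <command> [options]
#
# Commands:
#   fit-tissue --manifest <csv> --out <dir>
#   synth      --seed <int> --out <dir>
#   prestress  --seed <int> --out <dir>
#   deploy     --variant {A,B,C} --seed <int> --out <dir>
#   validate   --sim <apex csv> --ref <apex csv> --out <dir>
#   run        --variant {A,B,C} --seed <int> --out <dir>

suppressPackageStartupMessages(library(stentring))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: sgdeploy.R <command> [options]")
cmd <- args[1]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
out_dir <- opt("--out", "sgdeploy-out")
seed <- as.integer(opt("--seed", "1"))
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

if (cmd == "fit-tissue") {
  manifest <- opt("--manifest")
  if (is.null(manifest)) stop("fit-tissue requires --manifest")
  res <- fit_tissue(read_tensile_samples(manifest))
  utils::write.csv(res$table, file.path(out_dir, "tissue_fits.csv"),
                   row.names = FALSE)
  print(res$mean_params)
} else if (cmd == "synth") {
  v <- generate_vessel(seed = seed)
  write_vessel_csv(v, file.path(out_dir, "vessel.csv"))
  print(v)
} else if (cmd == "prestress") {
  v <- generate_vessel(seed = seed)
  ps <- prestress_fixed_point(v)
  write_vessel_csv(ps$vessel, file.path(out_dir, "vessel_prestressed.csv"))
  utils::write.csv(
    data.frame(iteration = seq_along(ps$deviation_history),
               max_deviation_mm = ps$deviation_history),
    file.path(out_dir, "prestress_convergence.csv"), row.names = FALSE)
  print(ps)
} else if (cmd == "deploy") {
  variant <- opt("--variant", "C")
  v <- generate_vessel(seed = seed)
  d <- deploy(stent_graft(), v, deployment_config(variant = variant))
  utils::write.csv(d$ends,
                   file.path(out_dir, sprintf("deployment_%s.csv", variant)),
                   row.names = FALSE)
  write_apex_xyz(d$apex_points,
                 file.path(out_dir, sprintf("apex_points_%s.csv", variant)))
  print(d)
  print(wall_stress_report(d, v))
} else if (cmd == "validate") {
  sim <- read_apex_csv(opt("--sim"))
  ref <- read_apex_csv(opt("--ref"))
  rep <- validation_report(sim, ref)
  utils::write.csv(rep$per_end, file.path(out_dir, "validation_per_end.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$per_section$e_loa,
                   file.path(out_dir, "validation_e_loa.csv"), row.names = FALSE)
  utils::write.csv(rep$per_section$e_c,
                   file.path(out_dir, "validation_e_c.csv"), row.names = FALSE)
  print(rep)
} else if (cmd == "run") {
  variant <- opt("--variant")
  variants <- if (is.null(variant)) c("A", "B", "C") else variant
  out <- run_pipeline(variants = variants, seed = seed, out_dir = out_dir)
  cat("pipeline complete; artifacts in", out_dir,
      "(config hash", out$config_hash, ")\n")
} else {
  stop("unknown command: ", cmd)
}
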