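sg <- stent_graft()
cfg <- deployment_config(variant = "A")

test_that("device and config constructors validate their invariants", {
  expect_error(stent_graft(n_struts = 0), "n_struts")
  expect_error(stent_graft(nominal_diameter = -1), "nominal_diameter")
  expect_error(deployment_config(predilation_from = 8, predilation_to = 6),
               "predilation")
  expect_length(sg$end_labels, 18)
})

test_that("a virgin ring at nominal radius exerts no pressure", {
  out <- stent_radial_pressure(sg$nominal_diameter / 2, nitinol_state(),
                               sg, cfg)
  expect_equal(out$pressure, 0)
})

test_that("crimping strain lands inside the design window", {
  # crimping 28 -> 7 mm must load the wire just past the forward plateau
  eps <- cfg$kappa * (14 - 3.5) / 14
  np <- sg$wire
  expect_gte(eps, np$eps_L)
  expect_lte(eps, np$eps_L + np$sigma_LE / np$E_M + 0.01)
})

test_that("release pressure is below crimp pressure at the same radius", {
  crimped <- nitinol_drive(nitinol_state(), cfg$kappa * (14 - 3.5) / 14,
                           sg$wire, d_eps_max = 2e-4)
  for (r in c(5, 8, 11)) {
    virgin_up <- stent_radial_pressure(r, nitinol_state(), sg, cfg)
    released <- stent_radial_pressure(r, crimped, sg, cfg)
    expect_lt(released$pressure, virgin_up$pressure)
    expect_gt(released$pressure, 0)
  }
})

test_that("re-crimping and re-releasing a deployed ring closes the path", {
  crimp_eps <- cfg$kappa * (14 - 3.5) / 14
  crimped <- nitinol_drive(nitinol_state(), crimp_eps, sg$wire)
  r_dep <- 9
  dep <- stent_radial_pressure(r_dep, crimped, sg, cfg)
  re_crimped <- nitinol_drive(dep$state, crimp_eps, sg$wire)
  re_dep <- stent_radial_pressure(r_dep, re_crimped, sg, cfg)
  expect_lt(abs(re_dep$pressure - dep$pressure), 1e-6)
  expect_lt(abs(re_dep$state$stress - dep$state$stress), 1e-6)
})

test_that("pre-dilation opens only the narrowed stations and never shrinks", {
  v <- generate_vessel(seed = 1)
  before <- v$stations$ct_radius
  v2 <- predilate(v, cfg)
  after <- v2$stations$ct_radius
  expect_true(all(after >= before))
  expect_equal(min(after), 4)                     # 8 mm balloon target
  expect_equal(after[before >= 4], before[before >= 4])  # wide stations unchanged
  narrow <- before < 4
  expect_true(all(after[narrow] == 4))
})

test_that("an oversized vessel lets every end reach the nominal radius", {
  v <- generate_vessel(list(r_healthy = 30, r_entry = 31, r_min = 25,
                            ds = 5), seed = 1)
  d <- deploy(sg, v, deployment_config(variant = "A"))
  expect_true(all(abs(d$ends$radius - 14) < 0.01))
  expect_true(all(!d$ends$contact))
  expect_true(all(d$ends$wall_radius > 20))
})

test_that("variant radii are ordered B <= C <= A with A/B/C mechanisms", {
  fx <- default_patient()
  eA <- fx$deployments$A$ends
  eB <- fx$deployments$B$ends
  eC <- fx$deployments$C$ends
  expect_identical(eA$label, eB$label)
  # graft pressure is a monotone outward load: B <= C at every end
  expect_true(all(eB$radius <= eC$radius + 1e-9))
  # removing pre-stress softens the wall: B <= A at every end
  expect_true(all(eB$radius <= eA$radius + 1e-9))
  # qualitative open-area ordering at the dissection-section ends
  diss <- eA$section == "dissection"
  expect_true(all(eB$loa[diss] <= eC$loa[diss] + 1e-6))
  expect_true(all(eC$loa[diss] <= eA$loa[diss] + 1e-6))
})

test_that("deployed radii stay within physical bounds", {
  fx <- default_patient()
  v <- predilate(fx$vessel, fx$deployments$C$config)
  lum <- v$stations$ct_radius[match(fx$deployments$A$ends$station_s,
                                    v$stations$s)]
  for (d in fx$deployments) {
    e <- d$ends
    expect_true(all(e$radius >= fx$deployments$A$config$crimp_diameter / 2))
    expect_true(all(e$radius <= 14 + 0.01))       # graft cap
    expect_true(all(e$wall_radius >= e$radius - 1e-6))
  }
  # without pre-stress the wall never recoils below its reference, so the
  # stent can only hold it at or beyond the pre-deployment lumen radius
  eA <- fx$deployments$A$ends
  expect_true(all(eA$radius >= pmin(lum, 14) - 1e-6))
})

test_that("the section open-area pattern matches the follow-up picture", {
  fx <- default_patient()
  e <- fx$deployments$C$ends
  m <- tapply(e$loa, e$section, mean)
  expect_gt(m[["entry_tear"]], m[["healthy"]])
  expect_lt(m[["dissection"]], m[["healthy"]])
})

test_that("wall stress falls at the entry tear and rises in the dissection", {
  fx <- default_patient()
  rep_c <- wall_stress_report(fx$deployments$C, fx$vessel)
  expect_identical(rep_c$direction[rep_c$section == "entry_tear"], "decrease")
  expect_identical(rep_c$direction[rep_c$section == "dissection"], "increase")
})

test_that("with no contact and no loads the wall stress is unchanged", {
  # oversized vessel, variant A: nothing touches the stress-free wall, so
  # post-deployment stress identically equals the pre-deployment stress
  v <- generate_vessel(list(r_healthy = 30, r_entry = 31, r_min = 25,
                            ds = 20), seed = 1)
  d <- deploy(sg, v, deployment_config(variant = "A"))
  expect_true(all(!d$ends$contact))
  expect_equal(d$ends$wall_stress_post, d$ends$wall_stress_pre,
               tolerance = 1e-9)
})

test_that("deployment refuses a device longer than the covered centreline", {
  v <- generate_vessel(seed = 1)
  expect_error(deploy(sg, v, deployment_config(variant = "A",
                                               landing_offset = 150)),
               "beyond the vessel")
})
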