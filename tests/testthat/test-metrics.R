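test_that("open area of dense circular apex sets matches pi r^2", {
  ctr <- c(3, -2, 7); nrm <- c(0.2, 0.5, 0.84)
  r <- sqrt(468.0 / pi)   # ~12.21 mm
  pts <- stentring:::circle_points(ctr, nrm, r, 64)
  a <- local_open_area(pts)
  expect_lt(abs(a - pi * r^2) / (pi * r^2), 0.001)
  # convergence with density
  err <- vapply(c(8, 16, 32, 64), function(n)
    abs(local_open_area(stentring:::circle_points(ctr, nrm, r, n)) -
          pi * r^2) / (pi * r^2), numeric(1))
  expect_gt(err[1], err[4])
  expect_lt(err[4], 1e-3)
})

test_that("polygon mode reproduces the shoelace identity", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(local_open_area(sq, mode = "polygon"), 1, tolerance = 1e-12)
})

test_that("spline area of a pentagon lies between polygon and circle areas", {
  r <- 2
  pent <- stentring:::circle_points(c(0, 0, 0), c(0, 0, 1), r, 5)
  a_poly <- local_open_area(pent, mode = "polygon")
  a_spline <- local_open_area(pent)
  expect_equal(a_poly, 5 / 2 * r^2 * sin(2 * pi / 5), tolerance = 1e-9)
  expect_gt(a_spline, a_poly)
  expect_lt(a_spline, pi * r^2)
})

test_that("open area is invariant under rigid-body transforms", {
  pts <- stentring:::circle_points(c(0, 0, 0), c(0, 0, 1), 5, 7)
  pts <- pts + cbind(0.3 * sin(1:7), 0.2 * cos(1:7), 0.1 * sin(2 * (1:7)))
  a0 <- local_open_area(pts)
  for (sd in 1:5) {
    a1 <- local_open_area(rigid_transform(pts, seed = sd))
    expect_lt(abs(a1 - a0) / a0, 1e-9)
  }
})

test_that("degenerate apex sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(local_open_area(line), "collinear")
  bow <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(local_open_area(bow), "self-intersecting")
  expect_error(local_open_area(rbind(c(0, 0, 0), c(1, 1, 1))), "n >= 3")
})

test_that("strut-centre deviation is the centroid distance and a metric", {
  pts <- stentring:::circle_points(c(0, 0, 0), c(0, 0, 1), 5, 8)
  expect_equal(strut_centre_deviation(pts, pts), 0)
  shifted <- sweep(pts, 2, c(-3, -4, 0))
  expect_equal(strut_centre_deviation(pts, shifted), 5)
  # rotation about the centroid leaves e_c at zero
  rot <- rigid_transform(pts, seed = 2)
  rot <- sweep(rot, 2, colMeans(rot) - colMeans(pts))
  expect_equal(strut_centre_deviation(pts, rot), 0, tolerance = 1e-9)
  # symmetry and triangle inequality on three configurations
  a <- pts; b <- sweep(pts, 2, c(1, 2, 3)); c3 <- sweep(pts, 2, c(-2, 0, 4))
  expect_equal(strut_centre_deviation(a, b), strut_centre_deviation(b, a))
  expect_lte(strut_centre_deviation(a, c3),
             strut_centre_deviation(a, b) + strut_centre_deviation(b, c3))
  attr(a, "label") <- "P1"; attr(b, "label") <- "D1"
  expect_error(strut_centre_deviation(a, b), "label mismatch")
})

test_that("section summaries use the population SD and report extremes", {
  sm <- default_section_map()
  vals <- stats::setNames(rep(7, 18), names(sm))
  out <- section_summary(vals, sm)
  expect_true(all(out$sd == 0))
  two <- c(P1 = -6.2, D1 = 28.8)
  out2 <- section_summary(two, sm)
  expect_equal(out2$mean, mean(two))
  expect_equal(out2$min, -6.2); expect_equal(out2$max, 28.8)
  expect_equal(out2$sd, sqrt(mean((two - mean(two))^2)))
  expect_error(section_summary(c(Q7 = 1), sm), "assigned")
})

test_that("the default section map follows the landing-zone numbering", {
  sm <- default_section_map()
  expect_identical(unname(sm[c("P1", "D2", "P3")]),
                   rep("healthy", 3))
  expect_identical(unname(sm[c("D3", "P4", "D4", "P5")]),
                   rep("entry_tear", 4))
  expect_identical(unname(sm[c("D5", "P7", "D9")]),
                   rep("dissection", 3))
})

test_that("reference fixtures round-trip the printed section statistics", {
  # build a reference configuration whose entry-tear ends have mean LOA
  # 468.0 and dissection ends 137.3, then recover those means
  sm <- default_section_map()
  entry <- c(D3 = 468 - 30, P4 = 468 + 30, D4 = 468 - 10, P5 = 468 + 10)
  diss_lab <- names(sm)[sm == "dissection"]
  diss <- stats::setNames(137.3 + seq(-20, 20, length.out = length(diss_lab)),
                          diss_lab)
  targets <- c(entry, diss)
  centres <- data.frame(label = names(targets),
                        cx = 0, cy = 0, cz = seq_along(targets) * 15,
                        tx = 0, ty = 0, tz = 1)
  cfg <- reference_stent_configuration(targets, centres, n_points = 64)
  loa <- vapply(cfg, local_open_area, numeric(1))
  out <- section_summary(loa, sm)
  expect_equal(out$mean[out$section == "entry_tear"], 468.0, tolerance = 1e-3)
  expect_equal(out$mean[out$section == "dissection"], 137.3, tolerance = 1e-3)
})

test_that("border jumps reproduce the fixture differences and are symmetric", {
  loa <- c(P3 = 294.4, D3 = 468.0, P5 = 460, D5 = 255.9)
  j <- loa_border_jump(loa)
  expect_equal(unname(j["P3_D3"]), 173.6)
  expect_equal(unname(j["P5_D5"]), 204.1)
  swapped <- loa; swapped[c("P3", "D3")] <- loa[c("D3", "P3")]
  expect_equal(loa_border_jump(swapped), j)
  expect_equal(unname(loa_border_jump(c(P3 = 5, D3 = 5, P5 = 2, D5 = 2))),
               c(0, 0))
  expect_error(loa_border_jump(loa[-1]), "missing")
})

test_that("validation reports compare simulated against reference ends", {
  fx <- default_patient()
  simC <- fx$deployments$C$apex_points
  rep0 <- validation_report(simC, simC)
  expect_true(all(abs(rep0$per_end$e_loa) < 1e-9))
  expect_true(all(rep0$per_end$e_c < 1e-9))
  repA <- validation_report(fx$deployments$A$apex_points, simC)
  # model A over-opens the dissection relative to C
  diss <- repA$per_end$section == "dissection"
  expect_gte(mean(repA$per_end$e_loa[diss]), 0)
  expect_equal(nrow(repA$per_end), 18)
})
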