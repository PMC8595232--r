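p_ref <- yeoh_params(17.5, 58.9, 116.1)

test_that("stress-stretch conversion applies grip kinematics and unit bridge", {
  # L0 = 25 mm, 5 mm displacement -> lambda = 1.2; F = 1 N on 10 mm^2 at
  # lambda = 1.2 -> 0.12 MPa = 120 kPa (after preload referencing)
  s <- tensile_sample("hand", c(0, 2.5, 5), c(0.05, 0.5, 1.05),
                      width0 = 10, thickness0 = 1)
  cv <- to_stress_stretch(s)
  expect_equal(cv$lam, c(1, 1.1, 1.2))
  expect_equal(cv$sigma[1], 0)
  expect_equal(cv$sigma[3], (1.05 - 0.05) * 1.2 / 10 * 1000)
})

test_that("conversion rejects bad records", {
  expect_error(tensile_sample("x", c(0, 1, 0.5), c(0.1, 0.2, 0.3), 10, 1),
               "non-decreasing")
  expect_error(tensile_sample("x", c(0, 1), c(0.1, 0.2), 0, 1),
               "cross-section")
  s <- tensile_sample("x", c(0, 1, 2), c(0.01, 0.02, 0.03), 10, 1)
  expect_error(to_stress_stretch(s), "preconditioning")
})

test_that("yield detection picks the first global maximum", {
  mk <- function(sig) structure(list(lam = seq(1, by = 0.01,
                                               length.out = length(sig)),
                                     sigma = sig, yield_index = NA),
                                class = "stress_stretch_curve")
  expect_identical(detect_yield(mk(c(0, 1, 5, 3, 2))), 3L)
  expect_identical(detect_yield(mk(c(0, 1, 5, 5, 2))), 3L)  # tie: first
  k <- detect_yield(mk(c(0, 1, 2, 3, 4)))
  expect_identical(as.integer(k), 5L)
  expect_true(isTRUE(attr(k, "no_interior_max")))
  expect_error(detect_yield(mk(c(0, 1, 2))), "at least 5")
})

test_that("fitting noiseless self-generated data recovers the parameters", {
  smp <- generate_tensile_data(p_ref, n_samples = 1, noise_sd = 0,
                               lam_max = 1.3, n_points = 50, seed = 7)[[1]]
  fit <- fit_yeoh(to_stress_stretch(smp))
  expect_lt(abs(fit$params$c10 - 17.5) / 17.5, 1e-3)
  expect_lt(abs(fit$params$c20 - 58.9) / 58.9, 1e-3)
  expect_lt(abs(fit$params$c30 - 116.1) / 116.1, 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("round trip holds for other positive triples (4 significant figures)", {
  for (prm in list(yeoh_params(5, 1, 0.5), yeoh_params(40, 200, 900),
                   yeoh_params(100, 10, 10))) {
    smp <- generate_tensile_data(prm, n_samples = 1, noise_sd = 0,
                                 lam_max = 1.25, n_points = 60, seed = 3)[[1]]
    fit <- fit_yeoh(to_stress_stretch(smp))
    got <- c(fit$params$c10, fit$params$c20, fit$params$c30)
    want <- c(prm$c10, prm$c20, prm$c30)
    expect_lt(max(abs(got - want) / want), 5e-4)
  }
})

test_that("nested neo-Hookean data drives c20 and c30 to zero", {
  smp <- generate_tensile_data(yeoh_params(20, 0, 0), n_samples = 1,
                               noise_sd = 0, lam_max = 1.3, seed = 2)[[1]]
  fit <- fit_yeoh(to_stress_stretch(smp))
  expect_equal(fit$params$c10, 20, tolerance = 1e-4)
  expect_lt(abs(fit$params$c20), 1e-2)
  expect_lt(abs(fit$params$c30), 1e-1)
})

test_that("fit is invariant to uniform subsampling", {
  smp <- generate_tensile_data(p_ref, n_samples = 1, noise_sd = 0,
                               lam_max = 1.3, n_points = 100, seed = 5)[[1]]
  cv <- to_stress_stretch(smp)
  half <- structure(list(lam = cv$lam[seq(1, length(cv$lam), 2)],
                         sigma = cv$sigma[seq(1, length(cv$sigma), 2)],
                         yield_index = NA_integer_, sample_id = "half"),
                    class = "stress_stretch_curve")
  half$yield_index <- detect_yield(half)
  f1 <- fit_yeoh(cv); f2 <- fit_yeoh(half)
  rel <- abs(c(f1$params$c10 - f2$params$c10,
               f1$params$c20 - f2$params$c20,
               f1$params$c30 - f2$params$c30)) /
    c(f1$params$c10, f1$params$c20, f1$params$c30)
  expect_lt(max(rel), 0.005)
})

test_that("parameter averaging is the arithmetic mean of coefficients", {
  mkfit <- function(a, b, c) structure(
    list(params = yeoh_params(a, b, c), r_squared = 1), class = "yeoh_fit")
  one <- mkfit(10, 10, 10)
  expect_equal(average_params(list(one))$c10, 10)
  avg <- average_params(list(mkfit(10, 10, 10), mkfit(20, 20, 20)))
  expect_equal(c(avg$c10, avg$c20, avg$c30), c(15, 15, 15))
  expect_error(average_params(list()), "at least one")
  # 12 fits constructed so the mean is the reference triple
  fits <- lapply(seq_len(12), function(i) {
    d <- (i - 6.5) / 10
    mkfit(17.5 + d, 58.9 - d, 116.1 + 2 * d)
  })
  avg <- average_params(fits)
  expect_equal(c(avg$c10, avg$c20, avg$c30), c(17.5, 58.9, 116.1))
})

test_that("the full tissue pipeline reads files and reports per-sample rows", {
  dir <- withr::local_tempdir()
  smps <- generate_tensile_data(p_ref, n_samples = 3, noise_sd = 0, seed = 11)
  files <- vapply(seq_along(smps), function(i) {
    f <- sprintf("s%02d.csv", i)
    utils::write.csv(data.frame(displacement_mm = smps[[i]]$displacement_mm,
                                force_N = smps[[i]]$force_N),
                     file.path(dir, f), row.names = FALSE)
    f
  }, character(1))
  utils::write.csv(data.frame(sample_id = paste0("s", 1:3), file = files,
                              width0 = 10, thickness0 = 2,
                              grip_distance0 = 25),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  res <- fit_tissue(read_tensile_samples(file.path(dir, "manifest.csv")))
  expect_equal(nrow(res$table), 4)  # 3 samples + mean row
  expect_equal(res$mean_params$c10, 17.5, tolerance = 1e-3)
})
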