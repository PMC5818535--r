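test_that("weighted CSP reproduces hand arithmetic and is sign-invariant", {
  free <- data.frame(residue = 1, delta_H = 8.0, delta_N = 115.0)
  expect_equal(compute_csp(free, free)$delta_delta, 0)

  bound <- data.frame(residue = 1, delta_H = 8.10, delta_N = 116.0)
  expect_equal(compute_csp(free, bound)$delta_delta,
               sqrt(0.5 * (0.10^2 + 0.15 * 1.00^2)), tolerance = 1e-12)
  expect_equal(compute_csp(free, bound)$delta_delta, 0.2828, tolerance = 1e-3)

  flipped <- data.frame(residue = 1, delta_H = 7.90, delta_N = 114.0)
  expect_equal(compute_csp(free, flipped)$delta_delta,
               compute_csp(free, bound)$delta_delta)

  expect_error(compute_csp(free, data.frame(residue = 2, delta_H = 8,
                                            delta_N = 115)),
               "mismatch")
})

test_that("bound fraction ratio clips to [0, 1] and rejects zero saturation", {
  expect_equal(as.numeric(chi_B(0.20, 0.20)), 1)
  expect_equal(as.numeric(chi_B(0, 0.20)), 0)
  expect_equal(as.numeric(chi_B(0.05, 0.20)), 0.25)
  expect_message(x <- chi_B(0.30, 0.20), "clipped")
  expect_equal(as.numeric(x), 1)
  expect_identical(attr(x, "clipped"), 1L)
  expect_error(chi_B(0.1, 0), "undefined")
  expect_error(chi_B(-0.1, 0.2), "nonnegative")
})

test_that("multi-ligand bound fraction matches the mass-action oracle", {
  expect_equal(binding_model_chiB(200, 0, 21, 7.8), 0)
  expect_equal(binding_model_chiB(200, 1600, 21, 7.8), 0.735, tolerance = 1e-3)
  # stoichiometric limit: K_D = 0 with exactly L*P total ligand
  expect_equal(binding_model_chiB(200, 7.8 * 200, 0, 7.8), 1)

  set.seed(101)
  for (i in 1:100) {
    P <- runif(1, 10, 500)
    C <- runif(1, 0, 5000)
    K_D <- runif(1, 0.5, 500)
    L <- runif(1, 0.5, 20)
    expect_equal(binding_model_chiB(P, C, K_D, L),
                 chiB_mass_action(P, C, K_D, L), tolerance = 1e-6)
  }
})

test_that("bound fraction is nondecreasing in ligand concentration", {
  grid <- seq(0, 10000, by = 50)
  for (pars in list(c(200, 21, 7.8), c(50, 300, 2), c(400, 5, 15))) {
    chi <- binding_model_chiB(pars[1], grid, pars[2], pars[3])
    expect_true(all(diff(chi) >= -1e-12))
    expect_true(all(chi >= 0 & chi <= 1))
    # saturates toward 1
    expect_gt(binding_model_chiB(pars[1], 1e9, pars[2], pars[3]), 0.999)
  }
})

test_that("global fit round-trips noiseless generator output within 1%", {
  for (K_D in c(5, 60, 200)) {
    for (L in c(1, 6, 12)) {
      s <- generate_titration(seed = 17, K_D = K_D, L = L, noise = 0)
      f <- fit_binding(s)
      expect_lt(abs(f$K_D - K_D) / K_D, 0.01)
      expect_lt(abs(f$L - L) / L, 0.01)
      expect_true(all(f$delta_sat >= 0))
    }
  }
})

test_that("global fit reports uncertainties and residue selection", {
  s <- generate_titration(seed = 4)
  f <- fit_binding(s)
  expect_s3_class(f, "binding_fit")
  expect_true(all(is.finite(f$se)))
  expect_true(all(f$residues_used %in%
                    c(104, 107, 112, 119, 123, 124, 126, 127, 129, 130,
                      135, 136, 137)))
  expect_output(print(f), "K_D")
})

test_that("degenerate titrations are rejected", {
  flat <- make_series(dsat_H = rep(0, 6))
  expect_error(fit_binding(flat, residues = 3), "unidentifiable|signal")
  short <- make_series(concs = c(0, 100, 3200))
  expect_error(fit_binding(short, residues = 3), "4 titration points")
  s <- make_series()
  expect_error(fit_binding(s, residues = integer(0)), "no residues")
})

test_that("residue ranking returns the perturbed sites in order", {
  s <- make_series(dsat_H = c(0, 0, 0.2, 0, 0.1, 0))
  expect_identical(rank_perturbed_residues(s, top_k = 2), c(3L, 5L))
  expect_identical(rank_perturbed_residues(s, threshold = 0.001), c(3L, 5L))
  # nothing perturbed: empty under a threshold
  flat <- make_series(dsat_H = rep(0, 6))
  expect_length(rank_perturbed_residues(flat, threshold = 1e-6), 0)
  # single perturbed residue
  one <- make_series(residues = 100:140, dsat_H = ifelse(100:140 == 120, 0.2, 0))
  expect_identical(rank_perturbed_residues(one, top_k = 1), 120L)
  expect_error(rank_perturbed_residues(s, top_k = 2, threshold = 0.1),
               "exactly one")
})

test_that("the 13 reference sites carry the largest CSPs in generated data", {
  s <- generate_titration(seed = 23)
  sites <- c(104, 107, 112, 119, 123, 124, 126, 127, 129, 130, 135, 136, 137)
  expect_setequal(rank_perturbed_residues(s, top_k = 13), sites)
})

test_that("broadening detection separates intensity loss from shifts", {
  s <- make_series(intensity = rep(1, 6))
  expect_length(detect_broadening(s), 0)

  # 50% attenuation at residues 70-75, threshold 0.7
  res <- 60:90
  s2 <- make_series(residues = res, dsat_H = rep(0, length(res)),
                    intensity = rep(1, length(res)))
  last <- length(s2$points)
  att <- s2$points[[last]]$residue %in% 70:75
  s2$points[[last]]$intensity[att] <- 0.5
  expect_identical(detect_broadening(s2, ratio_threshold = 0.7), 70:75)

  # a residue that shifts strongly but keeps intensity is not broadened
  s3 <- generate_titration(seed = 12)
  found <- detect_broadening(s3)
  expect_true(all(found >= 61 & found <= 95))
  expect_setequal(found, c(65, 70, 71, 74, 80, 85))

  # zero baseline intensity is skipped with a warning
  s4 <- make_series(intensity = c(0, rep(1, 5)))
  expect_warning(detect_broadening(s4), "zero baseline")
})
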