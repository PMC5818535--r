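test_that("all generators are byte-reproducible under a fixed seed", {
  gens <- list(
    titration = function(s) generate_titration(seed = s),
    cest = function(s) generate_cest(seed = s, residues = c(1, 70, 120)),
    storm = function(s) generate_synaptosome_locs(seed = s,
                                                  n_synaptosomes = 2),
    vesicles = function(s) generate_vesicle_field(seed = s, preset = "egta",
                                                  n_vesicles = 100),
    tht = function(s) generate_tht(seed = s, preset = "ca_only", n_wells = 2),
    ms = function(s) generate_spectrum(seed = s)
  )
  for (nm in names(gens)) {
    a <- gens[[nm]](7)
    b <- gens[[nm]](7)
    expect_identical(a, b, info = nm)
    expect_false(identical(a, gens[[nm]](8)), info = nm)
    expect_false(is.null(attr(a, "truth")), info = nm)
  }
})

test_that("generators leave the global RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_vesicle_field(seed = 1, preset = "egta",
                                   n_vesicles = 50))
  expect_identical(.Random.seed, before)
})

test_that("written files are byte-identical across reruns", {
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_locs_csv(generate_vesicle_field(seed = 3, preset = "calcium"), f1)
  write_locs_csv(generate_vesicle_field(seed = 3, preset = "calcium"), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("titration generator honors site lists and validates them", {
  expect_error(generate_titration(sites = c(10, 200)), "outside")
  # perturbation confined to the C terminus
  s2 <- generate_titration(seed = 2, sites = c(100, 120, 139))
  expect_true(all(rank_perturbed_residues(s2, top_k = 3) %in%
                    c(100, 120, 139)))
  truth <- attr(s2, "truth")
  expect_identical(sort(truth$sites), c(100, 120, 139))
  # zero noise reproduces the binding model exactly
  s3 <- generate_titration(seed = 2, K_D = 40, L = 3, noise = 0,
                           sites = c(120))
  f <- fit_binding(s3, residues = 120)
  expect_equal(f$K_D, 40, tolerance = 1e-4)
  expect_equal(f$L, 3, tolerance = 1e-4)
})

test_that("CEST generator is flat far off resonance without binding", {
  cest <- generate_cest(seed = 1, residues = 1:2,
                        pb_no_ca = c(N_terminus = 0, NAC = 0, C_terminus = 0),
                        noise = 0)
  parts <- split_cest_reference(cest$no_ca)
  norm <- normalize_cest(parts$saturated, parts$reference)
  # away from the direct-saturation notch the profile sits at 1
  far <- norm$intensity[abs(norm$offset_kHz) >= 3]
  expect_equal(far, rep(1, length(far)), tolerance = 0.02)
})

test_that("vesicle generator rejects impossible densities and bad fractions", {
  expect_error(generate_vesicle_field(seed = 1, preset = "egta",
                                      n_vesicles = 4000,
                                      field_nm = 5000), "packing")
  expect_error(generate_vesicle_field(seed = 1,
                                      fractions = c(single = 0.5, pair = 0.2,
                                                    multi = 0.2)), "sum to 1")
  f1 <- generate_vesicle_field(seed = 1, fractions = c(single = 1, pair = 0,
                                                       multi = 0),
                               n_vesicles = 80)
  expect_equal(classify_clusters(f1)$pct_singles, 100)
})

test_that("ThT generator uses the plate-reader time grid", {
  d <- generate_tht(seed = 1, preset = "ca_only", n_wells = 2)
  one <- d[d$well == "W01", ]
  expect_equal(nrow(one), 300)
  expect_equal(diff(one$time_h)[1], 16 / 60, tolerance = 1e-12)
  expect_setequal(unique(d$well), c("W01", "W02"))
})

test_that("spectrum generator spans the requested charge envelope", {
  sp <- generate_spectrum(seed = 1, n_ca_max = 0, noise = 0)
  # apo envelope only: peaks at (M + z mp)/z for z = 9..19
  for (z in c(9, 14, 19)) {
    target <- theoretical_mz(14460, 0, z)
    i <- which.min(abs(sp$mz - target))
    expect_gt(sp$intensity[i], 0.1 * max(sp$intensity))
  }
  expect_identical(count_stoichiometry(
    charge_deconvolve(sp, mass_range = c(14400, 14600)), 14460), 0L)
})
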