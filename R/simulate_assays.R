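# Synthetic assay data: ThT plate-reader time courses from the Finke-Watzky
# model and multi-charge-state ESI ion envelopes with calcium adducts.

# Per-condition kinetic presets in per-hour units. The transition sharpness
# lambda = k1 + k2*A0 and the tangent lag are chosen to land near the
# reference lag times of the four experimental arms; k1 is solved from the
# closed-form inflection-tangent lag. The reference rate-constant values
# themselves are printed in units that cannot be reconciled with the 16-min
# sampling interval and are not reproduced.
THT_PRESETS <- list(
  ca_only  = list(lag_h = 3.95,  lambda = 1.0),
  ca_sv    = list(lag_h = 5.55,  lambda = 1.2),
  egta_sv  = list(lag_h = 44.72, lambda = 0.45),
  egta_only = list(lag_h = 78.95, lambda = 0.40)
)

# Solve k1 (with k2 = (lambda - k1)/A0) so the closed-form tangent lag equals
# lag_h at transition sharpness lambda.
tht_params_for_lag <- function(lag_h, lambda, A0 = 100) {
  f <- function(k1) fw_lag_closed_form(A0, k1, (lambda - k1) / A0) - lag_h
  k1 <- stats::uniroot(f, c(1e-18, lambda * 0.5), tol = 1e-20)$root
  list(A0 = A0, k1 = k1, k2 = (lambda - k1) / A0)
}

#' Generate synthetic ThT aggregation curves
#'
#' Evaluates the Finke-Watzky model on the plate-reader time grid (one
#' reading every 16 min for `n_cycles` cycles) for `n_wells` replicate wells,
#' adding a per-well baseline offset and multiplicative noise.
#'
#' @param seed RNG seed.
#' @param preset one of `"ca_only"`, `"ca_sv"`, `"egta_sv"`, `"egta_only"`;
#'   or `NULL` to pass `A0`, `k1`, `k2` directly.
#' @param A0,k1,k2 model parameters (signal units, /h, /(h*unit)); used when
#'   `preset` is NULL.
#' @param n_wells replicate wells (default 18).
#' @param n_cycles readings per well at 16-min spacing (default 300).
#' @param baseline_range per-well baseline offset range, signal units.
#' @param noise multiplicative Gaussian noise SD (default 0.02).
#' @param condition condition label (defaults to the preset name).
#' @return long-format data frame `time_h, well, condition, fluorescence`
#'   with a `truth` attribute carrying the generating parameters and the
#'   closed-form tangent lag.
#' @export
generate_tht <- function(seed = 1, preset = c("ca_only", "ca_sv", "egta_sv",
                                              "egta_only"),
                         A0 = NULL, k1 = NULL, k2 = NULL,
                         n_wells = 18, n_cycles = 300,
                         baseline_range = c(5, 15), noise = 0.02,
                         condition = NULL) {
  if (is.null(A0)) {
    preset <- match.arg(preset)
    p <- THT_PRESETS[[preset]]
    pars <- tht_params_for_lag(p$lag_h, p$lambda)
    A0 <- pars$A0; k1 <- pars$k1; k2 <- pars$k2
    if (is.null(condition)) condition <- preset
  } else {
    if (is.null(condition)) condition <- "custom"
  }
  t <- (seq_len(n_cycles) - 1) * 16 / 60
  signal <- fw_model(t, A0, k1, k2)
  with_seed(seed, {
    wells <- lapply(seq_len(n_wells), function(w) {
      base <- stats::runif(1, baseline_range[1], baseline_range[2])
      data.frame(time_h = t, well = sprintf("W%02d", w),
                 condition = condition,
                 fluorescence = base +
                   signal * (1 + stats::rnorm(length(t), 0, noise)))
    })
    structure(do.call(rbind, wells),
              truth = list(seed = seed, condition = condition, A0 = A0,
                           k1 = k1, k2 = k2,
                           lag_h = fw_lag_closed_form(A0, k1, k2),
                           n_wells = n_wells, n_cycles = n_cycles,
                           noise = noise))
  })
}

#' Generate a synthetic ESI spectrum of protein-calcium complexes
#'
#' Places Gaussian peaks at the theoretical m/z of every species with
#' 0..`n_ca_max` bound calcium ions across the 9+ to 19+ charge envelope,
#' with geometric abundance decay in the adduct number and a bell-shaped
#' charge-state envelope, plus optional uniform baseline noise.
#'
#' @param seed RNG seed.
#' @param protein_mass neutral average protein mass, Da (default 14460).
#' @param n_ca_max maximum calcium stoichiometry (default 6).
#' @param z_range charge states (default 9:19).
#' @param adduct_decay abundance ratio between consecutive adduct numbers
#'   (default 0.65).
#' @param peak_sd Gaussian peak SD in Th (default 0.02).
#' @param mz_step m/z sampling step in Th (default 0.01).
#' @param noise baseline noise amplitude as a fraction of the maximum peak
#'   (default 0.03; set 0 for a noiseless envelope).
#' @return data frame `mz, intensity` with a `truth` attribute (species
#'   masses and stoichiometries).
#' @export
generate_spectrum <- function(seed = 1, protein_mass = 14460, n_ca_max = 6,
                              z_range = 9:19, adduct_decay = 0.65,
                              peak_sd = 0.02, mz_step = 0.01, noise = 0.03) {
  stopifnot(n_ca_max >= 0)
  n_ca <- 0:n_ca_max
  species_mass <- protein_mass + n_ca * CA_ADDUCT_SHIFT
  z_weight <- stats::dnorm(z_range, mean = mean(z_range), sd = 3)
  z_weight <- z_weight / max(z_weight)
  centers <- outer(n_ca, z_range, function(n, z) theoretical_mz(protein_mass, n, z))
  heights <- outer(adduct_decay^n_ca, z_weight)
  mz <- seq(min(centers) - 2, max(centers) + 2, by = mz_step)
  intensity <- numeric(length(mz))
  for (i in seq_along(centers)) {
    ctr <- centers[i]
    sel <- which(mz >= ctr - 5 * peak_sd & mz <= ctr + 5 * peak_sd)
    intensity[sel] <- intensity[sel] +
      heights[i] * exp(-(mz[sel] - ctr)^2 / (2 * peak_sd^2))
  }
  with_seed(seed, {
    if (noise > 0) {
      intensity <- intensity + stats::runif(length(mz), 0, noise * max(intensity))
    }
    structure(data.frame(mz = mz, intensity = intensity),
              truth = list(seed = seed, protein_mass = protein_mass,
                           n_ca_max = n_ca_max, z_range = z_range,
                           species_mass = species_mass, noise = noise))
  })
}
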