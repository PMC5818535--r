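# Average masses used throughout the intact-protein regime.
MASS_CA <- 40.078      # average calcium, Da
MASS_PROTON <- 1.00728 # proton, Da
# Each bound Ca2+ displaces two protons, so one calcium adds this much mass
# to the neutral species.
CA_ADDUCT_SHIFT <- MASS_CA - 2 * MASS_PROTON

#' Theoretical m/z of a protein-calcium complex
#'
#' Charge-balanced adduct model: each bound Ca2+ displaces two protons and the
#' observed ion carries `z` protons net, giving
#' m/z = (M + n_ca * m_Ca - 2 n_ca * m_p + z * m_p) / z with average masses
#' m_Ca = 40.078 Da and m_p = 1.00728 Da.
#'
#' @param protein_mass neutral average protein mass, Da.
#' @param n_ca number of bound calcium ions (>= 0).
#' @param z positive charge state (>= 1).
#' @return m/z in Th.
#' @export
theoretical_mz <- function(protein_mass, n_ca, z) {
  stopifnot(all(z >= 1), all(n_ca >= 0), protein_mass > 0)
  (protein_mass + n_ca * MASS_CA - 2 * n_ca * MASS_PROTON + z * MASS_PROTON) / z
}

#' Charge deconvolution of an ESI ion envelope
#'
#' Grid search over candidate neutral masses: for each mass M on the grid, the
#' intensities within `tolerance` of the theoretical m/z = (M + z m_p)/z are
#' summed at every charge in `z_range`; local maxima of that evidence score
#' above the noise floor, with support at a minimum number of charge states,
#' become deconvolved species.
#'
#' @param spectrum data frame `mz, intensity`, mz ascending.
#' @param z_range integer charge states considered (default 9:19).
#' @param mass_range candidate neutral mass range in Da; `NULL` derives it
#'   from the m/z range at the extreme charges.
#' @param mass_step mass grid step, Da (default 0.2).
#' @param tolerance m/z matching tolerance, Th (default 0.05).
#' @param noise_mult noise floor on the evidence score: median plus
#'   `noise_mult` x MAD of the per-mass scores (default 3), so that the floor
#'   tracks the baseline of the score trace rather than single-sample
#'   intensities.
#' @param min_charges minimum supporting charge states per species (default:
#'   all but one of `z_range`). Harmonic artifact masses coincide with
#'   genuine peaks at only a few charges, so near-full support across the
#'   envelope is the strongest artifact filter.
#' @param baseline_window width, in samples, of the rolling-median baseline
#'   subtracted from the spectrum before scoring (default 201; 0 disables).
#'   Without it, baseline noise summed over all charge windows drowns the
#'   weakest species and promotes noise bumps to species on wide mass grids.
#' @param rel_floor additional floor as a fraction of the strongest species
#'   score (default 0.02), guarding against residual noise when the robust
#'   floor degenerates on mostly-empty mass grids.
#' @return data frame `mass, abundance, n_charges_supporting`, by decreasing
#'   abundance; zero rows for an empty spectrum.
#' @export
charge_deconvolve <- function(spectrum, z_range = 9:19, mass_range = NULL,
                              mass_step = 0.2, tolerance = 0.05,
                              noise_mult = 3,
                              min_charges = max(2, length(z_range) - 1),
                              baseline_window = 201, rel_floor = 0.02) {
  empty <- data.frame(mass = numeric(0), abundance = numeric(0),
                      n_charges_supporting = integer(0))
  if (nrow(spectrum) == 0) return(empty)
  mz <- spectrum$mz
  intensity <- spectrum$intensity
  if (baseline_window > 1 && length(intensity) > baseline_window) {
    k <- baseline_window + (1 - baseline_window %% 2)  # odd
    # keep the residual zero-mean: clamping negatives would bias the summed
    # evidence upward by half the noise amplitude per sample
    intensity <- intensity - stats::runmed(intensity, k)
  }
  if (is.null(mass_range)) {
    mass_range <- c(min(mz) * min(z_range) - max(z_range) * MASS_PROTON,
                    max(mz) * max(z_range))
  }
  grid <- seq(mass_range[1], mass_range[2], by = mass_step)
  score <- numeric(length(grid))
  support <- integer(length(grid))
  csum <- c(0, cumsum(intensity))
  for (z in z_range) {
    target <- (grid + z * MASS_PROTON) / z
    lo <- findInterval(target - tolerance, mz)
    hi <- findInterval(target + tolerance, mz)
    s_z <- csum[hi + 1] - csum[lo + 1]
    score <- score + s_z
    # a charge state supports a mass only when its window rises above that
    # charge's own noise level; this rejects harmonic masses that coincide
    # with genuine peaks at just one or two charges
    support <- support + (s_z > 3 * stats::mad(s_z))
  }
  floor_val <- max(stats::median(score) + noise_mult * stats::mad(score),
                   rel_floor * max(score))
  if (!is.finite(floor_val) || floor_val <= 0) floor_val <- 1e-9 * max(score)
  is_peak <- score > floor_val & support >= min_charges
  # local maxima on the grid
  left <- c(-Inf, score[-length(score)])
  right <- c(score[-1], -Inf)
  is_peak <- is_peak & score >= left & score > right
  if (!any(is_peak)) return(empty)
  out <- data.frame(mass = grid[is_peak], abundance = score[is_peak],
                    n_charges_supporting = support[is_peak])
  # greedy de-duplication: keep the strongest peak, drop anything within 2 Da
  # of an already kept peak
  out <- out[order(-out$abundance), ]
  kept <- integer(0)
  for (i in seq_len(nrow(out))) {
    if (length(kept) == 0 || min(abs(out$mass[kept] - out$mass[i])) > 2) {
      kept <- c(kept, i)
    }
  }
  out <- out[kept, ]
  rownames(out) <- NULL
  out
}

#' Maximum calcium stoichiometry from deconvolved species
#'
#' Assigns each deconvolved mass the nearest rung of the calcium-adduct
#' ladder M + n * (m_Ca - 2 m_p), rejects assignments further than
#' `tolerance` from the ladder, and returns the largest accepted n (0 when
#' only the apo protein is present or the list is empty).
#'
#' @param species data frame from [charge_deconvolve()].
#' @param protein_mass neutral apo protein mass, Da.
#' @param tolerance assignment tolerance, Da (default 2).
#' @return integer maximum bound calcium count.
#' @export
count_stoichiometry <- function(species, protein_mass, tolerance = 2) {
  if (nrow(species) == 0) return(0L)
  n <- round((species$mass - protein_mass) / CA_ADDUCT_SHIFT)
  resid <- abs(species$mass - (protein_mass + n * CA_ADDUCT_SHIFT))
  ok <- n >= 0 & resid <= tolerance
  if (!any(ok)) return(0L)
  as.integer(max(n[ok]))
}
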