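# Synthetic NMR data: calcium titration peak lists and CEST intensity tables.

# C-terminal residues carrying the major calcium CSPs (default perturbation
# sites for the titration generator).
CSP_SITES_DEFAULT <- c(104, 107, 112, 119, 123, 124, 126, 127, 129, 130,
                       135, 136, 137)

# Calcium titration schedule (uM): 0 to 3.6 mM at fixed 200 uM protein.
TITRATION_CONCS_DEFAULT <- c(0, 100, 200, 400, 600, 800, 1200, 1600, 2400, 3600)

#' Generate a synthetic calcium titration series
#'
#' Simulates per-residue 1H/15N peak lists across a calcium titration of a
#' 140-residue protein at fixed protein concentration. Perturbation sites get
#' a saturation CSP drawn from `dsat_range` (weighted ppm), split between the
#' 1H and 15N axes consistently with the 0.15 nitrogen weighting; observed
#' shifts follow the multi-ligand binding model ([binding_model_chiB()]) with
#' multiplicative Gaussian noise on the perturbation. Exchange broadening is
#' emulated as intensity attenuation at `broadening_sites`, scaled by the
#' bound fraction.
#'
#' @param seed RNG seed (fixed seed gives identical output).
#' @param K_D,L ground-truth binding parameters (defaults: the reference fit,
#'   21 uM and 7.8).
#' @param protein_conc protein concentration, uM (default 200).
#' @param ligand_concs calcium concentrations, uM, strictly ascending from 0.
#' @param sites residues carrying CSPs (default: the 13 C-terminal sites).
#' @param dsat_range range of saturation weighted CSPs, ppm.
#' @param noise multiplicative Gaussian noise SD on the shift perturbation
#'   (default 0.01).
#' @param broadening_sites NAC residues losing intensity (default a fixed
#'   six-residue subset of aa 61-95).
#' @param broadening_loss fractional intensity loss at saturation
#'   (default 0.5).
#' @param n_residues protein length (default 140).
#' @return `titration_series` list (`protein_conc`, `ligand_concs`, `points`)
#'   with a `truth` attribute recording all ground-truth parameters.
#' @export
generate_titration <- function(seed = 1, K_D = 21, L = 7.8,
                               protein_conc = 200,
                               ligand_concs = TITRATION_CONCS_DEFAULT,
                               sites = CSP_SITES_DEFAULT,
                               dsat_range = c(0.08, 0.3),
                               noise = 0.01,
                               broadening_sites = c(65, 70, 71, 74, 80, 85),
                               broadening_loss = 0.5,
                               n_residues = 140) {
  if (!all(sites %in% seq_len(n_residues))) stop("perturbation sites outside 1..n_residues")
  if (!all(broadening_sites %in% seq_len(n_residues))) stop("broadening sites outside 1..n_residues")
  with_seed(seed, {
    res <- seq_len(n_residues)
    free_H <- stats::runif(n_residues, 7.9, 8.7)
    free_N <- stats::runif(n_residues, 110, 126)
    base_int <- stats::runif(n_residues, 0.8, 1.2)

    dsat <- numeric(n_residues)
    dsat[sites] <- stats::runif(length(sites), dsat_range[1], dsat_range[2])
    theta <- stats::runif(n_residues, 0.2, pi / 2 - 0.2)
    sgn_H <- sample(c(-1, 1), n_residues, replace = TRUE)
    sgn_N <- sample(c(-1, 1), n_residues, replace = TRUE)
    dsat_H <- sgn_H * dsat * sqrt(2) * cos(theta)
    dsat_N <- sgn_N * dsat * sqrt(2 / 0.15) * sin(theta)

    chi <- binding_model_chiB(protein_conc, ligand_concs, K_D, L)
    chi_max <- max(chi)
    points <- lapply(seq_along(ligand_concs), function(j) {
      eps_H <- stats::rnorm(n_residues, 0, noise)
      eps_N <- stats::rnorm(n_residues, 0, noise)
      atten <- rep(1, n_residues)
      if (chi_max > 0) {
        atten[broadening_sites] <- 1 - broadening_loss * chi[j] / chi_max
      }
      data.frame(residue = res,
                 delta_H = free_H + chi[j] * dsat_H * (1 + eps_H),
                 delta_N = free_N + chi[j] * dsat_N * (1 + eps_N),
                 intensity = base_int * atten *
                   (1 + stats::rnorm(n_residues, 0, noise)))
    })
    structure(list(protein_conc = protein_conc, ligand_concs = ligand_concs,
                   points = points),
              class = "titration_series",
              truth = list(seed = seed, K_D = K_D, L = L,
                           protein_conc = protein_conc, sites = sites,
                           delta_sat = stats::setNames(dsat[sites], sites),
                           noise = noise,
                           broadening_sites = broadening_sites,
                           broadening_loss = broadening_loss))
  })
}

# --- CEST ------------------------------------------------------------------

# Printed saturation offset schedule (kHz) and the far-off-resonance
# reference offset.
CEST_OFFSETS_KHZ <- c(-9, -7, -5, -4, -3, -1.5, 0, 1.5, 3, 4, 5, 7, 9)
CEST_REFERENCE_KHZ <- -100

# Steady signal of the visible state after CW saturation, from two-state
# Bloch-McConnell evolution. All rates in s^-1, offset in kHz relative to the
# resonance; w1 is the saturation field in Hz.
bm_visible_signal <- function(offset_khz, pB, w1 = 400, t_sat = 0.5,
                              R1 = 1.5, R2_free = 5, R2_bound = 700,
                              k_ex = 100) {
  pA <- 1 - pB
  om <- 2 * pi * offset_khz * 1000
  w1r <- 2 * pi * w1
  kAB <- k_ex * pB
  kBA <- k_ex * pA
  # state vector (MxA, MyA, MzA, MxB, MyB, MzB, 1); both states on resonance
  # relative to their own shift (the kHz offsets dwarf the ppm shift range)
  A <- matrix(0, 7, 7)
  A[1, ] <- c(-R2_free - kAB, -om, 0, kBA, 0, 0, 0)
  A[2, ] <- c(om, -R2_free - kAB, w1r, 0, kBA, 0, 0)
  A[3, ] <- c(0, -w1r, -R1 - kAB, 0, 0, kBA, R1 * pA)
  A[4, ] <- c(kAB, 0, 0, -R2_bound - kBA, -om, 0, 0)
  A[5, ] <- c(0, kAB, 0, om, -R2_bound - kBA, w1r, 0)
  A[6, ] <- c(0, 0, kAB, 0, -w1r, -R1 - kBA, R1 * pB)
  M0 <- c(0, 0, pA, 0, 0, pB, 1)
  M <- as.vector(Matrix::expm(A * t_sat) %*% M0)
  M[3] / pA
}

#' Generate synthetic CEST tables for the +/- calcium conditions
#'
#' Two-state Bloch-McConnell simulation of CW saturation transfer between free
#' protein and a broad vesicle-bound state, on the printed offset schedule
#' with a -100 kHz reference row, for two conditions that differ in their
#' per-region bound fractions. In the no-calcium condition the N terminus
#' carries the largest bound fraction; adding calcium raises the C-terminal
#' (and part of the NAC) bound fractions while leaving the N terminus
#' unchanged.
#'
#' @param seed RNG seed.
#' @param residues residues to simulate (default 1:140).
#' @param pb_no_ca,pb_ca named numeric: bound fraction per region
#'   (`N_terminus`, `NAC`, `C_terminus`) in the two conditions.
#' @param nac_enhanced_sites NAC residues whose +Ca bound fraction is raised
#'   to `pb_nac_enhanced`.
#' @param pb_nac_enhanced bound fraction at those sites under +Ca.
#' @param w1 saturation field, Hz (default 400).
#' @param t_sat saturation time, s (default 0.5).
#' @param noise Gaussian noise SD on normalized intensities (default 0.02).
#' @param offsets saturation offsets, kHz.
#' @return list with raw tables `with_ca` and `no_ca` (columns
#'   `residue, offset_kHz, intensity`, reference rows at -100 kHz) and a
#'   `truth` attribute with the per-residue bound fractions.
#' @export
generate_cest <- function(seed = 1, residues = 1:140,
                          pb_no_ca = c(N_terminus = 0.10, NAC = 0.04,
                                       C_terminus = 0.02),
                          pb_ca = c(N_terminus = 0.10, NAC = 0.04,
                                    C_terminus = 0.08),
                          nac_enhanced_sites = 76:85,
                          pb_nac_enhanced = 0.07,
                          w1 = 400, t_sat = 0.5, noise = 0.02,
                          offsets = CEST_OFFSETS_KHZ) {
  regions <- region_map()
  pb_for <- function(pb_regions, enhance) {
    pb <- pb_regions[region_of(residues, regions)]
    if (enhance) pb[residues %in% nac_enhanced_sites] <- pb_nac_enhanced
    stats::setNames(pb, residues)
  }
  pb1 <- pb_for(pb_no_ca, enhance = FALSE)
  pb2 <- pb_for(pb_ca, enhance = TRUE)
  with_seed(seed, {
    ref_level <- stats::setNames(stats::runif(length(residues), 80, 120),
                                 residues)
    simulate_condition <- function(pb) {
      # profiles only depend on the bound fraction: compute once per level
      levels <- sort(unique(pb))
      prof <- lapply(levels, function(p) {
        c(vapply(offsets, bm_visible_signal, numeric(1),
                 pB = p, w1 = w1, t_sat = t_sat),
          bm_visible_signal(CEST_REFERENCE_KHZ, pB = p, w1 = w1,
                            t_sat = t_sat))
      })
      rows <- lapply(seq_along(residues), function(i) {
        r <- residues[i]
        sig <- prof[[match(pb[[as.character(r)]], levels)]]
        sig <- sig * (1 + stats::rnorm(length(sig), 0, noise))
        data.frame(residue = r,
                   offset_kHz = c(offsets, CEST_REFERENCE_KHZ),
                   intensity = ref_level[[as.character(r)]] * sig)
      })
      do.call(rbind, rows)
    }
    structure(list(no_ca = simulate_condition(pb1),
                   with_ca = simulate_condition(pb2)),
              truth = list(seed = seed, pb_no_ca = pb1, pb_ca = pb2,
                           w1 = w1, t_sat = t_sat, noise = noise))
  })
}

#' Split a raw CEST table into saturated and reference parts
#'
#' @param raw table with reference rows at offset `ref_offset`.
#' @param ref_offset the reference offset, kHz (default -100).
#' @return list with `saturated` and `reference` (columns
#'   `residue, intensity`) suitable for [normalize_cest()].
#' @export
split_cest_reference <- function(raw, ref_offset = CEST_REFERENCE_KHZ) {
  is_ref <- raw$offset_kHz == ref_offset
  if (!any(is_ref)) stop("no reference rows at offset ", ref_offset)
  list(saturated = raw[!is_ref, ],
       reference = raw[is_ref, c("residue", "intensity")])
}
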