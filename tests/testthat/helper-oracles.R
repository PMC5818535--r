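# Independent oracles used to pin expected values.

# Mass-action oracle for the multi-ligand bound fraction: root-finding on the
# equilibrium K_D = [U][X]/[B] with totals P = [U] + [B] and C/L = [X] + [B],
# independent of the closed-form expression under test.
chiB_mass_action <- function(P, C, K_D, L) {
  cl <- C / L
  if (cl == 0) return(0)
  f <- function(b) (P - b) * (cl - b) - K_D * b
  upper <- min(P, cl)
  if (f(upper) == 0) return(upper / P)
  b <- stats::uniroot(f, c(0, upper), tol = 1e-13)$root
  b / P
}

# Inflection-tangent lag of the Finke-Watzky curve by numeric
# differentiation: locate the steepest point on a fine grid, refine the slope
# by central differences, extend the tangent to the zero baseline.
fw_lag_numeric <- function(A0, k1, k2, t_max = NULL) {
  lam <- k1 + k2 * A0
  if (is.null(t_max)) t_max <- 3 * log(k2 * A0 / max(k1, 1e-300)) / lam + 20 / lam
  tg <- seq(0, t_max, length.out = 20000)
  h <- tg[2] - tg[1]
  b <- fw_model(tg, A0, k1, k2)
  slope <- (b[-(1:2)] - b[seq_len(length(b) - 2)]) / (2 * h)
  i <- which.max(slope) + 1
  tt <- tg[i]
  s <- slope[i - 1]
  tt - b[i] / s
}

# Deterministic tiny titration series built by hand (no generator) for
# contract tests.
make_series <- function(concs = c(0, 50, 200, 800, 3200), residues = 1:6,
                        dsat_H = c(0, 0, 0.2, 0, 0.1, 0),
                        P = 200, K_D = 30, L = 5, intensity = NULL) {
  if (is.null(intensity)) intensity <- rep(1, length(residues))
  chi <- binding_model_chiB(P, concs, K_D, L)
  points <- lapply(chi, function(x) {
    data.frame(residue = residues,
               delta_H = 8 + x * dsat_H,
               delta_N = 115,
               intensity = intensity)
  })
  structure(list(protein_conc = P, ligand_concs = concs, points = points),
            class = "titration_series")
}
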