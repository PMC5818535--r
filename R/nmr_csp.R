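#' Weighted chemical shift perturbation
#'
#' Combines the amide 1H and 15N shift differences between a free and a bound
#' (or partially bound) state into a single weighted perturbation
#' \deqn{\Delta\delta = \sqrt{\tfrac{1}{2}(\delta_H^2 + 0.15\,\delta_N^2)}}
#' where \eqn{\delta_H}, \eqn{\delta_N} are the shift differences in ppm.
#' The 0.15 weight compensates the larger ppm range of the nitrogen dimension.
#'
#' @param free,bound data frames (or lists) with fields `residue`, `delta_H`,
#'   `delta_N` for the same residue(s) in the two states. Vectorized over rows.
#' @return data frame with columns `residue` and `delta_delta` (ppm, >= 0).
#' @export
compute_csp <- function(free, bound) {
  if (!all(free$residue == bound$residue)) {
    stop("residue mismatch between free and bound records")
  }
  dH <- bound$delta_H - free$delta_H
  dN <- bound$delta_N - free$delta_N
  data.frame(residue = free$residue,
             delta_delta = sqrt(0.5 * (dH^2 + 0.15 * dN^2)))
}

#' Bound fraction from observed and saturation shift perturbations
#'
#' \eqn{\chi_B = \Delta\delta_{obs} / \Delta\delta_{sat}}, clipped to [0, 1].
#' Values above 1 arise from noise when the observed perturbation exceeds the
#' saturation estimate; the number of clipped values is reported via a
#' `clipped` attribute and a message.
#'
#' @param delta_obs observed weighted CSP, ppm (>= 0; vectorized).
#' @param delta_sat saturation weighted CSP, ppm (> 0).
#' @return numeric vector of bound fractions in [0, 1].
#' @export
chi_B <- function(delta_obs, delta_sat) {
  if (any(delta_sat <= 0)) stop("delta_sat must be positive: bound fraction undefined")
  if (any(delta_obs < 0)) stop("delta_obs must be nonnegative")
  x <- delta_obs / delta_sat
  n_clip <- sum(x > 1)
  if (n_clip > 0) message(sprintf("chi_B: clipped %d value(s) > 1 to 1", n_clip))
  x <- pmin(pmax(x, 0), 1)
  attr(x, "clipped") <- n_clip
  x
}

#' Multi-ligand binding model for the bound fraction
#'
#' Closed-form bound fraction for the equilibrium in which L calcium ions bind
#' one protein molecule as a single ligand unit:
#' \deqn{\chi_B = \frac{P + C/L + K_D - \sqrt{(P + C/L + K_D)^2 - 4 P C / L}}{2P}}
#' with P the total protein concentration and C the total calcium
#' concentration. The discriminant is mathematically nonnegative; tiny
#' negative values from floating-point cancellation are clamped to zero with
#' a warning.
#'
#' @param protein_conc total protein concentration, uM (> 0).
#' @param ligand_conc total calcium concentration, uM (>= 0; vectorized).
#' @param K_D dissociation constant, uM (>= 0).
#' @param L number of calcium ions per protein (> 0, real-valued).
#' @return bound fraction(s) in [0, 1]; nondecreasing in `ligand_conc`.
#' @export
binding_model_chiB <- function(protein_conc, ligand_conc, K_D, L) {
  stopifnot(protein_conc > 0, L > 0, K_D >= 0, all(ligand_conc >= 0))
  P <- protein_conc
  cl <- ligand_conc / L
  S <- P + cl + K_D
  disc <- S^2 - 4 * P * cl
  if (any(disc < 0)) {
    warning("negative discriminant clamped to 0 (floating-point cancellation)")
    disc <- pmax(disc, 0)
  }
  chi <- (S - sqrt(disc)) / (2 * P)
  pmin(pmax(chi, 0), 1)
}

# Per-residue weighted CSPs relative to the first titration point, as a
# residues x concentrations matrix. Internal workhorse for the fit/ranking.
csp_matrix <- function(series) {
  validate_titration(series)
  free <- series$points[[1]]
  ord <- order(free$residue)
  free <- free[ord, ]
  m <- sapply(series$points, function(pt) {
    pt <- pt[order(pt$residue), ]
    compute_csp(free, pt)$delta_delta
  })
  rownames(m) <- free$residue
  m
}

validate_titration <- function(series) {
  stopifnot(is.list(series), !is.null(series$points),
            !is.null(series$ligand_concs), !is.null(series$protein_conc))
  if (series$protein_conc <= 0) stop("protein_conc must be positive")
  cc <- series$ligand_concs
  if (any(cc < 0) || is.unsorted(cc, strictly = TRUE)) {
    stop("ligand_concs must be nonnegative and strictly ascending")
  }
  if (length(series$points) != length(cc)) {
    stop("one point set per ligand concentration required")
  }
  res_sets <- lapply(series$points, function(p) sort(p$residue))
  if (!all(vapply(res_sets, identical, logical(1), res_sets[[1]]))) {
    stop("all concentrations must cover the same residue set")
  }
  invisible(series)
}

#' Select residues carrying the major perturbations
#'
#' Default residue-selection rule for the global fit: residues whose weighted
#' CSP at the highest calcium concentration exceeds mean + 2 SD over all
#' residues.
#'
#' @param series a titration series (see [generate_titration()]).
#' @return integer vector of residue indices.
#' @export
select_major_perturbations <- function(series) {
  dd <- csp_matrix(series)
  last <- dd[, ncol(dd)]
  as.integer(names(last)[last > mean(last) + 2 * stats::sd(last)])
}

#' Global multi-ligand binding fit of a calcium titration
#'
#' Jointly fits the dissociation constant `K_D`, the ligand number `L` and one
#' saturation perturbation per selected residue by bounded
#' Levenberg-Marquardt least squares, modelling each residue's weighted CSP at
#' calcium concentration C as
#' \eqn{\Delta\delta_{sat,r}\,\chi_B(C; K_D, L)} (see [binding_model_chiB()]).
#' Standard errors come from the Jacobian at the optimum.
#'
#' Starting values: by default a coarse variable-projection grid search over
#' (K_D, L) — the saturation shifts are linear given (K_D, L) and are profiled
#' out in closed form — selects the start, which avoids the local minimum at
#' the stoichiometric (K_D -> 0) corner that a fixed start can fall into when
#' K_D is well below the protein concentration. Pass `init` to override.
#'
#' @param series titration series; first point is taken as the free reference.
#' @param residues residues to include; `NULL` uses
#'   [select_major_perturbations()].
#' @param init named list with starting values `K_D` (uM) and `L`, or `NULL`
#'   (default) for the grid-searched start.
#' @param lower,upper bounds on `(K_D, L)`; saturation shifts are bounded
#'   below by 0.
#' @return list of class `binding_fit` with elements `K_D`, `L`, `se`
#'   (named, for K_D and L), `delta_sat` (named per residue), `residues_used`,
#'   `rss`, `fitted` (residues x concentrations matrix) and `convergence info`.
#' @export
fit_binding <- function(series, residues = NULL, init = NULL,
                        lower = c(K_D = 1e-6, L = 1e-6),
                        upper = c(K_D = 1e4, L = 50)) {
  validate_titration(series)
  if (length(series$ligand_concs) < 4) {
    stop("at least 4 titration points required for the global fit")
  }
  dd <- csp_matrix(series)
  if (is.null(residues)) residues <- select_major_perturbations(series)
  residues <- sort(as.integer(residues))
  if (length(residues) < 1) stop("no residues selected for the fit")
  dd <- dd[as.character(residues), , drop = FALSE]
  if (all(dd == 0)) {
    stop("no shift perturbation signal in selected residues; K_D unidentifiable")
  }
  concs <- series$ligand_concs
  P <- series$protein_conc
  nr <- length(residues)

  obs <- as.vector(dd)  # residues fastest, then concentrations
  resid_fun <- function(par) {
    chi <- binding_model_chiB(P, concs, par[1], par[2])
    model <- outer(par[-(1:2)], chi)
    as.vector(model) - obs
  }
  if (is.null(init)) {
    # profile out the (linear) saturation shifts on a log grid over (K_D, L)
    kd_grid <- exp(seq(log(max(lower[["K_D"]], 0.1)), log(upper[["K_D"]]),
                       length.out = 25))
    l_grid <- exp(seq(log(max(lower[["L"]], 0.5)), log(upper[["L"]]),
                      length.out = 25))
    best <- NULL
    for (kd in kd_grid) for (l in l_grid) {
      chi <- binding_model_chiB(P, concs, kd, l)
      cc <- sum(chi^2)
      if (cc == 0) next
      dsat <- pmax(as.vector(dd %*% chi) / cc, 0)
      rss <- sum((dd - outer(dsat, chi))^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(K_D = kd, L = l, dsat = dsat, rss = rss)
      }
    }
    start <- c(best$K_D, best$L, best$dsat)
  } else {
    start <- c(init$K_D, init$L, dd[, ncol(dd)])
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    lower = c(lower[["K_D"]], lower[["L"]], rep(0, nr)),
    upper = c(upper[["K_D"]], upper[["L"]], rep(Inf, nr)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info < 1 || fit$info > 4) {
    stop("binding fit did not converge: ", fit$message)
  }
  par <- fit$par
  # SEs from the Gauss-Newton approximation of the covariance
  dof <- length(obs) - length(par)
  sig2 <- fit$deviance / max(dof, 1)
  vcov <- tryCatch(sig2 * solve(fit$hessian / 2), error = function(e) NULL)
  se <- if (is.null(vcov)) rep(NA_real_, 2) else sqrt(pmax(diag(vcov)[1:2], 0))
  chi_hat <- binding_model_chiB(P, concs, par[1], par[2])
  structure(list(
    K_D = par[1], L = par[2],
    se = c(K_D = se[1], L = se[2]),
    delta_sat = stats::setNames(par[-(1:2)], residues),
    residues_used = residues,
    rss = fit$deviance,
    fitted = outer(stats::setNames(par[-(1:2)], residues), chi_hat,
                   FUN = `*`),
    info = fit$info, message = fit$message
  ), class = "binding_fit")
}

#' @method print binding_fit
#' @export
print.binding_fit <- function(x, ...) {
  cat("Global multi-ligand binding fit\n")
  cat(sprintf("  K_D = %.3g uM (SE %.2g)\n", x$K_D, x$se[["K_D"]]))
  cat(sprintf("  L   = %.3g Ca2+ per protein (SE %.2g)\n", x$L, x$se[["L"]]))
  cat(sprintf("  %d residue(s) in fit, RSS = %.3g\n",
              length(x$residues_used), x$rss))
  invisible(x)
}

#' Rank residues by chemical shift perturbation
#'
#' Sorts residues by their weighted CSP at the highest ligand concentration
#' and returns either the `top_k` most perturbed or all residues above a
#' threshold.
#'
#' @param series titration series with at least 2 concentrations.
#' @param top_k number of residues to return (mutually exclusive with
#'   `threshold`).
#' @param threshold minimum weighted CSP in ppm.
#' @return integer residue indices, most perturbed first; empty when nothing
#'   exceeds the threshold.
#' @export
rank_perturbed_residues <- function(series, top_k = NULL, threshold = NULL) {
  validate_titration(series)
  if (length(series$ligand_concs) < 2) stop("need at least 2 concentrations")
  if (is.null(top_k) == is.null(threshold)) {
    stop("supply exactly one of top_k or threshold")
  }
  dd <- csp_matrix(series)
  last <- sort(dd[, ncol(dd)], decreasing = TRUE)
  if (!is.null(threshold)) last <- last[last > threshold]
  if (!is.null(top_k)) last <- utils::head(last, top_k)
  as.integer(names(last))
}

#' Detect exchange-broadened residues from intensity loss
#'
#' Flags residues whose peak intensity at the highest calcium concentration
#' drops below `ratio_threshold` of the zero-calcium intensity, excluding
#' residues whose weighted CSP exceeds `shift_cut` (those are shifted, not
#' broadened). Residues with zero baseline intensity are skipped with a
#' warning.
#'
#' @param series titration series with intensities at first and last point.
#' @param ratio_threshold intensity ratio below which a residue counts as
#'   broadened (default 0.7).
#' @param shift_cut weighted CSP (ppm) above which a residue is treated as
#'   shifted rather than broadened (default 0.05).
#' @return integer residue indices, ascending.
#' @export
detect_broadening <- function(series, ratio_threshold = 0.7, shift_cut = 0.05) {
  validate_titration(series)
  first <- series$points[[1]]
  last <- series$points[[length(series$points)]]
  first <- first[order(first$residue), ]
  last <- last[order(last$residue), ]
  if (is.null(first$intensity) || is.null(last$intensity)) {
    stop("intensities required at first and last concentration")
  }
  zero_base <- first$intensity <= 0
  if (any(zero_base)) {
    warning(sprintf("skipping %d residue(s) with zero baseline intensity",
                    sum(zero_base)))
  }
  ratio <- last$intensity / first$intensity
  dd <- csp_matrix(series)
  shifted <- dd[, ncol(dd)] > shift_cut
  sel <- !zero_base & ratio < ratio_threshold & !shifted
  sort(first$residue[sel])
}
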