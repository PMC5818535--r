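# Synthetic imaging data: dSTORM localization tables inside synaptosome-scale
# discs and STED vesicle coordinate fields with controlled cluster fractions.

#' Generate a synthetic synaptosome localization table
#'
#' Places circular synaptosome ROIs (~700 nm diameter) in a square field and
#' draws emitters per disc either from compact Gaussian sub-clusters
#' (`preset = "clustered"`, polarized labeling) or from a single broad central
#' Gaussian spanning the synaptosome interior (`preset = "dispersed"`, SD =
#' half the disc radius), so the dispersed condition's characteristic cluster
#' scale is the synaptosome itself. Isotropic Gaussian localization noise is
#' added to every emitter.
#'
#' @param seed RNG seed.
#' @param preset `"clustered"` or `"dispersed"`.
#' @param n_synaptosomes number of discs (default 6).
#' @param field_nm square field side, nm (default 10000).
#' @param disc_diameter_nm synaptosome diameter, nm (default 700).
#' @param n_locs localizations per synaptosome (default 300).
#' @param n_subclusters sub-clusters per disc for the clustered preset
#'   (default 4).
#' @param cluster_sigma_nm sub-cluster Gaussian SD, nm (default 30).
#' @param loc_noise_nm localization precision SD, nm (default 10).
#' @return data frame `x_nm, y_nm` with a `truth` attribute (disc centers,
#'   preset, and all geometry parameters).
#' @export
generate_synaptosome_locs <- function(seed = 1,
                                      preset = c("clustered", "dispersed"),
                                      n_synaptosomes = 6, field_nm = 10000,
                                      disc_diameter_nm = 700, n_locs = 300,
                                      n_subclusters = 4, cluster_sigma_nm = 30,
                                      loc_noise_nm = 10) {
  preset <- match.arg(preset)
  R <- disc_diameter_nm / 2
  with_seed(seed, {
    centers <- place_centers(n_synaptosomes, field_nm,
                             min_dist = 2.5 * disc_diameter_nm,
                             margin = disc_diameter_nm)
    pts <- lapply(seq_len(n_synaptosomes), function(i) {
      ctr <- centers[i, ]
      if (preset == "dispersed") {
        # broad spread across the synaptosome interior, truncated to the disc
        s <- R / 2
        xy <- matrix(numeric(0), ncol = 2)
        while (nrow(xy) < n_locs) {
          cand <- cbind(stats::rnorm(n_locs, ctr[1], s),
                        stats::rnorm(n_locs, ctr[2], s))
          inside <- (cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2 <= R^2
          xy <- rbind(xy, cand[inside, , drop = FALSE])
        }
        xy <- xy[seq_len(n_locs), , drop = FALSE]
        colnames(xy) <- c("x", "y")
      } else {
        sub <- runif_region(n_subclusters,
                            list(shape = "disc", center = ctr,
                                 radius = R - 3 * cluster_sigma_nm))
        assign_to <- sample.int(n_subclusters, n_locs, replace = TRUE)
        xy <- cbind(x = sub[assign_to, 1] + stats::rnorm(n_locs, 0, cluster_sigma_nm),
                    y = sub[assign_to, 2] + stats::rnorm(n_locs, 0, cluster_sigma_nm))
      }
      xy
    })
    xy <- do.call(rbind, pts)
    out <- data.frame(x_nm = xy[, 1] + stats::rnorm(nrow(xy), 0, loc_noise_nm),
                      y_nm = xy[, 2] + stats::rnorm(nrow(xy), 0, loc_noise_nm))
    if (nrow(out) == 0) out <- data.frame(x_nm = numeric(0), y_nm = numeric(0))
    structure(out,
              truth = list(seed = seed, preset = preset, centers = centers,
                           disc_diameter_nm = disc_diameter_nm,
                           n_locs = n_locs, n_subclusters = n_subclusters,
                           cluster_sigma_nm = cluster_sigma_nm,
                           loc_noise_nm = loc_noise_nm))
  })
}

# Dart-throwing placement of component centers with a minimum separation.
place_centers <- function(n, field_nm, min_dist, margin, max_tries = 5000) {
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < n) {
    tries <- tries + 1
    if (tries > max_tries * n) {
      stop("infeasible packing density: use a larger field or fewer components")
    }
    cand <- stats::runif(2, margin, field_nm - margin)
    if (nrow(centers) == 0 ||
        min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) >=
          min_dist) {
      centers <- rbind(centers, cand)
    }
  }
  dimnames(centers) <- list(NULL, c("x", "y"))
  centers
}

# Named single/pair/multi vesicle fractions per experimental condition.
# The singles fractions are the reported condition percentages; the split of
# the clustered remainder between pairs and larger clusters is a generator
# choice (about two thirds pairs).
VESICLE_PRESETS <- list(
  egta    = c(single = 0.88, pair = 0.08, multi = 0.04),
  calcium = c(single = 0.84, pair = 0.10, multi = 0.06),
  asyn_ca = c(single = 0.81, pair = 0.12, multi = 0.07)
)

#' Generate a synthetic vesicle field with controlled cluster fractions
#'
#' Places vesicles in a square field as isolated singles, pairs
#' (inter-distance uniform in 40-200 nm), and triples-and-larger clusters,
#' targeting the per-condition single/pair/multi fractions. Component centers
#' are kept at least 750 nm apart so that distinct components are never
#' linked at the 250 nm classification radius.
#'
#' @param seed RNG seed.
#' @param preset `"egta"`, `"calcium"`, or `"asyn_ca"`; or `NULL` to supply
#'   `fractions` directly.
#' @param fractions named vector `single, pair, multi` summing to 1 (used when
#'   `preset` is NULL).
#' @param n_vesicles total vesicles (default 300).
#' @param field_nm square field side, nm (default 20000).
#' @return data frame `x_nm, y_nm` with a `truth` attribute holding the
#'   realized fractions and component sizes.
#' @export
generate_vesicle_field <- function(seed = 1, preset = c("egta", "calcium",
                                                        "asyn_ca"),
                                   fractions = NULL, n_vesicles = 300,
                                   field_nm = 20000) {
  if (is.null(fractions)) {
    preset <- match.arg(preset)
    fractions <- VESICLE_PRESETS[[preset]]
  } else {
    preset <- "custom"
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be nonnegative and sum to 1")
  }
  n_single <- round(fractions[["single"]] * n_vesicles)
  n_pairs <- round(fractions[["pair"]] * n_vesicles / 2)
  n_multi_v <- n_vesicles - n_single - 2 * n_pairs
  # multi components of size 3, with one larger component absorbing remainder
  multi_sizes <- if (n_multi_v == 0) integer(0) else {
    k <- n_multi_v %/% 3
    sizes <- rep(3L, max(k, 1))
    sizes[1] <- sizes[1] + n_multi_v - sum(sizes)
    sizes[sizes >= 3]
  }
  sizes <- c(rep(1L, n_single), rep(2L, n_pairs), multi_sizes)
  with_seed(seed, {
    centers <- place_centers(length(sizes), field_nm, min_dist = 750,
                             margin = 250)
    idx <- sample(nrow(centers))  # shuffle component positions
    pts <- lapply(seq_along(sizes), function(i) {
      ctr <- centers[idx[i], ]
      s <- sizes[i]
      if (s == 1) return(matrix(ctr, ncol = 2))
      if (s == 2) {
        d <- stats::runif(1, 40, 200)
        th <- stats::runif(1, 0, 2 * pi)
        off <- c(cos(th), sin(th)) * d / 2
        return(rbind(ctr + off, ctr - off))
      }
      # larger cluster: members on a tight ring, neighbors within 40-200 nm
      th0 <- stats::runif(1, 0, 2 * pi)
      th <- th0 + 2 * pi * seq_len(s) / s
      ring_r <- stats::runif(1, 50, 90)
      cbind(ctr[1] + ring_r * cos(th), ctr[2] + ring_r * sin(th))
    })
    xy <- do.call(rbind, pts)
    out <- data.frame(x_nm = xy[, 1], y_nm = xy[, 2])
    realized <- c(single = n_single, pair = 2 * n_pairs,
                  multi = sum(multi_sizes)) / nrow(out)
    structure(out,
              truth = list(seed = seed, preset = preset,
                           target_fractions = as.list(fractions),
                           realized_fractions = as.list(realized),
                           component_sizes = sizes, field_nm = field_nm))
  })
}
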