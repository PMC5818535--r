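#' Run the simulate-then-analyze pipeline end to end
#'
#' Executes the requested stages on seeded synthetic inputs, writes per-stage
#' CSV/JSON outputs plus `truth.json` sidecars under `out_dir`, and returns a
#' combined run report (also written as `report.json`). Each stage derives
#' its own seed from the run seed so stage selections do not shift one
#' another's random streams. A run log records the package version, seed, and
#' a hash of the full configuration.
#'
#' @param stages character subset of
#'   `c("titration", "cest", "storm", "vesicles", "tht", "ms")`.
#' @param seed integer run seed.
#' @param out_dir output directory (created if needed).
#' @param params optional named list of per-stage argument overrides passed to
#'   the stage's generator, e.g. `list(titration = list(noise = 0.02))`.
#' @param quiet suppress progress messages.
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(stages = c("titration", "cest", "storm", "vesicles",
                                    "tht", "ms"),
                         seed = 1, out_dir = "pipeline_out", params = list(),
                         quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(stages = stages, seed = seed, params = params)
  say <- function(...) if (!quiet) message(sprintf(...))
  log_lines <- c(sprintf("synucalc %s", as.character(utils::packageVersion("synucalc"))),
                 sprintf("seed %d", seed),
                 sprintf("config hash %s", config_hash(config)))
  report <- list(package_version = as.character(utils::packageVersion("synucalc")),
                 seed = seed, config_hash = config_hash(config),
                 stages = list())
  stage_seed <- function(k) seed * 100 + k

  runners <- list(
    titration = function() {
      args <- utils::modifyList(list(seed = stage_seed(1)),
                                params$titration %||% list())
      series <- do.call(generate_titration, args)
      write_peaklist_csv(series, file.path(out_dir, "titration_peaks.csv"))
      write_truth_json(series, file.path(out_dir, "titration_truth.json"))
      fit <- fit_binding(series)
      write_binding_report(fit, series,
                           file.path(out_dir, "titration_fit.csv"),
                           file.path(out_dir, "titration_fit.json"))
      list(K_D_uM = fit$K_D, L = fit$L, n_residues = length(fit$residues_used))
    },
    cest = function() {
      args <- utils::modifyList(list(seed = stage_seed(2)),
                                params$cest %||% list())
      cest <- do.call(generate_cest, args)
      write_cest_csv(cest$no_ca, file.path(out_dir, "cest_no_ca.csv"))
      write_cest_csv(cest$with_ca, file.path(out_dir, "cest_with_ca.csv"))
      write_truth_json(cest, file.path(out_dir, "cest_truth.json"))
      score_one <- function(raw) {
        parts <- split_cest_reference(raw)
        cest_score(normalize_cest(parts$saturated, parts$reference))
      }
      s_ca <- score_one(cest$with_ca)
      s_no <- score_one(cest$no_ca)
      cmp <- compare_regions(s_ca, s_no)
      utils::write.csv(cmp, file.path(out_dir, "cest_region_comparison.csv"),
                       row.names = FALSE)
      as.list(stats::setNames(cmp$mean_diff, paste0("diff_", cmp$region)))
    },
    storm = function() {
      args <- utils::modifyList(list(seed = stage_seed(3)),
                                params$storm %||% list())
      locs <- do.call(generate_synaptosome_locs, args)
      write_locs_csv(locs, file.path(out_dir, "storm_locs.csv"))
      write_truth_json(locs, file.path(out_dir, "storm_truth.json"))
      rois <- segment_rois(locs)
      radii <- vapply(rois, function(p) {
        cluster_radius(p, seed = stage_seed(3))$radius
      }, numeric(1))
      utils::write.csv(data.frame(roi = seq_along(radii), radius_nm = radii),
                       file.path(out_dir, "storm_radii.csv"), row.names = FALSE)
      list(n_rois = length(rois), mean_radius_nm = mean(radii))
    },
    vesicles = function() {
      args <- utils::modifyList(list(seed = stage_seed(4)),
                                params$vesicles %||% list())
      field <- do.call(generate_vesicle_field, args)
      write_locs_csv(field, file.path(out_dir, "vesicle_spots.csv"))
      write_truth_json(field, file.path(out_dir, "vesicle_truth.json"))
      cls <- classify_clusters(field)
      utils::write.csv(cls, file.path(out_dir, "vesicle_classification.csv"),
                       row.names = FALSE)
      as.list(cls[, c("pct_singles", "pct_pairs", "pct_multi")])
    },
    tht = function() {
      args <- utils::modifyList(list(seed = stage_seed(5)),
                                params$tht %||% list())
      tht <- do.call(generate_tht, args)
      write_tht_csv(tht, file.path(out_dir, "tht_curves.csv"))
      write_truth_json(tht, file.path(out_dir, "tht_truth.json"))
      avg <- average_tht_curves(tht)[[1]]
      fit <- fit_fw(avg)
      lag <- lag_time_tangent(avg)
      jsonlite::write_json(list(A0 = fit$A0, k1 = fit$k1, k2 = fit$k2,
                                lag_h = lag$lag),
                           file.path(out_dir, "tht_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      list(k1 = fit$k1, k2 = fit$k2, lag_h = lag$lag)
    },
    ms = function() {
      args <- utils::modifyList(list(seed = stage_seed(6)),
                                params$ms %||% list())
      spec <- do.call(generate_spectrum, args)
      write_spectrum_csv(spec, file.path(out_dir, "spectrum.csv"))
      write_truth_json(spec, file.path(out_dir, "spectrum_truth.json"))
      truth <- attr(spec, "truth")
      species <- charge_deconvolve(spec,
                                   mass_range = truth$protein_mass + c(-50, 400))
      utils::write.csv(species, file.path(out_dir, "ms_species.csv"),
                       row.names = FALSE)
      list(n_species = nrow(species),
           max_stoichiometry = count_stoichiometry(species,
                                                   truth$protein_mass))
    }
  )

  for (st in stages) {
    say("stage %s ...", st)
    result <- tryCatch(runners[[st]](), error = function(e) {
      writeLines(c(log_lines, sprintf("stage %s FAILED: %s", st,
                                      conditionMessage(e))),
                 file.path(out_dir, "run.log"))
      stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
           call. = FALSE)
    })
    report$stages[[st]] <- result
    log_lines <- c(log_lines, sprintf("stage %s done", st))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
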