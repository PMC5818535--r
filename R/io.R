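# Readers and writers for the plain-text dialects used across the pipeline.
# All files are UTF-8 CSV with a header row.

#' Write / read a titration peak list
#'
#' Dialect: `residue,conc_uM,delta_H_ppm,delta_N_ppm,intensity`, one row per
#' residue per concentration.
#'
#' @param series a `titration_series` (see [generate_titration()]).
#' @param path file path.
#' @return `read_peaklist_csv` returns a `titration_series`; the protein
#'   concentration is given by `protein_conc` since the dialect does not
#'   carry it.
#' @export
write_peaklist_csv <- function(series, path) {
  rows <- do.call(rbind, lapply(seq_along(series$ligand_concs), function(j) {
    p <- series$points[[j]]
    data.frame(residue = p$residue, conc_uM = series$ligand_concs[j],
               delta_H_ppm = p$delta_H, delta_N_ppm = p$delta_N,
               intensity = p$intensity)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaklist_csv
#' @param protein_conc protein concentration in uM for the reconstructed
#'   series.
#' @export
read_peaklist_csv <- function(path, protein_conc) {
  d <- utils::read.csv(path)
  concs <- sort(unique(d$conc_uM))
  points <- lapply(concs, function(cc) {
    p <- d[d$conc_uM == cc, ]
    data.frame(residue = p$residue, delta_H = p$delta_H_ppm,
               delta_N = p$delta_N_ppm, intensity = p$intensity)
  })
  structure(list(protein_conc = protein_conc, ligand_concs = concs,
                 points = points), class = "titration_series")
}

#' Write / read a CEST intensity table
#'
#' Dialect: `residue,offset_kHz,intensity`; reference rows use offset -100.
#'
#' @param raw data frame in the dialect above.
#' @param path file path.
#' @export
write_cest_csv <- function(raw, path) {
  utils::write.csv(raw[, c("residue", "offset_kHz", "intensity")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cest_csv
#' @export
read_cest_csv <- function(path) {
  utils::read.csv(path)
}

#' Write / read localization and vesicle-spot coordinate tables
#'
#' Dialect: `x_nm,y_nm` (extra ThunderSTORM-style columns such as `frame` or
#' `uncertainty_nm` are preserved on read but ignored by the analyses).
#'
#' @param table coordinate data frame.
#' @param path file path.
#' @export
write_locs_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_locs_csv
#' @export
read_locs_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x_nm", "y_nm") %in% names(d))) {
    stop("localization table must have x_nm and y_nm columns")
  }
  d
}

#' Write / read long-format ThT plate data
#'
#' Dialect: `time_h,well,condition,fluorescence`.
#'
#' @param tht long-format data frame.
#' @param path file path.
#' @export
write_tht_csv <- function(tht, path) {
  utils::write.csv(tht[, c("time_h", "well", "condition", "fluorescence")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tht_csv
#' @export
read_tht_csv <- function(path) {
  utils::read.csv(path)
}

#' Write / read a two-column mass spectrum
#'
#' Dialect: `mz,intensity`, m/z ascending.
#'
#' @param spectrum data frame `mz, intensity`.
#' @param path file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(spectrum[, c("mz", "intensity")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  if (is.unsorted(d$mz)) d <- d[order(d$mz), ]
  d
}

#' Write a generator's ground-truth sidecar as JSON
#'
#' @param x any object produced by a generator (its `truth` attribute is
#'   written).
#' @param path file path (conventionally `truth.json`).
#' @export
write_truth_json <- function(x, path) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("object carries no truth attribute")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a binding-fit report
#'
#' Writes a per-residue CSV (`residue,delta_delta,delta_sat`) and a JSON
#' summary (`K_D_uM`, `L`, `se`, `residues_used`).
#'
#' @param fit a `binding_fit` from [fit_binding()].
#' @param series the fitted titration series (for the observed CSPs).
#' @param csv_path,json_path output paths.
#' @export
write_binding_report <- function(fit, series, csv_path, json_path) {
  dd <- csp_matrix(series)
  last <- dd[as.character(fit$residues_used), ncol(dd)]
  utils::write.csv(data.frame(residue = fit$residues_used,
                              delta_delta = unname(last),
                              delta_sat = unname(fit$delta_sat)),
                   csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(K_D_uM = fit$K_D, L = fit$L,
                            se = as.list(fit$se),
                            residues_used = fit$residues_used),
                       json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(json_path)
}
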