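# File-format adapters: NIfTI volumes with a JSON manifest for structure
# sets, CSV feature tables, JSON run summaries. The manifest's grid is
# authoritative when volume headers disagree (a warning is issued).

#' Write a structure set as NIfTI volumes plus a JSON manifest
#'
#' One `.nii.gz` per structure (uint8 0/1) and a `manifest.json` carrying
#' `patient_id`, `image_label` and the authoritative grid (shape, spacing,
#' origin, mm, patient frame +x left / +y posterior / +z superior).
#'
#' @param ss a [structure_set()].
#' @param dir output directory (created if needed).
#' @param patient_id identifier written to the manifest.
#' @return the manifest path, invisibly.
#' @export
write_structure_set <- function(ss, dir, patient_id = "patient") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (nm in names(ss$structures)) {
    f <- sprintf("%s_%s.nii.gz", ss$image_label, nm)
    arr <- array(as.integer(ss$structures[[nm]]), dim = ss$grid$shape)
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, ss$grid$spacing)
    RNifti::writeNifti(img, file.path(dir, f))
    files[[nm]] <- f
  }
  manifest <- list(patient_id = patient_id, image_label = ss$image_label,
                   grid = list(shape = ss$grid$shape, spacing = ss$grid$spacing,
                               origin = ss$grid$origin),
                   frame = "+x left, +y posterior, +z superior",
                   structures = files)
  path <- file.path(dir, sprintf("%s_manifest.json", ss$image_label))
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a structure set from a manifest written by [write_structure_set()]
#'
#' @param manifest_path path to the JSON manifest.
#' @return A [structure_set()].
#' @export
read_structure_set <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  grid <- voxel_grid(man$grid$shape, man$grid$spacing, man$grid$origin)
  dir <- dirname(manifest_path)
  structures <- lapply(man$structures, function(f) {
    img <- RNifti::readNifti(file.path(dir, f))
    arr <- as.array(img)
    if (!identical(dim(arr), grid$shape)) {
      stop(sprintf("volume '%s' does not match the manifest grid", f))
    }
    pd <- tryCatch(RNifti::pixdim(img), error = function(e) NULL)
    if (!is.null(pd) && length(pd) >= 3 &&
        !isTRUE(all.equal(as.numeric(pd[1:3]), grid$spacing, tolerance = 1e-4))) {
      warning(sprintf("volume '%s' spacing disagrees with manifest; manifest wins", f))
    }
    arr > 0
  })
  structure_set(grid, structures, image_label = man$image_label)
}

#' Write a feature/target table as CSV
#' @param df data frame (e.g. `cohort$pairs`).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature/target table written by [write_feature_table()]
#' @param path CSV file.
#' @return data frame.
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# Small deterministic polynomial hash of a config for artifact stamping.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, digits = 10, auto_unbox = TRUE, force = TRUE)
  h <- 17
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Export a cohort trial summary and records to disk
#'
#' Writes `summary.csv` (per-patient totals, selections and key metrics) and
#' `trial.json` (p-value, config hash, seed) into `dir`.
#'
#' @param trial result of [run_cohort_trial()].
#' @param dir output directory.
#' @param cfg the [run_config()] used (hashed into the artifacts).
#' @param seed the seed used (stamped into the artifacts).
#' @return `dir`, invisibly.
#' @export
write_trial_summary <- function(trial, dir, cfg = NULL, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(trial$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(p_value = trial$p_value,
         n_patients = nrow(trial$summary),
         mean_dt_total = mean(trial$summary$dt_total),
         mean_clinical_total = mean(trial$summary$clinical_total),
         config_hash = if (!is.null(cfg)) config_hash(unclass(cfg)[c("trial", "rx")]) else NA,
         seed = seed),
    file.path(dir, "trial.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Score-comparison figure for a cohort trial
#'
#' Per-patient grouped bars of cumulative clinical vs digital-twin plan
#' scores. Requires ggplot2.
#'
#' @param summary the `summary` data frame from [run_cohort_trial()].
#' @return a ggplot object.
#' @export
plot_score_comparison <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  long <- rbind(
    data.frame(patient = summary$patient, course = "Clinical",
               total = summary$clinical_total),
    data.frame(patient = summary$patient, course = "Digital twin",
               total = summary$dt_total))
  ggplot2::ggplot(long, ggplot2::aes(x = patient, y = total, fill = course)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Cumulative plan-quality score", fill = NULL) +
    ggplot2::theme_minimal()
}
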