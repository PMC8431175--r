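## NIfTI / CSV / JSON interfaces and the end-to-end pipeline.
##
## Volume convention: multi-echo complex data are stored as two 4D NIfTI-1
## files, <stem>_real.nii.gz and <stem>_imag.nii.gz (x, y, z, echo, float32);
## masks are uint8; quantitative maps are float32. Voxel spacing is carried
## in the NIfTI pixdim.

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return List with `data` (numeric array), `spacing` (mm per axis, first
#'   three pixdims) and `image` (the underlying `niftiImage` carrying the
#'   full header/affine).
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  data <- array(as.vector(img), dim = dim(img))  # plain array, no header attrs
  list(data = data,
       spacing = RNifti::pixdim(img)[1:3],
       image = img)
}

#' Write a NIfTI volume
#'
#' @param data Numeric or logical array (3D or 4D).
#' @param path Output path (`.nii.gz`).
#' @param spacing Voxel spacing in mm (first three pixdims).
#' @param datatype NIfTI storage type: `"float"` (float32) or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(data, path, spacing = c(1, 1, 1),
                               datatype = c("float", "uint8")) {
  datatype <- match.arg(datatype)
  img <- RNifti::asNifti(data * 1)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- spacing
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

check_spacing_match <- function(sp_a, sp_b, tol = 1e-4, what = "volumes") {
  if (any(abs(sp_a - sp_b) > tol))
    stop(sprintf("voxel spacing mismatch between %s: (%s) vs (%s)",
                 what, paste(signif(sp_a, 8), collapse = ", "),
                 paste(signif(sp_b, 8), collapse = ", ")))
  invisible(TRUE)
}

#' Write / read a multi-echo complex series
#'
#' Stores the complex signal as paired real/imaginary 4D float32 NIfTI files
#' and the protocol as a JSON sidecar.
#'
#' @param series An [echo_series()].
#' @param stem Output path stem: writes `<stem>_real.nii.gz`,
#'   `<stem>_imag.nii.gz`, `<stem>_protocol.json`.
#' @return `stem`, invisibly.
#' @export
write_echo_series <- function(series, stem) {
  stopifnot(inherits(series, "echo_series"))
  sp <- series$protocol$voxel_spacing
  write_nifti_volume(Re(series$signal), paste0(stem, "_real.nii.gz"), sp)
  write_nifti_volume(Im(series$signal), paste0(stem, "_imag.nii.gz"), sp)
  p <- series$protocol
  jsonlite::write_json(
    list(n_echoes = p$n_echoes, te1 = p$te1, delta_te = p$delta_te,
         field_strength = p$field_strength, voxel_spacing = p$voxel_spacing,
         bipolar = p$bipolar),
    paste0(stem, "_protocol.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_echo_series
#' @export
read_echo_series <- function(stem) {
  pj <- jsonlite::read_json(paste0(stem, "_protocol.json"), simplifyVector = TRUE)
  protocol <- acquisition_protocol(pj$n_echoes, pj$te1, pj$delta_te,
                                   pj$field_strength, pj$voxel_spacing,
                                   pj$bipolar)
  re <- read_nifti_volume(paste0(stem, "_real.nii.gz"))
  im <- read_nifti_volume(paste0(stem, "_imag.nii.gz"))
  check_spacing_match(re$spacing, im$spacing, what = "real/imag volumes")
  check_spacing_match(re$spacing, protocol$voxel_spacing,
                      what = "volume and protocol")
  echo_series(re$data + 1i * im$data, protocol)
}

#' Write / read a muscle mask as uint8 NIfTI
#'
#' The axis annotation travels in a JSON sidecar `<path>.json`.
#'
#' @param mask A [muscle_mask()].
#' @param path Output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "muscle_mask"))
  write_nifti_volume(mask$voxels, path, mask$voxel_spacing, datatype = "uint8")
  jsonlite::write_json(
    list(axis = mask$axis, proximal_end = mask$proximal_end,
         label = mask$label),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- read_nifti_volume(path)
  side <- paste0(path, ".json")
  ann <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE)
  else stop("mask sidecar missing: ", side,
            " (axis annotation is required)")
  muscle_mask(v$data != 0, v$spacing, axis = ann$axis,
              proximal_end = ann$proximal_end,
              label = if (is.null(ann$label)) NULL else ann$label)
}

#' Run the full phantom-to-statistics pipeline
#'
#' Orchestrates the analysis end to end on synthetic data: (1) generate a
#' ground-truth phantom and forward-simulate the multi-echo acquisition;
#' (2) reconstruct PDFF/T2*/field maps by water-fat separation; (3) extract
#' whole-muscle and per-section metrics through the T2* filter; (4) generate
#' a longitudinal cohort, compute maximum changes, and run the correlation
#' battery. All outputs (NIfTI maps, CSV tables, provenance JSON) land in
#' `out_dir`; a fixed seed makes the run bit-reproducible.
#'
#' @param out_dir Output directory (created if absent).
#' @param shape Phantom grid dimensions.
#' @param pdff_profile Commanded per-third PDFF profile (see
#'   [generate_phantom()]).
#' @param snr Simulated SNR or `NULL` for noiseless.
#' @param n_subjects Cohort size for the statistics stage.
#' @param seed Master seed; stage seeds derive from it.
#' @param protocol An [acquisition_protocol()].
#' @return Invisibly, a list with `metrics` (per muscle/section data frame),
#'   `changes` (max-change table), `battery` (correlation results) and
#'   `paths`.
#' @export
run_pipeline <- function(out_dir, shape = c(32, 32, 18),
                         pdff_profile = c(14.1, 15.2, 22.5),
                         snr = 50, n_subjects = 56L, seed = 1L,
                         protocol = acquisition_protocol()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spectrum <- default_fat_spectrum()

  truth <- generate_phantom(shape, protocol, pdff_profile, seed = seed)
  series <- simulate_signal(truth, protocol, spectrum, snr = snr,
                            seed = seed + 1L)
  write_echo_series(series, file.path(out_dir, "echoes"))
  for (nm in names(truth$masks))
    write_mask(truth$masks[[nm]], file.path(out_dir, paste0("mask_", nm, ".nii.gz")))

  in_mask <- Reduce(`|`, lapply(truth$masks, function(m) m$voxels))
  maps <- separate(series, spectrum, mask = in_mask)
  sp <- protocol$voxel_spacing
  write_nifti_volume(maps$pdff, file.path(out_dir, "pdff.nii.gz"), sp)
  t2s <- maps$t2star; t2s[is.na(t2s)] <- -1
  write_nifti_volume(t2s, file.path(out_dir, "t2star.nii.gz"), sp)
  write_nifti_volume(maps$fieldmap, file.path(out_dir, "fieldmap.nii.gz"), sp)

  met <- do.call(rbind, lapply(names(truth$masks), function(nm) {
    cbind(muscle = nm,
          regional_metrics(maps$pdff, truth$masks[[nm]], maps$t2star))
  }))
  utils::write.csv(met, file.path(out_dir, "muscle_metrics.csv"),
                   row.names = FALSE)

  cohort <- generate_cohort(cohort_spec(n_subjects = n_subjects,
                                        seed = seed + 2L))
  utils::write.csv(cohort$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$metrics, file.path(out_dir, "metrics_long.csv"),
                   row.names = FALSE)
  changes <- max_change_table(cohort$metrics)
  utils::write.csv(changes, file.path(out_dir, "max_changes.csv"),
                   row.names = FALSE)
  battery <- run_study_battery(cohort$baseline, cohort$subjects)
  utils::write.csv(battery, file.path(out_dir, "correlation_battery.csv"),
                   row.names = FALSE)

  config <- list(shape = shape, pdff_profile = pdff_profile, snr = snr,
                 n_subjects = n_subjects, seed = seed,
                 protocol = list(n_echoes = protocol$n_echoes,
                                 te1 = protocol$te1,
                                 delta_te = protocol$delta_te,
                                 field_strength = protocol$field_strength,
                                 voxel_spacing = protocol$voxel_spacing,
                                 bipolar = protocol$bipolar))
  jsonlite::write_json(
    list(package = "musclepdff",
         version = as.character(utils::packageVersion("musclepdff")),
         r_version = R.version.string,
         seed = seed,
         config = config,
         config_hash = substr(paste(
           as.integer(charToRaw(jsonlite::toJSON(config, auto_unbox = TRUE))),
           collapse = ""), 1, 64)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(metrics = met, changes = changes, battery = battery,
                 maps = maps, truth = truth,
                 paths = list(out_dir = out_dir)))
}
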