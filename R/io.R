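#' Read a 4D DSC series from NIfTI plus a sidecar config
#'
#' NIfTI headers do not reliably carry the echo time, so TE and the frame
#' spacing are taken from a YAML or JSON sidecar with fields `te_seconds`
#' and `dt_seconds` (optional `baseline_index`).
#'
#' @param nifti_path Path to a 4D `.nii`/`.nii.gz` file.
#' @param sidecar_path Path to the YAML/JSON acquisition sidecar.
#' @return A [dsc_series()].
#' @export
read_dsc_series <- function(nifti_path, sidecar_path) {
  img <- RNifti::readNifti(nifti_path)
  meta <- read_config(sidecar_path)
  if (is.null(meta$te_seconds) || is.null(meta$dt_seconds))
    stop("sidecar must provide `te_seconds` and `dt_seconds`")
  dsc_series(array(as.numeric(img), dim = dim(img)),
             te_seconds = meta$te_seconds, dt_seconds = meta$dt_seconds,
             baseline_index = meta$baseline_index %||% 1L)
}

#' Write a CTC volume as 4D NIfTI
#' @param ctc A [ctc_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_ctc_volume <- function(ctc, path) {
  stopifnot(inherits(ctc, "ctc_volume"))
  RNifti::writeNifti(RNifti::asNifti(ctc$curves), path)
  invisible(path)
}

#' Read/write an arterial input function as two-column text
#'
#' Plain whitespace-separated text with a `time_s concentration` header; the
#' grid must be evenly spaced.
#'
#' @param aif_obj An [aif()].
#' @param path File path.
#' @return `write_aif` returns the path invisibly; `read_aif` an [aif()].
#' @export
write_aif <- function(aif_obj, path) {
  stopifnot(inherits(aif_obj, "aif"))
  df <- data.frame(time_s = (seq_along(aif_obj$values) - 1) * aif_obj$dt_seconds,
                   concentration = aif_obj$values)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_aif
#' @export
read_aif <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  dts <- diff(df$time_s)
  if (length(dts) < 1L || any(abs(dts - dts[1]) > 1e-9 * max(dts[1], 1)))
    stop("AIF file must be on an evenly spaced time grid")
  aif(df$concentration, dt_seconds = dts[1], source = paste0("file:", basename(path)))
}

#' Write perfusion maps as NIfTI volumes with a provenance sidecar
#'
#' Each of the five maps goes to `<dir>/<name>.nii.gz`; provenance (method,
#' thresholds, AIF source, QC counts) to `<dir>/provenance.json`.
#'
#' @param maps A `perfusion_maps` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_perfusion_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "perfusion_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(maps$maps)) {
    RNifti::writeNifti(RNifti::asNifti(maps$maps[[nm]]),
                       file.path(dir, paste0(nm, ".nii.gz")))
  }
  jsonlite::write_json(list(provenance = maps$provenance, qc = maps$qc),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# Sidecar / run configuration reader: YAML or JSON by extension.
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
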