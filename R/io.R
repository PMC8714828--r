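# NIfTI / bval / CSV / YAML input-output.
#
# b-values are stored FSL-style: one whitespace-separated line. No bvec file
# is read or written — the bi-exponential IVIM model is direction
# independent, so unlike most DWI tooling this package carries no gradient
# directions.

#' Read a b-value file
#'
#' @param path FSL-style `.bval` text file (whitespace-separated numbers,
#'   one line).
#' @return An [acquisition_scheme()].
#' @export
read_bvals <- function(path) {
  if (!file.exists(path)) stop(sprintf("bval file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  toks <- strsplit(trimws(txt), "\\s+")[[1L]]
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("unreadable b-value token '%s' at position %d in %s",
                 toks[bad], bad, path))
  }
  acquisition_scheme(vals)
}

#' Write a b-value file
#'
#' @param scheme An [acquisition_scheme()].
#' @param path Output path.
#' @export
write_bvals <- function(scheme, path) {
  writeLines(paste(format(scheme$bvalues, digits = 15, trim = TRUE,
                          scientific = FALSE), collapse = " "), path)
  invisible(path)
}

# NIfTI readers drop trailing singleton dimensions; single-slice masks and
# label maps come back 2-D and need their slice axis restored.
.as_vol3d <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

#' Read a 4-D diffusion-weighted volume with its b-values
#'
#' @param nifti_path Path to a 4-D NIfTI (.nii or .nii.gz).
#' @param bval_path Path to the matching `.bval` file.
#' @return List with `data` (4-D array), `scheme`
#'   ([acquisition_scheme()]) and `image` (the `RNifti` image carrying the
#'   affine/header, passed through to [write_maps()]).
#' @export
read_dwi <- function(nifti_path, bval_path) {
  if (!file.exists(nifti_path)) stop(sprintf("NIfTI not found: %s", nifti_path))
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4-D DWI volume, got %d dimensions", length(dim(arr))))
  scheme <- read_bvals(bval_path)
  if (dim(arr)[4L] != length(scheme$bvalues))
    stop(sprintf("volume count (%d) does not match b-value count (%d)",
                 dim(arr)[4L], length(scheme$bvalues)))
  list(data = arr, scheme = scheme, image = img)
}

#' Write fitted parameter maps as NIfTI plus a sidecar
#'
#' Writes `f.nii.gz`, `D.nii.gz`, `Dstar.nii.gz`, `residual.nii.gz`
#' (float32), a `flags.nii.gz` diagnostics volume (uint8 bitmask: bit 1
#' degenerate, bit 2 non-converged, bit 4 all-zero voxel) and a JSON sidecar
#' with the configuration and seed. The affine of `reference` (when given)
#' is passed through to every output.
#'
#' @param maps A `parameter_maps` object from [fit_volume()].
#' @param outdir Output directory (created if missing).
#' @param reference Optional `RNifti` image whose geometry the outputs
#'   inherit.
#' @return Invisibly, the vector of files written.
#' @export
write_maps <- function(maps, outdir, reference = NULL) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(arr, name, datatype) {
    p <- file.path(outdir, paste0(name, ".nii.gz"))
    img <- if (is.null(reference)) RNifti::asNifti(arr)
           else RNifti::asNifti(arr, reference = reference)
    RNifti::writeNifti(img, p, datatype = datatype)
    files <<- c(files, p)
  }
  wr(maps$f, "f", "float")
  wr(maps$D, "D", "float")
  wr(maps$Dstar, "Dstar", "float")
  wr(maps$residual, "residual", "float")
  wr(maps$flags, "flags", "uint8")
  sidecar <- file.path(outdir, "fit.json")
  jsonlite::write_json(
    list(method = maps$method,
         seed = maps$config$seed,
         config = unclass(maps$config)),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, sidecar)
  invisible(files)
}

#' Write a phantom to disk
#'
#' Emits `dwi.nii.gz`, `labels.nii.gz`, `gt_f.nii.gz`, `gt_D.nii.gz`,
#' `gt_Dstar.nii.gz`, an FSL-style `dwi.bval`, and `phantom.yaml` capturing
#' the full specification and seed.
#'
#' @param phantom A `phantom_output` from [make_phantom()].
#' @param outdir Output directory.
#' @return Invisibly, the files written.
#' @export
write_phantom <- function(phantom, outdir) {
  stopifnot(inherits(phantom, "phantom_output"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dwi = file.path(outdir, "dwi.nii.gz"),
             labels = file.path(outdir, "labels.nii.gz"),
             gt_f = file.path(outdir, "gt_f.nii.gz"),
             gt_D = file.path(outdir, "gt_D.nii.gz"),
             gt_Dstar = file.path(outdir, "gt_Dstar.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$dwi), paths["dwi"])
  RNifti::writeNifti(RNifti::asNifti(phantom$labels + 0L), paths["labels"], datatype = "uint8")
  RNifti::writeNifti(RNifti::asNifti(phantom$gt_f), paths["gt_f"])
  RNifti::writeNifti(RNifti::asNifti(phantom$gt_D), paths["gt_D"])
  RNifti::writeNifti(RNifti::asNifti(phantom$gt_Dstar), paths["gt_Dstar"])
  bval <- file.path(outdir, "dwi.bval")
  write_bvals(phantom$spec$scheme, bval)
  meta <- file.path(outdir, "phantom.yaml")
  spec <- phantom$spec
  yaml::write_yaml(list(
    shape = as.integer(spec$shape),
    snr_per_slice = spec$snr_per_slice,
    n_coils = spec$n_coils,
    s0 = spec$s0,
    seed = spec$seed,
    sigma_per_slice = phantom$sigma_per_slice,
    bvalues = spec$scheme$bvalues,
    tissue_table = lapply(seq_len(nrow(spec$tissue_table)), function(i)
      as.list(spec$tissue_table[i, ]))), meta)
  invisible(c(paths, bval = bval, meta = meta))
}

#' Read a run configuration file
#'
#' YAML with optional sections `topopro:` and `baselines:` mirroring
#' [topopro_config()] and [baseline_config()] field for field. Unknown keys
#' are rejected with an error naming the key.
#'
#' @param path YAML file.
#' @return List with `topopro` ([topopro_config()]) and `baselines`
#'   ([baseline_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed_top <- c("topopro", "baselines")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown))
    stop(sprintf("unknown configuration section '%s'", unknown[1L]))
  tp_args <- raw$topopro
  if (!is.null(tp_args)) {
    bad <- setdiff(names(tp_args), names(formals(topopro_config)))
    if (length(bad)) stop(sprintf("unknown topopro key '%s'", bad[1L]))
  }
  bl_args <- raw$baselines
  if (!is.null(bl_args)) {
    bad <- setdiff(names(bl_args), names(formals(baseline_config)))
    if (length(bad)) stop(sprintf("unknown baselines key '%s'", bad[1L]))
  }
  list(topopro = do.call(topopro_config, as.list(tp_args)),
       baselines = do.call(baseline_config, as.list(bl_args)))
}
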