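#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads a (possibly gzipped) NIfTI-1 file and returns it as a plain 3D
#' numeric array with a `voxel_size` attribute (mm).  Trailing singleton
#' dimensions are dropped; a genuinely 4D input is an error, because all
#' pipelines here operate on single 3D volumes (a multi-TI series is passed
#' as a list of files).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return Numeric 3D array with attributes `voxel_size` and `pixdim`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  d <- d[d > 1 | seq_along(d) <= 3]   # drop trailing singleton dims
  if (length(d) != 3)
    stop("expected a 3D volume, got ", length(d), "D input: ", path)
  a <- array(as.numeric(img), d)
  pd <- RNifti::pixdim(img)
  attr(a, "voxel_size") <- pd[seq_len(min(3, length(pd)))]
  a
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' Writes in double precision so that a write/read round trip reproduces the
#' array bit-for-bit.
#'
#' @param v 3D numeric array (logical arrays are written as 0/1), optionally
#'   with a `voxel_size` attribute.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (length(dim(v)) != 3) stop("expected a 3D volume")
  vs <- attr(v, "voxel_size")
  a <- array(as.numeric(v), dim(v))
  img <- RNifti::asNifti(a)
  if (!is.null(vs)) RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read GM/WM/CSF masks from NIfTI files
#'
#' @param gm,wm,csf paths to the three tissue masks or probability maps; the
#'   grids must agree.
#' @return A [tissue_masks()] object.
#' @export
read_masks <- function(gm, wm, csf) {
  tissue_masks(read_volume(gm), read_volume(wm), read_volume(csf))
}

#' Write a fitted T1 map and its report
#'
#' Writes the T1 values (invalid voxels as 0) as NIfTI and, optionally, a
#' JSON report with the method, configuration and calibration diagnostics,
#' so a run can be audited and reproduced.
#'
#' @param fit a `"t1require"` object.
#' @param path output NIfTI path.
#' @param report optional path for the JSON fit report.
#' @return `path`, invisibly.
#' @export
write_t1map <- function(fit, path, report = NULL) {
  stopifnot(inherits(fit, "t1require"))
  v <- fit$t1
  v[!fit$valid] <- 0
  write_volume(v, path)
  if (!is.null(report)) {
    rep <- list(method = fit$method,
                n_valid = sum(fit$valid),
                n_voxels = length(fit$valid),
                config = fit$config)
    if (fit$method == "SE-REQUIRE") rep$slice_fits <- fit$fit
    if (fit$method == "MPRAGE-REQUIRE")
      rep$fit <- fit$fit[c("M0", "residual", "tissue_means")]
    jsonlite::write_json(rep, report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "columns")
  }
  invisible(path)
}

#' Write a phantom with its ground truth to disk
#'
#' Writes the label volume, the T1/T2/proton-density maps and the three
#' hard tissue masks (gm/wm/csf) as NIfTI files plus a JSON sidecar
#' recording the seed, heterogeneity and reference table, i.e. everything
#' needed to reproduce, score against, or feed the phantom back through the
#' mapping pipelines.
#'
#' @param ph a [make_phantom()] phantom.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  stopifnot(inherits(ph, "tissue_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- ph$voxel_size
  for (nm in c("labels", "t1", "t2", "rho")) {
    v <- array(as.numeric(ph[[nm]]), dim(ph$labels))
    attr(v, "voxel_size") <- vs
    write_volume(v, file.path(dir, paste0(nm, ".nii.gz")))
  }
  hm <- phantom_masks(ph)
  for (nm in names(hm)) {
    v <- array(as.numeric(hm[[nm]]), dim(ph$labels))
    attr(v, "voxel_size") <- vs
    write_volume(v, file.path(dir, paste0(nm, ".nii.gz")))
  }
  side <- list(seed = ph$seed, heterogeneity = ph$heterogeneity,
               voxel_size = vs, shape = dim(ph$labels),
               refs = as.data.frame(unclass(ph$refs)))
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
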