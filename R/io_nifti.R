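#' Write a diffusion field as a NIfTI pair
#'
#' Writes the FA volume and the 3-volume principal-direction vector field
#' (RAS world convention) with the field's affine in the sform.
#'
#' @param field a [diffusion_field()].
#' @param fa_path,dirs_path output paths (`.nii` or `.nii.gz`).
#' @return invisibly, the two paths.
#' @export
write_diffusion_field <- function(field, fa_path, dirs_path) {
  write_volume(field$fa, field$affine, fa_path)
  write_volume(field$dirs, field$affine, dirs_path)
  invisible(c(fa_path, dirs_path))
}

#' Read a diffusion field from a NIfTI pair
#'
#' Validates that the two grids match, the affine is invertible, and the
#' direction vectors are unit norm.
#'
#' @param fa_path path to the FA scalar volume.
#' @param dirs_path path to the 3-volume direction field.
#' @return a [diffusion_field()].
#' @export
read_diffusion_field <- function(fa_path, dirs_path) {
  fa <- read_volume(fa_path)
  dirs <- read_volume(dirs_path)
  if (!isTRUE(all.equal(fa$affine, dirs$affine, tolerance = 1e-6)))
    stop("FA and direction volumes have different affines")
  diffusion_field(fa$data, dirs$data, fa$affine)
}

#' Write a volume (scalar, vector or integer label) as NIfTI
#'
#' @param data 3D or 4D array.
#' @param affine 4x4 voxel-to-world (RAS mm) matrix.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_volume <- function(data, affine, path) {
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path input path.
#' @return list with `data` (array) and `affine` (4x4, voxel -> world RAS
#'   mm); errors on a non-invertible affine.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- unclass(RNifti::xform(img))
  attr(affine, "code") <- NULL
  affine <- rbind(affine[1:3, ], c(0, 0, 0, 1))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("volume affine is not invertible")
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  list(data = data, affine = affine)
}
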