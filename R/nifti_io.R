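#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI (.nii or .nii.gz) and returns the grid (affine
#' taken from the header's preferred transform, sform over qform) together
#' with the image array as doubles. 4D images keep axis order (x, y, z, t).
#'
#' @param path Path to a .nii / .nii.gz file.
#' @return A list with `grid` (a [volume_grid()]) and `data` (3D or 4D array).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  dm <- dim(img)
  if (!(length(dm) %in% c(3L, 4L)))
    stop("expected a 3D or 4D volume, got ", length(dm), " dimensions")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- array(as.double(img), dim = dm)
  list(grid = volume_grid(dm[1:3], aff), data = arr)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D or 4D array with the grid's affine recorded in both the sform
#' and qform (code 2, "aligned"). Round-trips through [read_volume()] with
#' identical values and the affine reproduced to single precision.
#'
#' @param grid A [volume_grid()]; spatial shape must match the array.
#' @param array 3D or 4D numeric array.
#' @param path Output path ending in .nii or .nii.gz.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, array, path) {
  dm <- dim(array)
  if (!(length(dm) %in% c(3L, 4L)))
    stop("expected a 3D or 4D array, got ", length(dm), " dimensions")
  if (!identical(as.integer(dm[1:3]), as.integer(grid$shape)))
    stop("array spatial shape ", paste(dm[1:3], collapse = "x"),
         " does not match grid shape ", paste(grid$shape, collapse = "x"))
  img <- RNifti::asNifti(array)
  # pixdim must match the image dimensionality before the transforms are
  # installed, and the (exact) sform must be set last so it is preferred
  sp <- voxel_spacing(grid)
  img <- RNifti::`pixdim<-`(img, if (length(dm) == 4L) c(sp, 1) else sp)
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 6-column rigid-body motion parameter file
#'
#' Plain-text, one row per volume: three translations (mm) then three
#' rotations (radians), whitespace- or comma-delimited, no header.
#'
#' @param path Path to the motion file.
#' @return T x 6 numeric matrix with columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  if (ncol(m) != 6L)
    stop("motion file must have 6 columns, found ", ncol(m))
  storage.mode(m) <- "double"
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Write a 6-column motion parameter file
#' @param motion T x 6 numeric matrix (translations mm, rotations radians).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  utils::write.table(format(motion, digits = 10, scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
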