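#' 3D volume with spatial metadata
#'
#' A `volume_image` is the unit all preprocessing operates on: a 3D numeric
#' array plus voxel spacing in millimetres per axis, a 3-letter
#' axis-orientation code (direction of increase per array axis, e.g. `"RAS"` =
#' x increases to the Right, y to Anterior, z to Superior), and a role tag
#' saying whether voxels hold Hounsfield units or a binary mask.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, mm per voxel per axis; strictly positive.
#' @param orientation 3-character orientation code, one letter per axis from
#'   the pairs R/L, A/P, S/I, each pair used exactly once.
#' @param dtype_role `"HU"` or `"binary"`. Binary volumes may only contain
#'   0 and 1.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), orientation = "RAS",
                         dtype_role = c("HU", "binary")) {
  dtype_role <- match.arg(dtype_role)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be 3 strictly positive numbers", call. = FALSE)
  }
  check_orientation_code(orientation)
  if (dtype_role == "binary" && !all(values %in% c(0, 1))) {
    stop("binary volume contains values outside {0, 1}", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, orientation = toupper(orientation),
         dtype_role = dtype_role),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s  %s  spacing %s mm  orientation %s  foreground %d\n",
              paste(dim(x$values), collapse = "x"), x$dtype_role,
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              x$orientation,
              if (x$dtype_role == "binary") sum(x$values) else NA_integer_))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$values)

# orientation code -> per-axis letter, validated
check_orientation_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L) {
    stop("orientation code must be a 3-character string", call. = FALSE)
  }
  letters3 <- strsplit(toupper(code), "")[[1]]
  pair_of <- c(R = 1, L = 1, A = 2, P = 2, S = 3, I = 3)
  if (any(!letters3 %in% names(pair_of))) {
    stop(sprintf("unknown orientation code '%s'", code), call. = FALSE)
  }
  if (length(unique(pair_of[letters3])) != 3L) {
    stop(sprintf("orientation code '%s' does not use each anatomical axis once", code),
         call. = FALSE)
  }
  letters3
}

# letters whose direction-of-increase matches the canonical RAS convention
.canonical_letters <- c("R", "A", "S")
.flip_partner <- c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")

#' Read a NIfTI file as a volume_image
#'
#' Spacing and the orientation code are taken from the NIfTI header. Volumes
#' whose values are all 0/1 are tagged `dtype_role = "binary"`, anything else
#' `"HU"`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume_image].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("expected a 3D image, got %d dimensions", length(d)), call. = FALSE)
  }
  vals <- array(as.numeric(img), dim = d)
  role <- if (all(vals %in% c(0, 1))) "binary" else "HU"
  volume_image(vals,
               spacing = RNifti::pixdim(img)[1:3],
               orientation = RNifti::orientation(img),
               dtype_role = role)
}

#' Write a volume_image to a NIfTI file
#'
#' The header encodes spacing through pixdim and the orientation code through
#' the qform affine, so `read_nifti(write_nifti(v, f))` restores values,
#' spacing and orientation.
#'
#' @param volume a [volume_image].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  letters3 <- check_orientation_code(volume$orientation)
  pair_of <- c(R = 1, L = 1, A = 2, P = 2, S = 3, I = 3)
  aff <- matrix(0, 4, 4); aff[4, 4] <- 1
  for (ax in 1:3) {
    world <- pair_of[[letters3[ax]]]
    sgn <- if (letters3[ax] %in% .canonical_letters) 1 else -1
    aff[world, ax] <- sgn * volume$spacing[ax]
  }
  RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
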