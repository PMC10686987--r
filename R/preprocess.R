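#' Resample a volume to isotropic voxel spacing
#'
#' Each axis is resampled so that voxels measure `target_mm` on every side
#' while the physical extent (spacing x voxel count) is preserved to within
#' one voxel. Hounsfield-unit volumes are interpolated linearly (separably,
#' axis by axis); binary volumes use nearest-neighbour lookup so the mask
#' stays binary.
#'
#' @param volume a [volume_image] with known spacing.
#' @param target_mm target isotropic spacing in millimetres (default 1).
#' @return A [volume_image] with `spacing = c(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(volume, target_mm = 1.0) {
  stopifnot(inherits(volume, "volume_image"))
  stopifnot_scalar_number(target_mm, "target_mm")
  if (target_mm <= 0) stop("'target_mm' must be positive", call. = FALSE)
  d <- dim(volume$values)
  new_d <- pmax(1L, as.integer(round(d * volume$spacing / target_mm)))
  if (all(new_d == d) && all(volume$spacing == target_mm)) return(volume)
  linear <- volume$dtype_role == "HU"
  x <- volume$values
  for (ax in 1:3) {
    x <- resample_axis(x, ax, dim(x)[ax], new_d[ax],
                       volume$spacing[ax], target_mm, linear)
  }
  volume_image(x, spacing = rep(target_mm, 3), orientation = volume$orientation,
               dtype_role = volume$dtype_role)
}

# 1D resampling along one array axis, voxel-centre aligned:
# source coordinate of target voxel i (0-based) is (i + 0.5) * t/s - 0.5.
resample_axis <- function(x, axis, n_old, n_new, sp_old, sp_new, linear) {
  if (n_new == n_old && sp_old == sp_new) return(x)
  src <- ((seq_len(n_new) - 0.5) * sp_new / sp_old) - 0.5   # 0-based
  if (linear) {
    i0 <- pmin(pmax(floor(src), 0), n_old - 1)
    i1 <- pmin(i0 + 1, n_old - 1)
    f <- pmin(pmax(src - i0, 0), 1)
    lo <- slice_axis(x, axis, i0 + 1)
    hi <- slice_axis(x, axis, i1 + 1)
    y <- sweep_axis(lo, axis, 1 - f, "*") + sweep_axis(hi, axis, f, "*")
  } else {
    i <- pmin(pmax(round(src), 0), n_old - 1)
    y <- slice_axis(x, axis, i + 1)
  }
  y
}

slice_axis <- function(x, axis, idx) {
  switch(axis,
         x[idx, , , drop = FALSE],
         x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

# multiply array by a vector that varies along `axis`
sweep_axis <- function(x, axis, v, op = "*") {
  sweep(x, axis, v, FUN = op)
}

#' Reorder a volume to the canonical axis orientation
#'
#' Axes are permuted and flipped so that the direction of increase along the
#' three array axes is Right, Anterior, Superior (`"RAS"`). Voxel values are
#' only rearranged, never interpolated, so the multiset of values is
#' unchanged. Applying the operation twice equals applying it once.
#'
#' @param volume a [volume_image] with a valid orientation code.
#' @return A [volume_image] in `"RAS"` orientation.
#' @export
reorient_canonical <- function(volume) {
  stopifnot(inherits(volume, "volume_image"))
  letters3 <- check_orientation_code(volume$orientation)
  pair_of <- c(R = 1, L = 1, A = 2, P = 2, S = 3, I = 3)
  world <- pair_of[letters3]              # anatomical axis carried by each array axis
  perm <- match(1:3, world)               # array axis to place at position 1,2,3
  x <- aperm(volume$values, perm)
  sp <- volume$spacing[perm]
  flipped <- !(letters3[perm] %in% .canonical_letters)
  for (ax in 1:3) {
    if (flipped[ax]) {
      x <- slice_axis(x, ax, rev(seq_len(dim(x)[ax])))
    }
  }
  volume_image(x, spacing = sp, orientation = "RAS", dtype_role = volume$dtype_role)
}

#' Crop and/or zero-pad a volume to a fixed cube
#'
#' Content is kept centred. Padding uses value 0. When the size difference on
#' an axis is odd, the extra cropped or padded voxel goes to the trailing side
#' of that axis.
#'
#' @param volume a [volume_image].
#' @param side target side length in voxels (default 300).
#' @return A [volume_image] of dimension `side^3`.
#' @export
crop_or_pad <- function(volume, side = 300) {
  stopifnot(inherits(volume, "volume_image"))
  side <- as.integer(side)
  if (side <= 0) stop("'side' must be positive", call. = FALSE)
  x <- volume$values
  d <- dim(x)
  # crop each oversized axis first
  for (ax in 1:3) {
    n <- dim(x)[ax]
    if (n > side) {
      lead <- (n - side) %/% 2           # extra voxel removed from trailing side
      x <- slice_axis(x, ax, lead + seq_len(side))
    }
  }
  d <- dim(x)
  if (any(d < side)) {
    out <- array(0, c(side, side, side))
    lead <- (side - d) %/% 2             # extra padded voxel on trailing side
    out[lead[1] + seq_len(d[1]), lead[2] + seq_len(d[2]), lead[3] + seq_len(d[3])] <- x
    x <- out
  }
  volume_image(x, spacing = volume$spacing, orientation = volume$orientation,
               dtype_role = volume$dtype_role)
}

#' Binarize a Hounsfield-unit volume at a bone threshold
#'
#' Voxels at or above `threshold` HU become 1.0, all others 0.0. The default
#' of 500 HU isolates cortical and cancellous bone on bone-algorithm CT
#' reconstructions. Re-applying the operation with a threshold of at most 1 is
#' the identity on an already-binary volume.
#'
#' @param volume a [volume_image] (any role; typically `"HU"`).
#' @param threshold HU cutoff (default 500).
#' @return A binary [volume_image].
#' @export
binarize_hu <- function(volume, threshold = 500) {
  stopifnot(inherits(volume, "volume_image"))
  stopifnot_scalar_number(threshold, "threshold")
  vals <- (volume$values >= threshold) * 1.0
  dim(vals) <- dim(volume$values)
  volume_image(vals, spacing = volume$spacing, orientation = volume$orientation,
               dtype_role = "binary")
}

#' Full preprocessing pipeline
#'
#' Applies, in order: isotropic resampling, canonical reorientation, centred
#' crop/zero-pad to a cube, and HU binarization (skipped for volumes that are
#' already binary). The order matters only up to the final binarization (the
#' pad value 0 is below any bone threshold); it is fixed here so the pipeline
#' is deterministic and reproducible.
#'
#' @param volume a [volume_image].
#' @param side cube side in voxels (default 300).
#' @param target_mm isotropic spacing in mm (default 1).
#' @param threshold HU binarization threshold (default 500).
#' @return A binary [volume_image] of dimension `side^3` at `target_mm` spacing.
#' @export
preprocess_volume <- function(volume, side = 300, target_mm = 1.0, threshold = 500) {
  v <- resample_isotropic(volume, target_mm)
  v <- reorient_canonical(v)
  v <- crop_or_pad(v, side)
  if (v$dtype_role != "binary") v <- binarize_hu(v, threshold)
  v
}
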