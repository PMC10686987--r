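#' Training-time 3D augmentation configuration
#'
#' Ranges are "within realistic limits" for skull volumes and are declared
#' configuration, not measured values: rotations of at most a few degrees
#' around each axis, mild zoom, a cutout cuboid of at most a third of the
#' volume side (emulating missing bone), and a partial-affine region of
#' similar size (emulating displaced fracture fragments).
#'
#' @param flip_axis lateral axis index for mirror flips (default 1).
#' @param rotation_range max absolute rotation per axis, degrees (default 10).
#' @param zoom_range length-2 scale-factor interval (default `c(0.9, 1.1)`).
#' @param cutout_size_range length-2 cuboid side range in voxels.
#' @param partial_region_size cubic region side for the partial affine.
#' @param partial_rotation_range max absolute rotation of the region, degrees.
#' @param partial_translation_range max absolute translation, voxels.
#' @param p_flip,p_affine,p_cutout,p_partial per-operator application
#'   probabilities (defaults 0.5).
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(flip_axis = 1L,
                                rotation_range = 10,
                                zoom_range = c(0.9, 1.1),
                                cutout_size_range = NULL,
                                partial_region_size = NULL,
                                partial_rotation_range = 10,
                                partial_translation_range = 3,
                                p_flip = 0.5, p_affine = 0.5,
                                p_cutout = 0.5, p_partial = 0.5) {
  probs <- c(p_flip, p_affine, p_cutout, p_partial)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (rotation_range < 0 || partial_rotation_range < 0 ||
      partial_translation_range < 0 || any(zoom_range <= 0)) {
    stop("ranges must be non-negative (zoom strictly positive)", call. = FALSE)
  }
  structure(list(flip_axis = as.integer(flip_axis),
                 rotation_range = rotation_range, zoom_range = zoom_range,
                 cutout_size_range = cutout_size_range,
                 partial_region_size = partial_region_size,
                 partial_rotation_range = partial_rotation_range,
                 partial_translation_range = partial_translation_range,
                 p_flip = p_flip, p_affine = p_affine,
                 p_cutout = p_cutout, p_partial = p_partial),
            class = "augmentation_config")
}

as_vol_array <- function(volume) {
  if (inherits(volume, "volume_image")) volume$values else volume
}
rewrap_vol <- function(x, volume) {
  if (inherits(volume, "volume_image")) {
    out <- volume; out$values <- x; out
  } else x
}

#' Mirror a volume along the lateral axis
#'
#' @param volume binary 3D array or [volume_image].
#' @param axis lateral axis index (default 1).
#' @return The flipped volume, same type as the input.
#' @export
flip_lateral <- function(volume, axis = 1L) {
  x <- as_vol_array(volume)
  rewrap_vol(slice_axis(x, axis, rev(seq_len(dim(x)[axis]))), volume)
}

# rotation matrix about axis `ax` by `deg` degrees
rot_mat <- function(ax, deg) {
  th <- deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(ax,
         matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, byrow = TRUE),
         matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, byrow = TRUE),
         matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, byrow = TRUE))
}

# apply rotation R and scale `zoom` about the centre of an array, with an
# optional translation, by inverse mapping + nearest-neighbour lookup
affine_resample_nn <- function(x, R, zoom = 1, shift = c(0, 0, 0)) {
  d <- dim(x)
  ctr <- (d + 1) / 2
  g <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  src <- t((t(R) %*% t(sweep(g, 2, ctr + shift))) / zoom) # inverse transform
  src <- round(sweep(src, 2, ctr, "+"))
  ok <- src[, 1] >= 1 & src[, 1] <= d[1] &
        src[, 2] >= 1 & src[, 2] <= d[2] &
        src[, 3] >= 1 & src[, 3] <= d[3]
  out <- array(0, d)
  out[g[ok, , drop = FALSE]] <- x[src[ok, , drop = FALSE]]
  out
}

#' Random rotation and zoom about the volume centre
#'
#' Angles (one per axis) and a zoom factor are drawn uniformly within the
#' configured ranges. Nearest-neighbour lookup keeps binary volumes binary;
#' regions mapped from outside the volume are filled with 0. The sampled
#' parameters are logged in the `"aug_log"` attribute of the result.
#'
#' @param volume binary 3D array or [volume_image].
#' @param config an [augmentation_config].
#' @param seed RNG seed (optional).
#' @return The augmented volume.
#' @export
random_affine <- function(volume, config = augmentation_config(), seed = NULL) {
  x <- as_vol_array(volume)
  with_seed(seed, {
    ang <- stats::runif(3, -config$rotation_range, config$rotation_range)
    zoom <- stats::runif(1, config$zoom_range[1], config$zoom_range[2])
    R <- rot_mat(3, ang[3]) %*% rot_mat(2, ang[2]) %*% rot_mat(1, ang[1])
    out <- if (all(ang == 0) && zoom == 1) x else affine_resample_nn(x, R, zoom)
    out <- rewrap_vol(out, volume)
    attr(out, "aug_log") <- list(op = "random_affine", angles = ang, zoom = zoom)
    out
  })
}

#' Cutout: delete a random cuboid
#'
#' One axis-aligned cuboid with per-axis sizes drawn from
#' `cutout_size_range` (default 1 to side/3) at a uniform random position is
#' set to 0; every other voxel is untouched. Cuboids reaching past the bounds
#' are clipped. The sampled cuboid is logged in `"aug_log"`.
#'
#' @inheritParams random_affine
#' @return The augmented volume.
#' @export
cutout <- function(volume, config = augmentation_config(), seed = NULL) {
  x <- as_vol_array(volume)
  d <- dim(x)
  rng <- config$cutout_size_range %||% c(1L, floor(min(d) / 3))
  with_seed(seed, {
    sz <- rng[1] + sapply(1:3, function(a) sample.int(rng[2] - rng[1] + 1L, 1)) - 1L
    # uniform over positions where the cuboid fits; oversized cuboids clip
    lo <- sapply(1:3, function(a) sample.int(max(1L, d[a] - sz[a] + 1L), 1))
    hi <- pmin(lo + sz - 1L, d)
    x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 0
    out <- rewrap_vol(x, volume)
    attr(out, "aug_log") <- list(op = "cutout", lo = lo, hi = hi)
    out
  })
}

#' Partial affine: displace a sub-region in place
#'
#' A cubic sub-region of `partial_region_size` at a random position is
#' extracted, rotated and translated within the configured ranges (with
#' nearest-neighbour lookup and 0 fill), and written back at its original
#' position. Every voxel outside the region is bit-identical to the input —
#' the operator emulates a locally displaced fracture fragment. The region
#' and sampled transform are logged in `"aug_log"`.
#'
#' @inheritParams random_affine
#' @return The augmented volume.
#' @export
random_affine_partial <- function(volume, config = augmentation_config(),
                                  seed = NULL) {
  x <- as_vol_array(volume)
  d <- dim(x)
  rs <- config$partial_region_size %||% floor(min(d) / 3)
  if (any(rs > d)) stop("partial region larger than the volume", call. = FALSE)
  with_seed(seed, {
    lo <- sapply(1:3, function(a) sample.int(d[a] - rs + 1L, 1))
    hi <- lo + rs - 1L
    ang <- stats::runif(3, -config$partial_rotation_range,
                        config$partial_rotation_range)
    shift <- round(stats::runif(3, -config$partial_translation_range,
                                config$partial_translation_range))
    region <- x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    dim(region) <- c(rs, rs, rs)
    R <- rot_mat(3, ang[3]) %*% rot_mat(2, ang[2]) %*% rot_mat(1, ang[1])
    moved <- if (all(ang == 0) && all(shift == 0)) region else {
      affine_resample_nn(region, R, zoom = 1, shift = shift)
    }
    x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- moved
    out <- rewrap_vol(x, volume)
    attr(out, "aug_log") <- list(op = "random_affine_partial", lo = lo, hi = hi,
                                 angles = ang, shift = shift)
    out
  })
}

#' Apply the configured augmentations to a volume
#'
#' Each operator fires independently with its configured probability, in the
#' order flip, affine, cutout, partial affine.
#'
#' @inheritParams random_affine
#' @return The augmented volume.
#' @export
augment_volume <- function(volume, config = augmentation_config(), seed = NULL) {
  with_seed(seed, {
    out <- volume
    if (stats::runif(1) < config$p_flip) out <- flip_lateral(out, config$flip_axis)
    if (stats::runif(1) < config$p_affine) out <- random_affine(out, config)
    if (stats::runif(1) < config$p_cutout) out <- cutout(out, config)
    if (stats::runif(1) < config$p_partial) out <- random_affine_partial(out, config)
    out
  })
}
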