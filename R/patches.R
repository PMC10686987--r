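#' Tile a volume into a grid bag of patches
#'
#' Splits a cubic volume into non-overlapping cubic patches that tile it
#' exactly, in fixed lexicographic grid order (first array axis fastest).
#' A `(300, 300, 300)` volume with patch side 100 — or a `(60, 60, 60)`
#' volume with patch side 20 — yields a bag of 27 patches.
#'
#' @param volume 3D array or [volume_image]; every side must be divisible by
#'   `patch_side`.
#' @param patch_side patch side length in voxels.
#' @param label optional bag label in `{0, 1}` (female = 1).
#' @return A `patch_bag`: list with `patches` (array
#'   `patch_side^3 x K`), `origins` (K x 3 matrix of 1-based corner
#'   indices), `k`, `patch_side`, `label`.
#' @export
grid_patches <- function(volume, patch_side, label = NULL) {
  x <- as_vol_array(volume)
  d <- dim(x)
  if (length(d) != 3L) stop("'volume' must be 3D", call. = FALSE)
  patch_side <- as.integer(patch_side)
  if (any(d %% patch_side != 0L)) {
    stop(sprintf("volume sides (%s) are not divisible by patch side %d",
                 paste(d, collapse = ", "), patch_side), call. = FALSE)
  }
  nper <- d %/% patch_side
  starts <- lapply(nper, function(n) (seq_len(n) - 1L) * patch_side + 1L)
  grid <- as.matrix(expand.grid(starts[[1]], starts[[2]], starts[[3]]))
  K <- nrow(grid)
  p <- patch_side
  patches <- array(0, c(p, p, p, K))
  for (k in seq_len(K)) {
    o <- grid[k, ]
    patches[, , , k] <- x[o[1]:(o[1] + p - 1), o[2]:(o[2] + p - 1),
                          o[3]:(o[3] + p - 1)]
  }
  new_patch_bag(patches, origins = grid, label = label, source_dim = d)
}

new_patch_bag <- function(patches, origins, label = NULL, source_dim = NULL) {
  K <- dim(patches)[4]
  structure(list(patches = patches, origins = origins, k = K,
                 patch_side = dim(patches)[1], label = label,
                 source_dim = source_dim %||% dim(patches)[1:3]),
            class = "patch_bag")
}

#' @export
print.patch_bag <- function(x, ...) {
  cat(sprintf("<patch_bag> %d patches of %d^3%s\n", x$k, x$patch_side,
              if (!is.null(x$label)) sprintf("  label %d", x$label) else ""))
  invisible(x)
}

#' Reassemble a grid bag into its source volume
#'
#' Scatters each patch back to its origin. For a bag produced by
#' [grid_patches] this reproduces the input volume exactly.
#'
#' @param bag a `patch_bag`.
#' @param weights optional length-K weights; each patch is multiplied by its
#'   weight before scattering (used for attention heatmaps).
#' @return A 3D array.
#' @export
assemble_patches <- function(bag, weights = NULL) {
  stopifnot(inherits(bag, "patch_bag"))
  if (!is.null(weights) && length(weights) != bag$k) {
    stop("'weights' length does not match the number of patches", call. = FALSE)
  }
  d <- bag$source_dim
  out <- array(0, d)
  p <- bag$patch_side
  for (k in seq_len(bag$k)) {
    o <- bag$origins[k, ]
    w <- if (is.null(weights)) 1 else weights[k]
    out[o[1]:(o[1] + p - 1), o[2]:(o[2] + p - 1), o[3]:(o[3] + p - 1)] <-
      w * bag$patches[, , , k]
  }
  out
}
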