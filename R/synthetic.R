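#' Parameters of the synthetic skull phenotype
#'
#' Describes the analytic geometry used to synthesize class-labelled binary
#' "skull" volumes: a hollow spherical cranial shell, a hollow half
#' superellipsoid "mandible" whose cross-section morphs from rounded
#' (female-like) to square (male-like) as its angularity grows, and a
#' sagittal "ridge" crest on top of the shell that is more pronounced in
#' males. Putrefaction is emulated by random foreground deletions (porosity)
#' and injury by an optional missing cuboid (defect).
#'
#' @param side volume side length in voxels (default 60; 300 supported).
#' @param shell_center cranial shell centre, voxel coordinates (default
#'   `side * c(0.5, 0.5, 0.6)`).
#' @param shell_radius outer radius of the cranial shell in voxels.
#' @param shell_thickness shell thickness in voxels.
#' @param mandible_center centre of the mandible region.
#' @param mandible_axes semi-axes (a, b, c) of the mandible superellipsoid.
#' @param mandible_angularity baseline angularity in \[0, 1\]: 0 = rounded,
#'   1 = square cross-section.
#' @param angularity_sd per-specimen standard deviation of angularity.
#' @param class_gap separation between the female and male mean angularity
#'   (female mean = baseline − gap/2, male mean = baseline + gap/2), clamped
#'   to \[0, 1\].
#' @param ridge_amplitude maximal ridge protrusion height in voxels; males
#'   express the full amplitude, females 85% of it (a deliberately weak
#'   global signal next to the mandible shape).
#' @param porosity_rate probability that each foreground voxel is deleted.
#' @param defect_probability probability that one random cuboid is zeroed.
#' @param defect_size maximal defect cuboid side in voxels.
#' @return A list of class `skull_params`.
#' @export
skull_params <- function(side = 60,
                         shell_center = side * c(0.5, 0.5, 0.6),
                         shell_radius = 0.30 * side,
                         shell_thickness = max(2, 0.04 * side),
                         mandible_center = side * c(0.5, 0.5, 1 / 6),
                         mandible_axes = side * c(0.15, 0.15, 0.10),
                         mandible_angularity = 0.5,
                         angularity_sd = 0.12,
                         class_gap = 0.6,
                         ridge_amplitude = max(2, side / 30),
                         porosity_rate = 0.05,
                         defect_probability = 0.10,
                         defect_size = round(side / 7.5)) {
  p <- list(side = as.integer(side), shell_center = shell_center,
            shell_radius = shell_radius, shell_thickness = shell_thickness,
            mandible_center = mandible_center, mandible_axes = mandible_axes,
            mandible_angularity = mandible_angularity,
            angularity_sd = angularity_sd, class_gap = class_gap,
            ridge_amplitude = ridge_amplitude, porosity_rate = porosity_rate,
            defect_probability = defect_probability,
            defect_size = as.integer(defect_size))
  for (nm in c("porosity_rate", "defect_probability", "mandible_angularity")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  if (any(p$shell_center + p$shell_radius + p$ridge_amplitude > side) ||
      any(p$shell_center - p$shell_radius < 0)) {
    stop("shell_radius + ridge_amplitude does not fit inside the volume bounds",
         call. = FALSE)
  }
  if (any(p$mandible_center + p$mandible_axes > side) ||
      any(p$mandible_center - p$mandible_axes < 0)) {
    stop("mandible geometry does not fit inside the volume bounds", call. = FALSE)
  }
  class(p) <- "skull_params"
  p
}

# Cached voxel-centre coordinate grids for a given side length.
coord_grid <- function(side) {
  g <- seq_len(side) - 0.5
  list(x = g, y = g, z = g)
}

# Noise-free skull geometry for given drawn phenotype values.
# Returns a binary array of dim side^3. Deterministic (no RNG).
skull_geometry <- function(params, angularity, ridge_height) {
  s <- params$side
  g <- seq_len(s) - 0.5
  cx <- params$shell_center[1]; cy <- params$shell_center[2]; cz <- params$shell_center[3]
  dx <- g - cx; dy <- g - cy; dz <- g - cz
  # spherical shell: radial distance in [r - t, r]
  r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  r <- sqrt(r2)
  shell <- r <= params$shell_radius & r >= params$shell_radius - params$shell_thickness
  # sagittal ridge: crest along the midline on the upper shell surface
  if (ridge_height > 0) {
    near_mid <- abs(dx) <= 1.5                 # varies along x (axis 1)
    upper <- dz > 0                            # varies along z (axis 3)
    band <- r > params$shell_radius & r <= params$shell_radius + ridge_height
    near_arr <- array(rep(near_mid, times = s * s), c(s, s, s))
    upper_arr <- array(rep(upper, each = s * s), c(s, s, s))
    ridge <- near_arr & upper_arr & band
    shell <- shell | ridge
  }
  # mandible: lower half of a hollow superellipsoid, exponent grows with angularity
  mnd <- mandible_mask(params, angularity)
  out <- (shell | mnd) * 1.0
  dim(out) <- c(s, s, s)
  out
}

# Lower-half hollow superellipsoid mandible mask (logical array).
mandible_mask <- function(params, angularity) {
  s <- params$side
  g <- seq_len(s) - 0.5
  mc <- params$mandible_center; ax <- params$mandible_axes
  p <- 2 + 6 * max(0, min(1, angularity))       # 2 (round) .. 8 (square)
  ux <- abs((g - mc[1]) / ax[1])^p
  uy <- abs((g - mc[2]) / ax[2])^p
  uz <- abs((g - mc[3]) / ax[3])^p
  rho <- (outer(outer(ux, uy, "+"), uz, "+"))^(1 / p)
  lower <- g - mc[3] <= 0
  lower_arr <- array(rep(lower, each = s * s), c(s, s, s))
  rho <= 1 & rho >= 0.72 & lower_arr
}

#' Measure mandible angularity of a volume by corner-voxel occupancy
#'
#' Direct geometric readout of the class signal: the fraction of voxels in
#' the corner regions of the mandible bounding box (both lateral offsets
#' beyond 70% of the semi-axes, lower half) that are foreground. Rounded
#' mandibles leave the corners empty; square ones fill them.
#'
#' @param volume binary 3D array or [volume_image].
#' @param params the [skull_params] used to generate the volume.
#' @return Proportion in \[0, 1\].
#' @export
measure_angularity <- function(volume, params) {
  x <- if (inherits(volume, "volume_image")) volume$values else volume
  s <- params$side
  g <- seq_len(s) - 0.5
  mc <- params$mandible_center; ax <- params$mandible_axes
  in_x <- abs(g - mc[1]) >= 0.7 * ax[1] & abs(g - mc[1]) <= ax[1]
  in_y <- abs(g - mc[2]) >= 0.7 * ax[2] & abs(g - mc[2]) <= ax[2]
  in_z <- (mc[3] - g) >= 0 & (mc[3] - g) <= ax[3]
  corner <- outer(outer(in_x, in_y, "&"), in_z, "&")
  mean(x[corner])
}

#' Generate one synthetic skull specimen
#'
#' Draws the specimen's phenotype (mandible angularity from the
#' sex-conditional distribution, ridge height), synthesizes the noise-free
#' geometry, then applies porosity (independent foreground deletions) and at
#' most one cuboid defect. Bit-for-bit reproducible for identical
#' `(params, sex, age, seed)`.
#'
#' @param params a [skull_params].
#' @param sex `"female"` or `"male"`.
#' @param age age in years (metadata only; does not alter geometry).
#' @param seed integer seed for this specimen.
#' @param id optional id string.
#' @return A list of class `synthetic_specimen` with elements `id`, `volume`
#'   (binary [volume_image]), `sex`, `age`, `seed`, `angularity`,
#'   `ridge_height`.
#' @export
generate_specimen <- function(params, sex = c("female", "male"), age = 70,
                              seed = 1L, id = NULL) {
  stopifnot(inherits(params, "skull_params"))
  sex <- match.arg(sex)
  with_seed(seed, {
    mu <- params$mandible_angularity +
      (if (sex == "male") 0.5 else -0.5) * params$class_gap
    ang <- max(0, min(1, stats::rnorm(1, mu, params$angularity_sd)))
    ridge_scale <- if (sex == "male") 1 else 0.85   # weak global signal;
    # the dominant sex signal is the mandible shape, as the generator intends
    ridge <- params$ridge_amplitude * ridge_scale *
      max(0, min(1.5, stats::rnorm(1, 1, 0.15)))
    vol <- skull_geometry(params, ang, ridge)
    if (params$porosity_rate > 0) {
      fg <- which(vol == 1)
      drop <- fg[stats::runif(length(fg)) < params$porosity_rate]
      vol[drop] <- 0
    }
    if (params$defect_probability > 0 &&
        stats::runif(1) < params$defect_probability) {
      s <- params$side
      sz <- pmax(1L, sample.int(params$defect_size, 3, replace = TRUE))
      lo <- sapply(1:3, function(a) sample.int(s - sz[a] + 1L, 1))
      vol[lo[1]:(lo[1] + sz[1] - 1), lo[2]:(lo[2] + sz[2] - 1),
          lo[3]:(lo[3] + sz[3] - 1)] <- 0
    }
    structure(
      list(id = id %||% sprintf("%s-%d", substr(sex, 1, 1), seed),
           volume = volume_image(vol, spacing = c(1, 1, 1), orientation = "RAS",
                                 dtype_role = "binary"),
           sex = sex, age = age, seed = seed,
           angularity = ang, ridge_height = ridge),
      class = "synthetic_specimen")
  })
}

#' Generate a labelled synthetic cohort
#'
#' Ages are drawn per sex from truncated normal distributions (default: both
#' sexes share mean 75, sd 12, truncated to 18-100 years, so the two age
#' distributions overlap as they do after age matching). Every specimen uses
#' its own RNG stream derived from `(seed, id)`, so the cohort is reproducible
#' independent of generation order.
#'
#' @param n_female,n_male specimen counts per sex (> 0).
#' @param params a [skull_params].
#' @param age_model list with elements `female` and `male`, each
#'   `list(mean, sd)`; ages are truncated to `[18, 100]`.
#' @param seed cohort seed.
#' @param volumes if `FALSE`, skip volume synthesis and return metadata only
#'   (fast path for cohort/matching studies).
#' @return A list of class `synthetic_cohort` with `specimens` (list of
#'   [generate_specimen] results, or `NULL` ids if `volumes = FALSE`) and
#'   `metadata` (data.frame `id`, `sex`, `age`).
#' @export
generate_cohort <- function(n_female, n_male, params = skull_params(),
                            age_model = list(female = list(mean = 75, sd = 12),
                                             male = list(mean = 75, sd = 12)),
                            seed = 1L, volumes = TRUE) {
  if (n_female <= 0 || n_male <= 0) stop("counts must be positive", call. = FALSE)
  ids <- c(sprintf("F%03d", seq_len(n_female)), sprintf("M%03d", seq_len(n_male)))
  sexes <- rep(c("female", "male"), c(n_female, n_male))
  specimens <- vector("list", length(ids))
  ages <- numeric(length(ids))
  for (i in seq_along(ids)) {
    s_i <- derive_seed(seed, ids[i])
    am <- age_model[[sexes[i]]]
    ages[i] <- with_seed(s_i, draw_trunc_age(am$mean, am$sd))
    if (volumes) {
      specimens[[i]] <- generate_specimen(params, sexes[i], ages[i],
                                          seed = s_i, id = ids[i])
    }
  }
  structure(
    list(specimens = if (volumes) specimens else NULL,
         metadata = data.frame(id = ids, sex = sexes, age = ages,
                               stringsAsFactors = FALSE),
         params = params, seed = seed),
    class = "synthetic_cohort")
}

# inverse-CDF truncated normal draw on [18, 100]
draw_trunc_age <- function(mean, sd, lo = 18, hi = 100) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(1) * (phi - plo), mean, sd)
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI volume per specimen plus a `metadata.csv` with columns
#' `id,sex,age`.
#'
#' @param cohort a [generate_cohort] result with volumes.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$specimens)) stop("cohort was generated without volumes", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in cohort$specimens) {
    write_nifti(sp$volume, file.path(dir, paste0(sp$id, ".nii.gz")))
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Build a single-signal patch bag
#'
#' A unit-test fixture for attention: `k_patches` binary noise patches
#' (density 0.5) of which exactly one — at `signal_index` — carries the
#' class signal: a centred cube whose fill density is
#' `0.5 + signal_strength * (label - 0.5)`. At `signal_strength = 0` the bag
#' is indistinguishable from pure noise; at strength 1 and label 1 the cube
#' is solid, at label 0 it is empty.
#'
#' @param k_patches number of patches (>= 1).
#' @param signal_index 1-based index of the signal patch.
#' @param signal_strength in \[0, 1\].
#' @param seed RNG seed.
#' @param patch_side patch side in voxels (default 10).
#' @param label bag label in `{0, 1}` (female = 1); drawn uniformly if `NULL`.
#' @return A `patch_bag` (see [grid_patches]) with its `label` field set and
#'   an attribute `signal_index`.
#' @export
make_signal_bag <- function(k_patches, signal_index, signal_strength,
                            seed = 1L, patch_side = 10, label = NULL) {
  if (signal_index < 1 || signal_index > k_patches) {
    stop(sprintf("signal_index %d outside 1..%d", signal_index, k_patches),
         call. = FALSE)
  }
  if (signal_strength < 0 || signal_strength > 1) {
    stop("'signal_strength' must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    y <- label %||% stats::rbinom(1, 1, 0.5)
    p <- patch_side
    patches <- array(0, c(p, p, p, k_patches))
    for (k in seq_len(k_patches)) {
      patches[, , , k] <- (stats::runif(p^3) < 0.5) * 1.0
    }
    half <- max(1L, p %/% 2L)
    off <- (p - half) %/% 2
    cube_idx <- off + seq_len(half)
    dens <- 0.5 + signal_strength * (y - 0.5)
    patches[cube_idx, cube_idx, cube_idx, signal_index] <-
      (stats::runif(half^3) < dens) * 1.0
    bag <- new_patch_bag(patches,
                         origins = matrix(1L, nrow = k_patches, ncol = 3),
                         label = y)
    attr(bag, "signal_index") <- as.integer(signal_index)
    bag
  })
}
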