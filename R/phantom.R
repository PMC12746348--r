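# Synthetic head-and-neck MRI phantom generator. The phantoms reproduce the
# summary statistics of the pre-radiotherapy T2-weighted cohort the model
# targets: right-skewed tumor voxel fractions in roughly 0.000-0.004,
# tumor-region mean intensities peaking at 50-100 with standard deviations
# 0-50, at most one primary lesion (GTVp, label 1) and a variable number of
# nodal lesions (GTVn, label 2), on a 0.5 x 0.5 x 2.0 mm grid.
#
# Anatomical rationale for lesion placement: oropharyngeal primaries sit
# near the midline while nodal disease lies in the lateral neck levels, so
# GTVp is sampled near the in-plane centre of the head and GTVn laterally.
# This gives the phantoms a learnable positional cue separating the two
# foreground classes, standing in for the anatomy a real scan provides.

#' Phantom cohort specification
#'
#' @param volume_shape Voxel grid `(X, Y, Z)`. Default `c(64, 64, 32)` keeps
#'   test suites fast; full-size `c(512, 512, Z)` grids are accepted.
#' @param spacing_mm Voxel spacing in mm, default `c(0.5, 0.5, 2.0)`
#'   (in-plane / slice thickness).
#' @param gtvp_count Number of primary lesions, 0 or 1 (at most one primary
#'   per patient).
#' @param gtvn_count Number of nodal lesions, `>= 0`.
#' @param target_voxel_fraction_range Range the total tumor voxel fraction
#'   is drawn from; default `c(0, 0.004)`.
#' @param tumor_mean_intensity_range Range of per-lesion mean intensity,
#'   default `c(50, 100)`.
#' @param tumor_intensity_sd_range Range of the within-lesion intensity
#'   standard deviation, default `c(0, 50)`.
#' @param background_intensity_model `c(mean, sd)` of head-tissue intensity;
#'   air outside the head is exactly zero (the "invalid" region).
#' @param noise_sd Standard deviation of additive acquisition noise applied
#'   inside the head (Rician-like: the result is magnitude-clamped at zero).
#' @param seed Default generation seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(volume_shape = c(64L, 64L, 32L),
                         spacing_mm = c(0.5, 0.5, 2.0),
                         gtvp_count = 1L,
                         gtvn_count = 2L,
                         target_voxel_fraction_range = c(0, 0.004),
                         tumor_mean_intensity_range = c(50, 100),
                         tumor_intensity_sd_range = c(0, 50),
                         background_intensity_model = c(20, 8),
                         noise_sd = 2,
                         seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 8L)) {
    stop("`volume_shape` must be three dimensions, each >= 8 voxels")
  }
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be three positive values")
  }
  if (!gtvp_count %in% c(0L, 1L)) {
    stop("`gtvp_count` must be 0 or 1 (at most one primary lesion per case)")
  }
  if (gtvn_count < 0L) stop("`gtvn_count` must be >= 0")
  ranges <- list(target_voxel_fraction_range = target_voxel_fraction_range,
                 tumor_mean_intensity_range = tumor_mean_intensity_range,
                 tumor_intensity_sd_range = tumor_intensity_sd_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2]) stop("`", nm, "` must be an ordered (low, high) pair")
  }
  if (any(target_voxel_fraction_range < 0) || any(target_voxel_fraction_range > 1)) {
    stop("`target_voxel_fraction_range` must lie within [0, 1]")
  }
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  structure(list(volume_shape = volume_shape, spacing_mm = spacing_mm,
                 gtvp_count = as.integer(gtvp_count),
                 gtvn_count = as.integer(gtvn_count),
                 target_voxel_fraction_range = target_voxel_fraction_range,
                 tumor_mean_intensity_range = tumor_mean_intensity_range,
                 tumor_intensity_sd_range = tumor_intensity_sd_range,
                 background_intensity_model = background_intensity_model,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

new_mri_case <- function(case_id, volume, mask, spacing_mm) {
  stopifnot(all(dim(volume) == dim(mask)),
            all(mask %in% c(0L, 1L, 2L)),
            all(is.finite(volume)), all(volume >= 0))
  structure(list(case_id = case_id, volume = volume,
                 mask = mask, spacing_mm = spacing_mm),
            class = "mri_case")
}

# head: an axis-aligned ellipsoid of soft tissue filling most of the grid
head_mask <- function(shape) {
  cx <- (shape + 1) / 2
  ax <- c(0.42, 0.46, 0.60) * shape
  q <- outer(outer(((seq_len(shape[1]) - cx[1]) / ax[1])^2,
                   ((seq_len(shape[2]) - cx[2]) / ax[2])^2, `+`),
             ((seq_len(shape[3]) - cx[3]) / ax[3])^2, `+`)
  q <= 1
}

# smoothly perturbed ellipsoid lesion; returns a logical array over `shape`
lesion_blob <- function(shape, centre, target_vox, spacing) {
  # physical isotropy: semi-axes scale inversely with spacing per axis,
  # normalised so the expected voxel volume matches target_vox
  w <- (1 / spacing) / prod(1 / spacing)^(1 / 3)
  jit <- exp(runif(3, -0.2, 0.2))
  jit <- jit / prod(jit)^(1 / 3)
  r0 <- (3 * target_vox / (4 * pi))^(1 / 3)
  ax <- pmax(r0 * w * jit, 0.8)
  q <- outer(outer(((seq_len(shape[1]) - centre[1]) / ax[1])^2,
                   ((seq_len(shape[2]) - centre[2]) / ax[2])^2, `+`),
             ((seq_len(shape[3]) - centre[3]) / ax[3])^2, `+`)
  # low-frequency separable sinusoid perturbs the threshold so boundaries
  # stay smooth but non-ellipsoidal
  ph <- runif(3, 0, 2 * pi)
  amp <- 0.15
  s1 <- sin(seq_len(shape[1]) / max(4, ax[1]) + ph[1])
  s2 <- sin(seq_len(shape[2]) / max(4, ax[2]) + ph[2])
  s3 <- sin(seq_len(shape[3]) / max(2, ax[3]) + ph[3])
  pert <- amp * outer(outer(s1, s2, `+`), s3, `+`) / 3
  q <= 1 + pert
}

#' Generate one synthetic MRI case
#'
#' Draws a total tumor voxel fraction from a right-skewed distribution over
#' the spec range, splits the budget across the requested lesions, places
#' the primary lesion centrally and nodal lesions laterally inside the head
#' (mutually disjoint), fills lesions with `mean + sd * N(0,1)` intensities
#' drawn from the spec ranges, and adds magnitude-clamped Gaussian noise to
#' the head region. Identical `spec` and `seed` give bit-identical cases.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param case_id Identifier stored in the case.
#' @return An `mri_case` list: `case_id`, `volume` (nonnegative intensities),
#'   `mask` (integer labels over `{0,1,2}`), `spacing_mm`.
#' @export
generate_case <- function(spec = phantom_spec(), seed = spec$seed,
                          case_id = sprintf("case_%03d", seed)) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  shape <- spec$volume_shape
  V <- prod(shape)
  n_lesions <- spec$gtvp_count + spec$gtvn_count
  min_vox <- 24
  frange <- spec$target_voxel_fraction_range

  mask <- array(0L, shape)
  head <- head_mask(shape)
  vol <- array(0, shape)
  bg <- spec$background_intensity_model
  vol[head] <- abs(rnorm(sum(head), bg[1], bg[2]))

  if (n_lesions > 0L) {
    lo_feasible <- n_lesions * min_vox / V
    if (lo_feasible > frange[2]) {
      stop("infeasible target_voxel_fraction_range: ", n_lesions,
           " lesions of >= ", min_vox, " voxels need fraction >= ",
           signif(lo_feasible, 3), " but the upper bound is ", frange[2])
    }
    # right-skewed draw, kept away from the top of the range so that the
    # realised (thresholded) blobs stay inside it
    f <- frange[1] + (frange[2] - frange[1]) * 0.7 * rbeta(1, 1.3, 4)
    f <- min(max(f, lo_feasible), frange[2] * 0.85)
    budget <- f * V
    shares <- if (spec$gtvp_count == 1L) {
      c(0.55, rep(0.45 / max(spec$gtvn_count, 1), spec$gtvn_count))
    } else {
      rep(1 / n_lesions, n_lesions)
    }
    labels <- c(rep(1L, spec$gtvp_count), rep(2L, spec$gtvn_count))

    centres <- list()
    radii <- numeric(0)
    draw_centre <- function(label, rad) {
      cx <- (shape + 1) / 2
      for (try in 1:200) {
        if (label == 1L) {
          ctr <- c(cx[1] + runif(1, -0.10, 0.10) * shape[1],
                   cx[2] + runif(1, -0.10, 0.10) * shape[2],
                   cx[3] + runif(1, -0.25, 0.25) * shape[3])
        } else {
          side <- sample(c(-1, 1), 1)
          ctr <- c(cx[1] + side * runif(1, 0.17, 0.30) * shape[1],
                   cx[2] + runif(1, -0.15, 0.15) * shape[2],
                   cx[3] + runif(1, -0.30, 0.30) * shape[3])
        }
        ok <- TRUE
        for (i in seq_along(centres)) {
          if (sqrt(sum((ctr - centres[[i]])^2)) < rad + radii[i] + 2) ok <- FALSE
        }
        if (ok) return(ctr)
      }
      stop("could not place ", n_lesions, " disjoint lesions in a ",
           paste(shape, collapse = "x"), " volume")
    }

    for (i in seq_len(n_lesions)) {
      tv <- max(budget * shares[i], min_vox)
      rad <- (3 * tv / (4 * pi))^(1 / 3) * 1.6
      ctr <- draw_centre(labels[i], rad)
      centres[[i]] <- ctr
      radii <- c(radii, rad)
      blob <- lesion_blob(shape, ctr, tv, spec$spacing_mm)
      blob <- blob & head & mask == 0L      # lesions disjoint, inside the head
      mask[blob] <- labels[i]
      mu <- runif(1, spec$tumor_mean_intensity_range[1],
                  spec$tumor_mean_intensity_range[2])
      sdv <- runif(1, spec$tumor_intensity_sd_range[1],
                   spec$tumor_intensity_sd_range[2])
      vol[blob] <- pmax(mu + sdv * rnorm(sum(blob)), 0.5)
    }
  }

  if (spec$noise_sd > 0) {
    vol[head] <- abs(vol[head] + rnorm(sum(head), 0, spec$noise_sd))
  }
  new_mri_case(case_id, vol, mask, spec$spacing_mm)
}

#' Generate a reproducible cohort of synthetic cases
#'
#' Per-case seeds are `base_seed + case index - 1`, so the cohort is
#' deterministic under `base_seed` while cases remain distinct.
#'
#' @param n Number of cases, `>= 1`.
#' @param base_seed Integer base seed.
#' @param spec A [phantom_spec()] shared by all cases.
#' @return Named list of `mri_case` objects with unique ids.
#' @export
generate_cohort <- function(n, base_seed = 1L, spec = phantom_spec()) {
  if (n < 1L) stop("`n` must be >= 1")
  cases <- lapply(seq_len(n), function(i) {
    generate_case(spec, seed = base_seed + i - 1L,
                  case_id = sprintf("case_%03d", i))
  })
  names(cases) <- vapply(cases, `[[`, character(1), "case_id")
  cases
}

#' Summary statistics of a phantom cohort
#'
#' Per-case tumor voxel fraction and tumor-region intensity mean and
#' standard deviation, used to validate the generator against the target
#' cohort statistics. Cases without tumor voxels report `NA` intensity
#' statistics (the fraction is 0).
#'
#' @param cases Nonempty list of `mri_case` objects.
#' @return `data.frame` with one row per case.
#' @export
cohort_statistics <- function(cases) {
  if (length(cases) == 0L) stop("`cases` must be a nonempty list")
  do.call(rbind, lapply(cases, function(cs) {
    fg <- cs$mask != 0L
    nfg <- sum(fg)
    data.frame(case_id = cs$case_id,
               voxel_fraction = nfg / length(cs$mask),
               tumor_mean = if (nfg > 0) mean(cs$volume[fg]) else NA_real_,
               tumor_sd = if (nfg > 1) stats::sd(cs$volume[fg]) else NA_real_,
               n_gtvp_voxels = sum(cs$mask == 1L),
               n_gtvn_voxels = sum(cs$mask == 2L),
               stringsAsFactors = FALSE)
  }))
}
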