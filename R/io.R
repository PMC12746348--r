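# NIfTI reading/writing, intensity normalisation over the valid region,
# resampling to network resolution, lesion-slice screening, and
# test/five-fold partitioning.

#' Write a case as paired NIfTI files
#'
#' Writes `<id>_T2.nii.gz` (intensities, float64) and `<id>_mask.nii.gz`
#' (integer labels) with the voxel spacing recorded in the header.
#'
#' @param case An `mri_case`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the two paths, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "mri_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img <- RNifti::asNifti(case$volume)
  RNifti::pixdim(img) <- case$spacing_mm
  msk <- RNifti::asNifti(array(as.integer(case$mask), dim(case$mask)))
  RNifti::pixdim(msk) <- case$spacing_mm
  p_img <- file.path(dir, paste0(case$case_id, "_T2.nii.gz"))
  p_msk <- file.path(dir, paste0(case$case_id, "_mask.nii.gz"))
  RNifti::writeNifti(img, p_img, datatype = "double")
  RNifti::writeNifti(msk, p_msk, datatype = "int16")
  invisible(c(p_img, p_msk))
}

#' Read a case from paired NIfTI files
#'
#' @param image_path Path to the intensity volume.
#' @param mask_path Path to the label volume.
#' @param case_id Identifier; by default derived from the image file name.
#' @return An `mri_case`; image/mask shape mismatches and labels outside
#'   `{0,1,2}` are rejected.
#' @export
read_case <- function(image_path, mask_path,
                      case_id = sub("_T2\\.nii(\\.gz)?$", "", basename(image_path))) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  vol <- array(as.vector(img), dim = dim(img))
  mask <- array(as.vector(msk), dim = dim(msk))
  if (!all(dim(vol) == dim(mask))) {
    stop("image/mask shape mismatch: image is ",
         paste(dim(vol), collapse = "x"), " but mask is ",
         paste(dim(mask), collapse = "x"))
  }
  mask <- array(as.integer(round(mask)), dim(mask))
  bad <- setdiff(unique(as.vector(mask)), 0:2)
  if (length(bad) > 0) {
    stop("mask contains labels outside {0,1,2}: ", paste(bad, collapse = ", "))
  }
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  new_mri_case(case_id, vol, mask, spacing)
}

#' Read every `<id>_T2.nii.gz` / `<id>_mask.nii.gz` pair in a directory
#'
#' @param dir Directory of paired NIfTI files.
#' @return Named list of `mri_case` objects.
#' @export
read_cohort <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "_T2\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(imgs) == 0L) stop("no *_T2.nii[.gz] files found in ", dir)
  cases <- lapply(imgs, function(p) {
    mp <- sub("_T2\\.nii", "_mask.nii", p)
    if (!file.exists(mp)) stop("missing mask file for ", basename(p))
    read_case(p, mp)
  })
  names(cases) <- vapply(cases, `[[`, character(1), "case_id")
  cases
}

#' Z-score intensity normalisation over the valid region
#'
#' The valid region is the set of strictly positive voxels (MRI air
#' background is ~0). Valid voxels are z-scored with the valid-region mean
#' and standard deviation; invalid voxels are mapped to the minimum
#' normalised value so they stay at the bottom of the intensity range.
#'
#' @param volume Nonnegative finite 3D intensity array.
#' @return Normalised array of the same shape (valid-region mean 0, sd 1).
#'   A constant valid region yields zeros there, with a warning.
#' @export
normalize_intensity <- function(volume) {
  if (!all(is.finite(volume)) || any(volume < 0)) {
    stop("volume must contain finite nonnegative intensities")
  }
  valid <- volume > 0
  out <- volume
  if (!any(valid)) {
    warning("volume has no valid (positive) voxels; returning zeros")
    out[] <- 0
    return(out)
  }
  v <- volume[valid]
  s <- sqrt(mean((v - mean(v))^2))   # population sd: two-point {1,3} -> {-1,+1}
  if (!is.finite(s) || s == 0) {
    warning("valid region is constant; normalised values set to zero")
    out[valid] <- 0
    out[!valid] <- 0
    return(out)
  }
  z <- (v - mean(v)) / s
  out[valid] <- z
  out[!valid] <- min(z)
  out
}

#' Resample a 2D image/mask pair to network resolution
#'
#' The image is resized with bilinear interpolation and the mask with
#' nearest-neighbour so labels are preserved exactly. Inputs already at the
#' target size are returned unchanged.
#'
#' @param image Numeric 2D array.
#' @param mask Integer 2D array of the same shape.
#' @param side Target side length (default 448).
#' @return List with `image` and `mask`, each `side x side`.
#' @export
resample_slice <- function(image, mask, side = 448L) {
  if (is.null(dim(image)) || length(dim(image)) != 2L || any(dim(image) == 0L)) {
    stop("`image` must be a nonempty 2D array")
  }
  if (!all(dim(image) == dim(mask))) stop("image and mask shapes must match")
  side <- as.integer(side)
  if (all(dim(image) == c(side, side))) {
    return(list(image = image, mask = mask))
  }
  img <- EBImage::resize(image, w = side, h = side, filter = "bilinear")
  msk <- EBImage::resize(mask, w = side, h = side, filter = "none")
  list(image = matrix(as.numeric(img), side, side),
       mask = matrix(as.integer(msk), side, side))
}

#' Indices of axial slices containing pathological regions
#'
#' @param case An `mri_case`.
#' @return Ascending integer indices (third array axis) of slices whose
#'   mask has at least one nonzero voxel; possibly empty.
#' @export
screen_slices <- function(case) {
  stopifnot(inherits(case, "mri_case"))
  per_slice <- apply(case$mask != 0L, 3, sum)
  which(per_slice > 0)
}

#' Build the test / five-fold cross-validation plan
#'
#' Shuffles the ids with the seed, holds out the first third as the
#' independent test set, and splits the remainder into five disjoint
#' validation blocks; each fold trains on the other four blocks. With 150
#' ids this gives the 50/80/20 test/train/validation split.
#'
#' @param case_ids Character vector of at least 10 unique ids.
#' @param seed Shuffling seed.
#' @param n_folds Number of folds (default 5).
#' @return A `fold_plan` list: `test`, `folds` (each `list(train, val)`),
#'   `seed`.
#' @export
make_fold_plan <- function(case_ids, seed = 1L, n_folds = 5L) {
  case_ids <- as.character(case_ids)
  if (anyDuplicated(case_ids)) stop("case ids must be unique")
  n <- length(case_ids)
  if (n < 10L) stop("need at least 10 case ids")
  set.seed(seed)
  shuffled <- sample(case_ids)
  n_test <- round(n / 3)
  if (n - n_test < n_folds) stop("fewer non-test ids than folds")
  test <- shuffled[seq_len(n_test)]
  rest <- shuffled[(n_test + 1L):n]
  # contiguous blocks, so block sizes differ by at most 1
  blocks <- split(rest, cut(seq_along(rest), n_folds, labels = FALSE))
  folds <- lapply(seq_len(n_folds), function(k) {
    list(train = unname(unlist(blocks[-k])), val = unname(blocks[[k]]))
  })
  structure(list(test = test, folds = folds, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Serialise / read a fold plan as JSON
#'
#' @param plan A `fold_plan`.
#' @param path JSON file path.
#' @return `write_fold_plan`: the path, invisibly. `read_fold_plan`: the plan.
#' @export
write_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  jsonlite::write_json(list(test = plan$test,
                            folds = lapply(plan$folds, function(f) {
                              list(train = f$train, val = f$val)
                            }),
                            seed = plan$seed),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- if (is.data.frame(x$folds)) {
    lapply(seq_len(nrow(x$folds)), function(i) {
      list(train = x$folds$train[[i]], val = x$folds$val[[i]])
    })
  } else {
    lapply(x$folds, function(f) list(train = unlist(f$train), val = unlist(f$val)))
  }
  structure(list(test = x$test, folds = folds, seed = as.integer(x$seed[1])),
            class = "fold_plan")
}
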