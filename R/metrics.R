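# Segmentation evaluation: per-case and aggregated Dice, Hausdorff distance
# and its 95th-percentile variant in millimetres, with an explicit
# "undefined" (NA) policy for empty structures.

#' Dice similarity coefficient of two binary masks
#'
#' `2|gt n pred| / (|gt| + |pred|)`. When both masks are empty the
#' coefficient is uninformative and `NA` is returned (never 0 or 1).
#'
#' @param gt,pred Binary (logical or 0/1) arrays of identical shape.
#' @return Scalar in `[0, 1]`, or `NA` if both masks are empty.
#' @export
dsc_pair <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) {
    stop("gt and pred must have identical shapes")
  }
  gt <- gt != 0
  pred <- pred != 0
  denom <- sum(gt) + sum(pred)
  if (denom == 0) return(NA_real_)
  2 * sum(gt & pred) / denom
}

#' Aggregated Dice over a set of cases
#'
#' Pools the intersection and size counts across all cases before taking
#' the ratio, which keeps the metric defined (and meaningful) when some
#' cases lack the structure entirely.
#'
#' @param cases List of `list(gt = , pred = )` binary mask pairs.
#' @return Pooled Dice scalar, or `NA` if every mask in the pool is empty.
#' @export
dsc_agg <- function(cases) {
  if (length(cases) == 0L) stop("`cases` must be a nonempty list")
  inter <- 0
  size <- 0
  for (cs in cases) {
    gt <- cs$gt != 0
    pred <- cs$pred != 0
    if (!all(dim(gt) == dim(pred))) stop("each gt/pred pair must match in shape")
    inter <- inter + sum(gt & pred)
    size <- size + sum(gt) + sum(pred)
  }
  if (size == 0) return(NA_real_)
  2 * inter / size
}

# pairwise Euclidean distances between point matrices (rows = points)
pairwise_dist <- function(P, Q) {
  d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * tcrossprod(P, Q)
  sqrt(pmax(d2, 0))
}

scale_points <- function(P, spacing) {
  sweep(P, 2, spacing, `*`)
}

#' Hausdorff distance between two point sets
#'
#' `max{ h(P,Q), h(Q,P) }` with the directed distance
#' `h(P,Q) = max_p min_q ||p - q||`, computed in millimetres after scaling
#' voxel coordinates by the spacing.
#'
#' @param gt_points,pred_points Matrices of voxel coordinates (rows =
#'   points, columns = axes).
#' @param spacing_mm Positive voxel spacing per axis (default 1).
#' @return Distance in mm, or `NA` if either set is empty.
#' @export
hausdorff <- function(gt_points, pred_points, spacing_mm = NULL) {
  gt_points <- as.matrix(gt_points)
  pred_points <- as.matrix(pred_points)
  if (nrow(gt_points) == 0L || nrow(pred_points) == 0L) return(NA_real_)
  if (is.null(spacing_mm)) spacing_mm <- rep(1, ncol(gt_points))
  P <- scale_points(gt_points, spacing_mm)
  Q <- scale_points(pred_points, spacing_mm)
  D <- pairwise_dist(P, Q)
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

#' Boundary voxels of a binary mask
#'
#' A voxel is on the boundary if it is inside the mask and any
#' face-adjacent neighbour (or the array edge) lies outside.
#'
#' @param mask Binary 3D array.
#' @return Logical array marking boundary voxels.
#' @export
mask_boundary <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  # neighbour values along `ax` displaced by `shift`; out-of-range voxels
  # count as background, so mask voxels at the array edge are boundary
  shifted <- function(ax, shift) {
    out <- array(FALSE, d)
    if (d[ax] <= abs(shift)) return(out)
    src <- lapply(d, seq_len)
    dst <- lapply(d, seq_len)
    if (shift > 0) {
      src[[ax]] <- seq_len(d[ax] - shift)
      dst[[ax]] <- seq_len(d[ax] - shift) + shift
    } else {
      src[[ax]] <- seq_len(d[ax] + shift) - shift
      dst[[ax]] <- seq_len(d[ax] + shift)
    }
    do.call(`[<-`, c(list(out), dst,
                     list(do.call(`[`, c(list(m), src, list(drop = FALSE))))))
  }
  interior <- m
  for (ax in seq_along(d)) {
    interior <- interior & shifted(ax, 1L) & shifted(ax, -1L)
  }
  m & !interior
}

mask_points <- function(mask) {
  which(mask != 0, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance between two binary masks
#'
#' Boundary voxels are extracted from both masks; the directed
#' surface-to-surface minimum distances are pooled over both directions and
#' the 95th percentile of the pooled distribution is returned, in
#' millimetres.
#'
#' @param gt_mask,pred_mask Binary arrays of identical shape.
#' @param spacing_mm Positive voxel spacing per axis.
#' @return HD95 in mm, or `NA` if either mask is empty.
#' @export
hd95 <- function(gt_mask, pred_mask, spacing_mm = NULL) {
  if (!all(dim(gt_mask) == dim(pred_mask))) {
    stop("gt and pred masks must have identical shapes")
  }
  if (sum(gt_mask != 0) == 0L || sum(pred_mask != 0) == 0L) return(NA_real_)
  if (is.null(spacing_mm)) spacing_mm <- rep(1, length(dim(gt_mask)))
  P <- scale_points(mask_points(mask_boundary(gt_mask)), spacing_mm)
  Q <- scale_points(mask_points(mask_boundary(pred_mask)), spacing_mm)
  D <- pairwise_dist(P, Q)
  pooled <- c(apply(D, 1, min), apply(D, 2, min))
  unname(quantile(pooled, 0.95, type = 7))
}

#' Evaluate a predicted label volume against ground truth
#'
#' Computes DSC and HD95 separately for GTVp (label 1) and GTVn (label 2),
#' plus the average over the structures for which the metric is defined.
#'
#' @param gt Integer ground-truth label volume over `{0,1,2}`.
#' @param pred Integer predicted label volume over `{0,1,2}`.
#' @param spacing_mm Voxel spacing (mm) per axis.
#' @param case_id Optional case identifier recorded in the rows.
#' @return `data.frame` with columns `case_id`, `structure`
#'   (`"GTVp"`, `"GTVn"`, `"avg"`), `dsc`, `hd95_mm` (`NA` = undefined).
#' @export
evaluate_volume <- function(gt, pred, spacing_mm = c(1, 1, 1), case_id = "case") {
  if (!all(dim(gt) == dim(pred))) stop("gt and pred must have identical shapes")
  labs <- sort(unique(c(as.vector(gt), as.vector(pred))))
  if (!all(labs %in% c(0, 1, 2))) {
    stop("labels must lie in {0, 1, 2}; found: ",
         paste(setdiff(labs, 0:2), collapse = ", "))
  }
  rows <- lapply(c(GTVp = 1, GTVn = 2), function(lab) {
    g <- gt == lab
    p <- pred == lab
    data.frame(dsc = dsc_pair(g, p),
               hd95_mm = hd95(g, p, spacing_mm))
  })
  out <- data.frame(case_id = case_id,
                    structure = c("GTVp", "GTVn"),
                    dsc = c(rows$GTVp$dsc, rows$GTVn$dsc),
                    hd95_mm = c(rows$GTVp$hd95_mm, rows$GTVn$hd95_mm),
                    stringsAsFactors = FALSE)
  avg <- data.frame(case_id = case_id, structure = "avg",
                    dsc = mean(out$dsc, na.rm = TRUE),
                    hd95_mm = mean(out$hd95_mm, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  avg$dsc[is.nan(avg$dsc)] <- NA_real_
  avg$hd95_mm[is.nan(avg$hd95_mm)] <- NA_real_
  rbind(out, avg)
}

#' Build a full metric report for a set of cases
#'
#' @param gt_list,pred_list Lists of label volumes (matched order).
#' @param spacing_list List of per-case spacings (mm), or a single spacing
#'   recycled across cases.
#' @param case_ids Character vector of identifiers.
#' @return A `metric_report` list with `per_case` (data.frame),
#'   `aggregated` (pooled DSCagg per structure and their mean), and
#'   `averages` (mean DSC / HD95 over defined entries, with counts of
#'   undefined entries).
#' @export
metric_report <- function(gt_list, pred_list, spacing_list = list(c(1, 1, 1)),
                          case_ids = NULL) {
  n <- length(gt_list)
  if (n == 0L || length(pred_list) != n) {
    stop("gt_list and pred_list must be nonempty and of equal length")
  }
  if (is.null(case_ids)) case_ids <- sprintf("case_%03d", seq_len(n))
  if (length(spacing_list) == 1L) spacing_list <- rep(spacing_list, n)
  per_case <- do.call(rbind, lapply(seq_len(n), function(i) {
    evaluate_volume(gt_list[[i]], pred_list[[i]], spacing_list[[i]], case_ids[i])
  }))
  agg <- vapply(c(GTVp = 1, GTVn = 2), function(lab) {
    dsc_agg(lapply(seq_len(n), function(i) {
      list(gt = gt_list[[i]] == lab, pred = pred_list[[i]] == lab)
    }))
  }, numeric(1))
  structures <- per_case[per_case$structure != "avg", ]
  averages <- list(
    mean_dsc = mean(structures$dsc, na.rm = TRUE),
    mean_hd95_mm = mean(structures$hd95_mm, na.rm = TRUE),
    n_undefined_dsc = sum(is.na(structures$dsc)),
    n_undefined_hd95 = sum(is.na(structures$hd95_mm))
  )
  structure(list(per_case = per_case,
                 aggregated = c(as.list(agg), list(mean = mean(agg, na.rm = TRUE))),
                 averages = averages),
            class = "metric_report")
}

#' Serialise a metric report
#'
#' Writes the per-case table as CSV and the aggregate summary as JSON.
#'
#' @param report A [metric_report()].
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the report.
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  if (!is.null(csv_path)) {
    write.csv(report$per_case, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    summary <- list(
      GTVp = list(dsc_agg = report$aggregated$GTVp),
      GTVn = list(dsc_agg = report$aggregated$GTVn),
      avg = list(dsc_agg = report$aggregated$mean,
                 dsc_mean = report$averages$mean_dsc,
                 hd95_mean = report$averages$mean_hd95_mm)
    )
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(report)
}
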