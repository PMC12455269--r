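#' The default region-of-interest table
#'
#' The eight bilateral anatomical regions used throughout the pipeline, with
#' the flag marking which regions enter the transcriptome-atlas comparison.
#' The white-matter region is excluded from the atlas arm (no cortical mRNA
#' expression data; off-target tracer binding dominates there).
#'
#' @return A data.frame with columns `roi_id`, `name`,
#'   `include_in_atlas_comparison`.
#' @export
default_roi_table <- function() {
  data.frame(
    roi_id = c("entorhinal", "limbic_subcortical", "temporal",
               "anterior_cingulate", "precuneus_posterior_cingulate",
               "whole_cortex", "white_matter", "basal_ganglia"),
    name = c("Entorhinal cortex", "Limbic subcortical structures",
             "Temporal lobe cortex", "Rostral anterior cingulate",
             "Precuneus and posterior cingulate", "Whole cortex",
             "White matter", "Basal ganglia"),
    include_in_atlas_comparison = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                    FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Downsample a boolean mask to a coarser grid as volume-fraction overlap
#'
#' Each coarse voxel receives the exact fraction of its `factor^3` fine-grid
#' children lying inside the mask ("probability of inclusion" in the coarse
#' space). Fine dimensions must be divisible by the factor; no implicit
#' padding is performed.
#'
#' @param mask logical (or 0/1 numeric) 3D array on the fine grid.
#' @param factor positive integer decimation factor, scalar or length 3.
#' @return Numeric 3D array of inclusion fractions in `[0, 1]` on the coarse
#'   grid.
#' @export
downsample_mask_fraction <- function(mask, factor) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  f <- as.integer(rep(factor, length.out = 3))
  if (any(f < 1)) stop("factor must be a positive integer", call. = FALSE)
  d <- dim(mask)
  if (any(d %% f != 0)) {
    stop(sprintf("fine grid dims (%s) not divisible by factor (%s)",
                 paste(d, collapse = "x"), paste(f, collapse = "x")),
         call. = FALSE)
  }
  cd <- d %/% f
  m <- array(as.numeric(mask), c(f[1], cd[1], f[2], cd[2], f[3], cd[3]))
  m <- aperm(m, c(1, 3, 5, 2, 4, 6))
  dim(m) <- c(prod(f), prod(cd))
  frac <- colSums(m) / prod(f)
  array(frac, cd)
}

#' Threshold an inclusion-probability mask
#'
#' A coarse voxel is included iff its inclusion probability is at least
#' `tau` (inclusive boundary: probability exactly `tau` is kept). The
#' default 0.9 mitigates partial-volume effects at ROI borders.
#'
#' @param prob numeric 3D array of probabilities in `[0, 1]`.
#' @param tau threshold in `(0, 1]`; default 0.9.
#' @return Logical 3D array.
#' @export
threshold_mask <- function(prob, tau = 0.9) {
  stopifnot(is.array(prob), length(dim(prob)) == 3)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau > 1) {
    stop("tau must lie in (0, 1]", call. = FALSE)
  }
  prob >= tau
}

#' Extract voxel values and their mean over an ROI mask
#'
#' Values are returned in the package's fixed voxel ordering (first array
#' index fastest), so voxels pair up identically across modalities on a
#' shared grid. Non-finite map voxels are excluded with a logged count.
#'
#' @param map 3D numeric array.
#' @param mask logical 3D array on the same grid.
#' @param roi_id label used in error messages and logs.
#' @return List with `values` (finite voxel values), `mean`, `n` (finite
#'   count) and `n_excluded` (non-finite count inside the mask).
#' @export
extract_roi_values <- function(map, mask, roi_id = "roi") {
  .check_same_grid(map, mask, "map and ROI mask")
  vals <- .mask_values(map, mask)
  keep <- is.finite(vals)
  n_excluded <- sum(!keep)
  vals <- vals[keep]
  if (length(vals) == 0) {
    stop(sprintf("ROI '%s': mask empty after excluding non-finite voxels",
                 roi_id), call. = FALSE)
  }
  if (n_excluded > 0) {
    message(sprintf("extract_roi_values: ROI '%s' excluded %d non-finite voxel(s)",
                    roi_id, n_excluded))
  }
  list(values = vals, mean = mean(vals), n = length(vals),
       n_excluded = n_excluded)
}

#' Carve an axis-aligned box mask
#'
#' @param dim grid dimensions (length 3).
#' @param lo,hi inclusive 1-based corner indices (length 3).
#' @return Logical 3D array.
#' @export
box_mask <- function(dim, lo, hi) {
  stopifnot(length(dim) == 3, length(lo) == 3, length(hi) == 3,
            all(lo >= 1), all(hi <= dim), all(lo <= hi))
  m <- array(FALSE, dim)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

#' Carve a spherical mask
#'
#' @param dim grid dimensions (length 3).
#' @param centre voxel-index centre (length 3).
#' @param radius radius in voxels.
#' @return Logical 3D array.
#' @export
sphere_mask <- function(dim, centre, radius) {
  stopifnot(length(dim) == 3, length(centre) == 3, radius > 0)
  idx <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                     z = seq_len(dim[3]))
  d2 <- (idx$x - centre[1])^2 + (idx$y - centre[2])^2 + (idx$z - centre[3])^2
  array(d2 <= radius^2, dim)
}
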