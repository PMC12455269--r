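#' Voxel-wise Pearson correlation between two maps over an ROI
#'
#' Pairs voxels of two co-registered maps inside a boolean mask (fixed
#' voxel ordering) and returns the Pearson correlation over
#' pairwise-complete finite voxels.
#'
#' @param map_a,map_b 3D numeric arrays on a shared grid.
#' @param mask logical 3D array.
#' @return Pearson r (scalar). Errors with "zero variance in ROI" if either
#'   map is constant over the mask, or if fewer than 3 finite pairs remain.
#' @export
voxelwise_pearson <- function(map_a, map_b, mask) {
  .check_same_grid(map_a, map_b, "maps")
  .check_same_grid(map_a, mask, "map and mask")
  a <- .mask_values(map_a, mask)
  b <- .mask_values(map_b, mask)
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) < 3) {
    stop("need at least 3 finite paired voxels", call. = FALSE)
  }
  .pearson(a, b)
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r)`. Correlations within `1e-12` of +/-1 are clamped to
#' `+/-(1 - 1e-12)` with a warning so the transform stays finite.
#'
#' @param r correlation in `[-1, 1]`.
#' @return Fisher z value(s).
#' @export
fisher_transform <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("|r| must not exceed 1", call. = FALSE)
  }
  clamp <- abs(r) >= 1 - 1e-12
  if (any(clamp, na.rm = TRUE)) {
    warning(sprintf("%d correlation(s) at |r| ~ 1 clamped before atanh",
                    sum(clamp, na.rm = TRUE)))
    r[which(clamp)] <- sign(r[which(clamp)]) * (1 - 1e-12)
  }
  atanh(r)
}

#' Per-subject voxel-wise associations across a cohort
#'
#' For every subject, ROI and modality, computes the voxel-wise Pearson
#' correlation between the subject's amyloid map (SUVR or raw PET --
#' correlation is scale invariant) and the target map over the thresholded
#' ROI mask, plus its Fisher z. The transcriptome-atlas modality is
#' correlated once per subject against the shared atlas map and skips any
#' ROI flagged out of the atlas comparison (white matter). Subjects missing
#' a modality are skipped for that modality with a log entry.
#'
#' @param subject_maps named list (by subject id) of named lists of 3D maps;
#'   each subject must carry an `amyloid` map plus one map per modality.
#' @param roi_masks named list (by roi_id) of logical 3D masks.
#' @param modalities character vector of modality ids to process; the
#'   special id `"atlas"` uses the shared `atlas` map.
#' @param atlas shared 3D atlas map (required if `"atlas"` is requested).
#' @param roi_table data.frame as [default_roi_table()]; controls atlas-arm
#'   ROI exclusion.
#' @return A data.frame with columns `subject_id`, `roi_id`, `modality_id`,
#'   `n_voxels`, `r`, `z`; attribute `skipped` records skipped
#'   (subject, modality) pairs.
#' @export
cohort_association <- function(subject_maps, roi_masks, modalities,
                               atlas = NULL,
                               roi_table = default_roi_table()) {
  stopifnot(length(subject_maps) > 0, length(roi_masks) > 0)
  if ("atlas" %in% modalities && is.null(atlas)) {
    stop("atlas map required for the atlas modality", call. = FALSE)
  }
  atlas_rois <- roi_table$roi_id[roi_table$include_in_atlas_comparison]
  rows <- list()
  skipped <- list()
  for (sid in names(subject_maps)) {
    maps <- subject_maps[[sid]]
    if (is.null(maps$amyloid)) {
      stop(sprintf("subject '%s' has no amyloid map", sid), call. = FALSE)
    }
    for (mod in modalities) {
      target <- if (mod == "atlas") atlas else maps[[mod]]
      if (is.null(target)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(subject_id = sid, modality_id = mod,
                     reason = "missing modality",
                     stringsAsFactors = FALSE)
        next
      }
      roi_ids <- names(roi_masks)
      if (mod == "atlas") roi_ids <- intersect(roi_ids, atlas_rois)
      for (roi in roi_ids) {
        r <- voxelwise_pearson(maps$amyloid, target, roi_masks[[roi]])
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, roi_id = roi, modality_id = mod,
          n_voxels = sum(roi_masks[[roi]]), r = r,
          z = fisher_transform(r), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(subject_id = character(), modality_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  if (nrow(skipped) > 0) {
    message(sprintf("cohort_association: skipped %d (subject, modality) pair(s)",
                    nrow(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Correlate ROI-mean values with clinical variables across subjects
#'
#' Cells are Pearson correlations over pairwise-complete subjects between a
#' per-subject ROI-mean value (amyloid SUVR or an MRI metric) and a clinical
#' variable; cells with fewer than 3 complete pairs are flagged missing
#' (NA), never zero. The per-cell n is recorded.
#'
#' @param cohort_table data.frame of per-subject clinical values.
#' @param roi_means matrix (subjects x ROIs) of per-subject ROI means; row
#'   order must match `cohort_table`.
#' @param variables clinical column names to correlate; defaults to all
#'   numeric columns of `cohort_table` except `subject_id`/`group`.
#' @return Object of class `clinical_matrix`: list with `r` (ROIs x
#'   variables matrix) and `n` (per-cell complete-pair counts).
#' @export
clinical_matrix <- function(cohort_table, roi_means, variables = NULL) {
  stopifnot(is.matrix(roi_means), nrow(roi_means) == nrow(cohort_table))
  if (is.null(variables)) {
    num <- vapply(cohort_table, is.numeric, logical(1))
    variables <- setdiff(names(cohort_table)[num], c("subject_id", "group"))
  }
  rr <- matrix(NA_real_, ncol(roi_means), length(variables),
               dimnames = list(colnames(roi_means), variables))
  nn <- matrix(0L, ncol(roi_means), length(variables),
               dimnames = dimnames(rr))
  for (i in seq_len(ncol(roi_means))) {
    for (j in seq_along(variables)) {
      x <- roi_means[, i]
      y <- cohort_table[[variables[j]]]
      keep <- is.finite(x) & is.finite(y)
      nn[i, j] <- sum(keep)
      if (nn[i, j] >= 3 && stats::sd(x[keep]) > 0 && stats::sd(y[keep]) > 0) {
        rr[i, j] <- .pearson(x[keep], y[keep])
      }
    }
  }
  structure(list(r = rr, n = nn), class = "clinical_matrix")
}

#' @export
print.clinical_matrix <- function(x, ...) {
  cat("Clinical association matrix (Pearson r):\n")
  print(round(x$r, 3))
  invisible(x)
}
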