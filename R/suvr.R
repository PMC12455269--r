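#' Compute a standardised uptake value ratio (SUVR) map
#'
#' Divides every voxel of a PET uptake volume by the mean uptake over a
#' reference region (typically cerebellar), yielding a dimensionless
#' amyloid-load map. The reference mask may be boolean or a probability
#' volume in `[0, 1]`; in the probability case the reference mean is the
#' probability-weighted mean. Non-finite PET voxels propagate as non-finite
#' SUVR and are excluded from the reference mean with a logged count.
#'
#' @param pet 3D numeric array of PET uptake values.
#' @param reference logical or numeric array on the same grid; probabilities
#'   in `[0, 1]` or booleans marking the reference region.
#' @return An object of class `suvr_map`: list with `values` (array, same
#'   grid as `pet`), `reference_mean` (original-units weighted mean) and
#'   `n_nonfinite` (count of non-finite PET voxels inside the reference).
#' @examples
#' pet <- array(runif(64, 0.5, 2), c(4, 4, 4))
#' ref <- array(FALSE, c(4, 4, 4)); ref[1:2, 1:2, 1] <- TRUE
#' s <- compute_suvr(pet, ref)
#' mean(s$values[ref])  # 1 by construction
#' @export
compute_suvr <- function(pet, reference) {
  stopifnot(is.array(pet), length(dim(pet)) == 3)
  .check_same_grid(pet, reference, "PET and reference mask")
  w <- as.numeric(reference)
  if (any(w < 0 | w > 1, na.rm = TRUE)) {
    stop("reference mask values must be probabilities in [0, 1] or booleans",
         call. = FALSE)
  }
  if (sum(w) == 0) stop("empty reference mask", call. = FALSE)
  finite <- is.finite(as.numeric(pet))
  n_nonfinite <- sum(w > 0 & !finite)
  w_eff <- w * finite
  if (sum(w_eff) == 0) stop("empty reference mask", call. = FALSE)
  pv <- as.numeric(pet)
  pv[!finite] <- 0  # zero-weighted below
  ref_mean <- sum(w_eff * pv) / sum(w_eff)
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    stop("invalid reference intensity", call. = FALSE)
  }
  if (n_nonfinite > 0) {
    message(sprintf("compute_suvr: excluded %d non-finite PET voxel(s) from reference mean",
                    n_nonfinite))
  }
  structure(
    list(values = pet / ref_mean,
         reference_mean = ref_mean,
         n_nonfinite = n_nonfinite),
    class = "suvr_map")
}

#' @export
print.suvr_map <- function(x, ...) {
  cat("SUVR map", paste(dim(x$values), collapse = " x "),
      sprintf("(reference mean %.6g)\n", x$reference_mean))
  invisible(x)
}
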