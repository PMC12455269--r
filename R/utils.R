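#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the package flows from one root seed. Sub-seeds for
#' individual subjects, maps and permutation batches are derived by hashing
#' the root seed together with a path of string/integer labels, so that every
#' generated object is reproducible in isolation and insensitive to the order
#' in which other objects are generated.
#'
#' @param root integer root seed.
#' @param ... labels (strings or integers) identifying the consumer.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1, is.finite(root))
  m <- 2147483647  # 2^31 - 1, keeps products exact in doubles
  h <- abs(root) %% m
  for (part in list(...)) {
    codes <- if (is.character(part)) {
      utf8ToInt(paste(part, collapse = "/"))
    } else {
      as.integer(part)
    }
    for (cc in codes) h <- (h * 33 + (cc %% m)) %% m
  }
  as.integer(h)
}

# Pearson correlation from raw sums; used internally where cor()'s NA
# handling or dispatch overhead is unwanted. Inputs must be finite.
.pearson <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxy <- sum(xc * yc)
  sxx <- sum(xc * xc)
  syy <- sum(yc * yc)
  if (sxx <= 0 || syy <= 0) {
    stop("zero variance in ROI", call. = FALSE)
  }
  sxy / sqrt(sxx * syy)
}

.check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s are not on the same grid: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

# Fixed voxel ordering for value vectors: first array index fastest
# (R column-major), documented and used everywhere voxels are paired
# across modalities.
.mask_values <- function(map, mask) {
  map[which(mask)]
}
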