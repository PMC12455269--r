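#' Default ground-truth voxel-wise correlations per (ROI, modality)
#'
#' Targets chosen to mirror the qualitative pattern of the study this
#' pipeline emulates: a clear positive entorhinal association with the
#' transcriptome atlas and a basal-ganglia anti-correlation; consistent
#' positive microstructural associations (T1w/T2w, FA) and negative MD /
#' ODI / free-water associations across regions; positive perfusion
#' associations strongest in temporal and whole-cortex regions; and weak
#' functional (rs-fMRI) associations except in the basal ganglia. The
#' white-matter row of the atlas column is NA (excluded from the atlas arm).
#'
#' @return Matrix (8 ROIs x 11 modalities) of target correlations in
#'   `(-1, 1)`.
#' @export
default_target_rho <- function() {
  rois <- default_roi_table()$roi_id
  mods <- c("atlas", "t1t2_ratio", "fa", "md", "odi", "wvf", "ivf",
            "cbf", "wdece", "reho", "falff")
  m <- matrix(NA_real_, length(rois), length(mods),
              dimnames = list(rois, mods))
  m[, "atlas"] <- c(0.5, -0.1, 0.0, -0.15, -0.1, 0.05, NA, -0.35)
  m[, "t1t2_ratio"] <- 0.45
  m[, "fa"] <- 0.45
  m[, "md"] <- -0.3
  m[, "odi"] <- -0.3
  m[, "wvf"] <- -0.25
  m[, "ivf"] <- 0.2
  m[, "cbf"] <- c(0.35, 0.2, 0.4, 0.2, 0.2, 0.4, 0.2, 0.2)
  m[, "wdece"] <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.35)
  m[, "reho"] <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.35)
  m[, "falff"] <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.35)
  m
}

#' Default ground-truth correlation matrix of ROI-mean amyloid and clinical
#' variables
#'
#' Compound-symmetric correlation (0.6) among the eight ROI-mean amyloid
#' loads; modest positive amyloid correlations with BMI (0.45) and grip
#' strength (0.35), a mild positive age association (0.2) and weak
#' cognitive associations (0.1), matching the directionality the study
#' reports; weak correlations among the clinical variables themselves. The
#' matrix is validated positive definite.
#'
#' @return Symmetric 13 x 13 correlation matrix with unit diagonal; rows
#'   `amyloid_<roi>` then the five clinical variables.
#' @export
default_clinical_corr <- function() {
  rois <- default_roi_table()$roi_id
  vars <- c("age", "bmi", "grip_strength", "fluid_cognition",
            "crystallised_cognition")
  ids <- c(paste0("amyloid_", rois), vars)
  p <- length(ids)
  r <- matrix(0, p, p, dimnames = list(ids, ids))
  nr <- length(rois)
  r[seq_len(nr), seq_len(nr)] <- 0.6
  cross <- c(age = 0.2, bmi = 0.45, grip_strength = 0.35,
             fluid_cognition = 0.1, crystallised_cognition = 0.1)
  for (v in vars) {
    r[seq_len(nr), paste0("", v)] <- cross[[v]]
    r[v, seq_len(nr)] <- cross[[v]]
  }
  r["fluid_cognition", "crystallised_cognition"] <- 0.3
  r["crystallised_cognition", "fluid_cognition"] <- 0.3
  r["grip_strength", "fluid_cognition"] <- 0.2
  r["fluid_cognition", "grip_strength"] <- 0.2
  r["age", "bmi"] <- 0.1
  r["bmi", "age"] <- 0.1
  diag(r) <- 1
  .check_corr_psd(r)
  r
}

.check_corr_psd <- function(r, tol = 1e-8) {
  if (!isSymmetric(r) || any(abs(diag(r) - 1) > 1e-12)) {
    stop("clinical_corr must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("clinical_corr is not positive semidefinite", call. = FALSE)
  }
  invisible(TRUE)
}

# Clinical marginal means/SDs and availability of the emulated cohort
# (n = 35; crystallised cognition available for 34, grip strength for 31).
.clinical_marginals <- function() {
  data.frame(
    variable = c("age", "bmi", "grip_strength", "fluid_cognition",
                 "crystallised_cognition"),
    mean = c(73.17, 26.56, 101.81, 112.71, 109.85),
    sd = c(9.07, 4.45, 15.49, 15.28, 11.54),
    n_available = c(35L, 35L, 31L, 35L, 34L),
    stringsAsFactors = FALSE
  )
}

# Default disjoint box geometry on the coarse (2-mm) grid, coarse-cell
# aligned so thresholded coarse sizes are exact. Sizes span ~50 (entorhinal)
# to ~4000 (whole cortex) voxels.
.default_roi_geometry <- function() {
  list(
    entorhinal = list(lo = c(24, 24, 1), hi = c(28, 28, 2)),            # 50
    limbic_subcortical = list(lo = c(17, 17, 12), hi = c(22, 22, 15)),  # 144
    temporal = list(lo = c(1, 17, 1), hi = c(10, 24, 6)),               # 480
    anterior_cingulate = list(lo = c(1, 25, 8), hi = c(5, 29, 11)),     # 100
    precuneus_posterior_cingulate = list(lo = c(8, 25, 14),
                                         hi = c(13, 30, 18)),           # 180
    whole_cortex = list(lo = c(1, 1, 1), hi = c(16, 16, 16)),           # 4096
    white_matter = list(lo = c(17, 1, 1), hi = c(28, 10, 10)),          # 1200
    basal_ganglia = list(lo = c(20, 1, 20), hi = c(26, 6, 25))          # 252
  )
}

.default_reference_geometry <- function() {
  list(lo = c(1, 1, 25), hi = c(8, 8, 32))  # cerebellar-like, 512 voxels
}

# Subject-level coupling of each metric's ROI-mean profile to the amyloid
# ROI-mean profile: the ROI mean of a metric map varies across subjects as
# a mixture of the (standardised) subject amyloid load and independent
# noise. Microstructural metrics couple strongly (the study's clinical
# similarity finding), diffusivity/free-water negatively, functional
# metrics weakly.
.metric_profile_coupling <- function() {
  c(t1t2_ratio = 0.6, fa = 0.6, md = -0.4, odi = -0.4, wvf = -0.3,
    ivf = 0.2, cbf = 0.4, wdece = 0.1, reho = 0.1, falff = 0.1)
}

# Plausible marginal scales per generated modality map (mean, sd); linear
# rescaling leaves all correlations untouched.
.modality_scales <- function() {
  list(t1t2_ratio = c(1.6, 0.25), fa = c(0.4, 0.1), md = c(8e-4, 1e-4),
       odi = c(0.3, 0.08), wvf = c(0.2, 0.05), ivf = c(0.55, 0.08),
       cbf = c(45, 12), wdece = c(20, 8), reho = c(0.5, 0.15),
       falff = c(0.4, 0.1))
}

#' Build a validated synthetic-cohort configuration
#'
#' The defaults encode the emulated study conditions: 35 subjects, a 64^3
#' high-resolution grid decimated by an integer factor 2 to a 2-mm analysis
#' grid, disjoint box ROIs spanning ~50-4000 voxels, mask threshold 0.9, the
#' default ground-truth correlation targets, clinical marginals from the
#' cohort table (with 24/11 negative/positive amyloid readings, 2 subjects
#' missing DWI and 1 missing the perfusion map in sampling mode), and
#' 488-volume TR 0.8 s BOLD plus two-shell DWI raw series on small grids.
#'
#' @param n_subjects cohort size (default 35).
#' @param grid_hires high-resolution grid dimensions (default 64^3).
#' @param factor integer decimation factor to the analysis grid (default 2).
#' @param tau mask inclusion-probability threshold (default 0.9).
#' @param mode `"exact"` (sample moments forced, for oracle tests) or
#'   `"sampling"` (population moments, for calibration studies).
#' @param target_voxel_rho ROIs x modalities matrix of target voxel-wise
#'   correlations, as [default_target_rho()].
#' @param clinical_corr ground-truth correlation matrix, as
#'   [default_clinical_corr()].
#' @param roi_geometry named list of coarse-grid box corners.
#' @param reference_geometry coarse-grid box for the reference region.
#' @param include_timeseries generate raw BOLD and DWI series per subject.
#' @param bold,dwi parameter lists for the raw series.
#' @param apply_missingness drop modalities/clinical values per the study's
#'   availability; default TRUE only in sampling mode.
#' @param metric_profile_coupling named vector in `(-1, 1)`: correlation of
#'   each metric's subject-level ROI-mean profile with the amyloid profile.
#' @param suvr_voxel_sd within-ROI voxel SD of the amyloid SUVR field.
#' @param roi_mean_base,roi_mean_sd across-subject location/scale of
#'   ROI-mean amyloid SUVR.
#' @param ref_scale PET original-units intensity of the reference region.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 35,
                          grid_hires = c(64, 64, 64),
                          factor = 2,
                          tau = 0.9,
                          mode = c("exact", "sampling"),
                          target_voxel_rho = default_target_rho(),
                          clinical_corr = default_clinical_corr(),
                          roi_geometry = .default_roi_geometry(),
                          reference_geometry = .default_reference_geometry(),
                          include_timeseries = FALSE,
                          bold = list(shape = c(8, 8, 8), n_vols = 488,
                                      tr = 0.8, band_fraction = 0.8,
                                      coupling = 0.3),
                          dwi = list(shape = c(5, 5, 5), s0 = 1000,
                                     noise_sd = 0),
                          apply_missingness = NULL,
                          metric_profile_coupling = .metric_profile_coupling(),
                          suvr_voxel_sd = 0.15,
                          roi_mean_base = 1.5,
                          roi_mean_sd = 0.25,
                          ref_scale = 1400) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 3, length(grid_hires) == 3, factor >= 1)
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]", call. = FALSE)
  if (any(grid_hires %% factor != 0)) {
    stop("grid_hires must be divisible by factor", call. = FALSE)
  }
  if (any(abs(target_voxel_rho) >= 1, na.rm = TRUE)) {
    stop("target_voxel_rho must lie strictly inside (-1, 1)", call. = FALSE)
  }
  .check_corr_psd(clinical_corr)
  if (is.null(apply_missingness)) apply_missingness <- mode == "sampling"
  cfg <- list(n_subjects = as.integer(n_subjects), grid_hires = grid_hires,
              factor = as.integer(factor), tau = tau, mode = mode,
              target_voxel_rho = target_voxel_rho,
              clinical_corr = clinical_corr,
              roi_geometry = roi_geometry,
              reference_geometry = reference_geometry,
              include_timeseries = include_timeseries,
              bold = bold, dwi = dwi,
              apply_missingness = apply_missingness,
              metric_profile_coupling = metric_profile_coupling,
              suvr_voxel_sd = suvr_voxel_sd,
              roi_mean_base = roi_mean_base, roi_mean_sd = roi_mean_sd,
              ref_scale = ref_scale)
  class(cfg) <- "cohort_config"
  cfg
}

# exact-mode moment forcing: returns an n x p matrix whose sample
# correlation (and covariance) equals R exactly, columns mean 0 / sd 1
.force_sample_corr <- function(n, r, seed) {
  p <- ncol(r)
  if (n < p + 2) {
    stop(sprintf(
      "exact-mode moment forcing needs n_subjects >= %d for %d variables",
      p + 2, p), call. = FALSE)
  }
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n * p), n, p)
  z <- scale(z, center = TRUE, scale = FALSE)
  s <- stats::cov(z)
  z %*% solve(chol(s)) %*% chol(r)
}

#' Generate a synthetic multimodal cohort with known ground truth
#'
#' Builds per-subject co-registered maps on the analysis grid whose
#' within-ROI voxel-wise correlations with the amyloid map match the
#' configured targets (exactly in `"exact"` mode via
#' [forced_correlation_field()]; to sampling tolerance `~2/sqrt(V)` in
#' `"sampling"` mode), a shared transcriptome-like atlas map, a
#' cerebellar-like reference region whose amyloid SUVR mean is exactly 1, a
#' clinical table whose sample correlations with ROI-mean amyloid match the
#' configured matrix (exactly in exact mode), and optional raw BOLD/DWI
#' series. All randomness derives from `seed` via [derive_seed()]; the same
#' config and seed give bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @param seed integer root seed.
#' @return Object of class `synthetic_cohort`: list with `subjects` (each
#'   with `id`, `maps` incl. `amyloid` SUVR-scale field and `amyloid_pet`
#'   raw PET, optional `bold` and `dwi`), `atlas`, `reference_mask`,
#'   `roi_masks_hires`, `roi_prob`, `roi_masks`, `clinical`, `truth`,
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  f <- config$factor
  hdim <- config$grid_hires
  cdim <- hdim %/% f
  geo <- config$roi_geometry
  rois <- names(geo)
  mods <- colnames(config$target_voxel_rho)
  metric_mods <- setdiff(mods, "atlas")
  scales <- .modality_scales()

  to_hires <- function(box) {
    list(lo = (box$lo - 1L) * f + 1L, hi = box$hi * f)
  }
  roi_masks_hires <- lapply(geo, function(b) {
    hb <- to_hires(b)
    if (any(hb$hi > hdim)) stop("infeasible ROI geometry", call. = FALSE)
    box_mask(hdim, hb$lo, hb$hi)
  })
  overlap <- Reduce(`+`, lapply(roi_masks_hires, as.numeric))
  rb <- to_hires(config$reference_geometry)
  if (any(rb$hi > hdim)) stop("infeasible ROI geometry", call. = FALSE)
  ref_hires <- box_mask(hdim, rb$lo, rb$hi)
  if (max(overlap + as.numeric(ref_hires)) > 1) {
    stop("infeasible ROI geometry: regions overlap", call. = FALSE)
  }
  roi_prob <- lapply(roi_masks_hires, downsample_mask_fraction, factor = f)
  roi_masks <- lapply(roi_prob, threshold_mask, tau = config$tau)
  reference_mask <- threshold_mask(
    downsample_mask_fraction(ref_hires, f), config$tau)

  # shared transcriptome-like atlas map on the analysis grid
  set.seed(derive_seed(seed, "atlas"))
  atlas <- array(5 + 2 * stats::rnorm(prod(cdim)), cdim)

  # subject-level structure: ROI-mean amyloid + clinical variables
  r <- config$clinical_corr
  n <- config$n_subjects
  exact <- config$mode == "exact"
  y <- if (exact) {
    .force_sample_corr(n, r, derive_seed(seed, "clinical"))
  } else {
    set.seed(derive_seed(seed, "clinical"))
    matrix(stats::rnorm(n * ncol(r)), n, ncol(r)) %*% chol(r)
  }
  colnames(y) <- colnames(r)
  marg <- .clinical_marginals()
  clin_vars <- marg$variable
  clinical <- data.frame(subject_id = sprintf("sub%02d", seq_len(n)),
                         stringsAsFactors = FALSE)
  for (k in seq_along(clin_vars)) {
    clinical[[clin_vars[k]]] <-
      marg$mean[k] + marg$sd[k] * y[, clin_vars[k]]
  }
  amy_cols <- paste0("amyloid_", rois)
  amy_cols <- amy_cols[amy_cols %in% colnames(y)]
  roi_mean_targets <- config$roi_mean_base +
    config$roi_mean_sd * y[, amy_cols, drop = FALSE]
  colnames(roi_mean_targets) <- sub("^amyloid_", "", amy_cols)

  # group label (amyloid-positive clinical reading) and sex: study split
  # 24 negative / 11 positive, 22 female / 13 male, scaled for other n
  set.seed(derive_seed(seed, "labels"))
  n_pos <- max(1L, round(n * 11 / 35))
  clinical$group <- sample(rep(c("negative", "positive"),
                               c(n - n_pos, n_pos)))
  n_f <- round(n * 22 / 35)
  clinical$sex <- sample(rep(c("F", "M"), c(n_f, n - n_f)))

  # subject-level ROI-mean offsets for each metric map: coupled to the
  # standardised amyloid ROI-mean profile with independent noise, scaled to
  # half the metric's within-ROI voxel SD
  astd <- scale(roi_mean_targets)
  metric_offsets <- list()
  for (mod in metric_mods) {
    cval <- config$metric_profile_coupling[mod]
    if (is.na(cval)) cval <- 0
    sc <- scales[[mod]]
    if (is.null(sc)) sc <- c(0, 1)
    set.seed(derive_seed(seed, "profile", mod))
    eps <- matrix(stats::rnorm(n * length(rois)), n, length(rois),
                  dimnames = list(NULL, rois))
    off <- matrix(0, n, length(rois), dimnames = list(NULL, rois))
    for (roi in rois) {
      a <- if (roi %in% colnames(astd)) astd[, roi] else 0
      off[, roi] <- 0.5 * sc[2] *
        (cval * a + sqrt(1 - cval^2) * eps[, roi])
    }
    metric_offsets[[mod]] <- off
  }

  field_fun <- if (exact) forced_correlation_field else
    .sampled_correlation_field
  ref_idx <- which(reference_mask)

  subjects <- vector("list", n)
  names(subjects) <- clinical$subject_id
  for (s in seq_len(n)) {
    sid <- clinical$subject_id[s]
    set.seed(derive_seed(seed, "suvr-bg", s))
    suvr <- array(1.2 + 0.15 * stats::rnorm(prod(cdim)), cdim)
    # reference region: SUVR mean exactly 1
    ref_noise <- 0.05 * stats::rnorm(length(ref_idx))
    suvr[ref_idx] <- 1 + (ref_noise - mean(ref_noise))
    for (roi in rois) {
      idx <- which(roi_masks[[roi]])
      rho_a <- config$target_voxel_rho[roi, "atlas"]
      pat <- if (is.na(rho_a)) {
        set.seed(derive_seed(seed, "wm-pattern", s, roi))
        pp <- stats::rnorm(length(idx))
        (pp - mean(pp)) / stats::sd(pp)
      } else {
        field_fun(atlas[idx], rho_a,
                  derive_seed(seed, "amyloid", s, roi))
      }
      # exact mode: zero the pattern mean exactly so the ROI mean equals
      # its subject-level target (a constant shift leaves voxel-wise
      # correlations untouched)
      if (exact) pat <- pat - mean(pat)
      suvr[idx] <- roi_mean_targets[s, roi] + config$suvr_voxel_sd * pat
    }
    maps <- list(amyloid = suvr,
                 amyloid_pet = suvr * config$ref_scale)
    for (mod in metric_mods) {
      sc <- scales[[mod]]
      if (is.null(sc)) sc <- c(0, 1)
      set.seed(derive_seed(seed, "metric-bg", s, mod))
      mmap <- array(sc[1] + sc[2] * stats::rnorm(prod(cdim)), cdim)
      for (roi in rois) {
        rho <- config$target_voxel_rho[roi, mod]
        if (is.na(rho)) next
        idx <- which(roi_masks[[roi]])
        pat <- field_fun(suvr[idx], rho,
                         derive_seed(seed, "metric", s, mod, roi))
        if (exact) pat <- pat - mean(pat)
        mmap[idx] <- sc[1] + metric_offsets[[mod]][s, roi] + sc[2] * pat
      }
      maps[[mod]] <- mmap
    }
    bundle <- list(id = sid, maps = maps)
    if (isTRUE(config$include_timeseries)) {
      bundle$bold <- generate_bold_volume(
        config$bold$shape, config$bold$n_vols, config$bold$tr,
        config$bold$band_fraction, config$bold$coupling,
        seed = derive_seed(seed, "bold", s))
      tf <- random_tensor_field(config$dwi$shape,
                                seed = derive_seed(seed, "tensors", s))
      bundle$dwi <- generate_dwi_signals(
        tf, default_gradient_table(), s0 = config$dwi$s0,
        seed = derive_seed(seed, "dwi", s),
        noise_sd = config$dwi$noise_sd)
      bundle$tensor_field <- tf
    }
    subjects[[s]] <- bundle
  }

  missing_log <- data.frame(subject_id = character(), item = character(),
                            stringsAsFactors = FALSE)
  if (isTRUE(config$apply_missingness)) {
    set.seed(derive_seed(seed, "missingness"))
    # 2 subjects without DWI-derived maps, 1 without perfusion
    if (n >= 3) {
      no_dwi <- sample.int(n, 2)
      no_cbf <- sample.int(n, 1)
      for (s in no_dwi) {
        subjects[[s]]$maps$fa <- NULL
        subjects[[s]]$maps$md <- NULL
        missing_log <- rbind(missing_log,
                             data.frame(subject_id = clinical$subject_id[s],
                                        item = "dwi"))
      }
      subjects[[no_cbf]]$maps$cbf <- NULL
      missing_log <- rbind(missing_log,
                           data.frame(subject_id = clinical$subject_id[no_cbf],
                                      item = "cbf"))
    }
    # clinical availability per the cohort table
    for (k in seq_along(clin_vars)) {
      n_miss <- round(n * (35L - marg$n_available[k]) / 35)
      if (n_miss > 0 && n_miss < n) {
        clinical[[clin_vars[k]]][sample.int(n, n_miss)] <- NA_real_
      }
    }
  }

  structure(list(
    subjects = subjects,
    atlas = atlas,
    reference_mask = reference_mask,
    roi_masks_hires = roi_masks_hires,
    roi_prob = roi_prob,
    roi_masks = roi_masks,
    clinical = clinical,
    missing_log = missing_log,
    truth = list(target_voxel_rho = config$target_voxel_rho,
                 clinical_corr = config$clinical_corr,
                 roi_mean_targets = roi_mean_targets,
                 band_fraction = if (isTRUE(config$include_timeseries))
                   config$bold$band_fraction else NA_real_,
                 seed = seed),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %s mode, analysis grid %s\n",
              length(x$subjects), x$config$mode,
              paste(dim(x$atlas), collapse = "x")))
  invisible(x)
}
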