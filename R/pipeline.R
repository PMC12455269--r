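#' Build and validate a pipeline run configuration
#'
#' Defaults reproduce the emulated study's stated analysis parameters:
#' effect-size null `r0 = 0.3`, mask threshold `tau = 0.9`,
#' `n_perm = 10000`, `alpha = 0.05`, fALFF band 0.01-0.1 Hz and wDeCe
#' sparsity 0.1.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"user"` (load a cohort
#'   directory written in the [write_cohort()] layout).
#' @param cohort a [cohort_config()] for synthetic mode.
#' @param input_dir cohort directory for user mode.
#' @param r0 effect-size null on the correlation scale.
#' @param tau ROI-mask inclusion-probability threshold.
#' @param n_perm permutations for every permutation test.
#' @param alpha significance level applied to q-values.
#' @param falff_band fALFF frequency band in Hz.
#' @param wdece_sparsity wDeCe sparsity threshold.
#' @param seed root seed; every stage derives its own sub-seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "user"),
                       cohort = cohort_config(),
                       input_dir = NULL,
                       r0 = 0.3, tau = 0.9, n_perm = 10000, alpha = 0.05,
                       falff_band = c(0.01, 0.1), wdece_sparsity = 0.1,
                       seed = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(r0) || r0 <= 0 || r0 >= 1) {
    stop("r0 must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(tau) || tau <= 0 || tau > 1) {
    stop("tau must lie in (0, 1]", call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (mode == "user" && is.null(input_dir)) {
    stop("user mode requires input_dir", call. = FALSE)
  }
  structure(list(mode = mode, cohort = cohort, input_dir = input_dir,
                 r0 = r0, tau = tau, n_perm = as.integer(n_perm),
                 alpha = alpha, falff_band = falff_band,
                 wdece_sparsity = wdece_sparsity,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full three-aim association pipeline
#'
#' Executes, in order: cohort generation (or loading), SUVR normalisation
#' against the reference mask, ROI-mean extraction, per-subject voxel-wise
#' association (Aim 1: transcriptome atlas; Aim 3: MRI metric maps),
#' sign-flip effect-size inference with Storey FDR per aim, permutation
#' clinical correlations (Aim 2), clinical-profile similarity per metric,
#' and the supplementary group comparison. Writes one TSV per aim plus a
#' JSON manifest; reruns with the same config and seed are byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory for tables and the manifest; `NULL`
#'   skips writing.
#' @return Object of class `run_report`: list with `aim1`, `aim2`,
#'   `aim2_matrix`, `aim3`, `aim3_similarity`, `group_comparison`,
#'   `excluded`, `roi_means`, `association`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  if (config$mode == "synthetic") {
    ccfg <- config$cohort
    ccfg$tau <- config$tau  # analysis threshold governs mask logic
    cohort <- generate_cohort(ccfg, seed = seed)
  } else {
    cohort <- load_cohort(config$input_dir)
  }
  roi_masks <- cohort$roi_masks
  roi_ids <- names(roi_masks)
  clinical <- cohort$clinical
  n_sub <- length(cohort$subjects)

  # ---- SUVR normalisation -------------------------------------------------
  suvr_log <- 0L
  for (sid in names(cohort$subjects)) {
    maps <- cohort$subjects[[sid]]$maps
    pet <- if (!is.null(maps$amyloid_pet)) maps$amyloid_pet else maps$amyloid
    sm <- compute_suvr(pet, cohort$reference_mask)
    suvr_log <- suvr_log + sm$n_nonfinite
    cohort$subjects[[sid]]$maps$amyloid <- sm$values
  }

  # ---- per-subject ROI means of the SUVR map ------------------------------
  roi_means <- matrix(NA_real_, n_sub, length(roi_ids),
                      dimnames = list(names(cohort$subjects), roi_ids))
  for (sid in names(cohort$subjects)) {
    for (roi in roi_ids) {
      roi_means[sid, roi] <- extract_roi_values(
        cohort$subjects[[sid]]$maps$amyloid, roi_masks[[roi]], roi)$mean
    }
  }

  # ---- voxel-wise association ---------------------------------------------
  subject_maps <- lapply(cohort$subjects, function(s) s$maps)
  all_mods <- unique(unlist(lapply(subject_maps, function(m) {
    setdiff(names(m), c("amyloid", "amyloid_pet"))
  })))
  modalities <- c("atlas", all_mods)
  assoc <- cohort_association(subject_maps, roi_masks, modalities,
                              atlas = cohort$atlas)

  run_cell_test <- function(sub_assoc, label) {
    signflip_effect_size_test(
      sub_assoc$z, r0 = config$r0, n_perm = config$n_perm,
      seed = derive_seed(seed, "signflip", label))
  }

  # ---- Aim 1: transcriptome atlas -----------------------------------------
  a1_rows <- list()
  atlas_rois <- unique(assoc$roi_id[assoc$modality_id == "atlas"])
  for (roi in atlas_rois) {
    cell <- assoc[assoc$roi_id == roi & assoc$modality_id == "atlas", ]
    if (nrow(cell) < 3) next
    tst <- run_cell_test(cell, c("aim1", roi))
    a1_rows[[roi]] <- data.frame(
      roi_id = roi, n = tst$n, mean_r = mean(cell$r),
      mean_abs_r = tst$mean_abs_r, t_stat = tst$t_stat, p = tst$p,
      stringsAsFactors = FALSE)
  }
  aim1 <- do.call(rbind, a1_rows)
  rownames(aim1) <- NULL
  aim1$q <- as.numeric(storey_fdr(aim1$p))
  aim1$significant <- aim1$q < config$alpha

  # ---- Aim 3: MRI metric maps ---------------------------------------------
  a3_rows <- list()
  for (mod in all_mods) {
    for (roi in roi_ids) {
      cell <- assoc[assoc$roi_id == roi & assoc$modality_id == mod, ]
      if (nrow(cell) < 3) next
      tst <- run_cell_test(cell, c("aim3", roi, mod))
      a3_rows[[paste(roi, mod)]] <- data.frame(
        roi_id = roi, modality_id = mod, n = tst$n, mean_r = mean(cell$r),
        mean_abs_r = tst$mean_abs_r, t_stat = tst$t_stat, p = tst$p,
        stringsAsFactors = FALSE)
    }
  }
  aim3 <- do.call(rbind, a3_rows)
  rownames(aim3) <- NULL
  if (!is.null(aim3)) {
    aim3$q <- as.numeric(storey_fdr(aim3$p))
    aim3$significant <- aim3$q < config$alpha
  }

  # ---- Aim 2: clinical correlations ---------------------------------------
  clin_vars <- intersect(
    c("age", "bmi", "grip_strength", "fluid_cognition",
      "crystallised_cognition"), names(clinical))
  a2_rows <- list()
  for (roi in roi_ids) {
    for (v in clin_vars) {
      x <- roi_means[, roi]
      y <- clinical[[v]]
      keep <- is.finite(x) & is.finite(y)
      if (sum(keep) < 3) next
      tst <- permutation_corr_test(
        x, y, n_perm = config$n_perm,
        seed = derive_seed(seed, "aim2", roi, v))
      a2_rows[[paste(roi, v)]] <- data.frame(
        roi_id = roi, variable = v, n = tst$n, r = tst$r, p = tst$p,
        stringsAsFactors = FALSE)
    }
  }
  aim2 <- do.call(rbind, a2_rows)
  rownames(aim2) <- NULL
  aim2$q <- as.numeric(storey_fdr(aim2$p))
  aim2$significant <- aim2$q < config$alpha
  aim2_matrix <- clinical_matrix(clinical, roi_means, clin_vars)

  # ---- Aim 3 similarity: clinical profile of each metric vs amyloid -------
  perm_mats <- .permuted_amyloid_matrices(
    roi_means, clinical, clin_vars, config$n_perm,
    derive_seed(seed, "similarity"))
  sim_rows <- list()
  for (mod in all_mods) {
    mm_means <- matrix(NA_real_, n_sub, length(roi_ids),
                       dimnames = dimnames(roi_means))
    for (sid in names(cohort$subjects)) {
      m <- cohort$subjects[[sid]]$maps[[mod]]
      if (is.null(m)) next
      for (roi in roi_ids) {
        mm_means[sid, roi] <- extract_roi_values(m, roi_masks[[roi]], roi)$mean
      }
    }
    mm <- clinical_matrix(clinical, mm_means, clin_vars)
    res <- tryCatch(
      .similarity_null(mm$r, aim2_matrix$r, perm_mats),
      error = function(e) NULL)
    if (is.null(res)) next
    sim_rows[[mod]] <- data.frame(
      modality_id = mod, r_sim = res$observed,
      p = (1 + sum(abs(res$null) >= abs(res$observed))) /
        (1 + length(res$null)),
      n_cells = res$n_cells, stringsAsFactors = FALSE)
  }
  aim3_similarity <- do.call(rbind, sim_rows)
  rownames(aim3_similarity) <- NULL
  if (!is.null(aim3_similarity)) {
    aim3_similarity$q <- as.numeric(storey_fdr(aim3_similarity$p))
    aim3_similarity$significant <- aim3_similarity$q < config$alpha
  }

  # ---- supplementary group comparison -------------------------------------
  gd_vars <- c(clin_vars, intersect("sex", names(clinical)))
  group_comparison <- if ("group" %in% names(clinical)) {
    group_difference(clinical, "group", gd_vars)
  } else NULL

  excluded <- attr(assoc, "skipped")
  report <- structure(list(
    aim1 = aim1, aim2 = aim2, aim2_matrix = aim2_matrix, aim3 = aim3,
    aim3_similarity = aim3_similarity, group_comparison = group_comparison,
    excluded = excluded, roi_means = roi_means, association = assoc,
    suvr_nonfinite = suvr_log, config = config,
    cohort = cohort), class = "run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to TSV tables and a JSON manifest
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(format(df, digits = 10, trim = TRUE),
                       file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(report$aim1, "aim1_atlas.tsv")
  wt(report$aim2, "aim2_clinical.tsv")
  wt(as.data.frame(report$aim2_matrix$r), "aim2_matrix.tsv")
  wt(report$aim3, "aim3_metrics.tsv")
  wt(report$aim3_similarity, "aim3_similarity.tsv")
  if (!is.null(report$group_comparison)) {
    wt(report$group_comparison, "group_comparison.tsv")
  }
  if (!is.null(report$excluded) && nrow(report$excluded) > 0) {
    wt(report$excluded, "excluded.tsv")
  }
  cfg <- report$config
  manifest <- list(
    package = "amyspace",
    version = as.character(utils::packageVersion("amyspace")),
    mode = cfg$mode, r0 = cfg$r0, tau = cfg$tau, n_perm = cfg$n_perm,
    alpha = cfg$alpha, falff_band = cfg$falff_band,
    wdece_sparsity = cfg$wdece_sparsity, seed = cfg$seed,
    n_subjects = nrow(report$roi_means),
    rois = colnames(report$roi_means))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Three-aim association pipeline report\n")
  cat(sprintf("  Aim 1 (atlas): %d ROIs, %d significant\n",
              nrow(x$aim1), sum(x$aim1$significant)))
  cat(sprintf("  Aim 2 (clinical): %d cells, %d significant\n",
              nrow(x$aim2), sum(x$aim2$significant)))
  cat(sprintf("  Aim 3 (metrics): %d cells, %d significant\n",
              nrow(x$aim3), sum(x$aim3$significant)))
  invisible(x)
}
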