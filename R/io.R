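#' Write a 3D/4D volume to NIfTI-1
#'
#' @param x numeric array (3D or 4D).
#' @param path output file path (`.nii` / `.nii.gz`).
#' @param voxel_size isotropic voxel size in mm (default 2).
#' @param tr repetition time in seconds for 4D series (written to pixdim).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = 2, tr = NULL) {
  nd <- length(dim(x))
  img <- RNifti::asNifti(x + 0)
  pd <- c(rep(voxel_size, 3), if (nd == 4) (if (is.null(tr)) 1 else tr))
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array; 4D series carry a `tr` attribute taken from
#'   pixdim when present.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  pd <- RNifti::pixdim(img)
  if (length(dim(arr)) == 4 && length(pd) >= 4 && pd[4] > 0) {
    attr(arr, "tr") <- pd[4]
  }
  arr
}

#' Write an FSL-dialect gradient table
#'
#' `.bval` as one row of b-values; `.bvec` as three rows (x, y, z).
#'
#' @param gradients a [gradient_table()].
#' @param prefix path prefix; writes `<prefix>.bval` and `<prefix>.bvec`.
#' @return The prefix, invisibly.
#' @export
write_gradient_table <- function(gradients, prefix) {
  stopifnot(inherits(gradients, "gradient_table"))
  writeLines(paste(format(gradients$bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  rows <- apply(t(gradients$bvecs), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")
  })
  writeLines(rows, paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Read an FSL-dialect gradient table
#'
#' @param prefix path prefix of `<prefix>.bval` / `<prefix>.bvec`.
#' @return A [gradient_table()].
#' @export
read_gradient_table <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bvecs <- matrix(scan(paste0(prefix, ".bvec"), quiet = TRUE),
                  nrow = 3, byrow = TRUE)
  gradient_table(bvals, t(bvecs))
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI per subject per map (4D for BOLD/DWI), FSL-dialect
#' `.bval`/`.bvec`, a TSV clinical table, NIfTI ROI/reference masks and a
#' JSON ground-truth manifest. [load_cohort()] reads the layout back; the
#' same layout serves as the user-supplied input mode of the pipeline.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param voxel_size analysis-grid voxel size in mm (default 2).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, voxel_size = 2) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(cohort$atlas, file.path(dir, "atlas.nii.gz"), voxel_size)
  write_volume(cohort$reference_mask + 0,
               file.path(dir, "reference_mask.nii.gz"), voxel_size)
  mdir <- file.path(dir, "masks")
  dir.create(mdir, showWarnings = FALSE)
  for (roi in names(cohort$roi_masks)) {
    write_volume(cohort$roi_masks[[roi]] + 0,
                 file.path(mdir, paste0(roi, ".nii.gz")), voxel_size)
  }
  for (sub in cohort$subjects) {
    sdir <- file.path(dir, sub$id)
    dir.create(sdir, showWarnings = FALSE)
    for (map in names(sub$maps)) {
      write_volume(sub$maps[[map]],
                   file.path(sdir, paste0(map, ".nii.gz")), voxel_size)
    }
    if (!is.null(sub$bold)) {
      write_volume(sub$bold, file.path(sdir, "bold.nii.gz"), voxel_size,
                   tr = attr(sub$bold, "tr"))
    }
    if (!is.null(sub$dwi)) {
      write_volume(sub$dwi$signals, file.path(sdir, "dwi.nii.gz"),
                   voxel_size)
      write_gradient_table(sub$dwi$gradients, file.path(sdir, "dwi"))
    }
  }
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$target_voxel_rho <- as.data.frame(truth$target_voxel_rho)
  truth$clinical_corr <- as.data.frame(truth$clinical_corr)
  truth$roi_mean_targets <- as.data.frame(truth$roi_mean_targets)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return A list structured like a `synthetic_cohort` (maps, masks, atlas,
#'   clinical table); `truth` is carried when present.
#' @export
load_cohort <- function(dir) {
  clinical <- utils::read.delim(file.path(dir, "clinical.tsv"),
                                stringsAsFactors = FALSE)
  atlas <- read_volume(file.path(dir, "atlas.nii.gz"))
  reference_mask <- read_volume(file.path(dir, "reference_mask.nii.gz")) > 0.5
  mfiles <- list.files(file.path(dir, "masks"), pattern = "\\.nii",
                       full.names = TRUE)
  roi_masks <- lapply(mfiles, function(f) read_volume(f) > 0.5)
  names(roi_masks) <- sub("\\.nii(\\.gz)?$", "", basename(mfiles))
  subjects <- list()
  for (sid in clinical$subject_id) {
    sdir <- file.path(dir, sid)
    vfiles <- list.files(sdir, pattern = "\\.nii", full.names = TRUE)
    vfiles <- vfiles[!grepl("^(bold|dwi)\\.nii", basename(vfiles))]
    maps <- lapply(vfiles, read_volume)
    names(maps) <- sub("\\.nii(\\.gz)?$", "", basename(vfiles))
    bundle <- list(id = sid, maps = maps)
    bold_path <- file.path(sdir, "bold.nii.gz")
    if (file.exists(bold_path)) bundle$bold <- read_volume(bold_path)
    dwi_path <- file.path(sdir, "dwi.nii.gz")
    if (file.exists(dwi_path)) {
      bundle$dwi <- list(signals = read_volume(dwi_path),
                         gradients = read_gradient_table(file.path(sdir, "dwi")))
    }
    subjects[[sid]] <- bundle
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  list(subjects = subjects, atlas = atlas, reference_mask = reference_mask,
       roi_masks = roi_masks, clinical = clinical, truth = truth)
}
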