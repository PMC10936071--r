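# On-disk cohort exchange: per-lesion NIfTI volumes, clinical/outcome CSVs
# and a flat manifest, so extractions can run on externally supplied images.

#' Write a cohort to disk
#'
#' Per lesion: `<id>_ct.nii.gz`, `<id>_suv.nii.gz`, `<id>_mask.nii.gz` under
#' `dir/images`; plus `manifest.csv` (patient, lesion, region, files),
#' `clinical.csv` and `outcomes.csv`.
#'
#' @param cohort An `ith_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(); clin <- list(); outc <- list()
  for (p in cohort$patients) {
    for (l in p$lesions) {
      base <- file.path(img_dir, l$lesion_id)
      sp <- l$ct$spacing
      RNifti::writeNifti(RNifti::asNifti(l$ct$values, pixdim = sp),
                         paste0(base, "_ct.nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(l$suv$values, pixdim = sp),
                         paste0(base, "_suv.nii.gz"))
      RNifti::writeNifti(RNifti::asNifti(array(as.integer(l$mask),
                                               dim = dim(l$mask)),
                                         pixdim = sp),
                         paste0(base, "_mask.nii.gz"))
      manifest[[length(manifest) + 1L]] <- data.frame(
        patient_id = p$patient_id, lesion_id = l$lesion_id, region = l$region,
        dx = sp[1], dy = sp[2], dz = sp[3])
    }
    cv <- p$covariates
    clin[[length(clin) + 1L]] <- data.frame(
      patient_id = p$patient_id, age = cv$age, ca125 = cv$ca125,
      figo_stage = cv$figo_stage, sur_status = cv$sur_status,
      ascites_volume = cv$ascites_volume,
      ascites_character = cv$ascites_character,
      lnm_pelvic = as.integer(cv$lnm[1]), lnm_middle = as.integer(cv$lnm[2]),
      lnm_upper = as.integer(cv$lnm[3]), lnm_distant = as.integer(cv$lnm[4]),
      n_implants = cv$n_implants,
      invasion_pattern = cv$invasion_pattern, solid_ratio = cv$solid_ratio)
    outc[[length(outc) + 1L]] <- data.frame(
      patient_id = p$patient_id,
      pfs_time = p$pfs$time, pfs_event = p$pfs$event,
      os_time = p$os$time, os_event = p$os$event)
  }
  utils::write.csv(do.call(rbind, manifest),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, clin),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, outc),
                   file.path(dir, "outcomes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read lesion volumes listed in a manifest
#'
#' @param dir Directory written by [write_cohort()] (or following its layout).
#' @return List of `lesion_voi` grouped per patient (named list of lists).
#' @export
read_cohort_lesions <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  out <- list()
  for (i in seq_len(nrow(man))) {
    base <- file.path(dir, "images", man$lesion_id[i])
    sp <- c(man$dx[i], man$dy[i], man$dz[i])
    rd <- function(sfx) {
      v <- RNifti::readNifti(paste0(base, "_", sfx, ".nii.gz"))
      array(as.numeric(v), dim = dim(v))
    }
    les <- lesion_voi(man$lesion_id[i], man$region[i],
                      voxel_grid(rd("ct"), sp), voxel_grid(rd("suv"), sp),
                      rd("mask"))
    pid <- as.character(man$patient_id[i])
    out[[pid]] <- c(out[[pid]], list(les))
  }
  out
}
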