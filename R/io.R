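# On-disk layout of a synthetic cohort: NIfTI-1 images, TSV tables,
# single-column 50 Hz PPG CSVs, and a JSON manifest with MD5 checksums.

#' Write a synthetic cohort to disk
#'
#' Serializes a cohort as one directory per subject: 4D BOLD images and
#' tissue masks as NIfTI-1 (RAS affine, voxel size recorded), motion tables
#' as TSV, PPG traces as single-column CSV at 50 Hz, behavioural scores as
#' one TSV, plus a JSON manifest listing every file with its MD5 checksum.
#' Reading the files back reproduces the voxel arrays bit-exactly.
#'
#' @param dataset A `bh_cohort`.
#' @param directory Output directory.
#' @param overwrite Overwrite an existing non-empty directory? Default
#'   `FALSE` (refuses).
#' @return (Invisibly) the manifest as a list; also written to
#'   `manifest.json`.
#' @export
write_dataset <- function(dataset, directory, overwrite = FALSE) {
  stopifnot(inherits(dataset, "bh_cohort"))
  if (dir.exists(directory) && length(dir(directory)) > 0 && !overwrite) {
    abort_bh(
      sprintf("Directory '%s' is non-empty; set overwrite = TRUE.", directory),
      "io_error"
    )
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  rel <- function(p) sub(paste0("^", directory, "/?"), "", p)
  write_nii <- function(arr, path, tr = NULL) {
    im <- RNifti::asNifti(arr)
    im <- RNifti::`sform<-`(im, structure(dataset$atlas$affine, code = 2L))
    if (!is.null(tr)) RNifti::pixdim(im)[4] <- tr
    RNifti::writeNifti(im, path)
    files <<- c(files, path)
  }
  for (sub in dataset$subjects) {
    sdir <- file.path(directory, sub$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (j in seq_along(sub$sessions)) {
      ses <- sub$sessions[[j]]
      base <- file.path(sdir, sprintf("ses-%d_%s", j, ses$condition))
      write_nii(ses$img$data, paste0(base, "_bold.nii.gz"), tr = ses$img$tr_s)
      utils::write.table(
        ses$motion, paste0(base, "_motion.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
      files <- c(files, paste0(base, "_motion.tsv"))
      if (!is.null(ses$ppg)) {
        utils::write.table(
          data.frame(ppg = ses$ppg$samples), paste0(base, "_ppg.csv"),
          sep = ",", row.names = FALSE, col.names = TRUE, quote = FALSE
        )
        files <- c(files, paste0(base, "_ppg.csv"))
      }
    }
    write_nii(sub$sessions[[1]]$masks$wm * 1L, file.path(sdir, "mask_wm.nii.gz"))
    write_nii(sub$sessions[[1]]$masks$csf * 1L, file.path(sdir, "mask_csf.nii.gz"))
  }
  beh_path <- file.path(directory, "behaviors.tsv")
  utils::write.table(
    dataset$behaviors, beh_path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  files <- c(files, beh_path)
  manifest <- list(
    n_subjects = length(dataset$subjects),
    seed = dataset$seed,
    grid_shape = dataset$atlas$grid_shape,
    files = lapply(files, function(f) {
      list(path = rel(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(
    manifest, file.path(directory, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

#' Read a BOLD NIfTI image as a `ts_img`
#'
#' @param path Path to a 4D NIfTI file.
#' @param t0_s Acquisition offset of the first stored volume (seconds).
#' @return A `ts_img`.
#' @export
read_bold <- function(path, t0_s = 0) {
  im <- RNifti::readNifti(path)
  tr <- RNifti::pixdim(im)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 2
  ts_img(array(as.numeric(im), dim = dim(im)), tr, structure(RNifti::xform(im), dimnames = NULL), t0_s)
}

#' Read a single-column PPG CSV
#'
#' @param path Path to the CSV (one `ppg` column, 50 Hz samples).
#' @param rate_hz Sampling rate (default 50).
#' @param start_time_s Offset of the first sample relative to the fMRI
#'   session start (seconds).
#' @return A `ppg_trace`.
#' @export
read_ppg <- function(path, rate_hz = 50, start_time_s = 0) {
  x <- utils::read.csv(path)[[1]]
  structure(
    list(samples = as.numeric(x), rate_hz = rate_hz, start_time_s = start_time_s),
    class = "ppg_trace"
  )
}
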