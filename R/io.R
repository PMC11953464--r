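# On-disk interchange: events tables as TSV, BOLD runs as 4D NIfTI,
# ground truth and configs as JSON (YAML configs supported when the yaml
# package is available).

#' Write / read a trial events table
#'
#' Tab-separated events file with one row per trial: onset, duration
#' (stimulus span: SOA + stimulus duration), trial_type, soa, task_order,
#' map1, map2, rt1, rt2, correct.
#'
#' @param trials trial table (behavior columns optional).
#' @param path output file.
#' @param stim_dur stimulus duration used for the duration column (s).
#' @return \code{path}, invisibly.
#' @export
write_events_tsv <- function(trials, path, stim_dur = 0.2) {
  soa <- ifelse(is.na(trials$soa), 0, trials$soa)
  df <- data.frame(
    onset = trials$onset_t1,
    duration = soa + stim_dur,
    trial_type = trials$condition,
    soa = trials$soa,
    task_order = ifelse(is.na(trials$task2), trials$task1,
                        paste0(trials$task1, trials$task2)),
    map1 = trials$map1, map2 = trials$map2,
    rt1 = if (is.null(trials$rt1)) NA else trials$rt1,
    rt2 = if (is.null(trials$rt2)) NA else trials$rt2,
    correct = if (is.null(trials$correct)) NA else trials$correct,
    run = trials$run)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a BOLD run as 4D NIfTI
#'
#' Voxels are laid out along the first axis (voxels x 1 x 1 x time); the
#' TR is stored in the 4th pixdim. ROI labels travel in a JSON sidecar
#' next to the image.
#'
#' @param run a \code{\link{bold_run}}.
#' @param path output file (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_bold_nifti <- function(run, path) {
  arr <- array(t(run$data), dim = c(ncol(run$data), 1, 1, nrow(run$data)))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, run$tr))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(run = run$run, tr = run$tr,
                            roi_labels = run$roi_labels,
                            censor = run$censor),
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  data <- t(matrix(img, prod(d[1:3]), d[4]))
  tr <- RNifti::pixdim(img)[4]
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  roi <- rep("roi", ncol(data)); run_id <- 1L; censor <- rep(TRUE, nrow(data))
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    roi <- meta$roi_labels; run_id <- meta$run
    censor <- as.logical(meta$censor)
    if (!is.null(meta$tr)) tr <- meta$tr
  }
  bold_run(data, tr, run = run_id, roi_labels = roi, censor = censor)
}

#' Read a pipeline configuration (JSON or YAML)
#'
#' @param path file ending in .json, .yaml or .yml.
#' @return Nested list of configuration blocks.
#' @export
read_config <- function(path) {
  if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
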