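## Stack IO: NIfTI volume (slices along the third axis) plus a JSON sidecar
## carrying the per-slice metadata that NIfTI cannot (z position, timestamp,
## ground-truth phase, generator parameters).

#' Write a slice stack to NIfTI + JSON sidecar
#'
#' @param stack a \linkS4class{SliceStack}
#' @param path output NIfTI path (.nii or .nii.gz)
#' @param sidecar JSON sidecar path; defaults to \code{path} with a .json
#'   extension
#' @return invisibly, the two paths
#' @export
writeStack <- function(stack, path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  px <- stack@meta$pixel_mm
  dzs <- if (nSlices(stack) > 1) diff(stack@zMm[1:2]) else 1
  img <- RNifti::asNifti(stack@images)
  RNifti::pixdim(img) <- c(px, px, dzs)
  RNifti::writeNifti(img, path)
  side <- list(z_mm = stack@zMm, t_s = stack@tS, meta = stack@meta)
  if (length(stack@truthPhase) > 0) side$truth_phase <- stack@truthPhase
  jsonlite::write_json(side, sidecar, digits = NA, auto_unbox = TRUE)
  invisible(c(path, sidecar))
}

#' Read a slice stack from NIfTI + JSON sidecar
#'
#' The sidecar must list \code{z_mm} (and \code{t_s}) matching the number of
#' slices; if timestamps are missing they are inferred from the slice index
#' and \code{meta$tr_slice} when present, otherwise an error is raised.
#' z monotonicity is validated for swept stacks.
#'
#' @param path NIfTI path
#' @param sidecar JSON sidecar path; defaults to \code{path} with a .json
#'   extension
#' @return a \linkS4class{SliceStack}
#' @export
readStack <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  nii <- RNifti::readNifti(path)
  imgs <- array(as.numeric(nii), dim = dim(nii))
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ns <- dim(imgs)[3]
  z <- as.numeric(side$z_mm)
  if (length(z) != ns)
    stop(sprintf("sidecar lists %d z positions for %d slices", length(z), ns))
  if (any(!is.finite(z))) stop("non-finite z_mm in sidecar")
  tS <- as.numeric(side$t_s)
  if (length(tS) == 0) {
    trs <- side$meta$tr_slice
    if (is.null(trs)) stop("sidecar has no t_s and no meta$tr_slice to infer it from")
    tS <- (seq_len(ns) - 1) * as.numeric(trs)
  }
  if (length(tS) != ns)
    stop(sprintf("sidecar lists %d timestamps for %d slices", length(tS), ns))
  if (any(!is.finite(tS))) stop("non-finite t_s in sidecar")
  tp <- if (!is.null(side$truth_phase)) as.numeric(side$truth_phase) else numeric(0)
  meta <- if (!is.null(side$meta)) side$meta else list()
  new("SliceStack", images = imgs, zMm = z, tS = tS, truthPhase = tp,
      meta = meta)
}
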