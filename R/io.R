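#' @importFrom RNifti readNifti writeNifti asNifti sform<-
#' @importFrom jsonlite read_json write_json
NULL

.gridToJson <- function(grid) {
  list(shape = grid@shape, spacing = grid@spacing,
       affine = as.numeric(t(grid@affine)))
}

.gridFromJson <- function(g) {
  new("VoxelGrid", shape = as.integer(unlist(g$shape)),
      spacing = as.numeric(unlist(g$spacing)),
      affine = matrix(as.numeric(unlist(g$affine)), 4L, 4L, byrow = TRUE))
}

.writeNiftiWithAffine <- function(arr, affine, file) {
  img <- RNifti::asNifti(arr)
  sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, file)
}

#' Write a frame stack to NIfTI + JSON sidecar
#'
#' Writes \code{<stem>_ph.nii.gz} (phase, rad, float) and
#' \code{<stem>_mag.nii.gz} plus \code{<stem>.json} carrying everything
#' NIfTI cannot: the stack sensitivity, per-frame rigid transforms,
#' acquisition times, cardiac phases, frame weights and the full grid
#' geometry (the sidecar geometry is authoritative on read; the NIfTI
#' sform mirrors it).
#'
#' @param stack a [FrameStack-class].
#' @param stem output path stem.
#' @return \code{stem}, invisibly.
#' @export
writeFrameStack <- function(stack, stem) {
  frs <- stack@frames
  s <- stack@stackGrid@shape
  ph <- array(0, dim = s)
  mg <- array(0, dim = s)
  for (k in seq_along(frs)) {
    ph[, , k] <- frs[[k]]@phase
    mg[, , k] <- frs[[k]]@magnitude
  }
  aff <- stack@stackGrid@affine
  .writeNiftiWithAffine(ph, aff, paste0(stem, "_ph.nii.gz"))
  .writeNiftiWithAffine(mg, aff, paste0(stem, "_mag.nii.gz"))
  sens <- frs[[1]]@sensitivity
  side <- list(
    sensitivity = list(
      venc_cm_s = venc(sens),
      direction = sens@s / sqrt(sum(sens@s^2)),
      frame = sens@frame),
    grid = .gridToJson(stack@stackGrid),
    frames = lapply(frs, function(f) list(
      rotation = as.numeric(t(f@transform@rotation)),
      translation_mm = f@transform@translation,
      t_acq = f@tAcq,
      cardiac_phase = f@cardiacPhase,
      frame_weight = f@frameWeight)))
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read a frame stack written by [writeFrameStack()]
#'
#' @param stem path stem (expects \code{<stem>_ph.nii.gz},
#'   \code{<stem>_mag.nii.gz} and \code{<stem>.json}).
#' @return a [FrameStack-class].
#' @export
readFrameStack <- function(stem) {
  sidecarPath <- paste0(stem, ".json")
  if (!file.exists(sidecarPath))
    stop("missing sidecar JSON: ", sidecarPath)
  side <- jsonlite::read_json(sidecarPath)
  if (is.null(side$sensitivity))
    stop("sidecar is missing the required field \"sensitivity\"")
  if (is.null(side$sensitivity$venc_cm_s) ||
      is.null(side$sensitivity$direction))
    stop("sidecar sensitivity must provide \"venc_cm_s\" and \"direction\"")
  grid <- .gridFromJson(side$grid)
  ph <- RNifti::readNifti(paste0(stem, "_ph.nii.gz"))
  mg <- RNifti::readNifti(paste0(stem, "_mag.nii.gz"))
  ph <- array(as.numeric(ph), dim = dim(ph))
  mg <- array(as.numeric(mg), dim = dim(mg))
  if (!all(dim(ph) == grid@shape) || !all(dim(mg) == grid@shape))
    stop("phase/magnitude dimensions do not match the sidecar geometry")
  if (any(ph < -pi - 1e-3 | ph > pi + 1e-3))
    stop("phase values out of (-pi, pi] and no scaling declared")
  sens <- sensitivityFromVenc(
    as.numeric(side$sensitivity$venc_cm_s),
    as.numeric(unlist(side$sensitivity$direction)),
    frame = if (is.null(side$sensitivity$frame)) "stack"
            else side$sensitivity$frame)
  frames <- lapply(seq_len(grid@shape[3]), function(k) {
    fi <- side$frames[[k]]
    tr <- rigidTransform(
      matrix(as.numeric(unlist(fi$rotation)), 3L, 3L, byrow = TRUE),
      as.numeric(unlist(fi$translation_mm)))
    new("FrameSample",
        phase = matrix(wrapPhase(ph[, , k]), grid@shape[1], grid@shape[2]),
        magnitude = matrix(mg[, , k], grid@shape[1], grid@shape[2]),
        grid2d = .sliceGrid(grid, k - 1L),
        transform = tr, sensitivity = sens,
        tAcq = as.numeric(fi$t_acq),
        cardiacPhase = as.numeric(fi$cardiac_phase),
        frameWeight = as.numeric(fi$frame_weight))
  })
  new("FrameStack", frames = frames, stackGrid = grid)
}

#' Write a cine velocity volume as 5D NIfTI
#'
#' Layout (x, y, z, cardiac phase, component), cm/s, with a JSON sidecar
#' recording the cine phases and grid.
#'
#' @param v a [CineVelocityVolume-class].
#' @param stem output path stem (writes \code{<stem>.nii.gz} and
#'   \code{<stem>.json}).
#' @return \code{stem}, invisibly.
#' @export
writeVelocityVolume <- function(v, stem) {
  .writeNiftiWithAffine(v@values, v@grid@affine, paste0(stem, ".nii.gz"))
  jsonlite::write_json(
    list(grid = .gridToJson(v@grid), phases = v@phases,
         units = "cm/s", layout = "x,y,z,phase,component"),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a cine velocity volume written by [writeVelocityVolume()]
#' @param stem path stem.
#' @return a [CineVelocityVolume-class].
#' @export
readVelocityVolume <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"))
  arr <- RNifti::readNifti(paste0(stem, ".nii.gz"))
  arr <- array(as.numeric(arr), dim = dim(arr))
  new("CineVelocityVolume", values = arr, grid = .gridFromJson(side$grid),
      phases = as.numeric(unlist(side$phases)))
}

#' Write a volume mask as uint8 NIfTI
#' @param mask a [VolumeMask-class].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeMask <- function(mask, file) {
  img <- RNifti::asNifti(array(as.integer(mask@values),
                               dim = dim(mask@values)), datatype = "uint8")
  sform(img) <- structure(mask@grid@affine, code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}
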