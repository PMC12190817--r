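# NIfTI, table and container I/O.

#' Write a volume as NIfTI
#'
#' @param volume 3D numeric array (complex volumes are written as magnitude
#'   and phase pairs via [write_complex_nifti()]).
#' @param path Output file (.nii or .nii.gz).
#' @param voxel_size mm, 3-vector.
#' @export
write_volume_nifti <- function(volume, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume, pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attr(arr, "pixdim") <- RNifti::pixdim(RNifti::readNifti(path))
  arr
}

#' @rdname write_volume_nifti
#' @param prefix Output prefix; writes `<prefix>_mag.nii.gz` and
#'   `<prefix>_phase.nii.gz`.
#' @export
write_complex_nifti <- function(volume, prefix, voxel_size = c(1, 1, 1)) {
  write_volume_nifti(Mod(volume), paste0(prefix, "_mag.nii.gz"), voxel_size)
  write_volume_nifti(Arg(volume), paste0(prefix, "_phase.nii.gz"), voxel_size)
  invisible(prefix)
}

#' Export phantom parameter maps as NIfTI files
#'
#' One file per parameter map (label, m0, t1, r2star, chi, delta_f0).
#'
#' @param phantom A `tissue_phantom`. @param dir Output directory.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- c("label_map", "m0", "t1", "r2star", "chi", "delta_f0")
  for (m in maps)
    write_volume_nifti(phantom[[m]], file.path(dir, paste0(m, ".nii.gz")),
                       phantom$voxel_size)
  invisible(dir)
}

#' Write / read a motion trajectory as a delimited table
#'
#' One row per navigator interval: translations (mm), rotations (degrees),
#' B0 offset (Hz) and gradient (Hz/mm).
#'
#' @param trajectory A `motion_trajectory`. @param path CSV path.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  df$interval_duration <- trajectory$interval_duration
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  states <- lapply(seq_len(nrow(df)), function(i)
    motion_state(translation = c(df$tx[i], df$ty[i], df$tz[i]),
                 rotation = c(df$rx[i], df$ry[i], df$rz[i]),
                 b0_offset = df$b0[i],
                 b0_gradient = c(df$gx[i], df$gy[i], df$gz[i])))
  structure(list(states = states,
                 interval_duration = df$interval_duration[1], seed = NA),
            class = "motion_trajectory")
}

#' Persist / restore a raw k-space container
#'
#' The samples, pattern, shot-to-interval map and noise level are stored as
#' an RDS file with a JSON protocol sidecar (`<path>.json`).
#'
#' @param kspace A `kspace_data`. @param path Output path (.rds).
#' @export
save_kspace <- function(kspace, path) {
  saveRDS(kspace, path)
  sidecar <- unclass(kspace$protocol)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_kspace
#' @export
load_kspace <- function(path) {
  readRDS(path)
}
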