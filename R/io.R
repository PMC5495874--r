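#' Write / read a labeled volume as NIfTI-1
#'
#' The label volume is stored with an integer datatype and isotropic voxel
#' size; the origin is recorded in the qform offset (RAS, mm).
#'
#' @param grid a `labeled_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labeled_grid <- function(grid, path) {
  stopifnot(inherits(grid, "labeled_grid"))
  arr <- array(as.integer(grid$labels), dim = grid$shape)
  attr(arr, "pixdim") <- rep(grid$voxel_size, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  ## store the label table next to the volume
  tabpath <- paste0(path, ".labels.json")
  jsonlite::write_json(list(origin = grid$origin, voxel_size = grid$voxel_size,
                            label_table = as.list(grid$label_table)),
                       tabpath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labeled_grid
#' @param path path written by [write_labeled_grid()].
#' @export
read_labeled_grid <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".labels.json"), simplifyVector = TRUE)
  lab <- array(as.integer(img), dim = dim(img))
  structure(list(shape = dim(lab), voxel_size = meta$voxel_size,
                 origin = as.numeric(meta$origin), labels = lab,
                 label_table = unlist(meta$label_table)),
            class = "labeled_grid")
}

#' Write / read a tensor field as a 6-volume NIfTI-1
#'
#' Lower-triangle component ordering xx, xy, yy, xz, yz, zz along the 4th
#' dimension.
#'
#' @param tf a `tensor_field`.
#' @param path output path.
#' @export
write_tensor_field <- function(tf, path) {
  stopifnot(inherits(tf, "tensor_field"))
  arr <- tf$tensors
  attr(arr, "pixdim") <- c(rep(tf$voxel_size, 3), 1)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  jsonlite::write_json(list(origin = tf$origin, voxel_size = tf$voxel_size,
                            kind = tf$kind),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tensor_field
#' @export
read_tensor_field <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  a <- array(as.numeric(img), dim = dim(img))
  structure(list(shape = dim(a)[1:3], voxel_size = meta$voxel_size,
                 origin = as.numeric(meta$origin), tensors = a,
                 kind = meta$kind),
            class = "tensor_field")
}

#' Write / read a sensor array as whitespace-separated text
#'
#' One row per sensor: `name x y z` for EEG and
#' `name x y z ox oy oz baseline` for MEG, units mm, RAS coordinates.
#' The two modalities go into separate sections introduced by `# eeg` and
#' `# meg <type>` comment lines.
#'
#' @param sensors a `sensor_array`.
#' @param path output path.
#' @export
write_sensor_array <- function(sensors, path) {
  stopifnot(inherits(sensors, "sensor_array"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# eeg", con)
  utils::write.table(sensors$eeg, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(paste("# meg", sensors$meg_type), con)
  utils::write.table(sensors$meg, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_array
#' @export
read_sensor_array <- function(path) {
  lines <- readLines(path)
  sec <- cumsum(startsWith(lines, "#"))
  hdr <- lines[startsWith(lines, "#")]
  meg_type <- sub("^# meg\\s*", "", hdr[2])
  eeg_lines <- lines[sec == 1 & !startsWith(lines, "#")]
  meg_lines <- lines[sec == 2 & !startsWith(lines, "#")]
  eeg <- utils::read.table(text = eeg_lines,
                           col.names = c("name", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  meg <- utils::read.table(text = meg_lines,
                           col.names = c("name", "x", "y", "z", "ox", "oy", "oz", "baseline"),
                           stringsAsFactors = FALSE)
  structure(list(eeg = eeg, meg = meg, meg_type = meg_type, reference = "average"),
            class = "sensor_array")
}

#' Persist evoked data / raw trials / leadfields / meshes
#'
#' Hierarchical containers are stored as RDS with named fields mirroring
#' the in-memory objects (`data`, channel names, modality tags,
#' `noise_std`, `sampling_rate`, ...).
#'
#' @param x object to store.
#' @param path output `.rds` path.
#' @export
write_container <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) readRDS(path)

#' Write a cluster report as tab-separated text
#'
#' @param est a clustered `source_estimate`.
#' @param path output path.
#' @export
write_cluster_report <- function(est, path) {
  stopifnot(inherits(est, "source_estimate"))
  cl <- est$clusters %||% list()
  df <- if (length(cl)) data.frame(
    cluster = seq_along(cl),
    latency_ms = est$latency,
    modality = est$modality_set,
    n_nodes = vapply(cl, function(c) length(c$nodes), integer(1)),
    peak_f = vapply(cl, `[[`, numeric(1), "peak_f"),
    peak_x = vapply(cl, function(c) c$peak_position[1], numeric(1)),
    peak_y = vapply(cl, function(c) c$peak_position[2], numeric(1)),
    peak_z = vapply(cl, function(c) c$peak_position[3], numeric(1))
  ) else data.frame(cluster = integer(0), latency_ms = numeric(0),
                    modality = character(0), n_nodes = integer(0),
                    peak_f = numeric(0), peak_x = numeric(0),
                    peak_y = numeric(0), peak_z = numeric(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ROI cuboids as structured text
#'
#' @param boxes list of `roi_box` objects.
#' @param path output path.
#' @export
write_roi_boxes <- function(boxes, path) {
  df <- do.call(rbind, lapply(seq_along(boxes), function(i) {
    b <- boxes[[i]]
    data.frame(roi = i, cx = b$center[1], cy = b$center[2], cz = b$center[3],
               ex = b$extents[1], ey = b$extents[2], ez = b$extents[3])
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
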