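#' Concentric-sphere head phantom specification
#'
#' Defines a multi-shell spherical head model: an ordered set of concentric
#' shells (outermost first), each with an outer radius, a tissue name, an
#' integer label and an isotropic conductivity. The default is the classic
#' four-compartment model (scalp, skull, CSF, brain/GM) with the tissue
#' conductivities used throughout the package: scalp 0.43, skull compacta
#' 0.0033, CSF 1.79 and gray matter 0.33 S/m.
#'
#' @param center numeric length-3, sphere centre in mm.
#' @param radii numeric, strictly decreasing outer radii in mm (outer to
#'   inner), one per shell; at least 2 shells.
#' @param tissues character, tissue name per shell.
#' @param conductivities numeric, isotropic conductivity per shell in S/m.
#' @param labels integer labels per shell (default `seq_along(radii)`).
#' @return An object of class `sphere_spec`.
#' @seealso [voxelize_sphere_model()], [make_sensor_array()],
#'   [eeg_sphere_potential()]
#' @export
sphere_spec <- function(center = c(0, 0, 0),
                        radii = c(92, 86, 80, 78),
                        tissues = c("scalp", "skull", "csf", "gm"),
                        conductivities = c(0.43, 0.0033, 1.79, 0.33),
                        labels = seq_along(radii)) {
  stopifnot(length(center) == 3, is.numeric(center))
  n <- length(radii)
  if (n < 2) stopf("a sphere spec needs at least 2 shells, got %d", n)
  if (length(tissues) != n || length(conductivities) != n || length(labels) != n)
    stopf("radii, tissues, conductivities and labels must have equal length")
  if (any(diff(radii) >= 0)) stopf("shell radii must be strictly decreasing (outer to inner)")
  if (any(conductivities <= 0)) stopf("conductivities must be > 0")
  structure(list(
    center = as.numeric(center),
    shells = data.frame(outer_radius = as.numeric(radii), tissue = tissues,
                        label = as.integer(labels),
                        conductivity = as.numeric(conductivities),
                        stringsAsFactors = FALSE)
  ), class = "sphere_spec")
}

#' Default seven-tissue conductivity table
#'
#' Named vector of isotropic tissue conductivities in S/m for the
#' seven-compartment head model: scalp 0.43, skull compacta 0.0033, skull
#' spongiosa 0.0116, dura mater 0.1, CSF 1.79, gray matter 0.33 and white
#' matter 0.14. The white-matter value is the isotropic reference used by the
#' effective-medium anisotropy mapping and comes from the effective-medium
#' literature rather than a calibrated measurement; all values can be
#' overridden wherever a conductivity table is accepted.
#'
#' @return Named numeric vector (S/m).
#' @export
default_conductivities <- function() {
  c(scalp = 0.43, skull_compacta = 0.0033, skull_spongiosa = 0.0116,
    dura = 0.1, csf = 1.79, gm = 0.33, wm = 0.14)
}

#' Voxelize a sphere phantom into a labeled volume
#'
#' Rasterizes a [sphere_spec()] onto a regular isotropic voxel grid. Each
#' voxel is labeled by the shell containing its centre; a centre exactly on a
#' shell boundary is assigned to the region outside that boundary (the outer
#' shell, or background at the outermost radius). Voxels outside the
#' outermost shell get label 0. The grid is centred on the sphere centre.
#'
#' @param spec a [sphere_spec()].
#' @param voxel_size isotropic voxel edge length in mm.
#' @param shape integer length-3, grid dimensions in voxels.
#' @return A `labeled_grid`: list with `shape`, `voxel_size`, `origin` (mm
#'   position of the corner of voxel (1,1,1)), `labels` (3-D integer array)
#'   and `label_table` (named character vector label -> tissue).
#' @export
voxelize_sphere_model <- function(spec, voxel_size, shape) {
  stopifnot(inherits(spec, "sphere_spec"), voxel_size > 0, length(shape) == 3)
  shape <- as.integer(shape)
  rmax <- spec$shells$outer_radius[1]
  half <- shape * voxel_size / 2
  if (any(rmax + voxel_size > half))
    stopf("sphere of radius %.1f mm does not fit the %s grid with a 1-voxel margin",
          rmax, paste(shape, collapse = "x"))
  origin <- spec$center - half
  ii <- (seq_len(shape[1]) - 0.5) * voxel_size + origin[1] - spec$center[1]
  jj <- (seq_len(shape[2]) - 0.5) * voxel_size + origin[2] - spec$center[2]
  kk <- (seq_len(shape[3]) - 0.5) * voxel_size + origin[3] - spec$center[3]
  d2 <- outer(outer(ii^2, jj^2, `+`), kk^2, `+`)
  d <- sqrt(d2)
  lab <- array(0L, dim = shape)
  ## innermost shell with outer radius strictly greater than the distance;
  ## boundary ties therefore fall outside (documented tie-break)
  for (s in seq_len(nrow(spec$shells)))
    lab[d < spec$shells$outer_radius[s]] <- spec$shells$label[s]
  tab <- spec$shells$tissue
  names(tab) <- as.character(spec$shells$label)
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin,
                 labels = lab, label_table = tab),
            class = "labeled_grid")
}

## Fibonacci-spiral covering of the spherical cap z/R in [zmin, 1];
## cap_fraction is the covered fraction of the full sphere area.
fibonacci_cap <- function(n, radius, cap_fraction = 0.75, center = c(0, 0, 0)) {
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  z <- 1 - (i - 0.5) / n * 2 * cap_fraction
  phi <- i * golden
  r <- sqrt(pmax(0, 1 - z^2))
  sweep(radius * cbind(x = r * cos(phi), y = r * sin(phi), z = z), 2, -center)
}

#' Synthetic EEG/MEG sensor array on a sphere phantom
#'
#' Places EEG electrodes on a Fibonacci-spiral covering of the upper 3/4 of
#' the outermost sphere surface and MEG coils on the same covering at an
#' outward standoff, with radial (outward) orientations. Axial gradiometers
#' are modeled as two-coil differences: the second coil sits at `baseline`
#' millimetres further out along the coil orientation.
#'
#' @param spec a [sphere_spec()].
#' @param n_eeg,n_meg sensor counts per modality (>= 1). Defaults mirror a
#'   typical clinical montage of 80 electrodes and 275 gradiometers.
#' @param meg_standoff distance in mm from the scalp surface to the coil
#'   centres.
#' @param meg_type `"magnetometer"` or `"axial_gradiometer"`.
#' @param baseline gradiometer baseline in mm (ignored for magnetometers).
#' @return A `sensor_array`: list with `eeg` (data.frame name,x,y,z),
#'   `meg` (data.frame name,x,y,z,ox,oy,oz,baseline) and `meg_type`.
#' @export
make_sensor_array <- function(spec, n_eeg = 80, n_meg = 275, meg_standoff = 25,
                              meg_type = c("axial_gradiometer", "magnetometer"),
                              baseline = 50) {
  stopifnot(inherits(spec, "sphere_spec"), n_eeg >= 1, n_meg >= 1, meg_standoff > 0)
  meg_type <- match.arg(meg_type)
  R <- spec$shells$outer_radius[1]
  eeg_pos <- fibonacci_cap(n_eeg, R, center = spec$center)
  meg_dir <- fibonacci_cap(n_meg, 1, center = c(0, 0, 0))
  meg_pos <- sweep((R + meg_standoff) * meg_dir, 2, -spec$center)
  eeg <- data.frame(name = sprintf("E%03d", seq_len(n_eeg)),
                    x = eeg_pos[, 1], y = eeg_pos[, 2], z = eeg_pos[, 3],
                    stringsAsFactors = FALSE)
  meg <- data.frame(name = sprintf("M%03d", seq_len(n_meg)),
                    x = meg_pos[, 1], y = meg_pos[, 2], z = meg_pos[, 3],
                    ox = meg_dir[, 1], oy = meg_dir[, 2], oz = meg_dir[, 3],
                    baseline = if (meg_type == "axial_gradiometer") baseline else NA_real_,
                    stringsAsFactors = FALSE)
  structure(list(eeg = eeg, meg = meg, meg_type = meg_type, reference = "average"),
            class = "sensor_array")
}

#' Synthetic axially symmetric diffusion tensors for white matter
#'
#' Fills white-matter voxels of a labeled grid with axially symmetric
#' diffusion tensors of prescribed fractional anisotropy (FA) and constant
#' mean diffusivity; all other voxels get isotropic tensors. The principal
#' axis follows a named direction pattern: `"tangential"` (azimuthal
#' direction, tangent to spheres around the grid centre, mimicking fibres
#' running along folded surfaces), `"radial"`, or `"uniform_z"`. For FA = f
#' and mean diffusivity md, the eigenvalue ratio rho = l1/l2 of the axially
#' symmetric tensor solves f = (rho - 1)/sqrt(rho^2 + 2), giving
#' rho = (1 + f sqrt(3 - 2 f^2))/(1 - f^2).
#'
#' @param grid a `labeled_grid`.
#' @param wm_label integer label of the white-matter compartment.
#' @param fa requested fractional anisotropy in `[0, 1)`.
#' @param direction_field pattern name (see above).
#' @param mean_diffusivity constant mean diffusivity in mm^2/s.
#' @return A `tensor_field`: the grid geometry plus `tensors`, an array
#'   `shape x 6` in lower-triangle order (xx, xy, yy, xz, yz, zz), and
#'   `kind = "diffusion"`.
#' @export
synthesize_dti_tensors <- function(grid, wm_label, fa = 0.7,
                                   direction_field = c("tangential", "radial", "uniform_z"),
                                   mean_diffusivity = 7e-4) {
  stopifnot(inherits(grid, "labeled_grid"), fa >= 0, fa < 1)
  direction_field <- match.arg(direction_field)
  md <- mean_diffusivity
  shp <- grid$shape
  nt <- prod(shp)
  tens <- matrix(0, nt, 6)
  tens[, c(1, 3, 6)] <- md # isotropic everywhere first
  wm <- which(grid$labels == wm_label)
  if (fa > 0 && length(wm)) {
    rho <- (1 + fa * sqrt(3 - 2 * fa^2)) / (1 - fa^2)
    l2 <- 3 * md / (rho + 2)
    l1 <- rho * l2
    ai <- arrayInd(wm, shp)
    ctr <- grid$origin + shp * grid$voxel_size / 2
    p <- sweep((ai - 0.5) * grid$voxel_size, 2, -grid$origin) # voxel centres
    rel <- sweep(p, 2, ctr)
    v <- switch(direction_field,
      radial = rel,
      uniform_z = matrix(rep(c(0, 0, 1), each = nrow(rel)), ncol = 3),
      tangential = cbind(-rel[, 2], rel[, 1], 0))
    nv <- sqrt(rowSums(v^2))
    deg <- nv < 1e-9
    if (any(deg)) v[deg, ] <- matrix(rep(c(1, 0, 0), each = sum(deg)), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    ## T = l2 I + (l1 - l2) v v'
    dl <- l1 - l2
    tens[wm, 1] <- l2 + dl * v[, 1]^2
    tens[wm, 2] <- dl * v[, 1] * v[, 2]
    tens[wm, 3] <- l2 + dl * v[, 2]^2
    tens[wm, 4] <- dl * v[, 1] * v[, 3]
    tens[wm, 5] <- dl * v[, 2] * v[, 3]
    tens[wm, 6] <- l2 + dl * v[, 3]^2
  }
  structure(list(shape = shp, voxel_size = grid$voxel_size, origin = grid$origin,
                 tensors = array(tens, dim = c(shp, 6)), kind = "diffusion"),
            class = "tensor_field")
}

#' Fractional anisotropy of packed symmetric tensors
#'
#' @param tensors matrix with 6 columns in (xx, xy, yy, xz, yz, zz) order.
#' @return numeric vector of FA values.
#' @export
tensor_fa <- function(tensors) {
  tensors <- rbind(tensors)
  apply(tensors, 1, function(t6) {
    M <- matrix(c(t6[1], t6[2], t6[4], t6[2], t6[3], t6[5], t6[4], t6[5], t6[6]), 3, 3)
    l <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (sum(l^2) == 0) return(0)
    sqrt(1.5 * sum((l - mean(l))^2) / sum(l^2))
  })
}

#' @export
print.sphere_spec <- function(x, ...) {
  cat("Sphere phantom:", nrow(x$shells), "shells, centre (",
      paste(format(x$center), collapse = ", "), ") mm\n")
  print(x$shells, row.names = FALSE)
  invisible(x)
}

#' @export
print.labeled_grid <- function(x, ...) {
  cat("Labeled voxel grid ", paste(x$shape, collapse = " x "),
      " @ ", x$voxel_size, " mm\n", sep = "")
  tab <- table(x$labels[x$labels > 0])
  for (l in names(tab))
    cat(sprintf("  label %s (%s): %d voxels\n", l,
                x$label_table[[l]] %||% "?", tab[[l]]))
  invisible(x)
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("Sensor array:", nrow(x$eeg), "EEG electrodes,",
      nrow(x$meg), x$meg_type, "MEG sensors\n")
  invisible(x)
}
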