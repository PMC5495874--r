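#' Dipole source
#'
#' @param position numeric length-3, mm.
#' @param moment numeric length-3, nA.m.
#' @return A `dipole_source`.
#' @export
dipole_source <- function(position, moment) {
  stopifnot(length(position) == 3, length(moment) == 3)
  structure(list(position = as.numeric(position), moment = as.numeric(moment)),
            class = "dipole_source")
}

## label of the voxel containing a point (0 outside the labeled volume /
## grid box)
voxel_label_at <- function(mesh, pts) {
  pts <- rbind(pts)
  vi <- floor(sweep(pts, 2, mesh$origin) / mesh$voxel_size) + 1
  lab_of_vox <- integer(prod(mesh$grid_shape))
  lab_of_vox[mesh$voxel_index] <- mesh$labels
  out <- integer(nrow(pts))
  ok <- vi[, 1] >= 1 & vi[, 2] >= 1 & vi[, 3] >= 1 &
    vi[, 1] <= mesh$grid_shape[1] & vi[, 2] <= mesh$grid_shape[2] &
    vi[, 3] <= mesh$grid_shape[3]
  lin <- (vi[, 1] - 1) + (vi[, 2] - 1) * mesh$grid_shape[1] +
    (vi[, 3] - 1) * mesh$grid_shape[1] * mesh$grid_shape[2] + 1
  out[ok] <- lab_of_vox[lin[ok]]
  out
}

#' Venant monopole load vector for a dipole
#'
#' Replaces the dipole singularity by balanced monopole loads on the FE
#' nodes that share an element with the node nearest to the dipole: a
#' regularized least-squares fit matches the dipole's spatial moments up to
#' second order (zeroth moment zero — enforced exactly as a constraint, so
#' charge is conserved to machine precision; first moment equal to the
#' dipole moment; second moments zero), with offsets scaled by a reference
#' length.
#'
#' @param dipole a [dipole_source()] (moment in nA.m).
#' @param mesh a `hex_mesh`.
#' @param aref reference length in mm for moment scaling (default 20).
#' @param lambda Tikhonov weight on the load magnitudes (default 1e-6).
#' @return sparse numeric vector of node loads in amperes (SI, for the
#'   dipole's nA.m moment).
#' @export
venant_rhs <- function(dipole, mesh, aref = 20, lambda = 1e-6) {
  stopifnot(inherits(dipole, "dipole_source"), inherits(mesh, "hex_mesh"))
  vl <- venant_loads_xyz(dipole$position, mesh, aref, lambda)
  q <- vl$Q %*% (dipole$moment * 1e-9)
  v <- numeric(nrow(mesh$nodes))
  v[vl$nodes] <- q
  v
}

## Venant load basis for the three Cartesian unit moments (1 A.m) at a
## position: Q is k x 3, loads for moment m (A.m) are Q %*% m.
venant_loads_xyz <- function(position, mesh, aref = 20, lambda = 1e-6) {
  if (voxel_label_at(mesh, position) == 0L)
    stopf("dipole position (%s) mm is outside the mesh",
          paste(format(position), collapse = ", "))
  nn <- nearest_mesh_node(mesh, position)
  inct <- node_elem_incidence_t(mesh)
  elems <- inct@i[seq.int(inct@p[nn] + 1L, inct@p[nn + 1L])] + 1L
  nodes <- sort(unique(as.vector(mesh$elements[elems, , drop = FALSE])))
  s <- sweep(mesh$nodes[nodes, , drop = FALSE], 2, position) / aref
  aref_si <- aref * 1e-3
  X <- rbind(t(s), t(s^2)) # 6 x k: first and second scaled moments
  k <- length(nodes)
  KKT <- rbind(cbind(crossprod(X) + lambda * diag(k), rep(1, k)),
               c(rep(1, k), 0))
  ## targets for the three unit moments (first scaled moment = e_d / aref)
  T3 <- rbind(diag(3) / aref_si, matrix(0, 3, 3))
  sol <- solve(KKT, rbind(crossprod(X, T3), 0))
  list(nodes = nodes, Q = sol[seq_len(k), , drop = FALSE])
}

## first moment of a load vector about a position (A.m), for diagnostics
venant_moment <- function(rhs, mesh, position) {
  i <- which(rhs != 0)
  drop(crossprod(rhs[i], sweep(mesh$nodes[i, , drop = FALSE], 2, position) * 1e-3))
}

## --- transfer matrices ---------------------------------------------------

## scalp-surface nodes: nodes of outer-tissue elements that touch the
## background (fewer than 8 incident elements)
surface_nodes <- function(mesh) {
  inc <- node_elem_incidence(mesh)
  n_inc <- as.vector(Matrix::rowSums(inc))
  which(n_inc < 8)
}

#' EEG transfer matrix
#'
#' Snaps each electrode to the nearest scalp-surface FE node and solves one
#' FEM system per electrode, yielding a dense sensors-by-nodes matrix `T`
#' such that `T %*% rhs` equals the average-referenced electrode potentials
#' of the direct solve for any charge-balanced load vector. Rows are
#' average-referenced across sensors and mean-centred across nodes (both
#' operations leave read-outs of balanced loads unchanged).
#'
#' @param K a `fem_stiffness`.
#' @param sensors a `sensor_array`.
#' @param mesh the `hex_mesh`.
#' @param snap_tol maximum electrode-to-scalp-node distance in mm
#'   (default 10).
#' @param tol solver tolerance.
#' @return A `transfer_matrix` (modality `"eeg"`): `T`, snapped `nodes`,
#'   snapped `positions` (mm), `channel_names`.
#' @export
eeg_transfer <- function(K, sensors, mesh, snap_tol = 10, tol = 1e-9) {
  stopifnot(inherits(K, "fem_stiffness"), inherits(sensors, "sensor_array"))
  surf <- surface_nodes(mesh)
  ep <- as.matrix(sensors$eeg[, c("x", "y", "z")])
  snap <- integer(nrow(ep))
  for (s in seq_len(nrow(ep))) {
    d2 <- rowSums(sweep(mesh$nodes[surf, , drop = FALSE], 2, ep[s, ])^2)
    snap[s] <- surf[which.min(d2)]
  }
  dist <- sqrt(rowSums((mesh$nodes[snap, , drop = FALSE] - ep)^2))
  if (any(dist > snap_tol))
    stopf("electrode(s) farther than %g mm from the scalp surface: %s",
          snap_tol, paste(sensors$eeg$name[dist > snap_tol], collapse = ", "))
  stiffness_solver(K, mesh$node_ijk)
  ns <- length(snap)
  TT <- matrix(0, ns, K$n_nodes)
  for (s in seq_len(ns)) {
    e <- numeric(K$n_nodes)
    e[snap[s]] <- 1
    if (snap[s] == K$ground)
      stopf("electrode %s snapped to the reference node; choose different sensors", s)
    e[K$ground] <- 0
    TT[s, ] <- pcg_amg(K$cache$Ag, e, K$cache$levels, tol = tol)
  }
  TT <- TT - matrix(colMeans(TT), ns, K$n_nodes, byrow = TRUE) # average reference
  TT <- TT - rowMeans(TT)                                      # constant gauge
  structure(list(T = TT, modality = "eeg", nodes = snap,
                 positions = mesh$nodes[snap, , drop = FALSE],
                 channel_names = sensors$eeg$name),
            class = "transfer_matrix")
}

## coil table expanded to physical integration points: magnetometer -> one
## coil; axial gradiometer -> two coils with +1/-1 polarity
coil_points <- function(sensors) {
  meg <- sensors$meg
  pos <- as.matrix(meg[, c("x", "y", "z")])
  ori <- as.matrix(meg[, c("ox", "oy", "oz")])
  ori <- ori / sqrt(rowSums(ori^2))
  if (sensors$meg_type == "axial_gradiometer") {
    bl <- meg$baseline
    list(pos = rbind(pos, pos + bl * ori), ori = rbind(ori, ori),
         pol = c(rep(1, nrow(pos)), rep(-1, nrow(pos))),
         chan = rep(seq_len(nrow(pos)), 2))
  } else {
    list(pos = pos, ori = ori, pol = rep(1, nrow(pos)),
         chan = seq_len(nrow(pos)))
  }
}

#' MEG transfer matrix
#'
#' For each MEG channel, integrates the secondary (volume-current) flux
#' weight vector `w` over all elements with one Gauss point per element and
#' solves one FEM system, so that the channel's secondary field for any load
#' vector `b` is `t(w) %*% solve(K, b) = T %*% b`. Gradiometer channels are
#' two-coil differences along the baseline. The primary (source-space)
#' field is added separately from the analytic Biot-Savart term when
#' leadfields are computed.
#'
#' @inheritParams eeg_transfer
#' @return A `transfer_matrix` (modality `"meg"`) holding the solved rows
#'   `T` (channel x nodes, tesla per ampere-load) and the coil geometry.
#' @export
meg_transfer <- function(K, sensors, mesh, tol = 1e-9) {
  stopifnot(inherits(K, "fem_stiffness"), inherits(sensors, "sensor_array"))
  cp <- coil_points(sensors)
  if (any(voxel_label_at(mesh, cp$pos) != 0L))
    stopf("MEG coil(s) inside the head volume")
  W <- cpp_meg_weights(mesh$nodes * 1e-3, mesh$elements, mesh$tensors,
                       K$volumes * 1e-9, cp$pos * 1e-3, cp$ori)
  nchan <- max(cp$chan)
  Wc <- matrix(0, nchan, K$n_nodes)
  for (r in seq_len(nrow(W)))
    Wc[cp$chan[r], ] <- Wc[cp$chan[r], ] + cp$pol[r] * W[r, ]
  stiffness_solver(K, mesh$node_ijk)
  TT <- matrix(0, nchan, K$n_nodes)
  for (s in seq_len(nchan)) {
    w <- Wc[s, ]
    w[K$ground] <- 0 # weights vanish against constants; grounding is gauge-safe
    TT[s, ] <- pcg_amg(K$cache$Ag, w, K$cache$levels, tol = tol)
  }
  structure(list(T = TT, weights = Wc, modality = "meg",
                 coil = cp, channel_names = sensors$meg$name),
            class = "transfer_matrix")
}

## primary magnetic field (Biot-Savart of the current dipole) per MEG
## channel, tesla for a moment in A.m
primary_b <- function(cp, dip_pos_mm, mom_si) {
  p <- cp$pos * 1e-3
  R <- sweep(p, 2, dip_pos_mm * 1e-3)
  r3 <- rowSums(R^2)^1.5
  mxR <- cbind(mom_si[2] * R[, 3] - mom_si[3] * R[, 2],
               mom_si[3] * R[, 1] - mom_si[1] * R[, 3],
               mom_si[1] * R[, 2] - mom_si[2] * R[, 1])
  b <- 1e-7 * rowSums(mxR * cp$ori) / r3
  as.vector(tapply(b * cp$pol, cp$chan, sum))
}

#' Direct MEG forward solution for one dipole
#'
#' Total field = primary (Biot-Savart of the dipole in free space) +
#' secondary field of the volume currents `-sigma grad(u)`, integrated
#' element-wise with one Gauss point. Output in fT per the dipole's moment.
#'
#' @param K a `fem_stiffness`.
#' @param sensors a `sensor_array`.
#' @param mesh the `hex_mesh`.
#' @param dipole a [dipole_source()] (moment nA.m).
#' @param tol solver tolerance.
#' @return numeric vector of channel fields in fT.
#' @export
meg_forward <- function(K, sensors, mesh, dipole, tol = 1e-9) {
  cp <- coil_points(sensors)
  if (any(voxel_label_at(mesh, cp$pos) != 0L))
    stopf("MEG coil(s) inside the head volume")
  rhs <- venant_rhs(dipole, mesh)
  u <- solve_potential(K, rhs, mesh, tol = tol)
  W <- cpp_meg_weights(mesh$nodes * 1e-3, mesh$elements, mesh$tensors,
                       K$volumes * 1e-9, cp$pos * 1e-3, cp$ori)
  bsec <- as.vector(tapply(as.vector(W %*% u) * cp$pol, cp$chan, sum))
  bpri <- primary_b(cp, dipole$position, dipole$moment * 1e-9)
  (bpri + bsec) * 1e15
}

#' EEG potentials for one dipole by direct solve
#'
#' @inheritParams meg_forward
#' @param transfer an `eeg_transfer` result (for the snapped electrode
#'   nodes), or NULL to snap `sensors` here.
#' @return average-referenced electrode potentials in uV.
#' @export
eeg_forward <- function(K, sensors, mesh, dipole, transfer = NULL, tol = 1e-9) {
  rhs <- venant_rhs(dipole, mesh)
  u <- solve_potential(K, rhs, mesh, tol = tol)
  nodes <- if (!is.null(transfer)) transfer$nodes else {
    surf <- surface_nodes(mesh)
    ep <- as.matrix(sensors$eeg[, c("x", "y", "z")])
    vapply(seq_len(nrow(ep)), function(s)
      surf[which.min(rowSums(sweep(mesh$nodes[surf, , drop = FALSE], 2, ep[s, ])^2))],
      integer(1))
  }
  v <- u[nodes]
  (v - mean(v)) * 1e6
}

#' Compute stacked EEG/MEG leadfields over a source space
#'
#' Builds the Venant load vectors for three Cartesian unit moments
#' (1 nA.m) at every source position and maps them through the transfer
#' matrices; the MEG block additionally receives the analytic primary-field
#' term. EEG rows are in uV per nA.m, MEG rows in fT per nA.m; rows are
#' stacked EEG first with per-row modality tags.
#'
#' @param eeg_tm,meg_tm transfer matrices from [eeg_transfer()] /
#'   [meg_transfer()]; either may be NULL for a single-modality set.
#' @param source_space a `source_space`.
#' @param mesh the `hex_mesh`.
#' @return A `leadfield_set`: `L` (channels x 3*k), `modality` (per row),
#'   `channel_names`, `units`, `source_space` (positions, spacing, hash).
#' @export
compute_leadfields <- function(eeg_tm = NULL, meg_tm = NULL, source_space, mesh) {
  stopifnot(inherits(source_space, "source_space"))
  k <- nrow(source_space$positions)
  if (k == 0) stopf("empty source space")
  trip <- vector("list", k)
  for (s in seq_len(k)) {
    vl <- venant_loads_xyz(source_space$positions[s, ], mesh)
    nk <- length(vl$nodes)
    trip[[s]] <- list(i = rep(vl$nodes, 3),
                      j = rep(3L * (s - 1L) + 1:3, each = nk),
                      x = as.vector(vl$Q) * 1e-9) # per nA.m
  }
  B <- sparseMatrix(i = unlist(lapply(trip, `[[`, "i")),
                    j = unlist(lapply(trip, `[[`, "j")),
                    x = unlist(lapply(trip, `[[`, "x")),
                    dims = c(nrow(mesh$nodes), 3L * k))
  blocks <- list(); mods <- character(0); chans <- character(0)
  if (!is.null(eeg_tm)) {
    Le <- as.matrix(eeg_tm$T %*% B) * 1e6 # V -> uV (loads already per nA.m)
    blocks <- c(blocks, list(Le))
    mods <- c(mods, rep("eeg", nrow(Le)))
    chans <- c(chans, eeg_tm$channel_names)
  }
  if (!is.null(meg_tm)) {
    Lsec <- as.matrix(meg_tm$T %*% B)
    Lpri <- matrix(0, nrow(Lsec), ncol(Lsec))
    for (s in seq_len(k)) for (d in 1:3) {
      mom <- c(0, 0, 0); mom[d] <- 1e-9
      Lpri[, 3L * (s - 1L) + d] <- primary_b(meg_tm$coil, source_space$positions[s, ], mom)
    }
    Lm <- (Lpri + Lsec) * 1e15 # T -> fT
    blocks <- c(blocks, list(Lm))
    mods <- c(mods, rep("meg", nrow(Lm)))
    chans <- c(chans, meg_tm$channel_names)
  }
  if (!length(blocks)) stopf("at least one transfer matrix is required")
  L <- do.call(rbind, blocks)
  leadfield_set(L, mods, chans, source_space)
}

#' Construct a leadfield set
#'
#' @param L channels x (3 * sources) gain matrix; EEG rows uV/nA.m, MEG
#'   rows fT/nA.m.
#' @param modality character per row (`"eeg"`/`"meg"`).
#' @param channel_names character per row.
#' @param source_space the `source_space` the columns refer to.
#' @return A `leadfield_set`.
#' @export
leadfield_set <- function(L, modality, channel_names, source_space) {
  stopifnot(nrow(L) == length(modality), nrow(L) == length(channel_names),
            ncol(L) == 3 * nrow(source_space$positions))
  if (any(!is.finite(L))) stopf("leadfield contains non-finite entries")
  structure(list(L = L, modality = modality, channel_names = channel_names,
                 units = c(eeg = "uV/nAm", meg = "fT/nAm"),
                 source_space = source_space,
                 cache = new.env(parent = emptyenv())),
            class = "leadfield_set")
}

## columns of source j
lf_cols <- function(j) c(3L * (j - 1L) + 1L, 3L * (j - 1L) + 2L, 3L * j)

## modality subset of a leadfield set
#' @export
subset_leadfield <- function(lf, modality) {
  keep <- lf$modality %in% modality
  if (!any(keep)) stopf("no channels of modality %s", paste(modality, collapse = "/"))
  leadfield_set(lf$L[keep, , drop = FALSE], lf$modality[keep],
                lf$channel_names[keep], lf$source_space)
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("Transfer matrix (", x$modality, "): ", nrow(x$T), " channels x ",
      ncol(x$T), " FE nodes\n", sep = "")
  invisible(x)
}

#' @export
print.leadfield_set <- function(x, ...) {
  cat("Leadfield set:", nrow(x$L), "channels x", ncol(x$L), "columns (",
      nrow(x$source_space$positions), "sources )\n")
  cat("  modalities:", paste(sprintf("%s=%d", names(table(x$modality)),
                                     table(x$modality)), collapse = ", "), "\n")
  invisible(x)
}
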