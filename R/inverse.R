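#' Construct an evoked-data container
#'
#' @param data channels x time matrix.
#' @param channel_meta data.frame with `name`, `modality`, `noise_std`.
#' @param sampling_rate Hz.
#' @param time_zero sample index of the spike peak (time 0 ms).
#' @return An `evoked_data`.
#' @export
evoked_data <- function(data, channel_meta, sampling_rate, time_zero) {
  stopifnot(nrow(data) == nrow(channel_meta), all(channel_meta$noise_std > 0))
  structure(list(data = data, channel_meta = channel_meta,
                 sampling_rate = sampling_rate, time_zero = time_zero),
            class = "evoked_data")
}

## sample index for a latency in ms relative to time zero
evoked_sample <- function(ev, latency_ms) {
  s <- ev$time_zero + round(latency_ms * ev$sampling_rate / 1000)
  if (s < 1 || s > ncol(ev$data))
    stopf("latency %g ms is outside the data window", latency_ms)
  s
}

#' Topography at a latency
#' @param ev an `evoked_data`.
#' @param latency_ms latency in ms relative to the spike peak.
#' @return numeric channel vector.
#' @export
evoked_topography <- function(ev, latency_ms) ev$data[, evoked_sample(ev, latency_ms)]

#' Average marked spikes into an evoked response
#'
#' Aligns a window around each marker and averages across trials. The
#' per-channel noise standard deviation of the *average* is estimated from
#' the pre-onset baseline segment of the averaged window.
#'
#' @param trials a `raw_trials`.
#' @param markers sample index of the nominal spike peak per trial
#'   (defaults to the recorded event latencies).
#' @param window ms pair around the marker, e.g. `c(-150, 100)`.
#' @param baseline_end_ms end of the baseline segment in ms (default -80;
#'   the baseline runs from the window start to this latency).
#' @return An `evoked_data` with `time_zero` at the marker.
#' @export
average_spikes <- function(trials, markers = NULL, window = c(-150, 100),
                           baseline_end_ms = -80) {
  stopifnot(inherits(trials, "raw_trials"), length(window) == 2)
  markers <- markers %||% trials$event_latency
  ntr <- dim(trials$data)[3]
  if (length(markers) == 1) markers <- rep(markers, ntr)
  stopifnot(length(markers) == ntr)
  sr <- trials$sampling_rate
  w0 <- round(window[1] * sr / 1000)
  w1 <- round(window[2] * sr / 1000)
  if (any(markers + w0 < 1) || any(markers + w1 > dim(trials$data)[2]))
    stopf("averaging window [%g, %g] ms exceeds the trial bounds", window[1], window[2])
  nc <- dim(trials$data)[1]
  nt <- w1 - w0 + 1
  avg <- matrix(0, nc, nt)
  for (tr in seq_len(ntr))
    avg <- avg + trials$data[, (markers[tr] + w0):(markers[tr] + w1), tr]
  avg <- avg / ntr
  bl_end <- round(baseline_end_ms * sr / 1000) - w0 + 1
  if (bl_end < 2) stopf("baseline segment is empty; widen the window")
  noise_std <- apply(avg[, seq_len(bl_end), drop = FALSE], 1, sd)
  noise_std <- pmax(noise_std, 1e-12 * max(abs(avg), 1e-300))
  meta <- trials$channel_meta
  meta$noise_std <- noise_std
  evoked_data(avg, meta, sr, time_zero = 1 - w0)
}

#' Whiten and combine EEG and MEG into one joint problem
#'
#' Divides every channel of the data and the matching leadfield row by that
#' channel's noise standard deviation, rendering both modalities
#' dimensionless with unit noise variance, then stacks rows EEG first.
#' Errors if the two leadfields refer to different source spaces.
#'
#' @param eeg,meg `evoked_data` objects (either may be NULL).
#' @param eeg_lf,meg_lf matching `leadfield_set`s.
#' @return list with `evoked` (joint `evoked_data`) and `leadfield`
#'   (joint whitened `leadfield_set`).
#' @export
combine_emeg <- function(eeg = NULL, meg = NULL, eeg_lf = NULL, meg_lf = NULL) {
  parts <- list()
  if (!is.null(eeg)) parts$eeg <- list(ev = eeg, lf = eeg_lf)
  if (!is.null(meg)) parts$meg <- list(ev = meg, lf = meg_lf)
  if (!length(parts)) stopf("no modality supplied")
  hashes <- unique(vapply(parts, function(p) p$lf$source_space$hash, character(1)))
  if (length(hashes) > 1) stopf("leadfields refer to different source spaces")
  dat <- NULL; Lw <- NULL; meta <- NULL; mods <- character(0)
  sr <- unique(vapply(parts, function(p) p$ev$sampling_rate, numeric(1)))
  tz <- unique(vapply(parts, function(p) p$ev$time_zero, numeric(1)))
  if (length(sr) > 1 || length(tz) > 1)
    stopf("modalities are not time-aligned (sampling rate / time zero differ)")
  for (p in parts) {
    s <- p$ev$channel_meta$noise_std
    dat <- rbind(dat, p$ev$data / s)
    Lw <- rbind(Lw, p$lf$L / s)
    m <- p$ev$channel_meta
    m$noise_std <- rep(1, nrow(m))
    meta <- rbind(meta, m)
    mods <- c(mods, p$lf$modality)
  }
  ss <- parts[[1]]$lf$source_space
  list(evoked = evoked_data(dat, meta, sr, tz),
       leadfield = leadfield_set(Lw, mods, meta$name, ss))
}

#' Inverse configuration
#'
#' @param lambda fixed Tikhonov parameter, or NULL for the SNR-derived rule
#'   `lambda = trace(L L') / (n_sensors * SNR^2)` with the SNR estimated
#'   from the whitened topography.
#' @param threshold_fraction F-value display/cluster threshold as a
#'   fraction of the maximum (default 0.85).
#' @param analysis_latencies ms, default `c(-7, -23)` (near spike peak, and
#'   at the preceding onset peak).
#' @param min_cluster_size minimum cluster size in nodes (default 5).
#' @return An `inverse_config`.
#' @export
inverse_config <- function(lambda = NULL, threshold_fraction = 0.85,
                           analysis_latencies = c(-7, -23),
                           min_cluster_size = 5) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  structure(list(lambda = lambda, threshold_fraction = threshold_fraction,
                 analysis_latencies = analysis_latencies,
                 min_cluster_size = min_cluster_size),
            class = "inverse_config")
}

## cached spectral pieces of the sLORETA operator for one leadfield:
## G = L L' = U diag(d) U', A = L' U. For a given lambda,
##   J_j   = A_j diag(1/(d+lambda)) U' b          (minimum-norm estimate)
##   S_jj  = A_j diag(1/(d+lambda)) A_j'          (resolution block)
sloreta_operator <- function(lf) {
  op <- lf$cache$sloreta_op
  if (!is.null(op)) return(op)
  G <- tcrossprod(lf$L)
  eg <- eigen(G, symmetric = TRUE)
  op <- list(U = eg$vectors, d = pmax(eg$values, 0), A = crossprod(lf$L, eg$vectors),
             trG = sum(diag(G)), n = nrow(lf$L))
  lf$cache$sloreta_op <- op
  op
}

#' sLORETA source localization of a topography
#'
#' Computes the Tikhonov-regularized minimum-norm estimate and standardizes
#' each source node's 3-vector by the corresponding 3x3 diagonal block of
#' the resolution-derived variance, yielding a nonnegative pseudo-F value
#' per node (zero localization error for single noiseless sources). The
#' regularization parameter follows the config: a fixed value, or
#' `trace(L L') / (n * SNR^2)` with `SNR^2` estimated from the whitened
#' topography as `max(||b||^2 / n - 1, 1e-6)` (valid when the noise is
#' whitened to unit variance).
#'
#' @param leadfield a (whitened, for combined use) `leadfield_set`.
#' @param topography channel vector matching the leadfield rows.
#' @param config an [inverse_config()].
#' @param latency optional ms label attached to the estimate.
#' @param modality_set label (`"EEG"`, `"MEG"`, `"EMEG"`); derived from the
#'   leadfield when missing.
#' @return A `source_estimate` with per-node `f` values.
#' @export
sloreta <- function(leadfield, topography, config = inverse_config(),
                    latency = NA_real_, modality_set = NULL) {
  stopifnot(inherits(leadfield, "leadfield_set"))
  b <- as.numeric(topography)
  if (length(b) != nrow(leadfield$L))
    stopf("topography has %d channels, leadfield %d", length(b), nrow(leadfield$L))
  op <- sloreta_operator(leadfield)
  lambda <- config$lambda
  if (is.null(lambda)) {
    snr2 <- max(sum(b^2) / op$n - 1, 1e-6)
    lambda <- op$trG / (op$n * snr2)
  }
  if (lambda < 0) stopf("lambda must be >= 0")
  if (lambda == 0 && min(op$d) < 1e-12 * max(op$d))
    stopf("lambda = 0 with a rank-deficient gram matrix")
  w <- 1 / (op$d + lambda)
  Ub <- crossprod(op$U, b)
  J <- op$A %*% (w * Ub)          # 3k x 1 minimum-norm estimate
  Aw <- op$A * rep(sqrt(w), each = nrow(op$A))
  k <- ncol(leadfield$L) / 3
  dim(J) <- NULL
  ## per-node 3x3 resolution blocks S and F = J' S^+ J, via a ridge inverse
  ## that is exact in the limit because J lies in the row space of S
  i1 <- 3 * seq_len(k) - 2; i2 <- i1 + 1; i3 <- i1 + 2
  s11 <- rowSums(Aw[i1, , drop = FALSE]^2)
  s22 <- rowSums(Aw[i2, , drop = FALSE]^2)
  s33 <- rowSums(Aw[i3, , drop = FALSE]^2)
  s12 <- rowSums(Aw[i1, , drop = FALSE] * Aw[i2, , drop = FALSE])
  s13 <- rowSums(Aw[i1, , drop = FALSE] * Aw[i3, , drop = FALSE])
  s23 <- rowSums(Aw[i2, , drop = FALSE] * Aw[i3, , drop = FALSE])
  eps <- 1e-10 * (s11 + s22 + s33)
  s11 <- s11 + eps; s22 <- s22 + eps; s33 <- s33 + eps
  c11 <- s22 * s33 - s23^2
  c12 <- s13 * s23 - s12 * s33
  c13 <- s12 * s23 - s13 * s22
  c22 <- s11 * s33 - s13^2
  c23 <- s12 * s13 - s11 * s23
  c33 <- s11 * s22 - s12^2
  det <- s11 * c11 + s12 * c12 + s13 * c13
  j1 <- J[i1]; j2 <- J[i2]; j3 <- J[i3]
  f <- (j1 * (c11 * j1 + c12 * j2 + c13 * j3) +
        j2 * (c12 * j1 + c22 * j2 + c23 * j3) +
        j3 * (c13 * j1 + c23 * j2 + c33 * j3)) / det
  f <- pmax(f, 0)
  if (is.null(modality_set)) {
    mods <- unique(leadfield$modality)
    modality_set <- if (length(mods) > 1) "EMEG" else toupper(mods)
  }
  structure(list(f = f, latency = latency, modality_set = modality_set,
                 lambda = lambda, source_space = leadfield$source_space,
                 clusters = NULL),
            class = "source_estimate")
}

#' Threshold an F-map and cluster supra-threshold nodes
#'
#' Keeps nodes with `F >= threshold_fraction * max(F)`, groups them by
#' source-space adjacency (neighbours within 1.5 x spacing), discards
#' clusters below the minimum size and sorts clusters by peak F descending.
#'
#' @param est a `source_estimate`.
#' @param config an [inverse_config()].
#' @return The estimate with `clusters`: list of
#'   `{nodes, peak_node, peak_f}`.
#' @export
threshold_clusters <- function(est, config = inverse_config()) {
  stopifnot(inherits(est, "source_estimate"))
  if (!length(est$f)) stopf("empty source estimate")
  thr <- config$threshold_fraction * max(est$f)
  sel <- which(est$f >= thr)
  pos <- est$source_space$positions[sel, , drop = FALSE]
  radius <- 1.5 * est$source_space$spacing
  ## connected components by BFS over the adjacency graph
  nsel <- length(sel)
  comp <- integer(nsel)
  cur <- 0L
  for (s in seq_len(nsel)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      d2 <- rowSums(sweep(pos, 2, pos[v, ])^2)
      nb <- which(d2 <= radius^2 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  clusters <- lapply(seq_len(cur), function(ci) {
    nodes <- sel[comp == ci]
    pk <- nodes[which.max(est$f[nodes])]
    list(nodes = nodes, peak_node = pk, peak_f = est$f[pk],
         peak_position = est$source_space$positions[pk, ])
  })
  clusters <- Filter(function(cl) length(cl$nodes) >= config$min_cluster_size, clusters)
  clusters <- clusters[order(-vapply(clusters, `[[`, numeric(1), "peak_f"))]
  est$threshold <- thr
  est$clusters <- clusters
  est
}

#' Cuboid region of interest around a cluster peak
#'
#' Axis-aligned cuboid for planning a zoomed high-resolution MR
#' acquisition; the default extents are 160 x 82 x 28 mm.
#'
#' @param center mm point (typically a cluster peak position).
#' @param extents mm triple.
#' @return A `roi_box` with `center`, `extents`, `lo` and `hi` corners.
#' @export
roi_box <- function(center, extents = c(160, 82, 28)) {
  stopifnot(length(center) == 3, length(extents) == 3, all(extents > 0))
  structure(list(center = as.numeric(center), extents = as.numeric(extents),
                 lo = center - extents / 2, hi = center + extents / 2),
            class = "roi_box")
}

#' Dipole-scan residual-variance map
#'
#' For every source node, fits an unconstrained 3-vector moment to the
#' topography by least squares and records the residual variance
#' `RV = 1 - explained variance`, in `[0, 1]`.
#'
#' @param leadfield a `leadfield_set`.
#' @param topography channel vector.
#' @return numeric RV per node.
#' @export
dipole_scan_goal <- function(leadfield, topography) {
  b <- as.numeric(topography)
  nb2 <- sum(b^2)
  if (nb2 == 0) stopf("all-zero topography")
  k <- ncol(leadfield$L) / 3
  gram <- leadfield$cache$scan_gram
  if (is.null(gram)) {
    L <- leadfield$L
    i1 <- 3 * seq_len(k) - 2; i2 <- i1 + 1; i3 <- i1 + 2
    gram <- list(i1 = i1, i2 = i2, i3 = i3,
                 s11 = colSums(L[, i1, drop = FALSE]^2),
                 s22 = colSums(L[, i2, drop = FALSE]^2),
                 s33 = colSums(L[, i3, drop = FALSE]^2),
                 s12 = colSums(L[, i1, drop = FALSE] * L[, i2, drop = FALSE]),
                 s13 = colSums(L[, i1, drop = FALSE] * L[, i3, drop = FALSE]),
                 s23 = colSums(L[, i2, drop = FALSE] * L[, i3, drop = FALSE]))
    leadfield$cache$scan_gram <- gram
  }
  g <- crossprod(leadfield$L, b)
  j1 <- g[gram$i1]; j2 <- g[gram$i2]; j3 <- g[gram$i3]
  ## explained variance via a ridge-stabilized 3x3 inverse (exact in the
  ## limit: G'b lies in the row space of the Gram block)
  eps <- 1e-14 * (gram$s11 + gram$s22 + gram$s33)
  s11 <- gram$s11 + eps; s22 <- gram$s22 + eps; s33 <- gram$s33 + eps
  s12 <- gram$s12; s13 <- gram$s13; s23 <- gram$s23
  c11 <- s22 * s33 - s23^2
  c12 <- s13 * s23 - s12 * s33
  c13 <- s12 * s23 - s13 * s22
  c22 <- s11 * s33 - s13^2
  c23 <- s12 * s13 - s11 * s23
  c33 <- s11 * s22 - s12^2
  det <- s11 * c11 + s12 * c12 + s13 * c13
  expl <- (j1 * (c11 * j1 + c12 * j2 + c13 * j3) +
           j2 * (c12 * j1 + c22 * j2 + c23 * j3) +
           j3 * (c13 * j1 + c23 * j2 + c33 * j3)) / det
  pmin(pmax(1 - expl / nb2, 0), 1)
}

#' @export
print.source_estimate <- function(x, ...) {
  cat("sLORETA estimate (", x$modality_set, ") at ",
      if (is.na(x$latency)) "?" else x$latency, " ms: ",
      length(x$f), " nodes, max F = ", signif(max(x$f), 4), "\n", sep = "")
  if (!is.null(x$clusters)) {
    cat(length(x$clusters), "cluster(s) at threshold", signif(x$threshold, 4), "\n")
    for (i in seq_along(x$clusters)) {
      cl <- x$clusters[[i]]
      cat(sprintf("  #%d: %d nodes, peak F %.3g at (%s) mm\n", i,
                  length(cl$nodes), cl$peak_f,
                  paste(format(round(cl$peak_position, 1)), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
summary.source_estimate <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.source_estimate <- function(x, ...) {
  pos <- x$source_space$positions
  f <- x$f / max(x$f)
  cols <- grDevices::hcl.colors(100, "YlOrRd", rev = TRUE)[pmax(1, ceiling(f * 100))]
  graphics::plot(pos[, 1], pos[, 2], col = cols, pch = 16, cex = 0.4 + f,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("sLORETA F (%s, %s ms)", x$modality_set,
                                format(x$latency)), asp = 1, ...)
  if (!is.null(x$clusters))
    for (cl in x$clusters)
      graphics::points(cl$peak_position[1], cl$peak_position[2], pch = 4, cex = 2)
  invisible(x)
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("ROI cuboid %g x %g x %g mm centred at (%s) mm\n",
              x$extents[1], x$extents[2], x$extents[3],
              paste(format(round(x$center, 1)), collapse = ", ")))
  invisible(x)
}

#' @export
print.evoked_data <- function(x, ...) {
  cat("Evoked data:", nrow(x$data), "channels x", ncol(x$data), "samples @",
      x$sampling_rate, "Hz; time zero at sample", x$time_zero, "\n")
  invisible(x)
}
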