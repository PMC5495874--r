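## Legendre polynomials P_n and derivatives P'_n for n = 0..nmax at the
## values x (upward recurrences, stable on [-1, 1])
legendre_table <- function(nmax, x) {
  P <- matrix(0, length(x), nmax + 1)
  dP <- matrix(0, length(x), nmax + 1)
  P[, 1] <- 1
  P[, 2] <- x
  dP[, 2] <- 1
  for (n in 1:(nmax - 1)) {
    P[, n + 2] <- ((2 * n + 1) * x * P[, n + 1] - n * P[, n]) / (n + 1)
    dP[, n + 2] <- dP[, n] + (2 * n + 1) * P[, n + 1]
  }
  list(P = P, dP = dP)
}

#' Analytic EEG potentials in a multilayer sphere
#'
#' Closed-form Legendre-series solution for a current dipole inside the
#' innermost shell of a concentric isotropic multilayer sphere, evaluated at
#' electrode positions on (or outside all interfaces of) the outermost
#' shell, average-referenced. The series is written coordinate-free: with
#' `x = cos` of the angle between dipole and electrode directions the
#' degree-n angular factor is
#' `n * m_r * P_n(x) + P'_n(x) * (m . r_hat - x * m_r)`, and the radial
#' factor per layer solves the usual interface/outer-Neumann conditions with
#' per-layer scaled bases for numerical stability.
#'
#' @param spec a [sphere_spec()] (shells outer to inner).
#' @param dipole a [dipole_source()] (position mm, moment nA.m) strictly
#'   inside the innermost shell.
#' @param electrodes matrix (n x 3) of electrode positions in mm; radial
#'   distances must be >= the outermost radius minus a small tolerance (they
#'   are projected onto the outer surface).
#' @param n_terms series truncation (default 80, minimum 10); the truncation
#'   error scales like `(b / r_electrode)^n_terms`, below 1e-8 at the default
#'   for eccentricities up to 0.9 of the innermost radius.
#' @return average-referenced potentials in uV per the dipole's nA.m moment.
#' @export
eeg_sphere_potential <- function(spec, dipole, electrodes, n_terms = 80) {
  stopifnot(inherits(spec, "sphere_spec"), inherits(dipole, "dipole_source"),
            n_terms >= 10)
  radii <- rev(spec$shells$outer_radius) * 1e-3   # innermost first, metres
  sigmas <- rev(spec$shells$conductivity)
  L <- length(radii)
  pos <- (dipole$position - spec$center) * 1e-3
  mom <- dipole$moment * 1e-9
  b <- vnorm(pos)
  if (b >= radii[1])
    stopf("dipole at radius %.1f mm is not strictly inside the innermost shell (%.1f mm)",
          b * 1e3, radii[1] * 1e3)
  if (b / radii[1] > 0.95 && n_terms < 150)
    warning("high dipole eccentricity; consider increasing n_terms")
  el <- sweep(rbind(electrodes), 2, spec$center) * 1e-3
  er <- sqrt(rowSums(el^2))
  rh <- el / er
  er <- pmax(er, radii[L]) # project onto the outer surface
  zh <- if (b > 1e-12) pos / b else mom / vnorm(mom)
  x <- as.vector(rh %*% zh)
  mr <- sum(mom * zh)
  mdotr <- as.vector(rh %*% mom)
  leg <- legendre_table(n_terms, x)
  R0 <- c(0, radii) # inner radius of each layer
  V <- numeric(nrow(el))
  for (n in seq_len(n_terms)) {
    cn <- b^(n - 1) / (4 * pi * sigmas[1])
    if (L == 1) {
      AL <- (n + 1) * cn * radii[1]^(-(2 * n + 1)) / n
      rad <- AL * er^n + cn * er^(-(n + 1))
    } else {
      ## per-layer scaled bases u_j(r) = (r/R_j)^n, w_j(r) = (R_{j-1}/r)^(n+1)
      nun <- 2 * L - 1
      M <- matrix(0, nun, nun)
      rhs <- numeric(nun)
      colA <- function(j) if (j == 1) 1 else 2 * j - 2
      colB <- function(j) 2 * j - 1
      ueval <- function(j, r) (r / radii[j])^n
      dueval <- function(j, r) n / radii[j] * (r / radii[j])^(n - 1)
      weval <- function(j, r) (R0[j] / r)^(n + 1)
      dweval <- function(j, r) -(n + 1) / r * (R0[j] / r)^(n + 1)
      row <- 0
      for (j in seq_len(L - 1)) {
        R <- radii[j]
        row <- row + 1 # potential continuity
        M[row, colA(j)] <- ueval(j, R)
        if (j >= 2) M[row, colB(j)] <- weval(j, R)
        M[row, colA(j + 1)] <- -ueval(j + 1, R)
        M[row, colB(j + 1)] <- -weval(j + 1, R)
        if (j == 1) rhs[row] <- -cn * R^(-(n + 1))
        row <- row + 1 # normal current continuity
        M[row, colA(j)] <- sigmas[j] * dueval(j, R)
        if (j >= 2) M[row, colB(j)] <- sigmas[j] * dweval(j, R)
        M[row, colA(j + 1)] <- -sigmas[j + 1] * dueval(j + 1, R)
        M[row, colB(j + 1)] <- -sigmas[j + 1] * dweval(j + 1, R)
        if (j == 1) rhs[row] <- sigmas[1] * (n + 1) * cn * R^(-(n + 2))
      }
      row <- row + 1 # outer surface: no normal current
      M[row, colA(L)] <- dueval(L, radii[L])
      M[row, colB(L)] <- dweval(L, radii[L])
      sol <- solve(M, rhs)
      rad <- sol[colA(L)] * ueval(L, er) + sol[colB(L)] * weval(L, er)
    }
    ang <- n * mr * leg$P[, n + 1] + leg$dP[, n + 1] * (mdotr - x * mr)
    V <- V + rad * ang
  }
  V <- V * 1e6 # V -> uV
  V - mean(V)
}

#' Sarvas closed-form MEG field of a dipole in a conducting sphere
#'
#' Magnetic field outside a spherically symmetric conductor; independent of
#' the conductivity profile by construction, and exactly zero for radial
#' dipole moments. Supports the same coil conventions as the FEM forward
#' (magnetometers or two-coil axial gradiometer differences).
#'
#' @param center sphere centre, mm.
#' @param dipole a [dipole_source()] (moment nA.m).
#' @param sensors a `sensor_array` (MEG part used).
#' @return channel fields in fT per the dipole's nA.m moment.
#' @export
meg_sarvas <- function(center, dipole, sensors) {
  cp <- coil_points(sensors)
  r0 <- (dipole$position - center) * 1e-3
  q <- dipole$moment * 1e-9
  b <- numeric(nrow(cp$pos))
  for (i in seq_len(nrow(cp$pos))) {
    r <- (cp$pos[i, ] - center) * 1e-3
    a_vec <- r - r0
    a <- vnorm(a_vec)
    rn <- vnorm(r)
    if (rn <= vnorm(r0))
      stopf("coil %d is not outside the sphere of the dipole", i)
    FF <- a * (rn * a + rn^2 - sum(r0 * r))
    if (abs(FF) < 1e-30) stopf("coil %d sits at a field singularity (F = 0)", i)
    gF <- (a^2 / rn + sum(a_vec * r) / a + 2 * a + 2 * rn) * r -
      (a + 2 * rn + sum(a_vec * r) / a) * r0
    qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
              q[3] * r0[1] - q[1] * r0[3],
              q[1] * r0[2] - q[2] * r0[1])
    B <- 1e-7 / FF^2 * (FF * qxr0 - sum(qxr0 * r) * gF)
    b[i] <- sum(B * cp$ori[i, ])
  }
  as.vector(tapply(b * cp$pol, cp$chan, sum)) * 1e15
}

#' Topography error metrics (RDM and lnMAG)
#'
#' Relative difference measure `rdm = || a/||a|| - b/||b|| ||` (shape error,
#' in `[0, 2]`) and log magnitude ratio `lnmag = ln(||a|| / ||b||)`.
#'
#' @param a,b sensor vectors of equal length; neither may be all-zero.
#' @return list with `rdm` and `lnmag`.
#' @export
topography_error <- function(a, b) {
  if (length(a) != length(b)) stopf("topographies differ in length")
  na <- vnorm(a); nb <- vnorm(b)
  if (na == 0 || nb == 0) stopf("zero-norm topography")
  list(rdm = vnorm(a / na - b / nb), lnmag = log(na / nb))
}
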