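#' Assemble the trilinear FEM stiffness matrix
#'
#' Computes `K[a,b] = sum over elements of the integral of
#' grad(phi_a) . sigma_e grad(phi_b)` with 8-point Gauss quadrature per
#' hexahedron, using the per-element conductivity tensors. The matrix is
#' symmetric positive semidefinite with the constant vector in its null
#' space; a reference (ground) node near the volume centre is recorded and
#' used to fix the potential during solves. All quantities are converted to
#' SI internally (node coordinates metres), so potentials are volts for
#' monopole loads in amperes.
#'
#' @param mesh a `hex_mesh` with conductivity tensors assigned.
#' @return A `fem_stiffness` object: `K` (sparse dgCMatrix, SI units),
#'   `ground` (constrained node index), `n_nodes`, `volumes` (element
#'   volumes, mm^3) and an environment caching the AMG hierarchy.
#' @export
assemble_stiffness <- function(mesh) {
  stopifnot(inherits(mesh, "hex_mesh"))
  if (is.null(mesh$tensors)) stopf("mesh has no conductivity tensors; call assign_conductivities()")
  res <- cpp_assemble_stiffness(mesh$nodes * 1e-3, mesh$elements, mesh$tensors)
  n <- nrow(mesh$nodes)
  K <- sparseMatrix(i = res$i, j = res$j, x = res$x, dims = c(n, n))
  ctr <- colMeans(mesh$nodes)
  ground <- nearest_mesh_node(mesh, ctr)
  structure(list(K = K, ground = ground, n_nodes = n,
                 volumes = res$volumes * 1e9, # m^3 -> mm^3
                 cache = new.env(parent = emptyenv())),
            class = "fem_stiffness")
}

## --- algebraic multigrid (smoothed aggregation) -------------------------

## Geometric 2x2x2 aggregation on the node lattice, Jacobi-smoothed
## piecewise-constant prolongators, damped-Jacobi pre/post smoothing and a
## dense Cholesky on the coarsest level. Used as a preconditioner for CG.
amg_setup <- function(A, coords, coarse_n = 1200, omega_p = 4 / 3) {
  levels <- list()
  Acur <- A
  ccur <- coords
  repeat {
    nloc <- nrow(Acur)
    if (nloc <= coarse_n) break
    key <- (ccur[, 1] %/% 2) * 1 + (ccur[, 2] %/% 2) * 2^20 +
      (ccur[, 3] %/% 2) * 2^40
    f <- match(key, unique(key))
    nc <- max(f)
    if (nc >= nloc) break # aggregation stalled; stop coarsening
    P0 <- sparseMatrix(i = seq_len(nloc), j = f, x = 1, dims = c(nloc, nc))
    Dinv <- 1 / Matrix::diag(Acur)
    ## power-iteration estimate of lambda_max(D^-1 A) for the prolongator
    ## smoothing weight (deterministic start vector)
    v <- rep(1, nloc) + sin(seq_len(nloc))
    for (it in 1:8) {
      v <- Dinv * as.vector(Acur %*% v)
      v <- v / sqrt(sum(v^2))
    }
    lam <- sum(v * (Dinv * as.vector(Acur %*% v)))
    P <- P0 - (omega_p / lam) * (Dinv * (Acur %*% P0))
    Ac <- forceSymmetric(Matrix::t(P) %*% Acur %*% P)
    levels[[length(levels) + 1]] <- list(A = Acur, P = P, Dinv = Dinv)
    first <- which(!duplicated(f))
    ccur <- cbind(ccur[first, 1] %/% 2, ccur[first, 2] %/% 2, ccur[first, 3] %/% 2)
    Acur <- as(as(Ac, "generalMatrix"), "CsparseMatrix")
  }
  Amat <- as.matrix(Acur)
  ## tiny jitter: the projected coarse operator can be numerically
  ## semidefinite; this only perturbs the preconditioner
  diag(Amat) <- diag(Amat) + 1e-8 * mean(diag(Amat))
  levels[[length(levels) + 1]] <- list(A = Acur, R = chol(Amat))
  levels
}

amg_smooth <- function(lev, x, b, sweeps = 2, omega = 0.7) {
  for (s in seq_len(sweeps))
    x <- x + omega * lev$Dinv * (b - as.vector(lev$A %*% x))
  x
}

amg_vcycle <- function(levels, l, b) {
  lev <- levels[[l]]
  if (!is.null(lev$R))
    return(backsolve(lev$R, backsolve(lev$R, b, transpose = TRUE)))
  x <- amg_smooth(lev, numeric(length(b)), b)
  r <- b - as.vector(lev$A %*% x)
  x <- x + as.vector(lev$P %*% amg_vcycle(levels, l + 1, as.vector(Matrix::t(lev$P) %*% r)))
  amg_smooth(lev, x, b)
}

## grounded operator + AMG hierarchy, cached on the stiffness object
stiffness_solver <- function(K, node_ijk) {
  if (!is.null(K$cache$levels)) return(invisible(K))
  A <- K$K
  g <- K$ground
  ## fix the ground node: zero its row/column, unit diagonal
  A[g, ] <- 0; A[, g] <- 0; A[g, g] <- mean(Matrix::diag(A)[-g])
  A <- drop0(A)
  K$cache$Ag <- A
  K$cache$levels <- amg_setup(A, node_ijk)
  invisible(K)
}

#' Solve the FEM potential equation
#'
#' Solves `K u = rhs` for the node potentials with the conjugate-gradient
#' method preconditioned by a smoothed-aggregation algebraic-multigrid
#' V-cycle, fixing the reference node to zero and returning the mean-zero
#' solution. The right-hand side must be (numerically) orthogonal to
#' constants, i.e. its entries sum to zero, as Venant loads do.
#'
#' @param K a `fem_stiffness`.
#' @param rhs numeric or sparse vector of monopole loads (amperes).
#' @param mesh the `hex_mesh` the stiffness was assembled from (needed once
#'   to set up the multigrid hierarchy; subsequent solves reuse the cache).
#' @param tol relative residual tolerance (default 1e-9).
#' @param maxit iteration cap (default 500).
#' @return numeric vector of node potentials (volts), mean zero.
#' @export
solve_potential <- function(K, rhs, mesh = NULL, tol = 1e-9, maxit = 500) {
  stopifnot(inherits(K, "fem_stiffness"))
  rhs <- as.numeric(rhs)
  if (length(rhs) != K$n_nodes) stopf("rhs length %d != %d nodes", length(rhs), K$n_nodes)
  nb <- sqrt(sum(rhs^2))
  if (nb == 0) return(numeric(K$n_nodes))
  if (abs(sum(rhs)) > 1e-8 * nb)
    stopf("rhs is not charge-balanced (sum = %g); potentials are undefined", sum(rhs))
  if (is.null(K$cache$levels)) {
    if (is.null(mesh)) stopf("first solve needs the mesh to build the multigrid hierarchy")
    stiffness_solver(K, mesh$node_ijk)
  }
  b <- rhs
  b[K$ground] <- 0
  x <- pcg_amg(K$cache$Ag, b, K$cache$levels, tol = tol, maxit = maxit)
  x - mean(x)
}

pcg_amg <- function(A, b, levels, tol = 1e-9, maxit = 500) {
  x <- numeric(length(b))
  r <- b
  nb <- sqrt(sum(b^2))
  hist <- numeric(0)
  z <- amg_vcycle(levels, 1, r)
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / nb
    hist <- c(hist, res)
    if (res <= tol) return(x)
    z <- amg_vcycle(levels, 1, r)
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  stopf("AMG-CG did not converge in %d iterations; residual history tail: %s",
        maxit, paste(signif(tail(hist, 5), 3), collapse = ", "))
}
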