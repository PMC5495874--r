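## independent R-side quadrature oracle for the trilinear element stiffness
ref_hex_stiffness <- function(corners, sigma) {
  sgn <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  gp <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  K <- matrix(0, 8, 8)
  for (q in 1:8) {
    xi <- gp[q, ]
    dN <- t(vapply(1:8, function(a) {
      s <- sgn[a, ]
      c(s[1] * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3]),
        s[2] * (1 + s[1] * xi[1]) * (1 + s[3] * xi[3]),
        s[3] * (1 + s[1] * xi[1]) * (1 + s[2] * xi[2])) / 8
    }, numeric(3)))
    J <- t(dN) %*% corners
    G <- dN %*% solve(J)
    K <- K + (G %*% sigma %*% t(G)) * det(J)
  }
  K
}

test_that("element stiffness matches the quadrature oracle; assembly is symmetric and singular", {
  ## unit cube, identity conductivity: closed-form trilinear Laplacian
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  r <- emegfem:::cpp_assemble_stiffness(corners, matrix(1:8, 1),
                                        matrix(c(1, 0, 1, 0, 0, 1), 1))
  K <- matrix(0, 8, 8)
  K[cbind(r$i, r$j)] <- r$x
  expect_equal(K, ref_hex_stiffness(corners, diag(3)), tolerance = 1e-13)
  ## the classical values: diagonal 1/3, face/body-diagonal entries -1/12
  expect_equal(diag(K), rep(1 / 3, 8))

  ## distorted element with an anisotropic tensor still matches the oracle
  set.seed(1)
  crn2 <- corners + matrix(runif(24, -0.15, 0.15), 8, 3)
  A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  t6 <- c(A[1, 1], A[1, 2], A[2, 2], A[1, 3], A[2, 3], A[3, 3])
  r2 <- emegfem:::cpp_assemble_stiffness(crn2, matrix(1:8, 1), rbind(t6))
  K2 <- matrix(0, 8, 8)
  K2[cbind(r2$i, r2$j)] <- r2$x
  expect_equal(K2, ref_hex_stiffness(crn2, A), tolerance = 1e-12)

  ## assembled matrix: zero row sums (constants in the null space),
  ## exact symmetry, exact linearity in sigma
  m <- toy_mesh(4, 2, shift = 0.3)
  K <- assemble_stiffness(m)
  expect_lt(max(abs(Matrix::rowSums(K$K))), 1e-10)
  expect_equal(max(abs(K$K - Matrix::t(K$K))), 0)
  m2 <- m
  m2$tensors <- 3 * m$tensors
  K3 <- assemble_stiffness(m2)
  expect_equal(K3$K@x, 3 * K$K@x, tolerance = 1e-14)
})

test_that("Venant loads conserve charge exactly and reproduce the dipole moment", {
  co <- fx_get("coarse", fixture_coarse)
  set.seed(7)
  for (rep in 1:10) {
    pos <- runit() * runif(1, 5, 55)
    mom <- 30 * runit()
    dip <- dipole_source(pos, mom)
    rhs <- venant_rhs(dip, co$mesh)
    expect_lt(abs(sum(rhs)), 1e-12 * max(abs(rhs))) # charge conservation
    mo <- emegfem:::venant_moment(rhs, co$mesh, pos)
    expect_lt(sqrt(sum((mo - mom * 1e-9)^2)) / (1e-9 * sqrt(sum(mom^2))), 0.01)
  }
  expect_error(venant_rhs(dipole_source(c(500, 0, 0), c(1, 0, 0)), co$mesh),
               "outside the mesh")

  ## dipole exactly on a node, axis-aligned moment: antisymmetric loads
  m <- toy_mesh(5, 2, shift = 0)
  nd <- emegfem:::nearest_mesh_node(m, c(5, 5, 5))
  rhs <- venant_rhs(dipole_source(m$nodes[nd, ], c(1, 0, 0)), m)
  nz <- which(rhs != 0)
  offs <- sweep(m$nodes[nz, , drop = FALSE], 2, m$nodes[nd, ])
  ## mirror partner along x carries the opposite load
  for (i in seq_along(nz)) {
    mirror <- which(abs(offs[, 1] + offs[i, 1]) < 1e-9 &
                    abs(offs[, 2] - offs[i, 2]) < 1e-9 &
                    abs(offs[, 3] - offs[i, 3]) < 1e-9)
    expect_equal(rhs[nz[mirror]], -rhs[nz[i]], tolerance = 1e-9)
  }
})

test_that("the AMG-CG solve matches a dense direct solve and is gauge-safe", {
  m <- toy_mesh(5, 2, shift = 0.25)
  K <- assemble_stiffness(m)
  expect_equal(solve_potential(K, numeric(K$n_nodes), m), numeric(K$n_nodes))
  nd <- emegfem:::nearest_mesh_node(m, rbind(c(4, 4, 4), c(6, 6, 6)))
  rhs <- numeric(K$n_nodes)
  rhs[nd[1]] <- 1e-9
  rhs[nd[2]] <- -1e-9
  u <- solve_potential(K, rhs, m, tol = 1e-11)
  ## dense oracle: minimum-norm solution of the singular system
  Kd <- as.matrix(K$K)
  ud <- MASS::ginv(Kd) %*% rhs
  ud <- ud - mean(ud)
  expect_lt(max(abs(u - ud)) / max(abs(ud)), 1e-8)
  ## unbalanced rhs is rejected
  bad <- rhs
  bad[nd[2]] <- 0
  expect_error(solve_potential(K, bad, m), "charge-balanced")

  ## permutation equivariance: relabeling nodes does not change potentials
  set.seed(3)
  p <- sample(K$n_nodes)
  m2 <- m
  inv <- integer(K$n_nodes)
  inv[p] <- seq_len(K$n_nodes)
  m2$nodes <- m$nodes[p, , drop = FALSE]
  m2$node_ijk <- m$node_ijk[p, , drop = FALSE]
  m2$elements <- matrix(inv[m$elements], ncol = 8)
  m2$cache <- new.env(parent = emptyenv())
  K2 <- assemble_stiffness(m2)
  u2 <- solve_potential(K2, rhs[p], m2, tol = 1e-11)
  expect_lt(max(abs(u2[inv] - u)) / max(abs(u)), 1e-7)
})

test_that("transfer matrices reproduce direct solves; average reference behaves", {
  m <- toy_mesh(5, 3, shift = 0, sig = c(`1` = 0.3, `2` = 0.3))
  K <- assemble_stiffness(m)
  ## electrodes near the top surface, incl. one duplicated position
  sa <- structure(list(
    eeg = data.frame(name = c("a", "b", "c", "d"),
                     x = c(3, 9, 12, 3), y = c(3, 9, 3, 3), z = c(15.2, 15.2, 15.2, 15.2)),
    meg = data.frame(name = "m1", x = 7, y = 7, z = 60, ox = 0, oy = 0, oz = 1,
                     baseline = NA),
    meg_type = "magnetometer", reference = "average"), class = "sensor_array")
  te <- eeg_transfer(K, sa, m)
  ## rows sum to zero over nodes after average referencing
  expect_lt(max(abs(rowSums(te$T))), 1e-10 * max(abs(te$T)))
  ## duplicate electrode positions give identical rows
  expect_equal(te$T[1, ], te$T[4, ])
  ## transfer read-out == direct solve at the snapped electrodes
  set.seed(5)
  nd <- sample(K$n_nodes, 2)
  rhs <- numeric(K$n_nodes)
  rhs[nd[1]] <- 2e-9
  rhs[nd[2]] <- -2e-9
  u <- solve_potential(K, rhs, m, tol = 1e-11)
  v_dir <- u[te$nodes] - mean(u[te$nodes])
  v_tr <- as.vector(te$T %*% rhs)
  expect_lt(max(abs(v_tr - v_dir)), 1e-8 * max(abs(v_dir)))
  ## gauge safety: adding a constant to the potentials changes no read-out
  expect_equal(v_dir, (u[te$nodes] + 5) - mean(u[te$nodes] + 5))
  ## far-away electrode is rejected
  sa_bad <- sa
  sa_bad$eeg$z[1] <- 60
  expect_error(eeg_transfer(K, sa_bad, m), "farther than")
})

test_that("MEG forward: silent radial sources, exact linearity, gauge safety", {
  co <- fx_get("coarse", fixture_coarse)
  pos <- c(0, 0, 40)
  b_rad <- meg_forward(co$K, co$sensors, co$mesh, dipole_source(pos, c(0, 0, 25)))
  b_tan <- meg_forward(co$K, co$sensors, co$mesh, dipole_source(pos, c(25, 0, 0)))
  expect_lt(max(abs(b_rad)) / max(abs(b_tan)), 0.01)
  ## exact linearity in the moment (same solver path, scaled)
  b2 <- meg_forward(co$K, co$sensors, co$mesh, dipole_source(pos, c(50, 0, 0)),
                    tol = 1e-11)
  b1 <- meg_forward(co$K, co$sensors, co$mesh, dipole_source(pos, c(25, 0, 0)),
                    tol = 1e-11)
  expect_equal(b2, 2 * b1, tolerance = 1e-6)
  ## secondary-field weights annihilate constants (gauge safety)
  W <- co$tm$weights
  expect_lt(max(abs(rowSums(W))), 1e-12 * max(abs(W)))
  ## a coil inside the head is rejected
  sa_bad <- co$sensors
  sa_bad$meg$x[1] <- 0; sa_bad$meg$y[1] <- 0; sa_bad$meg$z[1] <- 50
  expect_error(meg_forward(co$K, sa_bad, co$mesh, dipole_source(pos, c(25, 0, 0))),
               "inside the head")
})

test_that("leadfield columns equal the venant-solve-readout path and sane units", {
  co <- fx_get("coarse", fixture_coarse)
  j <- 101
  pos <- co$src$positions[j, ]
  for (d in 1:3) {
    mom <- c(0, 0, 0); mom[d] <- 1
    dip <- dipole_source(pos, mom)
    v <- eeg_forward(co$K, co$sensors, co$mesh, dip, transfer = co$te, tol = 1e-10)
    b <- meg_forward(co$K, co$sensors, co$mesh, dip, tol = 1e-10)
    col <- co$lf$L[, 3 * (j - 1) + d]
    expect_equal(col[co$lf$modality == "eeg"], v, tolerance = 1e-5,
                 ignore_attr = TRUE)
    expect_equal(col[co$lf$modality == "meg"], b, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
  ## EEG column magnitudes in the uV range for 1 nA.m (order of magnitude)
  mx <- max(abs(co$lf$L[co$lf$modality == "eeg", ]))
  expect_gt(mx, 1e-3); expect_lt(mx, 1e2)
  ## linearity of the leadfield map
  mom <- c(1, -2, 0.5)
  b1 <- co$lf$L[, emegfem:::lf_cols(j)] %*% mom
  b2 <- co$lf$L[, emegfem:::lf_cols(j)] %*% (2 * mom)
  expect_equal(2 * as.vector(b1), as.vector(b2))
  ## EEG leadfield columns are average-referenced
  expect_lt(max(abs(colSums(co$lf$L[co$lf$modality == "eeg", ]))),
            1e-8 * max(abs(co$lf$L)))
})

test_that("forward accuracy degrades with eccentricity on average", {
  co <- fx_get("coarse", fixture_coarse)
  set.seed(11)
  rdm_at <- function(ecc, n = 3) {
    mean(vapply(seq_len(n), function(i) {
      u <- runit()
      pos <- u * ecc * 78
      dip <- dipole_source(pos, 25 * rtangential(pos))
      v <- eeg_forward(co$K, co$sensors, co$mesh, dip, transfer = co$te)
      topography_error(v, eeg_sphere_potential(co$spec, dip, co$te$positions))$rdm
    }, numeric(1)))
  }
  expect_gt(rdm_at(0.9), rdm_at(0.3))
})
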