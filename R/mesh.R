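#' Geometry-adapted hexahedral mesh from a labeled voxel grid
#'
#' Creates one hexahedral element per nonzero-label voxel, with shared nodes
#' deduplicated, then smooths staircase tissue boundaries by shifting
#' interface nodes. For every node the incident voxels (up to 8, missing
#' neighbours counting as a virtual background group) are grouped by label;
#' if the smallest group is unique, the node is moved by
#' `node_shift_factor` times the vector from the node to the centroid of
#' that minority group's voxel centres (for the background group, the
#' centres of the missing voxels). Nodes whose incident voxels are all one
#' label, and symmetric (tied) interface configurations such as flat
#' interfaces, are left on the lattice. All corner Jacobians are verified
#' positive after shifting.
#'
#' @param grid a `labeled_grid`.
#' @param node_shift_factor fraction in `[0, 0.49]`; 0 gives the regular
#'   voxel mesh. Default 0.33.
#' @return A `hex_mesh`: list with `nodes` (n x 3, mm), `elements`
#'   (m x 8 node indices in VTK corner order), `labels` (tissue label per
#'   element), `tensors` (NULL until conductivity is assigned),
#'   `node_ijk` (lattice index of each node), grid geometry fields and the
#'   per-element linear voxel index.
#' @export
build_hex_mesh <- function(grid, node_shift_factor = 0.33) {
  stopifnot(inherits(grid, "labeled_grid"),
            node_shift_factor >= 0, node_shift_factor <= 0.49)
  shp <- grid$shape
  h <- grid$voxel_size
  vox <- which(grid$labels > 0L)
  if (!length(vox)) stopf("grid has no nonzero-label voxels")
  ai <- arrayInd(vox, shp)
  np <- shp + 1L
  lin_node <- function(i, j, k) (i - 1L) + (j - 1L) * np[1] + (k - 1L) * np[1] * np[2] + 1L
  offs <- rbind(c(0L,0L,0L), c(1L,0L,0L), c(1L,1L,0L), c(0L,1L,0L),
                c(0L,0L,1L), c(1L,0L,1L), c(1L,1L,1L), c(0L,1L,1L))
  el_glob <- matrix(0L, length(vox), 8)
  for (c8 in 1:8)
    el_glob[, c8] <- lin_node(ai[, 1] + offs[c8, 1], ai[, 2] + offs[c8, 2],
                              ai[, 3] + offs[c8, 3])
  used <- sort(unique(as.vector(el_glob)))
  map <- integer(prod(np)); map[used] <- seq_along(used)
  elements <- matrix(map[el_glob], ncol = 8)
  node_ijk <- arrayInd(used, np) # 1-based lattice index
  nodes <- sweep((node_ijk - 1L) * h, 2, -grid$origin)
  labels <- grid$labels[vox]

  if (node_shift_factor > 0) {
    nn <- nrow(nodes)
    m <- nrow(elements)
    centers <- sweep((ai - 0.5) * h, 2, -grid$origin)
    labs <- sort(unique(labels))
    cnt <- matrix(0L, nn, length(labs) + 1L) # last column: virtual background
    cenx <- matrix(0, nn, 3)                 # accumulators per minority decision
    node_of <- as.vector(elements)
    elem_of <- rep(seq_len(m), times = 8)
    ## per-label incidence counts and centroid numerators
    num <- vector("list", length(labs))
    for (li in seq_along(labs)) {
      sel <- labels[elem_of] == labs[li]
      I <- sparseMatrix(i = node_of[sel], j = elem_of[sel], x = 1,
                        dims = c(nn, m))
      cnt[, li] <- as.integer(Matrix::rowSums(I))
      num[[li]] <- as.matrix(I %*% centers)
    }
    inc <- rowSums(cnt[, seq_along(labs), drop = FALSE])
    cnt[, length(labs) + 1L] <- 8L - inc
    ## background centroid: the 8 potential incident voxel centres of a node
    ## average to the node itself, so missing-centre centroid falls out of the
    ## present-centre sum
    pres_num <- Reduce(`+`, num)
    ngroups <- rowSums(cnt > 0L)
    cand <- which(ngroups >= 2L)
    if (length(cand)) {
      cc <- cnt[cand, , drop = FALSE]
      cc[cc == 0L] <- 99L
      mn <- apply(cc, 1, min)
      nmin <- rowSums(cc == mn)
      move <- nmin == 1L
      cand <- cand[move]
      if (length(cand)) {
        gi <- apply(cc[move, , drop = FALSE], 1, which.min)
        target <- matrix(0, length(cand), 3)
        for (li in seq_along(labs)) {
          sel <- gi == li
          if (any(sel))
            target[sel, ] <- num[[li]][cand[sel], , drop = FALSE] /
              cnt[cand[sel], li]
        }
        bg <- gi == length(labs) + 1L
        if (any(bg)) {
          nb <- cnt[cand[bg], length(labs) + 1L]
          target[bg, ] <- (8 * nodes[cand[bg], , drop = FALSE] -
                             pres_num[cand[bg], , drop = FALSE]) / nb
        }
        nodes[cand, ] <- nodes[cand, , drop = FALSE] +
          node_shift_factor * (target - nodes[cand, , drop = FALSE])
      }
    }
    jac <- cpp_corner_jacobians(nodes, elements)
    if (any(jac <= 0))
      stopf("node shifting produced a non-positive Jacobian in element %d",
            which(apply(jac <= 0, 1, any))[1])
  }

  structure(list(nodes = nodes, elements = elements, labels = labels,
                 tensors = NULL, node_ijk = node_ijk,
                 voxel_index = vox, grid_shape = shp, voxel_size = h,
                 origin = grid$origin, label_table = grid$label_table,
                 shift_factor = node_shift_factor,
                 cache = new.env(parent = emptyenv())),
            class = "hex_mesh")
}

#' Assign isotropic conductivities to mesh elements
#'
#' @param mesh a `hex_mesh`.
#' @param table either a named numeric vector mapping tissue label (as
#'   character) to conductivity in S/m, or a named vector keyed by tissue
#'   name matching the mesh's label table.
#' @return The mesh with `tensors` set (m x 6 packed symmetric tensors,
#'   sigma times identity per element).
#' @export
assign_conductivities <- function(mesh, table) {
  stopifnot(inherits(mesh, "hex_mesh"))
  if (any(table <= 0)) stopf("conductivities must be > 0")
  key <- as.character(mesh$labels)
  if (!all(unique(key) %in% names(table))) {
    ## allow tissue-name keyed tables
    byname <- mesh$label_table[key]
    if (all(unique(byname) %in% names(table))) key <- byname
  }
  missing <- setdiff(unique(key), names(table))
  if (length(missing))
    stopf("no conductivity for label(s): %s", paste(missing, collapse = ", "))
  sig <- as.numeric(table[key])
  tens <- matrix(0, nrow(mesh$elements), 6)
  tens[, c(1, 3, 6)] <- sig
  mesh$tensors <- tens
  mesh
}

## 3x3 symmetric eigen-decomposition helpers on packed (xx,xy,yy,xz,yz,zz)
unpack6 <- function(t6) matrix(c(t6[1], t6[2], t6[4],
                                 t6[2], t6[3], t6[5],
                                 t6[4], t6[5], t6[6]), 3, 3)
pack6 <- function(M) c(M[1, 1], M[1, 2], M[2, 2], M[1, 3], M[2, 3], M[3, 3])

#' Map diffusion tensors to white-matter conductivity tensors
#'
#' Effective-medium conversion: each white-matter element's conductivity
#' tensor shares the eigenvectors of the local diffusion tensor. In the
#' default `"volume"` mode the eigenvalues are scaled by a common factor so
#' the tensor volume (eigenvalue product) equals `iso_reference^3`,
#' preserving the diffusion eigenvalue ratios; `"linear"` mode scales the
#' diffusion tensor so its mean diffusivity maps to `iso_reference`.
#' Non-positive diffusion eigenvalues are clamped to a small fraction of the
#' largest eigenvalue with a warning. Non-WM elements are untouched.
#'
#' The diffusion tensor of an element is the arithmetic mean of the tensors
#' at the 8 voxel centres enclosing the element centre; when the tensor grid
#' coincides with the mesh grid this reduces to the element's own voxel.
#'
#' @param mesh a `hex_mesh` with conductivity tensors already assigned.
#' @param dti a `tensor_field` with `kind == "diffusion"`.
#' @param wm_label white-matter tissue label in the mesh.
#' @param iso_reference isotropic reference conductivity in S/m
#'   (default 0.14).
#' @param mode `"volume"` (volume-normalized) or `"linear"`.
#' @return The mesh with anisotropic white-matter tensors.
#' @export
map_dti_conductivity <- function(mesh, dti, wm_label, iso_reference = 0.14,
                                 mode = c("volume", "linear")) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(dti, "tensor_field"))
  mode <- match.arg(mode)
  if (dti$kind != "diffusion") stopf("tensor field must have kind 'diffusion'")
  if (iso_reference <= 0) stopf("iso_reference must be > 0")
  if (is.null(mesh$tensors)) stopf("assign conductivities before mapping DTI")
  wm <- which(mesh$labels == wm_label)
  if (!length(wm)) return(mesh)

  tmat <- matrix(dti$tensors, ncol = 6)
  same_grid <- identical(dti$shape, mesh$grid_shape) &&
    isTRUE(all.equal(dti$voxel_size, mesh$voxel_size)) &&
    isTRUE(all.equal(dti$origin, mesh$origin))
  getD <- function(e) {
    if (same_grid) return(tmat[mesh$voxel_index[e], ])
    ctr <- colMeans(mesh$nodes[mesh$elements[e, ], , drop = FALSE])
    q <- (ctr - dti$origin) / dti$voxel_size - 0.5
    base <- pmin(pmax(floor(q), 0), dti$shape - 2)
    acc <- numeric(6); n <- 0L
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      idx <- base + c(dx, dy, dz) + 1
      lin <- (idx[1] - 1) + (idx[2] - 1) * dti$shape[1] +
        (idx[3] - 1) * dti$shape[1] * dti$shape[2] + 1
      acc <- acc + tmat[lin, ]; n <- n + 1L
    }
    acc / n
  }
  clamped <- 0L
  for (e in wm) {
    D <- unpack6(getD(e))
    ed <- eigen(D, symmetric = TRUE)
    lam <- ed$values
    lmax <- max(lam)
    if (lmax <= 0) { lam <- rep(1, 3); lmax <- 1; clamped <- clamped + 1L }
    floorv <- 1e-3 * lmax
    if (any(lam < floorv)) { lam <- pmax(lam, floorv); clamped <- clamped + 1L }
    slam <- switch(mode,
      volume = lam * (iso_reference^3 / prod(lam))^(1 / 3),
      linear = lam * iso_reference / mean(lam))
    S <- ed$vectors %*% diag(slam) %*% t(ed$vectors)
    mesh$tensors[e, ] <- pack6(S)
  }
  if (clamped)
    warning(sprintf("clamped non-positive-definite diffusion tensors in %d element(s)", clamped))
  mesh
}

## nearest mesh node to each query point (mm). Uses the lattice structure:
## shifted nodes stay within half a voxel of their lattice site, so the true
## nearest node is among the 27 lattice neighbours of the rounded site.
nearest_mesh_node <- function(mesh, pts) {
  pts <- rbind(pts)
  np <- mesh$grid_shape + 1L
  lat <- mesh$cache$node_lattice
  if (is.null(lat)) {
    lat <- integer(prod(np))
    lin <- (mesh$node_ijk[, 1] - 1L) + (mesh$node_ijk[, 2] - 1L) * np[1] +
      (mesh$node_ijk[, 3] - 1L) * np[1] * np[2] + 1L
    lat[lin] <- seq_len(nrow(mesh$nodes))
    if (!is.null(mesh$cache)) mesh$cache$node_lattice <- lat
  }
  out <- integer(nrow(pts))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (p in seq_len(nrow(pts))) {
    q <- round((pts[p, ] - mesh$origin) / mesh$voxel_size) + 1
    best <- NA_integer_; bestd <- Inf
    for (o in seq_len(nrow(offs))) {
      ijk <- q + offs[o, ]
      if (any(ijk < 1) || any(ijk > np)) next
      id <- lat[(ijk[1] - 1) + (ijk[2] - 1) * np[1] + (ijk[3] - 1) * np[1] * np[2] + 1]
      if (id == 0L) next
      d <- sum((mesh$nodes[id, ] - pts[p, ])^2)
      if (d < bestd) { bestd <- d; best <- id }
    }
    if (is.na(best)) {
      ## far from the lattice neighbourhood: fall back to brute force
      d <- rowSums(sweep(mesh$nodes, 2, pts[p, ])^2)
      best <- which.min(d)
    }
    out[p] <- best
  }
  out
}

## node -> incident element incidence (nodes x elements), cached on the mesh
node_elem_incidence <- function(mesh) {
  inc <- mesh$cache$inc
  if (is.null(inc)) {
    inc <- sparseMatrix(i = as.vector(mesh$elements),
                        j = rep(seq_len(nrow(mesh$elements)), times = 8),
                        x = 1, dims = c(nrow(mesh$nodes), nrow(mesh$elements)))
    if (!is.null(mesh$cache)) mesh$cache$inc <- inc
  }
  inc
}

## transposed incidence (elements x nodes) for fast per-node element lookup
node_elem_incidence_t <- function(mesh) {
  inct <- mesh$cache$inc_t
  if (is.null(inct)) {
    inct <- Matrix::t(node_elem_incidence(mesh))
    if (!is.null(mesh$cache)) mesh$cache$inc_t <- inct
  }
  inct
}

#' Build a Venant-admissible source space inside gray matter
#'
#' Candidate positions lie on a regular axis-aligned grid of the requested
#' spacing, seeded at the centroid of the gray-matter compartment and
#' restricted to points inside GM-labeled elements. A candidate is admitted
#' only if it satisfies the Venant admissibility condition: in the default
#' `"node_neighborhood"` mode every element containing the FE node nearest
#' to the candidate must be GM-labeled (the strict variant); in
#' `"element_only"` mode only the element containing the candidate must be
#' GM.
#'
#' @param mesh a `hex_mesh`.
#' @param gm_label gray-matter tissue label.
#' @param spacing source grid spacing in mm (>= voxel size).
#' @param mode admissibility variant, see above.
#' @return A `source_space`: list with `positions` (k x 3 mm),
#'   `nearest_node` (FE node index per position), `spacing` and a content
#'   `hash` identifying the space.
#' @export
build_source_space <- function(mesh, gm_label, spacing,
                               mode = c("node_neighborhood", "element_only")) {
  stopifnot(inherits(mesh, "hex_mesh"), spacing >= mesh$voxel_size)
  mode <- match.arg(mode)
  gm <- mesh$labels == gm_label
  if (!any(gm)) stopf("no elements carry the gray-matter label %s", gm_label)
  gm_centers <- sweep((arrayInd(mesh$voxel_index[gm], mesh$grid_shape) - 0.5) *
                        mesh$voxel_size, 2, -mesh$origin)
  ctr <- colMeans(gm_centers)
  lo <- apply(gm_centers, 2, min); hi <- apply(gm_centers, 2, max)
  axes <- lapply(1:3, function(d) {
    k <- c(rev(seq(ctr[d], lo[d] - spacing, by = -spacing)),
           seq(ctr[d] + spacing, hi[d] + spacing, by = spacing))
    k
  })
  cand <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  colnames(cand) <- NULL
  ## keep candidates whose containing voxel is a GM element
  vi <- floor(sweep(cand, 2, mesh$origin) / mesh$voxel_size) + 1
  ok <- vi[, 1] >= 1 & vi[, 2] >= 1 & vi[, 3] >= 1 &
    vi[, 1] <= mesh$grid_shape[1] & vi[, 2] <= mesh$grid_shape[2] &
    vi[, 3] <= mesh$grid_shape[3]
  lin <- (vi[, 1] - 1) + (vi[, 2] - 1) * mesh$grid_shape[1] +
    (vi[, 3] - 1) * mesh$grid_shape[1] * mesh$grid_shape[2] + 1
  lab_of_vox <- integer(prod(mesh$grid_shape))
  lab_of_vox[mesh$voxel_index] <- mesh$labels
  ok[ok] <- lab_of_vox[lin[ok]] == gm_label
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) stopf("no source candidates inside GM; use a thicker GM compartment")
  nn <- nearest_mesh_node(mesh, cand)
  if (mode == "node_neighborhood") {
    inc <- node_elem_incidence(mesh)
    ## a node is admissible iff all incident elements are GM
    bad_count <- as.vector(inc %*% as.numeric(!gm))
    keep <- bad_count[nn] == 0
  } else {
    keep <- rep(TRUE, nrow(cand))
  }
  cand <- cand[keep, , drop = FALSE]
  nn <- nn[keep]
  if (!nrow(cand)) stopf("no Venant-admissible source positions; use a thicker GM compartment")
  ss <- structure(list(positions = cand, nearest_node = nn, spacing = spacing,
                       mode = mode),
                  class = "source_space")
  ss$hash <- object_hash(list(cand, spacing))
  ss
}

#' Per-element volumes of a hexahedral mesh (mm^3)
#' @param mesh a `hex_mesh`.
#' @return numeric vector of element volumes.
#' @export
element_volumes <- function(mesh) {
  tens <- mesh$tensors %||% matrix(rep(c(1, 0, 1, 0, 0, 1), each = nrow(mesh$elements)), ncol = 6)
  res <- cpp_assemble_stiffness(mesh$nodes, mesh$elements, tens)
  res$volumes
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat("Hexahedral FE mesh:", nrow(x$nodes), "nodes,", nrow(x$elements),
      "elements @", x$voxel_size, "mm (shift factor", x$shift_factor, ")\n")
  cat("  tissues:", paste(sprintf("%s=%d", x$label_table[as.character(sort(unique(x$labels)))],
                                  tabulate(match(x$labels, sort(unique(x$labels))))), collapse = ", "), "\n")
  cat("  conductivity tensors:", if (is.null(x$tensors)) "not assigned" else "assigned", "\n")
  invisible(x)
}

#' @export
print.source_space <- function(x, ...) {
  cat("Source space:", nrow(x$positions), "positions @", x$spacing,
      "mm spacing (", x$mode, ")\n")
  invisible(x)
}
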