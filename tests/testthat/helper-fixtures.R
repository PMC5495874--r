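## Shared fixtures, built once per test run and memoised. All fixtures are
## generated in code from fixed seeds; nothing is read from disk.

fx <- new.env()

fx_get <- function(name, builder) {
  if (is.null(fx[[name]])) fx[[name]] <- builder()
  fx[[name]]
}

## small two-label block grid for mesh/FEM unit tests
toy_grid <- function(n = 4, voxel = 2) {
  lab <- array(1L, dim = c(n, n, n))
  lab[, , (n %/% 2 + 1):n] <- 2L
  structure(list(shape = rep(n, 3L), voxel_size = voxel,
                 origin = c(0, 0, 0), labels = lab,
                 label_table = c(`1` = "a", `2` = "b")),
            class = "labeled_grid")
}

toy_mesh <- function(n = 4, voxel = 2, shift = 0, sig = c(`1` = 1, `2` = 2)) {
  assign_conductivities(build_hex_mesh(toy_grid(n, voxel), shift), sig)
}

## 4-shell sphere phantom at the tabulated tissue conductivities, 4 mm mesh
fixture_coarse <- function() {
  spec <- sphere_spec() # radii 92/86/80/78, sigma 0.43/0.0033/1.79/0.33
  grid <- voxelize_sphere_model(spec, 4, c(50, 50, 50))
  sensors <- make_sensor_array(spec, 40, 48, meg_standoff = 30,
                               meg_type = "magnetometer")
  tab <- spec$shells$conductivity
  names(tab) <- as.character(spec$shells$label)
  mesh <- assign_conductivities(build_hex_mesh(grid), tab)
  K <- assemble_stiffness(mesh)
  te <- eeg_transfer(K, sensors, mesh)
  tm <- meg_transfer(K, sensors, mesh)
  src <- build_source_space(mesh, 4, 8)
  lf <- compute_leadfields(te, tm, src, mesh)
  list(spec = spec, grid = grid, sensors = sensors, mesh = mesh, K = K,
       te = te, tm = tm, src = src, lf = lf)
}

## thicker-skull 4-shell phantom for inverse / calibration workloads (the
## skull band stays contiguous at 5 mm voxels)
fixture_inverse <- function() {
  spec <- sphere_spec(radii = c(92, 84, 72, 66))
  grid <- voxelize_sphere_model(spec, 5, c(40, 40, 40))
  sensors <- make_sensor_array(spec, 32, 48, meg_standoff = 25,
                               meg_type = "magnetometer")
  tab <- spec$shells$conductivity
  names(tab) <- as.character(spec$shells$label)
  mesh <- assign_conductivities(build_hex_mesh(grid), tab)
  K <- assemble_stiffness(mesh)
  src <- build_source_space(mesh, 4, 10)
  te <- eeg_transfer(K, sensors, mesh)
  tm <- meg_transfer(K, sensors, mesh)
  lf <- compute_leadfields(te, tm, src, mesh)
  list(spec = spec, sensors = sensors, mesh = mesh, K = K, src = src,
       te = te, tm = tm, lf = lf, lfe = subset_leadfield(lf, "eeg"),
       lfm = subset_leadfield(lf, "meg"), tab = tab)
}

## calibration bundle on the inverse phantom: memoised leadfield factory
## over the default 12-candidate grid plus truth leadfields
fixture_calibration <- function() {
  inv <- fx_get("inverse", fixture_inverse)
  grid <- calibration_grid()
  fac <- make_leadfield_factory(inv$mesh, inv$sensors, inv$src, inv$tab,
                                compacta_key = "2")
  truth_idx <- 6L
  truth <- grid$compacta_values[truth_idx]
  lft <- fac(truth, truth * grid$spongiosa_ratio)
  joint <- leadfield_set(rbind(lft$eeg$L, lft$meg$L),
                         c(lft$eeg$modality, lft$meg$modality),
                         c(lft$eeg$channel_names, lft$meg$channel_names),
                         inv$src)
  list(grid = grid, factory = fac, truth = truth, truth_idx = truth_idx,
       lft = lft, joint = joint, inv = inv)
}

## 2 mm 4-shell phantom at the tabulated conductivities (forward-oracle and
## Venant acceptance workloads)
fixture_fine <- function() {
  spec <- sphere_spec()
  grid <- voxelize_sphere_model(spec, 2, c(96, 96, 96))
  sensors <- make_sensor_array(spec, 80, 64, meg_standoff = 30,
                               meg_type = "magnetometer")
  tab <- spec$shells$conductivity
  names(tab) <- as.character(spec$shells$label)
  mesh <- assign_conductivities(build_hex_mesh(grid), tab)
  list(spec = spec, grid = grid, sensors = sensors, mesh = mesh, tab = tab)
}

split_evoked <- function(ev, modality) {
  sel <- ev$channel_meta$modality == modality
  evoked_data(ev$data[sel, , drop = FALSE], ev$channel_meta[sel, ],
              ev$sampling_rate, ev$time_zero)
}

nearest_source <- function(src, p) which.min(rowSums(sweep(src$positions, 2, p)^2))

loc_error <- function(src, est, true_node) {
  sqrt(sum((src$positions[which.max(est$f), ] - src$positions[true_node, ])^2))
}

## random unit vector / tangential unit vector at a position
runit <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }
rtangential <- function(pos) {
  u <- pos / sqrt(sum(pos^2))
  t1 <- c(-u[2], u[1], 0)
  if (sqrt(sum(t1^2)) < 1e-6) t1 <- c(1, 0, 0)
  t1 / sqrt(sum(t1^2))
}
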