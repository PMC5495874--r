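test_that("spike averaging: identity on one trial, sqrt(n) noise reduction", {
  inv <- fx_get("inverse", fixture_inverse)
  on <- dipole_source(inv$src$positions[60, ], c(30, 20, 30))
  pk <- dipole_source(inv$src$positions[700, ], c(20, -35, 25))
  cfg <- spike_sim_config(on, pk, snr_eeg = 1e9, snr_meg = 1e9, n_trials = 1, seed = 2)
  tr <- simulate_ied_recordings(inv$lf, cfg)
  ev <- average_spikes(tr, window = c(-100, 80))
  s0 <- tr$event_latency[1] - 100
  expect_equal(ev$data, tr$data[, s0:(s0 + 180), 1])
  ## n identical (noiseless) trials: average equals one trial
  cfg5 <- spike_sim_config(on, pk, snr_eeg = 1e9, snr_meg = 1e9, n_trials = 5, seed = 2)
  tr5 <- simulate_ied_recordings(inv$lf, cfg5)
  ev5 <- average_spikes(tr5, window = c(-100, 80))
  expect_equal(ev5$data, tr5$data[, s0:(s0 + 180), 1], tolerance = 1e-6)
  ## baseline noise of the average shrinks like 1/sqrt(n) (Monte-Carlo)
  rat <- vapply(1:15, function(sd) {
    cfgn <- spike_sim_config(on, pk, snr_eeg = 2, snr_meg = 2, n_trials = 9, seed = sd)
    trn <- simulate_ied_recordings(inv$lf, cfgn)
    evn <- average_spikes(trn)
    mean(evn$channel_meta$noise_std / trn$channel_meta$noise_std) * 3
  }, numeric(1))
  expect_lt(abs(mean(rat) - 1), 0.2)
  ## window exceeding the trial bounds errors
  expect_error(average_spikes(tr, window = c(-400, 100)), "bounds")
})

test_that("EMEG combination whitens both modalities onto a common scale", {
  inv <- fx_get("inverse", fixture_inverse)
  on <- dipole_source(inv$src$positions[60, ], c(30, 20, 30))
  pk <- dipole_source(inv$src$positions[700, ], c(20, -35, 25))
  cfg <- spike_sim_config(on, pk, seed = 3)
  ev <- average_spikes(simulate_ied_recordings(inv$lf, cfg))
  jt <- combine_emeg(split_evoked(ev, "eeg"), split_evoked(ev, "meg"),
                     inv$lfe, inv$lfm)
  ## whitened baseline variance ~ 1 per channel
  base <- jt$evoked$data[, 1:60]
  expect_lt(abs(mean(apply(base, 1, sd)) - 1), 0.25)
  expect_equal(nrow(jt$leadfield$L), nrow(inv$lf$L))
  expect_equal(jt$leadfield$modality, c(inv$lfe$modality, inv$lfm$modality))
  ## combining a modality with itself duplicates rows exactly
  ee <- split_evoked(ev, "eeg")
  same <- combine_emeg(ee, NULL, inv$lfe, NULL)
  dup <- rbind(same$leadfield$L, same$leadfield$L)
  two <- combine_emeg(ee, ee, inv$lfe, inv$lfe)
  ## (meg slot used for the second eeg copy)
  expect_equal(unname(two$leadfield$L), unname(dup))
  ## mismatched source spaces are rejected
  other <- inv$lfm
  other$source_space <- inv$src
  other$source_space$hash <- "different"
  expect_error(combine_emeg(ee, split_evoked(ev, "meg"), inv$lfe, other),
               "source spaces")
})

test_that("sLORETA localizes noiseless single sources exactly and is scale invariant", {
  inv <- fx_get("inverse", fixture_inverse)
  cfg0 <- inverse_config(lambda = 1e-10)
  set.seed(8)
  for (rep in 1:10) {
    j <- sample(nrow(inv$src$positions), 1)
    mom <- rnorm(3)
    b <- as.vector(inv$lf$L[, emegfem:::lf_cols(j)] %*% mom)
    est <- sloreta(inv$lf, b, cfg0)
    expect_identical(which.max(est$f), j)
    ## F invariant under positive rescaling of the topography
    est2 <- sloreta(inv$lf, 7.3 * b, cfg0)
    expect_equal(est2$f, 7.3^2 * est$f, tolerance = 1e-9)
    expect_identical(which.max(est2$f), j)
  }
  expect_true(all(sloreta(inv$lf, b, cfg0)$f >= 0))
})

test_that("two well-separated sources are recovered at their own latencies", {
  inv <- fx_get("inverse", fixture_inverse)
  j1 <- nearest_source(inv$src, c(-35, 10, 20))
  j2 <- nearest_source(inv$src, c(35, -10, 20))
  expect_gt(sqrt(sum((inv$src$positions[j1, ] - inv$src$positions[j2, ])^2)), 40)
  on <- dipole_source(inv$src$positions[j1, ], c(30, 20, 30))
  pk <- dipole_source(inv$src$positions[j2, ], c(20, -35, 25))
  cfg <- spike_sim_config(on, pk, snr_eeg = 1e9, snr_meg = 1e9, n_trials = 1, seed = 4)
  ev <- average_spikes(simulate_ied_recordings(inv$lf, cfg))
  icfg <- inverse_config(lambda = 1e-8)
  e23 <- sloreta(inv$lf, evoked_topography(ev, -23), icfg, latency = -23)
  e0 <- sloreta(inv$lf, evoked_topography(ev, 0), icfg, latency = 0)
  expect_identical(which.max(e23$f), j1)
  expect_identical(which.max(e0$f), j2)
})

test_that("thresholded clustering groups supra-threshold nodes by adjacency", {
  inv <- fx_get("inverse", fixture_inverse)
  icfg <- inverse_config()
  ## all-equal F: one cluster containing every node
  est <- structure(list(f = rep(1, nrow(inv$src$positions)), latency = 0,
                        modality_set = "EMEG", source_space = inv$src),
                   class = "source_estimate")
  cl <- threshold_clusters(est, icfg)
  expect_length(cl$clusters, 1)
  expect_length(cl$clusters[[1]]$nodes, nrow(inv$src$positions))
  ## single noiseless source: one cluster containing the true node (no
  ## minimum size: a noiseless peak can be sharper than 5 nodes at this
  ## source spacing)
  icfg <- inverse_config(min_cluster_size = 1)
  j <- 321
  b <- as.vector(inv$lf$L[, emegfem:::lf_cols(j)] %*% c(1, 2, -1))
  est1 <- threshold_clusters(sloreta(inv$lf, b, inverse_config(lambda = 1e-10)), icfg)
  expect_gte(length(est1$clusters), 1)
  expect_true(j %in% est1$clusters[[1]]$nodes)
  ## clusters are disjoint and sorted by peak F
  if (length(est1$clusters) > 1) {
    allnodes <- unlist(lapply(est1$clusters, `[[`, "nodes"))
    expect_equal(anyDuplicated(allnodes), 0)
    pf <- vapply(est1$clusters, `[[`, numeric(1), "peak_f")
    expect_true(all(diff(pf) <= 0))
  }
})

test_that("ROI cuboids have the default extents and contain compact clusters", {
  b <- roi_box(c(0, 0, 0))
  expect_equal(b$extents, c(160, 82, 28))
  expect_equal(b$lo, c(-80, -41, -14))
  expect_equal(b$hi, c(80, 41, 14))
  expect_error(roi_box(c(0, 0, 0), c(-1, 1, 1)))
  ## containment of a compact simulated cluster around its peak
  inv <- fx_get("inverse", fixture_inverse)
  j <- 400
  bb <- as.vector(inv$lf$L[, emegfem:::lf_cols(j)] %*% c(2, 1, 1))
  est <- threshold_clusters(sloreta(inv$lf, bb, inverse_config(lambda = 1e-10)),
                            inverse_config(min_cluster_size = 1))
  cl <- est$clusters[[1]]
  box <- roi_box(cl$peak_position)
  pos <- inv$src$positions[cl$nodes, , drop = FALSE]
  dia <- max(dist(pos))
  if (dia < min(box$extents))
    expect_true(all(t(pos) >= box$lo) && all(t(pos) <= box$hi))
})

test_that("dipole-scan residual variance is a proper goal map", {
  inv <- fx_get("inverse", fixture_inverse)
  j <- 222
  b <- as.vector(inv$lf$L[, emegfem:::lf_cols(j)] %*% c(1, -1, 2))
  rv <- dipole_scan_goal(inv$lf, b)
  expect_true(all(rv >= 0 & rv <= 1))
  expect_lt(rv[j], 1e-12)
  expect_identical(which.min(rv), as.integer(j))
  ## RV minimum coincides with the sLORETA argmax for a noiseless source
  est <- sloreta(inv$lf, b, inverse_config(lambda = 1e-10))
  expect_identical(which.min(rv), which.max(est$f))
  ## RV invariant to data rescaling
  expect_equal(dipole_scan_goal(inv$lf, 3 * b), rv, tolerance = 1e-10)
})

test_that("localization degrades monotonically as SNR drops", {
  inv <- fx_get("inverse", fixture_inverse)
  j <- nearest_source(inv$src, c(-32, 12, 16))
  set.seed(21)
  snrs <- c(20, 10, 5, 2, 1)
  med <- vapply(snrs, function(snr) {
    errs <- vapply(1:40, function(i) {
      m <- 30 * runit()
      cl <- as.vector(inv$lfe$L[, emegfem:::lf_cols(j)] %*% m)
      std <- max(abs(cl)) / snr
      ## whiten to unit noise variance so the SNR-derived lambda rule applies
      Lw <- leadfield_set(inv$lfe$L / std, inv$lfe$modality,
                          inv$lfe$channel_names, inv$src)
      b <- cl / std + rnorm(length(cl))
      best <- sloreta(Lw, b, inverse_config())
      loc_error(inv$src, best, j)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  ## non-decreasing within a small slack for Monte-Carlo jitter
  expect_true(all(diff(med) >= -inv$src$spacing / 2))
  expect_gt(med[5], med[1])
})
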