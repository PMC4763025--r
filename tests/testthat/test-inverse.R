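test_that("the unregularized inverse localizes every noiseless point source exactly", {
  lf <- fx_leadfield()
  op <- compute_inverse(lf, alpha = 0)
  expect_true(op$report$converged)
  for (v in seq_len(nrow(lf$voxels))) {
    pat <- as.numeric(lf$gain[, (3 * v - 2):(3 * v)] %*% c(0.3, -0.5, 0.8))
    loc <- localize_pattern(op, pat)
    expect_equal(which.max(loc$power), v)
  }
})

test_that("an exactly determined one-voxel problem reproduces least squares", {
  set.seed(5)
  K <- qr.Q(qr(matrix(rnorm(19 * 3), 19)))      # orthonormal columns
  H <- diag(19) - 1 / 19
  lf <- structure(list(
    gain = H %*% K, channels = paste0("E", 1:19),
    voxels = tibble::tibble(id = "v001", roi = "frontal", hemisphere = "left",
                            x = 0, y = 0, z = 0, brodmann = 9,
                            ox = 1, oy = 0, oz = 0),
    seed = 1L
  ), class = "eeg_leadfield")
  op <- compute_inverse(lf, alpha = 0)
  b <- c(1.2, -0.4, 2)
  x <- lf$gain %*% b
  expect_equal(as.numeric(lf$gain %*% (op$M %*% x)), as.numeric(x), tolerance = 1e-8)
})

test_that("the weight iteration is a fixed point once converged", {
  lf <- fx_leadfield()
  op <- fx_inverse(alpha = 0.05)
  op2 <- compute_inverse(lf, alpha = 0.05, init_weights = op$weights)
  expect_lte(op2$report$iterations, 1)
  expect_true(op2$report$converged)
})

test_that("source spectra are reference-invariant and quadratic in the data", {
  lf <- fx_leadfield()
  op <- fx_inverse()
  set.seed(6)
  a <- array(rnorm(19 * 256 * 5, sd = 5), dim = c(19, 256, 5))
  es <- epochs_from_array(a, 128)
  es$labels <- lf$channels
  ss <- apply_inverse(op, es)

  es_off <- es; es_off$epochs <- es_off$epochs + 42   # common offset
  expect_equal(apply_inverse(op, es_off)$values, ss$values, tolerance = 1e-8)

  es_sc <- es; es_sc$epochs <- 2 * es_sc$epochs
  expect_equal(apply_inverse(op, es_sc)$values, 4 * ss$values)

  es_zero <- es; es_zero$epochs[] <- 0
  expect_true(all(apply_inverse(op, es_zero)$values == 0))

  es_bad <- es; es_bad$labels[1] <- "XX"
  expect_error(apply_inverse(op, es_bad), "Fp1")
})

test_that("a simulated 10 Hz point source maximizes alpha1 current density at its voxel", {
  lf <- fx_leadfield()
  op <- fx_inverse(alpha = 0)
  v <- which(lf$voxels$roi == "parietal" & lf$voxels$hemisphere == "left")[1]
  fs <- 128; t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  src <- sin(2 * pi * 10 * t)
  pat <- as.numeric(lf$gain[, (3 * v - 2):(3 * v)] %*% c(0.2, 0.9, -0.4))
  X <- outer(pat, src)
  rec <- new_recording(X, fs, lf$channels)
  es <- segment_epochs(rereference_common_average(rec))
  ss <- apply_inverse(op, es)
  a1 <- rowMeans(ss$values[, ss$freqs >= 8 & ss$freqs <= 10.5])
  expect_equal(unname(which.max(a1)), v)
})

test_that("grand-mean normalization is exact, idempotent and scale-free", {
  lf <- fx_leadfield()
  freqs <- seq(0, 64, by = 0.5)
  set.seed(7)
  vals <- matrix(rexp(12 * length(freqs)), 12)
  ss <- eegmarkers:::new_source_spectra(vals, freqs, lf$voxels, n_epochs = 10)
  nn <- normalize_current_density(ss)
  rng <- freqs >= 0.5 & freqs <= 45
  expect_equal(mean(nn$values[, rng]), 1, tolerance = 1e-9)
  expect_equal(normalize_current_density(nn)$values, nn$values)
  ss_sc <- ss; ss_sc$values <- 13 * ss_sc$values
  expect_equal(normalize_current_density(ss_sc)$values, nn$values)

  const <- ss; const$values[] <- 7
  expect_true(all(normalize_current_density(const)$values == 1))

  bad <- ss; bad$values[] <- 0
  expect_error(normalize_current_density(bad), "degenerate")
})

test_that("ROI aggregation averages voxels and band bins", {
  lf <- make_toy_leadfield(19, 2, seed = 1)
  freqs <- seq(0, 64, by = 0.5)
  vals <- matrix(1, nrow(lf$voxels), length(freqs))
  ss <- eegmarkers:::new_source_spectra(vals, freqs, lf$voxels, 1)
  tab <- aggregate_roi(ss)
  expect_equal(nrow(tab), 42)
  expect_true(all(tab$value == 1))

  # an ROI whose voxels hold band values {2, 4} averages to 3
  occ <- lf$voxels$roi == "occipital"
  vals2 <- vals
  vals2[occ, ] <- rep(c(2, 4), length.out = sum(occ))
  tab2 <- aggregate_roi(eegmarkers:::new_source_spectra(vals2, freqs, lf$voxels, 1))
  expect_true(all(tab2$value[tab2$roi == "occipital"] == 3))

  vox_missing <- lf$voxels[lf$voxels$roi != "limbic", ]
  ss_missing <- eegmarkers:::new_source_spectra(vals[lf$voxels$roi != "limbic", ],
                                                freqs, vox_missing, 1)
  expect_error(aggregate_roi(ss_missing), "limbic")
})

test_that("permuting voxel order permutes the source estimates correspondingly", {
  lf <- fx_leadfield()
  set.seed(8)
  perm <- sample(nrow(lf$voxels))
  lf2 <- lf
  lf2$voxels <- lf$voxels[perm, ]
  cols <- as.vector(t(outer(perm, 1:3, function(v, k) 3 * (v - 1) + k)))
  lf2$gain <- lf$gain[, cols]
  op1 <- compute_inverse(lf, alpha = 0.05)
  op2 <- compute_inverse(lf2, alpha = 0.05)
  a <- array(rnorm(19 * 256 * 4, sd = 5), dim = c(19, 256, 4))
  es <- epochs_from_array(a, 128); es$labels <- lf$channels
  s1 <- apply_inverse(op1, es)$values
  s2 <- apply_inverse(op2, es)$values
  expect_equal(unname(s2), unname(s1[perm, ]), tolerance = 1e-6)
})
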