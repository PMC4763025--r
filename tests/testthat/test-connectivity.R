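test_that("cross-spectra are Hermitian with nonnegative real diagonals", {
  set.seed(20)
  a <- array(rnorm(3 * 256 * 12), dim = c(3, 256, 12))
  cs <- cross_spectrum(epochs_from_array(a, 128))
  for (b in c(1, 20, 50)) {
    S <- cs$S[, , b]
    expect_lt(max(abs(S - Conj(t(S)))), 1e-12)
    expect_true(all(Re(diag(S)) >= 0))
    expect_lt(max(abs(Im(diag(S)))), 1e-12)
  }
  a1 <- a[, , 1, drop = FALSE]
  expect_error(cross_spectrum(epochs_from_array(a1, 128)), "2 accepted epochs")
})

test_that("lagged coherence is zero for identical and for independent signals", {
  set.seed(21)
  x <- rnorm(256 * 30)
  a <- array(0, dim = c(2, 256, 30))
  a[1, , ] <- x; a[2, , ] <- x                 # identical: purely instantaneous
  cs <- cross_spectrum(epochs_from_array(a, 128))
  lc_self <- lagged_coherence(cs, 1, 2)
  expect_true(all(lc_self < 1e-20))

  b <- array(rnorm(2 * 256 * 150), dim = c(2, 256, 150))
  csb <- cross_spectrum(epochs_from_array(b, 128))
  lc_ind <- lagged_coherence(csb, 1, 2, f = seq(2, 40, by = 0.5))
  expect_lt(mean(lc_ind), 3 / 150)             # O(1/n_epochs) null level
  # coherency magnitude of identical signals is 1 wherever there is power
  coh <- abs(cs$S[1, 2, 10]) / sqrt(Re(cs$S[1, 1, 10]) * Re(cs$S[2, 2, 10]))
  expect_equal(coh, 1, tolerance = 1e-9)
})

test_that("lagged coherence is symmetric, bounded and matches a brute-force oracle", {
  set.seed(22)
  fs <- 128; n <- 256; n_ep <- 200
  # narrowband 10 Hz source, partner lagged by a quarter period + noise
  lag <- round(fs / 10 / 4)
  src <- as.numeric(stats::filter(rnorm(n * n_ep + lag + 500),
                                  c(2 * 0.97 * cos(2 * pi * 10 / fs), -0.97^2),
                                  method = "recursive"))
  src <- src[-(1:500)]
  xa <- src[(lag + 1):(lag + n * n_ep)]
  xb <- src[1:(n * n_ep)] + 0.5 * rnorm(n * n_ep) * sd(src)
  A <- array(0, dim = c(2, n, n_ep))
  A[1, , ] <- xa; A[2, , ] <- xb
  cs <- cross_spectrum(epochs_from_array(A, fs))
  lc_pkg <- lagged_coherence(cs, 1, 2, f = 10)
  lc_oracle <- oracle_lagged_coherence(matrix(xa, n), matrix(xb, n), fs, 10)
  expect_equal(lc_pkg, lc_oracle, tolerance = 0.02)
  expect_gt(lc_pkg, 0.2)                       # genuinely lagged coupling detected
  expect_equal(lagged_coherence(cs, 2, 1), lagged_coherence(cs, 1, 2))
  expect_true(all(lagged_coherence(cs, 1, 2) >= 0 & lagged_coherence(cs, 1, 2) <= 1))
})

test_that("instantaneous mixtures stay at the null level, lagged sharing exceeds it", {
  set.seed(23)
  fs <- 128; n <- 256; n_ep <- 60
  common <- as.numeric(stats::filter(rnorm(n * n_ep + 100),
                                     c(2 * 0.96 * cos(2 * pi * 10 / fs), -0.96^2),
                                     method = "recursive"))[-(1:97)]
  null95 <- llc_null_level(n_ep, n_bins = 1, prob = 0.95, seed = 99)
  mk_arr <- function(x1, x2) {
    A <- array(0, dim = c(2, n, n_ep)); A[1, , ] <- x1; A[2, , ] <- x2; A
  }
  s0 <- common[1:(n * n_ep)]
  # volume-conduction-like: two different instantaneous mixes of one source
  m1 <- 0.8 * s0 + 0.2 * sd(s0) * rnorm(n * n_ep)
  m2 <- -0.5 * s0 + 0.2 * sd(s0) * rnorm(n * n_ep)
  cs_mix <- cross_spectrum(epochs_from_array(mk_arr(m1, m2), fs))
  expect_lt(lagged_coherence(cs_mix, 1, 2, f = 10), null95)

  lagged <- common[4:(n * n_ep + 3)]
  l1 <- s0 + 0.3 * rnorm(n * n_ep)
  l2 <- lagged + 0.3 * rnorm(n * n_ep)
  cs_lag <- cross_spectrum(epochs_from_array(mk_arr(l1, l2), fs))
  expect_gt(lagged_coherence(cs_lag, 1, 2, f = 10), null95)
})

test_that("the ROI pair lists have the canonical sizes", {
  p <- roi_pairs()
  expect_equal(sum(p$pair_type == "inter"), 6)
  expect_equal(sum(p$pair_type == "intra_left"), 15)
  expect_equal(sum(p$pair_type == "intra_right"), 15)
  expect_true(all(p$roi_a[p$pair_type == "inter"] == p$roi_b[p$pair_type == "inter"]))
})

test_that("ROI-pair LLC reduces to the single voxel-pair value and subsampling is unbiased", {
  lf <- fx_leadfield()     # one voxel per ROI-hemisphere: degenerate averages
  op <- fx_inverse()
  s <- fx_cohort()[[1]]
  es <- segment_epochs(rereference_common_average(s$recording))
  srcser <- source_series(op, es)
  tab <- roi_pair_llc(srcser)
  expect_equal(nrow(tab), 36 * 7)
  expect_true(all(tab$llc >= 0 & tab$llc <= 1))
  expect_true(all(tab$n_voxel_pairs == 1))

  # degenerate average: equals the direct single-pair band-mean
  cs <- cross_spectrum(srcser)
  io <- which(lf$voxels$roi == "occipital" & lf$voxels$hemisphere == "left")
  jo <- which(lf$voxels$roi == "occipital" & lf$voxels$hemisphere == "right")
  direct <- mean(lagged_coherence(cs, io, jo, f = seq(8, 10.5, by = 0.5)))
  got <- tab$llc[tab$pair_type == "inter" & tab$roi_a == "occipital" & tab$band == "alpha1"]
  expect_equal(got, direct)

  # subsampled estimate agrees with full enumeration on a denser leadfield
  lf3 <- make_toy_leadfield(19, 3, seed = 2)
  op3 <- compute_inverse(lf3, alpha = 0.05)
  s3 <- simulate_subject(sim_config(duration = 30, seed = 11, artifact_rate = 0), lf3, "Nold", 8)
  es3 <- segment_epochs(rereference_common_average(s3$recording))
  ss3 <- source_series(op3, es3)
  pairs_occ <- roi_pairs()[roi_pairs()$pair_type == "inter", ][4, ]
  full <- roi_pair_llc(ss3, pairs_occ, max_voxel_pairs = 100)
  subs <- purrr::map_dbl(1:8, function(sd) {
    roi_pair_llc(ss3, pairs_occ, max_voxel_pairs = 5, seed = sd)$llc[3]
  })
  expect_false(any(roi_pair_llc(ss3, pairs_occ, max_voxel_pairs = 5, seed = 1)$subsampled == FALSE))
  expect_equal(mean(subs), full$llc[3], tolerance = 0.35 * full$llc[3] + 0.005)
})
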