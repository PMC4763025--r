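#' Cortical regions of interest
#'
#' The six macro-regions used for source aggregation and connectivity,
#' with their conventional Brodmann-area memberships (shipped as a reference
#' for users supplying atlas-labelled leadfields).
#'
#' @return `roi_names()`: character vector of the six ROI names.
#'   `roi_brodmann_map()`: tibble mapping each ROI to its Brodmann areas.
#' @export
roi_names <- function() {
  c("frontal", "central", "parietal", "occipital", "temporal", "limbic")
}

#' @rdname roi_names
#' @export
roi_brodmann_map <- function() {
  tibble::tibble(
    roi = rep(roi_names(), c(8L, 5L, 6L, 3L, 7L, 6L)),
    brodmann = c(
      8, 9, 10, 11, 44, 45, 46, 47,      # frontal
      1, 2, 3, 4, 6,                     # central
      5, 7, 30, 39, 40, 43,              # parietal
      17, 18, 19,                        # occipital
      20, 21, 22, 37, 38, 41, 42,        # temporal
      31, 32, 33, 34, 35, 36             # limbic
    )
  )
}

# Approximate 10-20 electrode positions on a 9 cm sphere
# (x: left->right, y: posterior->anterior, z: up).
electrode_positions_1020 <- function() {
  p <- rbind(
    Fp1 = c(-0.31,  0.95, 0.05), Fp2 = c( 0.31,  0.95, 0.05),
    F7  = c(-0.81,  0.59, 0.00), F3  = c(-0.55,  0.67, 0.50),
    Fz  = c( 0.00,  0.72, 0.70), F4  = c( 0.55,  0.67, 0.50),
    F8  = c( 0.81,  0.59, 0.00), T3  = c(-1.00,  0.00, 0.00),
    C3  = c(-0.71,  0.00, 0.71), Cz  = c( 0.00,  0.00, 1.00),
    C4  = c( 0.71,  0.00, 0.71), T4  = c( 1.00,  0.00, 0.00),
    T5  = c(-0.81, -0.59, 0.00), P3  = c(-0.55, -0.67, 0.50),
    Pz  = c( 0.00, -0.72, 0.70), P4  = c( 0.55, -0.67, 0.50),
    T6  = c( 0.81, -0.59, 0.00), O1  = c(-0.31, -0.95, 0.05),
    O2  = c( 0.31, -0.95, 0.05)
  )
  9 * p / sqrt(rowSums(p^2))
}

# Evenly spread unit-sphere points for non-standard channel counts.
fibonacci_sphere <- function(n, radius = 9) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  radius * cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Nominal ROI centres in cm (|x| lateral, y anterior-posterior, z vertical).
roi_centres <- function() {
  rbind(
    frontal   = c(3.5,  5.0, 3.0),
    central   = c(3.0,  0.0, 6.0),
    parietal  = c(3.5, -4.5, 5.0),
    occipital = c(2.0, -7.5, 1.0),
    temporal  = c(6.0, -1.0, 0.0),
    limbic    = c(1.5, -2.0, 2.5)
  )
}

#' Build a configurable toy leadfield
#'
#' Constructs a small forward model for testing and simulation: each of the
#' six ROIs gets `voxels_per_roi_per_hemisphere` voxels in each hemisphere,
#' placed with seeded jitter around nominal ROI centres inside a spherical
#' head, and the gain is the quasi-static current-dipole field of a
#' homogeneous conductor evaluated at the electrode positions (three columns
#' per voxel, one per dipole-moment component). A fixed random source
#' orientation is stored per voxel for use by the simulator. This stands in
#' for a realistic anatomical head model at desk scale; a user-supplied gain
#' matrix and voxel table can be used instead via [read_leadfield()].
#'
#' @param n_channels number of electrodes; 19 gives the standard 10-20
#'   montage, other counts use an even spherical layout with generic labels.
#' @param voxels_per_roi_per_hemisphere voxels per ROI and hemisphere (>= 1).
#' @param seed integer seed; the leadfield is deterministic given the seed.
#' @param cond_warn_ratio warn (not error) when `3 * voxels` exceeds
#'   `cond_warn_ratio * n_channels`, i.e. when the inverse problem becomes
#'   severely underdetermined.
#' @return An object of class `eeg_leadfield`: `gain` (channels x 3*voxels,
#'   microvolts per unit dipole moment), `channels`, and a `voxels` tibble
#'   (id, position, roi, hemisphere, brodmann, orientation).
#' @examples
#' lf <- make_toy_leadfield(19, 1, seed = 7)
#' dim(lf$gain) # 19 x 36
#' @export
make_toy_leadfield <- function(n_channels = 19, voxels_per_roi_per_hemisphere = 1,
                               seed = 1, cond_warn_ratio = 10) {
  if (n_channels < 2 || voxels_per_roi_per_hemisphere < 1) {
    abort("n_channels must be >= 2 and voxels_per_roi_per_hemisphere >= 1")
  }
  n_channels <- as.integer(n_channels)
  vprh <- as.integer(voxels_per_roi_per_hemisphere)
  n_vox <- 6L * 2L * vprh
  if (3 * n_vox > cond_warn_ratio * n_channels) {
    warn(sprintf("leadfield has %d gain columns for %d channels; inverse will be strongly underdetermined",
                 3 * n_vox, n_channels))
  }
  if (n_channels == 19L) {
    epos <- electrode_positions_1020()
    chan <- rownames(epos)
  } else {
    epos <- fibonacci_sphere(n_channels)
    chan <- paste0("E", seq_len(n_channels))
    rownames(epos) <- chan
  }
  with_seed(seed, {
    centres <- roi_centres()
    vox <- purrr::map_dfr(roi_names(), function(roi) {
      purrr::map_dfr(c("left", "right"), function(hemi) {
        sgn <- if (hemi == "left") -1 else 1
        ctr <- centres[roi, ] * c(sgn, 1, 1)
        pos <- matrix(rep(ctr, each = vprh), ncol = 3) +
          matrix(stats::runif(3 * vprh, -1.5, 1.5), ncol = 3)
        tibble::tibble(
          roi = roi, hemisphere = hemi,
          x = pos[, 1], y = pos[, 2], z = pos[, 3]
        )
      })
    })
    bamap <- roi_brodmann_map()
    vox$brodmann <- unlist(lapply(seq_len(nrow(vox)), function(i) {
      bas <- bamap$brodmann[bamap$roi == vox$roi[i]]
      bas[((i - 1L) %% length(bas)) + 1L]
    }))
    ori <- matrix(rnorm(3 * nrow(vox)), ncol = 3)
    ori <- ori / sqrt(rowSums(ori^2))
    vox$ox <- ori[, 1]; vox$oy <- ori[, 2]; vox$oz <- ori[, 3]
    vox <- dplyr::mutate(vox, id = sprintf("v%03d", dplyr::row_number()), .before = 1)

    gain <- matrix(0, n_channels, 3L * nrow(vox))
    for (v in seq_len(nrow(vox))) {
      d <- sweep(epos, 2L, c(vox$x[v], vox$y[v], vox$z[v]))
      r3 <- pmax(rowSums(d^2), 1)^1.5
      gain[, (3L * v - 2L):(3L * v)] <- d / r3
    }
    gain <- gain * (50 / stats::median(abs(gain)[abs(gain) > 0]))
    rownames(gain) <- chan
    structure(
      list(gain = gain, channels = chan, voxels = vox, seed = seed),
      class = "eeg_leadfield"
    )
  })
}

#' @export
print.eeg_leadfield <- function(x, ...) {
  cat(sprintf("<eeg_leadfield> %d channels, %d voxels (%d ROIs x 2 hemispheres)\n",
              length(x$channels), nrow(x$voxels), length(unique(x$voxels$roi))))
  invisible(x)
}

validate_leadfield <- function(lf) {
  stopifnot(inherits(lf, "eeg_leadfield"))
  if (!all(is.finite(lf$gain))) abort("leadfield gain contains non-finite values")
  if (ncol(lf$gain) != 3L * nrow(lf$voxels)) abort("gain must have 3 columns per voxel")
  if (!all(lf$voxels$roi %in% roi_names())) abort("unknown ROI label in voxel table")
  if (!all(lf$voxels$hemisphere %in% c("left", "right"))) abort("hemisphere must be left/right")
  invisible(lf)
}

n_voxels <- function(lf) nrow(lf$voxels)

# channels x voxels effective gain for fixed per-voxel orientations
effective_gain <- function(lf) {
  G <- matrix(0, nrow(lf$gain), n_voxels(lf))
  for (v in seq_len(n_voxels(lf))) {
    o <- c(lf$voxels$ox[v], lf$voxels$oy[v], lf$voxels$oz[v])
    G[, v] <- lf$gain[, (3L * v - 2L):(3L * v)] %*% o
  }
  rownames(G) <- lf$channels
  G
}
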