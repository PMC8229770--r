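#' Specification of a synthetic mandible-like phantom
#'
#' The phantom emulates the geometry that makes slice-recurrent segmentation
#' interesting: an anatomically connected U-shaped arch (horseshoe "body") in
#' the inferior slices that splits toward the superior slices into two rami,
#' which thin into narrow protrusions (condyle/coronoid analogues).  The
#' intensity volume is a lightly smoothed indicator of the mask (background
#' mean 0, foreground mean 1) plus Gaussian noise, and a random subset of
#' slices is corrupted by bright/dark streaks that overwrite intensities --
#' a desk-scale analogue of metal streak artifacts, which damage per-slice
#' appearance while leaving the inter-slice shape continuity informative.
#'
#' @param shape integer triple `(n_slices, n_rows, n_cols)`; at least 2 slices
#'   and 4 voxels in-plane.
#' @param spacing mm triple `(slice_mm, row_mm, col_mm)`.
#' @param arch_radius_mm radius of the arch midline in mm.
#' @param limb_thickness_mm tube diameter of the arch in mm.
#' @param protrusion_count number of thin processes each ramus splits into in
#'   the superior quarter of the stack (0 = rami simply taper out).
#' @param noise_sigma standard deviation of additive Gaussian intensity noise.
#' @param artifact_fraction fraction in `[0, 1]` of slices corrupted by streaks.
#' @param artifact_amplitude absolute intensity written along a streak (sign
#'   random per streak).
#' @param seed integer seed; phantoms are bit-reproducible from the spec alone.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(16L, 64L, 64L), spacing = c(1.25, 1, 1),
                         arch_radius_mm = 20, limb_thickness_mm = 9,
                         protrusion_count = 2L, noise_sigma = 0.1,
                         artifact_fraction = 0.3, artifact_amplitude = 2,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  if (shape[1] < 2L || any(shape[2:3] < 4L))
    stop("phantom_spec: need at least 2 slices and 4x4 in-plane voxels", call. = FALSE)
  spacing <- check_spacing(spacing)
  stopifnot(arch_radius_mm > 0, limb_thickness_mm > 0,
            protrusion_count >= 0, noise_sigma >= 0,
            artifact_amplitude >= 0)
  if (artifact_fraction < 0 || artifact_fraction > 1)
    stop("phantom_spec: artifact_fraction must be in [0, 1]", call. = FALSE)
  structure(list(shape = shape, spacing = spacing,
                 arch_radius_mm = arch_radius_mm,
                 limb_thickness_mm = limb_thickness_mm,
                 protrusion_count = as.integer(protrusion_count),
                 noise_sigma = noise_sigma,
                 artifact_fraction = artifact_fraction,
                 artifact_amplitude = artifact_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Geometry constants of the arch model (fractions of the slice stack).
.arch_geom <- list(
  theta_open = 50,    # half-angle (deg) of the anterior opening of the horseshoe
  split_s    = 0.45,  # slice fraction where the body splits into two rami
  prot_s     = 0.75,  # slice fraction where rami split into protrusions
  retract    = 0.85,  # fraction of each ramus arc retracted by the top slice
  taper      = 0.45,  # fraction of tube thickness lost by the top slice
  r_lo       = 0.85, r_hi = 1.15  # radius ramp across the stack
)

## Midline skeleton of one slice, as (row_mm, col_mm) points around `center`.
arch_skeleton <- function(s, center, spec) {
  g <- .arch_geom
  omega_full <- 180 - g$theta_open
  r <- spec$arch_radius_mm * (g$r_lo + (g$r_hi - g$r_lo) * s)
  omega <- if (s < g$split_s) omega_full else
    omega_full * (1 - g$retract * (s - g$split_s) / (1 - g$split_s))
  intervals <- list(c(g$theta_open, g$theta_open + omega))  # right ramus + body half
  p <- spec$protrusion_count
  if (s >= g$prot_s && p > 0) {
    shrink <- 1 - 0.65 * (s - g$prot_s) / (1 - g$prot_s)
    h <- omega / (2 * p) * shrink
    centers <- g$theta_open + omega * (seq_len(p) - 0.5) / p
    intervals <- lapply(centers, function(cc) c(cc - h, cc + h))
  }
  thetas <- unlist(lapply(intervals, function(iv) {
    n <- max(2L, ceiling((iv[2] - iv[1]) / 0.75))
    seq(iv[1], iv[2], length.out = n)
  }))
  thetas <- c(thetas, 360 - thetas)          # mirrored left side
  th <- thetas * pi / 180
  cbind(center[1] - r * cos(th), center[2] + r * sin(th))
}

arch_thickness <- function(s, spec) {
  g <- .arch_geom
  spec$limb_thickness_mm * (1 - g$taper * max(0, (s - g$split_s) / (1 - g$split_s)))
}

#' Generate a synthetic phantom volume with ground truth
#'
#' See [phantom_spec()] for the model.  With `noise_sigma = 0` and
#' `artifact_fraction = 0`, thresholding the volume at the midpoint between
#' the background (0) and foreground (1) mean intensities recovers the mask
#' exactly.  Streak corruption never alters the returned ground-truth mask.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([volume_grid()]), `mask`
#'   ([binary_mask()]) and `corrupted_slices` (sorted 1-based slice indices
#'   that received streak artifacts; `ceiling(artifact_fraction * n_slices)`
#'   of them, or none when the fraction is 0).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(8, 32, 32), arch_radius_mm = 9,
#'                                     limb_thickness_mm = 5, seed = 7))
#' sum(ph$mask$labels) > 0
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$shape[1]; R <- spec$shape[2]; C <- spec$shape[3]
  sp <- spec$spacing
  g <- .arch_geom
  center <- c((R - 1) / 2 * sp[2], (C - 1) / 2 * sp[3])
  r_max <- spec$arch_radius_mm * g$r_hi + spec$limb_thickness_mm / 2
  if (r_max > min(center[1], center[2]))
    stop(sprintf("geometry error: arch extent %.1f mm exceeds the in-plane field of view (%.1f mm half-extent)",
                 r_max, min(center[1], center[2])), call. = FALSE)

  ys <- ((seq_len(R)) - 1) * sp[2]
  xs <- ((seq_len(C)) - 1) * sp[3]
  pix <- cbind(rep(ys, times = C), rep(xs, each = R))  # column-major (row, col)

  mask <- array(0, c(S, R, C))
  for (t in seq_len(S)) {
    s <- (t - 1) / (S - 1)
    sk <- arch_skeleton(s, center, spec)
    dmin <- .nn_min_dists(pix, sk)
    mask[t, , ] <- matrix(as.numeric(dmin <= arch_thickness(s, spec) / 2), R, C)
  }

  vol <- smooth_indicator(mask)
  corrupted <- integer(0)
  with_local_seed(spec$seed, {
    n_corrupt <- ceiling(spec$artifact_fraction * S)
    if (n_corrupt > 0) {
      corrupted <- sort(sample.int(S, n_corrupt))
      for (t in corrupted) {
        sl <- vol[t, , ]
        for (k in seq_len(sample(4:8, 1))) {
          p0 <- c(runif(1, 0.15, 0.85) * max(ys), runif(1, 0.15, 0.85) * max(xs))
          phi <- runif(1, 0, pi)
          nrm <- c(-sin(phi), cos(phi))
          width <- sample(1:2, 1) * min(sp[2:3])
          d <- abs((pix[, 1] - p0[1]) * nrm[1] + (pix[, 2] - p0[2]) * nrm[2])
          hit <- d <= width / 2
          sl[matrix(hit, R, C)] <- sample(c(-1, 1), 1) * spec$artifact_amplitude
        }
        vol[t, , ] <- sl
      }
    }
    if (spec$noise_sigma > 0)
      vol <- vol + array(rnorm(length(vol), sd = spec$noise_sigma), dim(vol))
  })

  list(volume = volume_grid(vol, spacing = sp),
       mask = binary_mask(mask, spacing = sp),
       corrupted_slices = corrupted)
}

## 3^3 smoothing of a binary indicator whose centre weight (0.52) exceeds the
## total off-centre weight, so foreground voxels stay > 0.5 and background
## voxels stay < 0.5: midpoint thresholding is exact by construction.
smooth_indicator <- function(mask, center_w = 0.52) {
  d <- dim(mask)
  out <- array(0, d)
  off_w <- (1 - center_w) / 26
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    w <- if (di == 0 && dj == 0 && dk == 0) center_w else off_w
    src_i <- max(1, 1 - di):min(d[1], d[1] - di)
    src_j <- max(1, 1 - dj):min(d[2], d[2] - dj)
    src_k <- max(1, 1 - dk):min(d[3], d[3] - dk)
    out[src_i + di, src_j + dj, src_k + dk] <-
      out[src_i + di, src_j + dj, src_k + dk] + w * mask[src_i, src_j, src_k]
  }
  out
}

#' Generate a reproducible dataset of jittered phantoms
#'
#' Draws `n` phantoms from `spec_template` with per-case jitter of the arch
#' radius and limb thickness (+/-15%) and, optionally, the slice count
#' (75-125% of the template, never below 12 so superior protrusions remain
#' slice-to-slice connected), so downstream models see sequences of varied
#' length.  All randomness derives from `seed`; no two cases share a seed.
#'
#' @param n number of cases (>= 1).
#' @param spec_template a [phantom_spec()] providing the base parameters.
#' @param seed integer seed for the whole dataset.
#' @param jitter_slices logical; jitter the number of slices per case.
#' @return A list of `n` elements, each as returned by [generate_phantom()]
#'   with the per-case `spec` attached.
#' @export
generate_dataset <- function(n, spec_template = phantom_spec(), seed = 1L,
                             jitter_slices = TRUE) {
  if (n < 1) stop("generate_dataset: n must be >= 1", call. = FALSE)
  stopifnot(inherits(spec_template, "phantom_spec"))
  case_seeds <- derive_seeds(seed, n)
  jit <- with_local_seed(seed + 1L, {
    list(radius = runif(n, 0.85, 1.15),
         thick = runif(n, 0.85, 1.15),
         slices = round(spec_template$shape[1] * runif(n, 0.75, 1.25)))
  })
  lapply(seq_len(n), function(i) {
    sp <- spec_template
    sp$arch_radius_mm <- sp$arch_radius_mm * jit$radius[i]
    sp$limb_thickness_mm <- jit$thick[i] * sp$limb_thickness_mm
    if (jitter_slices) sp$shape[1] <- max(12L, as.integer(jit$slices[i]))
    sp$seed <- case_seeds[i]
    out <- generate_phantom(sp)
    out$spec <- sp
    out
  })
}
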