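## Synthetic brain-like diffusion phantom: ground-truth FOD fields with
## single-fiber, crossing and curved-bundle white matter, a GM rim and a CSF
## pocket; forward-simulated multi-shell signal; calibrated Rician noise.

#' Phantom configuration
#'
#' @param dim3 Grid size in voxels (length-3 integer).
#' @param voxel_size Isotropic voxel size in mm.
#' @param crossing_angle Angle between the two fiber populations of the
#'   crossing region, degrees in (0, 90].
#' @param bvals Per-shell b-values in s/mm^2 (first entry typically 0).
#' @param n_dirs Per-shell direction counts (b = 0 shells repeat a zero
#'   vector).
#' @param snr Signal-to-noise ratio of the magnitude images (`Inf` =
#'   noiseless).
#' @param lmax Maximum even SH order of the ground-truth FODs.
#' @param seed Seed controlling gradient directions and noise.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(dim3 = c(20L, 20L, 20L), voxel_size = 1.25,
                           crossing_angle = 60, bvals = c(0, 1200, 3000),
                           n_dirs = c(7L, 30L, 30L), snr = Inf, lmax = 8L,
                           seed = 0L) {
  if (crossing_angle <= 0 || crossing_angle > 90)
    stop("crossing_angle must lie in (0, 90] degrees", call. = FALSE)
  if (!(snr > 0)) stop("snr must be positive (or Inf)", call. = FALSE)
  if (length(bvals) != length(n_dirs))
    stop("bvals and n_dirs lengths differ", call. = FALSE)
  if (any(dim3 < 8L)) stop("phantom grid must be at least 8 voxels per axis",
                           call. = FALSE)
  structure(list(dim3 = as.integer(dim3), voxel_size = voxel_size,
                 crossing_angle = crossing_angle, bvals = bvals,
                 n_dirs = as.integer(n_dirs), snr = snr,
                 lmax = check_lmax(lmax), seed = as.integer(seed)),
            class = "phantom_config")
}

phantom_affine <- function(cfg) {
  a <- diag(c(rep(cfg$voxel_size, 3L), 1))
  a[1:3, 4L] <- -cfg$voxel_size * (cfg$dim3 - 1) / 2
  a
}

#' Build the ground-truth phantom
#'
#' White matter FODs are weighted sums of apodized delta kernels along
#' region-defined tangent fields: a single-fiber slab (fibers along x), a
#' crossing slab (two populations at the configured angle, equal weight) and
#' a curved bundle whose tangents follow circular arcs (high curvature near
#' the arc center). A one-voxel GM rim surrounds the tissue block and a CSF
#' sphere is embedded in the single-fiber slab. Fractions are binary per
#' region; the outermost margin is empty background.
#'
#' @param cfg A [phantom_config()].
#' @return A list of class `phantom_truth`: `fod` (4D array
#'   `[X,Y,Z,n_coeffs]` of WM FOD coefficients scaled by the WM fraction),
#'   `fractions` (4D array `[X,Y,Z,3]`, order WM/GM/CSF), `peaks` (list of
#'   per-voxel direction matrices with a `weights` attribute), `affine`,
#'   `region` (integer array: 0 background, 1 single-fiber, 2 crossing,
#'   3 curved, 4 GM, 5 CSF) and `cfg`.
#' @export
make_phantom <- function(cfg = phantom_config()) {
  d3 <- cfg$dim3
  nc <- n_coeffs(cfg$lmax)
  fod <- array(0, c(d3, nc))
  frac <- array(0, c(d3, 3L))
  region <- array(0L, d3)
  peaks <- vector("list", prod(d3))
  dim(peaks) <- d3

  ## tissue block bounds (1-based): leave a 1-voxel empty margin
  lo <- c(2L, 2L, 2L); hi <- d3 - 1L
  inner_lo <- lo + 1L; inner_hi <- hi - 1L       # WM interior; rim is GM
  zspan <- inner_hi[3L] - inner_lo[3L] + 1L
  z1 <- inner_lo[3L] + floor(zspan / 3) - 1L      # single-fiber: z <= z1
  z2 <- inner_lo[3L] + floor(2 * zspan / 3) - 1L  # crossing: z1 < z <= z2
  half <- cfg$crossing_angle * pi / 360           # half-angle in radians
  cross_dirs <- rbind(c(cos(half), sin(half), 0),
                      c(cos(half), -sin(half), 0))
  ## CSF sphere inside the single-fiber slab
  csf_center <- c(inner_lo[1L] + 2L, inner_lo[2L] + 2L,
                  inner_lo[3L] + max(1L, floor(zspan / 6)))
  csf_r <- 1.6
  ## curved bundle: arc center at the (x, y) lower-left inner corner
  arc_c <- c(inner_lo[1L] - 0.5, inner_lo[2L] - 0.5)

  for (i in seq_len(d3[1L])) for (j in seq_len(d3[2L])) for (k in seq_len(d3[3L])) {
    if (any(c(i, j, k) < lo) || any(c(i, j, k) > hi)) next
    if (sqrt(sum((c(i, j, k) - csf_center)^2)) <= csf_r) {
      frac[i, j, k, 3L] <- 1; region[i, j, k] <- 5L
      next
    }
    if (any(c(i, j, k) < inner_lo) || any(c(i, j, k) > inner_hi)) {
      frac[i, j, k, 2L] <- 1; region[i, j, k] <- 4L
      next
    }
    ## white matter
    frac[i, j, k, 1L] <- 1
    if (k <= z1) {
      dirs <- matrix(c(1, 0, 0), 1L); w <- 1; region[i, j, k] <- 1L
    } else if (k <= z2) {
      dirs <- cross_dirs; w <- c(0.5, 0.5); region[i, j, k] <- 2L
    } else {
      v <- c(i - arc_c[1L], j - arc_c[2L])
      tang <- c(-v[2L], v[1L], 0) / sqrt(sum(v^2))
      dirs <- matrix(tang, 1L); w <- 1; region[i, j, k] <- 3L
    }
    f <- numeric(nc)
    for (p in seq_len(nrow(dirs))) f <- f + w[p] * apodized_delta(cfg$lmax, dirs[p, ])
    fod[i, j, k, ] <- f            # WM fraction is 1 in all WM voxels
    peaks[[i, j, k]] <- structure(dirs, weights = w)
  }
  structure(list(fod = fod, fractions = frac, peaks = peaks,
                 affine = phantom_affine(cfg), region = region, cfg = cfg),
            class = "phantom_truth")
}

#' Tissue response functions from analytic diffusion models
#'
#' WM: axially symmetric diffusion tensor, zonal coefficients obtained by
#' Gauss-Legendre projection of `exp(-b v' D v)` onto the zonal harmonics per
#' shell. GM and CSF: isotropic mono-exponential decay, `l = 0` term only.
#' All coefficients are zonal SH coefficients of the unit-S0 canonical
#' signal, so the b = 0 row of every tissue is `(2*sqrt(pi), 0, ...)`.
#'
#' @param bvals Shell b-values (s/mm^2).
#' @param lmax Maximum even order of the WM response.
#' @param wm_diffusivity Axial and radial diffusivity of the WM tensor
#'   (mm^2/s).
#' @param gm_adc,csf_adc Isotropic diffusivities (mm^2/s).
#' @param s0 Non-diffusion-weighted signal scale per tissue
#'   (length 1 or 3, order WM/GM/CSF).
#' @return List of class `response_set` with matrices `wm`
#'   (`[n_shells x lmax/2+1]`), `gm`, `csf` (`[n_shells x 1]`), plus `bvals`
#'   and `lmax`.
#' @export
make_responses <- function(bvals, lmax = 8L,
                           wm_diffusivity = c(1.7e-3, 0.2e-3),
                           gm_adc = 0.8e-3, csf_adc = 3.0e-3, s0 = 1) {
  check_lmax(lmax)
  s0 <- rep(s0, length.out = 3L)
  gl <- pracma::gaussLegendre(64, -1, 1)
  P <- legendre_norm(lmax, gl$x)
  ls <- seq(0L, lmax, by = 2L)
  wm <- t(vapply(bvals, function(b) {
    sig <- s0[1L] * exp(-b * (wm_diffusivity[2L] +
                                (wm_diffusivity[1L] - wm_diffusivity[2L]) * gl$x^2))
    vapply(ls, function(l) 2 * pi * sum(gl$w * sig * P[, l + 1L, 1L]), 0)
  }, numeric(length(ls))))
  iso <- function(adc, s) matrix(s * exp(-bvals * adc) * sqrt(4 * pi), ncol = 1L)
  structure(list(wm = unname(wm), gm = iso(gm_adc, s0[2L]),
                 csf = iso(csf_adc, s0[3L]), bvals = bvals, lmax = lmax),
            class = "response_set")
}

#' Forward-simulate the diffusion signal of a phantom
#'
#' Per voxel and shell, each tissue's coefficients are convolved with that
#' tissue's response for the shell (spherical convolution with a zonal
#' kernel) and the results summed, then evaluated at the shell's gradient
#' directions. GM/CSF contribute through their single isotropic coefficient.
#' This is the same forward model the fitting objective uses.
#'
#' @param truth A [make_phantom()] result.
#' @param gtab A [gradient_table()] whose shells are covered by `responses`.
#' @param responses A [make_responses()] result (or compatible list).
#' @return 4D array `[X, Y, Z, n_volumes]` of noiseless signal amplitudes.
#' @export
synthesize_signal <- function(truth, gtab, responses) {
  M <- signal_matrix(gtab, responses, truth$cfg$lmax, mode = "msmt")
  d3 <- dim(truth$fod)[1:3]
  nvox <- prod(d3)
  K <- cbind(matrix(truth$fod, nvox, dim(truth$fod)[4L]),
             matrix(truth$fractions[, , , 2L], nvox) / (2 * sqrt(pi)),
             matrix(truth$fractions[, , , 3L], nvox) / (2 * sqrt(pi)))
  sig <- K %*% t(M)
  array(sig, c(d3, nrow(M)))
}

## Linear map from stacked tissue coefficients to the predicted signal.
## Rows: acquisition volumes; columns: WM SH coefficients (+ GM, CSF
## fraction coefficients in msmt mode). b = 0 rows use the z axis as a dummy
## direction (their responses carry l = 0 only, so the choice is immaterial).
signal_matrix <- function(gtab, responses, lmax, mode = c("msmt", "csd"),
                          volumes = NULL) {
  mode <- match.arg(mode)
  if (is.null(volumes)) volumes <- seq_along(gtab$bvals)
  nc <- n_coeffs(lmax)
  ncol_out <- if (mode == "msmt") nc + 2L else nc
  M <- matrix(0, length(volumes), ncol_out)
  cs <- convolution_scale(lmax)
  for (r in seq_along(volumes)) {
    v <- volumes[r]
    sid <- gtab$shell_id[v]
    b <- gtab$shells[sid]
    rrow <- which.min(abs(responses$bvals - b))
    if (abs(responses$bvals[rrow] - b) > 100)
      stop("no response for shell b = ", b, call. = FALSE)
    dir <- gtab$bvecs[v, ]
    if (sqrt(sum(dir^2)) < 0.5) dir <- c(0, 0, 1)
    Brow <- drop(sh_basis(matrix(dir, 1L), lmax))
    M[r, seq_len(nc)] <- Brow * cs * expand_zonal(responses$wm[rrow, ], lmax)
    if (mode == "msmt") {
      ## isotropic tissues: amplitude = f00_tissue * r00 (independent of dir)
      M[r, nc + 1L] <- responses$gm[rrow, 1L]
      M[r, nc + 2L] <- responses$csf[rrow, 1L]
    }
  }
  M
}

#' Add complex-Gaussian (Rician magnitude) noise to a DWI volume
#'
#' Gaussian noise of standard deviation `s_ref / snr` is added independently
#' to the real and imaginary channel (signal real) and the magnitude taken.
#'
#' @param data 4D signal array.
#' @param snr Target signal-to-noise ratio (`Inf` returns the input).
#' @param s_ref Reference amplitude; by default the mean of `data` over
#'   `ref_mask` in the `b0_volumes`.
#' @param seed Integer seed (reproducible noise).
#' @param ref_mask Logical/0-1 3D array selecting reference voxels (e.g. the
#'   WM mask); default all voxels with positive signal.
#' @param b0_volumes Indices of b = 0 volumes used for the reference mean.
#' @return Noisy 4D array, same shape, non-negative.
#' @export
add_noise <- function(data, snr, seed = 0L, s_ref = NULL, ref_mask = NULL,
                      b0_volumes = 1L) {
  if (!(snr > 0)) stop("snr must be positive", call. = FALSE)
  if (is.infinite(snr)) return(data)
  if (is.null(s_ref)) {
    b0 <- data[, , , b0_volumes, drop = FALSE]
    if (is.null(ref_mask)) ref_mask <- apply(b0 > 0, 1:3, all)
    s_ref <- mean(apply(b0, 4L, function(v) v[ref_mask > 0]))
  }
  sigma <- s_ref / snr
  set.seed(seed)
  n1 <- array(stats::rnorm(length(data), sd = sigma), dim(data))
  n2 <- array(stats::rnorm(length(data), sd = sigma), dim(data))
  sqrt((data + n1)^2 + n2^2)
}

#' Generate a complete synthetic diffusion dataset
#'
#' Convenience wrapper: builds the ground truth, the gradient table
#' (electrostatic-repulsion directions per shell, seeded), the tissue
#' responses, the noiseless signal, and optionally adds noise.
#'
#' @param cfg A [phantom_config()].
#' @return List of class `dmri_phantom` with `truth`, `gtab`, `responses`,
#'   `data` (4D array, noisy if `cfg$snr` is finite), `clean` (noiseless
#'   signal), `mask` (tissue mask), `wm_mask`, `affine`, `cfg`.
#' @export
dmri_phantom <- function(cfg = phantom_config()) {
  truth <- make_phantom(cfg)
  bvecs <- NULL; bvals <- NULL
  for (s in seq_along(cfg$bvals)) {
    if (cfg$bvals[s] <= 50) {
      bvecs <- rbind(bvecs, matrix(0, cfg$n_dirs[s], 3L))
    } else {
      bvecs <- rbind(bvecs,
                     repulsion_directions(cfg$n_dirs[s], seed = cfg$seed + s))
    }
    bvals <- c(bvals, rep(cfg$bvals[s], cfg$n_dirs[s]))
  }
  gtab <- gradient_table(bvecs, bvals)
  responses <- make_responses(cfg$bvals, lmax = cfg$lmax)
  clean <- synthesize_signal(truth, gtab, responses)
  wm_mask <- truth$fractions[, , , 1L] > 0
  data <- if (is.infinite(cfg$snr)) clean else
    add_noise(clean, cfg$snr, seed = cfg$seed + 1000L, ref_mask = wm_mask,
              b0_volumes = which(gtab$bvals <= 50))
  structure(list(truth = truth, gtab = gtab, responses = responses,
                 data = data, clean = clean,
                 mask = apply(truth$fractions, 1:3, sum) > 0,
                 wm_mask = wm_mask, affine = truth$affine, cfg = cfg),
            class = "dmri_phantom")
}

#' Write a phantom dataset to disk in standard formats
#'
#' Writes `dwi.nii.gz` (+ `.bval`/`.bvec`), `mask.nii.gz`, `truth_fod.nii.gz`
#' (SH image), `fractions.nii.gz`, `response_{wm,gm,csf}.txt` and a JSON
#' manifest with the configuration and seed.
#'
#' @param ph A [dmri_phantom()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(ph$data, ph$affine, file.path(dir, "dwi.nii.gz"), gtab = ph$gtab)
  write_nifti(ph$mask + 0L, ph$affine, file.path(dir, "mask.nii.gz"))
  write_sh_image(ph$truth$fod, ph$affine, file.path(dir, "truth_fod.nii.gz"))
  write_nifti(ph$truth$fractions, ph$affine, file.path(dir, "fractions.nii.gz"))
  write_response(ph$responses$wm, file.path(dir, "response_wm.txt"))
  write_response(ph$responses$gm, file.path(dir, "response_gm.txt"))
  write_response(ph$responses$csf, file.path(dir, "response_csf.txt"))
  cfg <- ph$cfg; class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
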