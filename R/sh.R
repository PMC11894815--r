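#' @keywords internal
#' @importFrom utils write.table read.table
#' @importFrom stats rnorm runif sd
"_PACKAGE"

## Real, even-order spherical harmonics in the MRtrix3 convention.
##
## Basis definition (even l only):
##   Y_l^m(theta, phi) = sqrt(2) * Im[Y_l^{|m|}]   if m < 0
##                     = Y_l^0                      if m = 0
##                     = sqrt(2) * Re[Y_l^m]        if m > 0
## where the complex Y_l^m are orthonormal and include the Condon-Shortley
## phase. The resulting real basis is orthonormal on the sphere. Coefficients
## are stored l-major with m ascending from -l to +l (the MRtrix3 on-disk
## ordering).

#' Number of coefficients of an even-order spherical-harmonic series
#'
#' @param lmax Maximum (even, non-negative) harmonic order.
#' @return `(lmax+1)(lmax+2)/2`, the number of real even-order SH
#'   coefficients up to order `lmax`.
#' @examples
#' n_coeffs(8) # 45
#' @export
n_coeffs <- function(lmax) {
  check_lmax(lmax)
  as.integer((lmax + 1L) * (lmax + 2L) / 2L)
}

check_lmax <- function(lmax) {
  if (length(lmax) != 1L || !is.finite(lmax) || lmax < 0 || lmax %% 2 != 0)
    stop("'lmax' must be a single even non-negative integer", call. = FALSE)
  invisible(as.integer(lmax))
}

#' Flat index of an (l, m) spherical-harmonic term
#'
#' Coefficient vectors are stored l-major (even l only), with m ascending
#' from -l to +l within each order.
#'
#' @param l Even harmonic order.
#' @param m Harmonic phase, `|m| <= l`.
#' @return 1-based index into the coefficient vector.
#' @seealso [sh_degrees()] for the inverse map.
#' @export
sh_index <- function(l, m) {
  if (any(l %% 2 != 0) || any(l < 0)) stop("'l' must be even and >= 0", call. = FALSE)
  if (any(abs(m) > l)) stop("'|m|' must not exceed 'l'", call. = FALSE)
  as.integer(l * (l + 1) / 2 + m + 1)
}

#' Orders and phases of each coefficient position
#'
#' @param lmax Maximum even order.
#' @return A data frame with columns `l` and `m`, one row per coefficient,
#'   in storage order.
#' @export
sh_degrees <- function(lmax) {
  check_lmax(lmax)
  l <- unlist(lapply(seq(0L, lmax, by = 2L), function(ll) rep(ll, 2L * ll + 1L)))
  m <- unlist(lapply(seq(0L, lmax, by = 2L), function(ll) seq(-ll, ll)))
  data.frame(l = as.integer(l), m = as.integer(m))
}

## Fully normalized associated Legendre functions Pbar_l^m(x) for all
## l = 0..lmax (even and odd; even rows extracted by callers), m = 0..lmax,
## such that the orthonormal complex SH is Y_l^m = Pbar_l^m(cos theta) e^{i m phi}.
## Includes the Condon-Shortley phase. Stable three-term recurrence.
legendre_norm <- function(lmax, x) {
  n <- length(x)
  P <- array(0, dim = c(n, lmax + 1L, lmax + 1L)) # [x, l+1, m+1]
  somx2 <- sqrt(pmax(0, 1 - x^2))
  P[, 1L, 1L] <- sqrt(1 / (4 * pi))
  if (lmax == 0L) return(P)
  ## sectoral terms Pbar_m^m
  for (m in seq_len(lmax)) {
    P[, m + 1L, m + 1L] <- -sqrt((2 * m + 1) / (2 * m)) * somx2 * P[, m, m]
  }
  ## Pbar_{m+1}^m
  for (m in 0:(lmax - 1L)) {
    P[, m + 2L, m + 1L] <- x * sqrt(2 * m + 3) * P[, m + 1L, m + 1L]
  }
  ## upward recurrence in l
  if (lmax >= 2L) {
    for (m in 0:(lmax - 2L)) {
      for (l in (m + 2L):lmax) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        P[, l + 1L, m + 1L] <- a * (x * P[, l, m + 1L] - b * P[, l - 1L, m + 1L])
      }
    }
  }
  P
}

#' Convert unit Cartesian directions to spherical angles
#'
#' @param dirs Numeric matrix `n x 3` of unit vectors (or a length-3 vector).
#' @return Matrix with columns `theta` (polar, `[0, pi]`) and `phi`
#'   (azimuth, `[0, 2*pi)`).
#' @export
cart_to_sph <- function(dirs) {
  dirs <- as_dir_matrix(dirs)
  theta <- acos(pmin(1, pmax(-1, dirs[, 3L])))
  phi <- atan2(dirs[, 2L], dirs[, 1L])
  phi[phi < 0] <- phi[phi < 0] + 2 * pi
  cbind(theta = theta, phi = phi)
}

#' Convert spherical angles to unit Cartesian directions
#'
#' @param theta Polar angles in radians.
#' @param phi Azimuths in radians.
#' @return `n x 3` matrix of unit vectors.
#' @export
sph_to_cart <- function(theta, phi) {
  cbind(x = sin(theta) * cos(phi), y = sin(theta) * sin(phi), z = cos(theta))
}

as_dir_matrix <- function(dirs, check_unit = TRUE) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, nrow = 1L)
  dirs <- as.matrix(dirs)
  if (ncol(dirs) != 3L) stop("directions must be n x 3", call. = FALSE)
  if (check_unit) {
    nrm <- sqrt(rowSums(dirs^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("directions must be unit vectors", call. = FALSE)
  }
  dirs
}

#' Evaluate the real even-order SH basis at a set of directions
#'
#' @param dirs `n x 3` matrix of unit direction vectors.
#' @param lmax Maximum even harmonic order.
#' @return `n x n_coeffs(lmax)` matrix; column `j` holds the basis function
#'   of the `(l, m)` pair at position `j` of the storage order.
#' @examples
#' B <- sh_basis(rbind(c(0, 0, 1)), 4)
#' B[1, 1] # 1 / (2 sqrt(pi))
#' @export
sh_basis <- function(dirs, lmax) {
  check_lmax(lmax)
  dirs <- as_dir_matrix(dirs)
  ang <- cart_to_sph(dirs)
  P <- legendre_norm(lmax, cos(ang[, "theta"]))
  n <- nrow(dirs)
  out <- matrix(0, n, n_coeffs(lmax))
  deg <- sh_degrees(lmax)
  for (j in seq_len(nrow(deg))) {
    l <- deg$l[j]; m <- deg$m[j]
    if (m == 0L) {
      out[, j] <- P[, l + 1L, 1L]
    } else if (m > 0L) {
      out[, j] <- sqrt(2) * P[, l + 1L, m + 1L] * cos(m * ang[, "phi"])
    } else {
      out[, j] <- sqrt(2) * P[, l + 1L, -m + 1L] * sin(-m * ang[, "phi"])
    }
  }
  out
}

#' Evaluate a spherical function from its SH coefficients
#'
#' @param coeffs Coefficient vector (length `n_coeffs(lmax)`) or a matrix with
#'   one coefficient vector per row.
#' @param dirs `n x 3` unit directions.
#' @param lmax Maximum even order; inferred from the coefficient length when
#'   omitted.
#' @return If `coeffs` is a vector, a length-`n` amplitude vector; if a
#'   matrix, an `nrow(coeffs) x n` amplitude matrix.
#' @export
sh_eval <- function(coeffs, dirs, lmax = NULL) {
  if (is.null(dim(coeffs))) {
    if (is.null(lmax)) lmax <- lmax_from_ncoef(length(coeffs))
    drop(sh_basis(dirs, lmax) %*% coeffs)
  } else {
    if (is.null(lmax)) lmax <- lmax_from_ncoef(ncol(coeffs))
    coeffs %*% t(sh_basis(dirs, lmax))
  }
}

lmax_from_ncoef <- function(nc) {
  lmax <- (-3 + sqrt(1 + 8 * nc)) / 2
  if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0)
    stop("coefficient length does not match an even lmax", call. = FALSE)
  as.integer(round(lmax))
}

#' Least-squares SH fit of sampled amplitudes
#'
#' Solves `sh_basis(dirs, lmax) %*% c ~ amplitudes` in the least-squares
#' sense, optionally with a Tikhonov ridge.
#'
#' @param amplitudes Amplitude vector (length `n`) or `k x n` matrix of `k`
#'   spherical functions sampled at the same directions.
#' @param dirs `n x 3` unit directions.
#' @param lmax Maximum even order of the fit.
#' @param regularization Non-negative ridge weight added as
#'   `regularization * I` to the normal equations.
#' @return Coefficient vector (or `k x n_coeffs` matrix).
#' @export
sh_fit <- function(amplitudes, dirs, lmax, regularization = 0) {
  B <- sh_basis(dirs, lmax)
  nc <- ncol(B)
  if (regularization == 0 && nrow(B) < nc)
    stop("under-determined SH fit: need n_dirs >= n_coeffs or regularization > 0",
         call. = FALSE)
  A <- crossprod(B) + diag(regularization, nc)
  ok <- tryCatch({ R <- chol(A); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("ill-conditioned SH fit; increase 'regularization' or direction count",
         call. = FALSE)
  if (is.null(dim(amplitudes))) {
    drop(backsolve(R, forwardsolve(t(R), crossprod(B, amplitudes))))
  } else {
    t(backsolve(R, forwardsolve(t(R), t(amplitudes %*% B))))
  }
}

#' Per-order scale factors of spherical convolution with a zonal kernel
#'
#' @param lmax Maximum even order.
#' @return Vector of `sqrt(4*pi / (2l+1))` repeated over the `m` positions of
#'   each even order `l`, in storage order.
#' @keywords internal
convolution_scale <- function(lmax) {
  deg <- sh_degrees(lmax)
  sqrt(4 * pi / (2 * deg$l + 1))
}

expand_zonal <- function(r, lmax) {
  ## r: one value per even l (l = 0, 2, ..., lmax_r); truncate/zero-pad to lmax
  deg <- sh_degrees(lmax)
  ridx <- deg$l / 2 + 1
  out <- numeric(nrow(deg))
  avail <- ridx <= length(r)
  out[avail] <- r[ridx[avail]]
  out
}

#' Spherical convolution with an axially symmetric (zonal) kernel
#'
#' Implements the per-coefficient form of spherical convolution:
#' `s_lm = sqrt(4*pi/(2l+1)) * f_lm * r_l0`, where `r_l0` are the zonal
#' harmonic coefficients of the kernel. This is the CSD forward model relating
#' an FOD to the diffusion signal through the tissue response function.
#'
#' @param fod SH coefficient vector of the spherical function being convolved.
#' @param response Zonal coefficients, one per even order
#'   (`l = 0, 2, ..., lmax_r`). If shorter than the FOD's order range the
#'   missing orders are treated as zero; if longer it is truncated.
#' @return SH coefficient vector of the convolved function, same length as
#'   `fod`.
#' @export
sh_convolve <- function(fod, response) {
  lmax <- lmax_from_ncoef(length(fod))
  fod * convolution_scale(lmax) * expand_zonal(response, lmax)
}

#' SH coefficients of a band-limited Dirac delta
#'
#' The projection of a symmetric Dirac delta oriented along `dir` onto the
#' even-order basis: coefficient `j` equals the basis function `j` evaluated
#' at `dir` (in the axis-aligned frame only the `m = 0` terms are nonzero,
#' with value `sqrt((2l+1)/(4*pi))`).
#'
#' @param lmax Maximum even order.
#' @param dir Unit direction of the delta.
#' @return SH coefficient vector.
#' @export
delta_coeffs <- function(lmax, dir) {
  drop(sh_basis(matrix(dir, 1L), lmax))
}

#' Apodized delta kernel coefficients
#'
#' A band-limited delta has negative ringing; for constructions that need a
#' non-negative, sharply peaked spherical function (e.g. ground-truth FODs) a
#' per-order taper is applied, derived from the zonal projection of the Watson
#' kernel `exp(-kappa * sin^2 theta)` normalized to unit integral. `kappa` is
#' chosen as the largest value (on a fixed grid) whose band-limited kernel
#' stays above `-1e-7` of its peak.
#'
#' @param lmax Maximum even order.
#' @param dir Unit direction of the peak.
#' @return SH coefficient vector of a non-negative, unit-integral,
#'   single-peaked spherical function aligned with `dir`.
#' @export
apodized_delta <- function(lmax, dir) {
  taper <- apodization_taper(lmax)
  delta_coeffs(lmax, dir) * expand_zonal(taper, lmax)
}

## cache for per-lmax tapers
.fodinr_cache <- new.env(parent = emptyenv())

apodization_taper <- function(lmax) {
  key <- paste0("taper", lmax)
  if (!is.null(.fodinr_cache[[key]])) return(.fodinr_cache[[key]])
  gl <- pracma::gaussLegendre(64, -1, 1)
  tfine <- seq(-1, 1, length.out = 2001)
  ls <- seq(0L, lmax, by = 2L)
  best <- NULL
  for (kappa in seq(1, 60, by = 0.5)) {
    w <- exp(-kappa * (1 - gl$x^2))
    ## zonal coefficients of the Watson kernel (axially symmetric):
    ## c_l = 2*pi * integral w(t) Pbar_l^0(t) dt
    P <- legendre_norm(lmax, gl$x)
    cl <- vapply(ls, function(l) 2 * pi * sum(gl$w * w * P[, l + 1L, 1L]), 0)
    ## normalize to unit integral: integral = c_0 * sqrt(4*pi) * Y00 * 4pi/...
    ## integral of the band-limited kernel over the sphere = c_0 * sqrt(4*pi)
    cl <- cl / (cl[1L] * sqrt(4 * pi))
    ## band-limited kernel on a fine grid
    Pf <- legendre_norm(lmax, tfine)
    vals <- as.vector(Pf[, ls + 1L, 1L] %*% cl)
    if (min(vals) >= -1e-7 * max(vals)) best <- cl else break
  }
  ## taper_l = zonal coefficients of the unit-integral Watson kernel divided
  ## by those of the unit-integral band-limited delta, sqrt((2l+1)/(4*pi))
  taper <- best / sqrt((2 * ls + 1) / (4 * pi))
  .fodinr_cache[[key]] <- taper
  taper
}

## ---- direction sets ----------------------------------------------------

#' Near-uniform points on the sphere or hemisphere (Fibonacci lattice)
#'
#' @param n Number of points.
#' @param hemisphere If `TRUE`, points are folded to the `z >= 0` hemisphere.
#' @return `n x 3` matrix of unit vectors. Deterministic.
#' @export
fibonacci_sphere <- function(n, hemisphere = FALSE) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  d <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  if (hemisphere) d[d[, 3L] < 0, ] <- -d[d[, 3L] < 0, ]
  d
}

#' Electrostatic-repulsion gradient direction set
#'
#' Minimizes the Coulomb energy of the antipodally symmetrized point set
#' (pairwise `1/r` over both each pair and its antipodes) by projected
#' gradient descent from a seeded random start. This is the standard
#' construction for uniform diffusion-gradient schemes.
#'
#' @param n Number of directions (hemisphere representatives).
#' @param seed Integer seed for the random initialization.
#' @param n_iter Number of descent iterations.
#' @return `n x 3` matrix of unit vectors with non-negative `z`.
#' @export
repulsion_directions <- function(n, seed = 0L, n_iter = 300L) {
  set.seed(seed)
  x <- matrix(stats::rnorm(3L * n), n, 3L)
  x <- x / sqrt(rowSums(x^2))
  step <- 0.05
  energy <- function(p) {
    e <- 0
    for (a in seq_len(n - 1L)) {
      d1 <- sqrt(colSums((t(p[(a + 1L):n, , drop = FALSE]) - p[a, ])^2))
      d2 <- sqrt(colSums((t(p[(a + 1L):n, , drop = FALSE]) + p[a, ])^2))
      e <- e + sum(1 / d1 + 1 / d2)
    }
    e
  }
  e_old <- energy(x)
  for (it in seq_len(n_iter)) {
    g <- matrix(0, n, 3L)
    for (a in seq_len(n)) {
      diff1 <- sweep(x, 2L, x[a, ])            # x_b - x_a
      diff2 <- sweep(x, 2L, -x[a, ])           # x_b + x_a
      r1 <- sqrt(rowSums(diff1^2)); r1[a] <- Inf
      r2 <- sqrt(rowSums(diff2^2)); r2[r2 < 1e-12] <- Inf
      ## force on a: sum (x_a - x_b)/r^3 + (x_a + x_b)/r^3
      g[a, ] <- -colSums(diff1 / r1^3) + colSums(diff2 / r2^3)
    }
    xn <- x + step * g
    xn <- xn / sqrt(rowSums(xn^2))
    e_new <- energy(xn)
    if (e_new < e_old) {
      x <- xn; e_old <- e_new; step <- step * 1.1
    } else {
      step <- step / 2
      if (step < 1e-8) break
    }
  }
  x[x[, 3L] < 0, ] <- -x[x[, 3L] < 0, ]
  x
}

#' The packaged 724-point antipodally symmetric direction set
#'
#' 362 hemisphere directions (electrostatic-repulsion optimized, shipped as a
#' plain-text fixture) mirrored through the origin. Used for the
#' non-negativity constraint, FOD peak finding, and as a dense evaluation set.
#'
#' @return `724 x 3` matrix of unit vectors.
#' @export
constraint_directions <- function() {
  if (is.null(.fodinr_cache$dirs724)) {
    f <- system.file("extdata", "dirs362.txt", package = "fodinr")
    h <- if (nzchar(f)) as.matrix(utils::read.table(f)) else
      repulsion_directions(362L, seed = 362L)
    h <- unname(h)
    .fodinr_cache$dirs724 <- rbind(h, -h)
  }
  .fodinr_cache$dirs724
}

## Product quadrature over the sphere: Gauss-Legendre in cos(theta),
## trapezoid (exact for trigonometric polynomials) in phi. Exact for
## band-limited functions up to high order; used as the integration oracle.
sphere_quadrature <- function(n_theta = 32L, n_phi = 64L) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  t <- rep(gl$x, times = n_phi)
  p <- rep(phi, each = n_theta)
  w <- rep(gl$w, times = n_phi) * (2 * pi / n_phi)
  theta <- acos(t)
  list(dirs = sph_to_cart(theta, p), w = w)
}
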