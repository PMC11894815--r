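## Continuous querying of a fitted model: supersampled grids, line samples,
## and the linear SH-interpolation comparison baseline.

#' Supersample a fitted model onto a finer grid
#'
#' Each voxel of the fitted grid is subdivided `factor` times per axis; the
#' model is evaluated at the centers of the fine voxels (in world space, so
#' the encoding is not re-normalized) and the affine updated so the fine
#' voxel centers land exactly where the subdivision puts them.
#'
#' @param object An `inr_fod` fit.
#' @param factor Integer subdivision factor per axis (> 1).
#' @return List with `field` (4D coefficient array on the fine grid) and
#'   `affine` (fine-grid voxel-to-world matrix).
#' @export
supersample_grid <- function(object, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 2L) stop("factor must be an integer > 1", call. = FALSE)
  fine <- refine_affine(object$affine, factor)
  dim_f <- object$dim3 * factor
  coords <- voxel_centers(dim_f, fine)
  K <- predict(object, coords)
  list(field = array(K, c(dim_f, ncol(K))), affine = fine)
}

## affine of the factor-times subdivided grid: fine voxel j covers original
## voxel floor(j/f); centers offset so the union of fine centers tiles each
## coarse voxel symmetrically.
refine_affine <- function(affine, factor) {
  fine <- affine
  fine[1:3, 1:3] <- affine[1:3, 1:3] / factor
  shift <- affine[1:3, 1:3] %*% rep((1 - factor) / (2 * factor), 3L)
  fine[1:3, 4L] <- affine[1:3, 4L] + shift
  fine
}

#' Sample a fitted model along the segment between two voxels
#'
#' @param object An `inr_fod` fit.
#' @param voxel_a,voxel_b 0-based voxel indices (length-3) of the endpoints.
#' @param n_steps Number of equidistant samples, endpoints included
#'   (`>= 2`).
#' @return List with `coords` (`n_steps x 3` world coordinates) and `K`
#'   (coefficient matrix).
#' @export
line_sample <- function(object, voxel_a, voxel_b, n_steps = 10L) {
  if (n_steps < 2L) stop("n_steps must be >= 2", call. = FALSE)
  wa <- drop(object$affine %*% c(voxel_a, 1))[1:3]
  wb <- drop(object$affine %*% c(voxel_b, 1))[1:3]
  t <- seq(0, 1, length.out = n_steps)
  coords <- cbind(wa[1L] + t * (wb[1L] - wa[1L]),
                  wa[2L] + t * (wb[2L] - wa[2L]),
                  wa[3L] + t * (wb[3L] - wa[3L]))
  list(coords = coords, K = predict(object, coords))
}

#' Trilinear interpolation of an SH coefficient image onto a finer grid
#'
#' Per-coefficient trilinear interpolation -- the conventional way to obtain
#' FODs off voxel centers from a voxel-wise fit, and the comparison baseline
#' for the spatial experiments. Fine-grid centers outside the coarse center
#' hull are clamped to the hull (nearest-edge extrapolation).
#'
#' @param field 4D coefficient array `[X, Y, Z, n_coeffs]`.
#' @param factor Integer subdivision factor per axis.
#' @return List with `field` (fine-grid 4D array) and the relative fine
#'   positions used.
#' @export
interpolate_sh_linear <- function(field, factor = 2L) {
  factor <- as.integer(factor)
  d3 <- dim(field)[1:3]
  nc <- dim(field)[4L]
  dim_f <- d3 * factor
  ## fine voxel center positions in coarse voxel coordinates (0-based)
  pos <- lapply(1:3, function(ax)
    ((seq_len(dim_f[ax]) - 0.5) / factor) - 0.5)
  g <- as.matrix(expand.grid(x = pos[[1L]], y = pos[[2L]], z = pos[[3L]]))
  out <- matrix(0, nrow(g), nc)
  i0 <- pmin(pmax(floor(g), 0), matrix(rep(d3 - 2L, each = nrow(g)), ncol = 3L))
  fr <- pmin(pmax(g - i0, 0), 1)
  fl <- matrix(field, prod(d3), nc)
  idx <- function(i, j, k) 1L + i + d3[1L] * (j + d3[2L] * k)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[, 1L] else 1 - fr[, 1L]) *
         (if (dy) fr[, 2L] else 1 - fr[, 2L]) *
         (if (dz) fr[, 3L] else 1 - fr[, 3L])
    out <- out + w * fl[idx(i0[, 1L] + dx, i0[, 2L] + dy, i0[, 3L] + dz), ,
                        drop = FALSE]
  }
  list(field = array(out, c(dim_f, nc)), positions = g)
}
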