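## Voxel-wise single-shell constrained spherical deconvolution (the
## comparator to the continuous fit): iteratively reweighted soft-constrained
## least squares after Tournier et al.'s scheme.

#' Constrained spherical deconvolution of one voxel
#'
#' (1) An initial FOD is obtained by unconstrained low-order (`lmax = 4`)
#' deconvolution through the zonal-convolution scaling; (2) amplitudes are
#' evaluated on the packaged 724-direction set and directions below
#' `threshold_factor` times the mean initial amplitude are flagged (the
#' threshold is frozen at iteration 0); (3) the regularized normal equations
#' combining data fidelity and the flagged-amplitude soft constraint are
#' re-solved until the flagged set stops changing or `max_iter` is reached.
#'
#' @param signal Signal amplitudes on one shell (length `n_dirs`).
#' @param dirs `n_dirs x 3` unit gradient directions.
#' @param response Zonal response coefficients of the shell (one value per
#'   even order).
#' @param lmax Maximum even order of the FOD.
#' @param lambda Soft-constraint weight.
#' @param threshold_factor Constraint threshold as a fraction of the initial
#'   FOD's mean amplitude.
#' @param max_iter Iteration cap.
#' @param constrained Disable the constraint (`FALSE`) to obtain the
#'   closed-form least-squares deconvolution.
#' @return List with `coeffs` (SH coefficient vector), `iterations`,
#'   `converged`.
#' @export
csd_fit_voxel <- function(signal, dirs, response, lmax = 8L, lambda = 1,
                          threshold_factor = 0.1, max_iter = 50L,
                          constrained = TRUE) {
  dirs <- as_dir_matrix(dirs)
  if (length(signal) != nrow(dirs))
    stop("signal/direction count mismatch", call. = FALSE)
  if (nrow(dirs) < 6L) stop("need at least 6 directions", call. = FALSE)
  B <- sh_basis(dirs, lmax)
  conv <- convolution_scale(lmax) * expand_zonal(response, lmax)
  C <- sweep(B, 2L, conv, "*")
  if (!constrained) {
    return(list(coeffs = qr.solve(C, signal), iterations = 0L, converged = TRUE))
  }
  ## initial lmax = 4 unconstrained fit (ridge guards rank deficiency, e.g.
  ## an isotropic response zeroing all l > 0 columns)
  l4 <- min(lmax, 4L)
  nc4 <- n_coeffs(l4)
  C4 <- C[, seq_len(nc4), drop = FALSE]
  G4 <- crossprod(C4)
  ridge <- 1e-8 * mean(diag(G4))
  f0 <- numeric(n_coeffs(lmax))
  f0[seq_len(nc4)] <- solve(G4 + diag(ridge, nc4), crossprod(C4, signal))
  P <- sh_basis(constraint_directions(), lmax)
  tau <- threshold_factor * mean(P %*% f0)
  CtC <- crossprod(C)
  Cts <- crossprod(C, signal)
  f <- f0
  flag_old <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- drop(P %*% f)
    flag <- which(A < tau)
    if (identical(flag, flag_old)) { converged <- TRUE; break }
    flag_old <- flag
    Pf <- P[flag, , drop = FALSE]
    H <- CtC + lambda^2 * crossprod(Pf)
    f <- tryCatch(solve(H, Cts), error = function(e)
      solve(H + diag(1e-10, ncol(H)), Cts))
    f <- drop(f)
  }
  if (!converged)
    warning("CSD did not converge within ", max_iter, " iterations")
  list(coeffs = f, iterations = it, converged = converged)
}

#' Voxel-wise CSD over a volume
#'
#' Independent per-voxel fits on a single shell; the result does not depend
#' on voxel visit order.
#'
#' @param data 4D signal array.
#' @param gtab The matching [gradient_table()].
#' @param shell Nominal b-value of the fitted shell.
#' @param response Zonal response coefficients for that shell (vector), or a
#'   [make_responses()] result (the WM row of the shell is used).
#' @param mask Optional 3D mask; voxels outside get zero coefficients.
#' @param lmax,lambda,threshold_factor,max_iter See [csd_fit_voxel()].
#' @return List with `field` (4D coefficient array) and `qc` (3D integer
#'   array: iterations used, negative when unconverged).
#' @export
csd_fit_volume <- function(data, gtab, shell, response, mask = NULL,
                           lmax = 8L, lambda = 1, threshold_factor = 0.1,
                           max_iter = 50L) {
  idx <- shell_indices(gtab, shell)
  dirs <- gtab$bvecs[idx, , drop = FALSE]
  if (inherits(response, "response_set")) {
    rrow <- which.min(abs(response$bvals - gtab$shells[which.min(abs(gtab$shells - shell))]))
    response <- response$wm[rrow, ]
  }
  d3 <- dim(data)[1:3]
  nvox <- prod(d3)
  S <- matrix(data, nvox, dim(data)[4L])[, idx, drop = FALSE]
  vox <- if (is.null(mask)) seq_len(nvox) else which(as.logical(mask))
  out <- matrix(0, nvox, n_coeffs(lmax))
  qc <- integer(nvox)
  for (v in vox) {
    fit <- withCallingHandlers(
      csd_fit_voxel(S[v, ], dirs, response, lmax, lambda, threshold_factor,
                    max_iter),
      warning = function(w) invokeRestart("muffleWarning"))
    out[v, ] <- fit$coeffs
    qc[v] <- if (fit$converged) fit$iterations else -fit$iterations
  }
  list(field = array(out, c(d3, n_coeffs(lmax))), qc = array(qc, d3))
}
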