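## FOD evaluation metrics: angular correlation coefficient (ACC), apparent
## fiber density (AFD), number of fiber orientations (NuFO), and field-level
## summaries.

#' Metrics configuration
#'
#' @param afd_peak_threshold Absolute amplitude a peak must reach to count
#'   toward NuFO.
#' @param wm_mask_threshold Ground-truth `f00` above which a voxel enters the
#'   evaluation mask.
#' @param peak_separation Minimum angular separation between counted peaks,
#'   degrees.
#' @param neighbor_angle Angular radius of the local-maximum neighborhood on
#'   the dense direction set, degrees.
#' @return List of class `metrics_config`.
#' @export
metrics_config <- function(afd_peak_threshold = 0.07, wm_mask_threshold = 0.05,
                           peak_separation = 25, neighbor_angle = 12) {
  stopifnot(afd_peak_threshold > 0, wm_mask_threshold > 0,
            peak_separation > 0, neighbor_angle > 0)
  structure(list(afd_peak_threshold = afd_peak_threshold,
                 wm_mask_threshold = wm_mask_threshold,
                 peak_separation = peak_separation,
                 neighbor_angle = neighbor_angle),
            class = "metrics_config")
}

#' Angular correlation coefficient of two SH series
#'
#' Normalized inner product of the anisotropic (`l >= 2`) coefficients;
#' the isotropic term is excluded, so ACC measures angular profile agreement
#' irrespective of FOD scale. Bounded in `[-1, 1]`.
#'
#' @param u,v SH coefficient vectors of equal `lmax`.
#' @return Scalar in `[-1, 1]`, or `NA` when either argument has no
#'   anisotropic energy (undefined).
#' @export
acc <- function(u, v) {
  if (length(u) != length(v)) stop("coefficient lengths differ", call. = FALSE)
  u2 <- u[-1L]; v2 <- v[-1L]
  nu <- sum(u2^2); nv <- sum(v2^2)
  if (nu == 0 || nv == 0) return(NA_real_)
  max(-1, min(1, sum(u2 * v2) / sqrt(nu * nv)))
}

## vectorized ACC over coefficient matrices (rows = voxels)
acc_rows <- function(U, V) {
  U2 <- U[, -1L, drop = FALSE]; V2 <- V[, -1L, drop = FALSE]
  nu <- rowSums(U2^2); nv <- rowSums(V2^2)
  out <- rowSums(U2 * V2) / sqrt(nu * nv)
  out[nu == 0 | nv == 0] <- NA_real_
  pmax(-1, pmin(1, out))
}

#' Total apparent fiber density
#'
#' @param coeffs SH coefficient vector (or matrix, rows = voxels).
#' @return The first (`l = 0`) coefficient per FOD.
#' @export
afd_total <- function(coeffs) {
  if (is.null(dim(coeffs))) unname(coeffs[1L]) else unname(coeffs[, 1L])
}

#' Number of fiber orientations of an FOD
#'
#' Amplitudes are evaluated on the packaged dense antipodally symmetric
#' direction set; local maxima over the hemisphere neighbor graph are kept if
#' they reach the absolute amplitude threshold, then thinned greedily (by
#' descending amplitude) to enforce the minimum pairwise separation.
#'
#' @param coeffs SH coefficient vector of the FOD.
#' @param cfg A [metrics_config()].
#' @return Integer peak count.
#' @export
nufo <- function(coeffs, cfg = metrics_config()) {
  pk <- fod_peaks(coeffs, cfg, refine = FALSE) # counting needs no refinement
  nrow(pk$dirs)
}

#' Peak directions of an FOD
#'
#' Discrete maxima on the dense set are refined by two stages of local cap
#' search (unless `refine = FALSE`), giving sub-degree angular resolution —
#' the dense set itself has a mean spacing of about 7.7 degrees.
#'
#' @inheritParams nufo
#' @param refine Refine each peak beyond the dense-set resolution.
#' @return List with `dirs` (`k x 3` unit vectors, descending amplitude) and
#'   `amplitudes`.
#' @export
fod_peaks <- function(coeffs, cfg = metrics_config(), refine = TRUE) {
  hemi <- peak_graph(cfg)
  A <- sh_eval(coeffs, hemi$dirs)
  is_max <- vapply(seq_along(A), function(i)
    A[i] >= max(A[hemi$nb[[i]]]) - 1e-12, TRUE)
  cand <- which(is_max & A >= cfg$afd_peak_threshold)
  cand <- cand[order(A[cand], decreasing = TRUE)]
  sel <- integer()
  min_cos <- cos(cfg$peak_separation * pi / 180)
  for (i in cand) {
    if (!length(sel) ||
        all(abs(hemi$dirs[sel, , drop = FALSE] %*% hemi$dirs[i, ]) < min_cos))
      sel <- c(sel, i)
  }
  dirs <- hemi$dirs[sel, , drop = FALSE]
  amps <- A[sel]
  if (refine && length(sel)) {
    for (k in seq_along(sel)) {
      r <- refine_peak(coeffs, dirs[k, ])
      dirs[k, ] <- r$dir
      amps[k] <- r$amplitude
    }
  }
  list(dirs = dirs, amplitudes = amps)
}

## two-stage cap search around a starting direction
refine_peak <- function(coeffs, v, caps = c(6, 1, 0.2), n_cap = 120L) {
  for (alpha in caps * pi / 180) {
    e1 <- if (abs(v[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * v) * v; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(v[2L] * e1[3L] - v[3L] * e1[2L], v[3L] * e1[1L] - v[1L] * e1[3L],
            v[1L] * e1[2L] - v[2L] * e1[1L])
    i <- seq_len(n_cap)
    th <- alpha * sqrt(i / n_cap)
    phi <- pi * (1 + sqrt(5)) * i
    pts <- rbind(v, outer(cos(th), v) +
                   sin(th) * (cos(phi) %o% e1 + sin(phi) %o% e2))
    a <- sh_eval(coeffs, pts)
    v <- pts[which.max(a), ]
  }
  list(dir = v, amplitude = max(a))
}

## hemisphere directions + neighbor lists, cached per neighbor angle
peak_graph <- function(cfg) {
  key <- paste0("peaks", cfg$neighbor_angle)
  if (is.null(.fodinr_cache[[key]])) {
    dirs <- constraint_directions()
    hemi <- dirs[dirs[, 3L] >= 0, , drop = FALSE]
    ## antipodal-aware angular proximity
    ct <- abs(tcrossprod(hemi))
    thr <- cos(cfg$neighbor_angle * pi / 180)
    nb <- lapply(seq_len(nrow(hemi)), function(i) {
      j <- which(ct[i, ] >= thr)
      setdiff(j, i)
    })
    .fodinr_cache[[key]] <- list(dirs = hemi, nb = nb)
  }
  .fodinr_cache[[key]]
}

#' Evaluate an estimated FOD field against the phantom ground truth
#'
#' Restricts to voxels where the ground-truth WM `f00` exceeds the mask
#' threshold, then reports mean and SD of the ACC, mean and SD of the AFD
#' (both fields), the mean absolute AFD error, the NuFO histogram of both
#' fields (counts at 0..4 and 5+), and voxel counts. ACC-undefined voxels
#' are excluded from the ACC average and counted.
#'
#' @param estimate 4D WM coefficient array (or matrix of row-coefficients in
#'   grid order) on the same grid as the truth.
#' @param truth A [make_phantom()] result (or a 4D ground-truth coefficient
#'   array).
#' @param cfg A [metrics_config()].
#' @param with_nufo Compute the NuFO histograms (the slowest part).
#' @return List of class `fod_evaluation`.
#' @export
evaluate_field <- function(estimate, truth, cfg = metrics_config(),
                           with_nufo = TRUE) {
  tf <- if (inherits(truth, "phantom_truth")) truth$fod else truth
  d3 <- dim(tf)[1:3]
  nc <- dim(tf)[4L]
  Tm <- matrix(tf, prod(d3), nc)
  Em <- if (is.null(dim(estimate)) || length(dim(estimate)) == 2L)
    as.matrix(estimate) else matrix(estimate, prod(dim(estimate)[1:3]),
                                    dim(estimate)[4L])
  Em <- Em[, seq_len(nc), drop = FALSE]
  if (nrow(Em) != nrow(Tm)) stop("grid mismatch", call. = FALSE)
  mask <- Tm[, 1L] > cfg$wm_mask_threshold
  a <- acc_rows(Em[mask, , drop = FALSE], Tm[mask, , drop = FALSE])
  afd_e <- Em[mask, 1L]; afd_t <- Tm[mask, 1L]
  hist6 <- function(counts) {
    k <- pmin(counts, 5L)
    tabulate(k + 1L, nbins = 6L)
  }
  nufo_e <- nufo_t <- NULL
  if (with_nufo) {
    nufo_e <- hist6(apply(Em[mask, , drop = FALSE], 1L, nufo, cfg = cfg))
    nufo_t <- hist6(apply(Tm[mask, , drop = FALSE], 1L, nufo, cfg = cfg))
  }
  structure(list(
    n_voxels = sum(mask), n_acc_undefined = sum(is.na(a)),
    acc_mean = mean(a, na.rm = TRUE), acc_sd = stats::sd(a, na.rm = TRUE),
    afd_mean = mean(afd_e), afd_sd = stats::sd(afd_e),
    afd_true_mean = mean(afd_t), afd_true_sd = stats::sd(afd_t),
    afd_mae = mean(abs(afd_e - afd_t)),
    nufo_estimate = nufo_e, nufo_truth = nufo_t,
    cfg = cfg), class = "fod_evaluation")
}

#' @export
print.fod_evaluation <- function(x, ...) {
  cat(sprintf("FOD evaluation over %d masked voxels (%d ACC-undefined)\n",
              x$n_voxels, x$n_acc_undefined))
  cat(sprintf("  ACC  %.3f +/- %.3f\n", x$acc_mean, x$acc_sd))
  cat(sprintf("  AFD  %.3f +/- %.3f (truth %.3f +/- %.3f), MAE %.4f\n",
              x$afd_mean, x$afd_sd, x$afd_true_mean, x$afd_true_sd, x$afd_mae))
  if (!is.null(x$nufo_estimate)) {
    cat("  NuFO (0..4, 5+): estimate", paste(x$nufo_estimate, collapse = " "),
        "\n                   truth   ", paste(x$nufo_truth, collapse = " "), "\n")
  }
  invisible(x)
}
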