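## Gaussian random Fourier positional encoding of 3D coordinates.

#' Create a Fourier positional encoding
#'
#' Frequencies are drawn once from `N(0, sigma^2)` and frozen; coordinates
#' are normalized per axis to `[-1, 1]` over the supplied bounding box before
#' encoding. The encoded vector is `[cos(2*pi*B*x), sin(2*pi*B*x)]` of length
#' `2 * np`.
#'
#' @param np Number of random frequencies (rows of the frequency matrix).
#' @param sigma Standard deviation of the Gaussian the frequencies are drawn
#'   from; larger values let the network represent finer spatial detail.
#' @param bbox `2 x 3` matrix: rows are the world-space minimum and maximum
#'   of the fitted volume's voxel centers.
#' @param seed Integer seed; the encoding is deterministic given the seed.
#' @return Object of class `fourier_encoding`.
#' @export
fourier_encoding <- function(np, sigma, bbox, seed = 0L) {
  if (np < 1L) stop("np must be >= 1", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  bbox <- as.matrix(bbox)
  if (!all(dim(bbox) == c(2L, 3L)) || any(bbox[2L, ] - bbox[1L, ] <= 0))
    stop("bbox must be 2 x 3 with positive extent on every axis", call. = FALSE)
  set.seed(seed)
  B <- matrix(stats::rnorm(np * 3L, sd = sigma), np, 3L)
  structure(list(B = B, np = as.integer(np), sigma = sigma,
                 bbox = unname(bbox), seed = as.integer(seed)),
            class = "fourier_encoding")
}

#' Encode world coordinates
#'
#' @param enc A [fourier_encoding()].
#' @param x `n x 3` matrix of world coordinates (or length-3 vector). Points
#'   outside the bounding box are extrapolated (the normalization is affine).
#' @return `n x 2*np` matrix, entries in `[-1, 1]`.
#' @export
encode <- function(enc, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  lo <- enc$bbox[1L, ]; hi <- enc$bbox[2L, ]
  xn <- sweep(sweep(x, 2L, lo), 2L, (hi - lo) / 2, "/") - 1
  arg <- 2 * pi * tcrossprod(xn, enc$B)
  cbind(cos(arg), sin(arg))
}
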