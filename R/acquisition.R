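## Gradient tables, DWI / response / SH-image I/O, angular subsampling.

#' Construct a gradient table
#'
#' Groups b-values into shells within a tolerance and validates the b-vectors.
#' b = 0 rows may carry zero vectors; all others must be unit within 1e-3.
#'
#' @param bvecs `n x 3` matrix of gradient directions.
#' @param bvals Length-`n` vector of b-values in s/mm^2.
#' @param shell_tolerance b-values closer than this are grouped into one
#'   shell (s/mm^2).
#' @param b0_threshold b-values at or below this count as b = 0.
#' @return An object of class `gradient_table`: list with `bvecs`, `bvals`,
#'   `shells` (sorted unique nominal b-values, b=0 first when present) and
#'   `shell_id` (1-based index into `shells` per volume).
#' @export
gradient_table <- function(bvecs, bvals, shell_tolerance = 50, b0_threshold = 50) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stop("'bvecs' must be n x 3", call. = FALSE)
  bvals <- as.numeric(bvals)
  if (nrow(bvecs) != length(bvals))
    stop("'bvecs' and 'bvals' lengths differ", call. = FALSE)
  if (any(bvals < 0)) stop("negative b-values", call. = FALSE)
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > b0_threshold
  if (any(abs(nrm[dw] - 1) > 1e-3))
    stop("diffusion-weighted b-vectors must be unit length (tol 1e-3)", call. = FALSE)
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  ## cluster b-values into shells
  b <- bvals
  b[!dw] <- 0
  ub <- sort(unique(b))
  shells <- ub[1L]
  for (x in ub[-1L]) if (x - shells[length(shells)] > shell_tolerance)
    shells <- c(shells, x)
  shell_id <- vapply(b, function(x) which.min(abs(shells - x)), 0L)
  ## nominal shell value: mean of members
  shells <- vapply(seq_along(shells), function(i) mean(b[shell_id == i]), 0)
  structure(list(bvecs = unname(bvecs), bvals = bvals, shells = shells,
                 shell_id = as.integer(shell_id)),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("Gradient table:", length(x$bvals), "volumes,", length(x$shells), "shells\n")
  for (i in seq_along(x$shells))
    cat(sprintf("  b = %.0f s/mm^2: %d directions\n",
                x$shells[i], sum(x$shell_id == i)))
  invisible(x)
}

#' Indices of volumes belonging to one shell
#'
#' @param gtab A [gradient_table()].
#' @param b Nominal b-value of the shell (matched within the table's shell
#'   spacing).
#' @return Integer vector of volume indices.
#' @export
shell_indices <- function(gtab, b) {
  i <- which.min(abs(gtab$shells - b))
  if (abs(gtab$shells[i] - b) > 100)
    stop("no shell near b = ", b, call. = FALSE)
  which(gtab$shell_id == i)
}

#' Read FSL-style bval/bvec files
#'
#' @param bval_path,bvec_path Paths to whitespace-delimited text files. The
#'   bvec file may be 3 x n (FSL) or n x 3; the orientation is disambiguated
#'   from the shape.
#' @return A [gradient_table()].
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) == 3L && ncol(bv) != 3L) bv <- t(bv)
  if (nrow(bv) == 3L && ncol(bv) == 3L) bv <- t(bv) # ambiguous: assume FSL 3 x 3
  if (ncol(bv) != 3L) stop("bvec file is not 3 x n or n x 3", call. = FALSE)
  if (nrow(bv) != length(bvals))
    stop("bval/bvec volume counts differ (", length(bvals), " vs ", nrow(bv), ")",
         call. = FALSE)
  gradient_table(bv, bvals)
}

#' Write FSL-style bval/bvec files
#'
#' @param gtab A [gradient_table()].
#' @param bval_path,bvec_path Output paths (bvec written 3 x n).
#' @export
write_bvals_bvecs <- function(gtab, bval_path, bvec_path) {
  cat(paste(format(gtab$bvals, trim = TRUE), collapse = " "), "\n",
      file = bval_path, sep = "")
  write.table(t(gtab$bvecs), bvec_path, row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a 4D diffusion-weighted NIfTI volume with its gradient table
#'
#' @param nifti_path Path to a 3D/4D NIfTI image.
#' @param bval_path,bvec_path FSL-style gradient files.
#' @return List with `data` (4D array), `affine` (4 x 4 voxel-to-world,
#'   0-based voxel indices), `voxel_size` (mm), and `gtab`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(nifti_path)
  gtab <- read_bvals_bvecs(bval_path, bvec_path)
  dat <- as.array(img)
  if (length(dim(dat)) == 3L) dim(dat) <- c(dim(dat), 1L)
  if (dim(dat)[4L] != length(gtab$bvals))
    stop("volume count mismatch: image has ", dim(dat)[4L], ", gradient table ",
         length(gtab$bvals), call. = FALSE)
  if (anyNA(dat)) stop("NaNs in image data", call. = FALSE)
  aff <- matrix(as.numeric(unclass(RNifti::xform(img))), 4L, 4L)
  list(data = dat, affine = aff,
       voxel_size = sqrt(colSums(aff[1:3, 1:3]^2)), gtab = gtab)
}

#' Write a 4D image (with gradient table) as NIfTI + bval/bvec
#'
#' @param data 3D or 4D array.
#' @param affine 4 x 4 voxel-to-world matrix (0-based voxel indices).
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param gtab Optional [gradient_table()]; when given, `<path>` is
#'   accompanied by `.bval`/`.bvec` files with the same stem.
#' @export
write_nifti <- function(data, affine, path, gtab = NULL) {
  vx <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::pixdim(img) <- vx
  RNifti::writeNifti(img, path)
  if (!is.null(gtab)) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    write_bvals_bvecs(gtab, paste0(stem, ".bval"), paste0(stem, ".bvec"))
  }
  invisible(path)
}

#' Read a NIfTI image as array + affine
#'
#' @param path NIfTI path.
#' @return List with `data` (array) and `affine`.
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(unclass(RNifti::xform(img))), 4L, 4L)
  list(data = as.array(img), affine = aff)
}

#' Write a field of SH coefficients as a 4D NIfTI image
#'
#' Volumes follow the package's coefficient ordering (l-major, m ascending),
#' which is the MRtrix3 on-disk ordering, so files interoperate with
#' MRtrix-produced SH images.
#'
#' @param field 4D array `[X, Y, Z, n_coeffs]`.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param path Output path.
#' @export
write_sh_image <- function(field, affine, path) {
  lmax_from_ncoef(dim(field)[4L]) # validates coefficient count
  write_nifti(field, affine, path)
}

## ---- response functions --------------------------------------------------

#' Read an MRtrix-style response function file
#'
#' Whitespace-delimited text, one row of zonal SH coefficients
#' (`l = 0, 2, ...`) per b-value. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Numeric matrix `[n_shells x n_orders]`.
#' @export
read_response <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged response file: ", path, call. = FALSE)
  mat <- do.call(rbind, rows)
  if (anyNA(mat)) stop("non-numeric response entries in ", path, call. = FALSE)
  unname(mat)
}

#' Write a response function file
#'
#' @param response Matrix `[n_shells x n_orders]` of zonal coefficients.
#' @param path Output path.
#' @export
write_response <- function(response, path) {
  write.table(format(response, digits = 17, scientific = TRUE, trim = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- angular subsampling ---------------------------------------------------

## Electrostatic energy of a direction set under antipodal symmetry:
## sum over unordered pairs of 1/sin(acute angle). (The symmetrized-set sum
## equals this up to a constant factor once degenerate self-antipodal pairs
## are excluded.)
hemispherical_energy <- function(dirs) {
  if (nrow(dirs) < 2L) return(0)
  ct <- abs(tcrossprod(dirs))
  ct <- pmin(ct[upper.tri(ct)], 1)
  sum(1 / sqrt(pmax(1e-12, 1 - ct^2)))
}

#' Greedy angular subsampling of a gradient shell
#'
#' Iteratively removes, one at a time, the direction whose removal leaves the
#' remaining set with the best hemispherical coverage, measured as the lowest
#' electrostatic energy `sum 1/sin(angle)` over antipodally symmetrized
#' pairs. Ties are broken toward the lowest original index. b = 0 volumes and
#' other shells are untouched. Deterministic.
#'
#' @param gtab A [gradient_table()].
#' @param b Nominal b-value of the shell to thin.
#' @param target_count Number of directions to keep on that shell.
#' @return List with the thinned `gtab` and `keep`, the indices of retained
#'   volumes in the original table.
#' @export
subsample_directions <- function(gtab, b, target_count) {
  idx <- shell_indices(gtab, b)
  if (target_count > length(idx))
    stop("target_count exceeds available directions", call. = FALSE)
  if (target_count < 6L)
    warning("fewer than 6 directions cannot support even an lmax=2 fit")
  keep <- idx
  while (length(keep) > target_count) {
    e <- vapply(seq_along(keep), function(i)
      hemispherical_energy(gtab$bvecs[keep[-i], , drop = FALSE]), 0)
    keep <- keep[-which.min(e)] # which.min breaks ties at lowest index
  }
  sel <- sort(c(setdiff(seq_along(gtab$bvals), idx), keep))
  list(gtab = gradient_table(gtab$bvecs[sel, , drop = FALSE], gtab$bvals[sel]),
       keep = sel)
}

## world coordinates of voxel centers (0-based indices) for a grid
voxel_centers <- function(dim3, affine) {
  g <- as.matrix(expand.grid(x = seq_len(dim3[1L]) - 1L,
                             y = seq_len(dim3[2L]) - 1L,
                             z = seq_len(dim3[3L]) - 1L))
  t(affine %*% rbind(t(g), 1))[, 1:3, drop = FALSE]
}
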