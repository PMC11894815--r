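test_that("gradient tables group shells and validate b-vectors", {
  bv <- rbind(c(0, 0, 0), fibonacci_sphere(6L, hemisphere = TRUE),
              fibonacci_sphere(8L, hemisphere = TRUE))
  bvals <- c(0, rep(1210, 3), rep(1190, 3), rep(3000, 8))
  gt <- gradient_table(bv, bvals)
  expect_length(gt$shells, 3L)
  expect_equal(gt$shells[1L], 0)
  expect_equal(gt$shells[2L], 1200, tolerance = 0.02)
  expect_identical(sum(gt$shell_id == 3L), 8L)
  expect_identical(shell_indices(gt, 3000), 8:15)

  # shell grouping invariant under volume permutation
  set.seed(1)
  p <- sample(length(bvals))
  gt2 <- gradient_table(bv[p, ], bvals[p])
  expect_equal(sort(gt2$shells), sort(gt$shells))
  expect_equal(table(gt2$shell_id), table(gt$shell_id))

  expect_error(gradient_table(bv * 2, bvals), "unit")
  expect_error(gradient_table(bv, bvals[-1L]), "differ")
})

test_that("bval/bvec files round-trip, transposed bvec auto-detected", {
  gt <- gradient_table(rbind(matrix(0, 2, 3), fibonacci_sphere(9L)),
                       c(0, 0, rep(2000, 9)))
  bvalf <- tempfile(); bvecf <- tempfile()
  write_bvals_bvecs(gt, bvalf, bvecf)
  gt2 <- read_bvals_bvecs(bvalf, bvecf)
  expect_equal(gt2$bvecs, gt$bvecs, tolerance = 1e-12)
  expect_equal(gt2$bvals, gt$bvals)

  # n x 3 orientation also accepted
  write.table(gt$bvecs, bvecf, row.names = FALSE, col.names = FALSE)
  gt3 <- read_bvals_bvecs(bvalf, bvecf)
  expect_equal(gt3$bvecs, gt$bvecs, tolerance = 1e-12)

  cat("0 0\n", file = bvalf)
  expect_error(read_bvals_bvecs(bvalf, bvecf), "differ")
})

test_that("DWI NIfTI round-trips with affine and gradients", {
  ph <- small_phantom()
  dir <- tempfile(); dir.create(dir)
  f <- file.path(dir, "dwi.nii.gz")
  write_nifti(ph$data, ph$affine, f, gtab = ph$gtab)
  back <- read_dwi(f, file.path(dir, "dwi.bval"), file.path(dir, "dwi.bvec"))
  expect_equal(back$data, ph$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$affine, ph$affine, tolerance = 1e-5)
  expect_equal(back$gtab$bvals, ph$gtab$bvals)
  expect_equal(back$voxel_size, rep(1.25, 3L), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("SH images round-trip and carry n_coeffs volumes", {
  ph <- small_phantom()
  f <- tempfile(fileext = ".nii.gz")
  write_sh_image(ph$truth$fod, ph$affine, f)
  back <- read_nifti(f)
  expect_identical(dim(back$data)[4L], 45L)
  expect_equal(back$data, ph$truth$fod, tolerance = 1e-6, ignore_attr = TRUE)
  # a constant-f00 field loads as a constant AFD map
  fld <- array(0, c(4, 4, 4, 6))
  fld[, , , 1L] <- 0.5
  write_sh_image(fld, diag(4), f)
  expect_equal(afd_total(matrix(read_nifti(f)$data, 64L, 6L)),
               rep(0.5, 64L), tolerance = 1e-7)
  expect_error(write_sh_image(array(0, c(4, 4, 4, 7)), diag(4), f))
})

test_that("response files round-trip and parse edge cases", {
  f <- tempfile()
  writeLines("1 0 0 0 0", f)
  r <- read_response(f)
  expect_equal(dim(r), c(1L, 5L))
  expect_equal(r[1L, ], c(1, 0, 0, 0, 0))

  resp <- make_responses(c(0, 1200, 3000))
  write_response(resp$wm, f)
  expect_equal(read_response(f), resp$wm, tolerance = 1e-14)
  expect_identical(nrow(read_response(f)), 3L)

  writeLines(c("1 2 3", "4 5"), f)
  expect_error(read_response(f), "ragged")
})

test_that("greedy subsampling matches the exhaustive single-step oracle", {
  gt <- small_phantom()$gtab
  shell <- 3000
  idx <- shell_indices(gt, shell)
  sub <- subsample_directions(gt, shell, length(idx) - 1L)
  # oracle: try every single removal, keep the minimal-energy remainder
  energies <- vapply(seq_along(idx), function(i)
    fodinr:::hemispherical_energy(gt$bvecs[idx[-i], ]), 0)
  oracle_keep <- sort(c(setdiff(seq_along(gt$bvals), idx),
                        idx[-which.min(energies)]))
  expect_identical(sub$keep, oracle_keep)

  # identity at target = N; b = 0 volumes always preserved
  expect_identical(subsample_directions(gt, shell, length(idx))$keep,
                   seq_along(gt$bvals))
  sub8 <- subsample_directions(gt, shell, 8L)
  b0 <- which(gt$bvals <= 50)
  expect_true(all(b0 %in% sub8$keep))
  expect_identical(sum(sub8$gtab$bvals > 2000), 8L)
  expect_error(subsample_directions(gt, shell, 100L), "exceeds")
  expect_warning(subsample_directions(gt, shell, 5L), "6 directions")
})
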