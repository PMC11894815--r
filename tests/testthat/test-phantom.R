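test_that("phantom ground truth satisfies its invariants", {
  ph <- small_phantom()
  fr <- ph$truth$fractions
  expect_true(all(fr >= 0))
  expect_true(all(apply(fr, 1:3, sum) <= 1 + 1e-6))

  # FOD amplitudes non-negative on the dense set
  K <- matrix(ph$truth$fod, prod(dim(fr)[1:3]), 45L)
  wm <- which(ph$wm_mask)
  A <- sh_eval(K[wm, ], constraint_directions())
  expect_gte(min(A), -1e-6)

  # region-level NuFO: single-fiber 1, crossing 2; CSF voxels pure
  sf <- which(ph$truth$region == 1L)[1L]
  cx <- which(ph$truth$region == 2L)[1L]
  expect_identical(nufo(K[sf, ]), 1L)
  expect_identical(nufo(K[cx, ]), 2L)
  csf <- which(ph$truth$region == 5L)
  expect_true(all(fr[, , , 3L][csf] == 1))
  expect_true(all(fr[, , , 1L][csf] == 0))

  # crossing angle honoured by the stored peaks
  pk <- ph$truth$peaks[[cx]]
  ang <- acos(abs(sum(pk[1L, ] * pk[2L, ]))) * 180 / pi
  expect_equal(ang, 60, tolerance = 1e-9)

  # ground truth scores perfectly against itself
  ev <- evaluate_field(ph$truth$fod, ph$truth, with_nufo = FALSE)
  expect_equal(ev$acc_mean, 1, tolerance = 1e-12)
  expect_equal(ev$afd_mae, 0, tolerance = 1e-14)
  expect_identical(ev$n_acc_undefined, 0L)
})

test_that("responses have their closed-form properties", {
  resp <- make_responses(c(0, 1200, 3000))
  # b = 0 row of every tissue: l = 0 only, value 2 sqrt(pi) at unit S0
  expect_equal(resp$wm[1L, 1L], 2 * sqrt(pi), tolerance = 1e-12)
  expect_lt(max(abs(resp$wm[1L, -1L])), 1e-12)
  expect_equal(resp$gm[1L, 1L], 2 * sqrt(pi), tolerance = 1e-12)
  expect_equal(resp$csf[1L, 1L], 2 * sqrt(pi), tolerance = 1e-12)

  # CSF isotropic decay: l = 0 ratio b1200/b0 = exp(-1200 * 3e-3)
  expect_equal(resp$csf[2L, 1L] / resp$csf[1L, 1L], exp(-3.6), tolerance = 1e-12)

  # prolate WM tensor: zonal coefficients alternate in sign at b = 3000
  w <- resp$wm[3L, ]
  expect_true(all(sign(w) == c(1, -1, 1, -1, 1)))

  # oracle: quadrature projection of the tensor signal
  q <- quad
  b <- 3000; dpar <- 1.7e-3; dperp <- 0.2e-3
  sig <- exp(-b * (dperp + (dpar - dperp) * q$dirs[, 3L]^2))
  B <- sh_basis(q$dirs, 8L)
  proj <- colSums(q$w * sig * B)
  deg <- sh_degrees(8L)
  expect_equal(w, proj[deg$m == 0L], tolerance = 1e-6)
})

test_that("synthesized signal follows the convolution forward model", {
  ph <- small_phantom()
  S <- matrix(ph$clean, prod(dim(ph$data)[1:3]), dim(ph$data)[4L])

  # zero fractions give zero signal
  bg <- which(ph$truth$region == 0L)
  expect_equal(max(abs(S[bg, ])), 0)

  # CSF voxels: direction-independent within each shell
  csf <- which(ph$truth$region == 5L)[1L]
  for (b in c(0, 1200, 3000)) {
    v <- S[csf, shell_indices(ph$gtab, b)]
    expect_lt(diff(range(v)), 1e-12)
  }

  # single-fiber voxel matches direct quadrature convolution per shell
  sf <- which(ph$truth$region == 1L)[1L]
  fod <- matrix(ph$truth$fod, nrow(S), 45L)[sf, ]
  famp <- sh_eval(fod, quad$dirs)
  for (b in c(1200, 3000)) {
    idx <- shell_indices(ph$gtab, b)
    rrow <- which.min(abs(ph$responses$bvals - b))
    r <- ph$responses$wm[rrow, ]
    direct <- vapply(idx, function(i) {
      ct <- pmin(1, pmax(-1, drop(quad$dirs %*% ph$gtab$bvecs[i, ])))
      Pl <- fodinr:::legendre_norm(8L, ct)
      Rk <- Pl[, 1L, 1L] * r[1L] + Pl[, 3L, 1L] * r[2L] + Pl[, 5L, 1L] * r[3L] +
        Pl[, 7L, 1L] * r[4L] + Pl[, 9L, 1L] * r[5L]
      sum(quad$w * famp * Rk)
    }, 0)
    expect_equal(S[sf, idx], direct, tolerance = 1e-3)
  }

  # linearity: doubling the FOD field and fractions doubles the signal
  truth2 <- ph$truth
  truth2$fod <- truth2$fod * 2
  truth2$fractions <- truth2$fractions * 2
  S2 <- synthesize_signal(truth2, ph$gtab, ph$responses)
  expect_equal(S2, ph$clean * 2, tolerance = 1e-12)
})

test_that("noise model is Rician with the requested SNR", {
  ph <- small_phantom()
  expect_identical(add_noise(ph$clean, Inf), ph$clean)

  noisy <- add_noise(ph$clean, 25, seed = 11L, ref_mask = ph$wm_mask,
                     b0_volumes = which(ph$gtab$bvals <= 50))
  expect_gte(min(noisy), 0)
  # reproducibility
  noisy2 <- add_noise(ph$clean, 25, seed = 11L, ref_mask = ph$wm_mask,
                      b0_volumes = which(ph$gtab$bvals <= 50))
  expect_identical(noisy, noisy2)

  # measured SNR on b=0 over WM ~ requested (Monte-Carlo, 10%)
  b0 <- which(ph$gtab$bvals <= 50)
  resid <- (noisy - ph$clean)[, , , b0, drop = FALSE]
  wm4 <- array(rep(ph$wm_mask, length(b0)), dim(resid))
  s_ref <- mean(ph$clean[, , , b0, drop = FALSE][wm4])
  measured <- s_ref / sd(resid[wm4])
  expect_equal(measured, 25, tolerance = 0.10)
})
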