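# A small noiseless phantom and a reduced network keep these runs fast while
# exercising the full training path.

tiny_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      ph <- small_phantom()
      memo <<- list(ph = ph,
                    fit = fit_inr(ph$data, ph$gtab, ph$responses, ph$affine,
                                  mode = "csd", shell = 3000, mask = ph$mask,
                                  np = 200L, width = 128L, layers = 3L,
                                  epochs = 300L, batch_size = 250L, lr = 1e-3,
                                  seed = 21L))
    }
    memo
  }
})

test_that("reconstruct_signal agrees with the phantom forward model", {
  ph <- small_phantom()
  nvox <- prod(dim(ph$data)[1:3])
  K <- cbind(matrix(ph$truth$fod, nvox, 45L),
             matrix(ph$truth$fractions[, , , 2L], nvox) / (2 * sqrt(pi)),
             matrix(ph$truth$fractions[, , , 3L], nvox) / (2 * sqrt(pi)))
  S_hat <- reconstruct_signal(K, ph$gtab, ph$responses, "msmt")
  expect_equal(S_hat, matrix(ph$clean, nvox, dim(ph$data)[4L]),
               tolerance = 1e-12)

  # zero coefficients give zero signal
  expect_equal(reconstruct_signal(numeric(45L), ph$gtab, ph$responses, "csd"),
               numeric(length(ph$gtab$bvals)))

  # single-shell with isotropic response: only f00 contributes, constant
  r_iso <- list(bvals = 3000, wm = matrix(c(1, 0, 0, 0, 0), 1L),
                gm = matrix(1), csf = matrix(1))
  set.seed(2)
  f <- rnorm(45L)
  idx <- shell_indices(ph$gtab, 3000)
  s <- reconstruct_signal(f, ph$gtab, r_iso, "csd", volumes = idx)
  expect_equal(s, rep(f[1L] * sqrt(4 * pi) / (2 * sqrt(pi)), length(idx)),
               tolerance = 1e-12)
})

test_that("non-negativity penalty flags the right amplitudes", {
  # strictly positive FOD with all amplitudes above threshold: no penalty
  pos <- apodized_delta(8L, c(0, 0, 1)) + c(10, numeric(44L))
  expect_equal(nonnegativity_penalty(pos), 0)

  # negative constant: every direction flagged, penalty = constant^2
  negc <- c(-2 * 2 * sqrt(pi), numeric(44L))
  expect_equal(nonnegativity_penalty(negc), 4, tolerance = 1e-12)

  # attenuating a negative lobe lowers the penalty monotonically
  base <- apodized_delta(8L, c(0, 0, 1))
  lobe <- delta_coeffs(8L, c(1, 0, 0)) - apodized_delta(8L, c(1, 0, 0))
  pens <- vapply(seq(1, 0, by = -0.25), function(a)
    nonnegativity_penalty(base + a * lobe), 0)
  expect_true(all(diff(pens) <= 1e-12))
})

test_that("loss terms are additive and vanish at the exact solution", {
  ph <- small_phantom()
  nvox <- prod(dim(ph$data)[1:3])
  K <- cbind(matrix(ph$truth$fod, nvox, 45L),
             matrix(ph$truth$fractions[, , , 2L], nvox) / (2 * sqrt(pi)),
             matrix(ph$truth$fractions[, , , 3L], nvox) / (2 * sqrt(pi)))
  M <- fodinr:::signal_matrix(ph$gtab, ph$responses, 8L, "msmt")
  P <- sh_basis(constraint_directions(), 8L)
  S <- matrix(ph$data, nvox, dim(ph$data)[4L])
  wm <- which(ph$wm_mask)
  lt <- fodinr:::inr_loss_terms(K[wm, ], S[wm, ], M, 1, P, 0.1, 45L)
  expect_lt(lt$mse, 1e-20)
  # the constraint is slightly active even at the truth (amplitudes in the
  # FOD's flat region sit below 0.1 x mean), but orders below the signal scale
  expect_lt(lt$constraint, 1e-4)
  expect_equal(lt$total, lt$mse + lt$constraint)

  # doubling residuals quadruples the mse
  K0 <- K[wm, ] * 0
  l1 <- fodinr:::inr_loss_terms(K[wm, ] * -1, S[wm, ], M, 0, P, 0.1, 45L)
  l2 <- fodinr:::inr_loss_terms(K[wm, ] * -3, S[wm, ], M, 0, P, 0.1, 45L)
  expect_equal(l2$mse, 4 * l1$mse, tolerance = 1e-9)

  # batch additivity: loss over the union is the weighted mean of halves
  h1 <- wm[seq_len(floor(length(wm) / 2))]
  h2 <- setdiff(wm, h1)
  la <- fodinr:::inr_loss_terms(K[h1, ] * 0, S[h1, ], M, 1, P, 0.1, 45L)
  lb <- fodinr:::inr_loss_terms(K[h2, ] * 0, S[h2, ], M, 1, P, 0.1, 45L)
  lu <- fodinr:::inr_loss_terms(K[wm, ] * 0, S[wm, ], M, 1, P, 0.1, 45L)
  expect_equal(lu$total,
               (length(h1) * la$total + length(h2) * lb$total) / length(wm),
               tolerance = 1e-10)
})

test_that("training reduces the loss and is seed-deterministic", {
  tf <- tiny_fit()
  h <- tf$fit$history
  expect_gte(h$total[1L] / tail(h$total, 1L), 10)

  # bitwise determinism of a re-run with identical seeds
  refit <- fit_inr(tf$ph$data, tf$ph$gtab, tf$ph$responses, tf$ph$affine,
                   mode = "csd", shell = 3000, mask = tf$ph$mask,
                   np = 200L, width = 128L, layers = 3L, epochs = 2L,
                   batch_size = 250L, lr = 1e-3, seed = 21L)
  refit2 <- fit_inr(tf$ph$data, tf$ph$gtab, tf$ph$responses, tf$ph$affine,
                    mode = "csd", shell = 3000, mask = tf$ph$mask,
                    np = 200L, width = 128L, layers = 3L, epochs = 2L,
                    batch_size = 250L, lr = 1e-3, seed = 21L)
  expect_identical(refit$model$net$W, refit2$model$net$W)
  expect_identical(refit$history, refit2$history)
})

test_that("the fitted representation recovers the FOD field", {
  tf <- tiny_fit()
  ev <- evaluate_field(coef(tf$fit), tf$ph$truth, with_nufo = FALSE)
  expect_gte(ev$acc_mean, 0.95)

  # continuity of the represented field
  x0 <- c(0, 0, 0)
  k0 <- predict(tf$fit, x0)
  k1 <- predict(tf$fit, x0 + 1e-4)
  k2 <- predict(tf$fit, x0 + 1e-2)
  expect_lt(sqrt(sum((k1 - k0)^2)), sqrt(sum((k2 - k0)^2)))
  expect_lt(sqrt(sum((k1 - k0)^2)), 1e-3)
})
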