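test_that("coefficient counting and (l,m) indexing", {
  expect_identical(n_coeffs(0L), 1L)
  expect_identical(n_coeffs(4L), 15L)
  expect_identical(n_coeffs(8L), 45L)
  expect_error(n_coeffs(3), "even")
  expect_error(n_coeffs(-2), "even")

  expect_identical(sh_index(0L, 0L), 1L)
  expect_identical(sh_index(2L, -2L), 2L)
  expect_identical(sh_index(8L, 8L), 45L)
  expect_error(sh_index(2L, 3L))
  expect_error(sh_index(3L, 1L))
  # bijection against the inverse map
  deg <- sh_degrees(8L)
  expect_identical(sh_index(deg$l, deg$m), seq_len(45L))
})

test_that("basis is orthonormal and antipodally symmetric", {
  B1 <- sh_basis(rbind(c(0, 0, 1), c(1, 0, 0)), 8L)
  expect_equal(B1[, 1L], rep(1 / (2 * sqrt(pi)), 2L))

  # Gram matrix over quadrature equals the identity (orthonormal real basis)
  Bq <- sh_basis(quad$dirs, 8L)
  G <- t(Bq) %*% (Bq * quad$w)
  expect_lt(max(abs(G - diag(45L))), 1e-10)

  set.seed(3)
  v <- rnorm(3); v <- v / sqrt(sum(v^2))
  expect_equal(sh_basis(rbind(v), 8L), sh_basis(rbind(-v), 8L))

  expect_error(sh_basis(rbind(c(1, 1, 0)), 4L), "unit")
})

test_that("evaluation and least-squares fitting round-trip", {
  # constant coefficient vector evaluates to the constant
  c0 <- c(1, numeric(44L))
  dirs <- fibonacci_sphere(50L)
  expect_equal(sh_eval(c0, dirs), rep(1 / (2 * sqrt(pi)), 50L))
  expect_equal(sh_eval(numeric(45L), dirs), numeric(50L))

  # fit inverts eval on a dense direction set
  set.seed(4)
  cc <- rnorm(45L)
  dense <- fibonacci_sphere(200L)
  expect_equal(sh_fit(sh_eval(cc, dense), dense, 8L), cc, tolerance = 1e-8)

  # constant signal: only the l = 0 coefficient survives
  fit <- sh_fit(rep(2, 200L), dense, 8L)
  expect_equal(fit[1L], 2 * 2 * sqrt(pi), tolerance = 1e-8)
  expect_lt(max(abs(fit[-1L])), 1e-8)

  # lmax = 0 fit is the mean amplitude scaled by 2 sqrt(pi) (closed form of
  # least squares with the constant regressor)
  amps <- sh_eval(cc, dense)
  f0 <- sh_fit(amps, dense, 0L)
  expect_equal(f0, 2 * sqrt(pi) * mean(amps), tolerance = 1e-12)

  expect_error(sh_fit(rep(1, 10L), fibonacci_sphere(10L), 8L), "under-determined")
})

test_that("Parseval identity holds under quadrature", {
  set.seed(5)
  for (rep in 1:5) {
    cc <- rnorm(45L)
    amps <- sh_eval(cc, quad$dirs)
    expect_equal(sum(quad$w * amps^2), sum(cc^2), tolerance = 1e-3)
  }
})

test_that("zonal convolution matches brute-force spherical convolution", {
  set.seed(6)
  nd <- 40L
  eval_dirs <- fibonacci_sphere(nd)
  for (rep in 1:5) {
    f <- rnorm(45L)
    r <- rnorm(5L)
    s <- sh_convolve(f, r)
    # oracle: s(v) = integral f(u) R(u . v) dOmega(u), R from its zonal series
    famp <- sh_eval(f, quad$dirs)
    Pl <- fodinr:::legendre_norm(8L, pmin(1, pmax(-1, quad$dirs %*% t(eval_dirs))))
    direct <- vapply(seq_len(nd), function(j) {
      Rk <- 0
      for (i in seq_along(r)) {
        l <- 2L * (i - 1L)
        Rk <- Rk + r[i] * Pl[, l + 1L, 1L][(j - 1L) * length(quad$w) + seq_along(quad$w)]
      }
      sum(quad$w * famp * Rk)
    }, 0)
    expect_equal(sh_eval(s, eval_dirs), direct, tolerance = 1e-3)
  }
})

test_that("zonal convolution scale factors and linearity", {
  f <- c(1, numeric(44L)); r <- c(1, numeric(4L))
  expect_equal(sh_convolve(f, r)[1L], sqrt(4 * pi))
  expect_equal(sh_convolve(f, numeric(5L)), numeric(45L))
  set.seed(7)
  f1 <- rnorm(45L); f2 <- rnorm(45L); r1 <- rnorm(5L); r2 <- rnorm(5L)
  expect_equal(sh_convolve(f1 + 2 * f2, r1), sh_convolve(f1, r1) + 2 * sh_convolve(f2, r1))
  expect_equal(sh_convolve(f1, r1 + 2 * r2), sh_convolve(f1, r1) + 2 * sh_convolve(f1, r2))
  # delta response reproduces the per-l scale factors exactly
  rd <- sqrt((2 * seq(0, 8, 2) + 1) / (4 * pi))
  deg <- sh_degrees(8L)
  expect_equal(sh_convolve(f1, rd), f1 * sqrt(4 * pi / (2 * deg$l + 1)) *
                 sqrt((2 * deg$l + 1) / (4 * pi)))
})

test_that("band-limited delta behaves like a delta", {
  d <- delta_coeffs(8L, c(0, 0, 1))
  deg <- sh_degrees(8L)
  expect_true(all(d[deg$m != 0L] == 0))
  expect_equal(d[deg$m == 0L], sqrt((2 * seq(0, 8, 2) + 1) / (4 * pi)))

  set.seed(8)
  v <- rnorm(3); v <- v / sqrt(sum(v^2))
  dv <- delta_coeffs(8L, v)
  dense <- fibonacci_sphere(2000L)
  expect_gte(sh_eval(dv, rbind(v)), max(sh_eval(dv, dense)) - 1e-9)
})

test_that("apodized delta is non-negative, unit integral, single-peaked", {
  set.seed(9)
  v <- rnorm(3); v <- v / sqrt(sum(v^2))
  a <- apodized_delta(8L, v)
  amps <- sh_eval(a, quad$dirs)
  expect_gte(min(amps), -1e-7 * max(amps))
  expect_equal(sum(quad$w * amps), 1, tolerance = 1e-9)
  expect_equal(nufo(a), 1L)
})
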