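# Shared fixtures, built once per test run.

# small noiseless phantom reused across files
small_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- dmri_phantom(phantom_config(dim3 = c(10L, 10L, 10L),
                                                        seed = 7L))
    ph
  }
})

# dense spherical quadrature for integration oracles
quad <- fodinr:::sphere_quadrature(32L, 64L)

# random coefficient vectors with anisotropic energy
random_coeffs <- function(n, lmax = 8L, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(n * n_coeffs(lmax)), n)
}
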