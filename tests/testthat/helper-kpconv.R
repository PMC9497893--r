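# Shared fixtures for the test suite.

# The eight published layer configurations (input channels, filters, group
# width) with every planner column and the resulting weight totals.
table1_rows <- function() {
  data.frame(
    ic    = c(14, 160, 160, 192, 192, 1152, 1152, 3840, 3840),
    f     = c(10, 3840, 3840, 1152, 1152, 320, 320, 640, 640),
    ch    = c(4, 16, 32, 16, 32, 16, 32, 16, 32),
    gk1   = c(4, 10, 5, 12, 6, 72, 36, 240, 120),
    fgk1  = c(2, 384, 768, 96, 192, 4, 8, 2, 5),
    gk2   = c(2, 0, 0, 0, 0, 32, 32, 160, 40),
    gl1   = c(3, 0, 0, 0, 0, 20, 10, 40, 20),
    fgl1  = c(3, 0, 0, 0, 0, 16, 32, 16, 32),
    gl2   = c(1, 0, 0, 0, 0, 0, 0, 0, 0),
    total = c(80, 61440, 122880, 18432, 36864, 10240, 20480, 20480, 40960),
    pct   = c(57.14, 10.00, 20.00, 8.33, 16.67, 2.78, 5.56, 0.83, 1.67)
  )
}

# random feature maps with fixed dimensions
rand_maps <- function(n, h, w, c, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(n * h * w * c), c(n, h, w, c))
}

# reference two-step computation through the densified matrices
densified_forward <- function(plan, weights, x) {
  eff <- densify(plan, weights)
  k <- pointwise_conv(x, eff$wk_eff)
  if (plan$has_l)
    k + pointwise_conv(k[, , , plan$interleave, drop = FALSE], eff$wl_eff)
  else k
}

expect_rel_equal <- function(got, want, tol = 1e-8) {
  scale <- max(1, max(abs(want)))
  expect_lt(max(abs(got - want)) / scale, tol)
}
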