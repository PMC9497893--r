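# Reference convolution oracle: standard and grouped pointwise forward
# passes and the plan densifier.

test_that("pointwise conv matches identity, zero and matrix-product oracles", {
  x <- array(1, c(1, 2, 2, 3))
  expect_equal(pointwise_conv(x, diag(3)), x)
  expect_equal(pointwise_conv(array(0, c(2, 3, 3, 5)), matrix(1, 4, 5)),
               array(0, c(2, 3, 3, 4)))
  x <- rand_maps(3, 2, 4, 6, seed = 21)
  w <- matrix(rnorm(5 * 6), 5, 6)
  ref <- t(apply(matrix(x, ncol = 6), 1, function(v) w %*% v))
  got <- pointwise_conv(x, w)
  expect_rel_equal(matrix(got, ncol = 5), ref, tol = 1e-12)
  expect_error(pointwise_conv(x, matrix(0, 5, 7)), "does not match")
})

test_that("the oracle is linear and permutation-consistent", {
  set.seed(31)
  x <- rand_maps(2, 3, 3, 8); y <- rand_maps(2, 3, 3, 8)
  w <- matrix(rnorm(4 * 8), 4, 8)
  expect_rel_equal(pointwise_conv(2 * x - 3 * y, w),
                   2 * pointwise_conv(x, w) - 3 * pointwise_conv(y, w), 1e-12)
  # permuting input channels and weight columns identically is a no-op
  perm <- sample(8)
  expect_equal(pointwise_conv(x[, , , perm, drop = FALSE], w[, perm]),
               pointwise_conv(x, w))
})

test_that("grouped conv gathers, convolves and concatenates per group", {
  x <- rand_maps(2, 2, 2, 6, seed = 41)
  # identity weights per group return the gathered channels
  g <- grouped_pointwise_conv(x, list(diag(3), diag(3)), list(1:3, 4:6))
  expect_equal(g, x)
  # replicated indices are gathered twice
  g2 <- grouped_pointwise_conv(x, list(matrix(1, 1, 2)), list(c(2L, 2L)))
  expect_equal(g2, 2 * x[, , , 2, drop = FALSE])
  # one group covering all channels reduces to the standard conv
  w <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(grouped_pointwise_conv(x, list(w), list(1:6)),
               pointwise_conv(x, w))
  expect_error(grouped_pointwise_conv(x, list(w), list(1:7)), "out of range")
})

test_that("grouped conv uses ic*f/G weights under exact divisibility", {
  p <- substitution_plan(32, 64, 8)   # plain grouped case
  n_w <- p$k1$groups * p$k1$filters_per_group * p$spec$ch
  expect_equal(n_w, grouped_params(32, 64, p$k1$groups))
})

test_that("densify scatters weights into block-sparse full matrices", {
  p <- substitution_plan(14, 10, 4)
  cfg <- subnet_config(activation = "none")
  zw <- subnet_weights(p, subnet_config(weight_init = "zeros"))
  eff0 <- densify(p, zw)
  expect_equal(eff0$wk_eff, matrix(0, 10, 14))
  expect_equal(eff0$wl_eff, matrix(0, 10, 10))
  # distinct nonzero weights: K holds 10 filters x 4 weights = 40 slots;
  # replication may merge two slots into one accumulated column entry
  w <- subnet_weights(p, cfg, seed = 52)
  eff <- densify(p, w)
  # 10 filters x 4 weights in K; no index repeats within any single group
  # of this configuration, so all 40 scattered entries stay distinct
  expect_equal(sum(eff$wk_eff != 0), 40)
  # a channel gathered twice by one group accumulates both weights:
  # (ic=3, ch=4) yields the single group (1,2,3,1); ic < f so L is absent
  p2 <- substitution_plan(layer_spec(3, 4, 4), force = TRUE)
  w2 <- list(k1 = matrix(as.numeric(1:16), 4, 4, byrow = TRUE),
             k2 = NULL, l1 = NULL, l2 = NULL)
  eff2 <- densify(p2, w2)
  expect_equal(eff2$wk_eff[1, ], c(1 + 4, 2, 3))
  expect_equal(eff2$wk_eff[4, ], c(13 + 16, 14, 15))
})

test_that("densified two-step computation equals the grouped paths", {
  set.seed(61)
  for (spec in list(c(14, 10, 4), c(1152, 320, 16), c(192, 1152, 16))) {
    p <- substitution_plan(spec[1], spec[2], spec[3])
    w <- subnet_weights(p, subnet_config(activation = "none"), seed = spec[1])
    x <- rand_maps(2, 2, 2, spec[1])
    # route 1: grouped oracle applied path by path
    k_parts <- list()
    run_path <- function(q, wm) {
      ws <- lapply(seq_len(q$groups), function(m)
        wm[(m - 1) * q$filters_per_group + seq_len(q$filters_per_group), ,
           drop = FALSE])
      grouped_pointwise_conv(x, ws, q$input_groups)
    }
    k <- run_path(p$k1, w$k1)
    if (!is.null(p$k2)) {
      k2 <- run_path(p$k2, w$k2)
      tmp <- array(0, c(dim(k)[1:3], spec[2]))
      tmp[, , , seq_len(dim(k)[4])] <- k
      tmp[, , , dim(k)[4] + seq_len(dim(k2)[4])] <- k2
      k <- tmp
    }
    route1 <- if (p$has_l) {
      kp <- k[, , , p$interleave, drop = FALSE]
      run_path_on <- function(q, wm, xx) {
        ws <- lapply(seq_len(q$groups), function(m)
          wm[(m - 1) * q$filters_per_group + seq_len(q$filters_per_group), ,
             drop = FALSE])
        grouped_pointwise_conv(xx, ws, q$input_groups)
      }
      l <- run_path_on(p$l1, w$l1, kp)
      if (!is.null(p$l2)) {
        l2 <- run_path_on(p$l2, w$l2, kp)
        tmp <- array(0, c(dim(l)[1:3], spec[2]))
        tmp[, , , seq_len(dim(l)[4])] <- l
        tmp[, , , dim(l)[4] + seq_len(dim(l2)[4])] <- l2
        l <- tmp
      }
      k + l
    } else k
    # route 2: densified dense convolutions
    route2 <- densified_forward(p, w, x)
    expect_rel_equal(route1, route2, tol = 1e-10)
  }
})
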