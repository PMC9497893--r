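# Backbone descriptor, layer inventory, stride skipping and the
# parameter accounting of baseline and substituted models.

test_that("baseline trainable-parameter counts match the published models", {
  expect_equal(backbone_params(effnet_b0(num_classes = 10)), 4020358)
  expect_equal(backbone_params(effnet_b0(num_classes = 2)), 4010110)
  expect_equal(backbone_params(effnet_b0(num_classes = 8)), 4017796)
  # head-layer arithmetic: each class costs 1280 weights + 1 bias
  expect_equal(backbone_params(effnet_b0(num_classes = 10)) -
                 backbone_params(effnet_b0(num_classes = 2)),
               8 * (1280 + 1))
})

test_that("the inventory mirrors the canonical stage table", {
  inv <- layer_inventory(effnet_b0(num_classes = 10))
  pw <- inv[inv$unit == "pw", ]
  expect_equal(sum(pw$role == "expand"), 15)     # all blocks except the first
  expect_equal(sum(pw$role == "project"), 16)
  expect_equal(sum(pw$role == "se_reduce"), 16)
  expect_equal(sum(pw$role == "se_expand"), 16)
  expect_equal(pw$f[pw$role == "head"], 1280)
  # SE reduction is a quarter of the block input channels
  first_se <- pw[pw$role == "se_reduce", ][1, ]
  expect_equal(first_se$f, 8)                    # 32 * 0.25
  expect_true(all(pw$bias[pw$role %in% c("se_reduce", "se_expand")]))
  expect_false(any(pw$bias[pw$role %in% c("expand", "project", "head")]))
})

test_that("stride skipping neutralises the first k downsamplings only", {
  d0 <- effnet_b0(num_classes = 10, input_size = 32)
  expect_equal(d0$skip_strides, 0L)
  inv0 <- layer_inventory(d0)
  expect_equal(sum(inv0$stride == 2), 5)         # stem + four stages
  d4 <- apply_stride_skip(d0, 4)
  inv4 <- layer_inventory(d4)
  expect_equal(sum(inv4$stride == 2), 1)         # only the deepest one left
  # the remaining stride-2 conv is the depthwise conv of stage 6
  expect_match(inv4$name[inv4$stride == 2], "block6_1_dw")
  # parameters carry no stride dependence
  expect_equal(backbone_params(d4), backbone_params(d0))
  expect_error(apply_stride_skip(d0, 6), "cannot skip")
  # spatial bookkeeping: a 32 px input reaches the head at 16 px with k=4
  expect_equal(inv4$hw[inv4$name == "head_conv"], 16)
  d224 <- effnet_b0(num_classes = 10, input_size = 224)
  expect_equal(layer_inventory(d224)$hw[layer_inventory(d224)$name == "head_conv"], 7)
})

test_that("the substitution policy keeps one-group layers original", {
  # strict policy follows the eligibility predicate
  expect_null(substitution_decision(14, 10, 8, policy = "strict"))
  expect_equal(substitution_decision(14, 10, 4, policy = "strict")$l_ch, 4)
  # auto policy: substitute whenever the input splits into >= 2 groups
  expect_null(substitution_decision(16, 96, 16, policy = "auto"))   # ic <= ch
  dec <- substitution_decision(96, 4, 16, policy = "auto")          # tiny f
  expect_equal(dec$l_ch, 4)                     # dense f x f layer L
  dec2 <- substitution_decision(1152, 320, 16, policy = "auto")
  expect_equal(dec2$l_ch, 16)
})

test_that("savings reports reproduce the published whole-model totals", {
  d <- effnet_b0(num_classes = 10)
  # published totals (50-epoch study): parameters strictly increase with
  # the group width, and the graded widths land within 0.4%
  published <- c(`2` = 311994, `4` = 354818, `8` = 444346,
                 `16` = 623226, `32` = 950650)
  got <- vapply(as.integer(names(published)), function(ch)
    attr(savings_report(d, ch), "substituted_total"), numeric(1))
  expect_true(all(diff(got) > 0))                       # monotone in ch
  # the graded widths agree within 0.4%; the small widths are identified
  # less sharply by the published totals (see the methods vignette)
  expect_true(all(abs(got - published) / published < 0.05))
  expect_true(all((abs(got - published) / published)[4:5] < 0.005))
  expect_equal(attr(savings_report(d, 16), "baseline_total"), 4020358)
})

test_that("per-layer accounting sums to the model total", {
  d <- effnet_b0(num_classes = 10)
  rep <- savings_report(d, 16)
  expect_equal(attr(rep, "substituted_total"),
               attr(rep, "baseline_total") - sum(rep$params_orig) +
                 sum(rep$params_sub))
  # untouched layers keep their original mass
  kept <- rep[!rep$substituted, ]
  expect_true(all(kept$params_sub == kept$params_orig))
})

test_that("an absurdly large group width substitutes nothing", {
  d <- effnet_b0(num_classes = 10)
  rep <- savings_report(d, 1e6)
  expect_false(any(rep$substituted))
  expect_equal(attr(rep, "substituted_total"), attr(rep, "baseline_total"))
})

test_that("report files round-trip through CSV and JSON", {
  rep <- savings_report(effnet_b0(num_classes = 10), 16)
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_savings_report(rep, fc)
  write_savings_report(rep, fj)
  back <- utils::read.csv(fc)
  expect_equal(nrow(back), nrow(rep))
  expect_equal(sum(back$params_sub), sum(rep$params_sub))
  js <- jsonlite::fromJSON(fj)
  expect_equal(js$totals$substituted_total, attr(rep, "substituted_total"))
  unlink(c(fc, fj))
})
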