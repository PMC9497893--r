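# Planner: eligibility, channel grouping with replication, interleaving,
# path planning and parameter accounting.

test_that("eligibility requires the group width to stay below both halves", {
  expect_true(is_eligible(14, 10, 4))
  expect_false(is_eligible(4, 10, 4))    # ch > ic/2
  expect_false(is_eligible(14, 10, 6))   # ch > f/2
  expect_true(is_eligible(14, 10, 5))    # ch == f/2: "less or equal"
  expect_true(is_eligible(layer_spec(160, 3840, 16)))
  # boundary: ch == ic/2 == f/2 is allowed (real-valued halves)
  expect_true(is_eligible(8, 8, 4))
  expect_false(is_eligible(7, 8, 4))
})

test_that("layer_spec validates its fields", {
  expect_error(layer_spec(0, 10, 4), "positive integer")
  expect_error(layer_spec(14, -1, 4), "positive integer")
  expect_error(layer_spec(14, 10, 2.5), "positive integer")
})

test_that("channel grouping replicates leading channels into the last group", {
  # worked example: 14 channels in groups of 4 -> last group wraps around
  # (1-based translation of the published 0-based/1-based listings)
  expect_equal(channel_groups(14, 4),
               list(`1` = 1:4, `2` = 5:8, `3` = 9:12, `4` = c(13L, 14L, 1L, 2L)),
               ignore_attr = TRUE)
  # exact divisibility: no replication
  expect_equal(unname(channel_groups(8, 4)), list(1:4, 5:8))
  # deficit d = 3*3 - 7 = 2, independently enumerated
  expect_equal(unname(channel_groups(7, 3)), list(1:3, 4:6, c(7L, 1L, 2L)))
  # single short group: all real channels then wrap
  expect_equal(unname(channel_groups(3, 4)), list(c(1L, 2L, 3L, 1L)))
})

test_that("channel grouping invariants hold over many shapes", {
  for (n in c(1, 2, 3, 5, 7, 14, 16, 31, 160, 333)) {
    for (ch in c(1, 2, 3, 4, 8, 16)) {
      g <- channel_groups(n, ch)
      expect_length(g, ceiling(n / ch))
      expect_true(all(lengths(g) == ch))
      d <- length(g) * ch - n
      expect_true(d >= 0 && d < ch)
      expect_setequal(unique(unlist(g)), seq_len(n))   # full coverage
      # only the last group may contain repeated indices
      if (length(g) > 1)
        for (m in seq_len(length(g) - 1)) expect_false(anyDuplicated(g[[m]]) > 0)
    }
  }
})

test_that("interleaving puts odd channels first, even channels last", {
  expect_equal(interleave_permutation(10), c(1L, 3L, 5L, 7L, 9L, 2L, 4L, 6L, 8L, 10L))
  expect_equal(interleave_permutation(1), 1L)
  # odd n: the odd block carries the extra channel
  expect_equal(interleave_permutation(7), c(1L, 3L, 5L, 7L, 2L, 4L, 6L))
})

test_that("path planning matches the published layer table columns", {
  t1 <- table1_rows()
  for (i in seq_len(nrow(t1))) {
    r <- t1[i, ]
    p <- plan_paths(r$ic, r$f, r$ch)
    expect_equal(p$main$groups, r$gk1, info = paste("row", i))
    expect_equal(p$main$filters_per_group, r$fgk1, info = paste("row", i))
    if (r$gk2 == 0) expect_null(p$extra)
    else {
      expect_equal(p$extra$groups, r$gk2, info = paste("row", i))
      expect_equal(p$extra$filters_per_group, 1L)
      # extra path reuses the first channel groups of the main path
      expect_identical(unname(p$extra$input_groups),
                       unname(p$main$input_groups[seq_len(r$gk2)]))
    }
  }
})

test_that("degenerate planning moves all filters to the extra path", {
  p <- plan_paths(1152, 320, 2)
  expect_equal(p$main$groups, 576L)
  expect_equal(p$main$filters_per_group, 0L)
  expect_equal(p$extra$groups, 320L)
  expect_equal(p$extra$filters_per_group, 1L)
  expect_lte(p$extra$groups, p$main$groups)
})

test_that("full plans reproduce the published parameter totals and L-rule", {
  t1 <- table1_rows()
  for (i in seq_len(nrow(t1))) {
    r <- t1[i, ]
    p <- substitution_plan(r$ic, r$f, r$ch)
    expect_equal(p$has_l, r$ic >= r$f)
    expect_equal(count_params(p), r$total, info = paste("row", i))
    expect_equal(p$param_count, r$total)
    pct <- round(100 * count_params(p) / baseline_params(r$ic, r$f), 2)
    expect_equal(pct, r$pct, info = paste("row", i))
    if (p$has_l) {
      expect_equal(p$l1$groups, r$gl1)
      expect_equal(p$l1$filters_per_group, r$fgl1)
      expect_equal(if (is.null(p$l2)) 0L else p$l2$groups, r$gl2)
      expect_true(all(sort(p$interleave) == seq_len(r$f)))
    } else {
      expect_null(p$interleave)
    }
  }
})

test_that("ineligible layers are rejected with a distinct condition", {
  err <- tryCatch(substitution_plan(14, 10, 8), error = identity)
  expect_s3_class(err, "kpconv_ineligible")
  expect_match(conditionMessage(err), "keep the original")
  # force overrides, for the whole-model policy
  p <- substitution_plan(layer_spec(96, 4, 32), force = TRUE, l_ch = 4)
  expect_equal(count_params(p), 4L * 32L + 4L * 4L)
})

test_that("baseline, grouped and MAC accounting follow the closed forms", {
  expect_equal(baseline_params(14, 10), 140L)
  expect_equal(grouped_params(160, 3840, 10), 61440L)
  expect_error(grouped_params(14, 10, 4), "divide")
  p <- substitution_plan(14, 10, 4)
  expect_equal(count_macs(p, 1, 1), 80)
  expect_equal(count_macs(p, 2, 3), 480)
  # at the eligibility boundary ch = ic/2 with ic >= f, the subnetwork
  # costs exactly the original layer (2 * f * ic/2 = ic * f)
  p2 <- substitution_plan(8, 8, 4)
  expect_equal(count_params(p2), baseline_params(8, 8))
})

test_that("plans serialize to JSON and back", {
  p <- substitution_plan(14, 10, 4)
  json <- plan_to_json(p)
  q <- plan_from_json(json)
  expect_equal(q$spec, p$spec)
  expect_equal(q$param_count, p$param_count)
  expect_equal(q$interleave, p$interleave)
  expect_equal(unname(lapply(q$k1$input_groups, as.integer)),
               unname(lapply(p$k1$input_groups, as.integer)))
  tf <- tempfile(fileext = ".json")
  plan_to_json(p, tf)
  expect_equal(plan_from_json(tf)$param_count, 80L)
  unlink(tf)
})

test_that("summary row mirrors the conventional table layout", {
  s <- summary(substitution_plan(3840, 640, 32))
  expect_equal(unlist(s[c("gk1", "fgk1", "gk2", "gl1", "fgl1", "gl2")]),
               c(gk1 = 120, fgk1 = 5, gk2 = 40, gl1 = 20, fgl1 = 32, gl2 = 0))
  expect_equal(s$total, 40960)
  expect_equal(s$pct, 1.67)
})
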