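# EfficientNet-B0 model construction, wholesale pointwise substitution,
# forward/backward passes and parameter/MAC accounting.
#
# A model is a plain nested list:
#   $arch - structure (kernels, strides, residual flags, slot descriptors,
#           substitution plans) -- no weights
#   $par  - the trainable parameter tree (numeric leaves)
#   $rs   - batch-norm running statistics, parallel to $par (not trainable)

glorot_mat <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- substitution policy -------------------------------------------------

#' Decide how one pointwise layer is substituted
#'
#' The `"auto"` policy (the whole-model default) substitutes every 1x1
#' convolution whose input splits into at least two groups (`ic > ch`).
#' Where a grouped layer would collapse to a single group the plain dense
#' convolution is used instead: a one-group K keeps the original layer, and
#' a one-group L (`f <= ch`) is planned as a dense `f x f` convolution.
#' The `"strict"` policy applies the eligibility predicate
#' (`ch <= ic/2` and `ch <= f/2`) and keeps every other layer original.
#'
#' @param ic,f Input channels and filters of the layer.
#' @param ch Channels per group.
#' @param policy `"auto"` or `"strict"`.
#' @return `NULL` when the layer is kept original, otherwise a list with
#'   `l_ch` (group width used for layer L, `NULL` when L is absent).
#' @export
substitution_decision <- function(ic, f, ch, policy = c("auto", "strict")) {
  policy <- match.arg(policy)
  if (policy == "strict") {
    if (!is_eligible(ic, f, ch)) return(NULL)
    return(list(l_ch = if (ic >= f) ch))
  }
  if (ceiling(ic / ch) < 2) return(NULL)       # one group: keep original
  l_ch <- if (ic >= f) { if (ceiling(f / ch) >= 2) ch else f }
  list(l_ch = l_ch)
}

plan_for_model <- function(ic, f, ch, policy) {
  dec <- substitution_decision(ic, f, ch, policy)
  if (is.null(dec)) return(NULL)
  substitution_plan(layer_spec(ic, f, ch), force = TRUE, l_ch = dec$l_ch)
}

# ---- architecture / parameter tree construction --------------------------

make_slot <- function(ic, f, has_bias, ch, cfg, policy) {
  plan <- if (!is.null(ch)) plan_for_model(ic, f, ch, policy)
  if (is.null(plan)) {
    arch <- list(kind = "pw", ic = ic, f = f, bias = has_bias)
    par <- list(w = glorot_mat(f, ic, ic, f))
    if (has_bias) par$b <- numeric(f)
    rs <- NULL
  } else {
    scfg <- cfg
    scfg$use_bias <- has_bias
    arch <- list(kind = "subnet", ic = ic, f = f, bias = has_bias,
                 plan = plan, cfg = scfg)
    par <- subnet_weights(plan, scfg)
    rs <- if (plan$has_l && scfg$enable_l && scfg$l_batch_norm)
      new_bn_stats(f)
  }
  list(arch = arch, par = par, rs = rs)
}

slot_params <- function(par) sum(vapply(par, length, integer(1)))

#' Build the baseline or substituted classifier from a descriptor
#'
#' With `ch = NULL` this constructs the standard EfficientNet-B0
#' classifier.  With an integer `ch`, every pointwise convolution selected
#' by the policy is replaced by its grouped subnetwork at build time.
#'
#' @param desc A [effnet_b0()] descriptor.
#' @param ch Channels per group, or `NULL` for the unmodified baseline.
#' @param cfg A [subnet_config()] for the substituted layers.  The default
#'   enables the L-branch batch-norm, matching the whole-model accounting.
#' @param policy Substitution policy, see [substitution_decision()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `"kpconv_model"`.
#' @export
build_model <- function(desc, ch = NULL,
                        cfg = subnet_config(l_batch_norm = TRUE),
                        policy = c("auto", "strict"), seed = 1L) {
  stopifnot(inherits(desc, "backbone_descriptor"))
  policy <- match.arg(policy)
  if (!is.null(ch)) ch <- check_count(ch, "ch")
  set.seed(seed)
  st <- desc$stages
  arch <- list(desc = desc, ch = ch, policy = policy)
  par <- list(); rs <- list()

  par$stem <- list(w = array(stats::runif(9L * 3L * desc$stem_filters,
                                          -sqrt(6 / (27 + desc$stem_filters)),
                                          sqrt(6 / (27 + desc$stem_filters))),
                             c(3L, 3L, 3L, desc$stem_filters)),
                   bn = new_bn(desc$stem_filters))
  rs$stem <- list(bn = new_bn_stats(desc$stem_filters))
  eff <- effective_strides(desc)
  arch$stem_stride <- if (eff$stem) 2L else 1L

  blocks_arch <- list(); blocks_par <- list(); blocks_rs <- list()
  ic <- desc$stem_filters
  for (i in seq_len(nrow(st))) {
    for (r in seq_len(st$repeats[i])) {
      nm <- sprintf("block%d_%d", i, r)
      stride <- if (r == 1L && st$stride[i] == 2L && eff$stage[i]) 2L else 1L
      exp <- ic * st$expand[i]
      out <- st$filters[i]
      ba <- list(kernel = st$kernel[i], stride = stride,
                 residual = stride == 1L && ic == out)
      bp <- list(); br <- list()
      if (st$expand[i] != 1L) {
        s <- make_slot(ic, exp, FALSE, ch, cfg, policy)
        ba$expand <- s$arch; bp$expand <- s$par
        if (!is.null(s$rs)) br$expand <- s$rs
        bp$expand_bn <- new_bn(exp); br$expand_bn <- new_bn_stats(exp)
      }
      k <- st$kernel[i]
      bp$dw <- array(stats::runif(k * k * exp, -sqrt(6 / (k * k + 1)),
                                  sqrt(6 / (k * k + 1))), c(k, k, exp))
      bp$dw_bn <- new_bn(exp); br$dw_bn <- new_bn_stats(exp)
      se <- max(1L, as.integer(ic * desc$se_ratio))
      s <- make_slot(exp, se, TRUE, ch, cfg, policy)
      ba$se_reduce <- s$arch; bp$se_reduce <- s$par
      if (!is.null(s$rs)) br$se_reduce <- s$rs
      s <- make_slot(se, exp, TRUE, ch, cfg, policy)
      ba$se_expand <- s$arch; bp$se_expand <- s$par
      if (!is.null(s$rs)) br$se_expand <- s$rs
      s <- make_slot(exp, out, FALSE, ch, cfg, policy)
      ba$project <- s$arch; bp$project <- s$par
      if (!is.null(s$rs)) br$project <- s$rs
      bp$project_bn <- new_bn(out); br$project_bn <- new_bn_stats(out)
      blocks_arch[[nm]] <- ba; blocks_par[[nm]] <- bp; blocks_rs[[nm]] <- br
      ic <- out
    }
  }
  arch$blocks <- blocks_arch
  par$blocks <- blocks_par
  rs$blocks <- blocks_rs

  s <- make_slot(ic, desc$head_filters, FALSE, ch, cfg, policy)
  arch$head <- s$arch; par$head <- s$par
  if (!is.null(s$rs)) rs$head <- s$rs
  par$head_bn <- new_bn(desc$head_filters)
  rs$head_bn <- new_bn_stats(desc$head_filters)
  par$fc <- list(w = glorot_mat(desc$head_filters, desc$num_classes,
                                desc$head_filters, desc$num_classes),
                 b = numeric(desc$num_classes))
  structure(list(arch = arch, par = par, rs = rs), class = "kpconv_model")
}

#' Build the unmodified EfficientNet-B0 classifier
#'
#' @param desc A [effnet_b0()] descriptor.
#' @param seed Integer seed for weight initialisation.
#' @return A `"kpconv_model"` with standard pointwise convolutions.
#' @examples
#' \donttest{
#' m <- build_baseline(effnet_b0(num_classes = 10))
#' model_params(m)    # 4020358
#' }
#' @export
build_baseline <- function(desc, seed = 1L) build_model(desc, ch = NULL, seed = seed)

#' Substitute every selected pointwise convolution of a backbone
#'
#' Builds the grouped-subnetwork variant of the classifier at the given
#' group width and returns it together with a per-layer
#' [savings_report()].
#'
#' @inheritParams build_model
#' @return A `"kpconv_model"` whose `$report` holds the savings report.
#' @examples
#' \donttest{
#' m <- substitute_pointwise(effnet_b0(num_classes = 10), ch = 16)
#' model_params(m)
#' m$report
#' }
#' @export
substitute_pointwise <- function(desc, ch,
                                 cfg = subnet_config(l_batch_norm = TRUE),
                                 policy = c("auto", "strict"), seed = 1L) {
  policy <- match.arg(policy)
  model <- build_model(desc, ch = ch, cfg = cfg, policy = policy, seed = seed)
  model$report <- savings_report(desc, ch, cfg = cfg, policy = policy)
  model
}

#' @export
print.kpconv_model <- function(x, ...) {
  d <- x$arch$desc
  cat(sprintf("EfficientNet-B0 classifier: %d classes, input %dx%d\n",
              d$num_classes, d$input_size, d$input_size))
  if (is.null(x$arch$ch)) cat("  standard pointwise convolutions (baseline)\n")
  else cat(sprintf("  grouped pointwise substitution at Ch = %d (%s policy)\n",
                   x$arch$ch, x$arch$policy))
  cat(sprintf("  trainable parameters: %s\n",
              format(model_params(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters of a built model
#'
#' Sums the lengths of every numeric leaf of the parameter tree: all
#' convolution and dense weights and biases plus batch-norm scale/shift
#' pairs.  Running statistics are not trainable and live outside the tree.
#'
#' @param model A `"kpconv_model"`.
#' @return Integer parameter count.
#' @export
model_params <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.numeric(x)) n <<- n + length(x)
    else if (is.list(x)) for (e in x) walk(e)
  }
  walk(model$par)
  n
}

# ---- accounting ----------------------------------------------------------

round_half_up <- function(x, digits = 1) floor(x * 10^digits + 0.5) / 10^digits

# parameter cost of one substituted pointwise layer under the model
# convention (subnet conv weights + optional per-path biases + L batch-norm)
substituted_layer_params <- function(ic, f, ch, has_bias, cfg, policy) {
  plan <- plan_for_model(ic, f, ch, policy)
  if (is.null(plan)) return(NULL)
  use_l <- plan$has_l && cfg$enable_l
  k_w <- f * ch
  l_w <- if (use_l) count_params(plan) - k_w else 0L
  k_w + l_w + (if (has_bias) f * (1L + use_l) else 0L) +
    (if (use_l && cfg$l_batch_norm) 2L * f else 0L)
}

#' Per-layer and whole-model savings report
#'
#' Lists every pointwise convolution of the backbone with its original and
#' substituted trainable-parameter and MAC cost, plus model totals
#' (including all untouched parameter mass) and percentages.
#'
#' @param desc A [effnet_b0()] descriptor.
#' @param ch Channels per group.
#' @param cfg A [subnet_config()]; governs the L batch-norm accounting.
#' @param policy Substitution policy.
#' @return An object of class `"savings_report"`: a data frame of layer
#'   rows with attributes `baseline_total`, `substituted_total`,
#'   `pct` and the MAC totals.
#' @export
savings_report <- function(desc, ch,
                           cfg = subnet_config(l_batch_norm = TRUE),
                           policy = c("auto", "strict")) {
  policy <- match.arg(policy)
  ch <- check_count(ch, "ch")
  inv <- layer_inventory(desc)
  pwr <- inv[inv$unit == "pw", ]
  rows <- lapply(seq_len(nrow(pwr)), function(i) {
    r <- pwr[i, ]
    orig <- unit_params(r)
    sub <- substituted_layer_params(r$ic, r$f, ch, r$bias, cfg, policy)
    plan <- plan_for_model(r$ic, r$f, ch, policy)
    conv_orig <- r$ic * r$f
    conv_sub <- if (is.null(plan)) conv_orig else count_params(plan)
    data.frame(name = r$name, role = r$role, ic = r$ic, f = r$f,
               substituted = !is.null(sub),
               params_orig = orig,
               params_sub = if (is.null(sub)) orig else sub,
               macs_orig = conv_orig * r$hw^2,
               macs_sub = conv_sub * r$hw^2)
  })
  rep <- do.call(rbind, rows)
  baseline_total <- backbone_params(desc)
  substituted_total <- baseline_total - sum(rep$params_orig) + sum(rep$params_sub)
  structure(rep, class = c("savings_report", "data.frame"),
            ch = ch, policy = policy,
            baseline_total = baseline_total,
            substituted_total = substituted_total,
            pct = round_half_up(100 * substituted_total / baseline_total, 1),
            macs_orig_total = sum(rep$macs_orig),
            macs_sub_total = sum(rep$macs_sub))
}

#' @export
print.savings_report <- function(x, ...) {
  cat(sprintf("pointwise substitution at Ch = %d (%s policy)\n",
              attr(x, "ch"), attr(x, "policy")))
  cat(sprintf("  layers substituted: %d of %d\n", sum(x$substituted), nrow(x)))
  cat(sprintf("  model parameters: %s -> %s (%.1f%%)\n",
              format(attr(x, "baseline_total"), big.mark = ","),
              format(attr(x, "substituted_total"), big.mark = ","),
              attr(x, "pct")))
  cat(sprintf("  pointwise-conv MACs: %s -> %s\n",
              format(attr(x, "macs_orig_total"), big.mark = ",", scientific = FALSE),
              format(attr(x, "macs_sub_total"), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Write a savings report to CSV or JSON
#'
#' @param report A [savings_report()].
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_savings_report <- function(report, path) {
  stopifnot(inherits(report, "savings_report"))
  totals <- list(ch = attr(report, "ch"),
                 baseline_total = attr(report, "baseline_total"),
                 substituted_total = attr(report, "substituted_total"),
                 pct = attr(report, "pct"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(layers = as.data.frame(report), totals = totals),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}

# ---- forward / backward --------------------------------------------------

tmp_subnet <- function(slot_arch, slot_par, slot_rs) {
  structure(list(plan = slot_arch$plan, cfg = slot_arch$cfg,
                 weights = slot_par, rs = slot_rs), class = "subnetwork")
}

slot_fwd <- function(sa, sp, sr, x, training) {
  if (sa$kind == "pw") pwconv_fwd(x, sp$w, sp$b)
  else subnet_forward(tmp_subnet(sa, sp, sr), x, training = training)
}

# forward + backward through one slot; returns dx, dpar and rs update
slot_run <- function(sa, sp, sr, x, training, dy) {
  if (sa$kind == "pw") {
    g <- pwconv_bwd(x, sp$w, dy, has_bias = sa$bias)
    dpar <- list(w = g$dw); if (sa$bias) dpar$b <- g$db
    return(list(dx = g$dx, dpar = dpar, rs = sr))
  }
  net <- tmp_subnet(sa, sp, sr)
  fw <- subnet_forward(net, x, keep_cache = TRUE, training = training)
  g <- subnet_backward(net, fw$cache, dy)
  rs2 <- sr
  if (!is.null(fw$cache$bnfw) && training)
    rs2 <- bn_update_stats(sr, fw$cache$bnfw)
  list(dx = g$dx, dpar = g$dw, rs = rs2)
}

swish_grad <- function(x) {
  y <- swish_grad_cpp(x, 1)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

block_fwd <- function(ba, bp, br, x, training) {
  h <- x
  if (!is.null(ba$expand)) {
    h <- slot_fwd(ba$expand, bp$expand, br$expand, h, training)
    h <- bn_fwd(h, bp$expand_bn, br$expand_bn, training)$y
    h <- swish(h)
  }
  h <- dwconv_fwd(h, bp$dw, ba$stride)$y
  h <- bn_fwd(h, bp$dw_bn, br$dw_bn, training)$y
  h <- swish(h)
  s <- gap_fwd(h)
  s <- slot_fwd(ba$se_reduce, bp$se_reduce, br$se_reduce, s, training)
  s <- swish(s)
  s <- slot_fwd(ba$se_expand, bp$se_expand, br$se_expand, s, training)
  s <- sigmoid(s)
  h <- scale_bc(h, s)
  h <- slot_fwd(ba$project, bp$project, br$project, h, training)
  h <- bn_fwd(h, bp$project_bn, br$project_bn, training)$y
  if (ba$residual) h <- h + x
  h
}

# forward (with caches) + backward through one MBConv block
block_run <- function(ba, bp, br, x, training, dy) {
  dpar <- list(); rs2 <- br
  h <- x
  if (!is.null(ba$expand)) {
    x_exp <- h
    h_exp <- slot_fwd(ba$expand, bp$expand, br$expand, h, training)
    bn1 <- bn_fwd(h_exp, bp$expand_bn, br$expand_bn, training)
    a1_in <- bn1$y
    h <- swish(a1_in)
  }
  x_dw <- h
  dwf <- dwconv_fwd(h, bp$dw, ba$stride)
  bn2 <- bn_fwd(dwf$y, bp$dw_bn, br$dw_bn, training)
  a2_in <- bn2$y
  h <- swish(a2_in)
  h_act <- h
  s0 <- gap_fwd(h)
  s1 <- slot_fwd(ba$se_reduce, bp$se_reduce, br$se_reduce, s0, training)
  s1a <- swish(s1)
  s2 <- slot_fwd(ba$se_expand, bp$se_expand, br$se_expand, s1a, training)
  gate <- sigmoid(s2)
  h_sc <- scale_bc(h_act, gate)
  proj_in <- h_sc
  h_pr <- slot_fwd(ba$project, bp$project, br$project, h_sc, training)
  bn3 <- bn_fwd(h_pr, bp$project_bn, br$project_bn, training)

  # ---- backward ----
  dh <- dy                                   # gradient at block output
  g3 <- bn_bwd(dh, bp$project_bn, bn3, training)
  dpar$project_bn <- list(gamma = g3$dgamma, beta = g3$dbeta)
  rs2$project_bn <- if (training) bn_update_stats(br$project_bn, bn3) else br$project_bn
  gp <- slot_run(ba$project, bp$project, br$project, proj_in, training, g3$dx)
  dpar$project <- gp$dpar; rs2$project <- gp$rs
  d_hsc <- gp$dx
  # through the SE scale: h_sc = h_act * gate
  d_hact <- scale_bc(d_hsc, gate)
  d_gate <- collapse_hw(d_hsc * h_act)
  d_s2 <- d_gate * gate * (1 - gate)
  ge <- slot_run(ba$se_expand, bp$se_expand, br$se_expand, s1a, training, d_s2)
  dpar$se_expand <- ge$dpar; rs2$se_expand <- ge$rs
  d_s1a <- ge$dx
  d_s1 <- d_s1a * swish_grad(s1)
  gr <- slot_run(ba$se_reduce, bp$se_reduce, br$se_reduce, s0, training, d_s1)
  dpar$se_reduce <- gr$dpar; rs2$se_reduce <- gr$rs
  d_s0 <- gr$dx
  d_hact <- d_hact + gap_bwd(d_s0, dim(h_act))
  d_a2in <- d_hact * swish_grad(a2_in)
  g2 <- bn_bwd(d_a2in, bp$dw_bn, bn2, training)
  dpar$dw_bn <- list(gamma = g2$dgamma, beta = g2$dbeta)
  rs2$dw_bn <- if (training) bn_update_stats(br$dw_bn, bn2) else br$dw_bn
  gdw <- dwconv_bwd(g2$dx, bp$dw, dwf, ba$stride)
  dpar$dw <- gdw$dw
  dx <- gdw$dx
  if (!is.null(ba$expand)) {
    d_a1in <- dx * swish_grad(a1_in)
    g1 <- bn_bwd(d_a1in, bp$expand_bn, bn1, training)
    dpar$expand_bn <- list(gamma = g1$dgamma, beta = g1$dbeta)
    rs2$expand_bn <- if (training) bn_update_stats(br$expand_bn, bn1) else br$expand_bn
    gx <- slot_run(ba$expand, bp$expand, br$expand, x_exp, training, g1$dx)
    dpar$expand <- gx$dpar; rs2$expand <- gx$rs
    dx <- gx$dx
  }
  if (ba$residual) dx <- dx + dy
  list(dx = dx, dpar = dpar, rs = rs2)
}

#' Run a model forward
#'
#' @param model A `"kpconv_model"`.
#' @param x Image batch, `N x H x W x 3` array with values in `[0, 1]`.
#' @param training Use batch statistics in batch-norm layers.
#' @return Logit matrix `N x num_classes`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  a <- model$arch; p <- model$par; r <- model$rs
  h <- conv2d_fwd(x, p$stem$w, a$stem_stride)$y
  h <- bn_fwd(h, p$stem$bn, r$stem$bn, training)$y
  h <- swish(h)
  for (nm in names(a$blocks))
    h <- block_fwd(a$blocks[[nm]], p$blocks[[nm]], r$blocks[[nm]], h, training)
  h <- slot_fwd(a$head, p$head, r$head, h, training)
  h <- bn_fwd(h, p$head_bn, r$head_bn, training)$y
  h <- swish(h)
  h <- gap_fwd(h)
  feat <- matrix(h, nrow = dim(x)[1L])
  sweep(feat %*% p$fc$w, 2L, p$fc$b, "+")
}

# loss + full gradient tree; block inputs are checkpointed and block
# internals recomputed during the backward sweep to bound memory
model_grad <- function(model, x, labels, training = TRUE) {
  a <- model$arch; p <- model$par; r <- model$rs
  n <- dim(x)[1L]
  stem_conv <- conv2d_fwd(x, p$stem$w, a$stem_stride)
  stem_bn <- bn_fwd(stem_conv$y, p$stem$bn, r$stem$bn, training)
  h <- swish(stem_bn$y)
  block_in <- list(); cur <- h
  for (nm in names(a$blocks)) {
    block_in[[nm]] <- cur
    cur <- block_fwd(a$blocks[[nm]], p$blocks[[nm]], r$blocks[[nm]], cur, training)
  }
  head_in <- cur
  h <- slot_fwd(a$head, p$head, r$head, cur, training)
  head_bn <- bn_fwd(h, p$head_bn, r$head_bn, training)
  hact_in <- head_bn$y
  h2 <- swish(hact_in)
  pooled <- gap_fwd(h2)
  feat <- matrix(pooled, nrow = n)
  logits <- sweep(feat %*% p$fc$w, 2L, p$fc$b, "+")
  ce <- softmax_xent(logits, labels)

  g <- list(); rs2 <- r
  g$fc <- list(w = crossprod(feat, ce$dlogits), b = colSums(ce$dlogits))
  dfeat <- ce$dlogits %*% t(p$fc$w)
  dpool <- array(dfeat, c(n, 1L, 1L, ncol(dfeat)))
  dh2 <- gap_bwd(dpool, dim(h2))
  dhact <- dh2 * swish_grad(hact_in)
  gh <- bn_bwd(dhact, p$head_bn, head_bn, training)
  g$head_bn <- list(gamma = gh$dgamma, beta = gh$dbeta)
  rs2$head_bn <- if (training) bn_update_stats(r$head_bn, head_bn) else r$head_bn
  gs <- slot_run(a$head, p$head, r$head, head_in, training, gh$dx)
  g$head <- gs$dpar; rs2$head <- gs$rs
  dh <- gs$dx
  g$blocks <- list()
  for (nm in rev(names(a$blocks))) {
    br <- block_run(a$blocks[[nm]], p$blocks[[nm]], r$blocks[[nm]],
                    block_in[[nm]], training, dh)
    g$blocks[[nm]] <- br$dpar
    rs2$blocks[[nm]] <- br$rs
    dh <- br$dx
  }
  dstem_act <- dh * swish_grad(stem_bn$y)
  gsb <- bn_bwd(dstem_act, p$stem$bn, stem_bn, training)
  g$stem <- list(w = conv2d_bwd(gsb$dx, p$stem$w, stem_conv, a$stem_stride)$dw,
                 bn = list(gamma = gsb$dgamma, beta = gsb$dbeta))
  rs2$stem <- list(bn = if (training) bn_update_stats(r$stem$bn, stem_bn) else r$stem$bn)
  acc <- mean(max.col(ce$probs) == labels)
  list(loss = ce$loss, acc = acc, grads = g, rs = rs2, probs = ce$probs)
}

#' Class probabilities or predictions from a model
#'
#' @param object A `"kpconv_model"`.
#' @param x Image batch `N x H x W x 3`.
#' @param type `"prob"`, `"class"` or `"logits"`.
#' @param ... Unused.
#' @return Probability matrix, integer class labels (1-based), or logits.
#' @export
predict.kpconv_model <- function(object, x, type = c("prob", "class", "logits"),
                                 ...) {
  type <- match.arg(type)
  logits <- model_forward(object, x, training = FALSE)
  switch(type,
         logits = logits,
         prob = softmax_rows(logits),
         class = max.col(softmax_rows(logits), ties.method = "first"))
}

#' Horizontal-flip ensemble inference
#'
#' Runs the model on the images and on their horizontal mirrors and sums
#' the two softmax outputs; the argmax of the sum is the prediction.
#' Trainable parameters are unchanged; forward cost doubles.
#'
#' @param model A `"kpconv_model"`.
#' @param x Image batch `N x H x W x 3`.
#' @return Matrix of summed class scores (rows sum to 2).
#' @export
hflip_ensemble_predict <- function(model, x) {
  p1 <- softmax_rows(model_forward(model, x))
  xf <- x[, , rev(seq_len(dim(x)[3L])), , drop = FALSE]
  p2 <- softmax_rows(model_forward(model, xf))
  p1 + p2
}
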