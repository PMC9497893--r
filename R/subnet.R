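#' Configuration of the substitution subnetwork
#'
#' @param activation Nonlinearity applied inside the subnetwork:
#'   `"swish"` (default), `"relu"`, or `"none"` (linear mode, used for
#'   oracle-equivalence testing).
#' @param swish_beta Slope of the sigmoid gate in swish (default 1, fixed).
#' @param enable_l When `FALSE`, the interleaving and layer L are dropped
#'   and the subnetwork output is the K concatenation alone (the "no L"
#'   ablation).
#' @param intermediate_activation Where the in-subnetwork activation sits:
#'   `"after_k"` (default; K's concatenated output is activated before the
#'   interleave and before the residual sum) or `"none"`.  The activation
#'   after the whole substituted layer belongs to the enclosing block and
#'   is never applied here.
#' @param weight_init `"glorot"` (uniform, default) or `"zeros"`.
#' @param use_bias Add one bias per filter to every layer (default `FALSE`;
#'   substituted convolutions are typically followed by batch
#'   normalisation, which absorbs any bias).
#' @param l_batch_norm Normalise the L concatenation with a trainable
#'   scale/shift batch-norm before the residual sum (default `FALSE` for a
#'   standalone subnetwork; the whole-model substitution enables it).
#' @return An object of class `"subnet_config"`.
#' @export
subnet_config <- function(activation = c("swish", "relu", "none"),
                          swish_beta = 1,
                          enable_l = TRUE,
                          intermediate_activation = c("after_k", "none"),
                          weight_init = c("glorot", "zeros"),
                          use_bias = FALSE,
                          l_batch_norm = FALSE) {
  structure(list(
    activation = match.arg(activation),
    swish_beta = swish_beta,
    enable_l = isTRUE(enable_l),
    intermediate_activation = match.arg(intermediate_activation),
    weight_init = match.arg(weight_init),
    use_bias = isTRUE(use_bias),
    l_batch_norm = isTRUE(l_batch_norm)
  ), class = "subnet_config")
}

#' Swish activation
#'
#' `x * sigmoid(beta * x)`, elementwise.  The smooth gating nonlinearity
#' used throughout EfficientNet-style models.
#'
#' @param x Numeric vector or array.
#' @param beta Gate slope (default 1).
#' @return Same shape as `x`.
#' @examples
#' swish(0)            # 0
#' swish(10)           # ~10
#' @export
swish <- function(x, beta = 1) {
  y <- swish_cpp(x, beta)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

activate <- function(x, cfg) {
  switch(cfg$activation,
         swish = swish(x, cfg$swish_beta),
         relu = pmax(x, 0),
         none = x)
}

activate_grad <- function(x, cfg) {
  # derivative of the activation w.r.t. its input, evaluated at x
  switch(cfg$activation,
         swish = { y <- swish_grad_cpp(x, cfg$swish_beta)
                   if (!is.null(dim(x))) dim(y) <- dim(x); y },
         relu = (x > 0) * 1,
         none = array(1, dim(x)))
}

n_path_filters <- function(p) if (is.null(p)) 0L else p$groups * p$filters_per_group

#' Initialise subnetwork weights for a plan
#'
#' One weight matrix per path, rows in group-major filter order and `ch`
#' columns.  Glorot-uniform initialisation draws from
#' `U(-l, l)` with `l = sqrt(6 / (ch + filters))` per path.
#'
#' @param plan A [substitution_plan()].
#' @param cfg A [subnet_config()].
#' @param seed Optional integer seed for reproducible initialisation.
#' @return List with matrices `k1`, `k2`, `l1`, `l2` (absent paths are
#'   `NULL`) and, when `cfg$use_bias`, vectors `bk`, `bl`.
#' @export
subnet_weights <- function(plan, cfg = subnet_config(), seed = NULL) {
  stopifnot(inherits(plan, "substitution_plan"))
  if (!is.null(seed)) set.seed(seed)
  init <- function(p) {
    if (is.null(p) || n_path_filters(p) == 0L) return(NULL)
    n <- n_path_filters(p)
    ch <- length(p$input_groups[[1L]])
    if (cfg$weight_init == "zeros") return(matrix(0, n, ch))
    lim <- sqrt(6 / (ch + n))
    matrix(stats::runif(n * ch, -lim, lim), n, ch)
  }
  use_l <- plan$has_l && cfg$enable_l
  w <- list(k1 = init(plan$k1), k2 = init(plan$k2),
            l1 = if (use_l) init(plan$l1),
            l2 = if (use_l) init(plan$l2))
  if (cfg$use_bias) {
    w$bk <- numeric(plan$spec$f)
    if (use_l) w$bl <- numeric(plan$spec$f)
  }
  if (use_l && cfg$l_batch_norm) {
    w$l_gamma <- rep(1, plan$spec$f)
    w$l_beta <- rep(0, plan$spec$f)
  }
  w
}

#' Materialise a substitution plan as a forward-callable subnetwork
#'
#' Builds the replacement for one pointwise layer: the grouped paths of
#' layer K, concatenation, optional activation, channel interleaving, the
#' grouped paths of layer L, and the residual sum of the two layers.
#' Maps `N x H x W x Ic` inputs to `N x H x W x F` outputs.
#'
#' @param plan A [substitution_plan()].
#' @param cfg A [subnet_config()].
#' @param seed Optional seed passed to [subnet_weights()].
#' @return An object of class `"subnetwork"`: a list with `plan`, `cfg`
#'   and `weights`.  Call it through [subnet_forward()].
#' @examples
#' net <- build_subnetwork(substitution_plan(14, 10, 4),
#'                         subnet_config(activation = "none"), seed = 1)
#' x <- array(rnorm(2 * 3 * 3 * 14), c(2, 3, 3, 14))
#' dim(subnet_forward(net, x))   # 2 3 3 10
#' @export
build_subnetwork <- function(plan, cfg = subnet_config(), seed = NULL) {
  stopifnot(inherits(plan, "substitution_plan"), inherits(cfg, "subnet_config"))
  net <- list(plan = plan, cfg = cfg, weights = subnet_weights(plan, cfg, seed))
  if (plan$has_l && cfg$enable_l && cfg$l_batch_norm)
    net$rs <- new_bn_stats(plan$spec$f)     # running stats, not trainable
  structure(net, class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("grouped pointwise subnetwork\n")
  print(x$plan)
  cat(sprintf("  activation: %s%s, trainable weights: %d\n",
              x$cfg$activation,
              if (!x$cfg$enable_l) " (L disabled)" else "",
              subnet_n_params(x)))
  invisible(x)
}

#' Number of trainable weights held by a subnetwork
#'
#' @param net A [build_subnetwork()] object.
#' @return Integer count; equals `plan$param_count` for the default
#'   bias-free configuration with L enabled.
#' @export
subnet_n_params <- function(net) {
  sum(vapply(net$weights, length, integer(1)))
}

# grouped conv forward on gathered channels; w rows are group-major filters
gconv_fwd <- function(x, w, path) {
  d <- dim(x)
  idx <- matrix(unlist(path$input_groups), ncol = path$groups)
  out <- gconv_fwd_cpp(x, prod(d[1:3]), w, idx, path$filters_per_group)
  dim(out) <- c(d[1:3], path$groups * path$filters_per_group)
  out
}

# backward: returns d_input (N,H,W,C) and d_w; replicated channel indices
# accumulate both contributions (scatter-add)
gconv_bwd <- function(x, w, path, dy) {
  d <- dim(x)
  idx <- matrix(unlist(path$input_groups), ncol = path$groups)
  g <- gconv_bwd_cpp(x, prod(d[1:3]), d[4L], dy, w, idx,
                     path$filters_per_group)
  dx <- g$dx
  dim(dx) <- d
  list(dx = dx, dw = g$dw)
}

layer_fwd <- function(x, main, extra, wm, we, bias = NULL) {
  parts <- list()
  if (!is.null(main) && main$filters_per_group > 0L)
    parts <- c(parts, list(gconv_fwd(x, wm, main)))
  if (!is.null(extra))
    parts <- c(parts, list(gconv_fwd(x, we, extra)))
  y <- if (length(parts) == 1L) parts[[1L]] else concat_channels(parts)
  if (!is.null(bias)) y <- y + rep(bias, each = prod(dim(y)[1:3]))
  y
}

layer_bwd <- function(x, main, extra, wm, we, dy) {
  d <- dim(dy)
  at <- 0L
  dx <- array(0, dim(x))
  g <- list(dwm = NULL, dwe = NULL)
  if (!is.null(main) && main$filters_per_group > 0L) {
    k <- n_path_filters(main)
    r <- gconv_bwd(x, wm, main, dy[, , , at + seq_len(k), drop = FALSE])
    dx <- dx + r$dx; g$dwm <- r$dw; at <- at + k
  }
  if (!is.null(extra)) {
    k <- n_path_filters(extra)
    r <- gconv_bwd(x, we, extra, dy[, , , at + seq_len(k), drop = FALSE])
    dx <- dx + r$dx; g$dwe <- r$dw
  }
  g$dx <- dx
  g
}

#' Run a subnetwork forward
#'
#' @param net A [build_subnetwork()] object.
#' @param x Rank-4 array `N x H x W x Ic`.
#' @param keep_cache Keep intermediate tensors for [subnet_backward()].
#' @param training Use batch statistics in the optional L batch-norm
#'   (otherwise the stored running statistics are used).
#' @return `N x H x W x F` output array; with `keep_cache = TRUE`, a list
#'   `list(y, cache)`.
#' @export
subnet_forward <- function(net, x, keep_cache = FALSE, training = FALSE) {
  plan <- net$plan; cfg <- net$cfg; w <- net$weights
  if (dim(x)[4L] != plan$spec$ic)
    stop(sprintf("input has %d channels, plan expects %d", dim(x)[4L], plan$spec$ic))
  k <- layer_fwd(x, plan$k1, plan$k2, w$k1, w$k2, w$bk)
  a <- if (cfg$intermediate_activation == "after_k") activate(k, cfg) else k
  use_l <- plan$has_l && cfg$enable_l
  bnfw <- NULL
  if (use_l) {
    ap <- a[, , , plan$interleave, drop = FALSE]
    l <- layer_fwd(ap, plan$l1, plan$l2, w$l1, w$l2, w$bl)
    if (cfg$l_batch_norm) {
      bnfw <- bn_fwd(l, list(gamma = w$l_gamma, beta = w$l_beta), net$rs, training)
      l <- bnfw$y
    }
    y <- a + l
  } else {
    ap <- NULL
    y <- a
  }
  if (!keep_cache) return(y)
  list(y = y, cache = list(x = x, k = k, a = a, ap = ap, bnfw = bnfw,
                           training = training))
}

#' Backpropagate through a subnetwork
#'
#' @param net A [build_subnetwork()] object.
#' @param cache The cache from `subnet_forward(net, x, keep_cache = TRUE)`.
#' @param dy Gradient of the loss w.r.t. the subnetwork output.
#' @return List with `dx` (gradient w.r.t. the input) and `dw` (gradient
#'   list shaped like `net$weights`).
#' @export
subnet_backward <- function(net, cache, dy) {
  plan <- net$plan; cfg <- net$cfg; w <- net$weights
  use_l <- plan$has_l && cfg$enable_l
  dw <- list()
  if (use_l) {
    dl <- dy
    if (cfg$l_batch_norm) {
      gbn <- bn_bwd(dy, list(gamma = w$l_gamma, beta = w$l_beta), cache$bnfw,
                    cache$training)
      dl <- gbn$dx
      dw$l_gamma <- gbn$dgamma; dw$l_beta <- gbn$dbeta
    }
    gl <- layer_bwd(cache$ap, plan$l1, plan$l2, w$l1, w$l2, dl)
    dw$l1 <- gl$dwm; dw$l2 <- gl$dwe
    if (cfg$use_bias) dw$bl <- colSums(matrix(dl, ncol = plan$spec$f))
    # undo the interleave on the gradient flowing back to `a`
    inv <- order(plan$interleave)
    da <- dy + gl$dx[, , , inv, drop = FALSE]
  } else {
    da <- dy
  }
  dk <- if (cfg$intermediate_activation == "after_k")
    da * activate_grad(cache$k, cfg) else da
  gk <- layer_bwd(cache$x, plan$k1, plan$k2, w$k1, w$k2, dk)
  dw$k1 <- gk$dwm; dw$k2 <- gk$dwe
  if (cfg$use_bias) dw$bk <- colSums(matrix(dk, ncol = plan$spec$f))
  list(dx = gk$dx, dw = dw[!vapply(dw, is.null, logical(1))])
}
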