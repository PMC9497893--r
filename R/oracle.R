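# Brute-force reference implementations of standard and grouped pointwise
# convolutions.  These are the ground truth that the fast subnetwork forward
# is tested against; clarity is preferred over speed throughout.

#' Create a feature-map stack
#'
#' Feature maps are plain numeric arrays in `N x H x W x C` layout
#' (batch, height, width, channels).  This helper validates the shape.
#'
#' @param values A rank-4 numeric array, or a vector with `dim` supplied.
#' @param dim Optional dimensions when `values` is a vector.
#' @return The array, dimension-checked.
#' @export
feature_maps <- function(values, dim = NULL) {
  if (!is.null(dim)) dim(values) <- dim
  if (length(dim(values)) != 4L)
    stop("feature maps must be a rank-4 array in N x H x W x C layout")
  if (!all(is.finite(values))) stop("feature maps must be finite")
  values
}

#' Standard pointwise (1x1) convolution, reference implementation
#'
#' Each output channel `j` at each spatial position is the inner product of
#' the input channel vector with filter row `j`.  Computed as one matrix
#' product in double precision; this routine is the equivalence oracle for
#' the grouped subnetwork.
#'
#' @param x Rank-4 array `N x H x W x C`.
#' @param w Weight matrix `F x C`, one row per filter.
#' @return Rank-4 array `N x H x W x F`.
#' @examples
#' x <- array(1, c(1, 2, 2, 3))
#' w <- diag(3)
#' all(pointwise_conv(x, w) == x)
#' @export
pointwise_conv <- function(x, w) {
  d <- dim(x)
  if (length(d) != 4L) stop("`x` must be a rank-4 N x H x W x C array")
  w <- as.matrix(w)
  if (ncol(w) != d[4L])
    stop(sprintf("filter width %d does not match %d input channels",
                 ncol(w), d[4L]))
  y <- matrix(x, ncol = d[4L]) %*% t(w)
  dim(y) <- c(d[1:3], nrow(w))
  y
}

#' Grouped pointwise convolution, reference implementation
#'
#' Applies [pointwise_conv()] independently to each group: the channels
#' listed in `input_groups[[m]]` are gathered (repeated indices are
#' gathered twice -- replication semantics) and convolved with
#' `per_group_weights[[m]]`; the group outputs are concatenated along the
#' channel axis in group order.
#'
#' @param x Rank-4 array `N x H x W x C`.
#' @param per_group_weights List of `Fg x ch` weight matrices.
#' @param input_groups List of 1-based channel index vectors, one per group.
#' @return Rank-4 array with `sum(filters per group)` channels.
#' @export
grouped_pointwise_conv <- function(x, per_group_weights, input_groups) {
  if (length(per_group_weights) != length(input_groups))
    stop("one weight matrix per input group is required")
  d <- dim(x)
  outs <- mapply(function(w, idx) {
    idx <- as.integer(idx)
    if (any(idx < 1L | idx > d[4L])) stop("channel index out of range")
    pointwise_conv(x[, , , idx, drop = FALSE], w)
  }, per_group_weights, input_groups, SIMPLIFY = FALSE)
  concat_channels(outs)
}

concat_channels <- function(tensors) {
  d <- dim(tensors[[1L]])
  cs <- vapply(tensors, function(t) dim(t)[4L], integer(1))
  out <- array(0, c(d[1:3], sum(cs)))
  at <- 0L
  for (t in tensors) {
    k <- dim(t)[4L]
    out[, , , at + seq_len(k)] <- t
    at <- at + k
  }
  out
}

#' Densify a substitution plan into equivalent full weight matrices
#'
#' Scatters the grouped, replicated filter weights of a plan into the
#' block-sparse full matrices they are equivalent to in linear mode
#' (no activations).  `wk_eff` is `F x Ic`: filter `j`'s `ch` weights land
#' in the columns its group gathers, and a channel gathered twice through
#' replication accumulates both weights.  `wl_eff` is `F x F` and acts on
#' the *interleaved* K output, so the linear subnetwork satisfies
#' `out = k + pointwise_conv(k[, , , perm], wl_eff)` with
#' `k = pointwise_conv(x, wk_eff)`.
#'
#' @param plan A [substitution_plan()].
#' @param weights Subnetwork weights as produced by [subnet_weights()]:
#'   a list with per-path matrices `k1`, `k2`, `l1`, `l2` (rows =
#'   filters in group-major order, `ch` columns).
#' @return List with `wk_eff` (`F x Ic`) and `wl_eff` (`F x F` or `NULL`).
#' @export
densify <- function(plan, weights) {
  stopifnot(inherits(plan, "substitution_plan"))
  s <- plan$spec
  scatter <- function(main, extra, wm, we, n_in) {
    eff <- matrix(0, s$f, n_in)
    row <- 0L
    add_path <- function(p, w) {
      if (is.null(p)) return(invisible())
      if (is.null(w) || nrow(w) != p$groups * p$filters_per_group ||
          ncol(w) != s$ch)
        stop("weight matrix shape does not match the plan")
      for (m in seq_len(p$groups)) {
        idx <- p$input_groups[[m]]
        for (j in seq_len(p$filters_per_group)) {
          row <<- row + 1L
          for (k in seq_len(s$ch))                 # accumulate: replicated
            eff[row, idx[k]] <<- eff[row, idx[k]] + w[(m - 1L) * p$filters_per_group + j, k]
        }
      }
    }
    add_path(main, wm); add_path(extra, we)
    eff
  }
  wk_eff <- scatter(plan$k1, plan$k2, weights$k1, weights$k2, s$ic)
  wl_eff <- if (plan$has_l)
    scatter(plan$l1, plan$l2, weights$l1, weights$l2, s$f)
  list(wk_eff = wk_eff, wl_eff = wl_eff)
}
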