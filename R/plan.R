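#' Describe a pointwise convolution layer to be substituted
#'
#' A `layer_spec` is the triple that fully determines a substitution:
#' the number of input channels `ic`, the number of filters (output
#' channels) `f`, and the number of input channels fed to each group of
#' filters, `ch`.  `ch` is the scheme's single hyperparameter.
#'
#' @param ic Number of input channels (positive integer).
#' @param f Number of filters, i.e. output channels (positive integer).
#' @param ch Channels per group of filters (positive integer).
#' @return An object of class `"layer_spec"`.
#' @examples
#' layer_spec(14, 10, 4)
#' @export
layer_spec <- function(ic, f, ch) {
  ic <- check_count(ic, "ic"); f <- check_count(f, "f"); ch <- check_count(ch, "ch")
  structure(list(ic = ic, f = f, ch = ch), class = "layer_spec")
}

check_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != round(x))
    stop(sprintf("`%s` must be a single positive integer, got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  as.integer(x)
}

#' @export
print.layer_spec <- function(x, ...) {
  cat(sprintf("pointwise layer: %d input channels, %d filters, Ch = %d\n",
              x$ic, x$f, x$ch))
  invisible(x)
}

#' Is a layer eligible for grouped substitution?
#'
#' A layer can be substituted only when `ch` does not exceed half the input
#' channel count and half the filter count; otherwise the grouped divisions
#' degenerate (fewer than two groups) and the original pointwise convolution
#' is kept.
#'
#' @param spec A [layer_spec()], or the `ic` value if `f` and `ch` are given.
#' @param f,ch Optional; supply all three integers instead of a `layer_spec`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_eligible(layer_spec(14, 10, 4))   # TRUE
#' is_eligible(14, 10, 8)               # FALSE: ch > f/2
#' @export
is_eligible <- function(spec, f = NULL, ch = NULL) {
  if (!inherits(spec, "layer_spec")) spec <- layer_spec(spec, f, ch)
  spec$ch <= spec$ic / 2 && spec$ch <= spec$f / 2
}

#' Partition channel indices into groups of fixed width
#'
#' Splits `n_channels` channel indices into `ceiling(n_channels / ch)`
#' groups of exactly `ch` indices each.  When `ch` does not divide
#' `n_channels` the last group is completed by replicating the leading
#' channels: it holds the remaining `ch - d` real indices followed by the
#' first `d` indices, where `d = ceiling(n_channels/ch) * ch - n_channels`
#' is the deficit of the division.  Every real channel appears at least
#' once.  Indices are 1-based.
#'
#' @param n_channels Number of channels to partition (positive integer).
#' @param ch Group width (positive integer).
#' @return A list of integer vectors, each of length `ch`.
#' @examples
#' channel_groups(14, 4)  # last group is c(13, 14, 1, 2)
#' channel_groups(8, 4)   # exact split, no replication
#' @export
channel_groups <- function(n_channels, ch) {
  n_channels <- check_count(n_channels, "n_channels"); ch <- check_count(ch, "ch")
  g <- ceiling(n_channels / ch)
  d <- g * ch - n_channels                 # deficit, 0 <= d < ch
  # rep_len cycles when the deficit exceeds the channel count (only
  # possible for ch > n_channels, outside the eligible regime)
  idx <- c(seq_len(n_channels), rep_len(seq_len(n_channels), d))
  split(idx, rep(seq_len(g), each = ch))
}

#' Odd-first channel interleaving permutation
#'
#' Returns the source-index order that places odd-numbered channels first
#' and even-numbered channels last, the fixed shuffle applied between the
#' two grouped layers so that the second layer's groups mix outputs
#' originating from different first-layer groups.  For odd `n` the odd
#' block carries the extra channel.
#'
#' @param n Number of channels (positive integer).
#' @return An integer permutation `p` of `1:n`; apply as `x[p]`.
#' @examples
#' interleave_permutation(10)  # 1 3 5 7 9 2 4 6 8 10
#' @export
interleave_permutation <- function(n) {
  n <- check_count(n, "n")
  c(seq.int(1L, n, by = 2L), if (n >= 2L) seq.int(2L, n, by = 2L))
}

#' Plan the grouped paths of one layer
#'
#' Computes the main grouped path and, when the filter count is not an
#' exact multiple of the group count, a second path holding one filter per
#' group, so that the two paths together emit exactly `f` channels.  The
#' main path has `ceiling(n_input / ch)` groups of
#' `floor(f / groups)` filters; the extra path reuses the leading channel
#' groups of the main path.  When `floor(f / groups)` is zero (very small
#' `ch` with many more input channels than filters) the main path carries
#' no filters and all `f` filters live in the extra path.
#'
#' @param n_input Number of input channels of this layer.
#' @param f Number of filters to emit.
#' @param ch Channels per group.
#' @return A list with components `main` and `extra`; each is a *path
#'   plan*: a list with `groups`, `filters_per_group` and `input_groups`
#'   (a list of 1-based index vectors of length `ch`).  `extra` is `NULL`
#'   when `f` is exactly covered by the main path.
#' @examples
#' plan_paths(14, 10, 4)    # main 4 x 2 filters, extra 2 x 1
#' plan_paths(160, 3840, 16) # main 10 x 384, no extra path
#' @export
plan_paths <- function(n_input, f, ch) {
  n_input <- check_count(n_input, "n_input")
  f <- check_count(f, "f"); ch <- check_count(ch, "ch")
  groups <- as.integer(ceiling(n_input / ch))
  fg <- f %/% groups
  igroups <- channel_groups(n_input, ch)
  main <- list(groups = groups, filters_per_group = as.integer(fg),
               input_groups = igroups)
  extra_g <- f - fg * groups
  extra <- if (extra_g > 0L) {
    list(groups = as.integer(extra_g), filters_per_group = 1L,
         input_groups = igroups[seq_len(extra_g)])
  }
  list(main = main, extra = extra)
}

#' Build the full substitution plan for one pointwise layer
#'
#' Turns a [layer_spec()] into the complete blueprint of the replacement
#' subnetwork: the grouped paths of layer K, and -- when the layer has at
#' least as many input channels as filters -- the interleaving permutation
#' and the grouped paths of layer L, whose output is summed with K's.
#' Layer L consumes the `f` interleaved outputs of K and emits `f`
#' channels, so its paths are planned with `n_input = f`.
#'
#' @param spec A [layer_spec()], or `ic` when `f` and `ch` are supplied.
#' @param f,ch Optional integers, see `spec`.
#' @param force Build the plan even when the eligibility predicate fails
#'   (used by the whole-model substitution policy, which applies a weaker
#'   minimum-group rule).  Default `FALSE`.
#' @param l_ch Group width used for layer L; defaults to `ch`.  The
#'   whole-model convention plans L as a dense `f x f` convolution
#'   (`l_ch = f`) when `f <= ch`, where a grouped L would degenerate to a
#'   single group.
#' @return An object of class `"substitution_plan"` with components
#'   `spec`, `k1`, `k2`, `has_l`, `interleave`, `l1`, `l2`,
#'   `param_count` and `mac_count_per_position`.
#' @examples
#' p <- substitution_plan(14, 10, 4)
#' p$param_count            # 80, against 140 for the standard layer
#' @seealso [is_eligible()], [count_params()], [plan_to_json()]
#' @export
substitution_plan <- function(spec, f = NULL, ch = NULL, force = FALSE,
                              l_ch = NULL) {
  if (!inherits(spec, "layer_spec")) spec <- layer_spec(spec, f, ch)
  if (!force && !is_eligible(spec))
    stop(ineligible_error(spec))
  k <- plan_paths(spec$ic, spec$f, spec$ch)
  has_l <- spec$ic >= spec$f
  if (is.null(l_ch)) l_ch <- spec$ch
  if (has_l) {
    perm <- interleave_permutation(spec$f)
    l <- plan_paths(spec$f, spec$f, l_ch)
  } else {
    perm <- NULL
    l <- list(main = NULL, extra = NULL)
  }
  plan <- structure(list(
    spec = spec, k1 = k$main, k2 = k$extra, has_l = has_l,
    interleave = perm, l1 = l$main, l2 = l$extra,
    param_count = as.integer(spec$f * spec$ch + has_l * spec$f * l_ch),
    mac_count_per_position = as.integer(spec$f * spec$ch + has_l * spec$f * l_ch)
  ), class = "substitution_plan")
  plan
}

ineligible_error <- function(spec) {
  structure(class = c("kpconv_ineligible", "error", "condition"),
            list(message = sprintf(
              "layer (ic=%d, f=%d) is not eligible for Ch=%d (needs ch <= ic/2 and ch <= f/2); keep the original pointwise convolution",
              spec$ic, spec$f, spec$ch), call = NULL, spec = spec))
}

#' Count trainable weights of a substitution plan
#'
#' Every filter in every path carries exactly `ch` weights and no bias, so
#' the total is `2 * f * ch` when layer L is present and `f * ch`
#' otherwise -- independent of how the filters are split into groups.
#'
#' @param plan A [substitution_plan()].
#' @return Integer weight count.
#' @examples
#' count_params(substitution_plan(14, 10, 4))  # 80
#' @export
count_params <- function(plan) {
  stopifnot(inherits(plan, "substitution_plan"))
  path_w <- function(p) {
    if (is.null(p)) return(0L)
    # each filter carries as many weights as its group is wide
    p$groups * p$filters_per_group * length(p$input_groups[[1L]])
  }
  as.integer(path_w(plan$k1) + path_w(plan$k2) + path_w(plan$l1) + path_w(plan$l2))
}

#' Weight count of a standard pointwise convolution
#'
#' @param ic Input channels, or a [layer_spec()].
#' @param f Filters; ignored when `ic` is a `layer_spec`.
#' @return `ic * f`, the bias-free weight count of a 1x1 convolution.
#' @export
baseline_params <- function(ic, f = NULL) {
  if (inherits(ic, "layer_spec")) { f <- ic$f; ic <- ic$ic }
  as.integer(ic) * as.integer(f)
}

#' Weight count of a plain grouped pointwise convolution
#'
#' @param ic Input channels.
#' @param f Filters.
#' @param g Number of groups; must divide both `ic` and `f`.
#' @return `ic * f / g`.
#' @export
grouped_params <- function(ic, f, g) {
  if (ic %% g != 0 || f %% g != 0)
    stop("a plain grouped convolution requires `g` to divide both `ic` and `f`")
  as.integer(ic * f / g)
}

#' Multiply-accumulate count of a plan over a spatial extent
#'
#' Counts one multiply-accumulate per weight per output spatial position,
#' i.e. `h * w * param_count`.  Activation evaluations are not included.
#'
#' @param plan A [substitution_plan()].
#' @param h,w Output spatial size (positive integers).
#' @return Numeric MAC count.
#' @export
count_macs <- function(plan, h, w) {
  stopifnot(inherits(plan, "substitution_plan"))
  check_count(h, "h") * check_count(w, "w") * plan$mac_count_per_position
}

path_str <- function(p) {
  if (is.null(p)) "-" else sprintf("%d x %d", p$groups, p$filters_per_group)
}

#' @export
print.substitution_plan <- function(x, ...) {
  s <- x$spec
  cat(sprintf("substitution plan for (ic=%d, f=%d), Ch=%d\n", s$ic, s$f, s$ch))
  cat(sprintf("  K: main %s, extra %s\n", path_str(x$k1), path_str(x$k2)))
  if (x$has_l) {
    cat(sprintf("  interleave: odd channels first (%d channels)\n", s$f))
    cat(sprintf("  L: main %s, extra %s, summed with K\n",
                path_str(x$l1), path_str(x$l2)))
  } else {
    cat("  L: absent (fewer input channels than filters)\n")
  }
  cat(sprintf("  params: %s of %s (%.2f%%)\n",
              format(x$param_count, big.mark = ","),
              format(baseline_params(s), big.mark = ","),
              100 * x$param_count / baseline_params(s)))
  invisible(x)
}

#' Summarise a plan as one row of the standard layer table
#'
#' @param object A [substitution_plan()].
#' @param ... Unused.
#' @return A one-row data frame with columns `ic`, `f`, `p`, `ch`, `gk1`,
#'   `fgk1`, `gk2`, `gl1`, `fgl1`, `gl2`, `total`, `pct` mirroring the
#'   conventional presentation of grouped-substitution layer tables.
#' @export
summary.substitution_plan <- function(object, ...) {
  s <- object$spec
  g <- function(p, field) if (is.null(p)) 0L else p[[field]]
  data.frame(
    ic = s$ic, f = s$f, p = baseline_params(s), ch = s$ch,
    gk1 = g(object$k1, "groups"), fgk1 = g(object$k1, "filters_per_group"),
    gk2 = g(object$k2, "groups"),
    gl1 = g(object$l1, "groups"), fgl1 = g(object$l1, "filters_per_group"),
    gl2 = g(object$l2, "groups"),
    total = object$param_count,
    pct = round(100 * object$param_count / baseline_params(s), 2)
  )
}

#' Serialize a substitution plan to JSON
#'
#' The document carries the layer triple, the group/filter counts and
#' channel-index groups of every path, the interleaving permutation and
#' the parameter count.  Channel indices are written 1-based, exactly as
#' stored.
#'
#' @param plan A [substitution_plan()].
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
plan_to_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "substitution_plan"))
  ser_path <- function(p) if (is.null(p)) NULL else
    list(groups = p$groups, filters_per_group = p$filters_per_group,
         input_groups = lapply(p$input_groups, as.integer))
  doc <- list(
    spec = unclass(plan$spec),
    k1 = ser_path(plan$k1), k2 = ser_path(plan$k2),
    has_l = plan$has_l,
    interleave = if (plan$has_l) as.integer(plan$interleave),
    l1 = ser_path(plan$l1), l2 = ser_path(plan$l2),
    param_count = plan$param_count
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}

#' Read a substitution plan back from JSON
#'
#' @param json A JSON string or a file path produced by [plan_to_json()].
#' @return A `"substitution_plan"` object.
#' @export
plan_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  de_path <- function(p) if (is.null(p)) NULL else
    list(groups = as.integer(p$groups),
         filters_per_group = as.integer(p$filters_per_group),
         input_groups = lapply(p$input_groups, as.integer))
  spec <- layer_spec(doc$spec$ic, doc$spec$f, doc$spec$ch)
  structure(list(
    spec = spec, k1 = de_path(doc$k1), k2 = de_path(doc$k2),
    has_l = isTRUE(doc$has_l),
    interleave = if (isTRUE(doc$has_l)) as.integer(doc$interleave),
    l1 = de_path(doc$l1), l2 = de_path(doc$l2),
    param_count = as.integer(doc$param_count),
    mac_count_per_position = as.integer(doc$param_count)
  ), class = "substitution_plan")
}
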