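# Declarative EfficientNet-B0 backbone: a stage table expanded into a flat
# layer inventory from which models are built and parameters are counted.

#' EfficientNet-B0 backbone descriptor
#'
#' The canonical B0 stage table: a 3x3 stem with 32 filters, seven MBConv
#' stages (16x1 k3 s1 e1; 24x2 k3 s2 e6; 40x2 k5 s2 e6; 80x3 k3 s2 e6;
#' 112x3 k5 s1 e6; 192x4 k5 s2 e6; 320x1 k3 s1 e6), squeeze-and-excitation
#' ratio 0.25 throughout, a 1x1 head convolution to 1280 channels, global
#' average pooling and a dense softmax classifier.
#'
#' @param num_classes Number of output classes (default 10).
#' @param input_size Input height = width in pixels (default 224).
#' @param skip_strides How many leading stride-2 convolutions are forced to
#'   stride 1 (counting the stem), so that low-resolution inputs such as
#'   32 x 32 traverse the full network.  Default 0.
#' @return An object of class `"backbone_descriptor"`.
#' @examples
#' effnet_b0(num_classes = 10)
#' effnet_b0(num_classes = 10, input_size = 32, skip_strides = 4)
#' @export
effnet_b0 <- function(num_classes = 10, input_size = 224, skip_strides = 0) {
  num_classes <- check_count(num_classes, "num_classes")
  if (num_classes < 2) stop("`num_classes` must be at least 2")
  stages <- data.frame(
    kernel = c(3L, 3L, 5L, 3L, 5L, 5L, 3L),
    repeats = c(1L, 2L, 2L, 3L, 3L, 4L, 1L),
    filters = c(16L, 24L, 40L, 80L, 112L, 192L, 320L),
    expand = c(1L, 6L, 6L, 6L, 6L, 6L, 6L),
    stride = c(1L, 2L, 2L, 2L, 1L, 2L, 1L)
  )
  desc <- structure(list(
    stages = stages, stem_filters = 32L, head_filters = 1280L,
    se_ratio = 0.25, num_classes = num_classes,
    input_size = check_count(input_size, "input_size"),
    skip_strides = 0L
  ), class = "backbone_descriptor")
  if (skip_strides > 0) desc <- apply_stride_skip(desc, skip_strides)
  desc
}

#' @export
print.backbone_descriptor <- function(x, ...) {
  cat(sprintf("EfficientNet-B0 descriptor: %d classes, input %dx%d",
              x$num_classes, x$input_size, x$input_size))
  if (x$skip_strides > 0)
    cat(sprintf(", first %d strides skipped", x$skip_strides))
  cat("\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Force the first k stride-2 convolutions to stride 1
#'
#' Counting the stem first and then the downsampling blocks in forward
#' order, the first `k` stride-2 convolutions are set to stride 1.  The
#' parameter count is unchanged (strides carry no weights); only spatial
#' sizes downstream change, which lets 32 x 32 inputs reach the head at a
#' useful resolution.
#'
#' @param desc A [effnet_b0()] descriptor.
#' @param k Number of leading stride-2 convolutions to neutralise.
#' @return The modified descriptor, with `skip_strides` recorded.
#' @export
apply_stride_skip <- function(desc, k) {
  stopifnot(inherits(desc, "backbone_descriptor"))
  k <- check_count(k, "k")
  n_stride2 <- 1L + sum(desc$stages$stride == 2L)  # stem is stride 2
  if (k > n_stride2)
    stop(sprintf("only %d stride-2 convolutions exist, cannot skip %d",
                 n_stride2, k))
  desc$skip_strides <- as.integer(desc$skip_strides + k)
  desc
}

# Which stride-2 units actually run at stride 2, given skip_strides.
# Unit 0 is the stem; units 1..n index the stages with stride 2 in order.
effective_strides <- function(desc) {
  s2_stage <- which(desc$stages$stride == 2L)
  units <- c(0L, s2_stage)               # forward order: stem then stages
  skipped <- seq_len(min(desc$skip_strides, length(units)))
  list(stem = !(1L %in% skipped),
       stage = vapply(seq_len(nrow(desc$stages)), function(i) {
         pos <- match(i, s2_stage)
         if (is.na(pos)) FALSE else !((pos + 1L) %in% skipped)
       }, logical(1)))
}

#' Flat layer inventory of a backbone
#'
#' Expands the stage table into one row per weighted unit: convolutions
#' (`conv`, `dw`, `pw`), batch-normalisations (`bn`) and the dense head.
#' Pointwise convolutions carry a `role` (`expand`, `se_reduce`,
#' `se_expand`, `project`, `head`) used by the substitution step.
#'
#' @param desc A [effnet_b0()] descriptor.
#' @return A data frame with columns `name`, `unit` (conv/dw/bn/dense),
#'   `role`, `ic`, `f`, `kernel`, `stride`, `bias`, and the output spatial
#'   size `hw` of each convolution given the descriptor's input size and
#'   stride skipping.
#' @export
layer_inventory <- function(desc) {
  stopifnot(inherits(desc, "backbone_descriptor"))
  eff <- effective_strides(desc)
  rows <- list()
  add <- function(name, unit, role, ic, f, kernel = 1L, stride = 1L,
                  bias = FALSE, hw = NA_integer_)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, unit = unit, role = role, ic = ic, f = f,
      kernel = kernel, stride = stride, bias = bias, hw = hw)
  hw <- desc$input_size
  stem_stride <- if (eff$stem) 2L else 1L
  hw <- ceiling(hw / stem_stride)
  add("stem_conv", "conv", "stem", 3L, desc$stem_filters, 3L, stem_stride, hw = hw)
  add("stem_bn", "bn", "stem", desc$stem_filters, desc$stem_filters)
  st <- desc$stages
  for (i in seq_len(nrow(st))) {
    ic <- if (i == 1L) desc$stem_filters else st$filters[i - 1L]
    for (r in seq_len(st$repeats[i])) {
      nm <- sprintf("block%d_%d", i, r)
      stride <- if (r == 1L && st$stride[i] == 2L && eff$stage[i]) 2L else 1L
      exp <- ic * st$expand[i]
      if (st$expand[i] != 1L) {
        add(paste0(nm, "_expand"), "pw", "expand", ic, exp, hw = hw)
        add(paste0(nm, "_expand_bn"), "bn", "expand", exp, exp)
      }
      hw <- ceiling(hw / stride)
      add(paste0(nm, "_dw"), "dw", "depthwise", exp, exp, st$kernel[i], stride, hw = hw)
      add(paste0(nm, "_dw_bn"), "bn", "depthwise", exp, exp)
      se <- max(1L, as.integer(ic * desc$se_ratio))
      add(paste0(nm, "_se_reduce"), "pw", "se_reduce", exp, se, bias = TRUE, hw = 1L)
      add(paste0(nm, "_se_expand"), "pw", "se_expand", se, exp, bias = TRUE, hw = 1L)
      add(paste0(nm, "_project"), "pw", "project", exp, st$filters[i], hw = hw)
      add(paste0(nm, "_project_bn"), "bn", "project", st$filters[i], st$filters[i])
      ic <- st$filters[i]
    }
  }
  add("head_conv", "pw", "head", st$filters[nrow(st)], desc$head_filters, hw = hw)
  add("head_bn", "bn", "head", desc$head_filters, desc$head_filters)
  add("classifier", "dense", "classifier", desc$head_filters, desc$num_classes,
      bias = TRUE, hw = 1L)
  inv <- do.call(rbind, rows)
  rownames(inv) <- NULL
  inv
}

# trainable weights of one inventory row (original, unsubstituted)
unit_params <- function(row) {
  with(row, switch(unit,
    conv = kernel^2 * ic * f + if (bias) f else 0L,
    pw = ic * f + if (bias) f else 0L,
    dw = kernel^2 * f,
    bn = 2L * f,                          # gamma and beta
    dense = ic * f + f))
}

#' Trainable-parameter count of the unmodified backbone
#'
#' @param desc A [effnet_b0()] descriptor.
#' @return Integer: the sum of convolution weights, batch-norm scale/shift
#'   pairs and dense weights/biases.  Batch-norm running statistics are
#'   not trainable and are not counted.
#' @examples
#' backbone_params(effnet_b0(num_classes = 10))  # 4020358
#' @export
backbone_params <- function(desc) {
  inv <- layer_inventory(desc)
  sum(vapply(seq_len(nrow(inv)), function(i) unit_params(inv[i, ]), numeric(1)))
}
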