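# Short optimisation loop for learnability checks.  This is a smoke-train
# facility: it verifies that a substituted model can fit small synthetic
# data, not a full training protocol.

tree_map2 <- function(f, a, b) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (nm in names(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
  out
}

tree_zero <- function(a) {
  if (is.numeric(a)) return(a * 0)
  lapply(a, tree_zero)
}

# one RMSProp step; returns list(par, state)
rmsprop_step <- function(par, grads, state, lr = 1e-3, rho = 0.9, eps = 1e-7) {
  state <- tree_map2(function(v, g) rho * v + (1 - rho) * g * g, state, grads)
  upd <- function(p, g, v) p - lr * g / (sqrt(v) + eps)
  walk <- function(p, g, v) {
    if (is.numeric(p)) return(upd(p, g, v))
    out <- p
    for (nm in names(p)) out[[nm]] <- walk(p[[nm]], g[[nm]], v[[nm]])
    out
  }
  list(par = walk(par, grads, state), state = state)
}

#' Smoke-train a model on a small dataset
#'
#' Runs a short RMSProp optimisation and records the loss and training
#' accuracy per epoch.  Intended as a learnability sanity check: with a
#' fixed seed, a substituted model should exceed chance accuracy on a
#' class-separable synthetic set within a few epochs.  Divergence
#' (non-finite loss) aborts with a distinct error.
#'
#' @param model A `"kpconv_model"`.
#' @param data A [generate_synthetic_set()] list with `images` and
#'   `labels` (1-based integer classes).
#' @param epochs Number of passes over the data; `0` returns an empty
#'   history and the model unchanged.
#' @param batch_size Minibatch size (default 16).
#' @param lr RMSProp learning rate (default 1e-3).
#' @param seed Integer seed controlling shuffling.
#' @return An object of class `"smoke_history"`: list with `history`
#'   (data frame of epoch, loss, acc) and the trained `model`.
#' @export
smoke_train <- function(model, data, epochs, batch_size = 16L, lr = 1e-3,
                        seed = 42L) {
  stopifnot(inherits(model, "kpconv_model"))
  epochs <- as.integer(epochs)
  if (epochs < 0) stop("`epochs` must be non-negative")
  hist <- data.frame(epoch = integer(), loss = numeric(), acc = numeric())
  if (epochs == 0L)
    return(structure(list(history = hist, model = model),
                     class = "smoke_history"))
  n <- dim(data$images)[1L]
  set.seed(seed)
  state <- tree_zero(model$par)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c(); accs <- c()
    for (b in seq_len(ceiling(n / batch_size))) {
      idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
      xb <- data$images[idx, , , , drop = FALSE]
      yb <- data$labels[idx]
      g <- model_grad(model, xb, yb, training = TRUE)
      if (!is.finite(g$loss))
        stop("smoke_train diverged: non-finite loss", call. = FALSE)
      model$rs <- g$rs
      st <- rmsprop_step(model$par, g$grads, state, lr = lr)
      model$par <- st$par; state <- st$state
      losses <- c(losses, g$loss); accs <- c(accs, g$acc)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   acc = mean(accs)))
  }
  structure(list(history = hist, model = model), class = "smoke_history")
}

#' @export
print.smoke_history <- function(x, ...) {
  if (nrow(x$history) == 0L) cat("empty training history (0 epochs)\n")
  else {
    cat("smoke-training history:\n")
    print(x$history, row.names = FALSE)
  }
  invisible(x)
}
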