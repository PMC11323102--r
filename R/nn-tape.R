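# Minimal reverse-mode autodiff on a linear tape.
#
# Activations are H x W x C x N arrays (or N x p matrices after pooling);
# nodes are environments recording value, parents and a backward closure.
# Backward walks the tape in reverse creation order, which is a valid
# topological order because the graph is built by a single forward pass.

new_tape <- function(training = TRUE) {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape$training <- training
  tape$pnodes <- new.env(parent = emptyenv())
  tape
}

tape_node <- function(tape, val, parents = list(), backward = NULL,
                      param = NULL) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$param <- param
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- node
  node
}

#' @keywords internal
accumulate_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# A learnable parameter: persistent across steps, with gradient and
# optimizer state slots.
nn_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$val <- value
  p$grad <- NULL
  p$name <- name
  p$s1 <- NULL  # optimizer slot (accumulated squared gradient / first moment)
  p$s2 <- NULL  # optimizer slot (accumulated squared update / second moment)
  p
}

# Wrap a parameter as a tape node, once per tape, so repeated use in one
# graph accumulates into a single gradient.
param_node <- function(tape, p) {
  key <- format(p)  # environment address: unique per parameter
  nd <- tape$pnodes[[key]]
  if (is.null(nd)) {
    nd <- tape_node(tape, p$val, param = p)
    assign(key, nd, envir = tape$pnodes)
  }
  nd
}

# Reverse sweep from a scalar loss node; gradients land in node$grad and
# are then folded into the underlying parameters.
tape_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    gs <- node$backward(node)
    for (j in seq_along(node$parents)) {
      if (!is.null(gs[[j]])) accumulate_grad(node$parents[[j]], gs[[j]])
    }
    if (i > 1L) node$backward <- NULL  # release closures early
  }
  for (i in seq_len(tape$n)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$param) && !is.null(node$grad)) {
      if (is.null(node$param$grad)) node$param$grad <- node$grad
      else node$param$grad <- node$param$grad + node$grad
    }
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
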