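# Reverse-mode tape for the network. Each node is a small environment with a
# value, an accumulated gradient, its parents and a backward closure mapping
# the node's gradient to its parents' gradients. When `tape` is NULL the ops
# run value-only (inference), so no graph is retained.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$count <- 0L
  t
}

ag_node <- function(tape, value, parents = list(), backward = NULL,
                    name = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$name <- name
  if (!is.null(tape)) {
    n$parents <- parents
    n$backward <- backward
    tape$count <- tape$count + 1L
    if (tape$count > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$count]] <- n
  }
  n
}

ag_accumulate <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# Seed the loss node with gradient 1 and sweep the tape in reverse.
ag_backward <- function(tape, loss) {
  loss$grad <- 1
  for (k in rev(seq_len(tape$count))) {
    n <- tape$nodes[[k]]
    if (is.null(n$grad) || is.null(n$backward)) next
    gs <- n$backward(n$grad)
    for (i in seq_along(gs)) {
      if (!is.null(gs[[i]])) ag_accumulate(n$parents[[i]], gs[[i]])
    }
  }
  invisible(NULL)
}

ag_conv <- function(tape, x, w, b) {
  y <- conv2d_fwd(x$value, w$value, b$value)
  ag_node(tape, y, list(x, w, b), function(g) {
    r <- conv2d_bwd(x$value, w$value, g)
    list(r$dx, r$dw, r$db)
  })
}

ag_convt2 <- function(tape, x, w, b) {
  y <- convt2_fwd(x$value, w$value, b$value)
  ag_node(tape, y, list(x, w, b), function(g) {
    r <- convt2_bwd(x$value, w$value, g)
    list(r$dx, r$dw, r$db)
  })
}

# Batch normalisation. In training mode the batch statistics are used and the
# running estimates updated in `state`; in inference mode the running
# estimates give a deterministic affine map (the stochasticity of the network
# comes from the permanently active dropout, not from normalisation).
ag_bn <- function(tape, x, gamma, beta, state, name, training,
                  eps = 1e-5, momentum = 0.9) {
  if (training) {
    st <- bn_stats(x$value)
    run <- state[[name]] %||% list(mean = st$mean * 0, var = st$var * 0 + 1)
    state[[name]] <- list(mean = momentum * run$mean + (1 - momentum) * st$mean,
                          var = momentum * run$var + (1 - momentum) * st$var)
    y <- bn_apply(x$value, st$mean, st$var, gamma$value, beta$value, eps)
    ag_node(tape, y, list(x, gamma, beta), function(g) {
      r <- bn_bwd(x$value, st$mean, st$var, gamma$value, eps, g)
      list(r$dx, r$dgamma, r$dbeta)
    })
  } else {
    run <- state[[name]] %||%
      list(mean = numeric(length(gamma$value)),
           var = numeric(length(gamma$value)) + 1)
    y <- bn_apply(x$value, run$mean, run$var, gamma$value, beta$value, eps)
    ag_node(tape, y, list(x, gamma, beta), function(g) {
      istd <- 1 / sqrt(run$var + eps)
      scale <- gamma$value * istd
      dims <- dim(x$value)
      hw <- dims[1] * dims[2]
      sc4 <- array(rep(rep(scale, times = dims[4]), each = hw), dims)
      list(g * sc4, NULL, NULL)
    })
  }
}

ag_relu <- function(tape, x) {
  y <- x$value * (x$value > 0)
  ag_node(tape, y, list(x), function(g) list(g * (x$value > 0)))
}

ag_add <- function(tape, x, y) {
  ag_node(tape, x$value + y$value, list(x, y), function(g) list(g, g))
}

ag_pool <- function(tape, x) {
  r <- maxpool2_fwd(x$value)
  ag_node(tape, r$y, list(x), function(g) {
    list(maxpool2_bwd(r$idx, g, dim(x$value)))
  })
}

ag_concat <- function(tape, xs) {
  dims <- lapply(xs, function(x) dim(x$value))
  chs <- vapply(dims, function(d) d[3], numeric(1))
  d0 <- dims[[1]]
  out <- array(0, c(d0[1], d0[2], sum(chs), d0[4]))
  at <- 0L
  for (x in xs) {
    ch <- dim(x$value)[3]
    out[, , at + seq_len(ch), ] <- x$value
    at <- at + ch
  }
  ag_node(tape, out, xs, function(g) {
    at <- 0L
    lapply(xs, function(x) {
      ch <- dim(x$value)[3]
      gi <- g[, , at + seq_len(ch), , drop = FALSE]
      at <<- at + ch
      gi
    })
  })
}

# Spatial (channel-wise) dropout, inverted scaling, permanently active: the
# same op runs at training and at inference, which is the method's defining
# trait. Draws from the session RNG.
ag_dropout_spatial <- function(tape, x, rate) {
  if (rate <= 0) return(x)
  dims <- dim(x$value)
  keep <- (stats::runif(dims[3] * dims[4]) >= rate) / (1 - rate)
  m4 <- array(rep(keep, each = dims[1] * dims[2]), dims)
  ag_node(tape, x$value * m4, list(x), function(g) list(g * m4))
}

# Binary cross-entropy on logits, mean over all pixels and batch items.
ag_bce_loss <- function(tape, logits, target) {
  p <- sigmoid(logits$value)
  eps <- 1e-12
  loss <- -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps))
  ag_node(tape, loss, list(logits), function(g) {
    list(g * (p - target) / length(target))
  })
}
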