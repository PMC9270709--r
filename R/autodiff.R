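# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Nodes are environments recorded on a tape in creation (topological) order;
# ad_backward() walks the tape in reverse accumulating gradients.  Only the
# operations the two neural sentence classifiers need are implemented.
# Everything is deliberately single-threaded and deterministic.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_record <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$tape <- tape
  if (tape$n == length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- nd
  nd
}

# Leaf holding a constant (no gradient flows further back).
ad_const <- function(tape, value) ad_record(tape, value)

# Leaf bound to a persistent parameter environment `p` (fields $value, $m,
# $v for Adam); after backward the gradient is read from the node.
ad_param <- function(tape, p) {
  nd <- ad_record(tape, p$value)
  nd$param <- p
  nd
}

ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad, nd)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      if (is.null(gs[[k]])) next
      p <- ps[[k]]
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(NULL)
}

ad_matmul <- function(a, b) {
  ad_record(a$tape, a$value %*% b$value, list(a, b), function(g, nd) {
    list(g %*% t(nd$parents[[2]]$value), t(nd$parents[[1]]$value) %*% g)
  })
}

# a %*% C for a constant matrix C on the right.
ad_matmul_constR <- function(a, C) {
  force(C)
  ad_record(a$tape, a$value %*% C, list(a),
            function(g, nd) list(g %*% t(C)))
}

# C %*% a for a constant matrix C on the left (pooling matrices).
ad_matmul_constL <- function(C, a) {
  force(C)
  ad_record(a$tape, C %*% a$value, list(a),
            function(g, nd) list(t(C) %*% g))
}

# Addition; `b` may be a 1 x k bias row broadcast over the rows of `a`.
ad_add <- function(a, b) {
  av <- a$value; bv <- b$value
  if (is.matrix(bv) && nrow(bv) == 1L && nrow(av) > 1L) {
    val <- av + matrix(bv, nrow(av), ncol(av), byrow = TRUE)
    ad_record(a$tape, val, list(a, b), function(g, nd) {
      list(g, matrix(colSums(g), 1L))
    })
  } else {
    ad_record(a$tape, av + bv, list(a, b), function(g, nd) list(g, g))
  }
}

ad_sub <- function(a, b) {
  ad_record(a$tape, a$value - b$value, list(a, b),
            function(g, nd) list(g, -g))
}

ad_hadamard <- function(a, b) {
  ad_record(a$tape, a$value * b$value, list(a, b), function(g, nd) {
    list(g * nd$parents[[2]]$value, g * nd$parents[[1]]$value)
  })
}

# Multiply by a numeric constant (scalar or same-shape matrix).
ad_scale <- function(a, s) {
  force(s)
  ad_record(a$tape, a$value * s, list(a), function(g, nd) list(g * s))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  ad_record(a$tape, v, list(a), function(g, nd) {
    list(g * nd$value * (1 - nd$value))
  })
}

ad_tanh <- function(a) {
  v <- tanh(a$value)
  ad_record(a$tape, v, list(a), function(g, nd) {
    list(g * (1 - nd$value^2))
  })
}

ad_relu <- function(a) {
  v <- a$value
  v[v < 0] <- 0
  ad_record(a$tape, v, list(a), function(g, nd) {
    list(g * (nd$value > 0))
  })
}

ad_transpose <- function(a) {
  ad_record(a$tape, t(a$value), list(a), function(g, nd) list(t(g)))
}

ad_cbind <- function(a, b) {
  ka <- ncol(a$value)
  ad_record(a$tape, cbind(a$value, b$value), list(a, b), function(g, nd) {
    list(g[, seq_len(ka), drop = FALSE],
         g[, -seq_len(ka), drop = FALSE])
  })
}

# Column slice (used to split stacked LSTM gate pre-activations).
ad_cols <- function(a, jidx) {
  force(jidx)
  nc <- ncol(a$value)
  ad_record(a$tape, a$value[, jidx, drop = FALSE], list(a),
            function(g, nd) {
              gf <- matrix(0, nrow(g), nc)
              gf[, jidx] <- g
              list(gf)
            })
}

# Embedding lookup: rows of a parameter matrix by (possibly repeated) index.
ad_rows <- function(E, idx) {
  force(idx)
  nr <- nrow(E$value)
  ad_record(E$tape, E$value[idx, , drop = FALSE], list(E),
            function(g, nd) {
              acc <- rowsum(g, group = idx)
              gE <- matrix(0, nr, ncol(g))
              gE[as.integer(rownames(acc)), ] <- acc
              list(gE)
            })
}

# Row-wise softmax of (a + addmask); addmask is a constant matrix of 0 /
# -Inf-like penalties implementing attention masking.
ad_softmax_rows <- function(a, addmask = NULL) {
  z <- a$value
  if (!is.null(addmask)) z <- z + addmask
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  v <- ez / rowSums(ez)
  ad_record(a$tape, v, list(a), function(g, nd) {
    s <- nd$value
    list(s * (g - rowSums(g * s)))
  })
}

# Weighted softmax cross-entropy over rows of `logits`; `y` is an integer
# class index per row, `w` a per-row weight.  Returns a scalar node.
ad_ce_loss <- function(logits, y, w) {
  force(y); force(w)
  z <- logits$value
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(z)
  wsum <- sum(w)
  loss <- -sum(w * log(pmax(p[cbind(seq_len(n), y)], 1e-12))) / wsum
  ad_record(logits$tape, loss, list(logits), function(g, nd) {
    grad <- p
    grad[cbind(seq_len(n), y)] <- grad[cbind(seq_len(n), y)] - 1
    list(g * grad * (w / wsum))
  })
}

# ---- parameter store / optimizer ------------------------------------------

# A parameter environment with Adam moment buffers.
new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$m <- value * 0
  p$v <- value * 0
  p
}

glorot_init <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

# One Adam step over param nodes recorded on a tape, with global-norm
# gradient clipping.  `state` carries the step counter.
adam_step <- function(tape, lr, state, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  pn <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$param) && !is.null(nd$grad)) pn[[length(pn) + 1]] <- nd
  }
  gnorm <- sqrt(sum(vapply(pn, function(nd) sum(nd$grad^2), numeric(1))))
  scale <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
  if (!is.finite(gnorm))
    stop("non-finite gradient; training aborted", call. = FALSE)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nd in pn) {
    p <- nd$param
    g <- nd$grad * scale
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
  }
  invisible(NULL)
}
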