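# Minimal reverse-mode automatic differentiation on a tape of matrix nodes.
# Internal machinery for training; every value is a base-R numeric matrix.
# Nodes are environments so gradients can accumulate by reference.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    needs_grad = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  if (is.null(needs_grad)) {
    needs_grad <- FALSE
    for (p in parents) if (p$needs_grad) { needs_grad <- TRUE; break }
  }
  nd$needs_grad <- needs_grad
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_const <- function(tape, x) {
  ad_node(tape, as_mat(x), needs_grad = FALSE)
}

ad_param <- function(tape, x) {
  ad_node(tape, as_mat(x), needs_grad = TRUE)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

ad_acc <- function(nd, g) {
  if (!nd$needs_grad) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Run the backward pass from a scalar loss node; afterwards every parameter
# node on the tape holds d loss / d param in $grad.
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backward) && nd$needs_grad && !is.null(nd$grad)) {
      nd$backward(nd)
    }
  }
  invisible(NULL)
}

ad_matmul <- function(a, b) {
  ad_node_tape2(a, b, a$value %*% b$value, function(nd) {
    g <- nd$grad
    p1 <- nd$parents[[1L]]
    p2 <- nd$parents[[2L]]
    if (p1$needs_grad) ad_acc(p1, tcrossprod(g, p2$value))
    if (p2$needs_grad) ad_acc(p2, crossprod(p1$value, g))
  })
}

# all binary ops share a tape lookup: nodes do not carry the tape, so the
# caller-facing constructors below receive it explicitly where needed.
# To keep call sites terse we stash the active tape in an environment.
.ad <- new.env(parent = emptyenv())

ad_use_tape <- function(tape) {
  .ad$tape <- tape
  invisible(tape)
}

ad_node_tape2 <- function(a, b, value, backward) {
  ad_node(.ad$tape, value, list(a, b), backward)
}

ad_node_tape1 <- function(a, value, backward) {
  ad_node(.ad$tape, value, list(a), backward)
}

ad_add <- function(a, b) {
  ad_node_tape2(a, b, a$value + b$value, function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad)
    ad_acc(nd$parents[[2L]], nd$grad)
  })
}

ad_sub <- function(a, b) {
  ad_node_tape2(a, b, a$value - b$value, function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad)
    ad_acc(nd$parents[[2L]], -nd$grad)
  })
}

ad_mul <- function(a, b) {
  ad_node_tape2(a, b, a$value * b$value, function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad * nd$parents[[2L]]$value)
    ad_acc(nd$parents[[2L]], nd$grad * nd$parents[[1L]]$value)
  })
}

# matrix + row vector (bias), v is a 1 x n node
ad_addvec <- function(a, v) {
  val <- a$value + rep(v$value, each = nrow(a$value))
  ad_node_tape2(a, v, val, function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad)
    ad_acc(nd$parents[[2L]], matrix(colSums(nd$grad), 1L))
  })
}

# scale row i of a by v[i]; v is a g x 1 node
ad_mul_colvec <- function(a, v) {
  vv <- as.vector(v$value)
  ad_node_tape2(a, v, a$value * vv, function(nd) {
    A <- nd$parents[[1L]]$value
    vvv <- as.vector(nd$parents[[2L]]$value)
    ad_acc(nd$parents[[1L]], nd$grad * vvv)
    ad_acc(nd$parents[[2L]], matrix(rowSums(nd$grad * A), ncol = 1L))
  })
}

ad_scale <- function(a, s) {
  ad_node_tape1(a, a$value * s, local({
    ss <- s
    function(nd) ad_acc(nd$parents[[1L]], nd$grad * ss)
  }))
}

ad_transpose <- function(a) {
  ad_node_tape1(a, t(a$value), function(nd) {
    ad_acc(nd$parents[[1L]], t(nd$grad))
  })
}

ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  nd <- ad_node_tape1(a, y, function(nd) {
    yy <- nd$value
    ad_acc(nd$parents[[1L]], nd$grad * yy * (1 - yy))
  })
  nd
}

ad_tanh <- function(a) {
  y <- tanh(a$value)
  ad_node_tape1(a, y, function(nd) {
    ad_acc(nd$parents[[1L]], nd$grad * (1 - nd$value^2))
  })
}

ad_relu <- function(a) {
  y <- a$value
  y[y < 0] <- 0
  ad_node_tape1(a, y, function(nd) {
    m <- nd$parents[[1L]]$value > 0
    ad_acc(nd$parents[[1L]], nd$grad * m)
  })
}

# numerically stable row-wise softmax
row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

ad_row_softmax <- function(a) {
  y <- row_softmax(a$value)
  ad_node_tape1(a, y, function(nd) {
    yy <- nd$value
    g <- nd$grad
    ad_acc(nd$parents[[1L]], yy * (g - rowSums(g * yy)))
  })
}

# row subset; idx must be distinct
ad_rows <- function(a, idx) {
  ad_node_tape1(a, a$value[idx, , drop = FALSE], local({
    ii <- idx
    function(nd) {
      g0 <- matrix(0, nrow(nd$parents[[1L]]$value), ncol(nd$grad))
      g0[ii, ] <- nd$grad
      ad_acc(nd$parents[[1L]], g0)
    }
  }))
}

ad_cbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, integer(1))
  nd <- ad_node(.ad$tape, do.call(cbind, vals), nodes, function(nd) {
    off <- 0L
    for (j in seq_along(nd$parents)) {
      w <- ncol(nd$parents[[j]]$value)
      ad_acc(nd$parents[[j]], nd$grad[, off + seq_len(w), drop = FALSE])
      off <- off + w
    }
  })
  nd
}

ad_colsums <- function(a) {
  ad_node_tape1(a, matrix(colSums(a$value), 1L), function(nd) {
    p <- nd$parents[[1L]]
    ad_acc(p, matrix(rep(nd$grad, each = nrow(p$value)), nrow(p$value)))
  })
}

# u / ||u||_2
ad_unit <- function(a) {
  nrm <- sqrt(sum(a$value^2))
  y <- a$value / nrm
  ad_node_tape1(a, y, local({
    nn <- nrm
    function(nd) {
      un <- nd$value
      g <- nd$grad
      ad_acc(nd$parents[[1L]], (g - un * sum(g * un)) / nn)
    }
  }))
}

# per-row standardisation (layer norm without affine terms)
ad_layernorm_rows <- function(a, eps = 1e-5) {
  x <- a$value
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  sd_ <- sqrt(va + eps)
  y <- xc / sd_
  ad_node_tape1(a, y, local({
    xc_ <- xc; sd__ <- sd_; n_ <- n
    function(nd) {
      g <- nd$grad
      xh <- nd$value
      gm <- rowMeans(g)
      gx <- rowMeans(g * xh)
      ad_acc(nd$parents[[1L]], (g - gm - xh * gx) / sd__)
    }
  }))
}

# cross-entropy of softmax(logits) against integer label y (1-based);
# logits is a 1 x C node
ad_ce <- function(a, y) {
  z <- as.vector(a$value)
  m <- max(z)
  lse <- m + log(sum(exp(z - m)))
  val <- matrix(lse - z[y], 1L, 1L)
  ad_node_tape1(a, val, local({
    yy <- y
    function(nd) {
      z2 <- as.vector(nd$parents[[1L]]$value)
      sm <- exp(z2 - max(z2))
      sm <- sm / sum(sm)
      sm[yy] <- sm[yy] - 1
      ad_acc(nd$parents[[1L]], matrix(sm, 1L) * as.vector(nd$grad))
    }
  }))
}

# mean squared difference against a constant target matrix
ad_mse <- function(a, target) {
  d <- a$value - target
  n <- length(d)
  ad_node_tape1(a, matrix(mean(d^2), 1L, 1L), local({
    dd <- d; nn <- n
    function(nd) {
      ad_acc(nd$parents[[1L]], (2 / nn) * dd * as.vector(nd$grad))
    }
  }))
}

ad_value <- function(nd) nd$value
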