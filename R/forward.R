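# Full differentiable forward pass over a temporal batch.
#
# Builds the whole computation (set encoding -> top-k summary -> matrix-GRU
# weight evolution -> attention adjacency -> reconstruction -> classifier)
# on a fresh autodiff tape and, on request, runs the backward pass to return
# analytic gradients for every parameter matrix.

# batch: list(x = list of T b x g matrices, tf = tf index vector, y = label)
marlene_forward <- function(params, batch, control, grad = TRUE) {
  tape <- ad_tape()
  ad_use_tape(tape)
  pn <- lapply(params, function(m) ad_param(tape, m))
  T_ <- length(batch$x)
  k <- control$k
  tf <- batch$tf
  WQ <- pn$W0Q
  WK <- pn$W0K
  A_nodes <- vector("list", T_)
  logits <- NULL
  gex_acc <- NULL
  for (t in seq_len(T_)) {
    Xn <- ad_const(tape, batch$x[[t]])
    G <- g_featurize(Xn, pn, control)
    if (control$evolve) {
      Z <- g_topk(G, pn$topk_u, k)
      WQ <- g_gru_step(Z, WQ, pn, "gruQ")
      WK <- g_gru_step(Z, WK, pn, "gruK")
    }
    A <- g_attend(G, WQ, WK, tf, k)
    A_nodes[[t]] <- A
    Xtf <- ad_const(tape, batch$x[[t]][, tf, drop = FALSE])
    R <- ad_matmul(Xtf, ad_transpose(A))
    if (identical(control$objective, "gex")) {
      m <- ad_mse(R, batch$x[[t]])
      gex_acc <- if (is.null(gex_acc)) m else ad_add(gex_acc, m)
    } else {
      lt <- g_decoder_logits(R, pn)
      logits <- if (is.null(logits)) lt else ad_add(logits, lt)
    }
  }
  loss <- if (identical(control$objective, "gex")) {
    ad_scale(gex_acc, 1 / T_)
  } else {
    ad_ce(logits, batch$y)
  }
  out <- list(
    loss = as.numeric(loss$value),
    A = lapply(A_nodes, ad_value),
    logits = if (!is.null(logits)) as.vector(logits$value) else NULL
  )
  if (grad) {
    ad_backward(tape, loss)
    grads <- lapply(pn, function(nd) {
      if (is.null(nd$grad)) matrix(0, nrow(nd$value), ncol(nd$value)) else nd$grad
    })
    names(grads) <- names(pn)
    out$grads <- grads
  }
  out
}

marlene_loss <- function(params, batch, control) {
  marlene_forward(params, batch, control, grad = FALSE)$loss
}

marlene_grad <- function(params, batch, control) {
  marlene_forward(params, batch, control, grad = TRUE)$grads
}
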