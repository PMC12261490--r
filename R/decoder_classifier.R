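# Reconstruction of expression from TF expression through the inferred
# adjacency, and cell-type classification of the temporal batch.

#' Reconstruct expression from TF expression and an adjacency matrix
#'
#' Returns `x_tf %*% t(A_t)`: because each row of `A_t` is a distribution
#' over TFs, every reconstructed gene is a convex combination of the cell's
#' TF expression values.
#'
#' @param x_tf b x p matrix of TF expression for a batch of cells.
#' @param A_t g x p adjacency matrix.
#' @return b x g reconstructed expression matrix.
#' @export
reconstruct_expression <- function(x_tf, A_t) {
  if (ncol(x_tf) != ncol(A_t)) {
    stop(sprintf("TF expression has %d columns but adjacency has %d TF columns",
                 ncol(x_tf), ncol(A_t)))
  }
  tcrossprod(x_tf, A_t)
}

#' Classify a temporal batch from its reconstructions
#'
#' Each cell's reconstructed expression vector passes through the affine
#' stack (rectified between layers, linear at the end); the batch logit
#' vector is the sum over cells and over time points, so the result is
#' exactly invariant to cell order within a time point and additive over
#' disjoint cell groups.
#'
#' @param recon_series list of b x g reconstruction matrices, one per time
#'   point.
#' @param params list with `weights` (list of layer weight matrices, first
#'   input dimension g, last output dimension C) and `biases` (matching list
#'   of 1 x out row vectors).
#' @return numeric vector of C logits.
#' @export
classify <- function(recon_series, params) {
  if (length(recon_series) == 0L) stop("empty reconstruction series")
  W <- params$weights
  B <- params$biases
  L <- length(W)
  C <- ncol(W[[L]])
  logits <- numeric(C)
  for (R in recon_series) {
    H <- R
    for (l in seq_len(L)) {
      H <- H %*% W[[l]] + rep(B[[l]], each = nrow(H))
      if (l < L) H[H < 0] <- 0
    }
    logits <- logits + colSums(H)
  }
  logits
}

#' Cross-entropy cell-type loss
#'
#' Cross-entropy of `softmax(logits)` against the batch's cell-type label.
#' Equals `log(C)` under uniform logits.
#'
#' @param logits numeric vector of C logits.
#' @param y integer class label in 1..C.
#' @return nonnegative scalar loss.
#' @export
loss_celltype <- function(logits, y) {
  C <- length(logits)
  if (y < 1L || y > C) stop("label out of range")
  m <- max(logits)
  (m + log(sum(exp(logits - m)))) - logits[y]
}

#' Expression-reconstruction loss (GEX ablation objective)
#'
#' Mean squared error between reconstructed and observed expression,
#' averaged over cells, genes, and time points.
#'
#' @param recon_series list of b x g reconstructions.
#' @param x_series list of matching observed b x g matrices.
#' @return scalar mean squared error.
#' @export
loss_gex <- function(recon_series, x_series) {
  if (length(recon_series) != length(x_series)) stop("series length mismatch")
  tot <- 0
  for (t in seq_along(recon_series)) {
    if (!all(dim(recon_series[[t]]) == dim(x_series[[t]]))) {
      stop("shape mismatch between reconstruction and observed expression")
    }
    tot <- tot + mean((recon_series[[t]] - x_series[[t]])^2)
  }
  tot / length(recon_series)
}

# ---- tape builders ----

g_decoder_logits <- function(R, pn) {
  H <- ad_relu(ad_addvec(ad_matmul(R, pn$dec_W1), pn$dec_b1))
  L <- ad_addvec(ad_matmul(H, pn$dec_W2), pn$dec_b2)
  ad_colsums(L)
}
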