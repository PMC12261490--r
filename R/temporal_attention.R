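# Time-evolving self-attention adjacency construction.
#
# At each time point the gene feature matrix G_t is summarised to a k x k
# matrix Z_t by top-k pooling; two matrix-valued GRUs take Z_t as input and
# evolve the query/key projection weights (their hidden states); scaled
# dot-product attention of all genes over the TF rows yields a row-stochastic
# g x p adjacency matrix A_t, the model's soft regulatory assignment.

#' Top-k pooling of a gene feature matrix
#'
#' Scores every gene by `s = G u / ||u||`, selects the k genes with largest
#' scores (ties broken toward the smaller gene index), and returns their
#' feature rows gated by `tanh(s)`, ordered by descending score. This
#' summarises G_t into the square k x k matrix fed to the matrix GRUs.
#'
#' @param G g x k gene feature matrix.
#' @param u scoring vector of length k with positive norm.
#' @return k x k matrix with attribute `"indices"` (the selected gene rows).
#' @export
topk_pool <- function(G, u) {
  u <- as.numeric(u)
  k <- length(u)
  if (ncol(G) != k) stop("scoring vector length must equal feature dimension k")
  if (nrow(G) < k) {
    stop(sprintf(
      "top-k pooling needs at least k = %d genes but got %d; lower k or add genes",
      k, nrow(G)))
  }
  nrm <- sqrt(sum(u^2))
  if (nrm == 0) stop("scoring vector must have positive norm")
  s <- as.vector(G %*% u) / nrm
  idx <- order(-s)[seq_len(k)]  # stable: ties keep ascending gene index
  Z <- G[idx, , drop = FALSE] * tanh(s[idx])
  attr(Z, "indices") <- idx
  attr(Z, "scores") <- s[idx]
  Z
}

#' One matrix-GRU step
#'
#' Standard GRU gates applied with matrix-valued input and hidden state:
#' `z = sigmoid(Uz Z + Vz W + Bz)`, `r = sigmoid(Ur Z + Vr W + Br)`,
#' `What = tanh(Uh Z + Vh (r * W) + Bh)`, and
#' `W_t = (1 - z) * W_prev + z * What` (elementwise products). The hidden
#' state is the attention projection weight matrix being evolved.
#'
#' @param Z k x k input (the pooled gene summary).
#' @param W_prev k x k previous hidden state.
#' @param params list with `Uz`, `Vz`, `Bz`, `Ur`, `Vr`, `Br`, `Uh`, `Vh`,
#'   `Bh`, all k x k.
#' @return k x k updated hidden state.
#' @export
matrix_gru_step <- function(Z, W_prev, params) {
  if (!all(is.finite(Z)) || !all(is.finite(W_prev))) {
    stop("non-finite input to matrix GRU step")
  }
  z <- logistic(params$Uz %*% Z + params$Vz %*% W_prev + params$Bz)
  r <- logistic(params$Ur %*% Z + params$Vr %*% W_prev + params$Br)
  What <- tanh(params$Uh %*% Z + params$Vh %*% (r * W_prev) + params$Bh)
  (1 - z) * W_prev + z * What
}

#' Attention adjacency at one time point
#'
#' `Q_t = G_t W_Q`, `K_t = G_t[tf rows] W_K`,
#' `A_t = row_softmax(Q_t K_t^T / sqrt(k))`. Source nodes (columns) are
#' restricted to the TF rows, so `A_t` is g x p and every gene's attention
#' over TFs sums to one.
#'
#' @param G g x k gene feature matrix.
#' @param state list with `W_Q` and `W_K`, both k x k.
#' @param tf_indices integer indices of TF genes (rows of `G`).
#' @return g x p row-stochastic matrix with attributes `"Q"` and `"K"`.
#' @export
attend <- function(G, state, tf_indices) {
  p <- length(tf_indices)
  if (p == 0L) stop("no TF indices supplied; the adjacency needs at least one TF column")
  k <- ncol(G)
  Q <- G %*% state$W_Q
  K <- G[tf_indices, , drop = FALSE] %*% state$W_K
  A <- row_softmax(tcrossprod(Q, K) / sqrt(k))
  attr(A, "Q") <- Q
  attr(A, "K") <- K
  A
}

#' Build the full time series of adjacency matrices
#'
#' Runs the recurrent construction for t = 1..T: summarise `G_t` with top-k
#' pooling, advance the query/key projection weights with one matrix-GRU step
#' each, and form the attention adjacency. With `evolve = FALSE` (the no-GRU
#' ablation) the projections stay fixed at the initial state, giving
#' time-independent attention for constant inputs.
#'
#' @param G_series list of T gene feature matrices (g x k).
#' @param init_state list with `W_Q`, `W_K` initial k x k projections.
#' @param gru_params list with elements `Q` and `K`, each a parameter list as
#'   in [matrix_gru_step()].
#' @param topk_params scoring vector `u` of length k.
#' @param tf_indices TF row indices.
#' @param evolve logical; evolve projections over time.
#' @return an object of class `"adjacency_series"`: list with `A`, `Q`, `K`,
#'   `Z` (per-time-point matrices) and `tf_indices`.
#' @export
build_adjacency_series <- function(G_series, init_state, gru_params,
                                   topk_params, tf_indices, evolve = TRUE) {
  T_ <- length(G_series)
  if (T_ < 1L) stop("need at least one time point")
  A <- Qs <- Ks <- Zs <- vector("list", T_)
  WQ <- init_state$W_Q
  WK <- init_state$W_K
  for (t in seq_len(T_)) {
    Z <- topk_pool(G_series[[t]], topk_params)
    if (evolve) {
      WQ <- matrix_gru_step(Z, WQ, gru_params$Q)
      WK <- matrix_gru_step(Z, WK, gru_params$K)
    }
    At <- attend(G_series[[t]], list(W_Q = WQ, W_K = WK), tf_indices)
    Zs[[t]] <- Z
    Qs[[t]] <- attr(At, "Q")
    Ks[[t]] <- attr(At, "K")
    attr(At, "Q") <- NULL
    attr(At, "K") <- NULL
    A[[t]] <- At
  }
  structure(list(A = A, Q = Qs, K = Ks, Z = Zs, tf_indices = tf_indices),
            class = "adjacency_series")
}

#' @export
print.adjacency_series <- function(x, ...) {
  g <- nrow(x$A[[1L]])
  p <- ncol(x$A[[1L]])
  cat(sprintf("adjacency series: %d time points, %d genes x %d TFs\n",
              length(x$A), g, p))
  invisible(x)
}

# ---- tape builders ----

g_topk <- function(G, u_node, k) {
  un <- ad_unit(u_node)
  s <- ad_matmul(G, un)
  sv <- as.vector(s$value)
  idx <- order(-sv)[seq_len(k)]
  Z <- ad_mul_colvec(ad_rows(G, idx), ad_tanh(ad_rows(s, idx)))
  Z
}

g_gru_step <- function(Z, W, pn, prefix) {
  p_ <- function(nm) pn[[paste0(prefix, "_", nm)]]
  z <- ad_sigmoid(ad_add(ad_add(ad_matmul(p_("Uz"), Z), ad_matmul(p_("Vz"), W)), p_("Bz")))
  r <- ad_sigmoid(ad_add(ad_add(ad_matmul(p_("Ur"), Z), ad_matmul(p_("Vr"), W)), p_("Br")))
  What <- ad_tanh(ad_add(ad_add(ad_matmul(p_("Uh"), Z), ad_matmul(p_("Vh"), ad_mul(r, W))), p_("Bh")))
  ad_add(ad_sub(W, ad_mul(z, W)), ad_mul(z, What))
}

g_attend <- function(G, WQ, WK, tf_indices, k) {
  Q <- ad_matmul(G, WQ)
  K <- ad_matmul(ad_rows(G, tf_indices), WK)
  ad_row_softmax(ad_scale(ad_matmul(Q, ad_transpose(K)), 1 / sqrt(k)))
}
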