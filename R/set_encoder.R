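# Permutation-invariant gene featurization of a cell batch.
#
# The pooling-by-multihead-attention (PMA) encoder treats the cells measured
# at one time point as an unordered set: a learnable seed matrix S (k x g)
# queries the batch through a multihead attention block (MAB), yielding k
# summary vectors whose transpose is the gene-by-feature matrix G_t used by
# the adjacency construction. A DeepSets featurizer is available as an
# ablation. Public functions here operate on plain matrices; g_* builders
# emit the same computation onto the autodiff tape for training.

logistic <- function(x) 1 / (1 + exp(-x))

norm_heads <- function(W) if (is.list(W)) W else list(W)

#' Multihead scaled dot-product attention
#'
#' Computes per-head `softmax(Q K^T / sqrt(d_h)) V` on projected inputs,
#' concatenates heads, and applies the output projection. Row `i` of the
#' result depends on query row `i` and the full key/value set, making
#' downstream pooling permutation invariant in the keys/values.
#'
#' @param queries m x d matrix.
#' @param keys,values c x d matrices (same row count).
#' @param params list with projection matrices `Wq`, `Wk`, `Wv` (a single
#'   d x d matrix for one head, or a list of d x d_h matrices for several)
#'   and output projection `Wo` (d x d).
#' @return m x d matrix.
#' @export
multihead_attention <- function(queries, keys, values, params) {
  Wq <- norm_heads(params$Wq); Wk <- norm_heads(params$Wk)
  Wv <- norm_heads(params$Wv)
  h <- length(Wq)
  if (nrow(keys) != nrow(values)) stop("keys and values must have equal row counts")
  if (ncol(queries) != nrow(Wq[[1L]])) {
    stop(sprintf("query width %d does not match projection input %d",
                 ncol(queries), nrow(Wq[[1L]])))
  }
  outs <- vector("list", h)
  for (i in seq_len(h)) {
    Qh <- queries %*% Wq[[i]]
    Kh <- keys %*% Wk[[i]]
    Vh <- values %*% Wv[[i]]
    dh <- ncol(Qh)
    outs[[i]] <- row_softmax(tcrossprod(Qh, Kh) / sqrt(dh)) %*% Vh
  }
  do.call(cbind, outs) %*% params$Wo
}

rff_apply <- function(M, params) {
  H <- M %*% params$rff_W1 + rep(params$rff_b1, each = nrow(M))
  H[H < 0] <- 0
  H %*% params$rff_W2 + rep(params$rff_b2, each = nrow(M))
}

layernorm_rows <- function(x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  xc / sqrt(rowMeans(xc^2) + eps)
}

#' Multihead attention block (MAB)
#'
#' `M = S + Multihead(S, X, X)`, followed by the residual row-wise
#' feedforward `M + rFF(M)`. By default no normalisation layers are applied
#' (the plain residual form); set `params$layernorm = TRUE` for the
#' Set-Transformer variant with row standardisation after each residual.
#'
#' @param S k x g seed matrix (the learnable queries).
#' @param X c x g cell-by-gene batch at one time point.
#' @param params encoder parameters: attention projections as in
#'   [multihead_attention()] plus `rff_W1`, `rff_b1`, `rff_W2`, `rff_b2`,
#'   and optional logical `layernorm`.
#' @return k x g matrix.
#' @export
mab <- function(S, X, params) {
  if (ncol(X) != ncol(S)) stop("cell matrix and seed matrix disagree on gene count")
  M <- S + multihead_attention(S, X, X, params)
  if (isTRUE(params$layernorm)) M <- layernorm_rows(M)
  H <- M + rff_apply(M, params)
  if (isTRUE(params$layernorm)) H <- layernorm_rows(H)
  H
}

#' PMA gene featurization
#'
#' Applies the shared MAB with seed matrix `S` to one time point's batch and
#' transposes the result into a gene-by-feature matrix `G_t` (g x k). The same
#' parameters are applied at every time point.
#'
#' @inheritParams mab
#' @return g x k gene feature matrix.
#' @export
pma_featurize <- function(X, S, params) {
  t(mab(S, X, params))
}

#' DeepSets gene featurization (ablation)
#'
#' Per-cell row-wise feedforward map `phi`, mean pooling over cells, then a
#' shared per-gene affine map `rho` from the pooled scalar to a k-vector.
#' Exactly permutation invariant by construction of the mean pool.
#'
#' @param X c x g cell-by-gene batch.
#' @param params list with `ds_phi_W1`, `ds_phi_b1`, `ds_phi_W2`, `ds_phi_b2`
#'   (the row-wise feedforward phi: g -> g with one rectified hidden layer)
#'   and `ds_rho_W` (1 x k), `ds_rho_b` (1 x k).
#' @return g x k gene feature matrix.
#' @export
deepset_featurize <- function(X, params) {
  H <- X %*% params$ds_phi_W1 + rep(params$ds_phi_b1, each = nrow(X))
  H[H < 0] <- 0
  Phi <- H %*% params$ds_phi_W2 + rep(params$ds_phi_b2, each = nrow(X))
  pooled <- matrix(colMeans(Phi), ncol = 1L)
  pooled %*% params$ds_rho_W + rep(params$ds_rho_b, each = nrow(pooled))
}

# ---- tape builders (training path) ----

enc_head_names <- function(params) {
  sum(grepl("^enc_Wq", names(params)))
}

g_multihead <- function(Q, K, V, Wq, Wk, Wv, Wo) {
  h <- length(Wq)
  outs <- vector("list", h)
  for (i in seq_len(h)) {
    Qh <- ad_matmul(Q, Wq[[i]])
    Kh <- ad_matmul(K, Wk[[i]])
    Vh <- ad_matmul(V, Wv[[i]])
    dh <- ncol(Qh$value)
    Wt <- ad_row_softmax(ad_scale(ad_matmul(Qh, ad_transpose(Kh)), 1 / sqrt(dh)))
    outs[[i]] <- ad_matmul(Wt, Vh)
  }
  O <- if (h == 1L) outs[[1L]] else ad_cbind(outs)
  ad_matmul(O, Wo)
}

g_pma <- function(Xn, pn, control) {
  h <- control$heads
  Wq <- lapply(seq_len(h), function(i) pn[[paste0("enc_Wq", i)]])
  Wk <- lapply(seq_len(h), function(i) pn[[paste0("enc_Wk", i)]])
  Wv <- lapply(seq_len(h), function(i) pn[[paste0("enc_Wv", i)]])
  M <- ad_add(pn$S, g_multihead(pn$S, Xn, Xn, Wq, Wk, Wv, pn$enc_Wo))
  if (isTRUE(control$layernorm)) M <- ad_layernorm_rows(M)
  Hh <- ad_relu(ad_addvec(ad_matmul(M, pn$rff_W1), pn$rff_b1))
  Ff <- ad_addvec(ad_matmul(Hh, pn$rff_W2), pn$rff_b2)
  H <- ad_add(M, Ff)
  if (isTRUE(control$layernorm)) H <- ad_layernorm_rows(H)
  ad_transpose(H)
}

g_deepset <- function(Xn, pn) {
  c_t <- nrow(Xn$value)
  H <- ad_relu(ad_addvec(ad_matmul(Xn, pn$ds_phi_W1), pn$ds_phi_b1))
  Phi <- ad_addvec(ad_matmul(H, pn$ds_phi_W2), pn$ds_phi_b2)
  pooled <- ad_transpose(ad_scale(ad_colsums(Phi), 1 / c_t))
  ad_addvec(ad_matmul(pooled, pn$ds_rho_W), pn$ds_rho_b)
}

g_featurize <- function(Xn, pn, control) {
  if (identical(control$encoder, "pma")) g_pma(Xn, pn, control) else g_deepset(Xn, pn)
}
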