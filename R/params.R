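# Parameter containers and initialisation.
#
# All learnable state lives in one flat named list of numeric matrices so the
# MAML inner loop can do purely functional updates (params - lr * grads) and
# the Adam meta-optimizer can keep per-matrix moment estimates.

unif_init <- function(nr, nc, fan_in) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

gru_param_names <- function(prefix) {
  paste0(prefix, "_", c("Uz", "Vz", "Bz", "Ur", "Vr", "Br", "Uh", "Vh", "Bh"))
}

init_gru_params <- function(k, prefix) {
  out <- lapply(gru_param_names(prefix), function(nm) unif_init(k, k, k))
  names(out) <- gru_param_names(prefix)
  # zero biases
  for (nm in paste0(prefix, "_", c("Bz", "Br", "Bh"))) {
    out[[nm]] <- matrix(0, k, k)
  }
  out
}

#' Initialize all model parameters
#'
#' Creates the flat named list of parameter matrices for the full
#' architecture: PMA seed matrix and multihead-attention projections (or the
#' DeepSets featurizer), top-k scoring vector, the two matrix GRUs with their
#' initial hidden states (the initial query/key projection weights), and the
#' decoder/classifier stack. Uses scaled uniform fan-in initialisation; biases
#' and GRU gate biases start at zero. Draws from the current R random
#' generator state.
#'
#' @param g number of genes.
#' @param p number of transcription factors (TF columns of the adjacency).
#' @param C number of cell-type classes.
#' @param control a [marlene_control()] list (uses `k`, `heads`, `encoder`,
#'   `decoder_hidden`).
#' @return named list of numeric matrices.
#' @export
init_marlene_params <- function(g, p, C, control = marlene_control()) {
  k <- control$k
  h <- control$heads
  if (g %% h != 0) stop("number of genes must be divisible by the head count")
  dh <- g %/% h
  pr <- list()
  pr$S <- unif_init(k, g, g)
  if (identical(control$encoder, "pma")) {
    for (i in seq_len(h)) {
      pr[[paste0("enc_Wq", i)]] <- unif_init(g, dh, g)
      pr[[paste0("enc_Wk", i)]] <- unif_init(g, dh, g)
      pr[[paste0("enc_Wv", i)]] <- unif_init(g, dh, g)
    }
    pr$enc_Wo <- unif_init(g, g, g)
    pr$rff_W1 <- unif_init(g, g, g)
    pr$rff_b1 <- matrix(0, 1L, g)
    pr$rff_W2 <- unif_init(g, g, g)
    pr$rff_b2 <- matrix(0, 1L, g)
  } else {
    pr$ds_phi_W1 <- unif_init(g, g, g)
    pr$ds_phi_b1 <- matrix(0, 1L, g)
    pr$ds_phi_W2 <- unif_init(g, g, g)
    pr$ds_phi_b2 <- matrix(0, 1L, g)
    pr$ds_rho_W <- unif_init(1L, k, 1L)
    pr$ds_rho_b <- matrix(0, 1L, k)
  }
  pr$topk_u <- unif_init(k, 1L, k)
  pr <- c(pr, init_gru_params(k, "gruQ"), init_gru_params(k, "gruK"))
  pr$W0Q <- unif_init(k, k, k)
  pr$W0K <- unif_init(k, k, k)
  dh2 <- control$decoder_hidden
  pr$dec_W1 <- unif_init(g, dh2, g)
  pr$dec_b1 <- matrix(0, 1L, dh2)
  pr$dec_W2 <- unif_init(dh2, C, dh2)
  pr$dec_b2 <- matrix(0, 1L, C)
  pr
}

params_axpy <- function(a, s, b) {
  # a + s * b over matching names
  out <- a
  for (nm in names(b)) out[[nm]] <- out[[nm]] + s * b[[nm]]
  out
}

params_norm <- function(p) {
  sqrt(sum(vapply(p, function(m) sum(m^2), numeric(1))))
}

params_zero_like <- function(p) {
  lapply(p, function(m) matrix(0, nrow(m), ncol(m)))
}

#' Model and training configuration
#'
#' All tunable parameters of the architecture and of meta-training.
#' Defaults follow the reference protocol: 16 seed vectors, batches of 16
#' cells, five inner gradient steps at a fixed inner rate of 1e-3, Adam
#' meta-updates starting at 1e-4 with exponential decay, and gradient
#' clipping.
#'
#' @param k number of learnable seed vectors in the PMA layer (feature
#'   dimension of the gene feature matrix).
#' @param heads attention heads in the set encoder.
#' @param encoder `"pma"` (pooling by multihead attention) or `"deepset"`
#'   (ablation featurizer).
#' @param layernorm apply row standardisation inside the MAB block (off by
#'   default; the adjacency construction follows the plain residual form).
#' @param decoder_hidden width of the decoder hidden layer.
#' @param objective `"celltype"` (classification, the main objective) or
#'   `"gex"` (expression-reconstruction ablation).
#' @param evolve evolve the attention projections with the matrix GRUs; set
#'   `FALSE` for the time-independent ablation.
#' @param batch_size cells per time point per batch.
#' @param inner_steps MAML inner-loop gradient steps.
#' @param inner_lr inner-loop (plain gradient descent) learning rate.
#' @param meta_lr initial Adam meta-learning rate.
#' @param lr_decay multiplicative meta-LR decay factor, applied every
#'   `lr_decay_every` meta-steps.
#' @param lr_decay_every meta-steps between decay applications.
#' @param clip_norm global gradient-norm ceiling for the meta-gradient.
#' @param meta_steps number of meta-updates.
#' @param first_order use the first-order MAML approximation of the
#'   meta-gradient.
#' @param weight_decay L2 penalty added to the meta-gradient for encoder and
#'   decoder weight matrices.
#' @param support_fraction fraction of each cell type's cells assigned to the
#'   support split.
#' @param checkpoint_every meta-steps between parameter checkpoints.
#' @param n_batches_avg forward batches averaged when extracting a GRN.
#' @param hvp_eps base step for the Hessian-vector products used by
#'   second-order meta-gradients.
#' @return a list of class `"marlene_control"`.
#' @export
marlene_control <- function(k = 16L, heads = 1L, encoder = c("pma", "deepset"),
                            layernorm = FALSE, decoder_hidden = 128L,
                            objective = c("celltype", "gex"), evolve = TRUE,
                            batch_size = 16L, inner_steps = 5L,
                            inner_lr = 1e-3, meta_lr = 1e-4, lr_decay = 0.99,
                            lr_decay_every = 10L, clip_norm = 1.0,
                            meta_steps = 200L, first_order = FALSE,
                            weight_decay = 1e-4, support_fraction = 0.5,
                            checkpoint_every = 10L, n_batches_avg = 32L,
                            hvp_eps = 1e-5) {
  encoder <- match.arg(encoder)
  objective <- match.arg(objective)
  stopifnot(k >= 1, inner_steps >= 1, inner_lr >= 0, meta_lr >= 0,
            clip_norm > 0, batch_size >= 1,
            support_fraction > 0, support_fraction < 1)
  structure(list(
    k = as.integer(k), heads = as.integer(heads), encoder = encoder,
    layernorm = layernorm, decoder_hidden = as.integer(decoder_hidden),
    objective = objective, evolve = evolve,
    batch_size = as.integer(batch_size), inner_steps = as.integer(inner_steps),
    inner_lr = inner_lr, meta_lr = meta_lr, lr_decay = lr_decay,
    lr_decay_every = as.integer(lr_decay_every), clip_norm = clip_norm,
    meta_steps = as.integer(meta_steps), first_order = first_order,
    weight_decay = weight_decay, support_fraction = support_fraction,
    checkpoint_every = as.integer(checkpoint_every),
    n_batches_avg = as.integer(n_batches_avg), hvp_eps = hvp_eps
  ), class = "marlene_control")
}
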