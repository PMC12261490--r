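# Shared fixtures: tiny parameter sets, batches, and simulated datasets,
# all generated in code under fixed seeds.

toy_control <- function(...) {
  marlene_control(k = 2L, decoder_hidden = 8L, meta_steps = 5L,
                  batch_size = 3L, ...)
}

# random parameters for a toy model (g genes, p TFs, C classes)
toy_params <- function(g = 6L, p = 2L, C = 2L, control = toy_control(),
                       seed = 42L) {
  set.seed(seed)
  init_marlene_params(g, p, C, control)
}

toy_batch <- function(g = 6L, p = 2L, T_ = 2L, b = 3L, y = 1L, seed = 7L) {
  set.seed(seed)
  list(x = lapply(seq_len(T_), function(t) matrix(abs(rnorm(b * g)), b, g)),
       tf = seq_len(p), y = y)
}

# small simulated dataset reused by several files
small_sim <- function(seed = 5L, ...) {
  set.seed(seed)
  cfg <- sim_config(g = 20L, p = 4L, T_ = 2L, C = 2L, cells = c(25L, 25L),
                    rewiring = 0.3, ...)
  simulate_expression(plant_networks(cfg))
}

# encoder parameter list for the public numeric API, from a flat param list
encoder_params <- function(pr, layernorm = FALSE) {
  list(Wq = pr$enc_Wq1, Wk = pr$enc_Wk1, Wv = pr$enc_Wv1, Wo = pr$enc_Wo,
       rff_W1 = pr$rff_W1, rff_b1 = pr$rff_b1, rff_W2 = pr$rff_W2,
       rff_b2 = pr$rff_b2, layernorm = layernorm)
}

gru_params_of <- function(pr, prefix) {
  nm <- c("Uz", "Vz", "Bz", "Ur", "Vr", "Br", "Uh", "Vh", "Bh")
  out <- lapply(nm, function(n) pr[[paste0(prefix, "_", n)]])
  names(out) <- nm
  out
}

identity_mha_params <- function(d) {
  I <- diag(d)
  list(Wq = I, Wk = I, Wv = I, Wo = I)
}

# independent hypergeometric enrichment tail by direct enumeration
enum_hyper_tail <- function(N, K, n, a) {
  if (a <= 0) return(1)
  xs <- a:min(K, n)
  xs <- xs[xs >= max(0, n + K - N)]
  if (!length(xs)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(1e-12, max(abs(y))), tol)
}
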