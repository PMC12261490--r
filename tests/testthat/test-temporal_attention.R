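# Top-k pooling, matrix GRU, attention adjacency, and the recurrent series.

brute_topk <- function(G, u) {
  s <- as.vector(G %*% u) / sqrt(sum(u^2))
  ord <- order(-s, seq_along(s))
  idx <- ord[seq_len(length(u))]
  G[idx, , drop = FALSE] * tanh(s[idx])
}

test_that("top-k pooling matches the brute-force sort oracle, including ties", {
  set.seed(10)
  for (i in 1:50) {
    g <- sample(3:12, 1L); k <- sample(seq_len(min(g, 5L)), 1L)
    G <- matrix(rnorm(g * k), g, k)
    if (i %% 3 == 0) G <- round(G, 1)  # force frequent score ties
    u <- rnorm(k)
    Z <- topk_pool(G, u)
    expect_equal(unclass(Z), brute_topk(G, u), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  # stated tie rule: equal scores resolve to the smaller gene index
  G <- rbind(c(1, 0), c(1, 0), c(0.2, 0))
  Z <- topk_pool(G, c(1, 0))
  expect_equal(attr(Z, "indices"), c(1L, 2L))
  # axis-aligned scoring vector selects rows hot in that coordinate
  G2 <- diag(3)[, 1:2]
  expect_equal(attr(topk_pool(G2, c(0, 1)), "indices")[1L], 2L)
  expect_error(topk_pool(matrix(0, 2, 3), c(1, 1, 1)), "lower k")
})

scalar_gru <- function(z_in, w_prev, p, i, j) {
  # entrywise oracle: the gate algebra applied to single entries of the
  # pre-activation matrices
  az <- (p$Uz %*% z_in + p$Vz %*% w_prev)[i, j] + p$Bz[i, j]
  ar <- (p$Ur %*% z_in + p$Vr %*% w_prev)[i, j] + p$Br[i, j]
  z <- 1 / (1 + exp(-az))
  r <- 1 / (1 + exp(-ar))
  ah <- (p$Uh %*% z_in)[i, j] + (p$Vh %*% ((r_full(z_in, w_prev, p)) * w_prev))[i, j] + p$Bh[i, j]
  wh <- tanh(ah)
  (1 - z) * w_prev[i, j] + z * wh
}

r_full <- function(z_in, w_prev, p) {
  1 / (1 + exp(-(p$Ur %*% z_in + p$Vr %*% w_prev + p$Br)))
}

test_that("matrix GRU step equals the entrywise scalar-gate oracle", {
  set.seed(11)
  for (rep in 1:20) {
    k <- 3L
    p <- lapply(setNames(nm = c("Uz", "Vz", "Bz", "Ur", "Vr", "Br",
                                "Uh", "Vh", "Bh")),
                function(nm) matrix(rnorm(k * k), k, k))
    Z <- matrix(rnorm(k * k), k, k)
    W <- matrix(rnorm(k * k), k, k)
    out <- matrix_gru_step(Z, W, p)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      expect_equal(out[i, j], scalar_gru(Z, W, p, i, j), tolerance = 1e-12)
    }
  }
})

test_that("GRU gates behave as stated in the degenerate settings", {
  k <- 2L
  zero <- matrix(0, k, k)
  p0 <- list(Uz = zero, Vz = zero, Bz = zero, Ur = zero, Vr = zero, Br = zero,
             Uh = zero, Vh = zero, Bh = zero)
  W <- matrix(c(1, -2, 3, 4), k, k)
  # all-zero parameters: z = 1/2, candidate 0 -> half the previous state
  expect_equal(matrix_gru_step(zero, W, p0), W / 2, tolerance = 1e-12)
  # saturated update gate (large negative bias): identity evolution
  p_id <- p0; p_id$Bz <- matrix(-50, k, k)
  expect_equal(matrix_gru_step(matrix(rnorm(4), k, k), W, p_id), W,
               tolerance = 1e-10)
  expect_error(matrix_gru_step(matrix(NaN, k, k), W, p0), "non-finite")
})

test_that("attention adjacency is row-stochastic and matches a hand computation", {
  # g=3, p=2, k=1, identity projections: A = softmax over products
  G <- matrix(c(0.5, -1, 2), 3, 1)
  st <- list(W_Q = matrix(1, 1, 1), W_K = matrix(1, 1, 1))
  A <- attend(G, st, tf_indices = c(1L, 2L))
  for (i in 1:3) {
    sc <- c(G[i] * G[1], G[i] * G[2]) / sqrt(1)
    expect_equal(A[i, ], exp(sc) / sum(exp(sc)), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  expect_equal(rowSums(A), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(A > 0))
  # zero projections: uniform attention 1/p
  st0 <- list(W_Q = matrix(0, 1, 1), W_K = matrix(0, 1, 1))
  A0 <- attend(G, st0, c(1L, 2L))
  expect_equal(unclass(A0), matrix(0.5, 3, 2), ignore_attr = TRUE)
  expect_error(attend(G, st, integer(0)), "at least one TF")
})

test_that("the recurrent series is row-stochastic and the no-GRU ablation is static", {
  k <- 3L; g <- 8L
  set.seed(12)
  pr <- init_marlene_params(g, 3L, 2L, marlene_control(k = k))
  gp <- list(Q = gru_params_of(pr, "gruQ"), K = gru_params_of(pr, "gruK"))
  init <- list(W_Q = pr$W0Q, W_K = pr$W0K)
  G1 <- matrix(rnorm(g * k), g, k)
  Gs <- list(G1, G1, G1)
  u <- as.numeric(pr$topk_u)
  # evolving weights: valid rows at every t
  adj <- build_adjacency_series(Gs, init, gp, u, 1:3, evolve = TRUE)
  for (A in adj$A) {
    expect_equal(rowSums(A), rep(1, g), ignore_attr = TRUE, tolerance = 1e-6)
    expect_true(all(A > 0 & A < 1))
  }
  # frozen weights + constant features: exactly constant adjacency
  adj0 <- build_adjacency_series(Gs, init, gp, u, 1:3, evolve = FALSE)
  expect_identical(adj0$A[[1L]], adj0$A[[2L]])
  expect_identical(adj0$A[[1L]], adj0$A[[3L]])
  # with evolution the weights drift even under constant features
  expect_gt(max(abs(adj$A[[1L]] - adj$A[[3L]])), 0)
  # T = 1 works
  adj1 <- build_adjacency_series(Gs[1L], init, gp, u, 1:3)
  expect_length(adj1$A, 1L)
})

test_that("adjacency gradients w.r.t. the initial projection pass a finite-difference check", {
  # k=2, g=4, p=2: d mean(A_T) / d W0Q via the tape against central differences
  ctl <- marlene_control(k = 2L, decoder_hidden = 4L)
  set.seed(13)
  pr <- init_marlene_params(4L, 2L, 2L, ctl)
  X <- list(matrix(abs(rnorm(12)), 3, 4), matrix(abs(rnorm(12)), 3, 4))
  mean_AT <- function(p) {
    ep <- encoder_params(p)
    G <- lapply(X, pma_featurize, S = p$S, params = ep)
    adj <- build_adjacency_series(G, list(W_Q = p$W0Q, W_K = p$W0K),
                                  list(Q = gru_params_of(p, "gruQ"),
                                       K = gru_params_of(p, "gruK")),
                                  as.numeric(p$topk_u), 1:2)
    mean(adj$A[[length(X)]])
  }
  tape <- marlene:::ad_tape()
  marlene:::ad_use_tape(tape)
  pn <- lapply(pr, function(m) marlene:::ad_param(tape, m))
  WQ <- pn$W0Q; WK <- pn$W0K
  A_last <- NULL
  for (t in seq_along(X)) {
    Xn <- marlene:::ad_const(tape, X[[t]])
    G <- marlene:::g_pma(Xn, pn, ctl)
    Z <- marlene:::g_topk(G, pn$topk_u, 2L)
    WQ <- marlene:::g_gru_step(Z, WQ, pn, "gruQ")
    WK <- marlene:::g_gru_step(Z, WK, pn, "gruK")
    A_last <- marlene:::g_attend(G, WQ, WK, 1:2, 2L)
  }
  loss <- marlene:::ad_scale(marlene:::ad_colsums(
    marlene:::ad_matmul(A_last, marlene:::ad_const(tape, matrix(1, 2, 1)))),
    1 / length(A_last$value))
  marlene:::ad_backward(tape, loss)
  eps <- 1e-6
  for (idx in list(c(1L, 1L), c(2L, 1L), c(1L, 2L))) {
    pp <- pr; pp$W0Q[idx[1L], idx[2L]] <- pp$W0Q[idx[1L], idx[2L]] + eps
    pm <- pr; pm$W0Q[idx[1L], idx[2L]] <- pm$W0Q[idx[1L], idx[2L]] - eps
    fd <- (mean_AT(pp) - mean_AT(pm)) / (2 * eps)
    an <- pn$W0Q$grad[idx[1L], idx[2L]]
    expect_lt(abs(fd - an) / max(1e-8, abs(fd)), 1e-4)
  }
})
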