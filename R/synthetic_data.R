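# Planted-network single-cell simulator.
#
# Generates time-series count matrices for several cell types whose target
# genes are driven by planted TF -> target networks that rewire smoothly
# over time. Counts follow a Gamma-Poisson (negative-binomial-like) scheme
# with Bernoulli dropout; cell types are separable through type-specific TF
# means so the cell-type classification objective is well posed.

#' Simulator configuration
#'
#' @param g total genes (the first `p` are the TFs).
#' @param p transcription factors.
#' @param T_ time points.
#' @param C cell types.
#' @param cells integer vector of length C: cells per type per time point
#'   (may include a rare type).
#' @param density planted edge density over the g x p pair universe.
#' @param shared_core fraction of each type's edges shared by all types.
#' @param rewiring vector of length T_-1: fraction of edges rewired at each
#'   transition (exact counts, `ceiling(rho * m)`).
#' @param tf_shape Gamma shape of latent TF expression (dispersion control).
#' @param effect effect scale beta linking TF expression to target rates.
#' @param dropout Bernoulli zeroing probability for observed counts.
#' @param depth mean-count scaling (sequencing depth proxy).
#' @param baseline baseline target rate before TF input.
#' @param type_tf_frac fraction of TFs boosted per cell type (class signal).
#' @param type_tf_boost multiplicative boost of those TFs' means.
#' @param time_sd log-normal SD of per-time TF mean fluctuation.
#' @param neg_frac fraction of repressive (negative-weight) planted edges.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(g = 60L, p = 12L, T_ = 3L, C = 3L,
                       cells = c(120L, 120L, 30L), density = 0.08,
                       shared_core = 0.5, rewiring = c(0.5, 0.1),
                       tf_shape = 1, effect = 1.5, dropout = 0.3,
                       depth = 3, baseline = 0.1, type_tf_frac = 0.25,
                       type_tf_boost = 2.5, time_sd = 0.15,
                       neg_frac = 0.2) {
  stopifnot(p >= 1, p < g, T_ >= 1, C >= 1, length(cells) == C,
            density > 0, density < 1, shared_core >= 0, shared_core <= 1,
            length(rewiring) == T_ - 1L, all(rewiring >= 0), all(rewiring < 1),
            dropout >= 0, dropout < 1)
  structure(list(g = as.integer(g), p = as.integer(p), T_ = as.integer(T_),
                 C = as.integer(C), cells = as.integer(cells),
                 density = density, shared_core = shared_core,
                 rewiring = rewiring, tf_shape = tf_shape, effect = effect,
                 dropout = dropout, depth = depth, baseline = baseline,
                 type_tf_frac = type_tf_frac, type_tf_boost = type_tf_boost,
                 time_sd = time_sd, neg_frac = neg_frac),
            class = "sim_config")
}

sim_gene_names <- function(cfg) {
  c(sprintf("TF%02d", seq_len(cfg$p)),
    sprintf("G%03d", seq.int(cfg$p + 1L, cfg$g)))
}

#' Plant smoothly rewiring TF -> target networks
#'
#' Each cell type starts from a base network of `m = ceiling(density * g * p)`
#' edges: a shared core (the `shared_core` fraction, common to all types)
#' plus type-specific edges. At transition t, exactly `ceiling(rewiring[t] * m)`
#' edges are removed uniformly and the same number added uniformly from
#' absent pairs, so the IoU between consecutive planted networks is the
#' count-exact `(1 - r/m) / (1 + r/m)`. Targets are the non-TF genes; every
#' edge carries a persistent signed weight (a `neg_frac` fraction are
#' repressive). Draws from the current R random generator state.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `"planted_network_series"`: list with
#'   `networks` (per type, list of T binary g x p matrices), `weights`
#'   (matching signed weight matrices), `core` (logical g x p core mask),
#'   `gene_names`, `tf_names`, and `config`.
#' @export
plant_networks <- function(cfg) {
  g <- cfg$g; p <- cfg$p
  genes <- sim_gene_names(cfg)
  tfs <- genes[seq_len(p)]
  m <- ceiling(cfg$density * g * p)
  # candidate pairs: (target row, TF column) with targets restricted to
  # non-TF genes, so regulators and regulated genes stay distinct
  cand <- as.matrix(expand.grid(row = seq.int(p + 1L, g), col = seq_len(p)))
  N <- nrow(cand)
  r_max <- if (length(cfg$rewiring)) max(ceiling(cfg$rewiring * m)) else 0L
  if (m > N) stop("edge density too high for the available TF-target pairs")
  if (m + r_max > N) {
    stop("density too high to rewire without exhausting absent pairs")
  }
  pair_id <- function(rc) (rc[, 2L] - 1L) * g + rc[, 1L]
  all_ids <- pair_id(cand)
  n_core <- round(cfg$shared_core * m)
  core_ids <- sample(all_ids, n_core)
  blank <- function() {
    M <- matrix(0, g, p, dimnames = list(genes, tfs))
    M
  }
  networks <- weights <- vector("list", cfg$C)
  for (ci in seq_len(cfg$C)) {
    own <- sample(setdiff(all_ids, core_ids), m - n_core)
    ids <- c(core_ids, own)
    W <- blank()
    draw_w <- function(n) {
      stats::runif(n, 0.5, 1.5) *
        ifelse(stats::runif(n) < cfg$neg_frac, -1, 1)
    }
    W[ids] <- draw_w(length(ids))
    nets_t <- wts_t <- vector("list", cfg$T_)
    A <- blank(); A[ids] <- 1
    nets_t[[1L]] <- A
    wts_t[[1L]] <- W * A
    cur <- ids
    for (t in seq_len(cfg$T_ - 1L)) {
      r <- ceiling(cfg$rewiring[t] * m)
      if (r > 0) {
        drop_ids <- sample(cur, r)
        add_ids <- sample(setdiff(all_ids, cur), r)
        cur <- c(setdiff(cur, drop_ids), add_ids)
        need_w <- add_ids[W[add_ids] == 0]
        W[need_w] <- draw_w(length(need_w))
      }
      A <- blank(); A[cur] <- 1
      nets_t[[t + 1L]] <- A
      wts_t[[t + 1L]] <- W * A
    }
    networks[[ci]] <- nets_t
    weights[[ci]] <- wts_t
  }
  core <- blank(); core[core_ids] <- 1
  type_names <- sprintf("type%d", seq_len(cfg$C))
  names(networks) <- names(weights) <- type_names
  structure(list(networks = networks, weights = weights, core = core == 1,
                 gene_names = genes, tf_names = tfs, config = cfg),
            class = "planted_network_series")
}

#' @export
print.planted_network_series <- function(x, ...) {
  cfg <- x$config
  m <- sum(x$networks[[1L]][[1L]])
  cat(sprintf(
    "planted networks: %d types x %d time points, %d genes x %d TFs, %d edges each\n",
    cfg$C, cfg$T_, cfg$g, cfg$p, m))
  invisible(x)
}

# edges of one planted network as a data frame
planted_edges <- function(nets, type, t) {
  A <- nets$networks[[type]][[t]]
  idx <- which(A == 1, arr.ind = TRUE)
  data.frame(tf = colnames(A)[idx[, 2L]], target = rownames(A)[idx[, 1L]],
             stringsAsFactors = FALSE)
}

softplus <- function(x) {
  # stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Simulate time-series single-cell counts from planted networks
#'
#' Per cell of type c at time t: latent TF expression is Gamma with type-
#' and time-specific means (a boosted TF subset makes types classifiable);
#' each target gene's rate is `softplus(effect * w . x_tf + baseline)` using
#' the planted signed weights; observed counts are Poisson at `depth` times
#' the rate, with Bernoulli dropout zeroing entries at the configured rate.
#' Draws from the current R random generator state.
#'
#' @param nets a [plant_networks()] result.
#' @param cfg the simulator configuration (defaults to the one stored in
#'   `nets`).
#' @return list with `series` (an [expression_series()] of raw counts, TF
#'   indices set), `networks` (the ground truth), and `edge_db` (the union
#'   of planted edges across types and times, as an `"edge_db"` data frame).
#' @export
simulate_expression <- function(nets, cfg = nets$config) {
  g <- cfg$g; p <- cfg$p; T_ <- cfg$T_; C <- cfg$C
  genes <- nets$gene_names
  type_names <- names(nets$networks)
  base_tf <- exp(stats::rnorm(p, 0, 0.4))
  boost <- matrix(1, C, p)
  for (ci in seq_len(C)) {
    nb <- max(1L, ceiling(cfg$type_tf_frac * p))
    boost[ci, sample(p, nb)] <- cfg$type_tf_boost
  }
  mats <- vector("list", T_)
  ctypes <- vector("list", T_)
  for (t in seq_len(T_)) {
    rows <- NULL
    labs <- NULL
    for (ci in seq_len(C)) {
      n <- cfg$cells[ci]
      mu_tf <- base_tf * boost[ci, ] * exp(stats::rnorm(p, 0, cfg$time_sd))
      Wt <- nets$weights[[ci]][[t]]
      x_tf <- matrix(stats::rgamma(n * p, shape = cfg$tf_shape,
                                   scale = rep(mu_tf, each = n) / cfg$tf_shape),
                     n, p)
      rate <- softplus(cfg$effect * tcrossprod(x_tf, Wt[-seq_len(p), , drop = FALSE]) +
                         cfg$baseline)
      lambda <- cbind(x_tf, rate) * cfg$depth
      counts <- matrix(stats::rpois(n * g, lambda), n, g)
      if (cfg$dropout > 0) {
        keep <- matrix(stats::rbinom(n * g, 1L, 1 - cfg$dropout), n, g)
        counts <- counts * keep
      }
      rows <- rbind(rows, counts)
      labs <- c(labs, rep(type_names[ci], n))
    }
    mats[[t]] <- rows
    ctypes[[t]] <- labs
  }
  series <- expression_series(mats, genes,
                              time_labels = sprintf("t%d", seq_len(T_)),
                              cell_types = ctypes,
                              tf_indices = seq_len(p))
  edges <- unique(do.call(rbind, lapply(type_names, function(ct) {
    do.call(rbind, lapply(seq_len(T_), function(t) planted_edges(nets, ct, t)))
  })))
  edges$mode <- "Unknown"
  edges$self_loop <- FALSE
  rownames(edges) <- NULL
  class(edges) <- c("edge_db", "data.frame")
  list(series = series, networks = nets, edge_db = edges)
}

#' Write a simulated dataset to files
#'
#' Emits the expression series (MatrixMarket + metadata + gene and TF
#' lists), the planted edges per cell type and time point, and the union
#' edge database in TRRUST-style tab-separated form.
#'
#' @param sim a [simulate_expression()] result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_series(sim$series, dir)
  db <- sim$edge_db
  write.table(data.frame(TF = db$tf, target = db$target, mode = db$mode),
              file.path(dir, "edges_union.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  nets <- sim$networks
  rows <- NULL
  for (ct in names(nets$networks)) {
    for (t in seq_along(nets$networks[[ct]])) {
      E <- planted_edges(nets, ct, t)
      if (nrow(E)) {
        rows <- rbind(rows, cbind(data.frame(cell_type = ct, time = t), E))
      }
    }
  }
  write.table(rows, file.path(dir, "planted_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
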