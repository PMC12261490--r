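# The user-facing fitting function and its S3 methods.

# Reorder/subset a series' gene columns to the model's training gene set
# (e.g. after database restriction during fitting).
align_to_model <- function(model, series) {
  if (identical(series$gene_names, model$gene_names) &&
      identical(series$tf_indices, model$tf_indices)) {
    return(series)
  }
  idx <- match(model$gene_names, series$gene_names)
  if (anyNA(idx)) {
    stop(sprintf("series is missing %d gene(s) the model was trained on",
                 sum(is.na(idx))))
  }
  expression_series(lapply(series$matrices, function(m) m[, idx, drop = FALSE]),
                    model$gene_names, series$time_labels, series$cell_types,
                    model$tf_indices)
}

#' Fit a meta-learned temporal GRN model
#'
#' Trains the full architecture (PMA set encoder, GRU-evolved self-attention
#' adjacency, reconstruction/classification head) on a time-series
#' single-cell expression dataset, treating each cell type as a MAML task:
#' parameters are adapted with a few gradient steps on support cells and the
#' shared initialization is meta-updated on query cells. The checkpoint with
#' the lowest mean query loss is retained for GRN extraction.
#'
#' @param series an [expression_series()], typically [preprocess()]ed. If
#'   `edges` is supplied the series is first restricted to database genes and
#'   the TF universe is taken from the database.
#' @param edges optional [load_edge_database()] result defining the TF
#'   universe.
#' @param control a [marlene_control()] configuration.
#' @param meta logical; `TRUE` for MAML training, `FALSE` for plain pooled
#'   training (ablation).
#' @param seed integer seed controlling all randomness of the fit
#'   (initialisation, task splits, batch sampling).
#' @param verbose print progress every 10 steps.
#' @return an object of class `"marlene"` with components `params` (selected
#'   checkpoint), `final_params`, `checkpoints`, `selected`, `log`,
#'   `control`, `meta`, `seed`, and the series metadata (`gene_names`,
#'   `tf_indices`, `time_labels`, `cell_type_levels`).
#' @seealso [predict.marlene()], [average_adjacency()], [sparsify_top_fraction()]
#' @examples
#' sim <- simulate_expression(plant_networks(sim_config(
#'   g = 20, p = 4, T_ = 2, C = 2, cells = c(30, 30), rewiring = 0.3)))
#' fit <- marlene(preprocess(sim$series),
#'                control = marlene_control(k = 4, decoder_hidden = 16,
#'                                          meta_steps = 3, first_order = TRUE),
#'                seed = 1)
#' fit
#' @export
marlene <- function(series, edges = NULL, control = marlene_control(),
                    meta = TRUE, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(series, "expression_series"))
  cl <- match.call()
  if (!is.null(edges)) series <- restrict_to_database_genes(series, edges)
  if (!length(series$tf_indices)) {
    stop("series has no TF universe; supply `edges` or set tf_indices")
  }
  if (length(series$cell_type_levels) < 2L) {
    stop("need at least 2 cell types for the classification objective")
  }
  set.seed(seed)
  splits <- make_task_splits(series, control$support_fraction)
  tr <- train_loop(series, splits, control, meta = meta, verbose = verbose)
  sel <- select_checkpoint(tr$checkpoints)
  structure(list(
    params = tr$checkpoints[[sel]]$params,
    final_params = tr$params,
    checkpoints = lapply(tr$checkpoints, function(ck) {
      ck[c("step", "mean_query_loss")]
    }),
    all_checkpoint_params = lapply(tr$checkpoints, `[[`, "params"),
    selected = sel,
    log = tr$log,
    control = control,
    meta = meta,
    seed = seed,
    gene_names = series$gene_names,
    tf_indices = series$tf_indices,
    time_labels = series$time_labels,
    cell_type_levels = series$cell_type_levels,
    trained_types = names(splits),
    call = cl
  ), class = "marlene")
}

#' @export
print.marlene <- function(x, ...) {
  cat("Meta-learned temporal GRN model\n")
  cat(sprintf("  %d genes, %d TFs, %d time points, %d cell types (%s training)\n",
              length(x$gene_names), length(x$tf_indices),
              length(x$time_labels), length(x$cell_type_levels),
              if (x$meta) "MAML" else "pooled"))
  n <- nrow(x$log)
  if (n) {
    cat(sprintf("  %d steps; query loss %.4f -> %.4f; selected checkpoint at step %d\n",
                n, x$log$mean_query_loss[1L], x$log$mean_query_loss[n],
                x$checkpoints[[x$selected]]$step))
  }
  invisible(x)
}

#' @export
summary.marlene <- function(object, ...) {
  out <- list(
    dims = c(genes = length(object$gene_names),
             tfs = length(object$tf_indices),
             time_points = length(object$time_labels),
             cell_types = length(object$cell_type_levels)),
    meta = object$meta,
    seed = object$seed,
    steps = nrow(object$log),
    initial_loss = object$log$mean_query_loss[1L],
    final_loss = object$log$mean_query_loss[nrow(object$log)],
    selected_step = object$checkpoints[[object$selected]]$step,
    selected_loss = object$checkpoints[[object$selected]]$mean_query_loss,
    n_parameters = sum(vapply(object$params, length, numeric(1)))
  )
  class(out) <- "summary.marlene"
  out
}

#' @export
print.summary.marlene <- function(x, ...) {
  cat("Meta-learned temporal GRN model\n")
  cat(sprintf("  genes %d | TFs %d | time points %d | cell types %d\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$dims[4L]))
  cat(sprintf("  training: %s, %d steps, seed %d, %.0f parameters\n",
              if (x$meta) "MAML" else "pooled", x$steps, x$seed, x$n_parameters))
  cat(sprintf("  mean query loss: %.4f (initial) -> %.4f (final)\n",
              x$initial_loss, x$final_loss))
  cat(sprintf("  selected checkpoint: step %d, loss %.4f\n",
              x$selected_step, x$selected_loss))
  invisible(x)
}

#' @export
coef.marlene <- function(object, ...) object$params

#' @export
plot.marlene <- function(x, ...) {
  graphics::plot(x$log$step, x$log$mean_query_loss, type = "l",
                 xlab = "meta-step", ylab = "mean query loss", ...)
  ck <- x$checkpoints[[x$selected]]
  graphics::points(ck$step, ck$mean_query_loss, pch = 19)
  invisible(x)
}

#' Average attention adjacency matrices over batches
#'
#' Runs `n_batches` forward passes on freshly sampled single-type temporal
#' batches and averages the resulting adjacency matrices elementwise; the
#' mean of row-stochastic matrices is row-stochastic. For a MAML-trained
#' model the selected parameters are first adapted to the cell type with the
#' usual inner loop on a sampled support batch.
#'
#' @param model a fitted [marlene()] object.
#' @param series the [expression_series()] to sample batches from (must have
#'   the same genes as the training data).
#' @param cell_type which cell type to extract.
#' @param n_batches forward passes to average.
#' @param adapt run the inner adaptation first (default: the model's
#'   training mode).
#' @return an `"adjacency_series"` whose `A` matrices carry gene row names
#'   and TF column names.
#' @export
average_adjacency <- function(model, series, cell_type,
                              n_batches = model$control$n_batches_avg,
                              adapt = model$meta) {
  if (!cell_type %in% unlist(series$cell_types)) {
    stop(sprintf("cell type '%s' absent from series", cell_type))
  }
  series <- align_to_model(model, series)
  control <- model$control
  params <- model$params
  if (adapt) {
    sup <- suppressWarnings(
      sample_temporal_batch(series, cell_type, control$batch_size))
    params <- inner_adapt(params, sup, control)$params
  }
  acc <- NULL
  for (i in seq_len(n_batches)) {
    batch <- suppressWarnings(
      sample_temporal_batch(series, cell_type, control$batch_size))
    fw <- marlene_forward(params, batch, control, grad = FALSE)
    acc <- if (is.null(acc)) fw$A else Map(`+`, acc, fw$A)
  }
  A <- lapply(acc, function(m) {
    m <- m / n_batches
    rownames(m) <- model$gene_names
    colnames(m) <- model$gene_names[model$tf_indices]
    m
  })
  structure(list(A = A, tf_indices = model$tf_indices,
                 cell_type = cell_type, n_batches = n_batches),
            class = "adjacency_series")
}

#' Extract cell-type-specific temporal GRNs from a fitted model
#'
#' For each requested cell type, averages adjacency matrices over sampled
#' batches ([average_adjacency()]) and, if `fraction` is given, sparsifies
#' each time point's matrix to its top-scoring edges.
#'
#' @param object a fitted [marlene()] object.
#' @param series an [expression_series()] to sample cells from.
#' @param cell_types character vector (default: all types in the series).
#' @param n_batches forward passes averaged per cell type.
#' @param fraction if non-NULL, keep the top `fraction` of edges per time
#'   point (e.g. 0.02) and return weighted edge lists; otherwise return the
#'   dense adjacency series.
#' @param adapt run the MAML inner adaptation per cell type.
#' @param ... unused.
#' @return named list per cell type of either `"adjacency_series"` objects
#'   (dense) or `"weighted_grn"` objects (sparsified; see
#'   [sparsify_top_fraction()]).
#' @export
predict.marlene <- function(object, series, cell_types = NULL,
                            n_batches = object$control$n_batches_avg,
                            fraction = NULL, adapt = object$meta, ...) {
  if (is.null(cell_types)) {
    cell_types <- intersect(object$cell_type_levels, unique(unlist(series$cell_types)))
  }
  out <- lapply(cell_types, function(ct) {
    adj <- average_adjacency(object, series, ct, n_batches, adapt = adapt)
    if (is.null(fraction)) return(adj)
    grn_from_adjacency(adj, fraction, object$gene_names,
                       object$gene_names[object$tf_indices],
                       time_labels = object$time_labels)
  })
  names(out) <- cell_types
  out
}
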