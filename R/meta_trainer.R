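# MAML training over cell-type tasks, plus plain pooled training for
# ablation. The inner loop is plain gradient descent on the support batch;
# the meta-update is Adam on the query loss, with global gradient-norm
# clipping and an exponentially decaying meta-learning rate.

#' Adapt parameters on a support batch (MAML inner loop)
#'
#' Performs `control$inner_steps` plain gradient-descent updates at
#' `control$inner_lr` on the cell-type loss of the support batch. The input
#' parameters are not modified (functional update).
#'
#' @param params named list of parameter matrices.
#' @param support_batch a temporal batch (see [sample_temporal_batch()]).
#' @param control a [marlene_control()].
#' @return list with `params` (adapted), `trajectory` (the parameter iterates
#'   before each inner step, used by the second-order meta-gradient), and
#'   `losses` (support loss before each step).
#' @export
inner_adapt <- function(params, support_batch, control) {
  n <- control$inner_steps
  traj <- vector("list", n)
  losses <- numeric(n)
  cur <- params
  for (i in seq_len(n)) {
    traj[[i]] <- cur
    fw <- marlene_forward(cur, support_batch, control, grad = TRUE)
    if (!is.finite(fw$loss)) stop("non-finite support loss during inner adaptation")
    losses[i] <- fw$loss
    cur <- params_axpy(cur, -control$inner_lr, fw$grads)
  }
  list(params = cur, trajectory = traj, losses = losses)
}

# Hessian-vector product of the support loss at theta, by central
# differencing of the analytic gradient along v.
support_hvp <- function(theta, batch, v, control) {
  nv <- params_norm(v)
  if (nv == 0) return(params_zero_like(v))
  h <- control$hvp_eps * (1 + params_norm(theta)) / nv
  gp <- marlene_grad(params_axpy(theta, h, v), batch, control)
  gm <- marlene_grad(params_axpy(theta, -h, v), batch, control)
  out <- v
  for (nm in names(out)) out[[nm]] <- (gp[[nm]] - gm[[nm]]) / (2 * h)
  out
}

# Meta-gradient for one task: adapt on support, evaluate on query, and (for
# second-order MAML) back-propagate through the unrolled inner loop via
# v <- (I - eta H(theta_i)) v.
task_meta_grad <- function(params, support_batch, query_batch, control) {
  ad <- inner_adapt(params, support_batch, control)
  qf <- marlene_forward(ad$params, query_batch, control, grad = TRUE)
  v <- qf$grads
  if (!control$first_order) {
    for (i in rev(seq_along(ad$trajectory))) {
      hv <- support_hvp(ad$trajectory[[i]], support_batch, v, control)
      v <- params_axpy(v, -control$inner_lr, hv)
    }
  }
  list(grad = v, query_loss = qf$loss, support_losses = ad$losses)
}

adam_init <- function(params, lr) {
  list(m = params_zero_like(params), v = params_zero_like(params),
       t = 0L, lr = lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_update <- function(params, grads, st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grads[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      st$lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + st$eps)
  }
  list(params = params, state = st)
}

clip_global_norm <- function(grads, clip_norm) {
  nrm <- params_norm(grads)
  if (nrm > clip_norm) {
    s <- clip_norm / nrm
    grads <- lapply(grads, function(m) m * s)
  }
  list(grads = grads, norm = nrm, clipped_norm = min(nrm, clip_norm))
}

decayed_weight_names <- function(params) {
  nms <- names(params)
  nms[grepl("^(S$|enc_|rff_W|ds_phi_W|ds_rho_W|dec_W)", nms)]
}

add_weight_decay <- function(grads, params, wd) {
  if (wd <= 0) return(grads)
  for (nm in decayed_weight_names(params)) {
    grads[[nm]] <- grads[[nm]] + wd * params[[nm]]
  }
  grads
}

#' One meta-update over a set of cell-type tasks
#'
#' For every task: adapt on its support batch, evaluate the cell-type loss
#' on its query batch with the adapted parameters, and form the MAML
#' meta-gradient (differentiated through the inner loop unless
#' `control$first_order`). The mean task meta-gradient, plus weight decay on
#' encoder/decoder weights, is clipped to `control$clip_norm` (global norm)
#' and applied with Adam.
#'
#' @param params named list of parameter matrices.
#' @param tasks list of tasks, each a list with elements `support` and
#'   `query` (temporal batches).
#' @param opt_state Adam state from [adam_init] (internal) or a previous
#'   call; pass `NULL` to initialize at `control$meta_lr`.
#' @param control a [marlene_control()].
#' @return list with `params`, `opt_state`, and `log_row` (per-task query
#'   losses, mean query loss, pre/post-clip gradient norms, learning rate).
#' @export
meta_step <- function(params, tasks, opt_state, control) {
  if (!length(tasks)) stop("meta_step needs at least one task")
  if (is.null(opt_state)) opt_state <- adam_init(params, control$meta_lr)
  acc <- NULL
  qlosses <- numeric(length(tasks))
  for (j in seq_along(tasks)) {
    tg <- task_meta_grad(params, tasks[[j]]$support, tasks[[j]]$query, control)
    qlosses[j] <- tg$query_loss
    acc <- if (is.null(acc)) tg$grad else params_axpy(acc, 1, tg$grad)
  }
  grads <- lapply(acc, function(m) m / length(tasks))
  grads <- add_weight_decay(grads, params, control$weight_decay)
  cl <- clip_global_norm(grads, control$clip_norm)
  if (control$meta_lr > 0 && opt_state$lr > 0) {
    up <- adam_update(params, cl$grads, opt_state)
    params <- up$params
    opt_state <- up$state
  }
  list(params = params, opt_state = opt_state,
       log_row = list(query_losses = qlosses,
                      mean_query_loss = mean(qlosses),
                      grad_norm = cl$norm,
                      grad_norm_clipped = cl$clipped_norm,
                      lr = opt_state$lr))
}

# Full training loop shared by MAML and pooled training. Returns parameters,
# checkpoints, and a step-indexed log. Assumes the RNG seed was set by the
# caller.
train_loop <- function(series, splits, control, meta = TRUE, verbose = FALSE) {
  types <- names(splits)
  g <- length(series$gene_names)
  p <- length(series$tf_indices)
  C <- length(series$cell_type_levels)
  params <- init_marlene_params(g, p, C, control)
  opt <- adam_init(params, control$meta_lr)
  log <- NULL
  checkpoints <- list()
  last_good <- params
  for (step in seq_len(control$meta_steps)) {
    row <- tryCatch({
      if (meta) {
        tasks <- lapply(types, function(ct) {
          suppressWarnings(list(
            support = sample_temporal_batch(series, ct, control$batch_size,
                                            splits[[ct]]$support),
            query = sample_temporal_batch(series, ct, control$batch_size,
                                          splits[[ct]]$query)))
        })
        st <- meta_step(params, tasks, opt, control)
        params <- st$params
        opt <- st$opt_state
        st$log_row
      } else {
        acc <- NULL
        losses <- numeric(length(types))
        for (j in seq_along(types)) {
          batch <- suppressWarnings(
            sample_temporal_batch(series, types[[j]], control$batch_size))
          fw <- marlene_forward(params, batch, control, grad = TRUE)
          losses[j] <- fw$loss
          acc <- if (is.null(acc)) fw$grads else params_axpy(acc, 1, fw$grads)
        }
        grads <- lapply(acc, function(m) m / length(types))
        grads <- add_weight_decay(grads, params, control$weight_decay)
        cl <- clip_global_norm(grads, control$clip_norm)
        up <- adam_update(params, cl$grads, opt)
        params <- up$params
        opt <- up$state
        list(query_losses = losses, mean_query_loss = mean(losses),
             grad_norm = cl$norm, grad_norm_clipped = cl$clipped_norm,
             lr = opt$lr)
      }
    }, error = function(e) e)
    if (inherits(row, "error") || !is.finite(row$mean_query_loss)) {
      warning(sprintf("training aborted at step %d (%s); last checkpoint retained",
                      step, if (inherits(row, "error")) conditionMessage(row)
                      else "non-finite loss"))
      params <- last_good
      break
    }
    last_good <- params
    log <- rbind(log, data.frame(step = step,
                                 mean_query_loss = row$mean_query_loss,
                                 task_query_losses = paste(
                                   signif(row$query_losses, 6), collapse = ","),
                                 grad_norm = row$grad_norm,
                                 grad_norm_clipped = row$grad_norm_clipped,
                                 lr = row$lr))
    if (verbose && step %% 10L == 0L) {
      message(sprintf("step %4d  loss %.4f  |g| %.3f  lr %.2e",
                      step, row$mean_query_loss, row$grad_norm, opt$lr))
    }
    if (step %% control$checkpoint_every == 0L || step == control$meta_steps) {
      checkpoints[[length(checkpoints) + 1L]] <-
        list(step = step, params = params,
             mean_query_loss = row$mean_query_loss)
    }
    if (step %% control$lr_decay_every == 0L) {
      opt$lr <- opt$lr * control$lr_decay
    }
  }
  list(params = params, checkpoints = checkpoints, log = log)
}

#' Select the best checkpoint
#'
#' Returns the index of the checkpoint with the lowest mean query loss;
#' ties go to the earliest checkpoint.
#'
#' @param checkpoints list of checkpoints (each with `mean_query_loss`), or
#'   a data frame with a `mean_query_loss` column.
#' @return integer index.
#' @export
select_checkpoint <- function(checkpoints) {
  if (is.data.frame(checkpoints)) {
    losses <- checkpoints$mean_query_loss
  } else {
    losses <- vapply(checkpoints, function(ck) ck$mean_query_loss, numeric(1))
  }
  if (!length(losses)) stop("no checkpoints to select from")
  which.min(losses) # which.min returns the first (earliest) minimum
}
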