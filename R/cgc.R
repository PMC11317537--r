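#' @name cgc
#' @title Gated mixture-of-experts multitask core
#' @description
#' Customized gate control (CGC): each task (kcat, Km) owns specific
#' expert subnetworks and shares a pool of shared experts; a per-task
#' softmax gating network computes, from the fused input, the weights with
#' which the task's specific and the shared expert outputs are summed; a
#' per-task tower maps the fused representation to the scalar log10
#' prediction. Stacking more than one extraction layer
#' (`n_cgc_layers > 1`) yields the progressive-layered-extraction style
#' variant in which intermediate layers also maintain a gated shared path.
#' Training minimizes a masked L2 loss with Adam, so entries carrying only
#' one of the two labels still contribute to their task.
NULL

#' Configuration of the multitask model
#'
#' Defaults follow the reference training setup: 4 specific experts per
#' task and 4 shared experts, one affine layer per expert with 768 hidden
#' units and dropout 0.2, towers of dimensions 128-128-1, a single CGC
#' extraction layer, Adam with learning rate 1e-4, batch size 1, 50
#' epochs. Tests and desk-scale runs shrink the dimensions; results are
#' gated on properties, not on a particular capacity.
#'
#' @param input_dim fused input dimension d.
#' @param n_shared_experts number of shared experts (m_s).
#' @param n_specific_experts specific experts per task (m_k).
#' @param expert_layers affine layers inside each expert.
#' @param expert_dim expert output width.
#' @param expert_dropout dropout rate on expert outputs during training.
#' @param tower_dims widths of the tower layers; last must be 1. ReLU is
#'   applied between hidden tower layers, the final output is linear so
#'   negative log10 values are representable.
#' @param n_cgc_layers extraction layers (1 = plain CGC, >1 = stacked).
#' @param learning_rate,batch_size,epochs Adam training parameters.
#' @param tasks `"both"` for multitask, or `"kcat"` / `"km"` for a
#'   single-task model of matched capacity.
#' @param seed integer; threads through initialization, shuffling and
#'   dropout.
#' @return object of class `cgc_config`.
#' @export
cgc_config <- function(input_dim,
                       n_shared_experts = 4L,
                       n_specific_experts = 4L,
                       expert_layers = 1L,
                       expert_dim = 768L,
                       expert_dropout = 0.2,
                       tower_dims = c(128L, 128L, 1L),
                       n_cgc_layers = 1L,
                       learning_rate = 1e-4,
                       batch_size = 1L,
                       epochs = 50L,
                       tasks = c("both", "kcat", "km"),
                       seed = 1L) {
  tasks <- match.arg(tasks)
  stopifnot(input_dim >= 1, n_shared_experts >= 0, n_specific_experts >= 1,
            expert_layers >= 1, expert_dim >= 1,
            expert_dropout >= 0, expert_dropout < 1,
            tower_dims[length(tower_dims)] == 1L, n_cgc_layers >= 1,
            learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(
    input_dim = as.integer(input_dim),
    n_shared_experts = as.integer(n_shared_experts),
    n_specific_experts = as.integer(n_specific_experts),
    expert_layers = as.integer(expert_layers),
    expert_dim = as.integer(expert_dim),
    expert_dropout = expert_dropout,
    tower_dims = as.integer(tower_dims),
    n_cgc_layers = as.integer(n_cgc_layers),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    tasks = tasks,
    seed = as.integer(seed)
  ), class = "cgc_config")
}

task_names <- function(config) {
  if (config$tasks == "both") c("kcat", "km") else config$tasks
}

# uniform fan-in initialization for an affine map
init_affine <- function(d_in, d_out) {
  lim <- 1 / sqrt(d_in)
  list(W = matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out),
       b = stats::runif(d_out, -lim, lim))
}

init_expert <- function(d_in, config) {
  dims <- c(d_in, rep(config$expert_dim, config$expert_layers))
  lapply(seq_len(config$expert_layers),
         function(s) init_affine(dims[s], dims[s + 1]))
}

init_tower <- function(config) {
  dims <- c(config$expert_dim, config$tower_dims)
  lapply(seq_along(config$tower_dims),
         function(s) init_affine(dims[s], dims[s + 1]))
}

#' Initialize a CGC model
#'
#' @param config [cgc_config()].
#' @param spec optional [feature_spec()]; when given, the trainable
#'   auxiliary-encoder parameters (RBF linear maps, organism embedding
#'   table) are created as part of the model and `input_dim` must equal
#'   `input_dim(spec)`.
#' @return object of class `cgc_model`.
#' @export
cgc_init <- function(config, spec = NULL) {
  if (!is.null(spec) && input_dim(spec) != config$input_dim) {
    stopf("config input_dim (%d) != feature spec input dim (%d)",
          config$input_dim, input_dim(spec))
  }
  tns <- task_names(config)
  with_seed(config$seed, {
    layers <- vector("list", config$n_cgc_layers)
    for (l in seq_len(config$n_cgc_layers)) {
      d_in <- if (l == 1L) config$input_dim else config$expert_dim
      m_k <- config$n_specific_experts
      m_s <- config$n_shared_experts
      lay <- list(
        specific = stats::setNames(lapply(tns, function(k) {
          lapply(seq_len(m_k), function(i) init_expert(d_in, config))
        }), tns),
        shared = lapply(seq_len(m_s), function(j) init_expert(d_in, config)),
        gates = stats::setNames(lapply(tns, function(k) {
          lim <- 1 / sqrt(d_in)
          matrix(stats::runif((m_k + m_s) * d_in, -lim, lim), m_k + m_s, d_in)
        }), tns)
      )
      if (l < config$n_cgc_layers) {
        n_all <- m_k * length(tns) + m_s
        lim <- 1 / sqrt(d_in)
        lay$gate_shared <- matrix(stats::runif(n_all * d_in, -lim, lim),
                                  n_all, d_in)
      }
      layers[[l]] <- lay
    }
    params <- list(
      layers = layers,
      towers = stats::setNames(lapply(tns, function(k) init_tower(config)),
                               tns)
    )
    if (!is.null(spec)) {
      params$aux <- aux_params_init(spec, seed = config$seed + 1L)
    }
    structure(list(config = config, params = params, spec = spec),
              class = "cgc_model")
  })
}

#' @export
print.cgc_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "CGC model: tasks=%s, d=%d, %d specific + %d shared experts (dim %d), %d layer(s)\n",
    cfg$tasks, cfg$input_dim, cfg$n_specific_experts, cfg$n_shared_experts,
    cfg$expert_dim, cfg$n_cgc_layers))
  invisible(x)
}

# row-wise numerically stable softmax
softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

relu <- function(x) (x > 0) * x

#' Gating weights for one input
#'
#' `w = Softmax(W_g x)`: a point on the probability simplex over the
#' task's specific experts followed by the shared experts.
#'
#' @param x fused input vector (length d).
#' @param W_g gate matrix, `(m_k + m_s) x d`.
#' @return weight vector summing to 1.
#' @export
gate_weights <- function(x, W_g) {
  if (ncol(W_g) != length(x)) stopf("gate/input shape mismatch")
  drop(softmax_rows(matrix(drop(W_g %*% x), nrow = 1)))
}

# evaluate one expert (eval mode) on a single input vector
expert_eval <- function(expert, x) {
  h <- matrix(x, nrow = 1)
  for (sub in expert) h <- relu(h %*% sub$W + rep(sub$b, each = 1))
  drop(h)
}

#' Matrix of expert outputs for one input
#'
#' Rows are ordered specific experts 1..m_k, then shared experts 1..m_s,
#' matching the gate-weight ordering. Evaluation mode (no dropout).
#'
#' @param model `cgc_model`.
#' @param x fused input vector.
#' @param task `"kcat"` or `"km"`.
#' @param layer extraction layer index.
#' @return matrix `(m_k + m_s) x expert_dim`.
#' @export
select_matrix <- function(model, x, task, layer = 1L) {
  lay <- model$params$layers[[layer]]
  outs <- c(lapply(lay$specific[[task]], expert_eval, x = x),
            lapply(lay$shared, expert_eval, x = x))
  do.call(rbind, outs)
}

#' Gate-weighted fusion of expert outputs for one input
#'
#' `g(x) = w(x) S(x)`: the gate-weighted sum of the expert output rows.
#'
#' @inheritParams select_matrix
#' @return numeric vector of length `expert_dim`.
#' @export
fuse <- function(model, x, task, layer = 1L) {
  w <- gate_weights(x, model$params$layers[[layer]]$gates[[task]])
  drop(w %*% select_matrix(model, x, task, layer))
}

# ---- batch forward ---------------------------------------------------------

# forward through one expert on a batch, caching pre-activations and masks
expert_forward <- function(expert, input, train, dropout) {
  hs <- list(input); zs <- list(); masks <- list()
  h <- input
  for (s in seq_along(expert)) {
    z <- h %*% expert[[s]]$W + rep(expert[[s]]$b, each = nrow(h))
    a <- relu(z)
    if (train && dropout > 0) {
      m <- matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a)) /
        (1 - dropout)
      a <- a * m
      masks[[s]] <- m
    }
    zs[[s]] <- z
    hs[[s + 1]] <- a
    h <- a
  }
  list(out = h, hs = hs, zs = zs, masks = masks)
}

expert_backward <- function(expert, cache, d_out, dropout, train) {
  dW <- vector("list", length(expert))
  dh <- d_out
  for (s in rev(seq_along(expert))) {
    if (train && dropout > 0) dh <- dh * cache$masks[[s]]
    dz <- dh * (cache$zs[[s]] > 0)
    dW[[s]] <- list(W = crossprod(cache$hs[[s]], dz), b = colSums(dz))
    dh <- dz %*% t(expert[[s]]$W)
  }
  list(grads = dW, d_in = dh)
}

tower_forward <- function(tower, G) {
  hs <- list(G); zs <- list()
  h <- G
  n_lay <- length(tower)
  for (s in seq_len(n_lay)) {
    z <- h %*% tower[[s]]$W + rep(tower[[s]]$b, each = nrow(h))
    h <- if (s < n_lay) relu(z) else z
    zs[[s]] <- z
    hs[[s + 1]] <- h
  }
  list(out = h, hs = hs, zs = zs)
}

tower_backward <- function(tower, cache, d_out) {
  dW <- vector("list", length(tower))
  dh <- d_out
  for (s in rev(seq_along(tower))) {
    dz <- if (s < length(tower)) dh * (cache$zs[[s]] > 0) else dh
    dW[[s]] <- list(W = crossprod(cache$hs[[s]], dz), b = colSums(dz))
    dh <- dz %*% t(tower[[s]]$W)
  }
  list(grads = dW, d_in = dh)
}

# full forward pass on a fused batch matrix X; returns predictions and cache
cgc_forward_X <- function(model, X, train = FALSE) {
  cfg <- model$config
  tns <- task_names(cfg)
  if (ncol(X) != cfg$input_dim) {
    stopf("input has %d columns, model expects %d", ncol(X), cfg$input_dim)
  }
  L <- cfg$n_cgc_layers
  xs <- stats::setNames(rep(list(X), length(tns) + 1),
                        c(tns, ".shared"))
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    lay <- model$params$layers[[l]]
    m_k <- cfg$n_specific_experts
    m_s <- cfg$n_shared_experts
    ec <- list(specific = list(), shared = list())
    for (k in tns) {
      ec$specific[[k]] <- lapply(lay$specific[[k]], expert_forward,
                                 input = xs[[k]], train = train,
                                 dropout = cfg$expert_dropout)
    }
    ec$shared <- lapply(lay$shared, expert_forward, input = xs$.shared,
                        train = train, dropout = cfg$expert_dropout)
    new_xs <- list()
    gate_w <- list()
    for (k in tns) {
      outs <- c(lapply(ec$specific[[k]], `[[`, "out"),
                lapply(ec$shared, `[[`, "out"))
      w <- softmax_rows(xs[[k]] %*% t(lay$gates[[k]]))
      g <- 0
      for (i in seq_along(outs)) g <- g + w[, i] * outs[[i]]
      new_xs[[k]] <- g
      gate_w[[k]] <- w
    }
    shared_w <- NULL
    if (l < L) {
      outs <- c(unlist(lapply(tns, function(k) {
        lapply(ec$specific[[k]], `[[`, "out")
      }), recursive = FALSE), lapply(ec$shared, `[[`, "out"))
      shared_w <- softmax_rows(xs$.shared %*% t(lay$gate_shared))
      g <- 0
      for (i in seq_along(outs)) g <- g + shared_w[, i] * outs[[i]]
      new_xs$.shared <- g
    }
    caches[[l]] <- list(xs = xs, experts = ec, gate_w = gate_w,
                        shared_w = shared_w)
    xs <- new_xs
  }
  tower_caches <- list()
  preds <- matrix(0, nrow(X), length(tns), dimnames = list(NULL, tns))
  for (k in tns) {
    tc <- tower_forward(model$params$towers[[k]], xs[[k]])
    tower_caches[[k]] <- tc
    preds[, k] <- tc$out
  }
  list(preds = preds, caches = caches, tower_caches = tower_caches,
       top_xs = xs)
}

#' Forward pass on a batch of fused inputs
#'
#' Evaluates every task head for every row of `X`. Evaluation mode is
#' deterministic (dropout disabled).
#'
#' @param model `cgc_model`.
#' @param X numeric matrix `n x input_dim` of fused inputs.
#' @return matrix `n x n_tasks` of log10-scale predictions, columns named
#'   by task.
#' @export
cgc_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  cgc_forward_X(model, X, train = FALSE)$preds
}

#' Masked L2 loss over observed labels
#'
#' Mean squared error over the labels each entry actually carries; masked
#' slots contribute nothing, so the placeholder stored there is
#' irrelevant.
#'
#' @param preds n x n_tasks prediction matrix.
#' @param labels n x n_tasks label matrix.
#' @param mask n x n_tasks logical matrix of observed labels.
#' @return scalar loss.
#' @export
masked_l2_loss <- function(preds, labels, mask) {
  n_obs <- sum(mask)
  if (n_obs == 0) stopf("masked_l2_loss: no observed labels in batch")
  sum(mask * (preds - labels)^2) / n_obs
}

# gradient of masked L2 loss w.r.t. predictions
masked_l2_grad <- function(preds, labels, mask) {
  2 * mask * (preds - labels) / sum(mask)
}

# zero-filled gradient skeleton matching a parameter tree
zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

# full backward pass; returns gradient tree mirroring model$params
cgc_backward <- function(model, fwd, d_preds, fs = NULL, rows = NULL,
                         train = TRUE) {
  cfg <- model$config
  tns <- task_names(cfg)
  L <- cfg$n_cgc_layers
  grads <- zero_like(model$params)

  d_xs <- list()
  for (ki in seq_along(tns)) {
    k <- tns[ki]
    tb <- tower_backward(model$params$towers[[k]], fwd$tower_caches[[k]],
                         d_preds[, ki, drop = FALSE])
    grads$towers[[k]] <- tb$grads
    d_xs[[k]] <- tb$d_in
  }
  d_xs$.shared <- NULL

  for (l in rev(seq_len(L))) {
    lay <- model$params$layers[[l]]
    cache <- fwd$caches[[l]]
    m_k <- cfg$n_specific_experts
    m_s <- cfg$n_shared_experts
    n <- nrow(cache$xs[[1]])
    d_expert_out <- list(
      specific = stats::setNames(lapply(tns, function(k) {
        lapply(seq_len(m_k), function(i) 0)
      }), tns),
      shared = lapply(seq_len(m_s), function(j) 0)
    )
    d_prev <- stats::setNames(rep(list(0), length(tns) + 1),
                              c(tns, ".shared"))

    # task gates
    for (k in tns) {
      dG <- d_xs[[k]]
      if (is.null(dG)) next
      w <- cache$gate_w[[k]]
      outs <- c(lapply(cache$experts$specific[[k]], `[[`, "out"),
                lapply(cache$experts$shared, `[[`, "out"))
      dw <- matrix(0, n, m_k + m_s)
      for (i in seq_along(outs)) {
        dw[, i] <- rowSums(dG * outs[[i]])
        contrib <- w[, i] * dG
        if (i <= m_k) {
          d_expert_out$specific[[k]][[i]] <-
            d_expert_out$specific[[k]][[i]] + contrib
        } else {
          j <- i - m_k
          d_expert_out$shared[[j]] <- d_expert_out$shared[[j]] + contrib
        }
      }
      dlog <- w * (dw - rowSums(dw * w))
      grads$layers[[l]]$gates[[k]] <- crossprod(dlog, cache$xs[[k]])
      d_prev[[k]] <- d_prev[[k]] + dlog %*% lay$gates[[k]]
    }

    # shared-path gate (intermediate layers of the stacked variant)
    if (l < L && !is.null(d_xs$.shared)) {
      dG <- d_xs$.shared
      w <- cache$shared_w
      outs <- c(unlist(lapply(tns, function(k) {
        lapply(cache$experts$specific[[k]], `[[`, "out")
      }), recursive = FALSE), lapply(cache$experts$shared, `[[`, "out"))
      dw <- matrix(0, n, length(outs))
      for (i in seq_along(outs)) {
        dw[, i] <- rowSums(dG * outs[[i]])
        contrib <- w[, i] * dG
        if (i <= m_k * length(tns)) {
          k <- tns[ceiling(i / m_k)]
          ii <- i - (ceiling(i / m_k) - 1) * m_k
          d_expert_out$specific[[k]][[ii]] <-
            d_expert_out$specific[[k]][[ii]] + contrib
        } else {
          j <- i - m_k * length(tns)
          d_expert_out$shared[[j]] <- d_expert_out$shared[[j]] + contrib
        }
      }
      dlog <- w * (dw - rowSums(dw * w))
      grads$layers[[l]]$gate_shared <- crossprod(dlog, cache$xs$.shared)
      d_prev$.shared <- d_prev$.shared + dlog %*% lay$gate_shared
    }

    # experts
    for (k in tns) {
      for (i in seq_len(m_k)) {
        dE <- d_expert_out$specific[[k]][[i]]
        if (is.matrix(dE)) {
          eb <- expert_backward(lay$specific[[k]][[i]],
                                cache$experts$specific[[k]][[i]], dE,
                                cfg$expert_dropout, train)
          grads$layers[[l]]$specific[[k]][[i]] <- eb$grads
          d_prev[[k]] <- d_prev[[k]] + eb$d_in
        }
      }
    }
    for (j in seq_len(m_s)) {
      dE <- d_expert_out$shared[[j]]
      if (is.matrix(dE)) {
        eb <- expert_backward(lay$shared[[j]], cache$experts$shared[[j]], dE,
                              cfg$expert_dropout, train)
        grads$layers[[l]]$shared[[j]] <- eb$grads
        d_prev$.shared <- d_prev$.shared + eb$d_in
      }
    }
    d_xs <- d_prev
  }

  # all layer-1 paths read the same fused input
  dX <- 0
  for (nm in names(d_xs)) dX <- dX + d_xs[[nm]]

  if (!is.null(fs) && !is.null(model$params$aux)) {
    d_fixed <- fs$spec$d_enzyme + fs$spec$d_substrate
    dA <- dX[, (d_fixed + 1):ncol(dX), drop = FALSE]
    grads$aux$W_ph <- crossprod(fs$R_ph[rows, , drop = FALSE], dA)
    grads$aux$W_temp <- crossprod(fs$R_temp[rows, , drop = FALSE], dA)
    dE <- matrix(0, nrow(model$params$aux$E_org), ncol(dA))
    oi <- fs$org_idx[rows]
    for (r in which(oi > 0L)) dE[oi[r], ] <- dE[oi[r], ] + dA[r, ]
    grads$aux$E_org <- dE
  }
  list(grads = grads, dX = dX)
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step_rec <- function(p, g, m, v, lr_t, beta1, beta2, eps) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    for (nm in seq_along(p)) {
      if (is.null(g[[nm]])) next
      r <- adam_step_rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]],
                         lr_t, beta1, beta2, eps)
      out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    return(list(p = out_p, m = out_m, v = out_v))
  }
  m2 <- beta1 * m + (1 - beta1) * g
  v2 <- beta2 * v + (1 - beta2) * g * g
  list(p = p - lr_t * m2 / (sqrt(v2) + eps), m = m2, v = v2)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  r <- adam_step_rec(params, grads, state$m, state$v, lr_t, beta1, beta2, eps)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# ---- training --------------------------------------------------------------

# predictions (eval mode) for a feature set, using the model's aux params
cgc_forward_fs <- function(model, fs, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(fs$n)
  sub <- list(XB = fs$XB[rows, , drop = FALSE],
              R_ph = fs$R_ph[rows, , drop = FALSE],
              R_temp = fs$R_temp[rows, , drop = FALSE],
              org_idx = fs$org_idx[rows])
  X <- fused_matrix(sub, model$params$aux)
  cgc_forward_X(model, X, train = FALSE)$preds
}

task_cols <- function(config) {
  match(task_names(config), c("kcat", "km"))
}

val_metrics <- function(preds, Y, mask, tns) {
  out <- list()
  for (ki in seq_along(tns)) {
    obs <- mask[, ki]
    if (sum(obs) >= 2 && stats::sd(Y[obs, ki]) > 0 &&
        stats::sd(preds[obs, ki]) > 0) {
      out[[paste0("pcc_", tns[ki])]] <- pcc(Y[obs, ki], preds[obs, ki])
      out[[paste0("r2_", tns[ki])]] <- r2(Y[obs, ki], preds[obs, ki])
      out[[paste0("rmse_", tns[ki])]] <- rmse(Y[obs, ki], preds[obs, ki])
    } else {
      out[[paste0("pcc_", tns[ki])]] <- NA_real_
      out[[paste0("r2_", tns[ki])]] <- NA_real_
      out[[paste0("rmse_", tns[ki])]] <- NA_real_
    }
  }
  out
}

#' Train a CGC model
#'
#' Minimizes the masked L2 loss with Adam over minibatches. Parameter
#' initialization, epoch shuffling and dropout are all driven by
#' `config$seed`, so identical seeds give identical training histories.
#' The returned model carries the parameters of the epoch with the lowest
#' validation loss (earliest epoch on ties).
#'
#' @param fs_train,fs_val [featurize_entries()] feature sets.
#' @param config [cgc_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `cgc_fit`: list with `model` (best-validation
#'   parameters), `history` (one row per epoch: training loss, validation
#'   loss, per-task validation PCC/R2/RMSE), `best_epoch`, `config`.
#' @export
cgc_train <- function(fs_train, fs_val, config, verbose = FALSE) {
  if (fs_train$n == 0) stopf("empty training set")
  tns <- task_names(config)
  cols <- task_cols(config)
  model <- cgc_init(config, fs_train$spec)
  state <- adam_state(model$params)
  history <- vector("list", config$epochs)
  best <- list(loss = Inf, params = model$params, epoch = 0L)

  Ytr <- fs_train$Y[, cols, drop = FALSE]
  Mtr <- fs_train$mask[, cols, drop = FALSE]
  Yva <- fs_val$Y[, cols, drop = FALSE]
  Mva <- fs_val$mask[, cols, drop = FALSE]

  with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(fs_train$n)
      tr_loss_num <- 0; tr_loss_den <- 0
      starts <- seq(1, fs_train$n, by = config$batch_size)
      for (s in starts) {
        rows <- idx[s:min(s + config$batch_size - 1L, fs_train$n)]
        if (!any(Mtr[rows, ])) next
        sub <- list(XB = fs_train$XB[rows, , drop = FALSE],
                    R_ph = fs_train$R_ph[rows, , drop = FALSE],
                    R_temp = fs_train$R_temp[rows, , drop = FALSE],
                    org_idx = fs_train$org_idx[rows])
        X <- fused_matrix(sub, model$params$aux)
        fwd <- cgc_forward_X(model, X, train = TRUE)
        yb <- Ytr[rows, , drop = FALSE]
        mb <- Mtr[rows, , drop = FALSE]
        loss <- masked_l2_loss(fwd$preds, yb, mb)
        tr_loss_num <- tr_loss_num + loss * sum(mb)
        tr_loss_den <- tr_loss_den + sum(mb)
        dp <- masked_l2_grad(fwd$preds, yb, mb)
        bk <- cgc_backward(model, fwd, dp, fs = fs_train, rows = rows,
                           train = TRUE)
        upd <- adam_update(model$params, bk$grads, state,
                           config$learning_rate)
        model$params <- upd$params
        state <- upd$state
      }
      preds_val <- cgc_forward_fs(model, fs_val)
      val_loss <- masked_l2_loss(preds_val, Yva, Mva)
      row <- c(list(epoch = epoch, train_loss = tr_loss_num / tr_loss_den,
                    val_loss = val_loss),
               val_metrics(preds_val, Yva, Mva, tns))
      history[[epoch]] <- as.data.frame(row)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        row$train_loss, val_loss))
      }
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = model$params, epoch = epoch)
      }
    }
  })
  model$params <- best$params
  structure(list(model = model, history = do.call(rbind, history),
                 best_epoch = best$epoch, config = config),
            class = "cgc_fit")
}

#' @export
print.cgc_fit <- function(x, ...) {
  cat(sprintf("CGC fit: %d epochs, best validation loss %.4f at epoch %d\n",
              nrow(x$history), min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' Predict kinetic parameters for curated entries
#'
#' Both task heads are evaluated for every entry regardless of label
#' availability. Predictions are reported on the log10 scale, on the
#' linear scale (s^-1 for kcat, mM for Km), and as the catalytic
#' efficiency `log10(kcat) - log10(Km)` used to rank enzyme variants.
#'
#' @param fit a `cgc_fit` (or a bare `cgc_model` carrying aux parameters).
#' @param entries `curated_entries`, or an existing `feature_set`.
#' @return data.frame, one row per entry, in input order.
#' @export
predict_entries <- function(fit, entries) {
  model <- if (inherits(fit, "cgc_fit")) fit$model else fit
  fs <- if (inherits(entries, "feature_set")) entries else
    featurize_entries(entries, model$spec)
  preds <- cgc_forward_fs(model, fs)
  tns <- task_names(model$config)
  out <- data.frame(row = seq_len(fs$n))
  for (k in tns) {
    out[[paste0("pred_log10_", k)]] <- preds[, k]
    out[[paste0("pred_", k)]] <- 10^preds[, k]
  }
  if (all(c("kcat", "km") %in% tns)) {
    out$pred_log10_efficiency <- preds[, "kcat"] - preds[, "km"]
  }
  out$row <- NULL
  cbind(fs$entries[intersect(c(key_cols, "enzyme_type"), names(fs$entries))],
        out)
}
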