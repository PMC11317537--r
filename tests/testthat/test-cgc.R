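# reference configuration for small model tests
tiny_config <- function(d, ..., seed = 1) {
  args <- list(input_dim = d, n_shared_experts = 2L,
               n_specific_experts = 1L, expert_dim = 5L,
               expert_dropout = 0, tower_dims = c(4L, 1L), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(cgc_config, args)
}

test_that("gate weights are a softmax over the experts", {
  # zero gate: uniform weights
  w0 <- gate_weights(rnorm(6), matrix(0, 4, 6))
  expect_equal(w0, rep(0.25, 4))
  # closed-form softmax of logits (ln 2, 0)
  x <- c(1, 0)
  W <- rbind(c(log(2), 0), c(0, 0))
  expect_equal(gate_weights(x, W), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_error(gate_weights(rnorm(3), matrix(0, 2, 5)), "mismatch")
})

test_that("gate outputs stay on the probability simplex", {
  withr::local_seed(7)
  W <- matrix(rnorm(5 * 12, sd = 2), 5, 12)
  for (i in seq_len(1000)) {
    w <- gate_weights(rnorm(12, sd = 5), W)
    expect_true(all(w > 0))
    expect_lt(abs(sum(w) - 1), 1e-9)
  }
})

test_that("select matrix rows match per-expert recomputation", {
  d <- 7
  cfg <- tiny_config(d, n_specific_experts = 2L, n_shared_experts = 1L)
  model <- cgc_init(cfg)
  x <- rnorm(d)
  S <- select_matrix(model, x, "kcat")
  expect_equal(dim(S), c(3L, cfg$expert_dim))
  # brute force: affine + ReLU per expert, specific then shared
  lay <- model$params$layers[[1]]
  experts <- c(lay$specific$kcat, lay$shared)
  for (i in seq_along(experts)) {
    e <- experts[[i]][[1]]
    expect_equal(S[i, ], pmax(drop(x %*% e$W) + e$b, 0), tolerance = 1e-12)
  }
  expect_identical(S, select_matrix(model, x, "kcat"))  # eval determinism
})

test_that("fusion equals the brute-force gate-weighted sum", {
  withr::local_seed(31)
  for (rep in 1:10) {
    d <- sample(4:16, 1)
    cfg <- tiny_config(d, n_specific_experts = sample(1:3, 1),
                       n_shared_experts = sample(0:3, 1),
                       expert_dim = sample(3:8, 1), seed = rep)
    model <- cgc_init(cfg)
    x <- rnorm(d)
    task <- sample(c("kcat", "km"), 1)
    g <- fuse(model, x, task)
    w <- gate_weights(x, model$params$layers[[1]]$gates[[task]])
    S <- select_matrix(model, x, task)
    brute <- colSums(sweep(S, 1, w, `*`))
    expect_equal(g, brute, tolerance = 1e-6)
  }
  # a single expert receives weight 1
  cfg1 <- tiny_config(5, n_specific_experts = 1L, n_shared_experts = 0L)
  m1 <- cgc_init(cfg1)
  x <- rnorm(5)
  expect_equal(fuse(m1, x, "km"),
               drop(select_matrix(m1, x, "km")), tolerance = 1e-12)
})

test_that("towers are affine chains with linear output", {
  cfg <- tiny_config(6)
  model <- cgc_init(cfg)
  # zero weights: output equals the final bias
  tw <- model$params$towers$kcat
  for (s in seq_along(tw)) tw[[s]]$W[] <- 0
  for (s in seq_along(tw)) tw[[s]]$b[] <- 0
  tw[[length(tw)]]$b <- 0.7
  out <- kinetmoe:::tower_forward(tw, matrix(rnorm(10 * cfg$expert_dim), 10))
  expect_equal(drop(out$out), rep(0.7, 10))
  # hand-computed single-layer affine
  tw1 <- list(list(W = matrix(1:5 / 10, 5, 1), b = -2))
  g <- matrix(c(1, 0, 2, 0, 1), 1)
  expect_equal(drop(kinetmoe:::tower_forward(tw1, g)$out),
               drop(g %*% tw1[[1]]$W) - 2)
  # outputs can be negative: no clamp at the head
  model0 <- cgc_init(tiny_config(6, seed = 5))
  X <- matrix(rnorm(200 * 6, sd = 3), 200)
  preds <- cgc_forward(model0, X)
  expect_true(any(preds < 0))
})

test_that("masked loss averages over observed labels only", {
  preds <- matrix(c(1, 1), 1)
  labels <- matrix(c(1, 99), 1)
  mask <- matrix(c(TRUE, FALSE), 1)
  expect_equal(masked_l2_loss(preds, labels, mask), 0)
  # errors (1, 2) over two observed labels -> (1 + 4) / 2
  expect_equal(masked_l2_loss(matrix(c(1, 2), 1), matrix(c(0, 0), 1),
                              matrix(c(TRUE, TRUE), 1)), 2.5)
  # masked placeholder is irrelevant
  l2 <- labels; l2[1, 2] <- -1e6
  expect_equal(masked_l2_loss(preds, l2, mask), 0)
  expect_error(masked_l2_loss(preds, labels, matrix(c(FALSE, FALSE), 1)),
               "no observed labels")
})

test_that("forward evaluates both heads and composes fuse and tower", {
  cfg <- tiny_config(8, seed = 3)
  model <- cgc_init(cfg)
  X <- matrix(rnorm(3 * 8), 3)
  preds <- cgc_forward(model, X)
  expect_equal(dim(preds), c(3L, 2L))
  expect_identical(colnames(preds), c("kcat", "km"))
  expect_identical(preds, cgc_forward(model, X))
  for (i in 1:3) {
    for (k in c("kcat", "km")) {
      g <- fuse(model, X[i, ], k)
      y <- kinetmoe:::tower_forward(model$params$towers[[k]],
                                    matrix(g, 1))$out
      expect_equal(unname(preds[i, k]), drop(y), tolerance = 1e-9)
    }
  }
  expect_error(cgc_forward(model, matrix(0, 2, 5)), "expects")
})

test_that("analytic gradients match finite differences", {
  s <- small_setup(n = 6, seed = 10, d_enz = 4, d_sub = 3, d_aux = 3)
  for (L in 1:2) {
    cfg <- cgc_config(input_dim = input_dim(s$spec), n_shared_experts = 2L,
                      n_specific_experts = 1L, expert_dim = 4L,
                      expert_dropout = 0, tower_dims = c(3L, 1L),
                      n_cgc_layers = L, seed = 3)
    model <- cgc_init(cfg, s$spec)
    loss_at <- function(v) {
      p <- unflat_params(v, model$params)
      m2 <- model; m2$params <- p
      X <- fused_of(s$fs, p$aux)
      fwd <- kinetmoe:::cgc_forward_X(m2, X, train = FALSE)
      masked_l2_loss(fwd$preds, s$fs$Y, s$fs$mask)
    }
    X <- fused_of(s$fs, model$params$aux)
    fwd <- kinetmoe:::cgc_forward_X(model, X, train = FALSE)
    dp <- kinetmoe:::masked_l2_grad(fwd$preds, s$fs$Y, s$fs$mask)
    bk <- kinetmoe:::cgc_backward(model, fwd, dp, fs = s$fs,
                                  rows = seq_len(s$fs$n), train = FALSE)
    v0 <- flat_params(model$params)
    g_ana <- flat_params(bk$grads)
    withr::local_seed(L)
    probe <- sample(length(v0), 60)  # spot-check a parameter subsample
    eps <- 1e-6
    for (i in probe) {
      vp <- v0; vp[i] <- vp[i] + eps
      vm <- v0; vm[i] <- vm[i] - eps
      g_num <- (loss_at(vp) - loss_at(vm)) / (2 * eps)
      expect_equal(g_ana[i], g_num, tolerance = 1e-5)
    }
  }
})

test_that("without shared experts the task losses decouple", {
  s <- small_setup(n = 8, seed = 12, d_enz = 4, d_sub = 3, d_aux = 3)
  cfg <- cgc_config(input_dim = input_dim(s$spec), n_shared_experts = 0L,
                    n_specific_experts = 2L, expert_dim = 4L,
                    expert_dropout = 0, tower_dims = c(3L, 1L), seed = 4)
  model <- cgc_init(cfg, s$spec)
  X <- fused_of(s$fs, model$params$aux)
  fwd <- kinetmoe:::cgc_forward_X(model, X, train = FALSE)
  # gradient of the kcat-only loss
  mask_kcat <- s$fs$mask
  mask_kcat[, "km"] <- FALSE
  dp <- kinetmoe:::masked_l2_grad(fwd$preds, s$fs$Y, mask_kcat)
  bk <- kinetmoe:::cgc_backward(model, fwd, dp, fs = s$fs,
                                rows = seq_len(s$fs$n), train = FALSE)
  km_grads <- c(flat_params(bk$grads$layers[[1]]$specific$km),
                flat_params(bk$grads$layers[[1]]$gates$km),
                flat_params(bk$grads$towers$km))
  expect_true(all(km_grads == 0))
  kcat_grads <- flat_params(bk$grads$layers[[1]]$specific$kcat)
  expect_gt(max(abs(kcat_grads)), 0)
})

test_that("training descends on a learnable signal, reproducibly", {
  gen <- gen_dataset(synth_spec(n_entries = 500, seed = 21, noise_sd = 0.3,
                                duplicate_rate = 0, mutant_fraction = 0))
  cur <- curate_pipeline(gen$records)
  sp <- stratified_split(cur$entries, seed = 21)
  spec <- feature_spec(sp$train, hash_embedder(16, salt = 1),
                       hash_embedder(8, salt = 2), aux_dim = 8)
  fs_tr <- featurize_entries(sp$train, spec)
  fs_va <- featurize_entries(sp$val, spec)
  cfg <- cgc_config(input_dim = input_dim(spec), n_shared_experts = 2L,
                    n_specific_experts = 2L, expert_dim = 16L,
                    tower_dims = c(16L, 1L), learning_rate = 3e-3,
                    batch_size = 32L, epochs = 8L, seed = 21)
  fit <- cgc_train(fs_tr, fs_va, cfg)
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
  # identical seeds give identical histories; a different seed differs
  fit2 <- cgc_train(fs_tr, fs_va, cfg)
  expect_identical(fit$history, fit2$history)
  cfg3 <- cfg; cfg3$seed <- 99L
  fit3 <- cgc_train(fs_tr, fs_va, cfg3)
  expect_false(isTRUE(all.equal(fit$history$train_loss,
                                fit3$history$train_loss)))
})

test_that("pure-noise labels give near-zero held-out R2", {
  withr::local_seed(55)
  s <- small_setup(n = 1000, seed = 55, d_enz = 8, d_sub = 4, d_aux = 4)
  entries <- s$entries
  entries$log10_kcat <- rnorm(1000)
  entries$log10_km <- rnorm(1000)
  sp <- stratified_split(entries, seed = 55)
  spec <- feature_spec(sp$train, hash_embedder(8, salt = 1),
                       hash_embedder(4, salt = 2), aux_dim = 4)
  fs_tr <- featurize_entries(sp$train, spec)
  fs_va <- featurize_entries(sp$val, spec)
  fs_te <- featurize_entries(sp$test, spec)
  cfg <- cgc_config(input_dim = input_dim(spec), n_shared_experts = 2L,
                    n_specific_experts = 2L, expert_dim = 8L,
                    tower_dims = c(8L, 1L), learning_rate = 3e-3,
                    batch_size = 32L, epochs = 6L, seed = 55)
  fit <- cgc_train(fs_tr, fs_va, cfg)
  preds <- predict_entries(fit, fs_te)
  for (k in c("kcat", "km")) {
    col <- paste0("log10_", k)
    obs <- !is.na(sp$test[[col]])
    expect_lt(abs(r2(sp$test[[col]][obs],
                     preds[[paste0("pred_log10_", k)]][obs])), 0.1)
  }
})

test_that("predictions expose both scales and the efficiency", {
  s <- small_setup(n = 20, seed = 14)
  cfg <- cgc_config(input_dim = input_dim(s$spec), n_shared_experts = 1L,
                    n_specific_experts = 1L, expert_dim = 6L,
                    tower_dims = c(4L, 1L), epochs = 2L, batch_size = 8L,
                    learning_rate = 1e-3, seed = 14)
  fit <- cgc_train(s$fs, s$fs, cfg)
  preds <- predict_entries(fit, s$entries)
  expect_equal(nrow(preds), 20)
  expect_equal(preds$canonical_smiles, s$entries$canonical_smiles)  # order
  expect_true(all(preds$pred_kcat > 0))
  expect_true(all(preds$pred_km > 0))
  expect_equal(preds$pred_log10_efficiency,
               preds$pred_log10_kcat - preds$pred_log10_km,
               tolerance = 1e-12)
})

test_that("stacked extraction layers train and predict", {
  s <- small_setup(n = 40, seed = 16)
  cfg <- cgc_config(input_dim = input_dim(s$spec), n_shared_experts = 1L,
                    n_specific_experts = 1L, expert_dim = 6L,
                    tower_dims = c(4L, 1L), n_cgc_layers = 2L,
                    epochs = 3L, batch_size = 8L, learning_rate = 1e-3,
                    seed = 16)
  fit <- cgc_train(s$fs, s$fs, cfg)
  expect_equal(nrow(fit$history), 3)
  preds <- predict_entries(fit, s$entries)
  expect_equal(nrow(preds), 40)
})
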