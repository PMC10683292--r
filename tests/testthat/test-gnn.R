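test_that("configuration invariants are enforced", {
  expect_error(gnn_config(M = 0), "M must be >= 1")
  expect_error(gnn_config(learning_rate = 0), "learning_rate")
  expect_error(gnn_config(weight_decay = -0.1), "weight_decay")
  cfg <- gnn_config()
  expect_equal(cfg$M, 6L)
  expect_equal(cfg$learning_rate, 1e-3)
  expect_equal(cfg$weight_decay, 0.01)
})

test_that("one graph-network block reproduces a hand-computed forward pass", {
  ones_mlp <- function(d_in) list(W1 = matrix(1, d_in, 1), b1 = 0,
                                  W2 = matrix(1, 1, 1), b2 = 0)
  bp <- list(edge = ones_mlp(4), node = ones_mlp(3), global = ones_mlp(3))
  state <- list(nodes = matrix(c(2, 3), 2, 1), edges = matrix(1, 2, 1),
                global = 0, senders = c(1L, 2L), receivers = c(2L, 1L))
  out <- gn_block(state, bp)
  # edge updates: relu(1+2+3+0) = 6 in both directions
  expect_equal(as.numeric(out$edges), c(6, 6))
  # node updates: relu(mean incoming 6 + v + 0) -> 8 and 9
  expect_equal(as.numeric(out$nodes), c(8, 9))
  # global update: relu(mean(6,6) + mean(8,9) + 0) = 14.5
  expect_equal(as.numeric(out$global), 14.5)
  # ReLU clamps a negative pre-activation
  state$nodes <- matrix(c(-5, -9), 2, 1)
  out2 <- gn_block(state, bp)
  expect_equal(as.numeric(out2$edges), c(0, 0))  # 1-5-9 and 1-9-5 < 0
})

test_that("all-zero parameters collapse every state to the bias vector", {
  zero_mlp <- function(d_in, h) list(W1 = matrix(0, d_in, h),
                                     b1 = rep(0, h),
                                     W2 = matrix(0, h, h), b2 = seq_len(h))
  h <- 3
  bp <- list(edge = zero_mlp(4 * h, h), node = zero_mlp(3 * h, h),
             global = zero_mlp(3 * h, h))
  state <- list(nodes = matrix(rnorm(6), 2, h),
                edges = matrix(rnorm(6), 2, h), global = rnorm(h),
                senders = c(1L, 2L), receivers = c(2L, 1L))
  out <- gn_block(state, bp)
  expect_equal(out$nodes, matrix(1:3, 2, h, byrow = TRUE))
  expect_equal(out$edges, matrix(1:3, 2, h, byrow = TRUE))
  expect_equal(as.numeric(out$global), 1:3)
})

test_that("compiled kernel agrees with the R reference implementation", {
  d <- tiny_synth(10, seed = 3)
  vocab <- build_element_vocabulary(d)
  cfg <- gnn_config(M = 3, hidden_width = 6)
  graphs <- lapply(d$records, molecule_to_graph, vocabulary = vocab)
  b <- nmrgraph:::.collate_graphs(graphs)
  b <- nmrgraph:::.standardize_batch(b, nmrgraph:::.feature_stats(b))
  tstd <- (b$targets - mean(b$targets[b$mask])) / sd(b$targets[b$mask])
  params <- withr::with_seed(7, nmrgraph:::.init_params(
    ncol(b$V), ncol(b$E), 6L, 3L, FALSE))
  fwR <- nmrgraph:::.gnn_forward(params, b, cfg)
  mlR <- nmrgraph:::.masked_loss(fwR$pred, tstd, b$mask, "mae")
  grR <- nmrgraph:::.gnn_backward(params, b, fwR, mlR$d_pred, cfg)
  cp <- nmrgraph:::.gnn_pass(params, b, cfg, tstd, b$mask, want_grad = TRUE)
  expect_equal(cp$pred, unname(fwR$pred), tolerance = 1e-12)
  expect_equal(cp$loss, mlR$loss, tolerance = 1e-12)
  flat <- function(x) if (is.list(x)) unlist(lapply(x, flat)) else as.numeric(x)
  expect_equal(flat(cp$grads), flat(grR), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("gradients match central finite differences", {
  d <- tiny_synth(5, seed = 4)
  vocab <- build_element_vocabulary(d)
  cfg <- gnn_config(M = 2, hidden_width = 4, loss_name = "mse")
  graphs <- lapply(d$records, molecule_to_graph, vocabulary = vocab)
  b <- nmrgraph:::.collate_graphs(graphs)
  b <- nmrgraph:::.standardize_batch(b, nmrgraph:::.feature_stats(b))
  tstd <- (b$targets - mean(b$targets[b$mask])) / sd(b$targets[b$mask])
  params <- withr::with_seed(11, nmrgraph:::.init_params(
    ncol(b$V), ncol(b$E), 4L, 2L, FALSE))
  got <- nmrgraph:::.gnn_pass(params, b, cfg, tstd, b$mask, want_grad = TRUE)
  loss_at <- function(p) nmrgraph:::.gnn_pass(p, b, cfg, tstd, b$mask,
                                              want_grad = TRUE)$loss
  eps <- 1e-6
  paths <- list(c("encV", "W1"), list("blocks", 1L, "edge", "W2"),
                list("blocks", 2L, "node", "W1"),
                list("blocks", 2L, "global", "b1"), c("readout", "W2"))
  rget <- function(x, p) { for (k in p) x <- x[[k]]; x }
  rset <- function(x, p, v) {
    if (length(p) == 1L) { x[[p[[1]]]] <- v; return(x) }
    x[[p[[1]]]] <- rset(x[[p[[1]]]], p[-1], v)
    x
  }
  set.seed(2)
  for (path in paths) {
    W <- rget(params, path)
    g <- rget(got$grads, path)
    for (i in sample(length(W), min(3, length(W)))) {
      Wp <- W; Wp[i] <- Wp[i] + eps
      Wm <- W; Wm[i] <- Wm[i] - eps
      num <- (loss_at(rset(params, path, Wp)) -
                loss_at(rset(params, path, Wm))) / (2 * eps)
      expect_equal(as.numeric(g[i]), num, tolerance = 1e-5)
    }
  }
})

test_that("training is reproducible and rejects degenerate inputs", {
  d <- tiny_synth(12, seed = 5)
  cfg <- fast_config(seed = 3)
  f1 <- nmr_gnn(d, cfg)
  f2 <- nmr_gnn(d, cfg)
  expect_identical(f1$log$train_loss, f2$log$train_loss)
  expect_equal(predict(f1, d), predict(f2, d))
  # unlabeled-only data is rejected
  bare <- d
  bare$records <- lapply(bare$records, function(r) {
    r$shifts <- data.frame(atom = integer(0), ppm = numeric(0))
    r
  })
  expect_error(nmr_gnn(bare, cfg), "no labeled atoms")
  # a diverging learning rate aborts with diagnostics
  expect_error(nmr_gnn(d, fast_config(seed = 3, learning_rate = 1e6,
                                      epochs = 30)),
               "diverged|non-finite")
})

test_that("unlabeled molecules in a batch change nothing but the messages", {
  d <- tiny_synth(6, seed = 8)
  vocab <- build_element_vocabulary(d)
  cfg <- gnn_config(M = 2, hidden_width = 4)
  graphs <- lapply(d$records, molecule_to_graph, vocabulary = vocab)
  unlabeled <- graphs[[6]]
  unlabeled$targets[] <- NA_real_
  unlabeled$target_mask[] <- FALSE
  b1 <- nmrgraph:::.collate_graphs(graphs[1:5])
  b2 <- nmrgraph:::.collate_graphs(c(graphs[1:5], list(unlabeled)))
  fs <- nmrgraph:::.feature_stats(b1)
  b1 <- nmrgraph:::.standardize_batch(b1, fs)
  b2 <- nmrgraph:::.standardize_batch(b2, fs)
  params <- withr::with_seed(3, nmrgraph:::.init_params(
    ncol(b1$V), ncol(b1$E), 4L, 2L, FALSE))
  t1 <- (b1$targets - 100) / 10
  t2 <- (b2$targets - 100) / 10
  l1 <- nmrgraph:::.gnn_pass(params, b1, cfg, t1, b1$mask, want_grad = TRUE)
  l2 <- nmrgraph:::.gnn_pass(params, b2, cfg, t2, b2$mask, want_grad = TRUE)
  expect_equal(l1$loss, l2$loss, tolerance = 1e-12)
  expect_equal(l1$pred, l2$pred[seq_along(l1$pred)], tolerance = 1e-12)
})

test_that("predictions are total, finite and permutation-equivariant", {
  d <- tiny_synth(20, seed = 13)
  fit <- nmr_gnn(d, fast_config(seed = 2, epochs = 10))
  pred <- predict(fit, d, atoms = "element")
  expect_true(all(is.finite(pred$predicted_shift_ppm)))
  expect_false(any(pred$missing_flag))
  # every carbon atom gets a prediction
  n_carbon <- sum(unlist(lapply(d$records,
                                function(r) sum(r$elements == "C"))))
  expect_equal(nrow(pred), n_carbon)
  # permuting atoms permutes predictions
  r <- d$records[[4]]
  perm <- withr::with_seed(5, sample(seq_along(r$elements)) - 1L)
  rp <- permute_record(r, perm)
  p0 <- predict(fit, r, atoms = "element")
  p1 <- predict(fit, rp, atoms = "element")
  m0 <- p0$predicted_shift_ppm[order(perm[p0$atom_index + 1L])]
  m1 <- p1$predicted_shift_ppm[order(p1$atom_index)]
  expect_equal(m1, m0, tolerance = 1e-5)
})

test_that("prediction on elements outside the vocabulary fails loudly", {
  d <- tiny_synth(8, seed = 21, elements = c(C = 0.7, O = 0.3))
  fit <- nmr_gnn(d, fast_config(seed = 1))
  withF <- shift_record("cf", c("C", "F", "H", "H", "H"),
                        bonds = data.frame(a = 0L, b = 1:4,
                                           order = "single"),
                        shifts = data.frame(atom = 0L, ppm = 80),
                        nucleus = "13C")
  expect_error(predict(fit, withF), "not in the model vocabulary")
})

test_that("encoding rejects shape mismatches and respects isomorphism", {
  d <- tiny_synth(8, seed = 16)
  fit <- nmr_gnn(d, fast_config(seed = 1))
  g <- molecule_to_graph(d$records[[1]], fit$vocabulary)
  enc <- gnn_encode(fit, g)
  expect_equal(ncol(enc$nodes), fit$config$hidden_width)
  expect_true(all(enc$global == 0))
  # isomorphic graphs encode to the same multiset of node vectors
  perm <- withr::with_seed(9, sample(seq_along(d$records[[1]]$elements)) - 1L)
  gp <- molecule_to_graph(permute_record(d$records[[1]], perm),
                          fit$vocabulary)
  encp <- gnn_encode(fit, gp)
  expect_equal(encp$nodes[perm + 1L, ], enc$nodes, tolerance = 1e-10)
  # wrong feature dimensionality is a shape error
  g_bad <- g
  g_bad$node_features <- g$node_features[, -1, drop = FALSE]
  expect_error(gnn_encode(fit, g_bad), "shape error")
})

test_that("a model overfits a single molecule to sub-ppm accuracy", {
  d <- shift_dataset(list(ethanol_record()), "13C")
  cfg <- gnn_config(hidden_width = 16, epochs = 1500, batch_size = 1,
                    val_fraction = 0, learning_rate = 2e-3, seed = 4)
  fit <- nmr_gnn(d, cfg)
  pred <- predict(fit, d)
  expect_lt(mean(abs(pred$predicted_shift_ppm - pred$true_shift_ppm)), 0.5)
})

test_that("checkpoints round-trip to identical predictions", {
  d <- tiny_synth(10, seed = 19)
  fit <- nmr_gnn(d, fast_config(seed = 6))
  path <- withr::local_tempfile(fileext = ".rds")
  save_gnn(fit, path)
  back <- load_gnn(path)
  expect_equal(predict(back, d), predict(fit, d))
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_gnn(other), "not an nmrgraph GNN checkpoint")
})
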