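# Message-passing graph network for per-atom shift regression.
#
# Architecture: encoder MLPs map edge and node features to a hidden
# width; M graph-network rounds then update, in order, edge states
# (from edge + sender + receiver + global), node states (from mean
# incoming edge state + node + global) and a per-molecule global state
# (from mean edge + mean node + global); a readout MLP maps final node
# states to one shift per atom.  Aggregations are arithmetic means, so
# the network is invariant to molecule size and equivariant to atom
# permutations.  Training minimises masked MAE on z-scored targets with
# decoupled weight decay (AdamW).  Gradients are exact reverse-mode
# derivatives of this computation, implemented alongside the forward
# pass; molecules are collated into block-diagonal batches so each
# round is a handful of BLAS calls.

#' Graph-network hyperparameter configuration
#'
#' @param M Message-passing rounds (default 6).
#' @param learning_rate Adam learning rate (default `1e-3`).
#' @param weight_decay Decoupled weight decay applied to weight matrices
#'   (default 0.01).
#' @param hidden_width Latent width of all node/edge/global states and
#'   MLP hidden layers (default 32, sized for desk-scale CPU training
#'   on datasets of hundreds to a few thousand molecules).
#' @param epochs Maximum training epochs (default 300; early stopping
#'   usually ends sooner).
#' @param batch_size Molecules per minibatch (default 32).
#' @param seed Integer seed controlling initialisation, the validation
#'   carve-out and batch shuffling.
#' @param loss_name `"mae"` (default) or `"mse"`, on standardized
#'   targets.
#' @param share_blocks Share one block's parameters across all M rounds
#'   (default `FALSE`: distinct parameters per round).
#' @param val_fraction Fraction of training molecules carved out for
#'   early stopping (default 0.1; never taken from the test set).
#' @param patience Epochs without validation improvement before
#'   stopping (default 25).
#' @param keep `"best"` (default) to restore the best-validation
#'   weights, `"final"` for the last epoch's.
#' @return Object of class `gnn_config`.
#' @export
gnn_config <- function(M = 6L, learning_rate = 1e-3, weight_decay = 0.01,
                       hidden_width = 32L, epochs = 300L, batch_size = 32L,
                       seed = 1L, loss_name = c("mae", "mse"),
                       share_blocks = FALSE, val_fraction = 0.1,
                       patience = 15L, keep = c("best", "final")) {
  loss_name <- match.arg(loss_name)
  keep <- match.arg(keep)
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("M must be >= 1", call. = FALSE)
  if (!is.finite(learning_rate) || learning_rate <= 0)
    stop("learning_rate must be > 0", call. = FALSE)
  if (!is.finite(weight_decay) || weight_decay < 0)
    stop("weight_decay must be >= 0", call. = FALSE)
  stopifnot(hidden_width >= 1L, epochs >= 1L, batch_size >= 1L,
            val_fraction >= 0, val_fraction <= 0.5, patience >= 1L)
  structure(list(M = M, learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 hidden_width = as.integer(hidden_width),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss_name = loss_name,
                 share_blocks = isTRUE(share_blocks),
                 val_fraction = val_fraction,
                 patience = as.integer(patience), keep = keep),
            class = "gnn_config")
}

#' @export
print.gnn_config <- function(x, ...) {
  cat(sprintf("<gnn_config: M=%d, lr=%g, weight_decay=%g, width=%d, epochs=%d, batch=%d, loss=%s, seed=%d%s>\n",
              x$M, x$learning_rate, x$weight_decay, x$hidden_width,
              x$epochs, x$batch_size, x$loss_name, x$seed,
              if (x$share_blocks) ", shared blocks" else ""))
  invisible(x)
}

# ---- batching ----------------------------------------------------------

.collate_graphs <- function(graphs) {
  nB <- length(graphs)
  nn <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  if (any(nn == 0L)) stop("empty graph (0 atoms) in batch", call. = FALSE)
  offset <- cumsum(c(0L, nn[-nB]))
  V <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  E <- do.call(rbind, lapply(graphs, function(g) g$edge_features))
  s <- unlist(lapply(seq_len(nB),
                     function(i) graphs[[i]]$senders + offset[i]))
  r <- unlist(lapply(seq_len(nB),
                     function(i) graphs[[i]]$receivers + offset[i]))
  me <- vapply(graphs, function(g) length(g$senders), integer(1))
  list(V = V, E = E,
       s = as.integer(s), r = as.integer(r),
       gn = rep(seq_len(nB), nn), ge = rep(seq_len(nB), me),
       B = nB, N = sum(nn), Mq = sum(me),
       targets = unlist(lapply(graphs, function(g) g$targets)),
       mask = unlist(lapply(graphs, function(g) g$target_mask)),
       elements = unlist(lapply(graphs, function(g) g$elements)),
       molecule_id = rep(vapply(graphs, function(g) g$molecule_id,
                                character(1)), nn),
       atom_index = unlist(lapply(nn, function(k) seq_len(k) - 1L)))
}

# z-score the scalar feature columns in place (one-hot blocks untouched)
.feature_stats <- function(batch) {
  dv <- ncol(batch$V)
  sc <- (dv - 3L):dv
  vm <- colMeans(batch$V[, sc, drop = FALSE])
  vs <- apply(batch$V[, sc, drop = FALSE], 2L, stats::sd)
  vs[!is.finite(vs) | vs == 0] <- 1
  if (nrow(batch$E) > 0L) {
    em <- mean(batch$E[, 1L]); es <- stats::sd(batch$E[, 1L])
    if (!is.finite(es) || es == 0) es <- 1
  } else { em <- 0; es <- 1 }
  list(node_cols = sc, node_mean = vm, node_sd = vs,
       edge_mean = em, edge_sd = es)
}

.standardize_batch <- function(batch, fs) {
  batch$V[, fs$node_cols] <-
    sweep(sweep(batch$V[, fs$node_cols, drop = FALSE], 2L, fs$node_mean),
          2L, fs$node_sd, "/")
  if (nrow(batch$E) > 0L)
    batch$E[, 1L] <- (batch$E[, 1L] - fs$edge_mean) / fs$edge_sd
  batch
}

# ---- parameters --------------------------------------------------------

.init_params <- function(dv, de, h, M, share) {
  n_blocks <- if (share) 1L else M
  list(encV = .mlp_init(dv, h, h),
       encE = .mlp_init(de, h, h),
       blocks = lapply(seq_len(n_blocks), function(i)
         list(edge = .mlp_init(4L * h, h, h),
              node = .mlp_init(3L * h, h, h),
              global = .mlp_init(3L * h, h, h))),
       readout = .mlp_init(h, 1L, h))
}

# ---- forward / backward ------------------------------------------------

.gn_round_forward <- function(pb, V, E, U, b) {
  h <- ncol(V)
  Xe <- cbind(E, V[b$s, , drop = FALSE], V[b$r, , drop = FALSE],
              U[b$ge, , drop = FALSE])
  ce <- .mlp_forward(pb$edge, Xe)
  Enew <- ce$out
  Ae <- .mean_scatter(Enew, b$r, b$N)
  Xv <- cbind(Ae, V, U[b$gn, , drop = FALSE])
  cv <- .mlp_forward(pb$node, Xv)
  Vnew <- cv$out
  AEg <- .mean_scatter(Enew, b$ge, b$B)
  AVg <- .mean_scatter(Vnew, b$gn, b$B)
  Xu <- cbind(AEg, AVg, U)
  cu <- .mlp_forward(pb$global, Xu)
  list(V = Vnew, E = Enew, U = cu$out,
       cache = list(ce = ce, cv = cv, cu = cu))
}

.gn_round_backward <- function(pb, cache, dV, dE, dU, b, h) {
  i1 <- seq_len(h); i2 <- h + i1; i3 <- 2L * h + i1; i4 <- 3L * h + i1
  bu <- .mlp_backward(pb$global, cache$cu, dU)
  dAEg <- bu$dX[, i1, drop = FALSE]
  dAVg <- bu$dX[, i2, drop = FALSE]
  dUprev <- bu$dX[, i3, drop = FALSE]
  dV <- dV + .mean_unscatter(dAVg, b$gn, b$B)
  bv <- .mlp_backward(pb$node, cache$cv, dV)
  dAe <- bv$dX[, i1, drop = FALSE]
  dVprev <- bv$dX[, i2, drop = FALSE]
  dUprev <- dUprev + .sum_scatter(bv$dX[, i3, drop = FALSE], b$gn, b$B)
  dE <- dE + .mean_unscatter(dAe, b$r, b$N) +
    .mean_unscatter(dAEg, b$ge, b$B)
  be <- .mlp_backward(pb$edge, cache$ce, dE)
  dEprev <- be$dX[, i1, drop = FALSE]
  dVprev <- dVprev + .sum_scatter(be$dX[, i2, drop = FALSE], b$s, b$N) +
    .sum_scatter(be$dX[, i3, drop = FALSE], b$r, b$N)
  dUprev <- dUprev + .sum_scatter(be$dX[, i4, drop = FALSE], b$ge, b$B)
  list(dV = dVprev, dE = dEprev, dU = dUprev,
       grads = list(edge = be$grad, node = bv$grad, global = bu$grad))
}

.gnn_forward <- function(params, b, cfg) {
  cV <- .mlp_forward(params$encV, b$V)
  cE <- .mlp_forward(params$encE, b$E)
  V <- cV$out; E <- cE$out
  U <- matrix(0, b$B, cfg$hidden_width)
  rounds <- vector("list", cfg$M)
  for (t in seq_len(cfg$M)) {
    pb <- params$blocks[[if (cfg$share_blocks) 1L else t]]
    st <- .gn_round_forward(pb, V, E, U, b)
    V <- st$V; E <- st$E; U <- st$U
    rounds[[t]] <- st$cache
  }
  cR <- .mlp_forward(params$readout, V)
  list(pred = drop(cR$out), cache = list(cV = cV, cE = cE, rounds = rounds,
                                         cR = cR))
}

.gnn_backward <- function(params, b, fw, d_pred, cfg) {
  h <- cfg$hidden_width
  bR <- .mlp_backward(params$readout, fw$cache$cR,
                      matrix(d_pred, ncol = 1L))
  dV <- bR$dX
  dE <- matrix(0, b$Mq, h)
  dU <- matrix(0, b$B, h)
  n_blocks <- if (cfg$share_blocks) 1L else cfg$M
  block_grads <- vector("list", n_blocks)
  for (t in rev(seq_len(cfg$M))) {
    bi <- if (cfg$share_blocks) 1L else t
    bk <- .gn_round_backward(params$blocks[[bi]], fw$cache$rounds[[t]],
                             dV, dE, dU, b, h)
    dV <- bk$dV; dE <- bk$dE; dU <- bk$dU
    block_grads[[bi]] <- if (is.null(block_grads[[bi]])) bk$grads
                         else .add_params(block_grads[[bi]], bk$grads)
  }
  bV <- .mlp_backward(params$encV, fw$cache$cV, dV)
  bE <- .mlp_backward(params$encE, fw$cache$cE, dE)
  list(encV = bV$grad, encE = bE$grad, blocks = block_grads,
       readout = bR$grad)
}

# Compiled fast path: one call = forward pass (+ exact gradients when
# training) for a collated batch.  The R functions above are the
# reference implementation the kernel is tested against.
.gnn_pass <- function(params, batch, cfg, targets_std = NULL, mask = NULL,
                      want_grad = FALSE) {
  .cpp_gnn_pass(params, batch, cfg$M, cfg$share_blocks, cfg$loss_name,
                want_grad,
                if (is.null(targets_std)) numeric(batch$N) else targets_std,
                if (is.null(mask)) logical(batch$N) else mask)
}

.masked_loss <- function(pred, targets_std, mask, loss_name) {
  idx <- which(mask)
  diff <- pred[idx] - targets_std[idx]
  d_pred <- numeric(length(pred))
  if (loss_name == "mae") {
    loss <- mean(abs(diff))
    d_pred[idx] <- sign(diff) / length(idx)
  } else {
    loss <- mean(diff^2)
    d_pred[idx] <- 2 * diff / length(idx)
  }
  list(loss = loss, d_pred = d_pred, n = length(idx))
}

# ---- public operations -------------------------------------------------

#' Encode a molecular graph into latent states
#'
#' Applies the fitted model's encoder MLPs to a graph's node and edge
#' features, returning the initial latent state of message passing:
#' hidden-width node and edge vectors and a zero global state.
#'
#' @param model A fitted [nmr_gnn()] model.
#' @param graph A `mol_graph` built with the model's vocabulary.
#' @return List with `nodes` (n x width), `edges` (m x width), `global`
#'   (1 x width, zeros), `senders`, `receivers`.
#' @export
gnn_encode <- function(model, graph) {
  stopifnot(inherits(model, "nmr_gnn"), inherits(graph, "mol_graph"))
  if (nrow(graph$node_features) == 0L)
    stop("shape error: empty graph (0 atoms)", call. = FALSE)
  if (ncol(graph$node_features) != nrow(model$params$encV$W1))
    stop("shape error: node feature dimension ",
         ncol(graph$node_features), " does not match model input ",
         nrow(model$params$encV$W1), call. = FALSE)
  b <- .standardize_batch(.collate_graphs(list(graph)), model$feat_stats)
  list(nodes = .mlp_forward(model$params$encV, b$V)$out,
       edges = .mlp_forward(model$params$encE, b$E)$out,
       global = matrix(0, 1L, model$config$hidden_width),
       senders = b$s, receivers = b$r)
}

#' Apply one graph-network block
#'
#' One round of message passing on a single graph's latent state: edge
#' update from (edge, sender, receiver, global), node update from
#' (mean incoming edge, node, global), global update from
#' (mean edge, mean node, global), all with arithmetic-mean
#' aggregation.  Exposed for inspection and testing; training uses the
#' same computation internally.
#'
#' @param state List with `nodes`, `edges`, `global`, `senders`,
#'   `receivers` as returned by [gnn_encode()].
#' @param block_params List with MLP parameter sets `edge`, `node`,
#'   `global` (each `W1`, `b1`, `W2`, `b2`).
#' @return Updated state (same shape).
#' @export
gn_block <- function(state, block_params) {
  V <- as.matrix(state$nodes); E <- as.matrix(state$edges)
  U <- matrix(as.numeric(state$global), nrow = 1L)
  if (ncol(U) != ncol(V) || (nrow(E) > 0L && ncol(E) != ncol(V)))
    stop("shape error: inconsistent latent dimensions", call. = FALSE)
  b <- list(s = as.integer(state$senders), r = as.integer(state$receivers),
            gn = rep(1L, nrow(V)), ge = rep(1L, nrow(E)),
            N = nrow(V), B = 1L, Mq = nrow(E))
  st <- .gn_round_forward(block_params, V, E, U, b)
  if (.any_nonfinite(list(st$V, st$E, st$U)))
    stop("training instability: non-finite state in graph-network block",
         call. = FALSE)
  list(nodes = st$V, edges = st$E, global = st$U,
       senders = state$senders, receivers = state$receivers)
}

# ---- training ----------------------------------------------------------

#' Fit the message-passing graph network
#'
#' Trains the shift-prediction network on a dataset: builds the element
#' vocabulary, featurizes every molecule, z-scores scalar features and
#' targets with training statistics, carves a validation fraction out
#' of the training molecules for early stopping, and optimises masked
#' MAE with AdamW.  Fully reproducible for a given config seed.
#'
#' @param data Training [shift_dataset()]; every molecule must be
#'   featurizable and at least one atom must carry a shift.
#' @param config A [gnn_config()].
#' @param verbose Print per-epoch progress.
#' @return Object of class `nmr_gnn` with elements `params`, `config`,
#'   `vocabulary`, `feat_stats`, `target_stats`, `nucleus`, `log`
#'   (per-epoch training loss and validation MAE), `best_epoch`.
#' @seealso [predict.nmr_gnn()], [save_gnn()]
#' @export
nmr_gnn <- function(data, config = gnn_config(), verbose = FALSE) {
  stopifnot(inherits(data, "shift_dataset"), inherits(config, "gnn_config"))
  if (length(data) == 0L) stop("empty training dataset", call. = FALSE)
  vocab <- build_element_vocabulary(data)
  graphs <- lapply(data$records, molecule_to_graph, vocabulary = vocab)
  if (!any(unlist(lapply(graphs, function(g) g$target_mask))))
    stop("no labeled atoms anywhere in the training data", call. = FALSE)
  full <- .collate_graphs(graphs)
  fs <- .feature_stats(full)
  t_mean <- mean(full$targets[full$mask])
  t_sd <- stats::sd(full$targets[full$mask])
  if (!is.finite(t_sd) || t_sd == 0) t_sd <- 1
  ts <- list(mean = t_mean, sd = t_sd)
  dv <- ncol(full$V); de <- ncol(full$E)
  h <- config$hidden_width

  model <- with_seed(config$seed, {
    n <- length(graphs)
    n_val <- floor(config$val_fraction * n)
    val_idx <- if (n_val >= 1L && n - n_val >= 2L) sample.int(n, n_val)
               else integer(0)
    train_idx <- setdiff(seq_len(n), val_idx)
    val_batch <- if (length(val_idx) > 0L) {
      .standardize_batch(.collate_graphs(graphs[val_idx]), fs)
    } else NULL
    params <- .init_params(dv, de, h, config$M, config$share_blocks)
    opt_state <- NULL
    step <- 0L
    best <- list(val = Inf, params = params, epoch = 0L)
    mark <- Inf
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_mae_ppm = numeric(0))
    stall <- 0L
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(train_idx)
      nb <- ceiling(length(idx) / config$batch_size)
      ep_loss <- 0; ep_n <- 0L
      for (k in seq_len(nb)) {
        sel <- idx[((k - 1L) * config$batch_size + 1L):
                   min(k * config$batch_size, length(idx))]
        bt <- .standardize_batch(.collate_graphs(graphs[sel]), fs)
        if (!any(bt$mask)) next
        ml <- .gnn_pass(params, bt, config,
                        targets_std = (bt$targets - ts$mean) / ts$sd,
                        mask = bt$mask, want_grad = TRUE)
        if (!is.finite(ml$loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (learning rate ", config$learning_rate, ")", call. = FALSE)
        step <- step + 1L
        upd <- .adamw_step(params, ml$grads, opt_state,
                           config$learning_rate, config$weight_decay, step)
        params <- upd$params
        opt_state <- upd$state
        ep_loss <- ep_loss + ml$loss * ml$n
        ep_n <- ep_n + ml$n
      }
      val_mae <- NA_real_
      if (!is.null(val_batch)) {
        pv <- .gnn_pass(params, val_batch, config)$pred
        err <- (pv * ts$sd + ts$mean) - val_batch$targets
        val_mae <- mean(abs(err[val_batch$mask]))
        if (val_mae < best$val)
          best <- list(val = val_mae, params = params, epoch = epoch)
        # patience only resets on a meaningful gain (0.001 ppm), so
        # training stops once validation MAE has effectively plateaued
        if (val_mae < mark - 1e-3) {
          mark <- val_mae
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = ep_loss / max(ep_n, 1L),
                                   val_mae_ppm = val_mae))
      if (verbose)
        cat(sprintf("epoch %3d  loss %.4f  val MAE %s ppm\n", epoch,
                    ep_loss / max(ep_n, 1L),
                    ifelse(is.na(val_mae), "-", sprintf("%.3f", val_mae))))
      if (!is.null(val_batch) && stall >= config$patience) break
    }
    final <- if (config$keep == "best" && !is.null(val_batch) &&
                 best$epoch > 0L) best$params else params
    list(params = final, log = log,
         best_epoch = if (!is.null(val_batch)) best$epoch else nrow(log),
         n_val = length(val_idx))
  })

  structure(list(params = model$params, config = config,
                 vocabulary = vocab, feat_stats = fs, target_stats = ts,
                 nucleus = data$nucleus, log = model$log,
                 best_epoch = model$best_epoch, n_val = model$n_val,
                 n_train = length(data)),
            class = "nmr_gnn")
}

#' Predict shifts with a fitted graph network
#'
#' The network always returns a finite shift for every queried atom (it
#' generalizes rather than abstains, unlike the HOSE lookup); outputs
#' are de-standardized to ppm.  Molecules containing an element outside
#' the training vocabulary are rejected with an explicit error.
#'
#' @param object A fitted [nmr_gnn()] model.
#' @param newdata A [shift_dataset()] or single [shift_record()].
#' @param atoms `"labeled"` (default) to return rows for atoms with
#'   assigned shifts, `"element"` for every atom of the nucleus's
#'   element.
#' @param ... Unused.
#' @return data.frame with the same columns as [predict.hose_model()]
#'   (`matched_spheres` is `NA`, `missing_flag` always `FALSE`,
#'   `method = "gnn"`).
#' @export
predict.nmr_gnn <- function(object, newdata,
                            atoms = c("labeled", "element"), ...) {
  atoms <- match.arg(atoms)
  if (inherits(newdata, "shift_record"))
    newdata <- shift_dataset(list(newdata), newdata$nucleus)
  stopifnot(inherits(newdata, "shift_dataset"))
  if (length(newdata) == 0L) stop("no molecules to predict", call. = FALSE)
  graphs <- lapply(newdata$records, molecule_to_graph,
                   vocabulary = object$vocabulary)
  b <- .standardize_batch(.collate_graphs(graphs), object$feat_stats)
  pred <- .gnn_pass(object$params, b, object$config)$pred
  if (any(!is.finite(pred)))
    stop("non-finite prediction; model numerically unstable", call. = FALSE)
  ppm <- pred * object$target_stats$sd + object$target_stats$mean
  el <- nucleus_element(object$nucleus)
  keep <- if (atoms == "labeled") b$mask else b$elements == el
  data.frame(molecule_id = b$molecule_id[keep],
             atom_index = b$atom_index[keep],
             true_shift_ppm = b$targets[keep],
             predicted_shift_ppm = ppm[keep],
             matched_spheres = NA_integer_, method = "gnn",
             missing_flag = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.nmr_gnn <- function(x, ...) {
  cat(sprintf("<nmr_gnn: %s, %d molecules, M=%d rounds, width %d, %d parameters, best epoch %d>\n",
              x$nucleus, x$n_train, x$config$M, x$config$hidden_width,
              .param_count(x$params), x$best_epoch))
  invisible(x)
}

#' @export
summary.nmr_gnn <- function(object, ...) {
  print(object)
  print(object$config)
  cat(sprintf("vocabulary: %s\n", paste(object$vocabulary, collapse = " ")))
  cat(sprintf("target standardization: mean %.3f ppm, sd %.3f ppm\n",
              object$target_stats$mean, object$target_stats$sd))
  lg <- object$log
  if (nrow(lg) > 0L) {
    cat(sprintf("trained %d epochs; final loss %.4f", nrow(lg),
                lg$train_loss[nrow(lg)]))
    if (any(!is.na(lg$val_mae_ppm)))
      cat(sprintf("; best val MAE %.3f ppm at epoch %d",
                  min(lg$val_mae_ppm, na.rm = TRUE), object$best_epoch))
    cat("\n")
  }
  invisible(object)
}

#' @export
coef.nmr_gnn <- function(object, ...) object$params

#' @export
plot.nmr_gnn <- function(x, ...) {
  lg <- x$log
  graphics::plot(lg$epoch, lg$train_loss, type = "l",
                 xlab = "epoch", ylab = "training loss (standardized)",
                 main = "Graph-network training", ...)
  if (any(!is.na(lg$val_mae_ppm))) {
    graphics::par(new = TRUE)
    graphics::plot(lg$epoch, lg$val_mae_ppm, type = "l", col = "red",
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4L, col.axis = "red")
    graphics::mtext("validation MAE (ppm)", side = 4L, line = 2,
                    col = "red", cex = 0.8)
    graphics::abline(v = x$best_epoch, lty = 3L, col = "red")
  }
  invisible(x)
}

# ---- checkpointing -----------------------------------------------------

#' Save / load a fitted graph network
#'
#' The checkpoint is a single self-describing archive holding weights,
#' configuration, element vocabulary, feature and target
#' standardization statistics and a format version.
#'
#' @param model A fitted [nmr_gnn()].
#' @param path Checkpoint file path.
#' @return `save_gnn` returns `path` invisibly; `load_gnn` returns the
#'   restored `nmr_gnn` model.
#' @export
save_gnn <- function(model, path) {
  stopifnot(inherits(model, "nmr_gnn"))
  obj <- unclass(model)
  obj$format <- "nmrgraph-gnn-1"
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_gnn
#' @export
load_gnn <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "nmrgraph-gnn-1"))
    stop("not an nmrgraph GNN checkpoint: ", path, call. = FALSE)
  obj$format <- NULL
  class(obj) <- "nmr_gnn"
  obj
}
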