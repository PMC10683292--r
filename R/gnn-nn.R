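# Dense-network primitives for the graph network: 2-layer MLPs with
# ReLU hidden activation and linear output, exact reverse-mode
# gradients, and a decoupled-weight-decay Adam optimiser.  Everything
# operates on plain matrices so the whole model stays in base R + BLAS.

.mlp_init <- function(d_in, d_out, hidden, rng_sd = NULL) {
  list(W1 = matrix(stats::rnorm(d_in * hidden, 0, sqrt(2 / d_in)),
                   d_in, hidden),
       b1 = numeric(hidden),
       W2 = matrix(stats::rnorm(hidden * d_out, 0, sqrt(1 / hidden)),
                   hidden, d_out),
       b2 = numeric(d_out))
}

# forward pass; returns output and the cache needed for backward
.mlp_forward <- function(p, X) {
  H1pre <- sweep(X %*% p$W1, 2L, p$b1, "+")
  H1 <- H1pre * (H1pre > 0)
  out <- sweep(H1 %*% p$W2, 2L, p$b2, "+")
  list(out = out, X = X, H1 = H1, mask = H1pre > 0)
}

# backward pass; returns gradient w.r.t. parameters and input
.mlp_backward <- function(p, cache, d_out) {
  dW2 <- crossprod(cache$H1, d_out)
  db2 <- colSums(d_out)
  dH1 <- tcrossprod(d_out, p$W2) * cache$mask
  dW1 <- crossprod(cache$X, dH1)
  db1 <- colSums(dH1)
  dX <- tcrossprod(dH1, p$W1)
  list(grad = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dX = dX)
}

# mean-scatter: group means of rows of X into an ng-row matrix
# (zero rows for empty groups)
.mean_scatter <- function(X, g, ng) {
  out <- matrix(0, ng, ncol(X))
  if (nrow(X) == 0L) return(out)
  rs <- rowsum(X, g)
  idx <- as.integer(rownames(rs))
  cnt <- tabulate(g, ng)
  out[idx, ] <- rs / cnt[idx]
  out
}

# sum-scatter: group sums of rows of X into an ng-row matrix
.sum_scatter <- function(X, g, ng) {
  out <- matrix(0, ng, ncol(X))
  if (nrow(X) == 0L) return(out)
  rs <- rowsum(X, g)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# gradient of .mean_scatter back onto items
.mean_unscatter <- function(d_agg, g, ng) {
  if (length(g) == 0L) return(matrix(0, 0L, ncol(d_agg)))
  cnt <- tabulate(g, ng)
  d_agg[g, , drop = FALSE] / cnt[g]
}

# elementwise recursion over nested parameter lists
.map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .map2_params(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like) else p * 0
}

.add_params <- function(a, b) .map2_params(a, b, `+`)

.param_count <- function(p) {
  if (is.list(p)) sum(vapply(p, .param_count, numeric(1))) else length(p)
}

.any_nonfinite <- function(p) {
  if (is.list(p)) any(vapply(p, .any_nonfinite, logical(1)))
  else any(!is.finite(p))
}

# One AdamW step over a nested parameter list.  Decoupled weight decay
# is applied to weight matrices only (leaves named W*), never biases.
.adamw_step <- function(params, grads, state, lr, wd, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v, decay) {
    if (is.list(p)) {
      nm <- names(p)
      for (i in seq_along(p)) {
        dec <- !is.null(nm) && grepl("^W", nm[i])
        res <- walk(p[[i]], g[[i]], m[[i]], v[[i]], dec)
        p[[i]] <- res$p; m[[i]] <- res$m; v[[i]] <- res$v
      }
      list(p = p, m = m, v = v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^step)
      vhat <- v / (1 - beta2^step)
      p <- p - lr * (mhat / (sqrt(vhat) + eps) + if (decay) wd * p else 0)
      list(p = p, m = m, v = v)
    }
  }
  if (is.null(state)) state <- list(m = .zeros_like(params),
                                    v = .zeros_like(params))
  res <- walk(params, grads, state$m, state$v, FALSE)
  list(params = res$p, state = list(m = res$m, v = res$v))
}
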