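# Graph attention network (GAT) node classifier, implemented directly with
# edge-indexed matrix ops and hand-derived gradients (gradient-checked in
# the test suite). Two layers: multi-head attention with concatenated heads
# + ELU, then a single-head attention output layer with bias and a softmax
# over the two classes. Self-loops are added so every node attends to
# itself. The per-edge attention arithmetic runs in the C++ kernels of
# src/core.cpp; the dense feature/weight products stay in R BLAS.

leaky_relu <- function(x, slope = 0.2) {
  pos <- x > 0
  x * pos + slope * x * (!pos)
}
leaky_relu_grad <- function(x, slope = 0.2) {
  pos <- x > 0
  pos + slope * (!pos)
}
elu <- function(x) {
  pos <- x > 0
  x * pos + expm1(pmin(x, 0)) * (!pos)
}
elu_grad <- function(x) {
  pos <- x > 0
  pos + exp(pmin(x, 0)) * (!pos)
}

# Edge arrays with self-loops (0-based copies feed the C++ kernels).
gat_edges <- function(instance) {
  ed <- directed_edges(instance$network)
  src <- c(ed$src, seq_len(ed$n))
  dst <- c(ed$dst, seq_len(ed$n))
  list(src = src, dst = dst, n = ed$n,
       src0 = src - 1L, dst0 = dst - 1L)
}

gat_init <- function(n_features, hidden = 16, heads = 4, n_classes = 2,
                     seed = 1) {
  glorot <- function(nr, nc) {
    matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
  }
  withr::with_seed(as.integer(seed), {
    params <- list(
      W1 = lapply(seq_len(heads), function(h) glorot(n_features, hidden)),
      a_src1 = lapply(seq_len(heads), function(h) glorot(hidden, 1)[, 1]),
      a_dst1 = lapply(seq_len(heads), function(h) glorot(hidden, 1)[, 1]),
      W2 = glorot(hidden * heads, n_classes),
      a_src2 = glorot(n_classes, 1)[, 1],
      a_dst2 = glorot(n_classes, 1)[, 1],
      b2 = rep(0, n_classes)
    )
  })
  params
}

# One attention head forward: feature projection in BLAS, edge-indexed
# attention (LeakyReLU logits, per-destination softmax, weighted
# aggregation) in C++.
att_forward <- function(X, W, a_src, a_dst, edges) {
  Zt <- t(X %*% W)
  res <- att_forward_cpp(Zt, a_src, a_dst, edges$src0, edges$dst0, edges$n)
  list(O = t(res$Ot), Zt = Zt, pre = res$pre, alpha = res$alpha)
}

# Backward through one attention head. dO: gradient at the head output.
att_backward <- function(dO, X, W, a_src, a_dst, edges, cache) {
  res <- att_backward_cpp(t(dO), cache$Zt, a_src, a_dst, edges$src0,
                          edges$dst0, cache$pre, cache$alpha, edges$n)
  dZ <- t(res$dZt)
  list(
    dW = crossprod(X, dZ),
    da_src = as.numeric(res$da_src),
    da_dst = as.numeric(res$da_dst),
    dX = dZ %*% t(W)
  )
}

gat_forward <- function(params, X, edges) {
  heads <- lapply(seq_along(params$W1), function(h) {
    att_forward(X, params$W1[[h]], params$a_src1[[h]], params$a_dst1[[h]],
                edges)
  })
  H <- do.call(cbind, lapply(heads, `[[`, "O"))
  A <- elu(H)
  out <- att_forward(A, params$W2, params$a_src2, params$a_dst2, edges)
  logits <- sweep(out$O, 2, params$b2, `+`)
  ex <- exp(logits - pmax(logits[, 1], logits[, 2]))
  P <- ex / rowSums(ex)
  list(P = P, logits = logits, heads = heads, H = H, A = A, out2 = out)
}

# Soft-label negative log likelihood of the PU objective: positives
# contribute with weight 1/|R| against one-hot labels, unlabeled genes with
# weight 1/|U| against their beliefs.
gat_loss_targets <- function(instance, beliefs) {
  is_pos <- instance$genes %in% instance$positives
  targets <- beliefs
  targets[is_pos, ] <- matrix(c(1, 0), nrow = sum(is_pos), ncol = 2,
                              byrow = TRUE)
  w <- ifelse(is_pos, 1 / sum(is_pos), 1 / sum(!is_pos))
  list(targets = targets, weights = w)
}

soft_nll <- function(targets, P, weights) {
  sum(weights * rowSums(-targets * log(pmax(P, 1e-300))))
}

gat_grad <- function(params, X, edges, fwd, targets, weights) {
  dlogits <- weights * (fwd$P - targets)
  bwd2 <- att_backward(dlogits, fwd$A, params$W2, params$a_src2,
                       params$a_dst2, edges, fwd$out2)
  dH <- (bwd2$dX) * elu_grad(fwd$H)
  hidden <- ncol(params$W1[[1]])
  grads <- list(
    W1 = vector("list", length(params$W1)),
    a_src1 = vector("list", length(params$W1)),
    a_dst1 = vector("list", length(params$W1)),
    W2 = bwd2$dW, a_src2 = bwd2$da_src, a_dst2 = bwd2$da_dst,
    b2 = colSums(dlogits)
  )
  for (h in seq_along(params$W1)) {
    cols <- (h - 1) * hidden + seq_len(hidden)
    bwd1 <- att_backward(dH[, cols, drop = FALSE], X, params$W1[[h]],
                         params$a_src1[[h]], params$a_dst1[[h]], edges,
                         fwd$heads[[h]])
    grads$W1[[h]] <- bwd1$dW
    grads$a_src1[[h]] <- bwd1$da_src
    grads$a_dst1[[h]] <- bwd1$da_dst
  }
  grads
}

# Full-batch Adam on the flattened parameter list.
gat_fit <- function(instance, beliefs, params, epochs = 60, lr = 0.01,
                    edges = NULL) {
  X <- instance$features
  if (is.null(X)) abort("instance has no feature matrix; see default_features()")
  edges <- edges %||% gat_edges(instance)
  lt <- gat_loss_targets(instance, beliefs)
  template <- params
  flat <- unlist(params, use.names = FALSE)
  m <- v <- numeric(length(flat))
  b1 <- 0.9; b2m <- 0.999; eps <- 1e-8
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    fwd <- gat_forward(params, X, edges)
    loss <- soft_nll(lt$targets, fwd$P, lt$weights)
    if (!is.finite(loss)) {
      abort(sprintf("non-finite classifier loss at epoch %d", ep))
    }
    grads <- gat_grad(params, X, edges, fwd, lt$targets, lt$weights)
    g <- unlist(grads, use.names = FALSE)
    m <- b1 * m + (1 - b1) * g
    v <- b2m * v + (1 - b2m) * g^2
    flat <- flat - lr * (m / (1 - b1^ep)) / (sqrt(v / (1 - b2m^ep)) + eps)
    params <- utils::relist(flat, template)
  }
  fwd <- gat_forward(params, X, edges)
  list(params = params, prob = fwd$P, loss = loss)
}
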