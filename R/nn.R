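# Minimal fully-connected network with tanh hidden units, trained by Adam.
# Supports squared-error and per-output binary cross-entropy (with logits)
# losses. Kept deliberately small: inputs here are pooled voxel descriptors or
# invariant graph descriptors, both a few hundred dimensions at most.

nn_new <- function(sizes, seed = 1L) {
  set.seed(seed)
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    sd <- sqrt(2 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd),
                     nrow = sizes[l], ncol = sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(sizes = sizes, W = W, b = b), class = "dense_net")
}

# forward pass; returns activations of every layer (a[[1]] is the input,
# a[[L+1]] the linear output layer, pre-sigmoid)
nn_forward <- function(net, X) {
  X <- matrix(X, ncol = net$sizes[1])
  L <- length(net$W)
  a <- vector("list", L + 1)
  a[[1]] <- X
  for (l in seq_len(L)) {
    z <- sweep(a[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    a[[l + 1]] <- if (l < L) tanh(z) else z
  }
  a
}

nn_predict <- function(net, X) {
  a <- nn_forward(net, X)
  a[[length(a)]]
}

# penultimate-layer activations (the learned embedding)
nn_embed <- function(net, X) {
  a <- nn_forward(net, X)
  a[[length(a) - 1]]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# gradient of mean loss wrt all parameters. loss: "mse" or "bce" (logits).
# sample_weight: optional per-row weights.
nn_grad <- function(net, X, Y, loss = c("mse", "bce"), sample_weight = NULL) {
  loss <- match.arg(loss)
  a <- nn_forward(net, X)
  L <- length(net$W)
  n <- nrow(a[[1]])
  out <- a[[L + 1]]
  Y <- matrix(Y, nrow = n)
  if (loss == "mse") {
    delta <- (out - Y) / n
    lv <- mean((out - Y)^2)
  } else {
    p <- sigmoid(out)
    delta <- (p - Y) / n
    eps <- 1e-12
    lv <- -mean(Y * log(p + eps) + (1 - Y) * log(1 - p + eps))
  }
  if (!is.null(sample_weight)) {
    sw <- sample_weight / mean(sample_weight)
    delta <- delta * sw
  }
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * (1 - a[[l]]^2)
    }
  }
  list(gW = gW, gb = gb, loss = lv)
}

adam_new <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0), vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0), vb = lapply(net$b, function(b) b * 0),
       t = 0L)
}

adam_step <- function(net, opt, grad, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * grad$gW[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * grad$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (opt$mW[[l]] / c1) / (sqrt(opt$vW[[l]] / c2) + eps)
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * grad$gb[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * grad$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (opt$mb[[l]] / c1) / (sqrt(opt$vb[[l]] / c2) + eps)
  }
  list(net = net, opt = opt)
}

# full-batch / minibatch training loop; returns net and per-epoch loss trace
nn_train <- function(net, X, Y, loss = "bce", epochs = 200, lr = 1e-3,
                     batch_size = NULL, seed = 1L) {
  set.seed(seed)
  X <- matrix(X, ncol = net$sizes[1])
  Y <- matrix(Y, nrow = nrow(X))
  n <- nrow(X)
  if (is.null(batch_size) || batch_size >= n) batch_size <- n
  opt <- adam_new(net)
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- if (batch_size < n) sample.int(n) else seq_len(n)
    tot <- 0; nb <- 0
    for (s in seq(1, n, by = batch_size)) {
      rows <- ord[s:min(s + batch_size - 1, n)]
      g <- nn_grad(net, X[rows, , drop = FALSE], Y[rows, , drop = FALSE], loss)
      if (!is.finite(g$loss)) stop("training diverged: non-finite loss")
      st <- adam_step(net, opt, g, lr = lr)
      net <- st$net; opt <- st$opt
      tot <- tot + g$loss; nb <- nb + 1
    }
    trace[e] <- tot / nb
  }
  list(net = net, trace = trace)
}
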